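#' Fit a property-fingerprint schema on training data
#'
#' For each selected continuous descriptor the training min and range fix
#' `bits` boundaries
#' \deqn{bound_i = val_{min} + i \cdot val_{range}/bits, \quad i = 0..bits-1,}
#' giving `bits + 1` bins; with `bits = 1` the training median is stored
#' instead.  Structural keys occupy one prefix bit each.  Boundaries and
#' medians are computed ONLY from training data and reused unchanged when
#' encoding any later compound (training or test).  A constant descriptor
#' (zero range) is flagged degenerate: every boundary equals the minimum,
#' so any larger value saturates the field.
#'
#' @param train_table `bbb_descriptor_table` of the training compounds.
#' @param selection `bbb_feature_selection` (descriptor order = descending
#'   MI-DSE; structural keys in selection order).
#' @param bits bits per descriptor field: 1, 4 or 8.
#' @return object of class `bbb_fingerprint_schema`: `structural_keys`,
#'   `encodings` (per-descriptor parameter list), `bits`, `total_length`.
#' @export
fit_schema <- function(train_table, selection, bits = 8) {
  stopifnot(inherits(train_table, "bbb_descriptor_table"),
            inherits(selection, "bbb_feature_selection"))
  assert_that(bits %in% c(1, 4, 8), "bits must be 1, 4 or 8")
  descs <- vapply(selection$continuous, `[[`, "", "descriptor_name")
  keys <- selection$structural_keys$descriptor
  missing <- setdiff(c(descs, keys), train_table$descriptor_names)
  assert_that(length(missing) == 0,
              paste0("selected descriptor(s) absent from training table: ",
                     paste(utils::head(missing, 5), collapse = ", ")))
  encodings <- lapply(descs, function(d) {
    v <- train_table$values[, d]
    v <- v[!is.na(v)]
    assert_that(length(v) > 0,
                paste0("descriptor ", d, " has no training values"))
    vmin <- min(v); vrange <- max(v) - vmin
    enc <- list(descriptor_name = d, bits = as.integer(bits),
                val_min = vmin, val_range = vrange,
                degenerate = vrange == 0)
    if (bits == 1) {
      enc$median <- stats::median(v)  # even count: mean of central pair
    } else {
      enc$boundaries <- vmin + (0:(bits - 1)) * vrange / bits
    }
    enc
  })
  names(encodings) <- descs
  structure(list(structural_keys = keys,
                 encodings = encodings,
                 bits = as.integer(bits),
                 total_length = length(keys) + length(descs) * as.integer(bits)),
            class = "bbb_fingerprint_schema")
}

#' @export
print.bbb_fingerprint_schema <- function(x, ...) {
  cat(sprintf("Fingerprint schema: %d structural key(s) + %d descriptor(s) x %d bit(s) = %d bits\n",
              length(x$structural_keys), length(x$encodings), x$bits,
              x$total_length))
  invisible(x)
}

#' Bin index of a descriptor value
#'
#' A value <= the first boundary lands in bin 0; a value above the last
#' boundary lands in bin `bits` (the fifth / ninth bin, counting the top
#' bin 1-indexed); otherwise bin i+1 where
#' `boundaries[i] < value <= boundaries[i+1]` (0-indexed boundaries).
#' Equivalently, the bin index equals the number of boundaries strictly
#' below the value.  The index doubles as the thermometer popcount j.
#'
#' @param value numeric (NA allowed: returns NA, the caller encodes an
#'   all-zero field and flags the compound).
#' @param enc a single-descriptor encoding from a fitted schema
#'   (bits 4 or 8).
#' @return integer in `[0, bits]`, or NA for a missing value.
#' @export
assign_bin <- function(value, enc) {
  assert_that(enc$bits %in% c(4L, 8L), "assign_bin needs a 4- or 8-bit encoding")
  if (is.na(value)) return(NA_integer_)
  sum(enc$boundaries < value)
}

# thermometer field of width `bits` with the first j bits set
thermometer_field <- function(j, bits) {
  as.integer(seq_len(bits) <= j)
}

#' Encode one compound into a property fingerprint
#'
#' Layout: one prefix bit per structural key (1 = substructure present,
#' i.e. the key descriptor's value is non-missing; 0 = absent), followed by
#' one thermometer field per continuous descriptor in schema order, with
#' popcount j = [assign_bin()] (4/8 bits) or j = 1 iff value >= training
#' median (1 bit).  A missing continuous value yields an all-zero field and
#' is flagged.
#'
#' @param compound_descriptors named numeric vector of descriptor values
#'   (NA = missing); must cover the schema's keys and descriptors.
#' @param schema fitted `bbb_fingerprint_schema`.
#' @param compound_id carried into the result.
#' @return object of class `bbb_fingerprint`: integer 0/1 vector `bits`,
#'   `compound_id`, and `missing_descriptors` (flagged continuous
#'   descriptors whose value was absent).
#' @export
encode <- function(compound_descriptors, schema, compound_id = NA_character_) {
  stopifnot(inherits(schema, "bbb_fingerprint_schema"))
  vals <- compound_descriptors
  need <- c(schema$structural_keys, names(schema$encodings))
  absent <- setdiff(need, names(vals))
  # descriptors entirely absent from the input behave like missing values
  if (length(absent)) vals[absent] <- NA_real_
  prefix <- as.integer(!is.na(vals[schema$structural_keys]))
  flagged <- character()
  fields <- lapply(schema$encodings, function(enc) {
    v <- vals[[enc$descriptor_name]]
    if (is.na(v)) {
      flagged <<- c(flagged, enc$descriptor_name)
      return(integer(enc$bits))
    }
    j <- if (enc$bits == 1L) as.integer(v >= enc$median) else assign_bin(v, enc)
    thermometer_field(j, enc$bits)
  })
  structure(list(bits = c(prefix, unlist(fields, use.names = FALSE)),
                 compound_id = compound_id,
                 missing_descriptors = flagged),
            class = "bbb_fingerprint")
}

#' @export
print.bbb_fingerprint <- function(x, ...) {
  cat(sprintf("Fingerprint %s: %d bits, popcount %d\n",
              x$compound_id %||% "<unnamed>", length(x$bits), sum(x$bits)))
  invisible(x)
}

#' Encode a whole descriptor table
#'
#' @param table `bbb_descriptor_table`.
#' @param schema fitted `bbb_fingerprint_schema`.
#' @return integer 0/1 matrix, one fingerprint per row, rownames =
#'   compound ids; attribute `missing_flags` maps compound id ->
#'   flagged descriptors.
#' @export
encode_table <- function(table, schema) {
  stopifnot(inherits(table, "bbb_descriptor_table"))
  fps <- lapply(seq_len(nrow(table$values)), function(i)
    encode(table$values[i, ], schema, compound_id = table$compound_ids[i]))
  M <- do.call(rbind, lapply(fps, `[[`, "bits"))
  rownames(M) <- table$compound_ids
  colnames(M) <- c(
    if (length(schema$structural_keys))
      paste0("key_", schema$structural_keys),
    unlist(lapply(schema$encodings, function(e)
      paste0(e$descriptor_name, "_b", seq_len(e$bits))), use.names = FALSE))
  flags <- lapply(fps, `[[`, "missing_descriptors")
  names(flags) <- table$compound_ids
  attr(M, "missing_flags") <- flags[vapply(flags, length, 0L) > 0]
  M
}

#' Serialize a fingerprint schema to JSON
#'
#' @param schema `bbb_fingerprint_schema`.
#' @param path output path.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "bbb_fingerprint_schema"))
  write_json_file(unclass(schema), path)
}

#' Load a fingerprint schema from JSON
#'
#' Round-trip identity: a schema written with [write_schema()] and read
#' back produces bit-identical fingerprints.
#'
#' @param path JSON file written by [write_schema()].
#' @return `bbb_fingerprint_schema`.
#' @export
read_schema <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  encodings <- lapply(raw$encodings, function(enc) {
    enc <- as.list(enc)
    enc$bits <- as.integer(enc$bits)
    if (!is.null(enc$boundaries)) enc$boundaries <- as.numeric(unlist(enc$boundaries))
    enc
  })
  names(encodings) <- vapply(encodings, `[[`, "", "descriptor_name")
  structure(list(structural_keys = as.character(raw$structural_keys %||% character()),
                 encodings = encodings,
                 bits = as.integer(raw$bits),
                 total_length = as.integer(raw$total_length)),
            class = "bbb_fingerprint_schema")
}

#' Morgan circular fingerprint (adapter)
#'
#' Baseline bit fingerprint computed by the structure toolkit; hashing
#' internals are delegated.
#'
#' @param smiles character vector of SMILES.
#' @param radius neighbourhood radius (default 2).
#' @param n_bits fingerprint length (default 2048).
#' @return integer 0/1 matrix, one row per molecule.
#' @export
morgan_fingerprints <- function(smiles, radius = 2, n_bits = 2048) {
  assert_that(length(smiles) > 0, "no SMILES supplied")
  res <- chem_worker("morgan", list(smiles = as.list(smiles),
                                    radius = radius, n_bits = n_bits))
  bad <- vapply(res$bits, is.null, TRUE) | is.na(res$bits)
  if (any(bad))
    abort_input("invalid structure string(s) at position(s): ",
                paste(utils::head(which(bad), 5), collapse = ", "))
  M <- do.call(rbind, lapply(res$bits, function(b)
    as.integer(strsplit(b, "")[[1]])))
  rownames(M) <- names(smiles)
  M
}
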