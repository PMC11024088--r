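#' Build a compound set
#'
#' Compounds are held as a data.frame (class `bbb_compounds`) with columns
#' `id`, `smiles`, `logbb`, `label`, `mw`.  Each record needs at least one
#' of `logbb`/`label`; a missing label is derived from logBB with the
#' threshold logBB >= -1 => active (BBB-permeating).  When both are given,
#' an explicit label wins, with a consistency warning if it contradicts the
#' logBB-derived one.
#'
#' @param id character compound identifiers.
#' @param smiles SMILES structure strings.
#' @param logbb numeric log10 brain/blood ratio (NA allowed).
#' @param label binary class (0/1 or "active"/"inactive"; NA allowed).
#' @param mw molecular weight in daltons (NA allowed; filled by
#'   [standardize_dataset()] from the structure when absent).
#' @param logbb_threshold activity threshold on logBB (inclusive).
#' @return `bbb_compounds` data.frame.
#' @export
compound_records <- function(id, smiles, logbb = NULL, label = NULL,
                             mw = NULL, logbb_threshold = -1) {
  n <- length(id)
  assert_that(!is.null(logbb) || !is.null(label),
              "at least one of logbb/label must be supplied")
  logbb <- as.numeric(logbb %||% rep(NA_real_, n))
  mw <- as.numeric(mw %||% rep(NA_real_, n))
  lab_explicit <- if (is.null(label)) rep(NA, n) else as_bbb_label(label)
  lab_derived <- factor(ifelse(is.na(logbb), NA,
                               ifelse(logbb >= logbb_threshold,
                                      "active", "inactive")),
                        levels = c("inactive", "active"))
  has_any <- !is.na(lab_explicit) | !is.na(lab_derived)
  assert_that(all(has_any), "every record needs a label or a logbb value")
  conflict <- !is.na(lab_explicit) & !is.na(lab_derived) &
    lab_explicit != lab_derived
  if (any(conflict))
    warning(sum(conflict), " record(s) have an explicit label contradicting ",
            "the logBB-derived one; the explicit label is kept: ",
            paste(utils::head(id[conflict], 5), collapse = ", "))
  label_final <- ifelse(!is.na(lab_explicit), as.character(lab_explicit),
                        as.character(lab_derived))
  out <- data.frame(id = as.character(id), smiles = as.character(smiles),
                    logbb = logbb,
                    label = factor(label_final, levels = c("inactive", "active")),
                    mw = mw, stringsAsFactors = FALSE)
  class(out) <- c("bbb_compounds", "data.frame")
  out
}

#' Load compounds from delimited text
#'
#' Expected columns: `id`, `smiles`, and at least one of the logBB / label
#' columns.  Records with an unparseable (empty) structure string are kept
#' but flagged with a warning.
#'
#' @param path CSV file.
#' @param logbb_column,label_column column names to read the value and/or
#'   class from.
#' @param mw_column optional molecular-weight column.
#' @param logbb_threshold activity threshold on logBB.
#' @return `bbb_compounds` data.frame.
#' @export
load_compounds <- function(path, logbb_column = "logbb",
                           label_column = "label", mw_column = "mw",
                           logbb_threshold = -1) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  df <- as.data.frame(data.table::fread(path, na.strings = c("", "NA", "NaN")))
  assert_that(all(c("id", "smiles") %in% names(df)),
              "compound file needs 'id' and 'smiles' columns")
  has_logbb <- logbb_column %in% names(df)
  has_label <- label_column %in% names(df)
  if (!has_logbb && !has_label)
    abort_input("neither '", logbb_column, "' nor '", label_column,
                "' column present in ", path)
  bad <- !nzchar(trimws(as.character(df$smiles))) | is.na(df$smiles)
  if (any(bad))
    warning(sum(bad), " record(s) have an empty structure string: ",
            paste(utils::head(df$id[bad], 5), collapse = ", "))
  compound_records(df$id, df$smiles,
                   logbb = if (has_logbb) df[[logbb_column]],
                   label = if (has_label) df[[label_column]],
                   mw = if (mw_column %in% names(df)) df[[mw_column]],
                   logbb_threshold = logbb_threshold)
}

#' Write compounds to CSV
#'
#' Round-trips through [load_compounds()] preserving ids, labels and logBB
#' to full precision.
#'
#' @param compounds `bbb_compounds`.
#' @param path output CSV path.
#' @export
write_compounds <- function(compounds, path) {
  stopifnot(inherits(compounds, "bbb_compounds"))
  df <- as.data.frame(compounds)
  df$label <- as.character(df$label)
  # shortest round-trippable decimal so logbb/mw survive a reload exactly
  for (col in c("logbb", "mw"))
    df[[col]] <- ifelse(is.na(df[[col]]), NA,
                        sprintf("%.17g", df[[col]]))
  data.table::fwrite(df, path, na = "NA")
  invisible(path)
}

# structure properties via the RDKit adapter, in one batch; returns a
# data.frame with one row per input SMILES
compound_structure_props <- function(smiles) {
  res <- chem_worker("props", list(smiles = as.list(smiles)))
  rec <- res$records
  if (!is.data.frame(rec)) rec <- do.call(rbind, lapply(rec, as.data.frame))
  for (col in c("canonical_smiles", "mw", "n_fragments", "organic"))
    if (is.null(rec[[col]])) rec[[col]] <- NA
  rec$valid <- rec$valid %in% TRUE
  rec
}

#' Standardize a compound dataset
#'
#' Applies the curation rules used before modelling: removes multi-fragment
#' structures (salts/mixtures) and structures containing atoms outside the
#' organic subset, removes compounds heavier than `mw_max` daltons
#' (strictly greater), collapses duplicates by canonical SMILES, and
#' removes *all* copies of structures whose duplicates carry contradictory
#' labels.  Unparseable structures are removed and logged.  Molecular
#' weight and canonical SMILES come from the structure toolkit; a
#' pre-supplied `mw` column is used as a fallback when the toolkit is
#' unavailable.
#'
#' @param compounds `bbb_compounds`.
#' @param mw_max molecular-weight cutoff in daltons (default 1000).
#' @param use_toolkit call the structure toolkit for canonical SMILES / MW
#'   (default TRUE).  Without it, deduplication falls back to the raw
#'   SMILES string and records without `mw` pass the weight filter,
#'   both with a warning.
#' @return `bbb_compounds` of retained records, with attribute
#'   `removal_log`: data.frame (`id`, `reason`) listing every removal.
#' @export
standardize_dataset <- function(compounds, mw_max = 1000, use_toolkit = TRUE) {
  stopifnot(inherits(compounds, "bbb_compounds"))
  df <- as.data.frame(compounds)
  removal <- data.frame(id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  drop <- function(mask, reason) {
    if (any(mask))
      removal <<- rbind(removal, data.frame(id = df$id[mask], reason = reason,
                                            stringsAsFactors = FALSE))
    df <<- df[!mask, , drop = FALSE]
  }

  if (use_toolkit) {
    props <- compound_structure_props(df$smiles)
    valid <- props$valid %in% TRUE
    df$canonical <- ifelse(valid, as.character(props$canonical_smiles), NA)
    df$mw_calc <- ifelse(valid, as.numeric(props$mw), NA)
    df$n_fragments <- ifelse(valid, as.integer(props$n_fragments), NA)
    df$organic <- ifelse(valid, props$organic %in% TRUE, NA)
    drop(!valid, "unparseable structure")
    drop(df$n_fragments > 1L, "multi-fragment (salt/mixture)")
    drop(!df$organic, "non-organic-subset atoms")
    df$mw <- ifelse(is.na(df$mw_calc), df$mw, df$mw_calc)
  } else {
    warning("structure toolkit disabled: deduplicating on raw SMILES, ",
            "no salt/organic filtering, supplied mw only")
    df$canonical <- df$smiles
  }

  drop(!is.na(df$mw) & df$mw > mw_max, sprintf("MW > %g Da", mw_max))

  # contradictory duplicates: all copies go; consistent duplicates: keep first
  key <- df$canonical
  n_lab <- tapply(as.character(df$label), key,
                  function(x) length(unique(x[!is.na(x)])))
  contradictory <- names(n_lab)[n_lab > 1]
  drop(key %in% contradictory, "contradictory duplicate labels")
  drop(duplicated(df$canonical), "duplicate structure")

  if (!nrow(df)) warning("standardization removed every compound")
  out <- df[, c("id", "smiles", "logbb", "label", "mw"), drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bbb_compounds", "data.frame")
  attr(out, "removal_log") <- removal
  out
}

#' Descriptor table container
#'
#' Compounds-by-descriptors numeric matrix with a per-descriptor dimension
#' tag.  A missing value (`NA`) in a 2D structure-based descriptor means
#' the probed substructure is absent from the molecule; in a 3D descriptor
#' it means the computation failed.
#'
#' @param values numeric matrix, rows = compounds.
#' @param compound_ids row identifiers (defaults to rownames).
#' @param descriptor_names column names (defaults to colnames).
#' @param dimension_tag "2D" or "3D", recycled or per-descriptor.
#' @return object of class `bbb_descriptor_table`.
#' @export
descriptor_table <- function(values, compound_ids = rownames(values),
                             descriptor_names = colnames(values),
                             dimension_tag = "2D") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  assert_that(!is.null(compound_ids) && length(compound_ids) == nrow(values),
              "compound_ids must match row count")
  assert_that(!is.null(descriptor_names) &&
                length(descriptor_names) == ncol(values),
              "descriptor_names must match column count")
  assert_that(!anyDuplicated(descriptor_names), "descriptor names must be unique")
  tag <- rep_len(dimension_tag, ncol(values))
  assert_that(all(tag %in% c("2D", "3D")), "dimension_tag must be 2D or 3D")
  dimnames(values) <- list(as.character(compound_ids), descriptor_names)
  structure(list(values = values,
                 compound_ids = as.character(compound_ids),
                 descriptor_names = descriptor_names,
                 dimension_tag = stats::setNames(tag, descriptor_names)),
            class = "bbb_descriptor_table")
}

#' @export
print.bbb_descriptor_table <- function(x, ...) {
  cat(sprintf("Descriptor table: %d compounds x %d descriptors (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(names(table(x$dimension_tag)),
                    table(x$dimension_tag), sep = ":", collapse = ", ")))
  invisible(x)
}

#' @export
dim.bbb_descriptor_table <- function(x) dim(x$values)

#' Read a precomputed descriptor table
#'
#' First column = compound id, header = descriptor names; "NaN"/empty cells
#' are missing.
#'
#' @param path delimited text file.
#' @param dimension_tag tag(s) applied to the columns.
#' @return `bbb_descriptor_table`.
#' @export
read_descriptor_table <- function(path, dimension_tag = "2D") {
  assert_that(file.exists(path), paste0("file not found: ", path))
  df <- as.data.frame(data.table::fread(path, na.strings = c("", "NA", "NaN")))
  descriptor_table(as.matrix(df[, -1, drop = FALSE]),
                   compound_ids = as.character(df[[1]]),
                   dimension_tag = dimension_tag)
}

#' Write a descriptor table
#'
#' @param table `bbb_descriptor_table`.
#' @param path output CSV path; missing values written as "NaN".
#' @export
write_descriptor_table <- function(table, path) {
  stopifnot(inherits(table, "bbb_descriptor_table"))
  # shortest round-trippable decimals so a reload reproduces the matrix bit
  # for bit; missing values spelled NaN
  V <- table$values
  C <- matrix(sprintf("%.17g", V), nrow(V), dimnames = dimnames(V))
  C[is.na(V)] <- "NaN"
  df <- data.frame(id = table$compound_ids, C, check.names = FALSE)
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' Obtain a descriptor table for a compound set
#'
#' Adapter around an external descriptor source.  Either reads a
#' precomputed table (the paper's Mordred output is consumed this way) and
#' aligns it to the compound ids, or — for 2D only — computes the structure
#' toolkit's 2D descriptor set from the SMILES.  Compounds whose 3D
#' computation failed (all-missing 3D rows) are dropped and logged; 3D
#' computation itself (conformer generation) is out of scope.
#'
#' @param compounds `bbb_compounds`.
#' @param dimension "2D" or "3D".
#' @param precomputed optional path to a precomputed table.
#' @return `bbb_descriptor_table` with attribute `dropped` (compound ids
#'   removed because their 3D row could not be computed).
#' @export
descriptor_adapter <- function(compounds, dimension = c("2D", "3D"),
                               precomputed = NULL) {
  stopifnot(inherits(compounds, "bbb_compounds"))
  dimension <- match.arg(dimension)
  if (!is.null(precomputed)) {
    tab <- read_descriptor_table(precomputed, dimension_tag = dimension)
    missing_ids <- setdiff(compounds$id, tab$compound_ids)
    assert_that(length(missing_ids) == 0,
                paste0("precomputed table lacks compounds: ",
                       paste(utils::head(missing_ids, 5), collapse = ", ")))
    tab <- descriptor_table(tab$values[compounds$id, , drop = FALSE],
                            dimension_tag = dimension)
  } else if (dimension == "2D") {
    res <- chem_worker("descriptors2d", list(smiles = as.list(compounds$smiles)))
    vals <- if (is.matrix(res$rows)) res$rows
    else do.call(rbind, lapply(res$rows, function(r)
      vapply(r, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)))
    storage.mode(vals) <- "double"
    colnames(vals) <- res$names
    rownames(vals) <- compounds$id
    tab <- descriptor_table(vals, dimension_tag = "2D")
  } else {
    abort_input("no descriptor calculator configured for 3D; ",
                "supply a precomputed table")
  }
  dropped <- character()
  if (dimension == "3D") {
    failed <- rowSums(!is.na(tab$values)) == 0
    if (any(failed)) {
      dropped <- tab$compound_ids[failed]
      warning(length(dropped), " compound(s) dropped: 3D computation failed")
      tab <- descriptor_table(tab$values[!failed, , drop = FALSE],
                              dimension_tag = tab$dimension_tag)
    }
  }
  attr(tab, "dropped") <- dropped
  tab
}

#' Combine 2D and 3D descriptor tables
#'
#' Inner-joins on compound id and concatenates the descriptor blocks,
#' keeping each block's dimension tags.
#'
#' @param table2d,table3d `bbb_descriptor_table`s.
#' @return combined `bbb_descriptor_table` (tag mix "2D"+"3D").
#' @export
combine_descriptor_tables <- function(table2d, table3d) {
  stopifnot(inherits(table2d, "bbb_descriptor_table"),
            inherits(table3d, "bbb_descriptor_table"))
  ids <- intersect(table2d$compound_ids, table3d$compound_ids)
  assert_that(length(ids) > 0, "no shared compounds between tables")
  assert_that(!any(table2d$descriptor_names %in% table3d$descriptor_names),
              "descriptor names overlap between tables")
  vals <- cbind(table2d$values[ids, , drop = FALSE],
                table3d$values[ids, , drop = FALSE])
  descriptor_table(vals, compound_ids = ids,
                   dimension_tag = c(unname(table2d$dimension_tag),
                                     unname(table3d$dimension_tag)))
}
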