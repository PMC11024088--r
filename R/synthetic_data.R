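#' Specification for a synthetic two-class descriptor table
#'
#' Describes a dataset with the statistical structure the pipeline assumes:
#' class-separated informative descriptors, pure-noise descriptors,
#' strongly correlated (redundant) descriptor pairs, and structural-key
#' descriptors whose missing-value (substructure-absence) rates differ
#' between classes.
#'
#' @param n_active,n_inactive class sizes.
#' @param n_informative descriptors whose class-conditional means differ by
#'   `separation` standard deviations.
#' @param n_noise descriptors independent of the class.
#' @param n_correlated_pairs pairs in which the first member is informative
#'   and the second is a redundant copy with population correlation ~0.95.
#' @param n_structural_keys descriptors carrying class-dependent
#'   missing-value patterns.
#' @param separation standardized mean difference between classes for the
#'   informative descriptors.
#' @param absence_rates length-2 (active, inactive) missing-value rates for
#'   the structural keys, or a matrix with one row per key.
#' @param bimodal_inactive draw the inactive class of informative
#'   descriptors from a two-component mixture (wider spread) instead of a
#'   single Gaussian.
#' @param seed RNG seed; fully determines the output.
#' @return object of class `bbb_synthetic_spec`.
#' @export
synthetic_spec <- function(n_active = 300, n_inactive = 100,
                           n_informative = 10, n_noise = 10,
                           n_correlated_pairs = 3, n_structural_keys = 4,
                           separation = 3,
                           absence_rates = c(0.1, 0.6),
                           bimodal_inactive = FALSE, seed = 1) {
  counts <- c(n_active, n_inactive, n_informative, n_noise,
              n_correlated_pairs, n_structural_keys)
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "counts must be non-negative integers")
  assert_that(n_active + n_inactive >= 2, "need at least two compounds")
  assert_that(separation >= 0, "separation must be >= 0")
  if (is.matrix(absence_rates)) {
    assert_that(nrow(absence_rates) == n_structural_keys &&
                  ncol(absence_rates) == 2,
                "absence_rates matrix must be n_structural_keys x 2")
  } else {
    assert_that(length(absence_rates) == 2, "absence_rates must be length 2")
    absence_rates <- matrix(rep(absence_rates, each = n_structural_keys),
                            ncol = 2)
  }
  assert_that(all(absence_rates >= 0 & absence_rates <= 1),
              "absence rates must lie in [0,1]")
  structure(list(n_active = as.integer(n_active),
                 n_inactive = as.integer(n_inactive),
                 n_informative = as.integer(n_informative),
                 n_noise = as.integer(n_noise),
                 n_correlated_pairs = as.integer(n_correlated_pairs),
                 n_structural_keys = as.integer(n_structural_keys),
                 separation = separation,
                 absence_rates = absence_rates,
                 bimodal_inactive = bimodal_inactive,
                 seed = as.integer(seed)),
            class = "bbb_synthetic_spec")
}

#' Imbalance presets mirroring the modelled dataset compositions
#'
#' "imbalanced" uses a ~3.6:1 active majority (1440/402 scaled to `n`),
#' "balanced" a 1:1 split.
#'
#' @param kind "imbalanced" or "balanced".
#' @param n total number of compounds.
#' @param ... forwarded to [synthetic_spec()].
#' @return `bbb_synthetic_spec`.
#' @export
synthetic_preset <- function(kind = c("imbalanced", "balanced"), n = 400, ...) {
  kind <- match.arg(kind)
  n_active <- if (kind == "imbalanced") round(n * 1440 / 1842) else round(n / 2)
  synthetic_spec(n_active = n_active, n_inactive = n - n_active, ...)
}

#' Generate a synthetic descriptor table
#'
#' Informative descriptors: active ~ N(separation, 1), inactive ~ N(0, 1)
#' (optionally a symmetric two-component mixture for the inactive class).
#' Noise descriptors: N(0, 1) for both classes.  Correlated pairs: an
#' informative first member plus a redundant second member
#' \eqn{B = 0.95 A + \sqrt{1-0.95^2}\,\epsilon}.  Structural keys: values
#' N(0, 1) masked to missing with the per-class absence rates.  Every
#' descriptor is tagged 2D except half of the informative block, tagged 3D
#' so mixed-dimension behaviour is exercised.
#'
#' @param spec `bbb_synthetic_spec`.
#' @return list with `table` (`bbb_descriptor_table`), `labels` (factor),
#'   and `manifest` (data.frame descriptor -> role).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "bbb_synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_active + spec$n_inactive
  act <- c(rep(TRUE, spec$n_active), rep(FALSE, spec$n_inactive))
  labels <- factor(ifelse(act, "active", "inactive"),
                   levels = c("inactive", "active"))

  draw_informative <- function() {
    v <- numeric(n)
    v[act] <- stats::rnorm(sum(act), mean = spec$separation)
    if (spec$bimodal_inactive) {
      comp <- stats::runif(sum(!act)) < 0.5
      v[!act] <- stats::rnorm(sum(!act), mean = ifelse(comp, -1.5, 1.5))
    } else {
      v[!act] <- stats::rnorm(sum(!act))
    }
    v
  }

  cols <- list(); roles <- character(); partners <- character()
  add <- function(name, values, role, partner = NA_character_) {
    cols[[name]] <<- values
    roles <<- c(roles, role)
    partners <<- c(partners, partner)
  }
  for (i in seq_len(spec$n_informative))
    add(sprintf("INF%02d", i), draw_informative(), "informative")
  for (i in seq_len(spec$n_noise))
    add(sprintf("NOISE%02d", i), stats::rnorm(n), "noise")
  rho <- 0.95
  for (i in seq_len(spec$n_correlated_pairs)) {
    a <- draw_informative()
    b <- rho * a + sqrt(1 - rho^2) * stats::rnorm(n)
    add(sprintf("CORA%02d", i), a, "informative_correlated")
    add(sprintf("CORB%02d", i), b, "redundant", sprintf("CORA%02d", i))
  }
  for (i in seq_len(spec$n_structural_keys)) {
    v <- stats::rnorm(n)
    p_absent <- ifelse(act, spec$absence_rates[i, 1], spec$absence_rates[i, 2])
    v[stats::runif(n) < p_absent] <- NA_real_
    add(sprintf("KEY%02d", i), v, "structural_key")
  }
  assert_that(length(cols) >= 1, "spec generates no descriptors")
  V <- do.call(cbind, cols)
  rownames(V) <- sprintf("cmp%04d", seq_len(n))

  # half the informative block is tagged 3D; keys must stay 2D
  tags <- rep("2D", ncol(V))
  inf_idx <- which(roles == "informative")
  tags[inf_idx[seq_len(floor(length(inf_idx) / 2))]] <- "3D"

  manifest <- data.frame(descriptor = colnames(V), role = roles,
                         partner = partners, dimension = tags,
                         stringsAsFactors = FALSE)
  list(table = descriptor_table(V, dimension_tag = tags),
       labels = labels, manifest = manifest)
}

#' Generate a seeded random bit matrix
#'
#' Exercises the 1-Tanimoto Kennard-Stone path.  Guaranteed to contain at
#' least two distinct rows (a bit is flipped deterministically if the draw
#' happens to be constant).
#'
#' @param n rows, `length` columns, `seed` RNG seed.
#' @param length number of bits per row.
#' @param seed RNG seed.
#' @param density probability of a set bit.
#' @return integer 0/1 matrix.
#' @export
generate_bit_dataset <- function(n, length, seed = 1, density = 0.3) {
  assert_that(n > 0 && length > 0, "n and length must be positive")
  set.seed(seed)
  M <- matrix(stats::rbinom(n * length, 1, density), nrow = n)
  if (n >= 2 && all(duplicated(M)[-1])) M[1, 1] <- 1L - M[1, 1]
  rownames(M) <- sprintf("bit%04d", seq_len(n))
  M
}

#' Write synthetic data to disk
#'
#' Descriptor CSV + labels CSV + manifest JSON, as produced by
#' [generate_synthetic()].
#'
#' @param synth list from [generate_synthetic()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_synthetic <- function(synth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  desc <- file.path(dir, "descriptors.csv")
  lab <- file.path(dir, "labels.csv")
  man <- file.path(dir, "manifest.json")
  write_descriptor_table(synth$table, desc)
  data.table::fwrite(data.frame(id = synth$table$compound_ids,
                                label = as.character(synth$labels)), lab)
  write_json_file(synth$manifest, man)
  invisible(c(descriptors = desc, labels = lab, manifest = man))
}
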