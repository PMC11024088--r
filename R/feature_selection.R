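#' Shannon entropy of a probability vector
#'
#' \eqn{H(p) = -\sum_k p_k \log_2 p_k} in bits; zero-probability bins
#' contribute 0.
#'
#' @param p numeric vector of non-negative probabilities summing to 1.
#' @param tol tolerance on the normalisation check.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(p, tol = 1e-9) {
  assert_that(all(p >= 0), "probabilities must be non-negative")
  assert_that(abs(sum(p) - 1) <= tol, "probability vector must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Class-wise histograms of a descriptor on a shared support
#'
#' Bins the two class samples into `n_bins` equidistant bins spanning the
#' combined (both-class) min-max range.  The combined histogram is the
#' per-bin arithmetic mean of the two normalised class histograms — not the
#' pooled histogram — which is what makes the downstream score invariant to
#' class imbalance.  Missing values are excluded before binning.  A
#' zero-width value range collapses to a single effective bin.
#'
#' @param values_active,values_inactive numeric vectors (NA allowed).
#' @param n_bins number of equidistant bins (>= 2).
#' @return object of class `bbb_class_histograms`: list with `bin_edges`,
#'   `p_active`, `p_inactive`, `p_combined`.
#' @export
bin_feature <- function(values_active, values_inactive, n_bins = 10) {
  assert_that(n_bins >= 2, "n_bins must be >= 2")
  a <- values_active[!is.na(values_active)]
  b <- values_inactive[!is.na(values_inactive)]
  assert_that(length(a) > 0 && length(b) > 0,
              "each class needs at least one non-missing value")
  lo <- min(a, b); hi <- max(a, b)
  if (lo == hi) {
    # degenerate range: everything lands in one bin
    return(structure(list(bin_edges = c(lo, hi),
                          p_active = 1, p_inactive = 1, p_combined = 1),
                     class = "bbb_class_histograms"))
  }
  # literal equidistant-edge formula; a value equal to an edge belongs to
  # the lower bin (the same convention the fingerprint boundaries use)
  edges <- lo + (0:n_bins) * (hi - lo) / n_bins
  hist_p <- function(x) {
    k <- findInterval(x, edges, rightmost.closed = TRUE, left.open = TRUE)
    k[k == 0L] <- 1L        # the minimum itself falls in the first bin
    k[k > n_bins] <- n_bins # guards the 1-ulp case where edges[n+1] < hi
    tabulate(k, nbins = n_bins) / length(x)
  }
  pa <- hist_p(a); pb <- hist_p(b)
  structure(list(bin_edges = edges, p_active = pa, p_inactive = pb,
                 p_combined = (pa + pb) / 2),
            class = "bbb_class_histograms")
}

#' MI-DSE score of one descriptor
#'
#' Mutual-information differential Shannon entropy:
#' \deqn{MIDSE(D) = H_{AB}(D) - \frac{H_A(D) + H_B(D)}{2}}
#' where \eqn{H_A}, \eqn{H_B} are the entropies of the binned class
#' distributions and \eqn{H_{AB}} the entropy of their per-bin mean.  With
#' base-2 logarithms the score lies in \[0,1\]: 0 for identical class
#' distributions, 1 for perfectly disjoint single-bin classes.  Because
#' each class distribution is normalised before mixing with weight 1/2,
#' the score does not depend on class sizes.
#'
#' @inheritParams bin_feature
#' @param descriptor_name label carried into the result.
#' @return object of class `bbb_feature_score`: list with `descriptor_name`,
#'   `midse`, `h_active`, `h_inactive`, `h_combined` and the `histograms`.
#' @export
midse <- function(values_active, values_inactive, n_bins = 10,
                  descriptor_name = NA_character_) {
  h <- bin_feature(values_active, values_inactive, n_bins)
  ha <- shannon_entropy(h$p_active)
  hb <- shannon_entropy(h$p_inactive)
  hab <- shannon_entropy(h$p_combined)
  score <- hab - (ha + hb) / 2
  # guard against tiny negative/overshoot from floating-point rounding
  score <- min(max(score, 0), 1)
  structure(list(descriptor_name = descriptor_name, midse = score,
                 h_active = ha, h_inactive = hb, h_combined = hab,
                 histograms = h),
            class = "bbb_feature_score")
}

#' @export
print.bbb_feature_score <- function(x, ...) {
  cat(sprintf("MI-DSE %s: %.4f (H_A=%.4f H_B=%.4f H_AB=%.4f, %d bins)\n",
              x$descriptor_name %||% "<unnamed>", x$midse, x$h_active,
              x$h_inactive, x$h_combined, length(x$histograms$p_combined)))
  invisible(x)
}

# MIN/MAX E-state style pairing: for names MAXxyz / MINxyz sharing a suffix,
# only the MAX member stays eligible.  SUM-type E-state descriptors encode
# substructure absence as 0, not NA, so they never enter (no NA to count).
drop_min_of_pairs <- function(names) {
  is_min <- grepl("^MIN", names)
  is_max <- grepl("^MAX", names)
  max_suffix <- sub("^MAX", "", names[is_max])
  keep <- !(is_min & sub("^MIN", "", names) %in% max_suffix)
  names[keep]
}

#' Structural-key selection from missing-value patterns
#'
#' For 2D structure-based descriptors a missing value means the probed
#' substructure is absent from the molecule.  A descriptor becomes a
#' structural key when the relative frequency of absence differs between
#' classes by at least `diff_cut`.  For MAX/MIN electrotopological-state
#' descriptor pairs of the same atom type only the MAX member is eligible
#' (both carry the identical absence pattern); sum-type E-state descriptors
#' report 0 instead of a missing value and therefore never qualify.
#'
#' @param table a `descriptor_table` tagged 2D (see [descriptor_table()]).
#' @param labels binary class labels, one per compound row.
#' @param diff_cut minimum between-class absence-frequency discrepancy.
#' @return data.frame with columns `descriptor`, `freq_active`,
#'   `freq_inactive`, `discrepancy`, ordered by decreasing discrepancy
#'   (ties broken by name).
#' @export
select_structural_keys <- function(table, labels, diff_cut = 0.2) {
  stopifnot(inherits(table, "bbb_descriptor_table"))
  lab <- as_bbb_label(labels)
  assert_that(length(lab) == nrow(table$values),
              "labels must match table rows")
  is2d <- table$dimension_tag == "2D"
  assert_that(any(is2d), "table has no 2D descriptors")
  cand <- drop_min_of_pairs(table$descriptor_names[is2d])
  V <- table$values[, cand, drop = FALSE]
  act <- lab == "active"
  fa <- colMeans(is.na(V[act, , drop = FALSE]))
  fi <- colMeans(is.na(V[!act, , drop = FALSE]))
  disc <- abs(fa - fi)
  keep <- which(disc >= diff_cut)
  out <- data.frame(descriptor = cand[keep],
                    freq_active = unname(fa[keep]),
                    freq_inactive = unname(fi[keep]),
                    discrepancy = unname(disc[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$discrepancy, out$descriptor), , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}

# Pearson correlation on pairwise-complete observations; NA when fewer than
# two complete pairs or a zero-variance margin.
pcc_complete <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  suppressWarnings(stats::cor(x[ok], y[ok]))
}

#' MI-DSE continuous-descriptor selection with redundancy pruning
#'
#' Scores every descriptor with [midse()], discards scores below
#' `min_score`, sorts the survivors by decreasing score (name-lexicographic
#' tie-break), then walks the ranking greedily, dropping any candidate whose
#' absolute Pearson correlation with an already-retained descriptor is
#' `>= pcc_cut` (computed on pairwise-complete observations), and finally
#' truncates to `max_n`.  Descriptors with fewer than `min_per_class`
#' non-missing values in either class are skipped with a warning.
#'
#' @param table a `descriptor_table`.
#' @param labels binary class labels, one per compound row.
#' @param n_bins histogram bins for the MI-DSE score.
#' @param max_n retained-descriptor cap.
#' @param min_score minimum MI-DSE score.
#' @param pcc_cut redundancy threshold on |PCC|.
#' @param diff_cut structural-key discrepancy threshold (2D tables only).
#' @param min_per_class minimum non-missing values per class to score.
#' @return object of class `bbb_feature_selection`: list with
#'   `continuous` (list of `bbb_feature_score`, descending score),
#'   `scores` (data.frame of all scored descriptors),
#'   `structural_keys` (data.frame, empty unless 2D descriptors present),
#'   `set_tag`, and the parameters used.
#' @export
select_features <- function(table, labels, n_bins = 10, max_n = 50,
                            min_score = 0.1, pcc_cut = 0.8, diff_cut = 0.2,
                            min_per_class = 5) {
  stopifnot(inherits(table, "bbb_descriptor_table"))
  lab <- as_bbb_label(labels)
  assert_that(length(lab) == nrow(table$values), "labels must match table rows")
  act <- lab == "active"
  assert_that(any(act) && any(!act), "both classes must be present")

  scores <- list()
  skipped <- character()
  for (d in table$descriptor_names) {
    va <- table$values[act, d]; vi <- table$values[!act, d]
    if (sum(!is.na(va)) < min_per_class || sum(!is.na(vi)) < min_per_class) {
      skipped <- c(skipped, d); next
    }
    scores[[d]] <- midse(va, vi, n_bins, descriptor_name = d)
  }
  if (length(skipped))
    warning(length(skipped), " descriptor(s) skipped (<", min_per_class,
            " non-missing values in a class): ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")

  score_tbl <- data.frame(
    descriptor = vapply(scores, `[[`, "", "descriptor_name"),
    midse = vapply(scores, `[[`, 0, "midse"),
    stringsAsFactors = FALSE, row.names = NULL)

  qualified <- score_tbl[score_tbl$midse >= min_score, , drop = FALSE]
  qualified <- qualified[order(-qualified$midse, qualified$descriptor), ,
                         drop = FALSE]
  retained <- character()
  for (d in qualified$descriptor) {
    redundant <- FALSE
    for (r in retained) {
      pcc <- pcc_complete(table$values[, d], table$values[, r])
      if (!is.na(pcc) && abs(pcc) >= pcc_cut) { redundant <- TRUE; break }
    }
    if (!redundant) retained <- c(retained, d)
    if (length(retained) >= max_n) break
  }
  if (!length(retained))
    warning("no descriptor passed the MI-DSE threshold; selection is empty")

  keys <- if (any(table$dimension_tag == "2D"))
    select_structural_keys(table, lab, diff_cut)
  else
    data.frame(descriptor = character(), freq_active = numeric(),
               freq_inactive = numeric(), discrepancy = numeric())

  structure(list(continuous = scores[retained],
                 scores = score_tbl[order(-score_tbl$midse,
                                          score_tbl$descriptor), ,
                                    drop = FALSE] |>
                   (\(d) {rownames(d) <- NULL; d})(),
                 structural_keys = keys,
                 set_tag = paste(sort(unique(table$dimension_tag)),
                                 collapse = "+"),
                 params = list(n_bins = n_bins, max_n = max_n,
                               min_score = min_score, pcc_cut = pcc_cut,
                               diff_cut = diff_cut)),
            class = "bbb_feature_selection")
}

#' @export
print.bbb_feature_selection <- function(x, ...) {
  cat(sprintf("Feature selection (%s): %d continuous descriptor(s), %d structural key(s)\n",
              x$set_tag, length(x$continuous), nrow(x$structural_keys)))
  if (length(x$continuous)) {
    top <- utils::head(x$continuous, 5)
    for (s in top)
      cat(sprintf("  %-20s MI-DSE %.4f\n", s$descriptor_name, s$midse))
    if (length(x$continuous) > 5) cat("  ...\n")
  }
  invisible(x)
}

#' Write a feature-selection report
#'
#' Emits a structured JSON report (scores, entropies, histograms,
#' structural-key frequencies) and a flat ranked CSV.
#'
#' @param selection a `bbb_feature_selection`.
#' @param json_path,csv_path output paths (either may be NULL to skip).
#' @return invisibly, the paths written.
#' @export
write_selection_report <- function(selection, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(selection, "bbb_feature_selection"))
  if (!is.null(json_path)) {
    rep <- list(
      set_tag = selection$set_tag,
      params = selection$params,
      continuous = lapply(unname(selection$continuous), function(s) list(
        descriptor = s$descriptor_name, midse = s$midse,
        h_active = s$h_active, h_inactive = s$h_inactive,
        h_combined = s$h_combined,
        bin_edges = s$histograms$bin_edges,
        p_active = s$histograms$p_active,
        p_inactive = s$histograms$p_inactive,
        p_combined = s$histograms$p_combined)),
      structural_keys = selection$structural_keys)
    write_json_file(rep, json_path)
  }
  if (!is.null(csv_path)) {
    ranked <- data.frame(
      rank = seq_along(selection$continuous),
      descriptor = vapply(selection$continuous, `[[`, "", "descriptor_name"),
      midse = vapply(selection$continuous, `[[`, 0, "midse"))
    data.table::fwrite(ranked, csv_path)
  }
  invisible(c(json = json_path, csv = csv_path))
}
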