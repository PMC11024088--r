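# Independent brute-force oracles, written literally from the defining
# formulas/algorithm statements.  They deliberately share no code with the
# implementation they check.

# MI-DSE = H_AB(D) - (H_A(D) + H_B(D)) / 2 on equidistant bins spanning the
# combined min-max range, combined histogram = per-bin mean of the two
# normalised class histograms, log base 2.
oracle_midse <- function(a, b, n_bins) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  lo <- min(c(a, b)); hi <- max(c(a, b))
  if (lo == hi) return(0)
  edges <- lo + (0:n_bins) * (hi - lo) / n_bins
  # bin of one value: 1 + number of interior/top edges strictly below it,
  # clamped to [1, n_bins]; a value equal to an edge takes the lower bin
  bin_of <- function(v) min(n_bins, max(1, 1 + sum(v > edges[-1])))
  pa <- tabulate(vapply(a, bin_of, 0), n_bins) / length(a)
  pb <- tabulate(vapply(b, bin_of, 0), n_bins) / length(b)
  pab <- (pa + pb) / 2
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  H(pab) - (H(pa) + H(pb)) / 2
}

# Literal transcription of the modified Kennard-Stone rule: seed with the
# maximal-distance pair, then repeatedly append the candidate whose
# distance to its nearest training sample is the maximum over candidates.
# Ties: lowest index.
oracle_kennard_stone <- function(D, train_size) {
  n <- nrow(D)
  best <- c(1, 2); best_d <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > best_d) { best_d <- D[i, j]; best <- c(i, j) }
  }
  train <- best
  while (length(train) < train_size) {
    cand <- setdiff(1:n, train)
    nearest <- vapply(cand, function(c) min(D[c, train]), 0)
    train <- c(train, cand[which.max(nearest)])
  }
  train
}

# Rank-comparison AUC: P(score_pos > score_neg) + 0.5 P(equal).
oracle_auc <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Direct formula evaluation of the metric suite on raw counts (NA where a
# denominator vanishes); vectorised over equal-length count vectors.
oracle_metric_formulas <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  div <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  acc <- div(tp + tn, n)
  prec <- div(tp, tp + fp)
  pe <- div((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn), n^2)
  list(
    sensitivity = sens,
    specificity = spec,
    accuracy = acc,
    balanced_accuracy = (sens + spec) / 2,
    precision = prec,
    f1 = ifelse(is.na(prec) | is.na(sens) | prec + sens == 0, NA_real_,
                2 * prec * sens / (prec + sens)),
    mcc = div(tp * tn - fp * fn,
              sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))),
    kappa = ifelse(pe == 1, NA_real_, (acc - pe) / (1 - pe)))
}

# harmonic mean of Eq. 7 with n arguments
oracle_harmonic_mean <- function(x) length(x) / sum(1 / x)
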