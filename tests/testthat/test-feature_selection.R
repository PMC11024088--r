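test_that("shannon_entropy matches direct evaluation and rejects bad input", {
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1.0)
  expect_equal(shannon_entropy(c(1.0, 0.0)), 0.0)
  expect_equal(shannon_entropy(c(0.25, 0.75)), 0.811278124459133, tolerance = 1e-12)
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
  expect_error(shannon_entropy(c(-0.1, 1.1)), "non-negative")
})

test_that("bin_feature builds per-class histograms on the combined range", {
  h <- bin_feature(c(0.1, 0.9), c(0.1, 0.9), 2)
  expect_equal(h$p_active, c(0.5, 0.5))
  expect_equal(h$p_inactive, c(0.5, 0.5))
  expect_equal(h$p_combined, c(0.5, 0.5))

  # disjoint single-bin classes of any size: combined is the mean, not pooled
  for (k in c(1, 3, 7)) {
    h2 <- bin_feature(rep(0.1, k), rep(0.9, 5), 2)
    expect_equal(h2$p_active, c(1, 0))
    expect_equal(h2$p_inactive, c(0, 1))
    expect_equal(h2$p_combined, c(0.5, 0.5))
  }

  # degenerate zero range collapses to one bin
  h3 <- bin_feature(rep(2, 4), rep(2, 6), 10)
  expect_equal(h3$p_active, 1)
  expect_equal(shannon_entropy(h3$p_combined), 0)

  expect_error(bin_feature(c(NA_real_, NA_real_), c(1, 2), 2), "non-missing")
})

test_that("midse reproduces the hand-derived example and the endpoints", {
  expect_equal(midse(c(1, 2, 3), c(1, 2, 3), 4)$midse, 0)
  s <- midse(c(rep(0.1, 4)), c(rep(0.9, 6)), 2)
  expect_equal(s$midse, 1)
  expect_equal(s$h_active, 0)
  expect_equal(s$h_combined, 1)

  s2 <- midse(c(0.1, 0.1, 0.9, 0.9), c(0.1, 0.9, 0.9, 0.9), 2)
  expect_equal(s2$h_active, 1.0)
  expect_equal(s2$h_inactive, 0.811278124459133, tolerance = 1e-9)
  expect_equal(s2$h_combined, shannon_entropy(c(0.375, 0.625)), tolerance = 1e-9)
  expect_equal(s2$midse,
               shannon_entropy(c(0.375, 0.625)) -
                 (1 + shannon_entropy(c(0.25, 0.75))) / 2,
               tolerance = 1e-12)
  expect_equal(s2$midse, 0.0488, tolerance = 2e-4)
  expect_equal(s2$midse, s2$h_combined - (s2$h_active + s2$h_inactive) / 2,
               tolerance = 1e-12)
})

test_that("midse equals the brute-force oracle on small random inputs", {
  set.seed(101)
  for (rep in 1:40) {
    na <- sample(2:20, 1); nb <- sample(2:20, 1)
    nb_bins <- sample(2:12, 1)
    a <- round(rnorm(na), 2)
    b <- round(rnorm(nb, sample(c(0, 1, 3), 1)), 2)
    expect_equal(midse(a, b, nb_bins)$midse,
                 oracle_midse(a, b, nb_bins), tolerance = 1e-9,
                 info = sprintf("rep %d", rep))
  }
})

test_that("midse is symmetric, bounded, and class-size invariant", {
  set.seed(7)
  for (rep in 1:25) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), mean = runif(1, 0, 4))
    s_ab <- midse(a, b, 10)$midse
    expect_equal(s_ab, midse(b, a, 10)$midse, tolerance = 1e-12)
    expect_gte(s_ab, 0); expect_lte(s_ab, 1)
    # replicating one class r times changes nothing
    for (r in c(2, 5, 10))
      expect_equal(midse(rep(a, r), b, 10)$midse, s_ab, tolerance = 1e-9)
  }
})

test_that("structural keys follow the absence-discrepancy rule", {
  mk <- function(fa, fi, n = 40) {
    v <- rnorm(2 * n)
    v[seq_len(n)][seq_len(round(fa * n))] <- NA
    v[n + seq_len(n)][seq_len(round(fi * n))] <- NA
    v
  }
  V <- cbind(BIG = mk(0.9, 0.2), SMALL = mk(0.55, 0.45),
             MAXtsC = mk(0.8, 0.1), MINtsC = mk(0.8, 0.1),
             PLAIN = rnorm(80))
  tab <- descriptor_table(V, compound_ids = sprintf("c%d", 1:80),
                          dimension_tag = "2D")
  labels <- rep(c("active", "inactive"), each = 40)
  keys <- select_structural_keys(tab, labels)
  expect_true("BIG" %in% keys$descriptor)        # 0.7 >= 0.2
  expect_false("SMALL" %in% keys$descriptor)     # 0.1 < 0.2
  expect_true("MAXtsC" %in% keys$descriptor)     # MAX member retained
  expect_false("MINtsC" %in% keys$descriptor)    # MIN of a MAX/MIN pair dropped
  expect_false("PLAIN" %in% keys$descriptor)     # no missing values at all
  expect_equal(keys$discrepancy,
               abs(keys$freq_active - keys$freq_inactive))
})

test_that("boundary: discrepancy exactly at diff_cut is retained", {
  v <- c(rep(NA, 4), rnorm(16), rnorm(20))  # active 0.2 absent, inactive 0
  tab <- descriptor_table(cbind(EDGE = v), compound_ids = sprintf("c%d", 1:40),
                          dimension_tag = "2D")
  keys <- select_structural_keys(tab, rep(c("active", "inactive"), each = 20))
  expect_true("EDGE" %in% keys$descriptor)
})

test_that("continuous selection: PCC pruning, threshold and cap", {
  tt <- tiny_table()
  sel <- suppressWarnings(  # KEYD is deliberately too sparse to score
    select_features(tt$table, tt$labels, n_bins = 5, min_per_class = 3))
  names_sel <- vapply(sel$continuous, `[[`, "", "descriptor_name")
  # COPY has PCC 1 with GOOD: only one survives, and ties broke on name
  expect_equal(sum(c("GOOD", "COPY") %in% names_sel), 1)
  # DULL scores ~0 and misses the 0.1 threshold
  expect_false("DULL" %in% names_sel)
  # KEYD is a structural key
  expect_true("KEYD" %in% sel$structural_keys$descriptor)

  # exhaustive pairwise |PCC| check on the retained set
  for (i in seq_along(names_sel)) for (j in seq_len(i - 1)) {
    v1 <- tt$table$values[, names_sel[i]]; v2 <- tt$table$values[, names_sel[j]]
    ok <- !is.na(v1) & !is.na(v2)
    expect_lt(abs(cor(v1[ok], v2[ok])), 0.8)
  }
})

test_that("PCC threshold is >= 0.8: a 0.79 pair keeps both members", {
  set.seed(11)
  n <- 400
  act <- rep(c(TRUE, FALSE), each = n / 2)
  base <- ifelse(act, rnorm(n, 3), rnorm(n))
  # construct a partner with sample correlation exactly 0.79
  rho <- 0.79
  resid <- stats::residuals(stats::lm(rnorm(n) ~ base))
  other <- rho * scale(base)[, 1] + sqrt(1 - rho^2) * scale(resid)[, 1]
  V <- cbind(A = base, B = other)
  expect_equal(abs(cor(V[, 1], V[, 2])), 0.79, tolerance = 1e-12)
  tab <- descriptor_table(V, compound_ids = sprintf("c%d", 1:n))
  sel <- select_features(tab, ifelse(act, "active", "inactive"), min_score = 0)
  expect_equal(length(sel$continuous), 2)
})

test_that("60 uncorrelated qualifying descriptors cap at the top 50 by score", {
  set.seed(5)
  n <- 200
  act <- rep(c(TRUE, FALSE), each = n / 2)
  # independent descriptors with graded separation -> graded MI-DSE
  seps <- seq(1.5, 6, length.out = 60)
  V <- sapply(seps, function(s) ifelse(act, rnorm(n, s), rnorm(n)))
  colnames(V) <- sprintf("D%02d", 1:60)
  tab <- descriptor_table(V, compound_ids = sprintf("c%d", 1:n))
  sel <- select_features(tab, ifelse(act, "active", "inactive"),
                         pcc_cut = 2)  # disable pruning: isolate the cap
  expect_equal(length(sel$continuous), 50)
  scores <- vapply(sel$continuous, `[[`, 0, "midse")
  expect_equal(scores, sort(scores, decreasing = TRUE))
  # the retained are the top-50 scoring of all 60
  all_scores <- sel$scores
  expect_setequal(vapply(sel$continuous, `[[`, "", "descriptor_name"),
                  all_scores$descriptor[1:50])
})

test_that("selection report writes JSON and ranked CSV", {
  tt <- tiny_table()
  sel <- suppressWarnings(  # KEYD is deliberately too sparse to score
    select_features(tt$table, tt$labels, min_per_class = 3))
  j <- tempfile(fileext = ".json"); cf <- tempfile(fileext = ".csv")
  write_selection_report(sel, j, cf)
  rep <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(nrow(rep$continuous), length(sel$continuous))
  expect_true(all(abs(rowSums(do.call(rbind, rep$continuous$p_active)) - 1) < 1e-9))
  ranked <- read.csv(cf)
  expect_equal(ranked$descriptor,
               unname(vapply(sel$continuous, `[[`, "", "descriptor_name")))
})
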