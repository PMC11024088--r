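#' Distance configuration for splitting
#'
#' @param metric "euclidean", "mahalanobis" or "tanimoto_complement"
#'   (1 - Tanimoto coefficient; bit vectors only).
#' @param include_labels append the binary class label as an extra 0/1
#'   coordinate before distance computation (used to incorporate the
#'   activities into the Mahalanobis splitting distance).
#' @param covariance_regularization ridge term added to the covariance
#'   diagonal before pseudo-inversion (Mahalanobis only).
#' @return object of class `bbb_distance_config`.
#' @export
distance_config <- function(metric = c("euclidean", "mahalanobis",
                                       "tanimoto_complement"),
                            include_labels = FALSE,
                            covariance_regularization = 0) {
  metric <- match.arg(metric)
  assert_that(covariance_regularization >= 0,
              "covariance_regularization must be >= 0")
  structure(list(metric = metric, include_labels = include_labels,
                 covariance_regularization = covariance_regularization),
            class = "bbb_distance_config")
}

tanimoto_distance_matrix <- function(X) {
  assert_that(all(X %in% c(0, 1)), "tanimoto distance needs binary input")
  inter <- tcrossprod(X)
  pop <- rowSums(X)
  union <- outer(pop, pop, `+`) - inter
  sim <- ifelse(union == 0, 1, inter / union)  # two empty vectors: identical
  D <- 1 - sim
  diag(D) <- 0
  rn <- rownames(X) %||% as.character(seq_len(nrow(X)))
  dimnames(D) <- list(rn, rn)
  D
}

mahalanobis_distance_matrix <- function(X, ridge = 0) {
  # covariance estimated on all rows; pseudo-inverse handles singular S
  S <- stats::cov(X)
  Sinv <- pseudo_inverse(S, ridge = ridge)
  e <- eigen(Sinv, symmetric = TRUE)
  pos <- pmax(e$values, 0)
  W <- e$vectors %*% diag(sqrt(pos), length(pos))
  Y <- X %*% W
  rownames(Y) <- rownames(X)
  as.matrix(stats::dist(Y))
}

#' Pairwise distance matrix
#'
#' @param X numeric feature matrix or 0/1 bit matrix (rows = samples).
#' @param config `bbb_distance_config` (labels, if configured, must already
#'   be appended by the caller — [kennard_stone()] does this).
#' @return symmetric matrix with zero diagonal.
#' @export
pairwise_distances <- function(X, config = distance_config()) {
  stopifnot(inherits(config, "bbb_distance_config"))
  X <- as.matrix(X)
  assert_that(nrow(X) >= 2, "need at least two rows")
  switch(config$metric,
         euclidean = as.matrix(stats::dist(X)),
         mahalanobis = mahalanobis_distance_matrix(
           X, ridge = config$covariance_regularization),
         tanimoto_complement = tanimoto_distance_matrix(X))
}

#' Modified Kennard-Stone train/test split
#'
#' Greedy max-min coverage design: the pair of samples at maximal distance
#' seeds the training set; thereafter the candidate whose distance to its
#' nearest training sample is largest joins, until `train_size` is reached.
#' Remaining samples form the test set.  With `include_labels` set in the
#' config the 0/1 class label is appended as an extra coordinate before
#' computing distances (not valid for the Tanimoto metric on bit input
#' unless labels are 0/1 bits, which they are).  Ties at any step are
#' broken by lowest row index; a fully degenerate input (all points
#' identical) therefore selects the lowest indices, with a warning.
#'
#' @param X feature or bit matrix; rownames (or indices) become ids.
#' @param train_size number of training samples, `2 <= train_size < n`.
#' @param config `bbb_distance_config`.
#' @param labels binary labels, required when `config$include_labels`.
#' @return object of class `bbb_split`: `train_ids` (in selection order),
#'   `test_ids`, `train_idx`, `test_idx`, `metric`, `train_fraction`, and
#'   `selection_distances` (the max-min distance at which each training
#'   sample after the first two was admitted).
#' @export
kennard_stone <- function(X, train_size, config = distance_config(),
                          labels = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  assert_that(train_size >= 2 && train_size < n,
              "train_size must satisfy 2 <= train_size < n")
  ids <- rownames(X) %||% as.character(seq_len(n))
  if (config$include_labels) {
    assert_that(!is.null(labels) && length(labels) == n,
                "include_labels requires one label per row")
    X <- cbind(X, as.integer(is_active(labels)))
  }
  D <- pairwise_distances(X, config)
  if (max(D) == 0)
    warning("all points identical: selection degenerates to lowest indices")

  # seed pair: maximal distance, ties -> lexicographically smallest (i, j)
  upper <- which(upper.tri(D), arr.ind = TRUE)
  upper <- upper[order(upper[, 1], upper[, 2]), , drop = FALSE]
  best <- upper[which.max(D[upper]), ]
  train <- c(best[1], best[2])
  sel_dist <- numeric()

  dmin <- pmin(D[, train[1]], D[, train[2]])
  in_train <- logical(n); in_train[train] <- TRUE
  while (length(train) < train_size) {
    cand <- which(!in_train)
    pick <- cand[which.max(dmin[cand])]  # which.max: first max = lowest index
    sel_dist <- c(sel_dist, dmin[pick])
    train <- c(train, pick)
    in_train[pick] <- TRUE
    dmin <- pmin(dmin, D[, pick])
  }
  test <- which(!in_train)
  structure(list(train_ids = ids[train], test_ids = ids[test],
                 train_idx = unname(train), test_idx = unname(test),
                 metric = config$metric,
                 train_fraction = train_size / n,
                 selection_distances = sel_dist),
            class = "bbb_split")
}

#' @export
print.bbb_split <- function(x, ...) {
  cat(sprintf("Kennard-Stone split (%s): %d train / %d test (fraction %.3f)\n",
              x$metric, length(x$train_ids), length(x$test_ids),
              x$train_fraction))
  invisible(x)
}

#' Seeded random split (baseline for tests)
#'
#' @param n number of samples.
#' @param train_size training-set size.
#' @param seed RNG seed.
#' @return list with `train_idx`, `test_idx`.
#' @export
random_split <- function(n, train_size, seed = 1) {
  assert_that(train_size >= 1 && train_size < n, "train_size out of range")
  set.seed(seed)
  idx <- sample.int(n, train_size)
  list(train_idx = sort(idx), test_idx = setdiff(seq_len(n), idx))
}

#' Write a split as two id CSVs
#'
#' @param split `bbb_split`.
#' @param train_path,test_path output CSVs (single `id` column).
#' @export
write_split <- function(split, train_path, test_path) {
  stopifnot(inherits(split, "bbb_split"))
  data.table::fwrite(data.frame(id = split$train_ids), train_path)
  data.table::fwrite(data.frame(id = split$test_ids), test_path)
  invisible(c(train = train_path, test = test_path))
}
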