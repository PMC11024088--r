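#' Balanced class weights
#'
#' \eqn{w_c = n\_samples / (n\_classes \cdot class\_count_c)} for each of
#' the two classes.
#'
#' @param labels binary label vector; both classes must be present.
#' @return object of class `bbb_class_weights`: list with `weight_active`,
#'   `weight_inactive`.
#' @export
class_weights <- function(labels) {
  lab <- as_bbb_label(labels)
  n_act <- sum(lab == "active"); n_inact <- sum(lab == "inactive")
  assert_that(n_act > 0 && n_inact > 0, "both classes must be present")
  n <- n_act + n_inact
  structure(list(weight_active = n / (2 * n_act),
                 weight_inactive = n / (2 * n_inact)),
            class = "bbb_class_weights")
}

#' Model specification
#'
#' @param family "random_forest", "svm_rbf" or "svm_poly".
#' @param ... hyperparameters for the family (random forest: `n_estimators`,
#'   `max_depth`, `max_features`, `criterion`, `class_weight`; SVM: `C`,
#'   `gamma`, and `degree` for the polynomial kernel; `class_weight` for
#'   all).  `max_depth`/`max_features` accept "none" for no limit.
#' @param seed RNG seed recorded in the spec (bootstrap, Platt scaling).
#' @return object of class `bbb_model_spec`.
#' @export
model_spec <- function(family = c("random_forest", "svm_rbf", "svm_poly"),
                       ..., seed = 1) {
  family <- match.arg(family)
  params <- list(...)
  allowed <- if (family == "random_forest")
    c("n_estimators", "max_depth", "max_features", "criterion", "class_weight")
  else c("C", "gamma", "degree", "class_weight")
  bad <- setdiff(names(params), allowed)
  assert_that(length(bad) == 0,
              paste0("invalid hyperparameter(s) for ", family, ": ",
                     paste(bad, collapse = ", ")))
  if (family == "svm_rbf")
    assert_that(!"degree" %in% names(params), "degree is not used by the RBF kernel")
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "bbb_model_spec")
}

#' Reference model specifications
#'
#' The best-performing random-forest configurations: the imbalanced-data
#' model uses 100 trees of depth 400 with the Gini criterion; the
#' balanced-data model 500 trees of depth 500, sqrt max-features and the
#' entropy criterion.
#'
#' @param dataset_kind "imbalanced" or "balanced".
#' @param seed recorded seed.
#' @return `bbb_model_spec`.
#' @export
reference_rf_spec <- function(dataset_kind = c("imbalanced", "balanced"),
                              seed = 1) {
  dataset_kind <- match.arg(dataset_kind)
  if (dataset_kind == "imbalanced")
    model_spec("random_forest", n_estimators = 100, max_depth = 400,
               criterion = "gini", max_features = "sqrt",
               class_weight = "balanced", seed = seed)
  else
    model_spec("random_forest", n_estimators = 500, max_depth = 500,
               criterion = "entropy", max_features = "sqrt",
               class_weight = "balanced", seed = seed)
}

#' Default hyperparameter grids
#'
#' The exhaustive grid-search ranges: for the imbalanced dataset the random
#' forest varies `max_depth` 200..900 and `n_estimators` 100..1000 (steps
#' of 100) with both gini and entropy criteria, and the SVMs use C in
#' 0.7..1.2 (step 0.1), gamma in 0.1..0.4 (step 0.1) and polynomial degree
#' 1..5.  For the balanced dataset the forest grid is `max_depth`
#' \{100, 500, 1000, 1500, none\} x `n_estimators` \{100, 500, 1000, 1500\}
#' x `max_features` \{sqrt, log2, none\} x criterion \{gini, entropy,
#' log_loss\}, and the SVMs use log-spaced C (1e-4..1e4) and gamma
#' (1e-4..1e2) with degree 1..6.
#'
#' @param family "random_forest", "svm_rbf" or "svm_poly".
#' @param dataset_kind "imbalanced" or "balanced".
#' @return data.frame, one row per grid point.
#' @export
default_grids <- function(family = c("random_forest", "svm_rbf", "svm_poly"),
                          dataset_kind = c("imbalanced", "balanced")) {
  family <- match.arg(family)
  dataset_kind <- match.arg(dataset_kind)
  if (family == "random_forest") {
    if (dataset_kind == "imbalanced")
      expand.grid(max_depth = seq(200, 900, by = 100),
                  n_estimators = seq(100, 1000, by = 100),
                  criterion = c("gini", "entropy"),
                  max_features = "sqrt",
                  stringsAsFactors = FALSE)
    else
      expand.grid(max_depth = c("100", "500", "1000", "1500", "none"),
                  n_estimators = c(100, 500, 1000, 1500),
                  max_features = c("sqrt", "log2", "none"),
                  criterion = c("gini", "entropy", "log_loss"),
                  stringsAsFactors = FALSE)
  } else if (dataset_kind == "imbalanced") {
    g <- expand.grid(C = seq(0.7, 1.2, by = 0.1),
                     gamma = seq(0.1, 0.4, by = 0.1))
    if (family == "svm_poly") g <- merge(g, data.frame(degree = 1:5))
    g
  } else {
    g <- expand.grid(C = 10^(-4:4), gamma = 10^(-4:2))
    if (family == "svm_poly") g <- merge(g, data.frame(degree = 1:6))
    g
  }
}

grid_to_configs <- function(grid, class_weight = "balanced") {
  lapply(seq_len(nrow(grid)), function(i) {
    cfg <- as.list(grid[i, , drop = FALSE])
    cfg <- lapply(cfg, function(v) if (is.factor(v)) as.character(v) else v)
    cfg$class_weight <- cfg$class_weight %||% class_weight
    cfg
  })
}

write_x_csv <- function(X) {
  path <- tempfile(fileext = ".csv")
  data.table::fwrite(data.table::as.data.table(unname(as.matrix(X))), path,
                     col.names = FALSE)
  path
}

fold_reports <- function(y, proba, fold) {
  lapply(sort(unique(fold)), function(f) {
    idx <- fold == f
    pred <- ifelse(proba[idx] >= 0.5, "active", "inactive")
    evaluate_predictions(y[idx], pred, probabilities = proba[idx])
  })
}

metric_names <- c("sensitivity", "specificity", "accuracy",
                  "balanced_accuracy", "precision", "f1", "mcc", "kappa",
                  "roc_auc")

summarize_folds <- function(reports) {
  vals <- sapply(metric_names, function(m)
    vapply(reports, function(r) as.numeric(r[[m]]), 0))
  c(colMeans(vals, na.rm = TRUE) |> stats::setNames(paste0("mean_", metric_names)),
    apply(vals, 2, stats::sd, na.rm = TRUE) |> stats::setNames(paste0("sd_", metric_names)))
}

#' Exhaustive grid search with stratified k-fold cross-validation
#'
#' Evaluates every grid row with stratified k-fold CV (one fold assignment
#' shared by all configurations, fixed by `seed`), computes the full metric
#' report per fold, and returns the configuration with the best mean
#' selection metric (ties broken by grid order).
#'
#' @param X fingerprint (0/1) or feature matrix.
#' @param y binary labels.
#' @param family learner family (see [model_spec()]).
#' @param grid data.frame of hyperparameter combinations; defaults to
#'   [default_grids()] for the family and an imbalance guess from `y`.
#' @param k number of folds (default 10).
#' @param seed RNG seed controlling fold shuffling and learner randomness.
#' @param selection_metric metric whose CV mean picks the winner
#'   ("accuracy" by default; any of the report's metrics).
#' @param class_weight class-weighting passed to the learner ("balanced" or
#'   "none").
#' @return object of class `bbb_grid_search`: `best_spec`
#'   (`bbb_model_spec`), `best_index`, `cv_table` (per-configuration mean
#'   and sd of every metric), and `fold_reports` for the winning
#'   configuration.
#' @export
grid_search_cv <- function(X, y, family, grid = NULL, k = 10, seed = 1,
                           selection_metric = "accuracy",
                           class_weight = "balanced") {
  lab <- as_bbb_label(y)
  assert_that(length(lab) >= k, "need at least k samples")
  assert_that(selection_metric %in% metric_names, "unknown selection metric")
  if (is.null(grid)) {
    ratio <- mean(lab == "active")
    kind <- if (abs(ratio - 0.5) < 0.1) "balanced" else "imbalanced"
    grid <- default_grids(family, kind)
  }
  assert_that(nrow(grid) >= 1, "empty grid")
  x_path <- write_x_csv(X)
  on.exit(unlink(x_path), add = TRUE)
  res <- learner_worker("cv", list(
    x_path = x_path, y = as.integer(lab == "active"), family = family,
    configs = grid_to_configs(grid, class_weight), k = as.integer(k),
    seed = as.integer(seed)))
  fold <- as.integer(res$fold)
  proba <- res$proba
  if (is.matrix(proba)) proba <- lapply(seq_len(nrow(proba)), function(i) proba[i, ])
  if (!is.list(proba)) proba <- list(proba)

  summaries <- lapply(seq_len(nrow(grid)), function(i)
    summarize_folds(fold_reports(lab, as.numeric(proba[[i]]), fold)))
  cv_table <- cbind(grid, do.call(rbind, summaries))
  best <- which.max(cv_table[[paste0("mean_", selection_metric)]])
  best_cfg <- grid_to_configs(grid[best, , drop = FALSE], class_weight)[[1]]
  best_spec <- do.call(model_spec, c(list(family = family, seed = seed), best_cfg))
  structure(list(best_spec = best_spec, best_index = best,
                 cv_table = cv_table,
                 fold_reports = fold_reports(lab, as.numeric(proba[[best]]), fold),
                 k = k, seed = seed, selection_metric = selection_metric),
            class = "bbb_grid_search")
}

#' @export
print.bbb_grid_search <- function(x, ...) {
  cat(sprintf("Grid search (%s, %d configurations, %d-fold CV)\n",
              x$best_spec$family, nrow(x$cv_table), x$k))
  cat(sprintf("  best (%s = %.4f): %s\n", x$selection_metric,
              x$cv_table[[paste0("mean_", x$selection_metric)]][x$best_index],
              paste(names(x$best_spec$params),
                    unlist(x$best_spec$params), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Train a classifier
#'
#' Fits the learner, stores it in a model directory together with the
#' training-data mean vector and covariance pseudo-inverse in fingerprint
#' space (the applicability-domain reference), the spec and an optional
#' schema reference.
#'
#' @param X training fingerprint/feature matrix.
#' @param y training labels.
#' @param spec `bbb_model_spec`.
#' @param dir model directory (created); defaults to a tempdir location.
#' @param schema optional `bbb_fingerprint_schema` stored alongside.
#' @param ad_reference "all" (default) or "active": which training
#'   compounds define the applicability-domain distance.
#' @return object of class `bbb_model`.
#' @export
train_model <- function(X, y, spec, dir = tempfile("bbb_model_"),
                        schema = NULL, ad_reference = c("all", "active")) {
  stopifnot(inherits(spec, "bbb_model_spec"))
  ad_reference <- match.arg(ad_reference)
  X <- as.matrix(X)
  lab <- as_bbb_label(y)
  assert_that(nrow(X) == length(lab), "X rows must match labels")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model_path <- file.path(dir, "model.joblib")
  learner_worker("train", list(
    x_path = write_x_csv(X), y = as.integer(lab == "active"),
    family = spec$family, params = spec$params, seed = spec$seed,
    model_path = model_path))
  ref <- if (ad_reference == "active") X[lab == "active", , drop = FALSE] else X
  ad <- list(mean = colMeans(ref),
             cov_pinv = pseudo_inverse(stats::cov(ref)),
             reference = ad_reference)
  meta <- list(spec = unclass(spec), n_features = ncol(X),
               n_train = nrow(X), ad_reference = ad_reference,
               schema_hash = if (!is.null(schema))
                 digest_schema(schema) else NULL)
  write_json_file(meta, file.path(dir, "model.json"))
  if (!is.null(schema)) write_schema(schema, file.path(dir, "schema.json"))
  saveRDS(ad, file.path(dir, "ad.rds"))
  structure(list(dir = dir, spec = spec, n_features = ncol(X), ad = ad,
                 schema = schema),
            class = "bbb_model")
}

digest_schema <- function(schema) {
  tmp <- tempfile(); on.exit(unlink(tmp))
  write_schema(schema, tmp)
  unname(tools::md5sum(tmp))
}

#' Load a saved model
#'
#' @param dir model directory written by [train_model()].
#' @return `bbb_model`.
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  spec <- do.call(model_spec, c(list(family = meta$spec$family,
                                     seed = meta$spec$seed),
                                as.list(meta$spec$params)))
  schema_path <- file.path(dir, "schema.json")
  structure(list(dir = dir, spec = spec,
                 n_features = as.integer(meta$n_features),
                 ad = readRDS(file.path(dir, "ad.rds")),
                 schema = if (file.exists(schema_path)) read_schema(schema_path)),
            class = "bbb_model")
}

#' Applicability-domain distance
#'
#' Mahalanobis distance of each row of `X` to the model's training-data
#' mean, under the training covariance pseudo-inverse.
#'
#' @param model `bbb_model`.
#' @param X fingerprint/feature matrix.
#' @return numeric vector of distances (>= 0).
#' @export
ad_distance <- function(model, X) {
  stopifnot(inherits(model, "bbb_model"))
  X <- as.matrix(X)
  d <- sweep(X, 2, model$ad$mean)
  sqrt(pmax(rowSums((d %*% model$ad$cov_pinv) * d), 0))
}

#' Predict with applicability-domain distances
#'
#' Returns, per compound, the positive-class probability, the label derived
#' from it at the 0.5 threshold (ties -> active, keeping probability and
#' label consistent by construction), and the Mahalanobis
#' applicability-domain distance to the training data.
#'
#' @param object `bbb_model`.
#' @param X fingerprint/feature matrix encoded with the model's schema.
#' @param ... unused.
#' @return data.frame with `compound_id`, `predicted_label`,
#'   `probability_active`, `ad_distance`.
#' @export
predict.bbb_model <- function(object, X, ...) {
  X <- as.matrix(X)
  assert_that(ncol(X) == object$n_features,
              sprintf("fingerprint length mismatch: model expects %d, got %d",
                      object$n_features, ncol(X)))
  x_path <- write_x_csv(X)
  on.exit(unlink(x_path), add = TRUE)
  res <- learner_worker("predict",
                        list(model_path = file.path(object$dir, "model.joblib"),
                             x_path = x_path))
  proba <- as.numeric(res$proba)
  data.frame(compound_id = rownames(X) %||% as.character(seq_len(nrow(X))),
             predicted_label = factor(ifelse(proba >= 0.5, "active", "inactive"),
                                      levels = c("inactive", "active")),
             probability_active = proba,
             ad_distance = ad_distance(object, X),
             stringsAsFactors = FALSE)
}

#' @export
print.bbb_model <- function(x, ...) {
  cat(sprintf("BBB model (%s): %d features, trained on %s; AD reference: %s\n",
              x$spec$family, x$n_features, x$dir, x$ad$reference))
  invisible(x)
}
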