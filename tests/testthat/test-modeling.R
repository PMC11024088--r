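test_that("class weights follow n_samples / (n_classes * class_count)", {
  w <- class_weights(c(rep("active", 100), rep("inactive", 100)))
  expect_equal(w$weight_active, 1.0)
  expect_equal(w$weight_inactive, 1.0)
  # counts from the imbalanced training set: 1108 active / 366 inactive
  w2 <- class_weights(c(rep(1, 1108), rep(0, 366)))
  expect_equal(round(w2$weight_active, 4), 0.6652)
  expect_equal(round(w2$weight_inactive, 4), 2.0137)
  w3 <- class_weights(c(1, 1, 1, 0))
  expect_equal(w3$weight_active, 4 / (2 * 3))
  expect_equal(w3$weight_inactive, 2.0)
  expect_error(class_weights(rep(1, 5)), "both classes")
})

test_that("class-weight formula matches brute force over the count grid", {
  for (a in seq(1, 50, by = 7)) for (b in seq(1, 50, by = 7)) {
    w <- class_weights(c(rep("active", a), rep("inactive", b)))
    expect_identical(w$weight_active, (a + b) / (2 * a))
    expect_identical(w$weight_inactive, (a + b) / (2 * b))
  }
})

test_that("default grids reproduce the published search spaces", {
  rf_i <- default_grids("random_forest", "imbalanced")
  expect_setequal(unique(rf_i$max_depth), seq(200, 900, 100))
  expect_setequal(unique(rf_i$n_estimators), seq(100, 1000, 100))
  expect_setequal(unique(rf_i$criterion), c("gini", "entropy"))
  expect_equal(nrow(rf_i), 8 * 10 * 2)

  rf_b <- default_grids("random_forest", "balanced")
  expect_setequal(unique(rf_b$max_depth), c("100", "500", "1000", "1500", "none"))
  expect_setequal(unique(rf_b$max_features), c("sqrt", "log2", "none"))
  expect_setequal(unique(rf_b$criterion), c("gini", "entropy", "log_loss"))

  sp_i <- default_grids("svm_poly", "imbalanced")
  expect_equal(sort(unique(sp_i$C)), seq(0.7, 1.2, 0.1))
  expect_equal(sort(unique(sp_i$gamma)), seq(0.1, 0.4, 0.1))
  expect_equal(sort(unique(sp_i$degree)), 1:5)
  expect_equal(nrow(sp_i), 6 * 4 * 5)

  sr_b <- default_grids("svm_rbf", "balanced")
  expect_equal(sort(unique(sr_b$C)), 10^(-4:4))
  expect_equal(sort(unique(sr_b$gamma)), 10^(-4:2))
  expect_false("degree" %in% names(sr_b))
  sp_b <- default_grids("svm_poly", "balanced")
  expect_equal(sort(unique(sp_b$degree)), 1:6)
})

test_that("model_spec validates hyperparameters per family", {
  expect_error(model_spec("random_forest", C = 1), "invalid hyperparameter")
  expect_error(model_spec("svm_rbf", degree = 3), "degree")
  sp <- reference_rf_spec("imbalanced")
  expect_equal(sp$params$n_estimators, 100)
  expect_equal(sp$params$max_depth, 400)
  expect_equal(sp$params$criterion, "gini")
  sp_b <- reference_rf_spec("balanced")
  expect_equal(sp_b$params$n_estimators, 500)
  expect_equal(sp_b$params$max_depth, 500)
  expect_equal(sp_b$params$max_features, "sqrt")
  expect_equal(sp_b$params$criterion, "entropy")
})

# small separable fingerprint-like dataset used by the learner tests
sep_data <- function(n_per = 30, p = 12, seed = 123) {
  set.seed(seed)
  X <- rbind(matrix(rbinom(n_per * p, 1, 0.85), n_per),
             matrix(rbinom(n_per * p, 1, 0.15), n_per))
  rownames(X) <- sprintf("s%03d", seq_len(2 * n_per))
  list(X = X, y = rep(c("active", "inactive"), each = n_per))
}

test_that("singleton grid is returned as best and CV is deterministic", {
  d <- sep_data()
  g <- data.frame(n_estimators = 25, max_depth = 4)
  gs1 <- grid_search_cv(d$X, d$y, "random_forest", grid = g, k = 5, seed = 11)
  expect_equal(gs1$best_index, 1)
  expect_equal(gs1$best_spec$params$n_estimators, 25)
  gs2 <- grid_search_cv(d$X, d$y, "random_forest", grid = g, k = 5, seed = 11)
  expect_identical(gs1$cv_table, gs2$cv_table)
  expect_length(gs1$fold_reports, 5)
})

test_that("separable data reaches CV accuracy >= 0.99 and picks a sane winner", {
  d <- sep_data(n_per = 40)
  g <- expand.grid(n_estimators = c(20, 50), max_depth = c(3, 6))
  gs <- grid_search_cv(d$X, d$y, "random_forest", grid = g, k = 5, seed = 2)
  expect_gte(max(gs$cv_table$mean_accuracy), 0.99)
  expect_true(all(c("mean_mcc", "sd_accuracy", "mean_roc_auc") %in%
                    names(gs$cv_table)))
})

test_that("svm families train and predict through the same surface", {
  d <- sep_data(n_per = 25)
  for (fam in c("svm_rbf", "svm_poly")) {
    spec <- if (fam == "svm_poly")
      model_spec(fam, C = 1, gamma = 0.1, degree = 3, seed = 4)
    else model_spec(fam, C = 1, gamma = 0.1, seed = 4)
    mod <- train_model(d$X, d$y, spec)
    pred <- predict(mod, d$X)
    expect_gte(mean(pred$predicted_label == d$y), 0.95)
  }
})

test_that("probability and label are consistent at the 0.5 threshold", {
  d <- sep_data(n_per = 30, seed = 9)
  mod <- train_model(d$X, d$y, model_spec("random_forest",
                                          n_estimators = 15, seed = 1))
  probe <- generate_bit_dataset(40, ncol(d$X), seed = 44)
  pred <- predict(mod, probe)
  expect_identical(pred$predicted_label == "active",
                   pred$probability_active >= 0.5)
})

test_that("training is reproducible and artifacts round-trip bit-identically", {
  d <- sep_data(n_per = 20, seed = 5)
  spec <- model_spec("random_forest", n_estimators = 20, max_depth = 5,
                     class_weight = "balanced", seed = 31)
  m1 <- train_model(d$X, d$y, spec)
  m2 <- train_model(d$X, d$y, spec)
  probe <- generate_bit_dataset(25, ncol(d$X), seed = 7)
  p1 <- predict(m1, probe); p2 <- predict(m2, probe)
  expect_identical(p1$probability_active, p2$probability_active)
  # save -> load -> predict is identical
  m3 <- load_model(m1$dir)
  p3 <- predict(m3, probe)
  expect_identical(p3, p1)
  expect_equal(m3$spec$params$n_estimators, 20)
})

test_that("AD distance is 0 at the training mean and flags planted outliers", {
  set.seed(61)
  X <- matrix(rnorm(200 * 6), 200)  # continuous features exercise the metric
  y <- rep(c("active", "inactive"), 100)
  mod <- train_model(X, y, model_spec("random_forest", n_estimators = 10,
                                      seed = 3))
  expect_equal(ad_distance(mod, matrix(colMeans(X), 1)), 0, tolerance = 1e-8)
  d_train <- ad_distance(mod, X)
  outlier <- matrix(colMeans(X) + 50, 1)
  expect_gt(ad_distance(mod, outlier), quantile(d_train, 0.99))
  # a fed-back training compound is unremarkable within the training AD
  expect_lt(ad_distance(mod, X[1, , drop = FALSE]), max(d_train) + 1e-9)
})

test_that("active-only AD reference is supported", {
  d <- sep_data(n_per = 25, seed = 8)
  mod <- train_model(d$X, d$y, model_spec("random_forest", n_estimators = 10,
                                          seed = 2), ad_reference = "active")
  act_mean <- colMeans(d$X[d$y == "active", ])
  expect_equal(ad_distance(mod, matrix(act_mean, 1)), 0, tolerance = 1e-8)
})

test_that("prediction rejects fingerprint length mismatches", {
  d <- sep_data(n_per = 15, seed = 2)
  mod <- train_model(d$X, d$y, model_spec("random_forest", n_estimators = 5,
                                          seed = 1))
  expect_error(predict(mod, d$X[, -1]), "length mismatch")
})
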