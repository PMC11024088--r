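#' Build a pipeline run configuration
#'
#' One structured object carrying every stage parameter; a run's config
#' plus inputs fully determine its outputs.  Inputs are either file paths
#' (`compounds`/`descriptors`/`labels`) or a synthetic preset.
#'
#' @param input list: either `list(synthetic = bbb_synthetic_spec)` or
#'   `list(descriptors = path, labels = path)` (descriptor CSV + labels
#'   CSV with columns id,label).
#' @param n_bins MI-DSE histogram bins.
#' @param max_n,min_score,pcc_cut,diff_cut feature-selection thresholds.
#' @param bits fingerprint bits per descriptor (1, 4 or 8).
#' @param metric splitting distance metric.
#' @param include_labels incorporate activities into the splitting distance.
#' @param train_fraction Kennard-Stone training fraction.
#' @param family learner family.
#' @param grid hyperparameter grid data.frame, or NULL for a singleton run
#'   of the reference spec, or "default" for the full default grid.
#' @param k CV folds used when a grid is searched.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return object of class `bbb_run_config`.
#' @export
run_config <- function(input, n_bins = 10, max_n = 50, min_score = 0.1,
                       pcc_cut = 0.8, diff_cut = 0.2, bits = 8,
                       metric = "mahalanobis", include_labels = FALSE,
                       train_fraction = 0.8, family = "random_forest",
                       grid = NULL, k = 10, seed = 1) {
  assert_that(bits %in% c(1, 4, 8), "bits must be 1, 4 or 8")
  assert_that(train_fraction > 0 && train_fraction < 1,
              "train_fraction must lie in (0,1)")
  assert_that(metric %in% c("euclidean", "mahalanobis", "tanimoto_complement"),
              "unknown metric")
  assert_that(family %in% c("random_forest", "svm_rbf", "svm_poly"),
              "unknown family")
  ok_input <- is.list(input) &&
    (inherits(input$synthetic, "bbb_synthetic_spec") ||
       (!is.null(input$descriptors) && !is.null(input$labels)))
  assert_that(ok_input,
              "input must carry a synthetic spec or descriptors+labels paths")
  structure(list(input = input, n_bins = n_bins, max_n = max_n,
                 min_score = min_score, pcc_cut = pcc_cut,
                 diff_cut = diff_cut, bits = bits, metric = metric,
                 include_labels = include_labels,
                 train_fraction = train_fraction, family = family,
                 grid = grid, k = k, seed = as.integer(seed)),
            class = "bbb_run_config")
}

read_labels_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  assert_that(all(c("id", "label") %in% names(df)),
              "labels file needs 'id' and 'label' columns")
  stats::setNames(as_bbb_label(df$label), df$id)
}

#' Run the full modelling pipeline
#'
#' Executes select -> fit-schema -> encode -> split -> (grid-search) ->
#' train -> evaluate on the configured input, writing every intermediate
#' artifact (selection report, schema JSON, fingerprint CSV, split id
#' lists, model directory, metrics JSON, resolved config, log) to
#' `out_dir`.  Stage failures abort with the stage name and cause.
#'
#' @param config `bbb_run_config`.
#' @param out_dir run directory (created).
#' @return object of class `bbb_run`: the key artifacts plus the external
#'   test-set `bbb_metrics` report.
#' @export
run_pipeline <- function(config, out_dir = tempfile("bbb_run_")) {
  stopifnot(inherits(config, "bbb_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                                "\n", file = log_path, append = TRUE)
  stage <- function(name, expr) {
    log_line("stage:", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inputs <- stage("input", {
    if (!is.null(config$input$synthetic)) {
      synth <- generate_synthetic(config$input$synthetic)
      write_synthetic(synth, file.path(out_dir, "input"))
      list(table = synth$table, labels = synth$labels)
    } else {
      tab <- read_descriptor_table(config$input$descriptors,
                                   dimension_tag = config$input$dimension %||% "2D")
      labs <- read_labels_csv(config$input$labels)
      assert_that(all(tab$compound_ids %in% names(labs)),
                  "labels missing for some compounds")
      list(table = tab, labels = labs[tab$compound_ids])
    }
  })

  split <- stage("split", {
    n <- nrow(inputs$table$values)
    cfg <- distance_config(config$metric,
                           include_labels = config$include_labels)
    # split on the raw descriptor space (complete columns only)
    complete <- colSums(is.na(inputs$table$values)) == 0
    Xs <- scale(inputs$table$values[, complete, drop = FALSE])
    Xs[is.nan(Xs)] <- 0
    sp <- kennard_stone(Xs, train_size = round(config$train_fraction * n),
                        config = cfg, labels = inputs$labels)
    write_split(sp, file.path(out_dir, "train_ids.csv"),
                file.path(out_dir, "test_ids.csv"))
    sp
  })

  train_ids <- split$train_ids
  test_ids <- split$test_ids
  lab_train <- inputs$labels[match(train_ids, inputs$table$compound_ids)]
  lab_test <- inputs$labels[match(test_ids, inputs$table$compound_ids)]

  selection <- stage("select", {
    train_tab <- descriptor_table(
      inputs$table$values[train_ids, , drop = FALSE],
      dimension_tag = unname(inputs$table$dimension_tag))
    sel <- select_features(train_tab, lab_train, n_bins = config$n_bins,
                           max_n = config$max_n, min_score = config$min_score,
                           pcc_cut = config$pcc_cut, diff_cut = config$diff_cut)
    write_selection_report(sel, file.path(out_dir, "selection.json"),
                           file.path(out_dir, "selection.csv"))
    sel
  })
  assert_that(length(selection$continuous) > 0,
              "feature selection retained no descriptor")

  schema <- stage("fit_schema", {
    train_tab <- descriptor_table(
      inputs$table$values[train_ids, , drop = FALSE],
      dimension_tag = unname(inputs$table$dimension_tag))
    sc <- fit_schema(train_tab, selection, bits = config$bits)
    write_schema(sc, file.path(out_dir, "schema.json"))
    sc
  })

  fp <- stage("encode", {
    M <- encode_table(inputs$table, schema)
    data.table::fwrite(data.frame(id = rownames(M), M, check.names = FALSE),
                       file.path(out_dir, "fingerprints.csv"))
    M
  })

  X_train <- fp[train_ids, , drop = FALSE]
  X_test <- fp[test_ids, , drop = FALSE]

  model <- stage("train", {
    spec <- if (is.null(config$grid)) {
      kind <- if (abs(mean(lab_train == "active") - 0.5) < 0.1)
        "balanced" else "imbalanced"
      reference_rf_spec(kind, seed = derive_seed(config$seed, "train"))
    } else {
      grid <- if (identical(config$grid, "default")) NULL else config$grid
      gs <- grid_search_cv(X_train, lab_train, config$family, grid = grid,
                           k = config$k,
                           seed = derive_seed(config$seed, "cv"))
      write_json_file(gs$cv_table, file.path(out_dir, "cv_table.json"))
      gs$best_spec
    }
    train_model(X_train, lab_train, spec,
                dir = file.path(out_dir, "model"), schema = schema)
  })

  report <- stage("evaluate", {
    pred <- predict(model, X_test)
    data.table::fwrite(pred, file.path(out_dir, "predictions.csv"))
    rep <- evaluate_predictions(lab_test, pred$predicted_label,
                                probabilities = pred$probability_active)
    write_metrics_report(rep, file.path(out_dir, "metrics.json"))
    rep
  })

  resolved <- config
  resolved$input <- lapply(config$input, function(x)
    if (inherits(x, "bbb_synthetic_spec")) unclass(x) else x)
  write_json_file(unclass(resolved), file.path(out_dir, "config.json"))
  log_line("done")
  structure(list(out_dir = out_dir, selection = selection, schema = schema,
                 split = split, model = model, metrics = report),
            class = "bbb_run")
}

#' Write a metrics report as JSON
#'
#' @param report `bbb_metrics`.
#' @param path output path.
#' @export
write_metrics_report <- function(report, path) {
  stopifnot(inherits(report, "bbb_metrics"))
  out <- lapply(report[setdiff(names(report), "counts")], function(v) {
    if (is.na(v)) list(undefined = attr(v, "undefined") %||% "NA")
    else as.numeric(v)
  })
  out$counts <- unclass(report$counts)
  write_json_file(out, path)
}

#' @export
print.bbb_run <- function(x, ...) {
  cat("Pipeline run:", x$out_dir, "\n")
  print(x$selection)
  print(x$schema)
  print(x$split)
  print(x$metrics)
  invisible(x)
}
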