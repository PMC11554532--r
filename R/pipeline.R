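# End-to-end orchestration: split -> train two CNNs -> extract GAP
# features -> select per block -> serial fusion -> shallow-NN
# classification of all five feature sets -> paired t-test. Mirrors the
# five-experiment design: raw block A, raw block B, selected A,
# selected B, fused.

#' Pipeline run configuration
#'
#' @param dataset either a directory in folder-per-class layout or an
#'   [image_set_spec()] for synthetic data.
#' @param models two-element list naming the CNNs to train: each either
#'   a [model_graph()] or one of `"micro_a"`, `"micro_b"`,
#'   `"three_residual"`, `"four_residual"` (resolved once the class
#'   count is known). The micro variants are desk-scale networks with
#'   different feature widths.
#' @param image_size square image side used for training.
#' @param train a [train_config()].
#' @param gndo a [gndo_config()] for feature selection.
#' @param fitness a [fitness_spec()].
#' @param classifiers classifier families to evaluate
#'   (see [classifier_spec()]).
#' @param classifier_epochs training epochs for the shallow classifiers.
#' @param cv_folds cross-validation folds for classifier metrics.
#' @param ttest_pair two classifier families compared by the paired
#'   accuracy t-test across the five experiments.
#' @param out_dir output directory for artifacts (created).
#' @param seed global seed; every stochastic stage receives a seed
#'   derived from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(dataset, models = list("micro_a", "micro_b"),
                       image_size = 32L, train = NULL, gndo = NULL,
                       fitness = NULL,
                       classifiers = c("narrow", "medium", "wide",
                                       "bilayered", "trilayered"),
                       classifier_epochs = 80L, cv_folds = 10L,
                       ttest_pair = c("medium", "trilayered"),
                       out_dir = tempfile("planefusion_run_"), seed = 1L) {
  if (is.character(dataset) && !dir.exists(dataset))
    stop_planefusion(sprintf("dataset directory '%s' does not exist", dataset),
                     "config_error")
  if (length(models) != 2)
    stop_planefusion("exactly two models are required", "config_error")
  if (!all(ttest_pair %in% classifiers) || length(ttest_pair) != 2)
    stop_planefusion("ttest_pair must name two of the configured classifiers",
                     "config_error")
  structure(list(dataset = dataset, models = models,
                 image_size = as.integer(image_size),
                 train = train %||% train_config(learning_rate = 0.04,
                                                 mini_batch = 32L,
                                                 momentum = 0.9,
                                                 l2_weight = 1e-4,
                                                 max_epochs = 15L),
                 gndo = gndo %||% gndo_config(20L, 60L),
                 fitness = fitness %||% fitness_spec(),
                 classifiers = classifiers,
                 classifier_epochs = as.integer(classifier_epochs),
                 cv_folds = as.integer(cv_folds), ttest_pair = ttest_pair,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

resolve_model <- function(m, k, shape) {
  if (inherits(m, "model_graph")) return(m)
  switch(m,
    micro_a = micro_cnn_graph(k, shape, width = 8L, gap_width = 32L),
    micro_b = micro_cnn_graph(k, shape, width = 10L, gap_width = 48L),
    three_residual = build_three_residual_model(k, shape),
    four_residual = build_four_residual_model(k, shape),
    stop_planefusion(sprintf("unknown model '%s'", m), "config_error"))
}

pipeline_log <- function(path, msg) {
  line <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), msg)
  cat(line, "\n", file = path, append = TRUE)
  message(line)
}

run_stage <- function(name, log_path, code) {
  pipeline_log(log_path, sprintf("stage %s: start", name))
  out <- tryCatch(force(code), error = function(e) {
    pipeline_log(log_path, sprintf("stage %s: FAILED (%s)", name,
                                   conditionMessage(e)))
    stop_planefusion(sprintf("stage '%s' failed: %s", name,
                             conditionMessage(e)), "stage_error")
  })
  pipeline_log(log_path, sprintf("stage %s: done", name))
  out
}

#' Run the full classification pipeline
#'
#' Executes the five experiments in order — deep features of each of the
#' two trained CNNs, the selected subset of each, and their serial
#' fusion — scoring every configured shallow classifier on each feature
#' set by stratified cross-validation, then comparing the configured
#' classifier pair with the paired accuracy t-test. Every stochastic
#' stage is seeded from the global seed and logged; artifacts are
#' written under `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return an object of class `run_report`: list with `accuracy_table`
#'   (experiment x classifier, percent), `metrics` (nested
#'   [metrics_report()]s), `selections` (per-block widths), `fused_width`,
#'   `ttest` (a `ttest_report`), and `artifacts` (paths).
#' @export
run_full_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  seed <- config$seed
  pipeline_log(log_path, sprintf("pipeline start (seed %d)", seed))

  imgs <- run_stage("data", log_path, {
    if (is.character(config$dataset))
      load_image_dir(config$dataset, size = config$image_size)
    else
      generate_plane_images(config$dataset, channels = 3L)
  })
  k <- length(imgs$class_names)
  shape <- c(config$image_size, config$image_size, 3L)

  sp <- run_stage("split", log_path,
    split_dataset(imgs$labels, 0.5, seed = seed + 1L))
  subset_imgs <- function(idx)
    image_set(imgs$images[idx],
              factor(imgs$class_names[imgs$labels[idx]],
                     levels = imgs$class_names))
  train_set <- subset_imgs(sp$train)
  test_set <- subset_imgs(sp$test)

  graphs <- lapply(config$models, resolve_model, k = k, shape = shape)
  names(graphs) <- c("model_a", "model_b")
  fits <- list(); feats <- list()
  for (j in 1:2) {
    nm <- names(graphs)[j]
    cfg <- config$train; cfg$seed <- seed + 1L + j
    fits[[nm]] <- run_stage(paste0("train_", nm), log_path,
                            train_model(graphs[[j]], train_set, cfg))
    feats[[nm]] <- run_stage(paste0("extract_", nm), log_path,
                             extract_features(fits[[nm]], test_set,
                                              source_model = nm))
    utils::write.csv(fits[[nm]]$loss_trace,
                     file.path(config$out_dir, paste0("loss_", nm, ".csv")),
                     row.names = FALSE)
    write_feature_matrix(feats[[nm]],
                         file.path(config$out_dir,
                                   paste0("features_", nm, ".csv")))
  }

  sels <- list(); selected <- list()
  for (j in 1:2) {
    nm <- names(graphs)[j]
    fit_spec <- config$fitness; fit_spec$seed <- seed + 13L + j
    gcfg <- config$gndo; gcfg$seed <- seed + 3L + j
    sels[[nm]] <- run_stage(paste0("select_", nm), log_path,
                            igndo_select(feats[[nm]], fit_spec, gcfg))
    selected[[nm]] <- apply_selection(feats[[nm]], sels[[nm]])
    write_selection_result(sels[[nm]],
                           file.path(config$out_dir,
                                     paste0("selection_", nm, ".json")))
  }
  fused <- run_stage("fuse", log_path,
                     serial_fuse(selected$model_a, selected$model_b))
  write_feature_matrix(fused, file.path(config$out_dir, "features_fused.csv"))
  pipeline_log(log_path, sprintf(
    "selected widths: %d + %d -> fused %d",
    sels$model_a$selected_width, sels$model_b$selected_width,
    ncol(fused$values)))

  experiments <- list(raw_a = feats$model_a, raw_b = feats$model_b,
                      selected_a = selected$model_a,
                      selected_b = selected$model_b, fused = fused)
  metrics <- list()
  acc <- matrix(NA_real_, length(experiments), length(config$classifiers),
                dimnames = list(names(experiments), config$classifiers))
  run_stage("classify", log_path, {
    for (en in names(experiments)) {
      metrics[[en]] <- list()
      for (family in config$classifiers) {
        spec <- classifier_spec(family, max_epochs = config$classifier_epochs,
                                seed = seed + 7L)
        rep <- kfold_cv(spec, experiments[[en]], k = config$cv_folds,
                        seed = seed + 6L)
        metrics[[en]][[family]] <- rep
        acc[en, family] <- rep$accuracy
        write_metrics_report(rep, file.path(
          config$out_dir, sprintf("metrics_%s_%s.json", en, family)))
      }
      pipeline_log(log_path, sprintf(
        "experiment %s: accuracies %s", en,
        paste(sprintf("%s=%.1f", config$classifiers, acc[en, ]),
              collapse = " ")))
    }
    invisible(NULL)
  })

  tt <- run_stage("ttest", log_path,
    paired_diff_ttest(pmax(acc[, config$ttest_pair[1]],
                           acc[, config$ttest_pair[2]]),
                      pmin(acc[, config$ttest_pair[1]],
                           acc[, config$ttest_pair[2]])))
  write_ttest_report(tt, file.path(config$out_dir, "ttest.json"))

  report <- structure(list(
    accuracy_table = as.data.frame(acc), metrics = metrics,
    selections = list(model_a = sels$model_a$selected_width,
                      model_b = sels$model_b$selected_width),
    fused_width = ncol(fused$values), ttest = tt,
    class_names = imgs$class_names, seed = seed,
    artifacts = list.files(config$out_dir, full.names = TRUE)),
    class = "run_report")
  jsonlite::write_json(
    list(seed = seed, class_names = imgs$class_names,
         accuracy_table = as.data.frame(acc),
         selected_widths = report$selections,
         fused_width = report$fused_width),
    file.path(config$out_dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  pipeline_log(log_path, "pipeline done")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> pooled CV accuracy (%) by experiment and classifier:\n")
  print(round(x$accuracy_table, 2))
  cat(sprintf("selected widths %d + %d -> fused %d\n",
              x$selections$model_a, x$selections$model_b, x$fused_width))
  cat(sprintf("t-test: t = %.4f, interval (%.3f, %.3f) -> %s\n",
              x$ttest$t, x$ttest$interval[1], x$ttest$interval[2],
              if (x$ttest$significant) "significant" else "not significant"))
  invisible(x)
}
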