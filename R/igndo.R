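# Wrapper feature selection: GNDO over continuous positions, scored by a
# held-out inner classifier, finished by the binary-cross-entropy
# threshold that turns the best position's scores into a feature mask.

#' Map optimizer positions to selection scores
#'
#' Logistic transform, componentwise; scores are strictly inside (0, 1).
#'
#' @param position finite numeric vector.
#' @return numeric vector of scores in (0, 1).
#' @export
position_to_scores <- function(position) {
  if (any(!is.finite(position)))
    stop_planefusion("position must be finite", "argument_error")
  # clip so scores stay strictly inside (0, 1) even for extreme positions
  clamp(logistic(position), 1e-12, 1 - 1e-12)
}

#' Binary cross-entropy of a score vector
#'
#' `CE = -(1/D) * sum(b * log(p) + (1 - b) * log(1 - p))` where
#' `b = 1` if the score is at least 0.5 and 0 otherwise — the entropy of
#' the scores against their own binarization. Confident scores (near 0
#' or 1) give a small CE; maximally uncertain scores give `log(2)`.
#' Scores are clipped to `[1e-12, 1 - 1e-12]` before the logs.
#'
#' @param scores numeric vector of selection scores in (0, 1).
#' @return scalar CE, `>= 0`.
#' @export
compute_cross_entropy <- function(scores) {
  if (!length(scores))
    stop_planefusion("scores must be non-empty", "argument_error")
  p <- clamp(scores, 1e-12, 1 - 1e-12)
  b <- as.numeric(p >= 0.5)
  -mean(b * log(p) + (1 - b) * log(1 - p))
}

#' Threshold scores into a selection mask
#'
#' Feature `j` is selected iff `score_j >= threshold`. If no feature
#' clears the threshold the rule falls back to 0.5 (with a warning), and
#' as a last resort selects the single best-scoring feature, so the mask
#' is never empty.
#'
#' @param scores numeric selection scores.
#' @param threshold scalar threshold, typically [compute_cross_entropy()]
#'   of the scores; must be `>= 0`.
#' @return an object of class `selection_result`: list with `scores`,
#'   `threshold`, `mask` (0/1 integer vector), `selected_width` and
#'   `fallback` flag.
#' @export
threshold_select <- function(scores, threshold) {
  if (threshold < 0)
    stop_planefusion("threshold must be >= 0", "argument_error")
  mask <- as.integer(scores >= threshold)
  fallback <- FALSE
  if (!sum(mask)) {
    warning("no score reached the cross-entropy threshold; falling back to 0.5")
    fallback <- TRUE
    mask <- as.integer(scores >= 0.5)
  }
  if (!sum(mask)) mask[which.max(scores)] <- 1L
  structure(list(scores = scores, threshold = threshold, mask = mask,
                 selected_width = sum(mask), fallback = fallback),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d / %d features, threshold %.4f\n",
              x$selected_width, length(x$mask), x$threshold))
  invisible(x)
}

#' Inner fitness specification for wrapper selection
#'
#' A candidate position is scored by the hold-out error of a
#' nearest-centroid classifier restricted to the columns whose logistic
#' score reaches 0.5, plus a small smooth sparsity term:
#' `fitness = (1 - w) * error + w * mean(scores)` with
#' `w = sparsity_weight`. The mean score is a continuous surrogate for
#' the selected width, so the search keeps receiving a sparsity signal
#' even while the binary mask (and hence the error) is unchanged. The
#' hold-out split is stratified, drawn once per run from `seed`.
#'
#' @param evaluator inner classifier identifier (`"nearest_centroid"`).
#' @param validation_fraction held-out fraction in (0, 1).
#' @param sparsity_weight weight of the mask-width term.
#' @param seed integer seed for the hold-out split.
#' @return an object of class `fitness_spec`.
#' @export
fitness_spec <- function(evaluator = "nearest_centroid",
                         validation_fraction = 0.3,
                         sparsity_weight = 0.01, seed = 1L) {
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop_planefusion("validation_fraction must be in (0, 1)", "config_error")
  if (!identical(evaluator, "nearest_centroid"))
    stop_planefusion(sprintf("unknown evaluator '%s'", evaluator), "config_error")
  structure(list(evaluator = evaluator,
                 validation_fraction = validation_fraction,
                 sparsity_weight = sparsity_weight, seed = as.integer(seed)),
            class = "fitness_spec")
}

# Nearest-centroid error on the held-out rows, masked columns only.
centroid_error <- function(X, labels, train_idx, val_idx, cols) {
  Xtr <- X[train_idx, cols, drop = FALSE]
  Xval <- X[val_idx, cols, drop = FALSE]
  classes <- sort(unique(labels[train_idx]))
  cents <- do.call(rbind, lapply(classes, function(cl)
    colMeans(Xtr[labels[train_idx] == cl, , drop = FALSE])))
  # squared Euclidean distance to each centroid
  d2 <- outer(rowSums(Xval^2), rep(1, length(classes))) -
    2 * Xval %*% t(cents) +
    outer(rep(1, length(val_idx)), rowSums(cents^2))
  pred <- classes[max.col(-d2, ties.method = "first")]
  mean(pred != labels[val_idx])
}

#' Select features with the improved GNDO algorithm
#'
#' Runs [gndo_minimize()] over one continuous position per feature in
#' bounds `[-4, 4]`; a position's fitness is the inner-classifier
#' hold-out error restricted to columns whose logistic score reaches
#' 0.5 (see [fitness_spec()]). On termination the best position's
#' scores are passed through [compute_cross_entropy()] and
#' [threshold_select()] to produce the final mask.
#'
#' @param features a [feature_matrix()] with at least 2 classes and
#'   2 columns.
#' @param fitness a [fitness_spec()].
#' @param config a [gndo_config()].
#' @return a `selection_result` with an extra `gndo` element (the
#'   underlying `gndo_result`).
#' @export
igndo_select <- function(features, fitness = fitness_spec(),
                         config = gndo_config()) {
  X <- features$values
  labels <- features$labels
  if (length(unique(labels)) < 2)
    stop_planefusion("feature selection needs at least 2 classes", "data_error")
  if (ncol(X) < 2)
    stop_planefusion("feature selection needs at least 2 columns", "data_error")
  # standardize so no column dominates the centroid distances
  mu <- colMeans(X); sd <- pmax(apply(X, 2, stats::sd), 1e-8)
  X <- sweep(sweep(X, 2, mu, "-"), 2, sd, "/")
  d <- ncol(X)
  val_idx <- local_seed(fitness$seed, {
    out <- integer(0)
    f <- factor(labels)
    for (cl in levels(f)) {
      idx <- which(f == cl)
      nv <- max(1L, floor(length(idx) * fitness$validation_fraction))
      out <- c(out, sample(idx, nv))
    }
    sort(out)
  })
  train_idx <- setdiff(seq_along(labels), val_idx)
  w <- fitness$sparsity_weight
  objective <- function(position) {
    sc <- logistic(position)
    cols <- which(sc >= 0.5)
    if (!length(cols)) return(2)  # empty mask: worse than any real error
    err <- centroid_error(X, labels, train_idx, val_idx, cols)
    (1 - w) * err + w * mean(sc)
  }
  res <- gndo_minimize(objective, gndo_bounds(rep(-4, d), rep(4, d)), config)
  scores <- position_to_scores(res$best$position)
  sel <- threshold_select(scores, compute_cross_entropy(scores))
  sel$gndo <- res
  sel
}

#' Apply a selection mask to a feature matrix
#'
#' @param features a [feature_matrix()].
#' @param selection a `selection_result` over its columns.
#' @return the column-subset [feature_matrix()].
#' @export
apply_selection <- function(features, selection) {
  if (length(selection$mask) != ncol(features$values))
    stop_planefusion("selection mask width does not match feature width",
                     "data_error")
  feature_matrix(features$values[, selection$mask == 1L, drop = FALSE],
                 features$labels, features$class_names,
                 paste0(features$source_model, ":selected"))
}

#' Persist a selection result
#'
#' Writes a JSON document with the threshold, 0-based selected indices,
#' selected width and per-feature scores; optionally also a one-column
#' CSV mask aligned to the feature columns.
#'
#' @param selection a `selection_result`.
#' @param path JSON output path.
#' @param mask_csv optional CSV path for the 0/1 mask.
#' @export
write_selection_result <- function(selection, path, mask_csv = NULL) {
  doc <- list(threshold = selection$threshold,
              selected_indices = which(selection$mask == 1L) - 1L,
              width = selection$selected_width,
              fallback = selection$fallback,
              scores = selection$scores)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(mask_csv))
    utils::write.csv(data.frame(mask = selection$mask), mask_csv,
                     row.names = FALSE)
  invisible(path)
}
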