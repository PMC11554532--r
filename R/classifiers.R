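# The five shallow fully connected classifiers applied to deep-feature
# blocks, with hidden layouts mirroring common classification-app
# defaults: narrow (10), medium (25), wide (100), bilayered (10, 10),
# trilayered (10, 10, 10); relu hidden activation, softmax output.
# Trained with the package's SGDM engine on standardized features.

shallow_layouts <- list(narrow = 10L, medium = 25L, wide = 100L,
                        bilayered = c(10L, 10L), trilayered = c(10L, 10L, 10L))

#' Shallow neural-network classifier specification
#'
#' @param family one of `"narrow"`, `"medium"`, `"wide"`, `"bilayered"`,
#'   `"trilayered"`; fixes the hidden layout unless `hidden` is given.
#' @param hidden optional explicit neurons-per-hidden-layer vector.
#' @param max_epochs training epochs.
#' @param learning_rate SGDM step size.
#' @param mini_batch mini-batch size.
#' @param seed integer seed (initialization and shuffling).
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("narrow", "medium", "wide",
                                       "bilayered", "trilayered"),
                            hidden = NULL, max_epochs = 120L,
                            learning_rate = 0.05, mini_batch = 32L,
                            seed = 1L) {
  family <- match.arg(family)
  hidden <- as.integer(hidden %||% shallow_layouts[[family]])
  structure(list(family = family, hidden = hidden,
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 mini_batch = as.integer(mini_batch),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

# Fully connected graph: input(1x1xD) -> [fc -> relu]* -> fc(k) -> softmax.
mlp_graph <- function(d, hidden, k) {
  layers <- list(layer_spec("input", "input"))
  edges <- list()
  last <- "input"
  for (i in seq_along(hidden)) {
    fc <- sprintf("fc_%d", i); rl <- sprintf("relu_%d", i)
    layers <- c(layers, list(layer_spec(fc, "fc", depth = hidden[i]),
                             layer_spec(rl, "relu")))
    edges <- c(edges, list(c(last, fc), c(fc, rl)))
    last <- rl
  }
  layers <- c(layers, list(layer_spec("fc_out", "fc", depth = k),
                           layer_spec("softmax", "softmax")))
  edges <- c(edges, list(c(last, "fc_out"), c("fc_out", "softmax")))
  model_graph(layers, edges, k, c(1L, 1L, d))
}

#' Train a shallow neural-network classifier
#'
#' @param spec a [classifier_spec()].
#' @param X a [feature_matrix()] with at least 2 classes and finite
#'   values.
#' @param row_idx optional training-row subset (all rows by default).
#' @return an object of class `shallow_nn` holding the fitted network,
#'   the standardization used, and the spec.
#' @export
train_shallow_nn <- function(spec, X, row_idx = NULL) {
  row_idx <- row_idx %||% seq_len(nrow(X$values))
  vals <- X$values[row_idx, , drop = FALSE]
  labels <- X$labels[row_idx]
  if (length(unique(labels)) < 2)
    stop_planefusion("classifier training needs at least 2 classes", "data_error")
  center <- colMeans(vals)
  scale <- pmax(apply(vals, 2, stats::sd), 1e-8)
  Z <- sweep(sweep(vals, 2, center, "-"), 2, scale, "/")
  k <- length(X$class_names)
  graph <- mlp_graph(ncol(Z), spec$hidden, k)
  net <- init_network(graph, seed = spec$seed)
  cfg <- train_config(learning_rate = spec$learning_rate,
                      mini_batch = spec$mini_batch, momentum = 0.9,
                      l2_weight = 1e-4, max_epochs = spec$max_epochs,
                      validation_fraction = 0, seed = spec$seed)
  out <- train_core(net, Z, labels, 1L, cfg)
  structure(list(network = out$net, loss_trace = out$trace, spec = spec,
                 center = center, scale = scale,
                 class_names = X$class_names), class = "shallow_nn")
}

#' @export
print.shallow_nn <- function(x, ...) {
  cat(sprintf("<shallow_nn> %s: hidden (%s), %d classes\n", x$spec$family,
              paste(x$spec$hidden, collapse = ", "), length(x$class_names)))
  invisible(x)
}

#' Predict class probabilities from a shallow classifier
#'
#' @param object a `shallow_nn`.
#' @param X a [feature_matrix()] (or numeric matrix) with the training
#'   feature width.
#' @param ... unused.
#' @return numeric matrix of class probabilities.
#' @export
predict.shallow_nn <- function(object, X, ...) {
  vals <- if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
  Z <- sweep(sweep(vals, 2, object$center, "-"), 2, object$scale, "/")
  p <- network_predict(object$network, Z, nrow(Z))
  colnames(p) <- object$class_names
  p
}

#' Evaluate a fitted classifier on a labeled feature matrix
#'
#' @param classifier a `shallow_nn`.
#' @param X a [feature_matrix()] with labels.
#' @return a [metrics_report()].
#' @export
evaluate <- function(classifier, X) {
  probs <- predict(classifier, X)
  metrics_report(X$labels, probs, X$class_names)
}

# Stratified fold assignment; returns integer fold id per sample.
stratified_folds <- function(labels, k, seed) {
  local_seed(seed, {
    folds <- integer(length(labels))
    f <- factor(labels)
    for (cl in levels(f)) {
      idx <- sample(which(f == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
  })
}

#' Stratified k-fold cross-validation
#'
#' Builds stratified folds, trains one classifier per fold, pools all
#' held-out predictions and scores them once. `k = n` gives
#' leave-one-out; otherwise, if some class has fewer than `k` members,
#' `k` is reduced to the smallest class size with a warning.
#'
#' @param spec a [classifier_spec()].
#' @param X a [feature_matrix()].
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return a [metrics_report()] on the pooled predictions, with the fold
#'   assignment attached as attribute `"folds"`.
#' @export
kfold_cv <- function(spec, X, k = 10L, seed = 1L) {
  n <- nrow(X$values)
  if (k > n)
    stop_planefusion(sprintf("k = %d exceeds sample count %d", k, n),
                     "config_error")
  if (k == n) {
    folds <- seq_len(n)  # leave-one-out
  } else {
    min_class <- min(table(X$labels))
    if (min_class < k) {
      warning(sprintf("smallest class has %d members; reducing folds to %d",
                      min_class, min_class))
      k <- min_class
    }
    folds <- stratified_folds(X$labels, k, seed)
  }
  probs <- matrix(NA_real_, n, length(X$class_names))
  for (fold in sort(unique(folds))) {
    test_idx <- which(folds == fold)
    fit <- train_shallow_nn(spec, X, row_idx = which(folds != fold))
    probs[test_idx, ] <- predict(
      fit, X$values[test_idx, , drop = FALSE])
  }
  rep <- metrics_report(X$labels, probs, X$class_names)
  attr(rep, "folds") <- folds
  rep
}
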