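# Dataset splitting, SGDM training and GAP-layer feature extraction.

#' Training configuration
#'
#' Defaults are the Bayesian-optimization-selected training
#' hyperparameters: learning rate 0.000274, mini-batch 128, momentum
#' 0.699, L2 weight 1e-6, stochastic gradient descent with momentum.
#'
#' @param learning_rate positive step size.
#' @param mini_batch mini-batch size (clamped to the dataset size).
#' @param momentum momentum coefficient in `[0, 1)`.
#' @param l2_weight L2 penalty on weight matrices.
#' @param max_epochs maximum training epochs.
#' @param validation_fraction fraction held out for early stopping
#'   (0 disables).
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed controlling initialization and shuffling.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.000274, mini_batch = 128L,
                         momentum = 0.699, l2_weight = 1e-6,
                         max_epochs = 50L, validation_fraction = 0.1,
                         patience = 10L, seed = 1L) {
  if (learning_rate <= 0) stop_planefusion("learning_rate must be > 0", "config_error")
  if (momentum < 0 || momentum >= 1)
    stop_planefusion("momentum must be in [0, 1)", "config_error")
  if (mini_batch < 1) stop_planefusion("mini_batch must be >= 1", "config_error")
  structure(list(learning_rate = learning_rate,
                 mini_batch = as.integer(mini_batch), momentum = momentum,
                 l2_weight = l2_weight, max_epochs = as.integer(max_epochs),
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified train/test split
#'
#' Splits sample indices class by class: each class contributes
#' `ceiling(n_class * train_fraction)` training samples (so a 1386-image
#' class at 0.5 gives 693/693 and a 1281-image class gives 641/640), the
#' rest go to test. Deterministic under `seed`.
#'
#' @param labels class labels (factor, character or integer).
#' @param train_fraction fraction of each class assigned to training.
#' @param stratified if `FALSE`, a single unstratified draw is used.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`, disjoint
#'   and jointly exhaustive.
#' @export
split_dataset <- function(labels, train_fraction = 0.5, stratified = TRUE,
                          seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_planefusion("train_fraction must be in (0, 1)", "config_error")
  f <- as.factor(labels)
  counts <- table(f)
  if (any(counts == 0))
    stop_planefusion(sprintf("class '%s' has no samples",
                             names(counts)[counts == 0][1]), "data_error")
  local_seed(seed, {
    train <- integer(0)
    if (stratified) {
      for (cl in levels(f)) {
        idx <- which(f == cl)
        n_tr <- ceiling(length(idx) * train_fraction)
        train <- c(train, sort(sample(idx, n_tr)))
      }
    } else {
      train <- sort(sample(seq_along(f), ceiling(length(f) * train_fraction)))
    }
    list(train = sort(train), test = setdiff(seq_along(f), train))
  })
}

#' Labeled image set
#'
#' @param images list of `height x width x channels` numeric arrays with
#'   values in `[0, 1]`.
#' @param labels class labels (coerced to factor).
#' @return an object of class `image_set`.
#' @export
image_set <- function(images, labels) {
  f <- as.factor(labels)
  if (length(images) != length(f))
    stop_planefusion("images and labels lengths differ", "data_error")
  structure(list(images = images, labels = as.integer(f),
                 class_names = levels(f)), class = "image_set")
}

# Convert a list of H x W x C arrays to the engine's activation layout.
images_to_activation <- function(images, shape) {
  h <- shape[1]; w <- shape[2]; ch <- shape[3]
  do.call(rbind, lapply(images, function(a) {
    if (!identical(as.integer(dim(a)), as.integer(shape)))
      stop_planefusion(sprintf("image of shape %s does not match model input %s",
                               paste(dim(a), collapse = "x"),
                               paste(shape, collapse = "x")), "data_error")
    matrix(a, h * w, ch)
  }))
}

# Resize a grayscale matrix (bilinear) and replicate to `channels`.
prep_image <- function(a, size, channels = 3L) {
  if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)  # to grayscale
  if (!all(dim(a) == size))
    a <- as.matrix(EBImage::resize(EBImage::Image(a), w = size, h = size))
  a <- clamp(a, 0, 1)
  array(rep(a, channels), c(size, size, channels))
}

#' Load a folder-per-class image dataset
#'
#' Expects `root/class_name/*.png`; images are loaded grayscale,
#' bilinearly resized to `size x size`, replicated to `channels`
#' channels and scaled to `[0, 1]`.
#'
#' @param root dataset root directory.
#' @param size target square side in pixels.
#' @param channels channel count expected by the model.
#' @return an [image_set()].
#' @export
load_image_dir <- function(root, size = 224L, channels = 3L) {
  if (!dir.exists(root))
    stop_planefusion(sprintf("dataset directory '%s' does not exist", root),
                     "data_error")
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (!length(classes))
    stop_planefusion(sprintf("no class folders under '%s'", root), "data_error")
  images <- list(); labels <- character(0)
  for (cl in classes) {
    files <- sort(list.files(file.path(root, cl), pattern = "\\.png$",
                             full.names = TRUE, ignore.case = TRUE))
    if (!length(files))
      stop_planefusion(sprintf("class '%s' has no images", cl), "data_error")
    for (fp in files) {
      a <- png::readPNG(fp)
      images[[length(images) + 1L]] <- prep_image(a, size, channels)
      labels <- c(labels, cl)
    }
  }
  image_set(images, labels)
}

# Core SGDM loop over an activation matrix with `hw` rows per sample.
train_core <- function(net, A, labels, hw, config) {
  n <- length(labels)
  rows_for <- function(idx)
    as.vector(outer(seq_len(hw), (idx - 1L) * hw, "+"))
  state <- new.env(parent = emptyenv())
  trace <- data.frame(epoch = integer(0), loss = numeric(0),
                      val_loss = numeric(0))
  local_seed(config$seed, {
    val_idx <- integer(0)
    if (config$validation_fraction > 0 && n >= 10) {
      f <- factor(labels)
      for (cl in levels(f)) {
        idx <- which(f == cl)
        nv <- floor(length(idx) * config$validation_fraction)
        if (nv > 0) val_idx <- c(val_idx, sample(idx, nv))
      }
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    mb <- min(config$mini_batch, length(tr_idx))
    best_val <- Inf; best_params <- NULL; wait <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample(tr_idx)
      losses <- numeric(0)
      for (start in seq(1, length(perm), by = mb)) {
        bidx <- perm[start:min(start + mb - 1L, length(perm))]
        bA <- A[rows_for(bidx), , drop = FALSE]
        fwd <- network_forward(net, bA, length(bidx), train = TRUE)
        probs <- fwd$acts[[net$order[length(net$order)]]]
        loss <- cross_entropy_loss(probs, labels[bidx])
        if (!is.finite(loss))
          stop_planefusion(
            "training diverged (non-finite loss); try a lower learning rate",
            "training_error")
        losses <- c(losses, loss)
        grads <- network_backward(net, fwd, labels[bidx], length(bidx))
        net <- sgdm_step(net, grads, state, config$learning_rate,
                         config$momentum, config$l2_weight)
        for (bn in names(fwd$caches)) {
          cc <- fwd$caches[[bn]]
          if (!is.null(cc$run_mean)) {
            net$params[[bn]]$run_mean <- cc$run_mean
            net$params[[bn]]$run_var <- cc$run_var
          }
        }
      }
      val_loss <- NA_real_
      if (length(val_idx)) {
        vp <- network_predict(net, A[rows_for(val_idx), , drop = FALSE],
                              length(val_idx))
        val_loss <- cross_entropy_loss(vp, labels[val_idx])
        if (val_loss < best_val - 1e-8) {
          best_val <- val_loss; best_params <- net$params; wait <- 0L
        } else wait <- wait + 1L
      }
      trace <- rbind(trace, data.frame(epoch = epoch, loss = mean(losses),
                                       val_loss = val_loss))
      if (length(val_idx) && wait >= config$patience) break
    }
    if (!is.null(best_params)) net$params <- best_params
  })
  list(net = net, trace = trace)
}

#' Train a network graph on a labeled image set
#'
#' Stochastic gradient descent with momentum and L2 penalty, minimizing
#' cross-entropy. A stratified validation slice drives early stopping
#' (see [train_config()]). The mini-batch shrinks to the dataset size
#' when larger.
#'
#' @param graph a [model_graph()] whose `num_classes` matches the label set.
#' @param images an [image_set()].
#' @param config a [train_config()].
#' @return an object of class `trained_network` with elements `network`,
#'   `loss_trace` (data.frame `epoch`, `loss`, `val_loss`), `class_names`
#'   and `config`.
#' @export
train_model <- function(graph, images, config = train_config()) {
  if (length(unique(images$labels)) < 2)
    stop_planefusion("training needs at least 2 classes", "data_error")
  net <- init_network(graph, seed = config$seed)
  A <- images_to_activation(images$images, graph$input_shape)
  hw <- prod(graph$input_shape[1:2])
  out <- train_core(net, A, images$labels, hw, config)
  structure(list(network = out$net, loss_trace = out$trace,
                 class_names = images$class_names, config = config,
                 input_shape = graph$input_shape),
            class = "trained_network")
}

#' @export
print.trained_network <- function(x, ...) {
  cat(sprintf("<trained_network> %d layers, %d epochs, final loss %.4f\n",
              length(x$network$graph$layers), nrow(x$loss_trace),
              utils::tail(x$loss_trace$loss, 1)))
  invisible(x)
}

#' Predict class probabilities
#'
#' @param object a `trained_network`.
#' @param images an [image_set()] (labels may be arbitrary).
#' @param ... unused.
#' @return matrix of class probabilities, one row per image.
#' @export
predict.trained_network <- function(object, images, ...) {
  if (!length(images$images))
    return(matrix(numeric(0), 0, object$network$graph$num_classes))
  A <- images_to_activation(images$images, object$input_shape)
  p <- network_predict(object$network, A, length(images$images))
  colnames(p) <- object$class_names
  p
}

#' Extract deep features from the global-average-pooling layer
#'
#' Runs the trained model forward in inference mode and returns the GAP
#' activations, one row per image in input order.
#'
#' @param model a `trained_network` (or `planefusion_network`).
#' @param images an [image_set()].
#' @param batch_size forward-pass batch size.
#' @param source_model identifier recorded on the output.
#' @return a [feature_matrix()] of shape `n_images x gap_width`.
#' @export
extract_features <- function(model, images, batch_size = 32L,
                             source_model = "model") {
  net <- if (inherits(model, "trained_network")) model$network else model
  gap_name <- names(net$graph$layers)[
    vapply(net$graph$layers, function(l) l$kind, "") == "gap"]
  if (!length(gap_name))
    stop_planefusion("model has no global-average-pooling layer", "graph_error")
  gap_name <- gap_name[1]
  width <- net$shapes[[gap_name]][3]
  n <- length(images$images)
  if (n == 0)
    return(feature_matrix(matrix(numeric(0), 0, width), integer(0),
                          images$class_names, source_model))
  shape <- net$graph$input_shape
  hw <- prod(shape[1:2])
  out <- matrix(NA_real_, n, width)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    A <- images_to_activation(images$images[idx], shape)
    fwd <- network_forward(net, A, length(idx), train = FALSE)
    out[idx, ] <- fwd$acts[[gap_name]]
  }
  feature_matrix(out, images$labels, images$class_names, source_model)
}
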