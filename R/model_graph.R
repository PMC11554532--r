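#' Layer specification
#'
#' A single layer of a network graph. Only the fields meaningful for the
#' layer kind are set: `depth` (filter / unit count) for `conv` and `fc`,
#' `kernel` and `stride` (pixels) for `conv` and `maxpool`, `padding`
#' (`"same"` or `"valid"`) for spatial layers.
#'
#' @param name unique layer identifier.
#' @param kind one of `"input"`, `"conv"`, `"relu"`, `"maxpool"`,
#'   `"batchnorm"`, `"add"`, `"gap"`, `"fc"`, `"softmax"`.
#' @param depth filter count (conv) or output width (fc).
#' @param kernel spatial kernel extent in pixels (conv, maxpool).
#' @param stride stride in pixels (conv, maxpool).
#' @param padding `"same"` keeps `ceiling(dim / stride)` spatial dims;
#'   `"valid"` uses only full windows.
#' @return an object of class `layer_spec`.
#' @export
layer_spec <- function(name, kind, depth = NULL, kernel = NULL, stride = NULL,
                       padding = "same") {
  kinds <- c("input", "conv", "relu", "maxpool", "batchnorm", "add", "gap",
             "fc", "softmax")
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_planefusion("layer name must be a non-empty string", "graph_error")
  if (!kind %in% kinds)
    stop_planefusion(sprintf("unknown layer kind '%s'", kind), "graph_error")
  if (kind %in% c("conv", "fc")) {
    if (is.null(depth) || depth < 1)
      stop_planefusion(sprintf("layer '%s': %s layers need depth >= 1", name, kind),
                       "graph_error")
  }
  if (kind %in% c("conv", "maxpool")) {
    if (is.null(kernel) || kernel < 1 || is.null(stride) || stride < 1)
      stop_planefusion(sprintf("layer '%s': %s layers need kernel >= 1 and stride >= 1",
                               name, kind), "graph_error")
    if (!padding %in% c("same", "valid"))
      stop_planefusion(sprintf("layer '%s': padding must be 'same' or 'valid'", name),
                       "graph_error")
  }
  structure(list(name = name, kind = kind,
                 depth = if (!is.null(depth)) as.integer(depth),
                 kernel = if (!is.null(kernel)) as.integer(kernel),
                 stride = if (!is.null(stride)) as.integer(stride),
                 padding = if (kind %in% c("conv", "maxpool")) padding),
            class = "layer_spec")
}

#' Network graph
#'
#' An ordered collection of [layer_spec()] nodes plus directed edges.
#' Validates: unique names, acyclicity, in-degrees (`input` 0, `add` 2,
#' all others 1), and that every sink is a `softmax` layer.
#'
#' @param layers list of [layer_spec()] objects.
#' @param edges two-column character matrix (or list of length-2 vectors)
#'   of `(src, dst)` layer names; skip connections are ordinary edges into
#'   `add` layers.
#' @param num_classes number of output classes (>= 2).
#' @param input_shape integer triple `c(height, width, channels)`.
#' @return an object of class `model_graph`.
#' @export
model_graph <- function(layers, edges, num_classes, input_shape) {
  if (is.list(edges)) edges <- do.call(rbind, edges)
  edges <- matrix(as.character(edges), ncol = 2)
  nms <- vapply(layers, function(l) l$name, "")
  if (anyDuplicated(nms))
    stop_planefusion(sprintf("duplicate layer name '%s'", nms[duplicated(nms)][1]),
                     "graph_error")
  names(layers) <- nms
  if (num_classes < 2)
    stop_planefusion("num_classes must be >= 2", "config_error")
  if (length(input_shape) != 3 || any(input_shape < 1))
    stop_planefusion("input_shape must be c(height, width, channels), all >= 1",
                     "config_error")
  bad <- setdiff(c(edges), nms)
  if (length(bad))
    stop_planefusion(sprintf("edge references unknown layer '%s'", bad[1]),
                     "graph_error")
  g <- structure(list(layers = layers, edges = edges,
                      num_classes = as.integer(num_classes),
                      input_shape = as.integer(input_shape)),
                 class = "model_graph")
  validate_graph(g)
  g
}

in_edges <- function(graph, name) graph$edges[graph$edges[, 2] == name, 1]

# Kahn topological order; errors on cycles.
topo_order <- function(graph) {
  nms <- names(graph$layers)
  indeg <- vapply(nms, function(n) sum(graph$edges[, 2] == n), 0L)
  order <- character(0)
  ready <- nms[indeg == 0L]
  while (length(ready)) {
    # keep declaration order for determinism
    n <- ready[order(match(ready, nms))][1]
    ready <- setdiff(ready, n)
    order <- c(order, n)
    for (m in graph$edges[graph$edges[, 1] == n, 2]) {
      indeg[m] <- indeg[m] - 1L
      if (indeg[m] == 0L) ready <- c(ready, m)
    }
  }
  if (length(order) != length(nms))
    stop_planefusion("graph contains a cycle", "graph_error")
  order
}

validate_graph <- function(graph) {
  for (l in graph$layers) {
    deg <- length(in_edges(graph, l$name))
    want <- switch(l$kind, input = 0L, add = 2L, 1L)
    if (deg != want)
      stop_planefusion(sprintf("layer '%s' (%s) has %d inbound edges, expected %d",
                               l$name, l$kind, deg, want), "graph_error")
  }
  topo_order(graph)
  srcs <- graph$edges[, 1]
  sinks <- names(graph$layers)[!names(graph$layers) %in% srcs]
  kinds <- vapply(graph$layers[sinks], function(l) l$kind, "")
  if (!length(sinks) || any(kinds != "softmax"))
    stop_planefusion("every terminal layer must be a softmax", "graph_error")
  invisible(graph)
}

# Output spatial extent of a windowed layer.
out_dim <- function(dim, kernel, stride, padding) {
  if (padding == "same") ceiling(dim / stride)
  else floor((dim - kernel) / stride) + 1L
}

#' Shape inference and parameter count
#'
#' Walks the graph in topological order, computing every layer's output
#' shape, verifying that both inputs of each `add` layer agree, and
#' counting learnable parameters: `kernel^2 * in * depth + depth` for
#' conv, `in * out + out` for fc, `2 * channels` for batchnorm; all other
#' kinds contribute none.
#'
#' @param graph a [model_graph()].
#' @return an object of class `shape_report`: list with `shapes` (named
#'   list of `c(h, w, c)`), `params` (named numeric), `total_params`, and
#'   `gap_width` (channels at the global-average-pooling output, `NA` if
#'   the graph has no gap layer).
#' @export
infer_shapes <- function(graph) {
  shapes <- list()
  params <- numeric(length(graph$layers))
  names(params) <- names(graph$layers)
  gap_width <- NA_integer_
  for (n in topo_order(graph)) {
    l <- graph$layers[[n]]
    ins <- lapply(in_edges(graph, n), function(m) shapes[[m]])
    s <- switch(l$kind,
      input = graph$input_shape,
      conv = {
        i <- ins[[1]]
        h <- out_dim(i[1], l$kernel, l$stride, l$padding)
        w <- out_dim(i[2], l$kernel, l$stride, l$padding)
        params[n] <- l$kernel^2 * i[3] * l$depth + l$depth
        c(h, w, l$depth)
      },
      maxpool = {
        i <- ins[[1]]
        c(out_dim(i[1], l$kernel, l$stride, l$padding),
          out_dim(i[2], l$kernel, l$stride, l$padding), i[3])
      },
      batchnorm = { params[n] <- 2 * ins[[1]][3]; ins[[1]] },
      add = {
        if (!identical(as.integer(ins[[1]]), as.integer(ins[[2]])))
          stop_planefusion(sprintf(
            "shape mismatch at add layer '%s': %s vs %s (mis-specified shortcut)",
            n, paste(ins[[1]], collapse = "x"), paste(ins[[2]], collapse = "x")),
            "graph_error")
        ins[[1]]
      },
      gap = { gap_width <- ins[[1]][3]; c(1L, 1L, ins[[1]][3]) },
      fc = {
        params[n] <- prod(ins[[1]]) * l$depth + l$depth
        c(1L, 1L, l$depth)
      },
      ins[[1]]  # relu, softmax
    )
    if (any(s < 1))
      stop_planefusion(sprintf(
        "layer '%s': output dimension collapses below 1 (%s)",
        n, paste(s, collapse = "x")), "graph_error")
    shapes[[n]] <- as.integer(s)
  }
  structure(list(shapes = shapes, params = params,
                 total_params = sum(params), gap_width = gap_width),
            class = "shape_report")
}

#' @export
print.model_graph <- function(x, ...) {
  cat(sprintf("<model_graph> %d layers, input %s, %d classes\n",
              length(x$layers), paste(x$input_shape, collapse = "x"),
              x$num_classes))
  invisible(x)
}

#' @export
print.shape_report <- function(x, ...) {
  cat(sprintf("<shape_report> %d layers, %s parameters, gap width %s\n",
              length(x$shapes), format(x$total_params, big.mark = ","),
              x$gap_width))
  invisible(x)
}
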