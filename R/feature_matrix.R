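#' Labeled feature matrix
#'
#' Samples-by-features matrix with class labels, the common currency
#' between feature extraction, selection, fusion and classification.
#'
#' @param values numeric matrix, one row per sample; all values finite.
#' @param labels integer class indices (1-based) or factor/character.
#' @param class_names class names; inferred from `labels` if omitted.
#' @param source_model identifier of the producing model.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, class_names = NULL,
                           source_model = "unknown") {
  values <- as.matrix(values)
  if (is.null(class_names)) {
    f <- as.factor(labels)
    class_names <- levels(f)
    labels <- as.integer(f)
  }
  labels <- as.integer(labels)
  if (nrow(values) != length(labels))
    stop_planefusion("row count does not match label count", "data_error")
  if (length(values) && any(!is.finite(values)))
    stop_planefusion("feature matrix contains non-finite values", "data_error")
  structure(list(values = values, labels = labels,
                 class_names = class_names, source_model = source_model),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features, %d classes (%s)\n",
              nrow(x$values), ncol(x$values), length(x$class_names),
              x$source_model))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Write / read a feature matrix as CSV
#'
#' Column header is `f0001 ... fNNNN, label`; labels are written as class
#' names.
#'
#' @param fm a [feature_matrix()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  d <- ncol(fm$values)
  df <- as.data.frame(fm$values)
  names(df) <- sprintf("f%04d", seq_len(d))
  df$label <- fm$class_names[fm$labels]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @param source_model identifier recorded on the loaded matrix.
#' @export
read_feature_matrix <- function(path, source_model = basename(path)) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df))
    stop_planefusion(sprintf("'%s' has no label column", path), "parse_error")
  f <- as.factor(df$label)
  vals <- as.matrix(df[setdiff(names(df), "label")])
  feature_matrix(vals, as.integer(f), levels(f), source_model)
}

#' Serial fusion of two feature blocks
#'
#' Columnwise concatenation of two feature matrices over the same
#' samples: the fused width is the sum of the two widths (e.g. 652- and
#' 742-wide selected blocks fuse to 1394), columns ordered a-then-b,
#' labels preserved.
#'
#' @param block_a,block_b [feature_matrix()] objects with equal row
#'   counts and identical label vectors.
#' @return a [feature_matrix()] of width `ncol(a) + ncol(b)`.
#' @export
serial_fuse <- function(block_a, block_b) {
  if (nrow(block_a$values) != nrow(block_b$values))
    stop_planefusion("serial fusion requires equal row counts", "data_error")
  if (!identical(block_a$labels, block_b$labels))
    stop_planefusion("serial fusion requires identical label vectors", "data_error")
  feature_matrix(cbind(block_a$values, block_b$values), block_a$labels,
                 block_a$class_names,
                 paste(block_a$source_model, block_b$source_model, sep = "+"))
}
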