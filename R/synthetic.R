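# Synthetic test inputs: toy ultrasound-plane-like images (distinct
# geometric motifs under a fan mask with multiplicative Rayleigh
# speckle) and feature matrices with a planted informative column set,
# so every pipeline stage is exercisable with known ground truth and no
# external data.

#' Synthetic image-set specification
#'
#' Each class is a distinct geometric motif echoing a fetal biometry
#' view: filled ellipse (abdominal circumference), ring (biparietal
#' skull outline), bright bar (femur), or pure speckle (no plane), all
#' under a fan-shaped insonation mask with multiplicative Rayleigh
#' speckle. Motifs are jittered (position +-10%, scale +-15%) so the
#' task is not trivially template-matchable.
#'
#' @param class_names subset of `"abdominal_circumference"`,
#'   `"biparietal_diameter"`, `"femur_length"`, `"no_plane"`.
#' @param per_class images per class.
#' @param size square image side in pixels.
#' @param speckle Rayleigh scale of the multiplicative speckle.
#' @param seed integer seed; the same seed reproduces identical pixels.
#' @return an object of class `image_set_spec`.
#' @export
image_set_spec <- function(class_names = c("abdominal_circumference",
                                           "biparietal_diameter",
                                           "femur_length", "no_plane"),
                           per_class = 50L, size = 64L, speckle = 1,
                           seed = 1L) {
  known <- c("abdominal_circumference", "biparietal_diameter",
             "femur_length", "no_plane")
  bad <- setdiff(class_names, known)
  if (length(bad))
    stop_planefusion(sprintf("unknown class template '%s'", bad[1]),
                     "config_error")
  if (per_class < 1 || size < 16)
    stop_planefusion("per_class must be >= 1 and size >= 16", "config_error")
  structure(list(class_names = class_names, per_class = as.integer(per_class),
                 size = as.integer(size), speckle = speckle,
                 seed = as.integer(seed)), class = "image_set_spec")
}

# Fan-shaped insonation mask: sector from an apex above the image.
fan_mask <- function(s) {
  x <- matrix(rep(seq_len(s), each = s), s) / s - 0.5
  y <- matrix(rep(seq_len(s), times = s), s) / s + 0.12
  r <- sqrt(x^2 + y^2)
  ang <- atan2(x, y)
  r < 1.05 & abs(ang) < 0.62
}

# Noise-free class template in [0, 1].
plane_template <- function(class_name, s) {
  x <- matrix(rep(seq_len(s), each = s), s) / s
  y <- matrix(rep(seq_len(s), times = s), s) / s
  jit <- function(v, amt) v * stats::runif(1, 1 - amt, 1 + amt)
  cx <- 0.5 + stats::runif(1, -0.05, 0.05)
  cy <- 0.55 + stats::runif(1, -0.05, 0.05)
  base <- matrix(0.18, s, s)
  tmpl <- switch(class_name,
    abdominal_circumference = {
      rx <- jit(0.24, 0.15); ry <- jit(0.20, 0.15)
      d <- ((x - cx) / rx)^2 + ((y - cy) / ry)^2
      base + 0.55 * (d < 1)
    },
    biparietal_diameter = {
      rx <- jit(0.26, 0.15); ry <- jit(0.19, 0.15)
      d <- ((x - cx) / rx)^2 + ((y - cy) / ry)^2
      base + 0.65 * (d < 1 & d > 0.62)
    },
    femur_length = {
      len <- jit(0.30, 0.15); th <- jit(0.035, 0.15)
      ang <- stats::runif(1, -0.45, 0.45)
      u <- (x - cx) * cos(ang) + (y - cy) * sin(ang)
      v <- -(x - cx) * sin(ang) + (y - cy) * cos(ang)
      base + 0.70 * (abs(u) < len & abs(v) < th)
    },
    no_plane = base + 0.07)
  tmpl
}

rayleigh <- function(n, sigma) sigma * sqrt(-2 * log(stats::runif(n)))

# One synthetic frame: template x Rayleigh speckle, clipped, fan-masked.
plane_image <- function(class_name, s, speckle) {
  tmpl <- plane_template(class_name, s)
  # Rayleigh scaled so the speckle field has unit mean at sigma = 1
  noise <- matrix(rayleigh(s * s, speckle) / sqrt(pi / 2), s, s)
  img <- clamp(tmpl * noise, 0, 1)
  img[!fan_mask(s)] <- 0
  img
}

#' Generate a synthetic ultrasound-plane image set
#'
#' @param spec an [image_set_spec()].
#' @param dir optional output directory; when given, images are written
#'   as 8-bit grayscale PNGs in a folder-per-class layout.
#' @param channels channel count of the returned arrays (grayscale
#'   replicated).
#' @return an [image_set()]; when `dir` is given, the files are written
#'   and the set returned invisibly.
#' @export
generate_plane_images <- function(spec, dir = NULL, channels = 3L) {
  images <- list(); labels <- character(0)
  local_seed(spec$seed, {
    for (cl in spec$class_names) {
      if (!is.null(dir)) {
        d <- file.path(dir, cl)
        if (!dir.exists(d) && !dir.create(d, recursive = TRUE))
          stop_planefusion(sprintf("cannot create directory '%s'", d), "io_error")
      }
      for (i in seq_len(spec$per_class)) {
        img <- plane_image(cl, spec$size, spec$speckle)
        # quantize to 8 bits so in-memory and on-disk pixels agree
        img <- round(img * 255) / 255
        if (!is.null(dir))
          png::writePNG(img, file.path(dir, cl, sprintf("%s_%03d.png", cl, i)))
        images[[length(images) + 1L]] <-
          array(rep(img, channels), c(spec$size, spec$size, channels))
        labels <- c(labels, cl)
      }
    }
  })
  out <- image_set(images, labels)
  if (is.null(dir)) out else invisible(out)
}

#' Planted-feature specification
#'
#' Feature matrices with a known informative column subset: informative
#' columns carry class-dependent means of magnitude `effect / 2` (in
#' within-class standard-deviation units, distinct cyclic sign patterns
#' per class so all classes are mutually separable), remaining columns
#' are standard normal noise. Classes are balanced.
#'
#' @param n total samples (divided evenly over classes).
#' @param d feature count.
#' @param informative integer indices of informative columns.
#' @param effect between-class mean shift in within-class SD units.
#' @param k number of classes.
#' @param seed integer seed.
#' @return an object of class `planted_feature_spec`.
#' @export
planted_feature_spec <- function(n = 300L, d = 100L, informative = 1:10,
                                 effect = 2, k = 4L, seed = 1L) {
  if (any(informative < 1 | informative > d))
    stop_planefusion("informative indices must lie in [1, d]", "argument_error")
  if (k < 2) stop_planefusion("k must be >= 2", "argument_error")
  if (effect < 0) stop_planefusion("effect must be >= 0", "argument_error")
  structure(list(n = as.integer(n), d = as.integer(d),
                 informative = as.integer(sort(unique(informative))),
                 effect = effect, k = as.integer(k), seed = as.integer(seed)),
            class = "planted_feature_spec")
}

#' Generate a planted feature matrix
#'
#' @param spec a [planted_feature_spec()].
#' @return list with `features` (a [feature_matrix()]) and
#'   `informative` (the ground-truth column indices).
#' @export
generate_feature_matrix <- function(spec) {
  local_seed(spec$seed, {
    labels <- rep(seq_len(spec$k), length.out = spec$n)
    X <- matrix(stats::rnorm(spec$n * spec$d), spec$n, spec$d)
    # cyclic +-1/2 sign pattern: class c, j-th informative column
    base <- rep(c(0.5, -0.5), each = ceiling(spec$k / 2))[seq_len(spec$k)]
    for (jj in seq_along(spec$informative)) {
      j <- spec$informative[jj]
      shift <- spec$effect * base[((labels + jj - 1L) %% spec$k) + 1L]
      X[, j] <- X[, j] + shift
    }
    list(features = feature_matrix(X, labels,
                                   sprintf("class_%d", seq_len(spec$k)),
                                   "planted"),
         informative = spec$informative)
  })
}

#' Write a miniature fixture bundle
#'
#' Emits a complete toy experiment — a small image set, a planted
#' feature matrix and the generating configuration — plus a JSON
#' manifest listing every emitted file with its MD5 checksum.
#'
#' @param dir output directory.
#' @param image_spec an [image_set_spec()].
#' @param feature_spec a [planted_feature_spec()].
#' @param force overwrite an existing non-empty directory.
#' @return the manifest, invisibly.
#' @export
write_fixture_bundle <- function(dir,
                                 image_spec = image_set_spec(per_class = 5L,
                                                             size = 32L),
                                 feature_spec = planted_feature_spec(n = 60L,
                                                                     d = 20L,
                                                                     informative = 1:4),
                                 force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop_planefusion(sprintf(
      "directory '%s' exists and is non-empty; use force = TRUE", dir),
      "io_error")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  generate_plane_images(image_spec, dir = file.path(dir, "images"))
  fm <- generate_feature_matrix(feature_spec)
  write_feature_matrix(fm$features, file.path(dir, "features.csv"))
  yaml::write_yaml(list(image_spec = unclass(image_spec),
                        feature_spec = unclass(feature_spec)),
                   file.path(dir, "config.yaml"))
  files <- sort(list.files(dir, recursive = TRUE))
  files <- files[files != "manifest.json"]
  manifest <- list(
    seeds = list(images = image_spec$seed, features = feature_spec$seed),
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(file.path(dir, f))))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
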