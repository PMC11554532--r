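test_that("position scores are logistic and monotone", {
  expect_identical(position_to_scores(0), 0.5)
  expect_equal(position_to_scores(10), 0.9999546, tolerance = 1e-6)
  x <- sort(stats::rnorm(50))
  expect_true(all(diff(position_to_scores(x)) > 0))
  expect_true(all(position_to_scores(c(-50, 50)) > 0 &
                    position_to_scores(c(-50, 50)) < 1))
  expect_error(position_to_scores(c(1, NA)), class = "argument_error")
})

test_that("binary cross-entropy matches hand arithmetic", {
  expect_equal(compute_cross_entropy(rep(0.5, 7)), log(2), tolerance = 1e-12)
  expect_equal(compute_cross_entropy(c(0.9, 0.1)), -log(0.9),
               tolerance = 1e-12)
  # confident, self-consistent scores drive the entropy to zero
  expect_lt(compute_cross_entropy(c(1e-15, 1 - 1e-15)), 1e-9)
  expect_error(compute_cross_entropy(numeric(0)), class = "argument_error")
})

test_that("thresholding selects scores at or above the threshold", {
  sel <- threshold_select(c(0.9, 0.2, 0.7), 0.6)
  expect_identical(sel$mask, c(1L, 0L, 1L))
  expect_identical(sel$selected_width, 2L)
  expect_false(sel$fallback)

  expect_warning(fb <- threshold_select(c(0.3, 0.6, 0.2), 0.95), "fall")
  expect_identical(fb$mask, c(0L, 1L, 0L))
  expect_true(fb$fallback)

  all_in <- threshold_select(c(0.1, 0.5, 0.9), 0)
  expect_identical(all_in$selected_width, 3L)
  # mask is never empty, even when every score is below 0.5 too
  expect_warning(last <- threshold_select(c(0.1, 0.3, 0.2), 0.9))
  expect_identical(last$selected_width, 1L)
  expect_identical(which(last$mask == 1L), 2L)
})

test_that("thresholding is idempotent on already-binarized scores", {
  # confident scores: the entropy threshold reproduces the binarization
  conf <- c(0.01, 0.99, 0.01, 0.99, 0.99)
  s1 <- threshold_select(conf, compute_cross_entropy(conf))
  expect_identical(s1$mask, c(0L, 1L, 0L, 1L, 1L))
  # and rerunning the thresholding never changes the mask
  for (scores in list(conf, c(1e-12, 1 - 1e-12, 1e-12),
                      stats::runif(20))) {
    a <- suppressWarnings(threshold_select(scores,
                                           compute_cross_entropy(scores)))
    b <- suppressWarnings(threshold_select(scores,
                                           compute_cross_entropy(scores)))
    expect_identical(a$mask, b$mask)
  }
})

test_that("serial fusion concatenates columns and preserves labels", {
  labels <- rep(1:2, 10)
  a <- feature_matrix(matrix(stats::rnorm(20 * 652), 20), labels,
                      c("x", "y"), "block_a")
  b <- feature_matrix(matrix(stats::rnorm(20 * 742), 20), labels,
                      c("x", "y"), "block_b")
  fused <- serial_fuse(a, b)
  expect_identical(ncol(fused$values), 1394L)
  expect_identical(fused$labels, labels)
  expect_identical(fused$values[, 3], a$values[, 3])
  expect_identical(fused$values[, 652 + 5], b$values[, 5])

  empty <- feature_matrix(matrix(numeric(0), 20, 0), labels, c("x", "y"))
  expect_identical(serial_fuse(a, empty)$values, a$values)
  # associativity in width
  c3 <- feature_matrix(matrix(1, 20, 7), labels, c("x", "y"))
  expect_identical(ncol(serial_fuse(serial_fuse(a, b), c3)$values),
                   652L + 742L + 7L)

  bad <- feature_matrix(matrix(1, 20, 3), rev(labels), c("x", "y"))
  expect_error(serial_fuse(a, bad), class = "data_error")
  expect_error(serial_fuse(a, feature_matrix(matrix(1, 10, 3), labels[1:10],
                                             c("x", "y"))),
               class = "data_error")
})

test_that("a perfectly label-aligned column is always selected", {
  withr::local_seed(5)
  n <- 60
  labels <- rep(1:2, n / 2)
  X <- matrix(stats::rnorm(n * 8), n, 8)
  X[, 3] <- labels  # the label itself
  fm <- feature_matrix(X, labels, c("a", "b"))
  # oracle: an exhaustive single-feature nearest-centroid scan must pick
  # column 3 (zero error by construction)
  errs <- vapply(1:8, function(j) {
    cents <- c(mean(X[labels == 1, j]), mean(X[labels == 2, j]))
    pred <- apply(abs(outer(X[, j], cents, "-")), 1, which.min)
    mean(pred != labels)
  }, 0)
  expect_identical(which.min(errs), 3L)
  expect_identical(errs[3], 0)
  for (seed in 1:3) {
    sel <- igndo_select(fm, fitness_spec(seed = seed),
                        gndo_config(20, 30, seed = seed * 11))
    expect_identical(sel$mask[3], 1L)
  }
})

test_that("selection works from the initial population alone", {
  pf <- tiny_planted(n = 80, d = 10, informative = 1:3, seed = 2)
  sel <- igndo_select(pf$features, fitness_spec(seed = 1),
                      gndo_config(20, 0, seed = 1))
  expect_s3_class(sel, "selection_result")
  expect_gte(sel$selected_width, 1L)
  expect_length(sel$mask, 10)
})

test_that("planted informative features are recovered", {
  pf <- tiny_planted(n = 200, d = 30, informative = 1:6, seed = 3)
  sel <- igndo_select(pf$features, fitness_spec(seed = 1),
                      gndo_config(20, 50, seed = 7))
  recall <- mean(pf$informative %in% which(sel$mask == 1L))
  expect_gte(recall, 0.8)
  expect_lt(sel$selected_width, 30)
  expect_gte(sel$selected_width, 1)
})

test_that("degenerate selection inputs are rejected", {
  one_class <- feature_matrix(matrix(stats::rnorm(40), 10), rep(1, 10), "a")
  expect_error(igndo_select(one_class), class = "data_error")
  thin <- feature_matrix(matrix(stats::rnorm(10), 10, 1), rep(1:2, 5),
                         c("a", "b"))
  expect_error(igndo_select(thin), class = "data_error")
})

test_that("selection results persist to JSON with 0-based indices", {
  sel <- threshold_select(c(0.9, 0.2, 0.7), 0.6)
  path <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_selection_result(sel, path, mask_csv = csv)
  doc <- jsonlite::fromJSON(path)
  expect_identical(doc$selected_indices, c(0L, 2L))
  expect_identical(doc$width, 2L)
  expect_identical(utils::read.csv(csv)$mask, c(1L, 0L, 1L))
})
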