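test_that("perfect predictions give the boundary metric values", {
  truth <- rep(1:4, each = 25)
  rep <- metrics_report(truth, onehot_probs(truth, 4))
  expect_identical(rep$accuracy, 100)
  expect_identical(rep$f1, 100)
  expect_identical(rep$fnr, 0)
  expect_equal(rep$mcc, 1, tolerance = 1e-12)
  expect_equal(rep$kappa, 1, tolerance = 1e-12)
})

test_that("perfectly anticorrelated binary predictions give MCC -1", {
  truth <- rep(1:2, each = 50)
  pred <- 3L - truth  # [[50,0],[0,50]] flipped to [[0,50],[50,0]]
  rep <- metrics_report(truth, onehot_probs(pred, 2))
  expect_equal(rep$mcc, -1, tolerance = 1e-12)
  expect_identical(rep$accuracy, 0)
})

test_that("label-independent predictions have near-zero kappa", {
  withr::local_seed(12)
  truth <- rep(1:4, each = 2500)
  pred <- sample(1:4, 1e4, replace = TRUE)
  rep <- metrics_report(truth, onehot_probs(pred, 4))
  expect_lt(abs(rep$kappa), 0.05)
  expect_lt(abs(rep$mcc), 0.05)
})

test_that("metric formulas agree with brute force on 200 random cases", {
  withr::local_seed(77)
  skip_if_not_installed("e1071")
  for (case in 1:200) {
    k <- sample(2:5, 1)
    n <- sample(30:100, 1)
    truth <- sample(seq_len(k), n, replace = TRUE)
    # bias predictions toward the truth so all regimes appear
    pred <- ifelse(stats::runif(n) < 0.6, truth,
                   sample(seq_len(k), n, replace = TRUE))
    if (length(unique(truth)) < 2) next
    rep <- suppressMessages(metrics_report(truth, onehot_probs(pred, k)))
    bf <- brute_metrics(truth, pred, k)
    expect_equal(rep$accuracy, bf$accuracy, tolerance = 1e-10)
    expect_equal(rep$precision, bf$precision, tolerance = 1e-10)
    expect_equal(rep$recall, bf$recall, tolerance = 1e-10)
    expect_equal(rep$f1, bf$f1, tolerance = 1e-10)
    expect_equal(rep$fnr, 100 - bf$recall, tolerance = 1e-10)
    expect_equal(rep$mcc, bf$mcc, tolerance = 1e-10)
    # independent kappa route
    cm <- rep$confusion
    expect_equal(rep$kappa, e1071::classAgreement(cm)$kappa,
                 tolerance = 1e-10)
  }
})

test_that("macro metrics are invariant to class relabeling", {
  withr::local_seed(5)
  truth <- sample(1:3, 200, replace = TRUE)
  pred <- ifelse(stats::runif(200) < 0.7, truth,
                 sample(1:3, 200, replace = TRUE))
  perm <- c(3L, 1L, 2L)
  r1 <- metrics_report(truth, onehot_probs(pred, 3))
  r2 <- metrics_report(perm[truth], onehot_probs(perm[pred], 3))
  for (f in c("accuracy", "precision", "recall", "f1", "mcc", "kappa"))
    expect_equal(r1[[f]], r2[[f]], tolerance = 1e-12)
})

test_that("the paired accuracy t-test reproduces the published chain", {
  high <- c(97.5, 97.7, 97.6, 98.0, 98.5)
  low <- c(96.9, 97.6, 97.0, 96.9, 98.4)
  tt <- paired_diff_ttest(high, low)
  expect_equal(tt$diffs, c(0.6, 0.1, 0.6, 1.1, 0.1), tolerance = 1e-12)
  expect_equal(tt$mu, 0.5, tolerance = 1e-12)
  expect_equal(tt$sigma_rounded, 0.4183)
  expect_equal(tt$t_rounded, 2.6728)
  expect_identical(tt$df, 4L)
  expect_false(tt$significant)  # 2.6728 sits inside (-2.776, 2.776)

  fetal <- paired_diff_ttest(c(78.3, 83.9, 78.8, 83.5, 88.6),
                             c(75.2, 83.6, 74.8, 83.4, 87.1))
  expect_equal(fetal$diffs, c(3.1, 0.3, 4.0, 0.1, 1.5), tolerance = 1e-12)
  expect_equal(fetal$mu, 1.8, tolerance = 1e-12)
})

test_that("degenerate difference vectors are handled explicitly", {
  same <- paired_diff_ttest(c(90, 91, 92), c(90, 91, 92))
  expect_identical(same$mu, 0)
  expect_false(same$significant)
  const <- paired_diff_ttest(c(91, 92, 93), c(90, 91, 92))
  expect_true(const$degenerate)
  expect_identical(const$t, Inf)
  expect_true(const$significant)
  expect_error(paired_diff_ttest(1:3, 1:4), class = "argument_error")
  expect_error(paired_diff_ttest(1, 1), class = "argument_error")
})

test_that("the t-test matches an independent recomputation", {
  withr::local_seed(31)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    high <- 90 + stats::runif(n, 0, 5)
    low <- high - stats::runif(n, 0, 3)
    tt <- paired_diff_ttest(high, low)
    ref <- stats::t.test(abs(high - low), mu = 0)
    expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(tt$df, unname(ref$parameter))
  }
})

test_that("critical t values match the Student-t distribution", {
  expect_equal(critical_t(0.05, 4), 2.776, tolerance = 5e-4)
  expect_equal(critical_t(0.05, 1e6), 1.960, tolerance = 1e-3)
  tt <- paired_diff_ttest(c(1, 2, 3), c(0, 1, 1))
  expect_identical(tt$interval, c(-tt$critical, tt$critical))
  expect_error(critical_t(1.5, 4), class = "argument_error")
  expect_error(critical_t(0.05, 0), class = "argument_error")
})

test_that("shallow classifiers are deterministic and introspectable", {
  pf <- tiny_planted(n = 120, d = 12, informative = 1:4, seed = 6)
  spec <- classifier_spec("trilayered", max_epochs = 20, seed = 4)
  expect_identical(spec$hidden, c(10L, 10L, 10L))
  f1 <- train_shallow_nn(spec, pf$features)
  f2 <- train_shallow_nn(spec, pf$features)
  expect_identical(predict(f1, pf$features), predict(f2, pf$features))
  kinds <- vapply(f1$network$graph$layers, function(l) l$kind, "")
  expect_identical(sum(kinds == "fc"), 4L)  # 3 hidden + output head
})

test_that("a narrow net beats the nearest-centroid baseline on planted data", {
  pf <- tiny_planted(n = 160, d = 10, informative = 1:4, k = 2, seed = 8)
  sp <- split_dataset(pf$features$labels, 0.5, seed = 1)
  fit <- train_shallow_nn(classifier_spec("narrow", max_epochs = 60),
                          pf$features, row_idx = sp$train)
  test_fm <- feature_matrix(pf$features$values[sp$test, ],
                            pf$features$labels[sp$test],
                            pf$features$class_names)
  acc <- evaluate(fit, test_fm)$accuracy
  # oracle baseline: nearest centroid on the training rows
  Xtr <- pf$features$values[sp$train, ]
  cents <- rbind(colMeans(Xtr[pf$features$labels[sp$train] == 1, ]),
                 colMeans(Xtr[pf$features$labels[sp$train] == 2, ]))
  d2 <- as.matrix(stats::dist(rbind(test_fm$values, cents)))
  nte <- nrow(test_fm$values)
  pred <- apply(d2[seq_len(nte), nte + (1:2)], 1, which.min)
  base <- 100 * mean(pred == test_fm$labels)
  expect_gt(acc, 90)
  expect_gte(acc, base - 5)
})

test_that("single-class classifier training is rejected", {
  fm <- feature_matrix(matrix(stats::rnorm(40), 10), rep(1, 10), "a")
  expect_error(train_shallow_nn(classifier_spec("narrow"), fm),
               class = "data_error")
})

test_that("k-fold assignment partitions samples and supports LOO", {
  pf <- tiny_planted(n = 20, d = 6, informative = 1:3, k = 2, seed = 9)
  rep <- kfold_cv(classifier_spec("narrow", max_epochs = 10), pf$features,
                  k = 20, seed = 1)
  folds <- attr(rep, "folds")
  expect_identical(sort(unique(folds)), 1:20)  # every fold of size one
  expect_identical(as.integer(table(folds)), rep(1L, 20))

  rep5 <- kfold_cv(classifier_spec("narrow", max_epochs = 10), pf$features,
                   k = 5, seed = 2)
  folds5 <- attr(rep5, "folds")
  expect_identical(length(folds5), 20L)
  expect_true(all(table(folds5, pf$features$labels) == 2))

  expect_error(kfold_cv(classifier_spec("narrow"), pf$features, k = 21),
               class = "config_error")
  expect_warning(kfold_cv(classifier_spec("narrow", max_epochs = 5),
                          pf$features, k = 15, seed = 1), "reducing")
})

test_that("pooled cross-validation accuracy is high on separable data", {
  pf <- tiny_planted(n = 120, d = 15, informative = 1:5, k = 2, seed = 10)
  rep <- kfold_cv(classifier_spec("narrow", max_epochs = 40), pf$features,
                  k = 10, seed = 3)
  expect_gt(rep$accuracy, 90)
  expect_gt(rep$auc, 0.9)
})
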