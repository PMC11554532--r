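sphere <- function(x) sum(x^2)

test_that("initialization respects bounds and the config contract", {
  withr::local_seed(1)
  b <- gndo_bounds(c(-2, 0, 10), c(1, 5, 11))
  pop <- initialize_population(b, gndo_config(10, 5, seed = 1), sphere)
  expect_identical(dim(pop$positions), c(10L, 3L))
  expect_true(all(sweep(pop$positions, 2, b$lower, ">=")))
  expect_true(all(sweep(pop$positions, 2, b$upper, "<=")))
  expect_identical(pop$best$fitness, min(pop$fitness))
  expect_error(gndo_bounds(c(0, 1), c(1, 1)), class = "bounds_error")
  expect_error(gndo_config(3), class = "config_error")
})

test_that("local exploitation follows the generalized mean and variance", {
  # all points coincide: mu = x, delta = 0, trial = x for any eta
  pop <- structure(list(
    positions = matrix(2.5, 4, 3), fitness = c(1, 2, 3, 4),
    best = list(position = rep(2.5, 3), fitness = 1),
    bounds = gndo_bounds(rep(-5, 3), rep(5, 3))), class = "gndo_population")
  withr::local_seed(8)
  expect_identical(local_exploitation(pop, 2), rep(2.5, 3))

  # y_i = 0, y_best = 3, M = 3: mu = 2, delta = sqrt(2)
  pop2 <- structure(list(
    positions = matrix(c(0, 3, 3, 6), 4, 1), fitness = c(1, 0, 2, 3),
    best = list(position = 3, fitness = 0),
    bounds = gndo_bounds(-10, 10)), class = "gndo_population")
  withr::with_seed(21, {
    trial <- local_exploitation(pop2, 1)
  })
  eta <- withr::with_seed(21, {
    gndo_penalty_factor(stats::runif(1), stats::runif(1),
                        stats::runif(1), stats::runif(1))
  })
  expect_equal(trial, 2 + sqrt(2) * eta, tolerance = 1e-12)
})

test_that("the penalty factor is symmetric with near-zero mean", {
  withr::local_seed(33)
  draws <- replicate(1e5, gndo_penalty_factor())
  expect_lt(abs(mean(draws)), 0.01)
  # heavy-tailed but mostly within [-1, 1]
  expect_gt(mean(abs(draws) <= 1), 0.75)
  expect_gt(max(abs(draws)), 1)
})

test_that("global exploration points toward fitter individuals", {
  # i is fittest and all partners coincide: v - y_i is a non-negative
  # multiple of (y_i - y_other), componentwise
  yi <- c(1, -1); yo <- c(3, 2)
  pop <- structure(list(
    positions = rbind(yi, yo, yo, yo), fitness = c(0, 5, 5, 5),
    best = list(position = yi, fitness = 0),
    bounds = gndo_bounds(rep(-10, 2), rep(10, 2))), class = "gndo_population")
  withr::local_seed(4)
  for (rep in 1:20) {
    v <- global_exploration(pop, 1)
    lam <- (v - yi) / (yi - yo)
    expect_equal(lam[1], lam[2], tolerance = 1e-9)
    expect_gte(lam[1], 0)
  }
  # all four coincide: trial collapses to y_i
  pop$positions <- rbind(yi, yi, yi, yi)
  pop$fitness <- rep(1, 4)
  expect_equal(global_exploration(pop, 1), yi, tolerance = 1e-12)
  pop$positions <- pop$positions[1:3, ]; pop$fitness <- pop$fitness[1:3]
  expect_error(global_exploration(pop, 1), class = "config_error")
})

test_that("partner indices are always distinct and never the focal index", {
  withr::local_seed(9)
  for (rep in 1:2000) {
    i <- sample(6, 1)
    p <- sample(setdiff(seq_len(6), i), 3L)  # the sampler used internally
    expect_length(unique(c(i, p)), 4)
  }
})

test_that("screening is greedy, monotone and bound-preserving", {
  withr::local_seed(17)
  b <- gndo_bounds(rep(-3, 4), rep(3, 4))
  pop <- initialize_population(b, gndo_config(8, 1, seed = 2), sphere)
  # explicit branch checks
  worse <- pop$positions + 10
  kept <- screen_population(pop, worse, sphere)
  expect_identical(kept$positions, pop$positions)
  better <- pop$positions * 0
  adopted <- screen_population(pop, better, sphere)
  expect_true(all(adopted$fitness == 0))
  # 100 random rounds on the sphere
  for (round in 1:100) {
    trials <- matrix(stats::rnorm(8 * 4, sd = 2), 8, 4)
    before <- min(pop$fitness)
    pop <- screen_population(pop, trials, sphere)
    expect_lte(min(pop$fitness), before)
    expect_true(all(pop$positions >= -3 & pop$positions <= 3))
    expect_identical(pop$best$fitness, min(pop$fitness))
  }
})

test_that("non-finite trial fitness is rejected with a message", {
  withr::local_seed(2)
  b <- gndo_bounds(rep(0, 2), rep(1, 2))
  pop <- initialize_population(b, gndo_config(4, 1, seed = 3), sphere)
  nasty <- function(x) if (x[1] < 2) NaN else sum(x^2)
  expect_message(out <- screen_population(pop, pop$positions * 0.5, nasty),
                 "non-finite")
  expect_identical(out$positions, pop$positions)
})

test_that("gndo_minimize honors its iteration and determinism contracts", {
  b <- gndo_bounds(rep(-5, 3), rep(5, 3))
  one <- gndo_minimize(sphere, b, gndo_config(6, 1, seed = 5))
  expect_identical(nrow(one$trace), 1L)
  r1 <- gndo_minimize(sphere, b, gndo_config(8, 25, seed = 9))
  r2 <- gndo_minimize(sphere, b, gndo_config(8, 25, seed = 9))
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best, r2$best)
  expect_true(all(diff(r1$trace$best_fitness) <= 0))
  const <- gndo_minimize(function(x) 4.5, b, gndo_config(6, 10, seed = 1))
  expect_identical(const$best$fitness, 4.5)
  expect_true(all(const$population$positions >= -5 &
                    const$population$positions <= 5))
})

test_that("the population mean matches its brute-force recomputation", {
  withr::local_seed(3)
  b <- gndo_bounds(rep(-2, 5), rep(2, 5))
  res <- gndo_minimize(sphere, b, gndo_config(7, 10, seed = 4))
  pos <- res$population$positions
  expect_equal(colMeans(pos),
               apply(pos, 2, function(col) sum(col) / length(col)),
               tolerance = 1e-12)
})
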