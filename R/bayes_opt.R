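# Gaussian-process Bayesian optimization with the expected-improvement
# acquisition, used to tune training hyperparameters (learning rate,
# mini-batch size, momentum) and exposed generically for any boxed
# objective. The surrogate is a Matern 5/2 GP with per-dimension
# lengthscales, fit by marginal-likelihood maximization; parameters are
# searched in a unit cube with log-scaled dimensions mapped back at
# evaluation time.

#' Hyperparameter search space
#'
#' @param params list of parameter definitions, each a list with `name`,
#'   `lower`, `upper`, and optionally `log = TRUE` (searched in log
#'   space) and `integer = TRUE` (rounded at evaluation time).
#' @return an object of class `search_space`.
#' @export
search_space <- function(params) {
  for (p in params) {
    if (is.null(p$name) || is.null(p$lower) || is.null(p$upper))
      stop_planefusion("every parameter needs name, lower, upper", "config_error")
    if (p$lower >= p$upper)
      stop_planefusion(sprintf("parameter '%s': lower must be < upper", p$name),
                       "config_error")
    if (isTRUE(p$log) && p$lower <= 0)
      stop_planefusion(sprintf("parameter '%s': log scale needs lower > 0", p$name),
                       "config_error")
  }
  structure(list(params = params, dim = length(params)), class = "search_space")
}

#' Default training-hyperparameter space
#'
#' Learning rate on a log scale over `[1e-5, 0.999]` (wide enough to
#' represent the published optimum 0.000274), integer mini-batch size
#' 16-256, momentum 0-1. Solver (SGDM) and the L2 penalty are fixed
#' settings, not searched.
#'
#' @return a [search_space()].
#' @export
default_hyperparameter_space <- function() {
  search_space(list(
    list(name = "learning_rate", lower = 1e-5, upper = 0.999, log = TRUE),
    list(name = "mini_batch", lower = 16, upper = 256, integer = TRUE),
    list(name = "momentum", lower = 0, upper = 1)))
}

# Map unit-cube coordinates to parameter values (and back).
space_decode <- function(space, u) {
  out <- list()
  for (j in seq_len(space$dim)) {
    p <- space$params[[j]]
    v <- if (isTRUE(p$log))
      exp(log(p$lower) + u[j] * (log(p$upper) - log(p$lower)))
    else p$lower + u[j] * (p$upper - p$lower)
    if (isTRUE(p$integer)) v <- as.integer(round(v))
    out[[p$name]] <- v
  }
  out
}

#' Expected improvement (minimization)
#'
#' With `z = (best - mean) / sd`:
#' `EI = sd * (z * pnorm(z) + dnorm(z))`; for `sd = 0` the degenerate
#' value `max(0, best - mean)`.
#'
#' @param pred_mean predictive mean(s).
#' @param pred_sd predictive standard deviation(s), `>= 0`.
#' @param best_so_far incumbent (lowest observed) objective value.
#' @return expected improvement, `>= 0`; vectorized.
#' @export
expected_improvement <- function(pred_mean, pred_sd, best_so_far) {
  if (any(pred_sd < 0))
    stop_planefusion("pred_sd must be >= 0", "argument_error")
  out <- pmax(0, best_so_far - pred_mean)
  pos <- pred_sd > 0
  if (any(pos)) {
    z <- (best_so_far - pred_mean[pos]) / pred_sd[pos]
    out[pos] <- pred_sd[pos] * (z * stats::pnorm(z) + stats::dnorm(z))
  }
  out
}

# --- Matern 5/2 GP ----------------------------------------------------

matern52 <- function(X1, X2, ell, sf2) {
  d <- ncol(X1)
  r2 <- matrix(0, nrow(X1), nrow(X2))
  for (j in seq_len(d))
    r2 <- r2 + outer(X1[, j], X2[, j], "-")^2 / ell[j]^2
  r <- sqrt(pmax(r2, 0))
  sf2 * (1 + sqrt(5) * r + 5 * r2 / 3) * exp(-sqrt(5) * r)
}

# Fit by marginal-likelihood maximization over log(ell), log(sf), log(sn).
fit_gp <- function(X, y) {
  X <- as.matrix(X)
  mu_y <- mean(y); sd_y <- max(stats::sd(y), 1e-8)
  ys <- (y - mu_y) / sd_y
  d <- ncol(X); n <- nrow(X)
  nll <- function(theta) {
    ell <- exp(theta[seq_len(d)]); sf2 <- exp(2 * theta[d + 1])
    sn2 <- exp(2 * theta[d + 2])
    K <- matern52(X, X, ell, sf2) + diag(sn2 + 1e-8, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    as.numeric(0.5 * sum(ys * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi))
  }
  start <- c(rep(log(0.3), d), log(1), log(1e-3))
  lower <- c(rep(log(0.02), d), log(0.05), log(1e-4))
  upper <- c(rep(log(10), d), log(10), log(1))
  opt <- tryCatch(
    stats::optim(start, nll, method = "L-BFGS-B", lower = lower, upper = upper),
    error = function(e) list(par = start))
  theta <- opt$par
  ell <- exp(theta[seq_len(d)]); sf2 <- exp(2 * theta[d + 1])
  sn2 <- exp(2 * theta[d + 2])
  K <- matern52(X, X, ell, sf2) + diag(sn2 + 1e-8, n)
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  structure(list(X = X, y = y, ys = ys, mu_y = mu_y, sd_y = sd_y,
                 ell = ell, sf2 = sf2, sn2 = sn2, chol = ch, alpha = alpha),
            class = "gp_posterior")
}

# Predictive mean and sd (on the original y scale) at unit-cube points.
predict_gp <- function(gp, Xnew) {
  Xnew <- matrix(Xnew, ncol = ncol(gp$X))
  Ks <- matern52(Xnew, gp$X, gp$ell, gp$sf2)
  mean_s <- as.numeric(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$chol), t(Ks))
  var_s <- pmax(gp$sf2 - colSums(v^2), 0)
  list(mean = mean_s * gp$sd_y + gp$mu_y, sd = sqrt(var_s) * gp$sd_y)
}

#' Propose the next configuration by maximizing expected improvement
#'
#' Scores a random candidate pool (plus a local refinement around the
#' pool's best) under the GP posterior and returns the EI-maximizing
#' candidate.
#'
#' @param posterior a fitted `gp_posterior` (>= 2 observations).
#' @param space a [search_space()].
#' @param n_pool size of the random candidate pool.
#' @return list with `unit` (unit-cube coordinates), `config` (decoded
#'   parameter values) and `ei`.
#' @export
propose_next <- function(posterior, space, n_pool = 2048L) {
  if (nrow(posterior$X) < 2)
    stop_planefusion("propose_next needs at least 2 observations", "argument_error")
  if (space$dim < 1)
    stop_planefusion("empty search space", "config_error")
  d <- space$dim
  best <- min(posterior$y)
  pool <- matrix(stats::runif(n_pool * d), n_pool, d)
  pr <- predict_gp(posterior, pool)
  ei <- expected_improvement(pr$mean, pr$sd, best)
  u0 <- pool[which.max(ei), ]
  neg_ei <- function(u) {
    p <- predict_gp(posterior, matrix(u, 1))
    -expected_improvement(p$mean, p$sd, best)
  }
  ref <- tryCatch(
    stats::optim(u0, neg_ei, method = "L-BFGS-B", lower = rep(0, d),
                 upper = rep(1, d)),
    error = function(e) list(par = u0, value = -max(ei)))
  u <- if (-ref$value >= max(ei)) ref$par else u0
  list(unit = u, config = space_decode(space, u),
       ei = max(-ref$value, max(ei)))
}

#' Bayesian-optimization search
#'
#' Space-filling (Latin hypercube) initial design followed by
#' GP-surrogate / expected-improvement iterations until the evaluation
#' budget is exhausted. Non-finite objective values are logged and
#' recorded with a large penalty.
#'
#' @param objective function taking a named list of parameter values and
#'   returning a scalar to minimize.
#' @param space a [search_space()].
#' @param budget total number of objective evaluations (>= 3).
#' @param seed integer seed.
#' @param n_init size of the initial design (default
#'   `min(budget, max(4, dim + 2))`).
#' @return an object of class `bo_result`: list with `best_config`,
#'   `best_value`, and `history` (data.frame: iteration, one column per
#'   parameter, `objective`).
#' @export
bo_search <- function(objective, space, budget, seed = 1L, n_init = NULL) {
  if (budget < 3)
    stop_planefusion("budget must be >= 3 (initial design)", "config_error")
  d <- space$dim
  n_init <- n_init %||% min(budget, max(4L, d + 2L))
  local_seed(seed, {
    U <- lhs::randomLHS(n_init, d)
    y <- numeric(0)
    configs <- list()
    eval_one <- function(u) {
      cfg <- space_decode(space, u)
      v <- tryCatch(objective(cfg), error = function(e) NaN)
      if (!is.finite(v)) {
        message("bo_search: objective evaluation failed; recording penalty")
        v <- if (length(y) && any(is.finite(y)))
          max(y[is.finite(y)]) + 3 * (diff(range(y[is.finite(y)])) + 1)
        else 1e6
      }
      configs[[length(configs) + 1L]] <<- cfg
      v
    }
    for (i in seq_len(n_init)) y <- c(y, eval_one(U[i, ]))
    while (length(y) < budget) {
      gp <- fit_gp(U, y)
      prop <- propose_next(gp, space)
      U <- rbind(U, prop$unit)
      y <- c(y, eval_one(prop$unit))
    }
    hist <- cbind(data.frame(iteration = seq_along(y)),
                  do.call(rbind, lapply(configs, as.data.frame)),
                  data.frame(objective = y))
    k <- which.min(y)
    structure(list(best_config = configs[[k]], best_value = y[k],
                   history = hist), class = "bo_result")
  })
}

#' @export
print.bo_result <- function(x, ...) {
  cat(sprintf("<bo_result> best objective %.6g after %d evaluations\n",
              x$best_value, nrow(x$history)))
  invisible(x)
}
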