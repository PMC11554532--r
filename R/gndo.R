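# Generalized normal distribution optimization (GNDO).
#
# A population metaheuristic whose update rules mimic sampling from
# generalized normal distributions. Each iteration every individual
# takes either a local-exploitation step (a draw around the generalized
# mean position, scaled by the generalized standard variance and a
# penalty factor) or a global-exploration step (signed differences
# toward fitter individuals), followed by greedy screening. Minimizes.
#
# RNG draw order (one shared stream, seeded from the config; fixed so
# traces are reproducible): initialization uses N*D uniforms row by row;
# per iteration, for each individual i in order: one uniform for the
# strategy switch alpha, then for the local branch the scalar pair
# (a, b) followed by the D-vectors lambda1 and lambda2, or for the
# global branch the permutation draw for (p1, p2, p3), one uniform
# beta and two standard normals.

#' Box bounds for GNDO
#'
#' @param lower,upper numeric vectors (recycled to a common length) with
#'   `lower < upper` componentwise.
#' @return an object of class `gndo_bounds`.
#' @export
gndo_bounds <- function(lower, upper) {
  d <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), d)
  upper <- rep_len(as.numeric(upper), d)
  if (any(lower >= upper))
    stop_planefusion("every lower bound must be strictly below its upper bound",
                     "bounds_error")
  structure(list(lower = lower, upper = upper, dim = d), class = "gndo_bounds")
}

#' GNDO configuration
#'
#' Defaults follow the published study settings: population size 20,
#' 200 iterations.
#'
#' @param pop_size population size N (>= 4: global exploration samples
#'   three distinct others).
#' @param max_iter iteration budget Tmax.
#' @param seed integer seed.
#' @return an object of class `gndo_config`.
#' @export
gndo_config <- function(pop_size = 20L, max_iter = 200L, seed = 1L) {
  if (pop_size < 4)
    stop_planefusion("pop_size must be >= 4", "config_error")
  if (max_iter < 0)
    stop_planefusion("max_iter must be >= 0", "config_error")
  structure(list(pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "gndo_config")
}

#' Initialize a GNDO population
#'
#' Positions are `lower + (upper - lower) * u` with `u ~ Uniform(0, 1)`
#' per component, drawn from the current RNG stream.
#'
#' @param bounds a [gndo_bounds()].
#' @param config a [gndo_config()].
#' @param objective optional objective; when given, fitness values are
#'   evaluated (non-finite values recorded as `Inf`).
#' @return an object of class `gndo_population` with `positions`
#'   (N x D), `fitness`, `best` (list `position`, `fitness`), `bounds`.
#' @export
initialize_population <- function(bounds, config, objective = NULL) {
  n <- config$pop_size; d <- bounds$dim
  pos <- matrix(NA_real_, n, d)
  for (i in seq_len(n))
    pos[i, ] <- bounds$lower + (bounds$upper - bounds$lower) * stats::runif(d)
  fit <- rep(NA_real_, n)
  if (!is.null(objective)) {
    fit <- apply(pos, 1, function(x) {
      v <- objective(x); if (is.finite(v)) v else Inf
    })
  }
  best <- if (all(is.na(fit))) NULL else {
    k <- which.min(fit); list(position = pos[k, ], fitness = fit[k])
  }
  structure(list(positions = pos, fitness = fit, best = best,
                 bounds = bounds), class = "gndo_population")
}

#' Penalty factor of the local-exploitation step
#'
#' `sqrt(-log(lambda1)) * cos(2*pi*lambda2)` when `a <= b`, otherwise
#' the phase-shifted branch `cos(2*pi*lambda2 + pi)`; symmetric around
#' zero, mostly inside `[-1, 1]` but heavy-tailed. The branch switch
#' `(a, b)` is a scalar pair while `lambda1`, `lambda2` are drawn per
#' component, so each coordinate receives an independent perturbation.
#'
#' @param a,b scalar uniforms in (0, 1); fresh draws by default.
#' @param lambda1,lambda2 uniform vectors in (0, 1); fresh scalar draws
#'   by default.
#' @return penalty factor vector, the length of `lambda1`.
#' @export
gndo_penalty_factor <- function(a = stats::runif(1), b = stats::runif(1),
                                lambda1 = stats::runif(1),
                                lambda2 = stats::runif(1)) {
  r <- sqrt(-log(lambda1))
  if (a <= b) r * cos(2 * pi * lambda2) else r * cos(2 * pi * lambda2 + pi)
}

#' Local exploitation trial vector
#'
#' `w_i = mu_i + delta_i * eta` with the generalized mean position
#' `mu_i = (y_i + y_best + M) / 3`, the componentwise generalized
#' standard variance
#' `delta_i = sqrt(((y_i - mu)^2 + (y_best - mu)^2 + (M - mu)^2) / 3)`
#' and the penalty factor `eta` ([gndo_penalty_factor()]).
#'
#' @param pop a `gndo_population` with evaluated fitness.
#' @param i individual index.
#' @return numeric trial vector (not yet clamped or screened).
#' @export
local_exploitation <- function(pop, i) {
  y <- pop$positions[i, ]
  d <- length(y)
  m <- colMeans(pop$positions)
  mu <- (y + pop$best$position + m) / 3
  delta <- sqrt(((y - mu)^2 + (pop$best$position - mu)^2 + (m - mu)^2) / 3)
  eta <- gndo_penalty_factor(stats::runif(1), stats::runif(1),
                             stats::runif(d), stats::runif(d))
  mu + delta * eta
}

#' Global exploration trial vector
#'
#' `v_i = y_i + beta * |g3| * v1 + (1 - beta) * |g4| * v2` where `v1` is
#' the signed difference toward the fitter of `{y_i, y_p1}`, `v2` the
#' signed difference toward the fitter of `{y_p2, y_p3}`, `p1, p2, p3`
#' distinct random indices different from `i`, `beta ~ Uniform(0, 1)`
#' and `g3, g4` standard normal.
#'
#' @inheritParams local_exploitation
#' @return numeric trial vector.
#' @export
global_exploration <- function(pop, i) {
  n <- nrow(pop$positions)
  if (n < 4)
    stop_planefusion("global exploration needs a population of at least 4",
                     "config_error")
  p <- sample(setdiff(seq_len(n), i), 3L)
  y <- pop$positions[i, ]
  f <- pop$fitness
  v1 <- if (f[i] < f[p[1]]) y - pop$positions[p[1], ]
        else pop$positions[p[1], ] - y
  v2 <- if (f[p[2]] < f[p[3]]) pop$positions[p[2], ] - pop$positions[p[3], ]
        else pop$positions[p[3], ] - pop$positions[p[2], ]
  beta <- stats::runif(1)
  y + beta * abs(stats::rnorm(1)) * v1 + (1 - beta) * abs(stats::rnorm(1)) * v2
}

#' Greedy screening
#'
#' Each individual is replaced by its trial vector (clamped to bounds)
#' iff the trial's fitness is strictly better; ties retain the
#' incumbent. Non-finite trial fitness rejects the trial (logged as a
#' message). Guarantees the population's best fitness never worsens.
#'
#' @param pop a `gndo_population`.
#' @param trials matrix of one trial row per individual.
#' @param objective objective function (lower is better).
#' @return the updated `gndo_population`.
#' @export
screen_population <- function(pop, trials, objective) {
  if (nrow(trials) != nrow(pop$positions))
    stop_planefusion("one trial per individual required", "config_error")
  for (i in seq_len(nrow(trials))) {
    trial <- clamp(trials[i, ], pop$bounds$lower, pop$bounds$upper)
    ft <- objective(trial)
    if (!is.finite(ft)) {
      message(sprintf("screening: trial %d rejected (non-finite fitness)", i))
      next
    }
    if (ft < pop$fitness[i]) {
      pop$positions[i, ] <- trial
      pop$fitness[i] <- ft
    }
  }
  k <- which.min(pop$fitness)
  if (is.null(pop$best) || pop$fitness[k] < pop$best$fitness)
    pop$best <- list(position = pop$positions[k, ], fitness = pop$fitness[k])
  pop
}

#' Minimize an objective with GNDO
#'
#' Per iteration each individual draws a fresh `alpha ~ Uniform(0, 1)`
#' and takes the local-exploitation branch if `alpha > 0.5`, otherwise
#' the global-exploration branch; all trials are then screened greedily.
#'
#' @param objective function mapping a numeric vector to a scalar
#'   (lower is better).
#' @param bounds a [gndo_bounds()].
#' @param config a [gndo_config()].
#' @return an object of class `gndo_result`: list with `best` (list
#'   `position`, `fitness`), `trace` (data.frame `iteration`,
#'   `best_fitness`, `mean_fitness`, one row per iteration) and the
#'   final `population`.
#' @export
gndo_minimize <- function(objective, bounds, config = gndo_config()) {
  local_seed(config$seed, {
    pop <- initialize_population(bounds, config, objective)
    trace <- data.frame(iteration = integer(0), best_fitness = numeric(0),
                        mean_fitness = numeric(0))
    if (config$max_iter >= 1) for (t in seq_len(config$max_iter)) {
      trials <- matrix(NA_real_, config$pop_size, bounds$dim)
      for (i in seq_len(config$pop_size)) {
        alpha <- stats::runif(1)
        trials[i, ] <- if (alpha > 0.5) local_exploitation(pop, i)
                       else global_exploration(pop, i)
      }
      pop <- screen_population(pop, trials, objective)
      trace <- rbind(trace, data.frame(
        iteration = t, best_fitness = pop$best$fitness,
        mean_fitness = mean(pop$fitness[is.finite(pop$fitness)])))
    }
    structure(list(best = pop$best, trace = trace, population = pop,
                   config = config), class = "gndo_result")
  })
}

#' @export
print.gndo_result <- function(x, ...) {
  cat(sprintf("<gndo_result> best fitness %.6g after %d iterations\n",
              x$best$fitness, nrow(x$trace)))
  invisible(x)
}

#' Write a GNDO fitness trace as CSV
#'
#' @param result a `gndo_result`.
#' @param path CSV path (columns iteration, best_fitness, mean_fitness).
#' @export
write_gndo_trace <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
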