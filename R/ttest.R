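# Paired classifier-comparison t-test on absolute accuracy differences
# across experiments.

#' Two-tailed Student-t critical value
#'
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @return the critical value `t_{alpha/2, df}`; the acceptance interval
#'   is its plus/minus pair.
#' @export
critical_t <- function(alpha, df) {
  if (alpha <= 0 || alpha >= 1)
    stop_planefusion("alpha must be in (0, 1)", "argument_error")
  if (df < 1) stop_planefusion("df must be >= 1", "argument_error")
  stats::qt(1 - alpha / 2, df)
}

#' Paired accuracy-difference t-test
#'
#' For per-experiment accuracies of a high- and a low-accuracy
#' classifier: `diff_i = |high_i - low_i|`, `mu = mean(diff)`,
#' `sigma` = sample standard deviation (denominator N - 1),
#' `t = sqrt(N) * mu / sigma`, df = N - 1, and the two-tailed acceptance
#' interval at level `alpha`. Alongside the full-precision chain, a
#' 4-decimal-rounded chain (`mu`, `sigma` rounded before forming `t`) is
#' reported, matching how such tables are usually printed.
#'
#' @param acc_high,acc_low equal-length accuracy vectors (percent),
#'   N >= 2.
#' @param alpha significance level.
#' @return an object of class `ttest_report`: `diffs`, `mu`, `sigma`,
#'   `t`, `mu_rounded`, `sigma_rounded`, `t_rounded`, `df`, `critical`,
#'   `interval`, `significant` (logical), `degenerate` (TRUE when
#'   `sigma = 0`, with `t = Inf`).
#' @export
paired_diff_ttest <- function(acc_high, acc_low, alpha = 0.05) {
  n <- length(acc_high)
  if (n != length(acc_low))
    stop_planefusion("accuracy vectors must have equal length", "argument_error")
  if (n < 2)
    stop_planefusion("need at least 2 paired experiments", "argument_error")
  diffs <- abs(acc_high - acc_low)
  mu <- mean(diffs)
  sigma <- stats::sd(diffs)
  degenerate <- sigma == 0
  # sigma = 0 with mu = 0 means literally identical accuracies: t = 0;
  # sigma = 0 with mu > 0 is a perfectly constant difference: t = +Inf.
  t_full <- if (!degenerate) sqrt(n) * mu / sigma else if (mu == 0) 0 else Inf
  mu_r <- round(mu, 4); sigma_r <- round(sigma, 4)
  t_r <- if (sigma_r != 0) round(sqrt(n) * mu_r / sigma_r, 4)
         else if (mu_r == 0) 0 else Inf
  crit <- critical_t(alpha, n - 1L)
  structure(list(diffs = diffs, mu = mu, sigma = sigma, t = t_full,
                 mu_rounded = mu_r, sigma_rounded = sigma_r, t_rounded = t_r,
                 df = n - 1L, alpha = alpha, critical = crit,
                 interval = c(-crit, crit),
                 significant = is.infinite(t_full) || abs(t_full) > crit,
                 degenerate = degenerate),
            class = "ttest_report")
}

#' @export
print.ttest_report <- function(x, ...) {
  cat(sprintf(paste0("<ttest_report> mu %.4f, sigma %.4f, t %.4f ",
                     "(df %d, interval %.3f..%.3f): %s\n"),
              x$mu, x$sigma, x$t, x$df, x$interval[1], x$interval[2],
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Persist a t-test report as JSON
#'
#' @param report a `ttest_report`.
#' @param path JSON output path.
#' @export
write_ttest_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
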