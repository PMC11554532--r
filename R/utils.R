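#' @keywords internal
"_PACKAGE"

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Componentwise clamp to [lower, upper] (vectors recycled).
clamp <- function(x, lower, upper) pmin(pmax(x, lower), upper)

#' Logistic (sigmoid) map
#'
#' Maps real-valued optimizer positions to scores strictly inside (0, 1).
#'
#' @param x numeric vector.
#' @return numeric vector of the same length, values in (0, 1).
#' @export
logistic <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_planefusion <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "planefusion_error")))
}
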