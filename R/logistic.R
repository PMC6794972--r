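#' Logistic trajectory parameters
#'
#' Bundle the three parameters of a logistic occlusion trajectory: the
#' daily occlusion rate `r`, the carrying capacity `K` (maximum attainable
#' percent occluded area, 100% unless stated otherwise), and the initial
#' percent occluded area `x0` at model time 0.
#'
#' @param r Occlusion rate, per day. Must be finite and non-negative.
#' @param K Carrying capacity, percent. Must be positive; defaults to 100.
#' @param x0 Initial percent occluded area at time 0, in `[0, K]`.
#'
#' @return An object of class `"logistic_params"`: a list with elements
#'   `r`, `K` and `x0`.
#'
#' @examples
#' p <- logistic_params(r = 0.95, x0 = 10)
#' logistic_solution(0:7, p)
#'
#' @export
logistic_params <- function(r, K = 100, x0) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r))
    stop("'r' must be a single finite number", call. = FALSE)
  if (r < 0)
    stop("'r' must be non-negative: a negative occlusion rate has no ",
         "interpretation in this model", call. = FALSE)
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("'K' must be a single positive finite number", call. = FALSE)
  if (!is.numeric(x0) || length(x0) != 1L || !is.finite(x0))
    stop("'x0' must be a single finite number", call. = FALSE)
  if (x0 < 0 || x0 > K)
    stop("'x0' must lie in [0, K]", call. = FALSE)
  structure(list(r = r, K = K, x0 = x0), class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, digits = 4, ...) {
  cat("Logistic trajectory parameters:\n")
  cat(sprintf("  rate r  = %s per day\n", format(x$r, digits = digits)))
  cat(sprintf("  K       = %s %%\n", format(x$K, digits = digits)))
  cat(sprintf("  x0      = %s %% (at t = 0)\n", format(x$x0, digits = digits)))
  invisible(x)
}

as_logistic_params <- function(x) {
  if (inherits(x, "logistic_params")) return(x)
  if (is.list(x) && all(c("r", "K", "x0") %in% names(x)))
    return(logistic_params(x$r, x$K, x$x0))
  stop("cannot interpret 'params' as logistic parameters", call. = FALSE)
}

#' Instantaneous occlusion rate of the logistic model
#'
#' Evaluate the right-hand side of the logistic differential equation
#' `dX/dt = r X (1 - X/K)` at given state values. The rate is zero exactly
#' at the two equilibria `X = 0` and `X = K`.
#'
#' @param x Percent occluded area (state value); may be a vector.
#' @param params A [logistic_params()] object.
#'
#' @return Occlusion rate(s) in percent per day, same length as `x`.
#'
#' @examples
#' logistic_rate(50, logistic_params(r = 0.95, x0 = 10))  # 23.75
#'
#' @export
logistic_rate <- function(x, params) {
  params <- as_logistic_params(params)
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)))
    stop("'x' must be finite numeric", call. = FALSE)
  params$r * x * (1 - x / params$K)
}

#' Closed-form logistic trajectory
#'
#' Evaluate the analytical solution of the logistic equation,
#' `X(t) = K C e^{rt} / (1 + C e^{rt})` with `C = x0 / (K - x0)`, at the
#' given times. For large `r t` the algebraically equivalent form
#' `K / (1 + e^{-rt}/C)` is used so the value stays finite in floating
#' point (no overflow up to `r t` of several hundred).
#'
#' Boundary parameter values are handled as the constant trajectories they
#' imply: `x0 = 0` stays at 0, `x0 = K` stays at `K`, and `r = 0` stays
#' at `x0`.
#'
#' @param t Time in days (vector allowed); continuous, not rounded.
#' @param params A [logistic_params()] object.
#'
#' @return Percent occluded area at each time, in `[0, K]`.
#'
#' @seealso [time_to_threshold()] for the inverse problem.
#' @export
logistic_solution <- function(t, params) {
  params <- as_logistic_params(params)
  if (!is.numeric(t) || length(t) == 0L || any(!is.finite(t)))
    stop("'t' must be finite numeric", call. = FALSE)
  r <- params$r; K <- params$K; x0 <- params$x0
  if (x0 == 0) return(rep(0, length(t)))
  if (x0 == K) return(rep(K, length(t)))
  if (r == 0) return(rep(x0, length(t)))
  C <- x0 / (K - x0)
  rt <- r * t
  out <- numeric(length(t))
  big <- rt > 30
  # standard form for moderate exponents, overflow-safe rearrangement beyond
  out[!big] <- K * C * exp(rt[!big]) / (1 + C * exp(rt[!big]))
  out[big] <- K / (1 + exp(-rt[big]) / C)
  out
}

#' Trajectory evaluated on a day grid
#'
#' Vectorized convenience wrapper around [logistic_solution()], used for
#' fitting and plotting. For `0 < x0 < K` and `r > 0` the returned values
#' are strictly increasing whenever `days` is strictly increasing.
#'
#' @param params A [logistic_params()] object.
#' @param days Numeric vector of times (days), finite and non-empty.
#'
#' @return Percent occluded area at each day.
#' @export
logistic_trajectory <- function(params, days) {
  logistic_solution(days, params)
}

#' Equilibria of the logistic model and their stability
#'
#' The logistic equation has two equilibria, the empty state 0 and the
#' carrying capacity `K`. Stability is read off the sign of the derivative
#' of the right-hand side `r X (1 - X/K)` at each equilibrium: for
#' `r > 0` the derivative is `+r` at 0 (unstable) and `-r` at `K`
#' (stable; the trajectory approaches `K` from any interior start, so the
#' occluded fraction cannot decay back to zero). For `r = 0` the dynamics
#' are frozen and every state is neutrally stable, reported as the labels
#' `"neutral"`; a negative rate is refused.
#'
#' @param params A [logistic_params()] object.
#'
#' @return A data frame of class `"equilibrium_report"` with columns
#'   `state` (percent) and `stability` (`"stable"`, `"unstable"` or
#'   `"neutral"`).
#'
#' @examples
#' equilibria(logistic_params(r = 0.95, x0 = 10))
#'
#' @export
equilibria <- function(params) {
  params <- as_logistic_params(params)
  if (params$r < 0)
    stop("equilibrium analysis requires a non-negative rate", call. = FALSE)
  if (params$r == 0) {
    rep <- data.frame(state = c(0, params$K),
                      stability = c("neutral", "neutral"),
                      stringsAsFactors = FALSE)
  } else {
    # d/dX [r X (1 - X/K)] = r (1 - 2X/K): +r at X = 0, -r at X = K
    deriv <- params$r * (1 - 2 * c(0, params$K) / params$K)
    rep <- data.frame(state = c(0, params$K),
                      stability = ifelse(deriv > 0, "unstable", "stable"),
                      stringsAsFactors = FALSE)
  }
  class(rep) <- c("equilibrium_report", "data.frame")
  attr(rep, "r") <- params$r
  rep
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("Equilibria of the logistic occlusion model:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  X* = %g%%  (%s)\n", x$state[i], x$stability[i]))
  if (identical(attr(x, "r"), 0))
    cat("  (zero rate: dynamics are frozen; every state is neutrally stable)\n")
  invisible(x)
}

#' Time for the trajectory to reach a threshold occlusion
#'
#' Closed-form inversion of the logistic trajectory: the time at which the
#' percent occluded area first equals `threshold`, namely
#' `t = (1/r) log( threshold (K - x0) / (x0 (K - threshold)) )`.
#'
#' The carrying capacity is an asymptote, so thresholds at or above `K`
#' are unreachable and raise an error; a threshold equal to `x0` is
#' reached at time 0, and one below `x0` is never reached for a growing
#' trajectory.
#'
#' @param params A [logistic_params()] object with `r > 0` and
#'   `0 < x0 < K`.
#' @param threshold Target percent occluded area, in `(x0, K)` (or equal
#'   to `x0`).
#'
#' @return Time in days (a single number).
#'
#' @examples
#' p <- logistic_params(r = 0.95, x0 = 10)
#' time_to_threshold(p, 50)   # log(9)/0.95, about 2.31 days
#'
#' @export
time_to_threshold <- function(params, threshold) {
  params <- as_logistic_params(params)
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("'threshold' must be a single finite number", call. = FALSE)
  r <- params$r; K <- params$K; x0 <- params$x0
  if (x0 <= 0 || x0 >= K)
    stop("time_to_threshold requires 0 < x0 < K", call. = FALSE)
  if (threshold >= K)
    stop("threshold at or above the carrying capacity is unreachable ",
         "(the trajectory approaches K asymptotically)", call. = FALSE)
  if (threshold == x0) return(0)
  if (threshold < x0)
    stop("threshold below the initial value is never reached by a ",
         "growing trajectory", call. = FALSE)
  if (r <= 0)
    stop("time_to_threshold requires r > 0", call. = FALSE)
  log(threshold * (K - x0) / (x0 * (K - threshold))) / r
}
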