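#' Weighted least-squares objective for a logistic trajectory
#'
#' Sum of squared deviations between a series' per-day mean percent
#' occluded area and the closed-form logistic trajectory, evaluated at
#' the series' model times (`day - time_origin`). Zero exactly when the
#' trajectory interpolates every observed mean.
#'
#' @param series An [occlusion_series()].
#' @param params A [logistic_params()] object.
#' @param weights `"unweighted"` (default) or `"inverse_variance"`, which
#'   weights day `i` by `n / sd_i^2` (the reciprocal of the squared
#'   standard error of the mean).
#' @param time_origin Day value mapped to model time 0. The default,
#'   the series' first day, makes `x0` the value at the first
#'   observation.
#'
#' @return The (weighted) sum of squared residuals, in squared percent.
#' @export
sse_objective <- function(series, params,
                          weights = c("unweighted", "inverse_variance"),
                          time_origin = series$days[1]) {
  stopifnot(inherits(series, "occlusion_series"))
  weights <- match.arg(weights)
  params <- as_logistic_params(params)
  w <- fit_weights(series, weights)
  resid <- series$means - logistic_solution(series$days - time_origin, params)
  sum(w * resid^2)
}

fit_weights <- function(series, weights) {
  if (weights == "unweighted") return(rep(1, length(series$days)))
  if (any(series$sds == 0))
    stop("inverse-variance weights are undefined when any SD is 0; ",
         "use weights = \"unweighted\"", call. = FALSE)
  series$n / series$sds^2
}

#' Fit the logistic occlusion model to a summary time series
#'
#' Estimates the daily occlusion rate (and optionally the initial value)
#' by bounded least squares of the closed-form logistic trajectory
#' against the observed per-day mean percent occluded areas. The
#' carrying capacity `K` is fixed, not fitted (100% by default: complete
#' occlusion of the measured area).
#'
#' Two policies for the initial value are available:
#' \describe{
#'   \item{`x0 = "anchor"` (default)}{Model time is `day - first day`,
#'     so the first observation sits at time 0, and `x0` is pinned to the
#'     first observed mean; only the rate `r` is estimated, by a coarse
#'     rate scan followed by golden-section refinement. This is the
#'     convention that reproduces the published rate estimates for the
#'     bundled data.}
#'   \item{`x0 = "fit"`}{`x0` is estimated jointly with `r`; model time
#'     is the day index itself, so `x0` is the latent pre-brushing value
#'     at day 0. Optimization is bounded `L-BFGS-B` from a fixed 5 x 5
#'     grid of deterministic starting points; the best converged start
#'     wins.}
#' }
#' A numeric `x0` fixes the initial value at that number (at model time
#' 0 = day 0) and estimates `r` alone.
#'
#' @param series An [occlusion_series()] with at least 3 observation
#'   days.
#' @param K Carrying capacity in percent (fixed). A warning is issued if
#'   it does not exceed the largest observed mean.
#' @param x0 `"anchor"`, `"fit"`, or a single number in `(0, K)`.
#' @param weights Passed to [sse_objective()].
#' @param r_bounds Length-2 bounds for the rate, per day.
#'
#' @return An object of class `"logistic_fit"` with components `params`
#'   ([logistic_params()]), `series`, `x0_policy`, `time_origin`, `sse`,
#'   `rmse`, `r_squared`, `converged`, `n_points`, and (for the joint
#'   policy) `starts`, the per-start results, plus `multimodal`, `TRUE`
#'   when some converged start was trapped away from the best objective. Standard methods are
#'   provided: [coef()], [predict()], [fitted()], [residuals()],
#'   [summary()], [plot()] and [simulate()].
#'
#' @examples
#' fit <- fit_logistic(occlusion_table1()[["EB@TiO2 / with_saliva"]])
#' coef(fit)
#' predict(fit, days = 8:10)
#'
#' @export
fit_logistic <- function(series, K = 100, x0 = c("anchor", "fit"),
                         weights = c("unweighted", "inverse_variance"),
                         r_bounds = c(1e-6, 10)) {
  stopifnot(inherits(series, "occlusion_series"))
  weights <- match.arg(weights)
  if (length(series$days) < 3L)
    stop("at least 3 observation days are required to fit the model",
         call. = FALSE)
  if (K <= max(series$means))
    warning("carrying capacity K = ", K, " does not exceed the largest ",
            "observed mean (", max(series$means), ")")
  numeric_x0 <- is.numeric(x0)
  if (!numeric_x0) x0 <- match.arg(x0)

  if (numeric_x0 || x0 == "anchor") {
    if (numeric_x0) {
      x0_val <- x0
      policy <- "fixed"
      t0 <- 0
      if (x0_val <= 0 || x0_val >= K)
        stop("a fixed 'x0' must lie strictly inside (0, K)", call. = FALSE)
    } else {
      x0_val <- series$means[1]
      policy <- "anchor"
      t0 <- series$days[1]
      if (x0_val <= 0 || x0_val >= K)
        stop("anchor policy needs the first observed mean strictly inside ",
             "(0, K); pass x0 = \"fit\" or a numeric x0", call. = FALSE)
    }
    res <- fit_rate_only(series, K, x0_val, t0, weights, r_bounds)
    params <- logistic_params(res$r, K, x0_val)
    converged <- res$converged
    starts <- NULL
  } else {
    t0 <- 0
    policy <- "fit"
    res <- fit_joint(series, K, t0, weights, r_bounds)
    params <- logistic_params(res$r, K, res$x0)
    converged <- res$converged
    starts <- res$starts
    if (!converged)
      warning("no multi-start run converged; returning the best point found")
  }
  multimodal <- if (is.null(starts)) FALSE else res$multimodal

  gof <- goodness_of_fit(series, params, time_origin = t0)
  structure(list(series = series, params = params, x0_policy = policy,
                 time_origin = t0, weights = weights,
                 sse = sse_objective(series, params, weights, t0),
                 rmse = gof$rmse, r_squared = gof$r_squared,
                 converged = converged, n_points = length(series$days),
                 multimodal = multimodal, starts = starts),
            class = "logistic_fit")
}

# 1-D rate estimation: coarse log-spaced scan, then golden-section
# refinement in the bracketing interval around the best scan point.
# Deterministic and robust to local minima in the rate profile.
fit_rate_only <- function(series, K, x0_val, t0, weights, r_bounds) {
  obj <- function(r)
    sse_objective(series, logistic_params(r, K, x0_val), weights, t0)
  grid <- exp(seq(log(r_bounds[1]), log(r_bounds[2]), length.out = 80))
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(obj, lower = lo, upper = hi, tol = 1e-10)
  r <- if (opt$objective <= vals[i]) opt$minimum else grid[i]
  list(r = r, converged = TRUE)
}

# joint (r, x0) estimation: bounded L-BFGS-B from a fixed grid of starts
fit_joint <- function(series, K, t0, weights, r_bounds) {
  obj <- function(p)
    sse_objective(series, logistic_params(p[1], K, p[2]), weights, t0)
  x0_bounds <- c(1e-6, K - 1e-6)
  r_starts <- exp(seq(log(0.05), log(5), length.out = 5))
  x0_starts <- pmin(K * c(0.01, 0.05, 0.15, 0.4, 0.8), x0_bounds[2])
  starts <- expand.grid(r = r_starts, x0 = x0_starts)
  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    runs[[i]] <- tryCatch(
      stats::optim(c(starts$r[i], starts$x0[i]), obj, method = "L-BFGS-B",
                   lower = c(r_bounds[1], x0_bounds[1]),
                   upper = c(r_bounds[2], x0_bounds[2]),
                   control = list(factr = 10, pgtol = 1e-12, maxit = 500)),
      error = function(e) list(par = c(NA, NA), value = Inf, convergence = 99))
  }
  vals <- vapply(runs, function(z) z$value, numeric(1))
  conv <- vapply(runs, function(z) z$convergence == 0, logical(1))
  best <- which.min(vals)
  starts$r_hat <- vapply(runs, function(z) z$par[1], numeric(1))
  starts$x0_hat <- vapply(runs, function(z) z$par[2], numeric(1))
  starts$sse <- vals
  starts$converged <- conv
  # converged runs stuck away from the best objective indicate local minima
  multimodal <- any(conv & vals > min(vals) * (1 + 1e-4) + 1e-8)
  list(r = runs[[best]]$par[1], x0 = runs[[best]]$par[2],
       converged = any(conv), starts = starts, multimodal = multimodal)
}

#' Goodness of fit of a logistic trajectory to a series
#'
#' Root-mean-square error of the per-day means about the trajectory, and
#' the coefficient of determination `1 - SSE/TSS` with the total sum of
#' squares taken about the mean of the observed means. For a constant
#' series the coefficient of determination is undefined and returned as
#' `NA`.
#'
#' @inheritParams sse_objective
#' @return A list with elements `rmse` (percent) and `r_squared`.
#' @export
goodness_of_fit <- function(series, params, time_origin = series$days[1]) {
  stopifnot(inherits(series, "occlusion_series"))
  params <- as_logistic_params(params)
  sse <- sse_objective(series, params, "unweighted", time_origin)
  tss <- sum((series$means - mean(series$means))^2)
  list(rmse = sqrt(sse / length(series$days)),
       r_squared = if (tss == 0) NA_real_ else 1 - sse / tss)
}

#' Fit every series in a table of occlusion groups
#'
#' Applies [fit_logistic()] to each paste x condition series. A series
#' whose fit fails does not abort the rest: its error message is kept
#' and the cell is flagged.
#'
#' @param table A list of [occlusion_series()] objects, e.g. from
#'   [occlusion_table1()] or [read_occlusion_csv()].
#' @param ... Passed on to [fit_logistic()].
#'
#' @return An object of class `"occlusion_fit_table"`: a list with
#'   `fits` (per-series [fit_logistic()] results or `NULL` on failure),
#'   `errors` (messages for failed cells) and `report`, a data frame
#'   with one row per series (`paste`, `condition`, `r`, `x0`, `K`,
#'   `sse`, `rmse`, `r_squared`, `converged`).
#'
#' @examples
#' fit_occlusion_table(occlusion_table1())
#'
#' @export
fit_occlusion_table <- function(table, ...) {
  stopifnot(is.list(table), length(table) > 0L)
  fits <- vector("list", length(table))
  errors <- character(length(table))
  for (i in seq_along(table)) {
    fits[i] <- list(tryCatch(fit_logistic(table[[i]], ...),
                             error = function(e) {
      errors[i] <<- conditionMessage(e); NULL
    }))
  }
  rows <- lapply(seq_along(table), function(i) {
    s <- table[[i]]
    f <- fits[[i]]
    if (is.null(f))
      data.frame(paste = s$paste, condition = s$condition, r = NA_real_,
                 x0 = NA_real_, K = NA_real_, sse = NA_real_, rmse = NA_real_,
                 r_squared = NA_real_, converged = FALSE,
                 stringsAsFactors = FALSE)
    else
      data.frame(paste = s$paste, condition = s$condition, r = f$params$r,
                 x0 = f$params$x0, K = f$params$K, sse = f$sse, rmse = f$rmse,
                 r_squared = f$r_squared, converged = f$converged,
                 stringsAsFactors = FALSE)
  })
  names(fits) <- vapply(table, series_key, character(1))
  structure(list(fits = fits, errors = errors,
                 report = do.call(rbind, rows)),
            class = "occlusion_fit_table")
}

#' @export
print.occlusion_fit_table <- function(x, digits = 4, ...) {
  cat("Logistic occlusion rates by paste and saliva condition:\n\n")
  rep <- x$report
  wide <- stats::reshape(rep[, c("paste", "condition", "r")],
                         idvar = "paste", timevar = "condition",
                         direction = "wide")
  names(wide) <- sub("^r\\.", "", names(wide))
  print(format(wide, digits = digits), row.names = FALSE)
  cat("\nFull report ($report): r, x0, K, sse, rmse, r_squared per cell\n")
  failed <- which(!vapply(x$fits, Negate(is.null), logical(1)))
  if (length(failed) > 0L)
    cat("Failed cells:", paste(names(x$fits)[failed], collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.logistic_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Logistic occlusion fit: %s, %s\n",
              x$series$paste, x$series$condition))
  cat(sprintf("  r = %s per day  (x0 %s at %s%%, K = %s%%)\n",
              format(x$params$r, digits = digits), x$x0_policy,
              format(x$params$x0, digits = digits),
              format(x$params$K, digits = digits)))
  cat(sprintf("  RMSE = %s%%, R^2 = %s on %d days\n",
              format(x$rmse, digits = digits),
              format(x$r_squared, digits = digits), x$n_points))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) {
  c(r = object$params$r, K = object$params$K, x0 = object$params$x0)
}

#' Predict percent occluded area from a fitted logistic model
#'
#' @param object A [fit_logistic()] result.
#' @param days Days at which to evaluate the fitted trajectory (on the
#'   same day scale as the data; the fit's time origin is applied
#'   internally). Defaults to the observed days.
#' @param ... Unused.
#'
#' @return Percent occluded area at each requested day.
#' @export
predict.logistic_fit <- function(object, days = object$series$days, ...) {
  logistic_solution(days - object$time_origin, object$params)
}

#' @export
fitted.logistic_fit <- function(object, ...) {
  predict(object)
}

#' @export
residuals.logistic_fit <- function(object, ...) {
  object$series$means - fitted(object)
}

#' @export
summary.logistic_fit <- function(object, ...) {
  structure(list(fit = object,
                 table = data.frame(day = object$series$days,
                                    observed = object$series$means,
                                    sd = object$series$sds,
                                    fitted = fitted(object),
                                    residual = residuals(object))),
            class = "summary.logistic_fit")
}

#' @export
print.summary.logistic_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nPer-day fit:\n")
  print(format(x$table, digits = digits), row.names = FALSE)
  f <- x$fit
  if (f$params$r > 0 && f$params$x0 > 0 && f$params$x0 < f$params$K) {
    thr <- 0.95 * f$params$K
    cat(sprintf("\nPredicted day reaching %s%% occlusion: %s\n",
                format(thr, digits = digits),
                format(f$time_origin + time_to_threshold(f$params, thr),
                       digits = digits)))
  }
  invisible(x)
}

#' Plot observed means and the fitted logistic trajectory
#'
#' Observed per-day means with +/- 1 SD bars, overlaid with the fitted
#' closed-form trajectory on a fine grid.
#'
#' @param x A [fit_logistic()] result.
#' @param n_grid Number of grid points for the fitted curve.
#' @param ... Further arguments to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.logistic_fit <- function(x, n_grid = 200, ...) {
  s <- x$series
  tt <- seq(min(s$days), max(s$days), length.out = n_grid)
  graphics::plot(s$days, s$means, ylim = c(0, max(100, x$params$K)),
                 xlab = "day", ylab = "occluded area (%)",
                 main = sprintf("%s, %s", s$paste, s$condition), pch = 19, ...)
  graphics::arrows(s$days, s$means - s$sds, s$days, s$means + s$sds,
                   angle = 90, code = 3, length = 0.04)
  graphics::lines(tt, predict(x, tt), col = "steelblue", lwd = 2)
  invisible(x)
}

#' Simulate specimen-level datasets from a fitted model
#'
#' Draws synthetic specimen trajectories from the fitted parameters with
#' additive Gaussian noise, mirroring the design of the series the model
#' was fitted to (same days and group size).
#'
#' @param object A [fit_logistic()] result.
#' @param nsim Number of datasets to simulate.
#' @param seed Integer seed; the RNG state is restored afterwards.
#' @param noise_sd Measurement noise SD in percent. Defaults to the mean
#'   of the series' per-day SDs.
#' @param ... Passed on to [simulate_occlusion()].
#'
#' @return A list of `nsim` long-format data frames (see
#'   [simulate_occlusion()]).
#' @export
simulate.logistic_fit <- function(object, nsim = 1, seed = NULL,
                                  noise_sd = mean(object$series$sds), ...) {
  truth <- data.frame(paste = object$series$paste,
                      condition = object$series$condition,
                      r = object$params$r, K = object$params$K,
                      x0 = object$params$x0, stringsAsFactors = FALSE)
  seeds <- if (is.null(seed)) rep(list(NULL), nsim)
           else as.list(seed + seq_len(nsim) - 1L)
  lapply(seeds, function(s)
    simulate_occlusion(truth, days = object$series$days,
                       n_specimens = object$series$n, noise_sd = noise_sd,
                       seed = s, time_origin = object$time_origin, ...))
}
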