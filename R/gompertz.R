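#' Evaluate the Gompertz growth law
#'
#' Colony area under the Gompertz model,
#' \deqn{f(t) = A_{min} + A_\Delta \exp(-\exp(k (t_m - t)))}{
#'       f(t) = A_min + A_delta * exp(-exp(k*(t_m - t)))}
#' an asymmetric sigmoid with inflection at `t_m`, where the maximum absolute
#' growth rate `A_delta * k / e` is attained. `k` (1/h) is the maximum relative
#' growth rate, `A_min` the baseline area and `A_min + A_delta` the asymptote.
#'
#' @param t time in hours (vector).
#' @param A_min baseline area.
#' @param A_delta area gain (asymptote minus baseline), must be positive for a
#'   growing colony.
#' @param k maximum relative growth rate (1/h).
#' @param t_m inflection time (h).
#' @return area at `t`, same length as `t`.
#' @seealso [fit_gompertz()], [max_growth_rate()], [lag_time()]
#' @export
#' @examples
#' gompertz_value(0, A_min = 0, A_delta = 1, k = 1, t_m = 0)  # 1/e
gompertz_value <- function(t, A_min, A_delta, k, t_m) {
  A_min + A_delta * exp(-exp(k * (t_m - t)))
}

gompertz_rhs <- function(t, par) {
  gompertz_value(t, par[["A_min"]], par[["A_delta"]], par[["k"]], par[["t_m"]])
}

#' Fit a Gompertz growth curve to a colony area trace
#'
#' Nonlinear least squares of the Gompertz law on (time, area) observations,
#' restarted from a deterministic grid of `n_starts` data-driven start points
#' (baseline from the earliest areas, amplitude from the observed range,
#' inflection times spanning the observed window, rates spanning the
#' log-range over plausible rise times). The best solution by residual sum of
#' squares is kept. Bounds keep `A_delta` and `k` positive.
#'
#' @param time observation times in hours, strictly increasing, length >= 5.
#'   Alternatively a `data.frame` with columns `time` and `area` (then `area`
#'   is ignored).
#' @param area colony areas, same length as `time`.
#' @param n_starts number of multistart initialisations (default 50).
#' @param maxiter per-start iteration cap passed to the optimiser.
#' @return an object of class `"gompertz_fit"`: a list with elements
#'   `A_min`, `A_delta`, `k`, `t_m`, `rss`, `converged`, `data`
#'   (the input series), `fitted` and `n_starts`.
#' @details Degenerate traces (constant area, or no start converging) return a
#'   fit with `converged = FALSE`; parameter fields are then `NA` and the
#'   caller decides exclusion.
#' @export
#' @examples
#' t <- seq(0, 15, by = 0.25)
#' a <- gompertz_value(t, 5, 300, 0.6, 7)
#' fit <- fit_gompertz(t, a)
#' coef(fit)
#' max_growth_rate(fit)
#' lag_time(fit)
fit_gompertz <- function(time, area, n_starts = 50, maxiter = 60) {
  if (is.data.frame(time)) {
    area <- time$area
    time <- time$time
  }
  stopifnot(length(time) == length(area))
  if (length(time) < 5) stop("need at least 5 time points")
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(time)) || any(!is.finite(area))) stop("non-finite input")

  bad <- structure(
    list(A_min = NA_real_, A_delta = NA_real_, k = NA_real_, t_m = NA_real_,
         rss = NA_real_, converged = FALSE,
         data = data.frame(time = time, area = area),
         fitted = rep(NA_real_, length(time)), n_starts = n_starts),
    class = "gompertz_fit")

  rng <- diff(range(area))
  if (rng <= 0) return(bad)  # constant trace carries no kinetics

  span <- diff(range(time))
  a0 <- min(area)
  # deterministic start grid: factorial in (t_m, k), cycled over amplitude scale
  n_tm <- max(2L, ceiling(sqrt(n_starts)))
  n_k <- max(2L, ceiling(n_starts / n_tm))
  tm_grid <- seq(min(time) + 0.05 * span, max(time) - 0.05 * span,
                 length.out = n_tm)
  # rise times between 2% and twice the window ~ k = e/rise (tangent slope)
  k_grid <- exp(seq(log(1 / (2 * span)), log(20 / span), length.out = n_k))
  starts <- expand.grid(t_m = tm_grid, k = k_grid)[seq_len(min(n_starts, n_tm * n_k)), ]

  lower <- c(A_min = -Inf, A_delta = rng * 1e-6, k = 1e-8, t_m = -Inf)
  upper <- c(A_min = Inf, A_delta = Inf, k = Inf, t_m = Inf)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(A_min = a0, A_delta = rng,
               k = starts$k[i], t_m = starts$t_m[i])
    # iteration-cap warnings are routine for bad starts; the best-RSS
    # solution across starts is what matters
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        area ~ A_min + A_delta * exp(-exp(k * (t_m - time))),
        data = data.frame(time = time, area = area),
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = maxiter))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = stats::coef(fit), rss = rss)
      if (rss <= 1e-14 * sum(area^2)) break  # exact fit, no point continuing
    }
  }
  if (is.null(best)) return(bad)

  p <- best$par
  structure(
    list(A_min = unname(p["A_min"]), A_delta = unname(p["A_delta"]),
         k = unname(p["k"]), t_m = unname(p["t_m"]),
         rss = best$rss, converged = TRUE,
         data = data.frame(time = time, area = area),
         fitted = gompertz_rhs(time, p), n_starts = n_starts),
    class = "gompertz_fit")
}

#' Maximum absolute growth rate of a fitted Gompertz curve
#'
#' The derivative of the Gompertz law at the inflection time `t_m`, in closed
#' form `A_delta * k / e` (area units per hour).
#'
#' @param fit a [fit_gompertz()] object (or any list with `A_delta` and `k`).
#' @return numeric scalar; `NA` for a non-converged fit.
#' @export
max_growth_rate <- function(fit) {
  fit$A_delta * fit$k / exp(1)
}

#' Lag time from a fitted Gompertz curve
#'
#' Time at which the tangent to the Gompertz curve at its inflection point
#' crosses a baseline area level: the standard geometric lag construction.
#' The tangent has slope `A_delta*k/e` through `(t_m, A_min + A_delta/e)`, so
#' the crossing with level `B` is
#' `t_m + (B - A_min - A_delta/e) * e / (A_delta * k)`;
#' for `baseline = A_min` this reduces to `t_m - 1/k`, and for a baseline of
#' zero (inoculum size taken as zero) to
#' `t_m - 1/k - A_min*e/(A_delta*k)`.
#'
#' `convention = "printed"` instead returns
#' `(A_min + (A_delta/e)(1 - k*t_m)) / ((A_delta/e) k)`, an alternative form
#' circulating in the literature which equals the negative of the zero-baseline
#' tangent crossing; it is provided for comparison and decreases as `t_m`
#' grows, so the tangent construction is the default.
#'
#' @param fit a [fit_gompertz()] object.
#' @param baseline area level the tangent is intersected with; defaults to the
#'   fitted `A_min`. Use `0` to take colony size at inoculation as zero.
#' @param convention `"tangent"` (default) or `"printed"`, see Details.
#' @return lag time in hours.
#' @export
lag_time <- function(fit, baseline = fit$A_min,
                     convention = c("tangent", "printed")) {
  convention <- match.arg(convention)
  if (!is.finite(fit$k) || fit$k <= 0) stop("lag time requires k > 0")
  mu <- fit$A_delta * fit$k / exp(1)
  if (convention == "printed") {
    return((fit$A_min + (fit$A_delta / exp(1)) * (1 - fit$k * fit$t_m)) /
             ((fit$A_delta / exp(1)) * fit$k))
  }
  fit$t_m + (baseline - fit$A_min - fit$A_delta / exp(1)) / mu
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("Gompertz growth fit\n")
  if (!x$converged) {
    cat("  did not converge (", nrow(x$data), " points)\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  A_min = %.4g, A_delta = %.4g, k = %.4g /h, t_m = %.4g h\n",
              x$A_min, x$A_delta, x$k, x$t_m))
  cat(sprintf("  max growth rate = %.4g area/h, lag = %.4g h, RSS = %.4g\n",
              max_growth_rate(x), lag_time(x), x$rss))
  invisible(x)
}

#' @export
coef.gompertz_fit <- function(object, ...) {
  c(A_min = object$A_min, A_delta = object$A_delta,
    k = object$k, t_m = object$t_m)
}

#' @export
fitted.gompertz_fit <- function(object, ...) object$fitted

#' @export
residuals.gompertz_fit <- function(object, ...) {
  object$data$area - object$fitted
}

#' Predict colony area from a Gompertz fit
#'
#' @param object a [fit_gompertz()] object.
#' @param newdata optional data frame with a `time` column (hours); defaults to
#'   the fitting times.
#' @param ... unused.
#' @return predicted areas.
#' @export
predict.gompertz_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time else newdata$time
  gompertz_rhs(t, coef(object))
}

#' @export
summary.gompertz_fit <- function(object, ...) {
  out <- list(
    coefficients = coef(object),
    mu_max = if (object$converged) max_growth_rate(object) else NA_real_,
    lag = if (object$converged) lag_time(object) else NA_real_,
    rss = object$rss,
    sigma = if (object$converged)
      sqrt(object$rss / max(1L, nrow(object$data) - 4L)) else NA_real_,
    n = nrow(object$data),
    converged = object$converged)
  class(out) <- "summary.gompertz_fit"
  out
}

#' @export
print.summary.gompertz_fit <- function(x, ...) {
  cat("Gompertz growth fit (", x$n, " points)\n", sep = "")
  print(round(x$coefficients, 6))
  cat(sprintf("mu_max = %.6g area/h, lag = %.6g h, residual sd = %.4g\n",
              x$mu_max, x$lag, x$sigma))
  if (!x$converged) cat("fit did not converge\n")
  invisible(x)
}

#' @export
plot.gompertz_fit <- function(x, ...) {
  plot(x$data$time, x$data$area, xlab = "time (h)", ylab = "area",
       pch = 16, cex = 0.6, ...)
  if (x$converged) {
    tt <- seq(min(x$data$time), max(x$data$time), length.out = 200)
    graphics::lines(tt, predict(x, data.frame(time = tt)), col = 2, lwd = 2)
    graphics::abline(v = lag_time(x), lty = 2, col = "grey40")
  }
  invisible(x)
}

#' Simulate area traces from a fitted Gompertz model
#'
#' Draws `nsim` replicate traces at the fitting times, adding i.i.d. Gaussian
#' noise with the residual standard deviation of the fit.
#'
#' @param object a converged [fit_gompertz()] object.
#' @param nsim number of replicate traces.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a matrix with one column per replicate.
#' @export
simulate.gompertz_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("cannot simulate from a non-converged fit")
  if (!is.null(seed)) set.seed(seed)
  s <- sqrt(object$rss / max(1L, nrow(object$data) - 4L))
  n <- nrow(object$data)
  matrix(rep(object$fitted, nsim) + stats::rnorm(n * nsim, 0, s), nrow = n)
}
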