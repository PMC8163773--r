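# Sliding-window OLS slopes for all contiguous windows via prefix sums.
# Returns the (start, end, slope, intercept) of the window with maximal slope
# among windows of length >= min_len; ties broken by the earliest window.
max_slope_window <- function(t, y, min_len) {
  n <- length(t)
  best <- list(slope = -Inf, start = NA_integer_, end = NA_integer_,
               intercept = NA_real_)
  cs_t <- cumsum(t); cs_y <- cumsum(y)
  cs_tt <- cumsum(t * t); cs_ty <- cumsum(t * y)
  for (len in min_len:n) {
    i <- seq_len(n - len + 1L)
    j <- i + len - 1L
    St <- cs_t[j] - c(0, cs_t)[i]
    Sy <- cs_y[j] - c(0, cs_y)[i]
    Stt <- cs_tt[j] - c(0, cs_tt)[i]
    Sty <- cs_ty[j] - c(0, cs_ty)[i]
    denom <- len * Stt - St^2
    slope <- (len * Sty - St * Sy) / denom
    b <- match(max(slope), slope)  # earliest window on exact ties
    if (slope[b] > best$slope) {   # strict >: ties keep the earliest/shortest
      best <- list(slope = slope[b], start = i[b], end = j[b],
                   intercept = (Sy[b] - slope[b] * St[b]) / len)
    }
  }
  best
}

#' Maximum respiratory rate from a colony redness trace
#'
#' Scans all contiguous windows of at least `min_window` time points of the
#' (time, red intensity) series, fits `intensity = alpha * t + beta` by
#' ordinary least squares in each, and returns the window with the largest
#' slope `alpha` (intensity units per hour) — the maximum rate at which the
#' colony reduces the redox dye, a proxy for respiratory rate. Ties are broken
#' by the earliest window.
#'
#' @param time times in hours.
#' @param red mean red intensity of the colony at each time.
#' @param min_window minimum window length in points (default 10).
#' @return a list with `alpha`, `beta` (offset), and `window`
#'   (integer start/end indices of the maximising window).
#' @export
#' @examples
#' t <- seq(0, 5, length.out = 30)
#' respiratory_rate(t, 2 * t)$alpha  # 2
respiratory_rate <- function(time, red, min_window = 10) {
  stopifnot(length(time) == length(red))
  if (length(time) < min_window)
    stop("need at least ", min_window, " points")
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  b <- max_slope_window(time, red, as.integer(min_window))
  list(alpha = b$slope, beta = b$intercept,
       window = c(start = b$start, end = b$end))
}

#' Batch-culture growth rate and lag from an OD600 curve
#'
#' Finds the time window of at least `min_window_min` minutes with the maximum
#' exponential growth rate by scanning all contiguous windows and fitting
#' `ln(OD)` against time. The lag time is where the fitted exponential,
#' extended backwards, meets the initial OD of the inoculum:
#' `lag = (ln(OD_0) - intercept) / rate`.
#'
#' @param time times in hours, strictly increasing.
#' @param od OD600 values, strictly positive.
#' @param min_window_min minimum window span in minutes (default 100).
#' @return a list with `rate` (1/h), `lag` (h), `window` (start/end times of
#'   the chosen window, h) and `r_squared` of the log-linear fit.
#' @export
batch_growth_params <- function(time, od, min_window_min = 100) {
  stopifnot(length(time) == length(od))
  if (any(od <= 0)) stop("OD values must be positive")
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  span_h <- min_window_min / 60
  if (diff(range(time)) < span_h) stop("series shorter than the minimum window")
  y <- log(od)
  n <- length(time)
  best <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (time[j] - time[i] < span_h) next
      tt <- time[i:j]; yy <- y[i:j]
      mt <- mean(tt); my <- mean(yy)
      sxx <- sum((tt - mt)^2)
      slope <- sum((tt - mt) * (yy - my)) / sxx
      if (is.null(best) || slope > best$rate) {
        icpt <- my - slope * mt
        ssr <- sum((yy - icpt - slope * tt)^2)
        sst <- sum((yy - my)^2)
        best <- list(rate = slope, intercept = icpt,
                     window = c(start = time[i], end = time[j]),
                     r_squared = if (sst > 0) 1 - ssr / sst else NA_real_)
      }
    }
  }
  best$lag <- (y[1] - best$intercept) / best$rate
  best[c("rate", "lag", "window", "r_squared")]
}

#' Per-colony growth and respiration phenotypes from tracked traces
#'
#' Runs [fit_gompertz()] on each colony's area trace and [respiratory_rate()]
#' on its red-intensity trace, returning one phenotype row per colony as
#' consumed by the Pareto trade-off analysis.
#'
#' @param tracks a data frame as produced by [quantify_plate()] (or
#'   [gen_colony_timeseries()]): columns `colony_id`, `time_h` (or
#'   `frame_time_min`), `area`, `red`, optionally `x`, `y`, `dist_center`.
#' @param n_starts multistart count for the Gompertz fit.
#' @param min_window minimum respiratory-rate window (points).
#' @param lag_baseline baseline for [lag_time()]; `"amin"` (default) or
#'   `"zero"`.
#' @return a data frame with one row per colony: `colony_id`, `mu_max`,
#'   `lag_h`, `resp_rate`, `k`, `t_m`, `A_min`, `A_delta`, `rss`, `converged`,
#'   and any of `x`, `y`, `dist_center` present in the input.
#' @export
colony_phenotypes <- function(tracks, n_starts = 50, min_window = 10,
                              lag_baseline = c("amin", "zero")) {
  lag_baseline <- match.arg(lag_baseline)
  if (!"time_h" %in% names(tracks)) {
    if ("frame_time_min" %in% names(tracks)) {
      tracks$time_h <- tracks$frame_time_min / 60
    } else stop("tracks need a time_h or frame_time_min column")
  }
  ids <- unique(tracks$colony_id)
  keep_cols <- intersect(c("x", "y", "dist_center"), names(tracks))
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$colony_id == id, ]
    tr <- tr[order(tr$time_h), ]
    fit <- fit_gompertz(tr$time_h, tr$area, n_starts = n_starts)
    lag <- NA_real_
    mu <- NA_real_
    if (fit$converged) {
      mu <- max_growth_rate(fit)
      base <- if (lag_baseline == "amin") fit$A_min else 0
      lag <- lag_time(fit, baseline = base)
    }
    red <- tr$red %||% tr$mean_r
    alpha <- NA_real_
    if (!is.null(red) && sum(!is.na(red)) >= min_window) {
      ok <- !is.na(red)
      alpha <- respiratory_rate(tr$time_h[ok], red[ok],
                                min_window = min_window)$alpha
    }
    out <- data.frame(colony_id = id, mu_max = mu, lag_h = lag,
                      resp_rate = alpha, k = fit$k, t_m = fit$t_m,
                      A_min = fit$A_min, A_delta = fit$A_delta,
                      rss = fit$rss, converged = fit$converged)
    for (cc in keep_cols) out[[cc]] <- tr[[cc]][nrow(tr)]
    out
  })
  do.call(rbind, rows)
}
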