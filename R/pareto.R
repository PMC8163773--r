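#' Min-max normalization to \[0, 1\]
#'
#' @param values numeric vector with at least two distinct values.
#' @return `(v - min) / (max - min)`.
#' @export
minmax_normalize <- function(values) {
  r <- range(values, finite = TRUE)
  if (diff(r) == 0) stop("cannot normalize a constant vector")
  (values - r[1]) / (r[2] - r[1])
}

#' Colony fitness as growth rate over lag time
#'
#' Approximates colony fitness as the ratio of (normalized) growth rate to
#' (normalized) lag time; isoclines of constant fitness are the level sets of
#' this ratio in the normalized growth-rate / inverse-lag plane.
#'
#' @param growth_norm normalized growth rate in \[0, 1\].
#' @param lag_norm normalized lag time in (0, 1].
#' @return fitness values `growth_norm / lag_norm`.
#' @export
fitness <- function(growth_norm, lag_norm) {
  if (any(lag_norm == 0)) stop("zero lag term")
  growth_norm / lag_norm
}

#' Per-colony fitness from a phenotype table
#'
#' Normalizes growth rate and lag time to \[0, 1\] (min-max) and returns
#' their ratio; `normalized = FALSE` uses raw axes instead.
#'
#' @param phenotypes data frame with `mu_max` (or `growth_rate`) and
#'   `lag_h` (or `lag_time`) columns.
#' @param normalized normalize axes before taking the ratio (default TRUE,
#'   matching the normalized trade-off plane).
#' @param eps small positive floor added to the normalized lag to keep the
#'   shortest-lag colony finite.
#' @return numeric fitness vector.
#' @export
colony_fitness <- function(phenotypes, normalized = TRUE, eps = 1e-3) {
  g <- phenotypes$mu_max %||% phenotypes$growth_rate
  l <- phenotypes$lag_h %||% phenotypes$lag_time
  if (normalized) {
    g <- minmax_normalize(g)
    l <- minmax_normalize(l) + eps
  }
  fitness(g, l)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pareto front over (growth rate, lag time)
#'
#' Returns the non-dominated colonies under the objectives maximize growth
#' rate, minimize lag time: a colony is on the front if no other colony is at
#' least as good in both objectives and strictly better in one.
#'
#' @param growth_rate numeric vector, or a phenotype data frame with
#'   `mu_max`/`growth_rate` and `lag_h`/`lag_time` columns.
#' @param lag_time numeric vector (ignored if a data frame is given).
#' @return logical vector marking front members.
#' @export
pareto_front <- function(growth_rate, lag_time = NULL) {
  if (is.data.frame(growth_rate)) {
    df <- growth_rate
    lag_time <- df$lag_h %||% df$lag_time
    growth_rate <- df$mu_max %||% df$growth_rate
  }
  n <- length(growth_rate)
  if (n == 0) return(logical(0))
  ord <- order(-growth_rate, lag_time)
  dominated <- logical(n)
  best_lag_strict <- Inf  # min lag among strictly faster-growing colonies
  i <- 1
  while (i <= n) {
    # process the run of equal growth rates together
    j <- i
    while (j < n && growth_rate[ord[j + 1]] == growth_rate[ord[i]]) j <- j + 1
    grp <- ord[i:j]
    min_lag_grp <- min(lag_time[grp])
    dominated[grp] <- best_lag_strict <= lag_time[grp] |
      lag_time[grp] > min_lag_grp
    best_lag_strict <- min(best_lag_strict, min_lag_grp)
    i <- j + 1
  }
  !dominated
}

#' Lag time of an equally fit cell at a given growth rate
#'
#' In a simple exponential growth model, cells reaching the same number of
#' divisions `D` within a fixed total time `T` satisfy
#' `lambda * (T - T_lag) = c` with `c = D * ln 2`; growth rate and lag time
#' are therefore inversely related along the equal-fitness curve
#' `T_lag = T - c / lambda`.
#'
#' @param T total time (h), > 0.
#' @param c divisions constant `D * ln 2`, > 0.
#' @param lambda growth rate(s); must exceed `c / T` for a feasible
#'   (non-negative) lag.
#' @return lag time(s) `T - c / lambda`.
#' @export
equal_fitness_lag <- function(T, c, lambda) {
  stopifnot(T > 0, c > 0)
  if (any(lambda < c / T)) stop("infeasible growth rate: lambda < c / T")
  T - c / lambda
}

#' Growth-respiration correlation within a fitness band
#'
#' Selects colonies whose fitness lies between two quantiles of the fitness
#' distribution (type-7 quantiles; fitness ties broken by colony id for
#' reproducible membership) and returns the Spearman correlation between
#' growth and respiratory rate inside the band. Near the Pareto front (high
#' bands) a negative correlation is the signature of the
#' respiro-/fermentative trade-off.
#'
#' @param phenotypes data frame with `mu_max`, `resp_rate`, and either a
#'   `fitness` column or the columns [colony_fitness()] needs.
#' @param band two quantiles in \[0, 1\] (default `c(0.7, 0.8)`).
#' @param min_n minimum band occupancy (default 10).
#' @return list with `rho`, `p_value`, `n`, `band`.
#' @export
fitness_band_correlation <- function(phenotypes, band = c(0.7, 0.8),
                                     min_n = 10) {
  fit <- phenotypes$fitness %||% colony_fitness(phenotypes)
  qs <- stats::quantile(fit, band, type = 7, names = FALSE)
  sel <- fit >= qs[1] & fit <= qs[2]
  if (sum(sel) < min_n) stop("band holds fewer than ", min_n, " colonies")
  ct <- spearman_cor(phenotypes$mu_max[sel], phenotypes$resp_rate[sel])
  list(rho = ct$rho, p_value = ct$p_value, n = sum(sel), band = band)
}

#' Baseline fitness histogram of a uniform random cloud
#'
#' The "expected by random choice" reference: points drawn uniformly over the
#' bounding rectangle of the normalized (growth, inverse-lag) data, binned by
#' fitness on the same breaks as the observed histogram.
#'
#' @param fitness_values observed fitness values (defines the breaks).
#' @param n_draws number of uniform points (default 10000).
#' @param breaks number of histogram bins.
#' @param seed integer RNG seed.
#' @return list with `breaks`, `observed` counts and `expected` counts
#'   (scaled to the observed total).
#' @export
random_choice_baseline <- function(fitness_values, n_draws = 10000,
                                   breaks = 30, seed = 1) {
  set.seed(seed)
  g <- stats::runif(n_draws)
  l <- stats::runif(n_draws, min = 1e-3, max = 1)
  f <- g / l
  br <- seq(0, max(fitness_values, f), length.out = breaks + 1)
  obs <- graphics::hist(pmin(fitness_values, max(br)), breaks = br,
                        plot = FALSE)$counts
  exp_ <- graphics::hist(pmin(f, max(br)), breaks = br, plot = FALSE)$counts
  list(breaks = br, observed = obs,
       expected = exp_ * length(fitness_values) / n_draws)
}

#' Bootstrap distribution of the coefficient of variation
#'
#' Repeatedly draws `n_draw` colonies without replacement and records the CV
#' (sd/mean) of each draw — the resampling protocol behind comparisons of
#' population variability between strains.
#'
#' @param values phenotype values of the population.
#' @param n_draw colonies per draw (default 400).
#' @param n_reps number of draws (default 1000).
#' @param seed integer RNG seed.
#' @return numeric vector of `n_reps` CVs; draws whose mean is not positive
#'   are returned as `NA` with a warning attribute.
#' @export
cv_bootstrap <- function(values, n_draw = 400, n_reps = 1000, seed = 1) {
  if (n_draw > length(values)) stop("n_draw exceeds the population size")
  set.seed(seed)
  cvs <- vapply(seq_len(n_reps), function(r) {
    v <- values[sample.int(length(values), n_draw)]
    m <- mean(v)
    if (m <= 0) return(NA_real_)
    stats::sd(v) / m
  }, numeric(1))
  n_bad <- sum(is.na(cvs))
  if (n_bad > 0) attr(cvs, "flagged_draws") <- n_bad
  cvs
}

#' Compare two CV bootstrap distributions
#'
#' Two-sided t-test between the CV distributions of two populations
#' (each from [cv_bootstrap()]).
#'
#' @param cv_a,cv_b CV samples.
#' @return list with `mean_a`, `mean_b`, `p_value`.
#' @export
cv_compare <- function(cv_a, cv_b) {
  tt <- stats::t.test(cv_a, cv_b)
  list(mean_a = mean(cv_a, na.rm = TRUE), mean_b = mean(cv_b, na.rm = TRUE),
       p_value = tt$p.value)
}

#' Spearman rank correlation with large-sample p-value
#'
#' Midrank-tie rank correlation; the p-value comes from the standard
#' t-approximation (testing no correlation against a nonzero alternative).
#'
#' @param x,y equal-length numeric vectors (n >= 4).
#' @return list with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 4) stop("need at least 4 observations")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Lowess trend on a grid
#'
#' Locally weighted linear regression (tricube weights) evaluated on a
#' regular grid over the range of `x`; the smoothed-average trend line used
#' to display phenotype relationships.
#'
#' @param x,y data (n >= 10).
#' @param span smoothing span (fraction of points per local fit).
#' @param n_grid grid resolution.
#' @return data frame with `x` (grid) and `y` (smoothed values).
#' @export
lowess_trend <- function(x, y, span = 0.3, n_grid = 100) {
  if (length(x) < 10) stop("need at least 10 points")
  fit <- stats::loess(y ~ x, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(x), max(x), length.out = n_grid)
  data.frame(x = grid, y = stats::predict(fit, newdata = data.frame(x = grid)))
}

#' Respired carbon fraction
#'
#' One-line helper: the fraction of glucose carbon not secreted as acetate,
#' `1 - acetate_c_flux / glucose_c_flux`.
#'
#' @param acetate_c_flux acetate carbon secretion flux.
#' @param glucose_c_flux glucose carbon uptake flux.
#' @return respired carbon fraction.
#' @export
respired_carbon_fraction <- function(acetate_c_flux, glucose_c_flux) {
  1 - acetate_c_flux / glucose_c_flux
}
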