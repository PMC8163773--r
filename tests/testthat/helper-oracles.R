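# Independent brute-force oracles used to check the fast implementations.

# Otsu threshold by exhaustive search over a 256-bin histogram
oracle_otsu <- function(v) {
  br <- seq(min(v), max(v), length.out = 257)
  h <- hist(v, breaks = br, plot = FALSE)$counts
  mids <- (br[-1] + br[-257]) / 2
  best <- c(var = -Inf, thr = NA)
  for (t in 1:255) {
    w0 <- sum(h[1:t]); w1 <- sum(h[(t + 1):256])
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:t] * mids[1:t]) / w0
    m1 <- sum(h[(t + 1):256] * mids[(t + 1):256]) / w1
    v_b <- w0 * w1 * (m0 - m1)^2
    if (v_b > best["var"]) best <- c(var = v_b, thr = mids[t])
  }
  best[["thr"]]
}

# k-nearest-neighbour mean of eta in log10(mu), ties at the window edge all
# included, O(N^2)
oracle_knn_mean <- function(mu, eta, frac = 0.05) {
  n <- length(mu)
  lm10 <- log10(mu)
  k <- ceiling(frac * n)
  sapply(seq_len(n), function(i) {
    d <- abs(lm10 - lm10[i])
    cut <- sort(d)[k]
    mean(eta[d <= cut])
  })
}

# exhaustive max-slope window search over all contiguous windows >= min_len
oracle_max_slope <- function(t, y, min_len = 10) {
  n <- length(t)
  best <- list(slope = -Inf)
  for (len in min_len:n) for (i in 1:(n - len + 1)) {
    j <- i + len - 1
    fit <- lm(y[i:j] ~ t[i:j])
    sl <- unname(coef(fit)[2])
    if (sl > best$slope) best <- list(slope = sl, start = i, end = j)
  }
  best
}

# O(n^2) Pareto dominance check: maximize g, minimize l
oracle_pareto <- function(g, l) {
  n <- length(g)
  sapply(seq_len(n), function(i) {
    !any(g >= g[i] & l <= l[i] & (g > g[i] | l < l[i]))
  })
}

# numeric derivative of the Gompertz curve (central difference)
oracle_gompertz_deriv <- function(par, t, h = 1e-6) {
  (gompertz_value(t + h, par[1], par[2], par[3], par[4]) -
     gompertz_value(t - h, par[1], par[2], par[3], par[4])) / (2 * h)
}

# tangent-baseline crossing solved numerically: root of the tangent line at
# t_m minus the baseline level
oracle_tangent_lag <- function(par, baseline) {
  A_min <- par[1]; A_delta <- par[2]; k <- par[3]; t_m <- par[4]
  f_tm <- A_min + A_delta / exp(1)
  slope <- A_delta * k / exp(1)
  tangent <- function(t) f_tm + slope * (t - t_m) - baseline
  uniroot(tangent, interval = t_m + c(-1e6, 1e6), tol = 1e-14)$root
}

# a small, fast synthetic plate shared by imaging tests
small_plate <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- plate_sim_config(plate_diameter_px = 220, n_colonies = 10,
                              n_frames = 64, rng_seed = 42)
      cache <<- gen_plate_timelapse(cfg)
    }
    cache
  }
})
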