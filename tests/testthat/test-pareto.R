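test_that("minmax normalization and its invariances", {
  expect_equal(minmax_normalize(c(1, 2, 3)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(0, 0.25, 1)), c(0, 0.25, 1))
  set.seed(61)
  v <- rnorm(50)
  expect_equal(minmax_normalize(3 * v - 7), minmax_normalize(v))
  expect_error(minmax_normalize(rep(2, 5)), "constant")
})

test_that("fitness is the growth/lag ratio and is scale-invariant", {
  expect_equal(fitness(0.8, 0.4), 2)
  expect_equal(fitness(0.4, 0.2), 2)
  expect_error(fitness(0.5, 0), "zero lag")
})

test_that("pareto front matches the O(n^2) dominance oracle", {
  expect_equal(pareto_front(c(2, 1), c(1, 1)), c(TRUE, FALSE))
  expect_equal(pareto_front(c(1, 2, 3), c(1, 2, 3)), rep(TRUE, 3))
  expect_equal(pareto_front(5, 2), TRUE)
  set.seed(62)
  for (n in c(10, 100, 500, 2000)) {
    g <- round(runif(n), 2)  # rounding forces ties
    l <- round(runif(n), 2)
    expect_identical(pareto_front(g, l), oracle_pareto(g, l))
  }
  # every colony is either on the front or dominated by a front member
  g <- runif(300); l <- runif(300)
  on <- pareto_front(g, l)
  for (i in which(!on)) {
    expect_true(any(g[on] >= g[i] & l[on] <= l[i] &
                      (g[on] > g[i] | l[on] < l[i])))
  }
})

test_that("equal-fitness curve: divisions are constant along it", {
  expect_equal(equal_fitness_lag(10, 5, 1), 5)
  expect_equal(equal_fitness_lag(10, 5, 0.5), 0)
  expect_equal(equal_fitness_lag(10, 5, 1e9), 10, tolerance = 1e-6)
  lam <- seq(0.6, 5, length.out = 50)
  lag <- equal_fitness_lag(T = 10, c = 5, lambda = lam)
  expect_equal(lam * (10 - lag), rep(5, 50))
  expect_error(equal_fitness_lag(10, 5, 0.4), "infeasible")
})

test_that("fitness-band correlation detects the trade-off near the front", {
  set.seed(63)
  n <- 2000
  g <- runif(n)
  # near-front colonies: lag approximately inverse to growth; respiration
  # falls with growth along the front
  front <- runif(n) < 0.3
  lag <- ifelse(front, 1 / (g + 0.5) + rnorm(n, 0, 0.02),
                runif(n, 1 / (g + 0.5), 2.5))
  resp <- ifelse(front, 1 - 0.8 * g, runif(n)) + rnorm(n, 0, 0.05)
  ph <- data.frame(colony_id = 1:n, mu_max = g, lag_h = lag, resp_rate = resp)
  hi <- fitness_band_correlation(ph, band = c(0.85, 1))
  expect_lt(hi$rho, -0.5)
  expect_lt(hi$p_value, 1e-4)
  # the whole-population band is just the overall correlation
  all_band <- fitness_band_correlation(ph, band = c(0, 1))
  expect_equal(all_band$n, n)
  ct <- spearman_cor(g, resp)
  expect_equal(all_band$rho, ct$rho)
  # independent respiration: no signal
  ph$resp_rate <- runif(n)
  expect_lt(abs(fitness_band_correlation(ph, band = c(0.7, 0.8))$rho), 0.25)
  expect_error(fitness_band_correlation(ph[1:20, ], band = c(0.7, 0.72)),
               "fewer than")
})

test_that("cv bootstrap reproduces known coefficients of variation", {
  expect_true(all(cv_bootstrap(rep(5, 600), n_draw = 100, n_reps = 50) == 0))
  set.seed(64)
  pop <- rnorm(5000, 10, 2)
  cvs <- cv_bootstrap(pop, n_draw = 400, n_reps = 300, seed = 1)
  expect_equal(mean(cvs), 0.2, tolerance = 0.02)
  # fixed seed reproduces the distribution
  expect_identical(cvs, cv_bootstrap(pop, n_draw = 400, n_reps = 300, seed = 1))
  expect_error(cv_bootstrap(1:10, n_draw = 20), "exceeds")
  # two-population comparison returns a t-test p-value
  cmp <- cv_compare(cvs, cv_bootstrap(rnorm(5000, 10, 3), 400, 300, seed = 2))
  expect_lt(cmp$p_value, 1e-6)
  expect_lt(cmp$mean_a, cmp$mean_b)
})

test_that("spearman correlation endpoints and null behaviour", {
  expect_equal(spearman_cor(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  set.seed(65)
  ct <- spearman_cor(rnorm(1000), rnorm(1000))
  expect_lt(abs(ct$rho), 0.1)
  expect_error(spearman_cor(1:5, 1:4), "mismatch")
})

test_that("lowess trend reproduces lines and tracks smooth signals", {
  x <- seq(0, 10, length.out = 50)
  tr <- lowess_trend(x, 2 * x + 1, span = 0.4)
  expect_equal(tr$y, 2 * tr$x + 1, tolerance = 1e-6)
  tr0 <- lowess_trend(x, rep(3, 50), span = 0.4)
  expect_equal(tr0$y, rep(3, 100), tolerance = 1e-8)
  set.seed(66)
  x2 <- sort(runif(400, 0, 2 * pi))
  y2 <- sin(x2) + rnorm(400, 0, 0.3)
  tr2 <- lowess_trend(x2, y2, span = 0.3)
  rmse <- sqrt(mean((tr2$y - sin(tr2$x))^2))
  expect_lt(rmse, 0.3)
})

test_that("random-choice baseline differs from a front-shaped population", {
  set.seed(67)
  # a population concentrated on one isocline (fitness ~ constant)
  g <- runif(3000, 0.2, 0.8)
  ph <- data.frame(mu_max = g, lag_h = g + rnorm(3000, 0, 0.01))
  f <- colony_fitness(ph)
  bl <- random_choice_baseline(f, n_draws = 5000, seed = 3)
  expect_equal(sum(bl$observed), 3000)
  expect_equal(sum(bl$expected), 3000, tolerance = 0.02)
  # concentrated population: observed distribution deviates from uniform cloud
  chi <- sum((bl$observed - bl$expected)^2 / pmax(bl$expected, 1))
  expect_gt(chi, qchisq(0.999, df = length(bl$observed) - 1))
})
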