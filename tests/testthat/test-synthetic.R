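test_that("colony time-series generator honours its ground truth", {
  # zero noise: traces are exactly the Gompertz curves of the true parameters
  sim <- gen_colony_timeseries(3, noise_sd = 0, n_frames = 40, seed = 7)
  for (i in 1:3) {
    tr <- sim$traces[sim$traces$colony_id == i, ]
    th <- sim$truth[i, ]
    expect_equal(tr$area,
                 gompertz_value(tr$time_h, th$A_min, th$A_delta, th$k, th$t_m))
  }
  # determinism under a fixed seed
  sim2 <- gen_colony_timeseries(3, noise_sd = 0, n_frames = 40, seed = 7)
  expect_identical(sim, sim2)
  expect_error(gen_colony_timeseries(2, noise_sd = -1), ">= 0")
})

test_that("sampled growth-rate dispersion matches the configuration", {
  dists <- default_growth_dists()
  sim <- gen_colony_timeseries(4000, param_dists = dists, noise_sd = 0,
                               n_frames = 2, seed = 8)
  k <- sim$truth$k
  expect_equal(mean(k), dists$k[["mean"]], tolerance = 0.02)
  expect_equal(sd(k) / mean(k), dists$k[["disp"]], tolerance = 0.05)
})

test_that("protein-noise generator obeys its limiting cases", {
  g0 <- gen_protein_noise_table(100, deviation_sd = 0, seed = 3)
  expect_true(all(g0$truth$eps == 1))
  # a = 0 removes the mean dependence: eta is flat at b
  gflat <- gen_protein_noise_table(100, a = 0, b = 0.04, deviation_sd = 0,
                                   seed = 3)
  eta <- compute_noise(gflat$table$mu, gflat$table$sigma)
  expect_equal(eta, rep(0.04, 100), tolerance = 1e-10)
  # mu, sigma strictly positive; eta from the table equals the configured one
  g <- gen_protein_noise_table(500, deviation_sd = 0.5, seed = 4)
  expect_true(all(g$table$mu > 0 & g$table$sigma > 0))
  expect_equal(compute_noise(g$table$mu, g$table$sigma), g$truth$eta,
               tolerance = 1e-12)
  expect_error(gen_protein_noise_table(10, a = -1), ">= 0")
})

test_that("flux panel: noiseless OLS recovers slopes, nulls give uniform p", {
  pan <- gen_flux_protein_panel(30, noise_sd = 0, seed = 5)
  # exact fits make summary.lm warn about unreliable inference; the slopes
  # are what this case checks
  sc <- suppressWarnings(protein_flux_scaling(pan$protein, pan$flux, pan$mapping))
  expect_equal(sc$slope, pan$truth$slope, tolerance = 1e-8)
  expect_equal(sc$n_conditions, rep(7, 30))
  # null enzymes across repeated simulation: slope p-values roughly uniform
  ps <- unlist(lapply(1:25, function(s) {
    pan <- gen_flux_protein_panel(20, frac_null = 1, noise_sd = 0.2, seed = s)
    protein_flux_scaling(pan$protein, pan$flux, pan$mapping)$p_value
  }))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("metabolome generator plants its effect where it says", {
  gm <- gen_metabolome_matrix(n_ions = 200, effect_size = 3, seed = 9)
  expect_identical(dim(gm$intensities), c(200L, 6L))
  planted <- gm$truth$ion_id[gm$truth$log2_effect != 0]
  expect_setequal(planted, gm$pathways[[1]])
  # fixed seed reproduces the matrix
  gm2 <- gen_metabolome_matrix(n_ions = 200, effect_size = 3, seed = 9)
  expect_identical(gm$intensities, gm2$intensities)
  expect_error(gen_metabolome_matrix(n_replicates = 1), ">= 2")
})

test_that("plate simulator renders Gompertz-consistent disks", {
  # one colony, no noise, no gradient: mask pixel count equals the lattice
  # discretization of the analytic area
  cfg <- plate_sim_config(plate_diameter_px = 120, n_colonies = 1,
                          n_frames = 50, illumination_gradient_amplitude = 0,
                          pixel_noise_sd = 0, rng_seed = 2)
  sim <- gen_plate_timelapse(cfg)
  th <- sim$truth[1, ]
  for (f in c(20, 35, 50)) {
    t_h <- (f - 1) * 10 / 60
    a_t <- gompertz_value(t_h, th$A_min, th$A_delta, th$k, th$t_m)
    mask <- sim$stack$frames[[f]][, , 2] > 0.4
    # exact lattice-disk count
    d <- cfg$plate_diameter_px
    rr <- matrix(seq_len(d), d, d); cc <- t(rr)
    lattice <- sum((rr - th$center_row)^2 + (cc - th$center_col)^2 <= a_t / pi)
    expect_equal(sum(mask), lattice)
    # discretization error of a lattice disk is O(r), not more
    expect_lt(abs(sum(mask) - a_t), 8 * sqrt(a_t / pi) + 9)
  }
})

test_that("plate simulator: empty plates, determinism, packing errors", {
  cfg0 <- plate_sim_config(plate_diameter_px = 64, n_colonies = 0,
                           n_frames = 3, pixel_noise_sd = 0)
  sim0 <- gen_plate_timelapse(cfg0)
  expect_equal(nrow(sim0$truth), 0)
  expect_true(all(sim0$stack$frames[[3]][, , 1] ==
                    sim0$stack$frames[[1]][, , 1]))
  cfg <- plate_sim_config(plate_diameter_px = 100, n_colonies = 4,
                          n_frames = 4, rng_seed = 11)
  expect_identical(gen_plate_timelapse(cfg), gen_plate_timelapse(cfg))
  # infeasible packing raises an explicit error
  cfg_bad <- plate_sim_config(plate_diameter_px = 80, n_colonies = 60,
                              n_frames = 3)
  expect_error(gen_plate_timelapse(cfg_bad), "packing")
})

test_that("colony masks never overlap and stay inside the plate", {
  sim <- small_plate()
  truth <- sim$truth
  n <- nrow(truth)
  rmax <- sqrt((truth$A_min + truth$A_delta) / pi)
  ctr <- sim$stack$plate_center
  expect_true(all(sqrt((truth$center_row - ctr[1])^2 +
                         (truth$center_col - ctr[2])^2) + rmax <=
                    sim$stack$plate_radius))
  dd <- as.matrix(dist(truth[, c("center_row", "center_col")]))
  diag(dd) <- Inf
  sep <- outer(rmax, rmax, "+")
  expect_true(all(dd > sep))
})
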