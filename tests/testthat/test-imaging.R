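test_that("temporal std projection matches hand-computed values", {
  # constant stack -> all-zero raster
  fr <- replicate(4, array(0.3, dim = c(8, 8, 3)), simplify = FALSE)
  expect_true(all(project_temporal_std(fr) == 0))
  # one pixel alternating 0/1 over an even number of frames: population SD 0.5
  fr2 <- replicate(6, array(0, dim = c(8, 8, 3)), simplify = FALSE)
  for (f in c(2, 4, 6)) fr2[[f]][3, 5, ] <- 1
  s <- project_temporal_std(fr2)
  expect_equal(s[3, 5], 0.5)
  expect_equal(sum(s > 0), 1)
  # permutation invariance over frame order
  expect_equal(project_temporal_std(fr2[c(4, 1, 6, 2, 5, 3)]), s)
  expect_error(project_temporal_std(fr2[1]), "at least 2")
})

test_that("plate-restricted Otsu separates two populations exactly", {
  set.seed(31)
  raster <- matrix(0.1, 40, 40)
  bright <- matrix(FALSE, 40, 40); bright[10:20, 10:20] <- TRUE
  raster[bright] <- 0.9
  fg <- threshold_plate(raster)
  thr <- attr(fg, "threshold")
  attr(fg, "threshold") <- NULL
  expect_identical(fg, bright)
  expect_true(thr > 0.1 && thr < 0.9)
  # agrees with a brute-force Otsu over a 256-bin histogram
  v <- runif(4000)^3
  r2 <- matrix(v, 50, 80)
  expect_equal(attr(threshold_plate(r2), "threshold"), oracle_otsu(v),
               tolerance = 0.02)
  # a mask excluding all bright pixels yields an empty foreground
  m <- !bright
  raster2 <- raster + matrix(rnorm(1600, 0, 1e-3), 40)
  expect_equal(sum(threshold_plate(raster2, m) & m), sum(raster2[m] >
                 attr(threshold_plate(raster2, m), "threshold")))
  expect_error(threshold_plate(matrix(1, 5, 5)), "degenerate")
})

test_that("Otsu symmetry: inverting the image complements the foreground", {
  set.seed(32)
  raster <- matrix(c(rnorm(800, 0.2, 0.02), rnorm(800, 0.8, 0.02)), 40, 40)
  fg <- threshold_plate(raster)
  fg_inv <- threshold_plate(1 - raster)
  # bright pixels of the original are the background of the inverted image
  expect_true(mean(fg == !fg_inv) > 0.99)
})

test_that("watershed splits disjoint and neck-merged disks", {
  mk_disk <- function(m, r0, c0, rad, val = 1) {
    d <- dim(m)
    rr <- matrix(seq_len(d[1]), d[1], d[2]); cc <- t(matrix(seq_len(d[2]), d[2], d[1]))
    m[(rr - r0)^2 + (cc - c0)^2 <= rad^2] <- val
    m
  }
  std <- matrix(0, 60, 60)
  std <- mk_disk(std, 20, 20, 8, 0.5)
  std <- mk_disk(std, 42, 42, 8, 0.5)
  lab <- segment_colonies(std, std > 0)
  expect_equal(max(lab), 2)
  st <- colonoise:::frame_stats(lab)
  expect_equal(sort(round(st$row)), c(20, 42), tolerance = 2)
  # two peaks merged by a thin flat neck still give two labels
  std2 <- matrix(0, 60, 60)
  std2 <- mk_disk(std2, 30, 18, 8, 0.3)
  std2 <- mk_disk(std2, 30, 44, 8, 0.3)
  std2 <- mk_disk(std2, 30, 18, 4, 0.6)
  std2 <- mk_disk(std2, 30, 44, 4, 0.6)
  std2[30, 18:44] <- pmax(std2[30, 18:44], 0.3)  # the neck
  expect_equal(max(segment_colonies(std2, std2 > 0, h = 0.1)), 2)
  # empty mask: zero labels
  expect_equal(max(segment_colonies(std, matrix(FALSE, 60, 60))), 0)
})

test_that("tracking links stationary colonies and respects the gate", {
  lab <- matrix(0L, 30, 30)
  lab[5:8, 5:8] <- 1L
  lab[20:23, 20:23] <- 2L
  tracks <- track_colonies(replicate(5, lab, simplify = FALSE))
  expect_equal(length(unique(tracks$colony_id)), 2)
  for (id in unique(tracks$colony_id)) {
    tr <- tracks[tracks$colony_id == id, ]
    expect_equal(length(unique(tr$row)), 1)
    expect_equal(nrow(tr), 5)
  }
  # a jump beyond the gate opens a new track instead of swapping identity
  labA <- matrix(0L, 30, 30); labA[2:4, 2:4] <- 1L
  labB <- matrix(0L, 30, 30); labB[25:27, 25:27] <- 1L
  tracks2 <- track_colonies(list(labA, labA, labB), gate = 5)
  expect_equal(length(unique(tracks2$colony_id)), 2)
})

test_that("artifact filter removes rim, shrinking and short tracks", {
  mk_track <- function(id, areas, row, col) {
    data.frame(colony_id = id, frame = seq_along(areas),
               frame_time_min = 10 * (seq_along(areas) - 1), area = areas,
               row = row, col = col, mean_r = 0.5, mean_g = 0.5, mean_b = 0.5)
  }
  good <- mk_track(1, c(0, 2, 5, 9, 14, 20), 50, 50)
  rim <- mk_track(2, c(0, 2, 5, 9, 14, 20), 50, 97)
  shrink <- mk_track(3, c(0, 5, 20, 8, 14, 20), 50, 30)
  short <- mk_track(4, c(0, 0, 0, 4, 9, 20), 30, 50)
  tracks <- rbind(good, rim, shrink, short)
  out <- filter_artifacts(tracks, min_frames = 3, edge_margin = 5,
                          plate_center = c(50, 50), plate_radius = 50)
  expect_setequal(unique(out$colony_id), c(1, 4))
  out2 <- filter_artifacts(tracks, min_frames = 5, edge_margin = 5,
                           plate_center = c(50, 50), plate_radius = 50)
  expect_setequal(unique(out2$colony_id), 1)
  # permissive configuration is the identity
  all_in <- filter_artifacts(tracks, min_frames = 0, min_area = 0,
                             edge_margin = -Inf, max_rel_decrease = Inf)
  expect_setequal(unique(all_in$colony_id), 1:4)
})

test_that("end-to-end quantification recovers the synthetic plate", {
  sim <- small_plate()
  tracks <- quantify_plate(sim$stack)
  ph <- colony_phenotypes(tracks, n_starts = 16)
  truth <- sim$truth
  expect_gte(nrow(ph), 0.95 * nrow(truth))
  hits <- sapply(seq_len(nrow(truth)), function(i) {
    d <- sqrt((ph$y - truth$center_row[i])^2 + (ph$x - truth$center_col[i])^2)
    min(d)
  })
  expect_lt(max(hits), 3)
  # tracking is deterministic on identical input
  tracks2 <- quantify_plate(sim$stack)
  expect_identical(tracks, tracks2)
  # labels are disjoint by construction; total area below the plate area
  per_frame <- tapply(tracks$area, tracks$frame, sum)
  expect_true(all(per_frame <= pi * sim$stack$plate_radius^2))
})

test_that("phenotype inputs carry distance-to-centre and the red slope", {
  sim <- small_plate()
  tracks <- quantify_plate(sim$stack)
  truth <- sim$truth
  ctr <- sim$stack$plate_center
  one <- tracks[tracks$colony_id == tracks$colony_id[1], ]
  inp <- extract_phenotype_inputs(one, plate_center = ctr)
  expect_named(inp, c("time_h", "area", "red", "dist_center"))
  i <- which.min(sqrt((truth$center_row - one$row[nrow(one)])^2 +
                        (truth$center_col - one$col[nrow(one)])^2))
  d_true <- unname(sqrt((truth$center_row[i] - ctr[1])^2 +
                          (truth$center_col[i] - ctr[2])^2))
  expect_equal(inp$dist_center[1], d_true, tolerance = 1)
  # OLS on the post-lag red series recovers the colony's alpha within 5%
  post <- !is.na(inp$red) & inp$time_h > truth$lag_h[i] + 0.5
  slope <- unname(coef(lm(inp$red[post] ~ inp$time_h[post]))[2])
  expect_equal(slope, truth$alpha[i], tolerance = 0.05)
})

test_that("plate detection finds the synthetic plate geometry", {
  sim <- small_plate()
  geo <- detect_plate(sim$stack$frames[[1]])
  expect_equal(unname(geo$center), unname(sim$stack$plate_center),
               tolerance = 2)
  expect_equal(geo$radius, sim$stack$plate_radius, tolerance = 4)
})
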