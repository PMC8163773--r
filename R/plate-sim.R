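#' Configuration for the plate time-lapse simulator
#'
#' Assembles and validates the parameters of [gen_plate_timelapse()]. Defaults
#' emulate a flatbed-scanner Petri-dish assay sampled every 10 minutes, at a
#' raster scale small enough for routine in-memory analysis.
#'
#' @param plate_diameter_px plate diameter in pixels.
#' @param n_colonies number of colonies to place (>= 0).
#' @param frame_interval sampling interval in minutes.
#' @param n_frames number of frames (>= 2).
#' @param growth_param_distributions per-parameter mean/dispersion list, see
#'   [default_growth_dists()].
#' @param respiration_rate_distribution `c(mean, disp)` of the red-accumulation
#'   slope alpha (intensity units per hour).
#' @param illumination_gradient_amplitude fractional amplitude of a smooth
#'   radial illumination gradient over the plate background.
#' @param pixel_noise_sd i.i.d. Gaussian pixel noise standard deviation
#'   (intensity units; intensities live in \[0, 1\]).
#' @param rng_seed integer RNG seed.
#' @return a validated list of class `"plate_sim_config"`.
#' @export
plate_sim_config <- function(plate_diameter_px = 360, n_colonies = 50,
                             frame_interval = 10, n_frames = 88,
                             growth_param_distributions = default_growth_dists(),
                             respiration_rate_distribution = c(mean = 0.02, disp = 0.3),
                             illumination_gradient_amplitude = 0.1,
                             pixel_noise_sd = 0.02, rng_seed = 1) {
  stopifnot(n_colonies >= 0, n_frames >= 2, plate_diameter_px >= 16,
            frame_interval > 0, pixel_noise_sd >= 0,
            illumination_gradient_amplitude >= 0)
  for (p in growth_param_distributions)
    if (p[["disp"]] < 0) stop("dispersions must be >= 0")
  if (respiration_rate_distribution[["disp"]] < 0)
    stop("dispersions must be >= 0")
  structure(list(
    plate_diameter_px = as.integer(plate_diameter_px),
    n_colonies = as.integer(n_colonies),
    frame_interval = frame_interval, n_frames = as.integer(n_frames),
    growth_param_distributions = growth_param_distributions,
    respiration_rate_distribution = respiration_rate_distribution,
    illumination_gradient_amplitude = illumination_gradient_amplitude,
    pixel_noise_sd = pixel_noise_sd, rng_seed = as.integer(rng_seed)),
    class = "plate_sim_config")
}

# Rejection-sample non-overlapping colony centres inside the plate.
# Coordinates are (row, col), 0-based, origin at the top-left of the raster.
place_colonies <- function(n, plate_radius, centre, radii, margin = 3,
                           max_attempts = 10000) {
  rows <- numeric(0); cols <- numeric(0)
  attempts <- 0
  for (i in seq_len(n)) {
    repeat {
      attempts <- attempts + 1
      if (attempts > max_attempts)
        stop("infeasible packing: could not place ", n,
             " colonies in ", max_attempts, " attempts")
      r_lim <- plate_radius - radii[i] - margin
      u <- sqrt(stats::runif(1)) * r_lim
      th <- stats::runif(1, 0, 2 * pi)
      rr <- centre[1] + u * sin(th)
      cc <- centre[2] + u * cos(th)
      if (length(rows) == 0 ||
          all(sqrt((rows - rr)^2 + (cols - cc)^2) >=
              radii[seq_along(rows)] + radii[i] + margin)) {
        rows <- c(rows, rr); cols <- c(cols, cc)
        break
      }
    }
  }
  data.frame(center_row = rows, center_col = cols)
}

#' Simulate a plate time-lapse image stack with known ground truth
#'
#' Renders an RGB frame series of a circular plate carrying disk-shaped
#' colonies. Each colony's pixel area follows its own Gompertz curve; its red
#' channel rises linearly at a colony-specific rate `alpha` starting at the
#' colony's lag time (redox-dye accumulation is tied to active metabolism).
#' A smooth radial illumination gradient and i.i.d. Gaussian pixel noise are
#' added. All randomness derives from `cfg$rng_seed`, so identical
#' configurations give bit-identical stacks.
#'
#' @param cfg a [plate_sim_config()].
#' @return a list with `stack` (an image stack as consumed by
#'   [quantify_plate()]: `frames` list of height x width x 3 arrays,
#'   `frame_times` in minutes, `plate_center` (row, col), `plate_radius`) and
#'   `truth` (per-colony true `A_min`, `A_delta`, `k`, `t_m`, `alpha`,
#'   `lag_h`, `center_row`, `center_col`).
#' @export
gen_plate_timelapse <- function(cfg = plate_sim_config()) {
  stopifnot(inherits(cfg, "plate_sim_config"))
  set.seed(cfg$rng_seed)
  d <- cfg$plate_diameter_px
  centre <- c(row = (d + 1) / 2, col = (d + 1) / 2)
  plate_radius <- d / 2
  t_h <- (seq_len(cfg$n_frames) - 1L) * cfg$frame_interval / 60

  n <- cfg$n_colonies
  truth <- if (n > 0) {
    pars <- sample_growth_params(n, cfg$growth_param_distributions)
    pars$alpha <- rlnorm_meancv(n, cfg$respiration_rate_distribution[["mean"]],
                                cfg$respiration_rate_distribution[["disp"]])
    pars$lag_h <- pars$t_m - 1 / pars$k
    rmax <- sqrt((pars$A_min + pars$A_delta) / pi)
    pos <- place_colonies(n, plate_radius, centre, rmax)
    cbind(colony_id = seq_len(n), pars, pos)
  } else {
    data.frame(colony_id = integer(0), A_min = numeric(0),
               A_delta = numeric(0), k = numeric(0), t_m = numeric(0),
               alpha = numeric(0), lag_h = numeric(0),
               center_row = numeric(0), center_col = numeric(0))
  }

  # static background: plate at 0.15 with a radial illumination gradient,
  # zero outside the plate
  rowg <- matrix(seq_len(d), d, d)
  colg <- matrix(seq_len(d), d, d, byrow = TRUE)
  dist2 <- (rowg - centre[1])^2 + (colg - centre[2])^2
  inplate <- dist2 <= plate_radius^2
  illum <- 1 + cfg$illumination_gradient_amplitude *
    (0.5 - dist2 / plate_radius^2)
  bg <- 0.15 * illum * inplate

  # per-colony pixel lists, precomputed once over each colony's bounding box
  col_pix <- lapply(seq_len(n), function(i) {
    rmax_i <- sqrt((truth$A_min[i] + truth$A_delta[i]) / pi)
    r0 <- max(1L, floor(truth$center_row[i] - rmax_i - 1))
    r1 <- min(d, ceiling(truth$center_row[i] + rmax_i + 1))
    c0 <- max(1L, floor(truth$center_col[i] - rmax_i - 1))
    c1 <- min(d, ceiling(truth$center_col[i] + rmax_i + 1))
    rr <- rep(r0:r1, times = c1 - c0 + 1L)
    cc <- rep(c0:c1, each = r1 - r0 + 1L)
    d2 <- (rr - truth$center_row[i])^2 + (cc - truth$center_col[i])^2
    list(idx = rr + (cc - 1L) * d, d2 = d2)
  })

  npx <- d * d
  frames <- vector("list", cfg$n_frames)
  for (f in seq_len(cfg$n_frames)) {
    gray <- bg
    redadd <- numeric(npx)
    for (i in seq_len(n)) {
      a_t <- gompertz_value(t_h[f], truth$A_min[i], truth$A_delta[i],
                            truth$k[i], truth$t_m[i])
      r_t2 <- a_t / pi
      sel <- col_pix[[i]]$idx[col_pix[[i]]$d2 <= r_t2]
      gray[sel] <- 0.55
      red_t <- truth$alpha[i] * max(0, t_h[f] - truth$lag_h[i])
      if (red_t > 0) redadd[sel] <- red_t
    }
    fr <- array(0, dim = c(d, d, 3))
    fr[, , 1] <- gray + redadd
    fr[, , 2] <- gray
    fr[, , 3] <- gray
    if (cfg$pixel_noise_sd > 0) {
      fr <- fr + array(stats::rnorm(3 * npx, 0, cfg$pixel_noise_sd),
                       dim = c(d, d, 3))
    }
    frames[[f]] <- pmin(pmax(fr, 0), 1)
  }
  stack <- list(frames = frames,
                frame_times = (seq_len(cfg$n_frames) - 1L) * cfg$frame_interval,
                plate_center = centre, plate_radius = plate_radius)
  class(stack) <- "image_stack"
  list(stack = stack, truth = truth)
}
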