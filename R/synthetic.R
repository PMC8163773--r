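# Sample a positive parameter: log-normal with mean `mean` and coefficient of
# variation `cv` (dispersion 0 collapses to the constant mean).
rlnorm_meancv <- function(n, mean, cv) {
  if (cv < 0) stop("dispersion must be >= 0")
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Default colony growth-parameter distributions
#'
#' Per-parameter mean and dispersion (coefficient of variation; sd in hours
#' for the normally distributed inflection time `t_m`) used by the colony
#' generators. Units: areas in pixels^2, `k` in 1/h, `t_m` in h.
#'
#' @return a named list of `c(mean, disp)` pairs for `A_min`, `A_delta`, `k`,
#'   `t_m`.
#' @export
default_growth_dists <- function() {
  list(A_min = c(mean = 6, disp = 0.2),
       A_delta = c(mean = 320, disp = 0.25),
       k = c(mean = 0.5, disp = 0.2),
       t_m = c(mean = 7, disp = 1.2))
}

sample_growth_params <- function(n, dists) {
  data.frame(
    A_min = rlnorm_meancv(n, dists$A_min[["mean"]], dists$A_min[["disp"]]),
    A_delta = rlnorm_meancv(n, dists$A_delta[["mean"]], dists$A_delta[["disp"]]),
    k = rlnorm_meancv(n, dists$k[["mean"]], dists$k[["disp"]]),
    t_m = stats::rnorm(n, dists$t_m[["mean"]], dists$t_m[["disp"]]))
}

#' Simulate per-colony area and redness traces with known ground truth
#'
#' Draws `n` colonies with Gompertz growth parameters from `param_dists`
#' (log-normal for `A_min`, `A_delta`, `k`; normal for `t_m`) and a redox-dye
#' accumulation slope `alpha` (AU/h, log-normal). Each colony's area trace is
#' the Gompertz curve plus i.i.d. Gaussian noise with standard deviation
#' `noise_sd * A_delta` (noise is relative to the colony's amplitude); redness
#' is flat at a baseline until the colony's lag time, then rises linearly at
#' rate `alpha`, with the same relative noise against an intensity scale of 1.
#'
#' @param n number of colonies (>= 1).
#' @param param_dists growth-parameter distributions, see
#'   [default_growth_dists()].
#' @param alpha_dist `c(mean, disp)` of the red-accumulation slope (AU/h).
#' @param noise_sd relative noise level (0 gives exact curves).
#' @param n_frames number of time points.
#' @param frame_interval sampling interval in minutes.
#' @param seed integer RNG seed.
#' @return a list with `traces` (data frame: `colony_id`, `time_h`, `area`,
#'   `red`) and `truth` (data frame of per-colony true `A_min`, `A_delta`,
#'   `k`, `t_m`, `alpha`, `lag_h`, `mu_max`).
#' @export
gen_colony_timeseries <- function(n, param_dists = default_growth_dists(),
                                  alpha_dist = c(mean = 0.02, disp = 0.3),
                                  noise_sd = 0.05, n_frames = 90,
                                  frame_interval = 10, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  pars <- sample_growth_params(n, param_dists)
  pars$alpha <- rlnorm_meancv(n, alpha_dist[["mean"]], alpha_dist[["disp"]])
  pars$lag_h <- pars$t_m - 1 / pars$k
  pars$mu_max <- pars$A_delta * pars$k / exp(1)
  t_h <- (seq_len(n_frames) - 1L) * frame_interval / 60
  traces <- do.call(rbind, lapply(seq_len(n), function(i) {
    a <- gompertz_value(t_h, pars$A_min[i], pars$A_delta[i],
                        pars$k[i], pars$t_m[i])
    if (noise_sd > 0) a <- a + stats::rnorm(n_frames, 0, noise_sd * pars$A_delta[i])
    red <- 0.55 + pars$alpha[i] * pmax(0, t_h - pars$lag_h[i])
    if (noise_sd > 0) red <- red + stats::rnorm(n_frames, 0, noise_sd * 0.1)
    data.frame(colony_id = i, time_h = t_h, area = a, red = red)
  }))
  pars$colony_id <- seq_len(n)
  list(traces = traces, truth = pars)
}

#' Simulate a single-cell protein summary table with known deviating noise
#'
#' Protein mean copy numbers `mu` are log-normal; the true noise is
#' `eta = (a / mu + b) * eps`, the standard intrinsic-plus-extrinsic
#' mean-dependence scaled by a per-protein deviation factor `eps` (log-normal
#' with log-sd `deviation_sd`, so `deviation_sd = 0` gives `eps = 1` for
#' all proteins). Standard deviations are `sigma = mu * sqrt(eta)`. Optional
#' annotation sets and an essentiality flag can be attached with a
#' configurable association between membership and high `eps`.
#'
#' @param n_proteins number of proteins.
#' @param mu_meanlog,mu_sdlog log-normal parameters of the copy-number
#'   distribution (defaults span roughly 1 to 1e5 copies).
#' @param a intrinsic-noise coefficient (>= 0), the `1/mu` term.
#' @param b extrinsic-noise floor (>= 0).
#' @param deviation_sd log-sd of the deviation factor `eps`.
#' @param n_sets number of random annotation sets to attach (0 for none).
#' @param set_size size of each annotation set.
#' @param set_bias association strength: sets are drawn with sampling weights
#'   `eps^set_bias`, so 0 gives unbiased sets and larger values concentrate
#'   membership on high-deviation proteins.
#' @param essential_frac fraction of proteins flagged essential, drawn with
#'   weights `eps^(-set_bias)` (essential genes biased to low deviation).
#' @param seed integer RNG seed.
#' @return a list with `table` (data frame: `protein_id`, `mu`, `sigma`,
#'   `essential`), `sets` (named list of protein-id vectors) and `truth`
#'   (data frame with true `eta` and `eps` per protein).
#' @export
gen_protein_noise_table <- function(n_proteins = 1000, mu_meanlog = log(500),
                                    mu_sdlog = 1.8, a = 200, b = 0.05,
                                    deviation_sd = 0.5, n_sets = 0,
                                    set_size = 25, set_bias = 0,
                                    essential_frac = 0, seed = 1) {
  if (a < 0 || b < 0) stop("a and b must be >= 0")
  if (deviation_sd < 0) stop("deviation_sd must be >= 0")
  set.seed(seed)
  mu <- stats::rlnorm(n_proteins, mu_meanlog, mu_sdlog)
  eps <- if (deviation_sd == 0) rep(1, n_proteins) else
    stats::rlnorm(n_proteins, -deviation_sd^2 / 2, deviation_sd)
  eta <- (a / mu + b) * eps
  sigma <- mu * sqrt(eta)
  ids <- sprintf("P%04d", seq_len(n_proteins))
  essential <- rep(FALSE, n_proteins)
  if (essential_frac > 0) {
    k <- round(essential_frac * n_proteins)
    w <- eps^(-set_bias)
    essential[sample.int(n_proteins, k, prob = w / sum(w))] <- TRUE
  }
  sets <- list()
  if (n_sets > 0) {
    w <- eps^set_bias
    sets <- stats::setNames(lapply(seq_len(n_sets), function(i) {
      ids[sample.int(n_proteins, set_size, prob = w / sum(w))]
    }), sprintf("SET%03d", seq_len(n_sets)))
  }
  list(table = data.frame(protein_id = ids, mu = mu, sigma = sigma,
                          essential = essential),
       sets = sets,
       truth = data.frame(protein_id = ids, mu = mu, eta = eta, eps = eps))
}

#' Simulate matched enzyme-abundance and flux panels across conditions
#'
#' Enzyme copy numbers vary log-normally across conditions; each enzyme's flux
#' is `flux = s * protein + noise` with a per-enzyme true slope `s` drawn
#' log-normally, except for a configurable subset with `s = 0` (fluxes then
#' pure noise). Emulates bulk proteome/fluxome panels measured across a small
#' number of growth conditions.
#'
#' @param n_enzymes number of enzymes.
#' @param n_conditions number of conditions (>= 3; default 7).
#' @param slope_dist `c(mean, disp)` of the log-normal slope distribution.
#' @param frac_null fraction of enzymes with zero slope.
#' @param noise_sd flux noise standard deviation, relative to each enzyme's
#'   mean |s * protein| signal (enzymes with `s = 0` get the panel-median
#'   signal scale).
#' @param seed integer RNG seed.
#' @return a list with `protein` and `flux` matrices (enzymes x conditions),
#'   a `mapping` data frame (enzyme to reaction, identity), and `truth`
#'   (per-enzyme true slope).
#' @export
gen_flux_protein_panel <- function(n_enzymes = 40, n_conditions = 7,
                                   slope_dist = c(mean = 1, disp = 0.5),
                                   frac_null = 0.25, noise_sd = 0.1,
                                   seed = 1) {
  if (n_conditions < 3) stop("need at least 3 conditions")
  set.seed(seed)
  ids <- sprintf("E%03d", seq_len(n_enzymes))
  prot <- matrix(stats::rlnorm(n_enzymes * n_conditions, log(1000), 0.6),
                 n_enzymes, n_conditions,
                 dimnames = list(ids, sprintf("cond%d", seq_len(n_conditions))))
  s <- rlnorm_meancv(n_enzymes, slope_dist[["mean"]], slope_dist[["disp"]])
  n_null <- round(frac_null * n_enzymes)
  if (n_null > 0) s[sample.int(n_enzymes, n_null)] <- 0
  signal <- abs(s) * rowMeans(prot)
  scale0 <- stats::median(signal[signal > 0])
  if (!is.finite(scale0)) scale0 <- stats::median(rowMeans(prot))
  signal[signal == 0] <- scale0
  flux <- s * prot
  if (noise_sd > 0) {
    flux <- flux + matrix(stats::rnorm(length(flux)), n_enzymes) *
      (noise_sd * signal)
  }
  rownames(flux) <- sub("^E", "R", ids)
  list(protein = prot, flux = flux,
       mapping = data.frame(enzyme_id = ids, reaction_id = rownames(flux)),
       truth = data.frame(enzyme_id = ids, slope = s))
}

#' Simulate an ion-by-sample metabolome intensity matrix
#'
#' Log-normal baseline intensities per ion; ions belonging to
#' `affected_pathway` are shifted by `effect_size` (log2 units) in group
#' `groups[2]`. Ions are partitioned into equally sized pathways.
#'
#' @param n_ions number of ions.
#' @param groups character vector of two group names.
#' @param n_replicates replicates per group.
#' @param n_pathways number of pathway sets the ions are partitioned into.
#' @param affected_pathway index (or name) of the pathway receiving the shift.
#' @param effect_size shift in log2 units applied in the second group.
#' @param rep_sd replicate log2 standard deviation.
#' @param seed integer RNG seed.
#' @return a list with `intensities` (ions x samples matrix), `samples`
#'   (data frame: `sample`, `group`, `replicate`), `pathways` (named list of
#'   ion ids) and `truth` (per-ion true log2 effect).
#' @export
gen_metabolome_matrix <- function(n_ions = 400, groups = c("WT", "mutant"),
                                  n_replicates = 3, n_pathways = 20,
                                  affected_pathway = 1, effect_size = 2,
                                  rep_sd = 0.3, seed = 1) {
  if (n_replicates < 2) stop("need >= 2 samples per group")
  set.seed(seed)
  n_pathways <- min(n_pathways, n_ions)
  ions <- sprintf("ion%04d", seq_len(n_ions))
  pw <- stats::setNames(
    split(ions, rep(seq_len(n_pathways), length.out = n_ions)),
    sprintf("PW%02d", seq_len(n_pathways)))
  base <- stats::rnorm(n_ions, 14, 2)  # log2 baseline
  effect <- rep(0, n_ions)
  effect[ions %in% pw[[affected_pathway]]] <- effect_size
  samples <- data.frame(
    sample = paste0(rep(groups, each = n_replicates), "_",
                    rep(seq_len(n_replicates), 2)),
    group = rep(groups, each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2))
  logm <- sapply(seq_len(nrow(samples)), function(j) {
    shift <- if (samples$group[j] == groups[2]) effect else 0
    base + shift + stats::rnorm(n_ions, 0, rep_sd)
  })
  dimnames(logm) <- list(ions, samples$sample)
  pw_of <- stats::setNames(rep(names(pw), lengths(pw)),
                           unlist(pw, use.names = FALSE))
  list(intensities = 2^logm, samples = samples, pathways = pw,
       truth = data.frame(ion_id = ions, log2_effect = effect,
                          pathway = unname(pw_of[ions])))
}
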