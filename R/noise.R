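#' Expression noise of a protein
#'
#' Squared coefficient of variation of protein copy number across cells,
#' `eta = sigma^2 / mu^2`.
#'
#' @param mu mean copy number (> 0), vectorised.
#' @param sigma standard deviation of copy number.
#' @return the noise `eta`.
#' @export
compute_noise <- function(mu, sigma) {
  if (any(mu <= 0)) stop("mu must be > 0")
  sigma^2 / mu^2
}

#' Expected mean noise at each protein's abundance
#'
#' For every protein, the expected noise level `eta_bar` is the average noise
#' of the proteins closest to it in abundance: the neighbourhood is all
#' proteins whose distance in `log10(mu)` is at most the k-th smallest
#' distance, with `k = ceiling(neighbor_fraction * N)` and the protein itself
#' included (distance ties at the window edge are all included). This is a
#' running-mean smoother of the noise-versus-abundance scaling law, against
#' which deviating noise is measured.
#'
#' @param mu mean copy numbers (> 0), length >= 20.
#' @param eta noise values from [compute_noise()].
#' @param neighbor_fraction fraction of proteins defining the abundance
#'   window (default 0.05, the 5% closest proteins).
#' @return `eta_bar`, same length as `mu`.
#' @export
smooth_mean_noise <- function(mu, eta, neighbor_fraction = 0.05) {
  n <- length(mu)
  stopifnot(length(eta) == n)
  if (n < 20) stop("need at least 20 proteins")
  if (any(mu <= 0)) stop("mu must be > 0")
  lm10 <- log10(mu)
  k <- ceiling(neighbor_fraction * n)
  vapply(seq_len(n), function(i) {
    d <- abs(lm10 - lm10[i])
    cut <- sort(d, partial = k)[k]
    mean(eta[d <= cut])
  }, numeric(1))
}

#' Deviating noise
#'
#' Ratio of a protein's noise to the mean noise of proteins with similar
#' abundance, `epsilon = eta / eta_bar`. Values above 1 (log2 above 0) mark
#' proteins noisier than their abundance predicts.
#'
#' @param eta noise values.
#' @param eta_bar expected noise from [smooth_mean_noise()].
#' @param log2 if `TRUE`, return `log2(epsilon)` so that zero marks
#'   "no deviation".
#' @return deviating noise values.
#' @export
deviating_noise <- function(eta, eta_bar, log2 = FALSE) {
  if (any(eta_bar <= 0)) stop("eta_bar must be > 0")
  eps <- eta / eta_bar
  if (log2) base::log2(eps) else eps
}

#' Deviating-noise table from a protein summary table
#'
#' Convenience wrapper chaining [compute_noise()], [smooth_mean_noise()] and
#' [deviating_noise()] on a table with columns `protein_id`, `mu`, `sigma`.
#'
#' @param table protein summary data frame.
#' @param neighbor_fraction see [smooth_mean_noise()].
#' @return the input with added columns `eta`, `eta_bar`, `epsilon`,
#'   `log2_epsilon`.
#' @export
protein_noise_table <- function(table, neighbor_fraction = 0.05) {
  table$eta <- compute_noise(table$mu, table$sigma)
  table$eta_bar <- smooth_mean_noise(table$mu, table$eta, neighbor_fraction)
  table$epsilon <- deviating_noise(table$eta, table$eta_bar)
  table$log2_epsilon <- log2(table$epsilon)
  table
}

#' Proportionality between enzyme abundance and reaction flux
#'
#' Per mapped (enzyme, reaction) pair, ordinary least squares of flux on
#' protein copy number across shared conditions: the slope quantifies how
#' directly expression changes translate into flux changes, its two-sided
#' p-value tests proportionality against the flat null.
#'
#' @param protein enzymes x conditions matrix of copy numbers.
#' @param flux reactions x conditions matrix of fluxes.
#' @param mapping data frame with columns `enzyme_id`, `reaction_id`;
#'   defaults to matching row names directly.
#' @return a data frame with `enzyme_id`, `reaction_id`, `slope`, `p_value`,
#'   `r_squared`, `n_conditions`. Enzymes without a mapped reaction are
#'   skipped with a message.
#' @export
protein_flux_scaling <- function(protein, flux, mapping = NULL) {
  if (is.null(mapping)) {
    mapping <- data.frame(enzyme_id = rownames(protein),
                          reaction_id = rownames(protein))
  }
  shared <- intersect(colnames(protein), colnames(flux))
  if (is.null(colnames(protein)) || is.null(colnames(flux)))
    shared <- seq_len(min(ncol(protein), ncol(flux)))
  unmapped <- sum(!(mapping$reaction_id %in% rownames(flux)) |
                    !(mapping$enzyme_id %in% rownames(protein)))
  if (unmapped > 0) message(unmapped, " unmapped pairs skipped")
  rows <- lapply(seq_len(nrow(mapping)), function(i) {
    e <- mapping$enzyme_id[i]; r <- mapping$reaction_id[i]
    if (!(e %in% rownames(protein)) || !(r %in% rownames(flux))) return(NULL)
    x <- protein[e, shared]; y <- flux[r, shared]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) stop("need at least 3 shared conditions for ", e)
    fit <- stats::lm(y[ok] ~ x[ok])
    sm <- summary(fit)
    data.frame(enzyme_id = e, reaction_id = r,
               slope = unname(stats::coef(fit)[2]),
               p_value = sm$coefficients[2, 4],
               r_squared = sm$r.squared, n_conditions = sum(ok))
  })
  do.call(rbind, rows)
}
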