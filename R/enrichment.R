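#' Storey q-values
#'
#' False-discovery-rate adjusted significance estimates. The proportion of
#' true nulls `pi0` is estimated on the grid `lambda = 0.05, 0.10, ..., 0.95`
#' as `#{p > lambda} / (m (1 - lambda))`, smoothed by a cubic smoothing
#' spline (df = 3) and read off at the largest lambda, then clipped to
#' (0, 1]. The q-value of each p-value is
#' `min over {j: p_j >= p_i} of pi0 * m * p_j / rank(p_j)`, which is monotone
#' in p and never smaller than `pi0 * p`.
#'
#' @param p p-values in \[0, 1\].
#' @param lambda grid for the pi0 estimate.
#' @return q-values, same order as `p`, with attribute `"pi0"`.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (any(p < 0 | p > 1 | !is.finite(p))) stop("p-values must be in [0, 1]")
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- if (m >= 100) {
    sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
    stats::predict(sp, x = max(lambda))$y
  } else {
    min(pi0_l)  # grid minimum is more stable for small m
  }
  pi0 <- min(max(pi0, 1 / m), 1)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(cummin(pmin(q, 1)), 1)[ro]
  attr(q, "pi0") <- pi0
  q
}

# shared permutation machinery: observed statistic of each set vs the null of
# same-size random draws from the score pool
permute_sets <- function(scores, sets, statistic, n_permutations, seed) {
  if (n_permutations < 100) stop("need at least 100 permutations")
  ids <- names(scores)
  if (is.null(ids)) stop("scores must be a named vector")
  sets <- lapply(sets, function(s) {
    known <- s[s %in% ids]
    dropped <- length(s) - length(known)
    if (dropped > 0) attr(known, "dropped") <- dropped
    known
  })
  n_dropped <- sum(vapply(sets, function(s)
    if (is.null(attr(s, "dropped"))) 0L else attr(s, "dropped"), integer(1)))
  if (n_dropped > 0) message(n_dropped, " unknown ids ignored")
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sum(empty), " empty sets skipped")
    sets <- sets[!empty]
  }
  set.seed(seed)
  sizes <- sort(unique(lengths(sets)))
  pool <- unname(scores)
  np <- length(pool)
  # one null matrix per distinct set size; draws without replacement
  nulls <- lapply(sizes, function(sz) {
    draws <- matrix(0, n_permutations, sz)
    for (r in seq_len(n_permutations))
      draws[r, ] <- pool[sample.int(np, sz)]
    apply(draws, 1, statistic)
  })
  names(nulls) <- as.character(sizes)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    obs <- statistic(scores[s])
    null <- nulls[[as.character(length(s))]]
    p_high <- (1 + sum(null >= obs)) / (1 + n_permutations)
    p_low <- (1 + sum(null <= obs)) / (1 + n_permutations)
    data.frame(set = nm, size = length(s), statistic = obs,
               p_high = p_high, p_low = p_low)
  })
  do.call(rbind, rows)
}

#' Permutation enrichment of scores over annotation sets
#'
#' Per set, compares the observed mean score of its members to a null
#' distribution of mean scores over `n_permutations` random same-size draws
#' from all scored proteins. Both one-sided p-values carry the add-one
#' correction `p = (1 + #{null >= obs}) / (1 + n_permutations)` so they are
#' never 0 and never above 1; Storey q-values are attached for the
#' high-score direction.
#'
#' @param scores named numeric vector of per-protein (or per-metabolite)
#'   scores.
#' @param sets named list of member-id vectors; unknown ids are ignored with
#'   a message, empty sets skipped with a warning.
#' @param n_permutations number of random draws (>= 100).
#' @param seed integer RNG seed.
#' @return data frame with `set`, `size`, `statistic` (mean score), `p_high`,
#'   `p_low`, `q_high`, `q_low`.
#' @export
set_enrichment <- function(scores, sets, n_permutations = 2000, seed = 1) {
  out <- permute_sets(scores, sets, mean, n_permutations, seed)
  out$q_high <- as.numeric(storey_qvalues(out$p_high))
  out$q_low <- as.numeric(storey_qvalues(out$p_low))
  out
}

#' Transcription-factor target enrichment for deviating noise
#'
#' For each TF, the median deviating noise of its target genes is compared to
#' the permutation null of same-size random target draws (same machinery as
#' [set_enrichment()], with the median as the set statistic). The Bonferroni
#' significance threshold at the conventional `p <= 1e-4` level across the
#' tested TFs is attached as an attribute.
#'
#' @param epsilon named vector of per-protein deviating noise.
#' @param tf_targets named list: TF name -> target protein ids.
#' @param n_permutations,seed see [set_enrichment()].
#' @return data frame with `tf`, `n_targets`, `median_epsilon`, `p_high`,
#'   `p_low`; attribute `"bonferroni_threshold"` = `1e-4 / number of TFs
#'   tested`.
#' @export
tf_enrichment <- function(epsilon, tf_targets, n_permutations = 2000,
                          seed = 1) {
  out <- permute_sets(epsilon, tf_targets, stats::median, n_permutations, seed)
  names(out)[names(out) == "set"] <- "tf"
  names(out)[names(out) == "size"] <- "n_targets"
  names(out)[names(out) == "statistic"] <- "median_epsilon"
  attr(out, "bonferroni_threshold") <- 1e-4 / nrow(out)
  out
}
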