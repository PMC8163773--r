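PROTON_MASS <- 1.007276466

#' Annotate ions by accurate mass
#'
#' Matches each detected ion m/z against the expected ion masses of a
#' metabolite list within a ppm tolerance. The default adduct is the
#' deprotonated ion \[M-H\]- (expected m/z = monoisotopic mass - 1.007276);
#' further adducts can be supplied as mass offsets. Ions matching more than
#' one metabolite are kept and flagged ambiguous (putative annotation).
#'
#' @param ion_mz numeric vector of detected m/z values (named by ion id, or
#'   ids auto-generated).
#' @param metabolite_mass named numeric vector of metabolite monoisotopic
#'   masses.
#' @param tolerance_ppm match tolerance in parts per million (> 0).
#' @param adducts named numeric vector of mass offsets added to the
#'   metabolite mass to form the expected ion m/z.
#' @return data frame with `ion_id`, `mz`, `metabolite_id`, `adduct`,
#'   `expected_mz`, `ppm_error`, `ambiguous`.
#' @export
annotate_ions <- function(ion_mz, metabolite_mass, tolerance_ppm = 5,
                          adducts = c("[M-H]-" = -PROTON_MASS)) {
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be > 0")
  if (is.null(names(ion_mz))) names(ion_mz) <- sprintf("ion%04d", seq_along(ion_mz))
  rows <- list()
  for (ad in names(adducts)) {
    exp_mz <- metabolite_mass + adducts[[ad]]
    for (i in seq_along(ion_mz)) {
      ppm <- (ion_mz[i] - exp_mz) / exp_mz * 1e6
      hit <- which(abs(ppm) <= tolerance_ppm)
      if (length(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          ion_id = names(ion_mz)[i], mz = unname(ion_mz[i]),
          metabolite_id = names(metabolite_mass)[hit], adduct = ad,
          expected_mz = unname(exp_mz[hit]), ppm_error = unname(ppm[hit]))
      }
    }
  }
  if (!length(rows))
    return(data.frame(ion_id = character(0), mz = numeric(0),
                      metabolite_id = character(0), adduct = character(0),
                      expected_mz = numeric(0), ppm_error = numeric(0),
                      ambiguous = logical(0)))
  out <- do.call(rbind, rows)
  nmatch <- table(out$ion_id)
  out$ambiguous <- nmatch[out$ion_id] > 1
  rownames(out) <- NULL
  out
}

# one representative ion per metabolite: the highest median intensity
collapse_ions <- function(intensities, annotation = NULL) {
  if (is.null(annotation)) return(intensities)
  med <- apply(intensities, 1, stats::median)
  keep <- vapply(split(annotation$ion_id, annotation$metabolite_id),
                 function(ii) ii[which.max(med[ii])], character(1))
  m <- intensities[keep, , drop = FALSE]
  rownames(m) <- names(keep)
  m
}

#' Differential metabolite abundance between two groups
#'
#' Log2 fold change of group mean intensities and a Welch two-tailed t-test
#' on `log2(intensity + 1)` per metabolite, with Storey q-values across the
#' whole result set. If an annotation table is supplied, ions are first
#' collapsed to metabolites (representative ion = highest median intensity).
#'
#' @param intensities features x samples matrix of non-negative intensities.
#' @param samples data frame with columns `sample` and `group` matching the
#'   matrix columns.
#' @param group_a,group_b the two group labels to contrast (fold change is
#'   `a` over `b`).
#' @param annotation optional [annotate_ions()] table to collapse ions.
#' @return data frame with `metabolite_id`, `log2_fold_change`, `mean_a`,
#'   `mean_b`, `p_value`, `q_value`, `degenerate` (zero-variance flag; such
#'   rows get `p = NA`).
#' @export
differential_abundance <- function(intensities, samples, group_a, group_b,
                                   annotation = NULL) {
  ia <- samples$sample[samples$group == group_a]
  ib <- samples$sample[samples$group == group_b]
  if (length(ia) < 2 || length(ib) < 2) stop("need >= 2 replicates per group")
  m <- collapse_ions(intensities, annotation)
  la <- log2(m[, ia, drop = FALSE] + 1)
  lb <- log2(m[, ib, drop = FALSE] + 1)
  mean_a <- rowMeans(m[, ia, drop = FALSE])
  mean_b <- rowMeans(m[, ib, drop = FALSE])
  res <- data.frame(metabolite_id = rownames(m),
                    log2_fold_change = log2(mean_a / mean_b),
                    mean_a = mean_a, mean_b = mean_b)
  pt <- vapply(seq_len(nrow(m)), function(i) {
    va <- stats::var(la[i, ]); vb <- stats::var(lb[i, ])
    if (va + vb == 0) return(c(NA_real_, TRUE))
    c(stats::t.test(la[i, ], lb[i, ])$p.value, FALSE)
  }, numeric(2))
  res$p_value <- pt[1, ]
  res$degenerate <- as.logical(pt[2, ])
  res$q_value <- NA_real_
  ok <- !is.na(res$p_value)
  if (any(ok)) res$q_value[ok] <- as.numeric(storey_qvalues(res$p_value[ok]))
  rownames(res) <- NULL
  res
}

#' Pathway enrichment of differential-abundance scores
#'
#' Permutation enrichment ([set_enrichment()]) of pathways over per-metabolite
#' scores; the default score is the absolute log2 fold change, so pathways
#' concentrating large changes in either direction rank first. `signed = TRUE`
#' uses the signed fold change instead.
#'
#' @param diff a [differential_abundance()] result.
#' @param pathways named list of metabolite-id sets.
#' @param n_permutations,seed see [set_enrichment()].
#' @param signed use signed log2 fold changes as scores.
#' @return the [set_enrichment()] data frame.
#' @export
pathway_enrichment <- function(diff, pathways, n_permutations = 2000,
                               seed = 1, signed = FALSE) {
  sc <- if (signed) diff$log2_fold_change else abs(diff$log2_fold_change)
  names(sc) <- diff$metabolite_id
  set_enrichment(sc[is.finite(sc)], pathways,
                 n_permutations = n_permutations, seed = seed)
}

#' Starvation time-course summaries per metabolite and strain
#'
#' Mean, standard deviation and replicate count of each metabolite per
#' (strain, timepoint) — trajectory tables for plotting — plus per-timepoint
#' differential tests between the two strains.
#'
#' @param intensities features x samples matrix.
#' @param samples data frame with `sample`, `strain` (or `group`),
#'   `timepoint`, `replicate`.
#' @param timepoints timepoints to summarise (default: all present); missing
#'   ones are skipped with a warning.
#' @return list with `trajectories` (data frame: `metabolite_id`, `strain`,
#'   `timepoint`, `mean`, `sd`, `n`) and `tests` (named list of
#'   [differential_abundance()] results per timepoint, when two strains with
#'   >= 2 replicates each are present).
#' @export
starvation_timecourse_summary <- function(intensities, samples,
                                          timepoints = NULL) {
  if (is.null(samples$strain)) samples$strain <- samples$group
  present <- sort(unique(samples$timepoint))
  if (is.null(timepoints)) timepoints <- present
  missing_tp <- setdiff(timepoints, present)
  if (length(missing_tp)) {
    warning("timepoints not in the data skipped: ",
            paste(missing_tp, collapse = ", "))
    timepoints <- intersect(timepoints, present)
  }
  traj <- list()
  tests <- list()
  strains <- unique(samples$strain)
  for (tp in timepoints) {
    for (st in strains) {
      cols <- samples$sample[samples$timepoint == tp & samples$strain == st]
      if (!length(cols)) next
      sub <- intensities[, cols, drop = FALSE]
      traj[[length(traj) + 1L]] <- data.frame(
        metabolite_id = rownames(intensities), strain = st, timepoint = tp,
        mean = rowMeans(sub),
        sd = apply(sub, 1, stats::sd),
        n = length(cols))
    }
    if (length(strains) == 2) {
      ss <- samples[samples$timepoint == tp, ]
      ss$group <- ss$strain
      if (all(table(ss$group) >= 2)) {
        tests[[as.character(tp)]] <- differential_abundance(
          intensities[, ss$sample, drop = FALSE], ss,
          strains[1], strains[2])
      }
    }
  }
  traj <- do.call(rbind, traj)
  rownames(traj) <- NULL
  list(trajectories = traj, tests = tests)
}
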