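---
title: "Quantifying colony-level metabolic heterogeneity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying colony-level metabolic heterogeneity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonoise)
```

## The scientific problem

Clonal bacterial populations are phenotypically heterogeneous: genetically
identical cells differ in how fast they grow, how quickly they resume growth
after starvation, and how they balance respiratory against fermentative
metabolism. `colonoise` implements an analysis chain that connects three
observation levels:

1. **Single-cell proteomics** — which proteins are unusually noisy for their
   abundance (*deviating noise*), and whether those proteins cluster in
   particular processes or under particular transcription factors.
2. **Colony time-lapses on agar plates** — per-colony maximum growth rate,
   lag time and respiratory rate, measured for thousands of colonies at once
   with a flatbed scanner and a redox-sensitive dye (TTC, reduced by the
   respiratory chain to red formazan).
3. **Population statistics** — whether the observed (growth rate, lag time)
   cloud is bounded by a Pareto front, how respiration varies along it, and
   which metabolites distinguish strains with shifted
   respiro-/fermentative balance.

Every stage consumes tables a laboratory would produce; a synthetic-data
module generates all of them with known ground truth so that the full
pipeline is testable offline.

## Growth model

Colony area over time is described by a Gompertz law,

$$f(t) = A_{\min} + A_\Delta\, e^{-e^{k (t_m - t)}},$$

an asymmetric sigmoid with inflection at $t_m$ where the absolute growth
rate peaks. Two derived quantities summarise the curve in closed form:

* maximum growth rate $\mu_{\max} = f'(t_m) = A_\Delta k / e$ (area/h);
* lag time, the crossing of the tangent at $t_m$ with a baseline level.
  For baseline $A_{\min}$ this is $t_m - 1/k$; for a baseline of zero
  (colony size at inoculation taken as zero) it is
  $t_m - 1/k - A_{\min} e /(A_\Delta k)$.

An alternative printed form of the lag,
$(A_{\min} + (A_\Delta/e)(1 - k t_m))/((A_\Delta/e)k)$, equals the
*negative* of the zero-baseline tangent crossing and therefore decreases as
$t_m$ grows; both conventions are exposed
(`lag_time(fit, convention =)`), and the tangent construction — the one
under which "lag" behaves like a delay — is the default. We deliberately do
not reconcile the two silently.

`fit_gompertz()` is the package's model-fitting core and returns a classed
`gompertz_fit` object with the usual `coef`, `predict`, `fitted`,
`residuals`, `summary`, `plot` and `simulate` methods. Fitting is bounded
nonlinear least squares (Levenberg–Marquardt with positivity bounds on
$A_\Delta$ and $k$) restarted from a **deterministic** grid of 50 start
points: inflection times spanning the observed window crossed with rates
log-spaced between half the window and twenty times its reciprocal, with
baseline and amplitude seeded from the data. A deterministic grid, rather
than random restarts, makes refits bit-reproducible; the best
residual-sum-of-squares solution wins, and constant traces or universal
non-convergence are returned flagged (`converged = FALSE`) for the caller to
exclude.

The **respiratory rate** is the largest slope $\alpha$ (intensity units/h)
of a linear fit $I = \alpha t + \beta$ over any contiguous window of at
least ten time points of a colony's mean-red-intensity trace; windows slide
by one point, ties go to the earliest window, and an exhaustive-enumeration
oracle confirms the incremental implementation exactly. Note that the
maximum over many noisy windows is slightly biased upward relative to the
underlying slope; since the same estimator is applied to every colony this
does not disturb colony rankings, which is what downstream correlation
analyses consume.

For batch cultures, `batch_growth_params()` scans all windows spanning at
least 100 min of an OD600 curve, keeps the window with the maximum
log-linear slope, and reports the lag as the time at which the fitted
exponential, extended backwards, meets the inoculum OD.

## Imaging pipeline

`quantify_plate()` reproduces a scanner-array analysis:

1. **Temporal std projection.** Pixels covered by a growing colony change
   over the series; the per-pixel population standard deviation of the
   grayscale stack (grayscale = RGB mean, keeping the red respiration signal
   out of the geometry) is the segmentation relief.
2. **Per-plate Otsu.** The threshold is computed only from pixels inside the
   plate circle (256-bin histogram), so light differences between plates do
   not shift it. One threshold per plate, not per frame: early frames
   contain no colonies, and a per-frame Otsu would binarise noise.
3. **Watershed.** The std relief is flooded from its local maxima; maxima
   shallower than a tolerance `h` (default 0.1 intensity units, roughly half
   the colony/background std contrast) are merged, which prevents noise
   texture from shattering a colony while still separating two colonies
   joined by a thin neck. A distance-transform relief is the fallback for
   flat inputs. Watershed labels are then expanded into full plate
   territories (nearest-territory assignment) so that rim pixels a colony
   reaches only late are still credited to it.
4. **Per-frame quantification.** A single plate-level intensity threshold,
   taken from the final (highest-contrast) frame, decides which pixels of a
   territory are colony at each frame; this yields per-frame areas, centroids
   and mean RGB.
5. **Tracking.** Nearest-centroid linking with a displacement gate of 1.5
   times the median final colony radius; unmatched detections open new
   tracks, and a would-be jump beyond the gate terminates a track rather
   than swapping identities. Pre-detection frames are recorded with zero
   area.
6. **Artifact filter.** Tracks are dropped when they have too few
   detections, implausible final area, centroids within a margin of the
   plate rim, or area collapsing between consecutive frames. The filter's
   criteria are declared defaults of this package, not inferred rules, and a
   permissive configuration is the identity.

Plate geometry comes from stack metadata when available; `detect_plate()`
estimates centre and radius from the first frame (centroid and area of the
bright region) when it is not. Image coordinates are R-matrix (row, col)
indices, 1-based, origin at the top-left; the plate centre is carried
explicitly in the stack metadata.

## Expression-noise statistics

Noise is the squared coefficient of variation $\eta_p = \sigma_p^2/\mu_p^2$.
Because $\eta$ falls with abundance (intrinsic noise dominates at low copy
number, extrinsic factors set a floor at high copy number), raw noise cannot
be compared across proteins of different abundance. The expected noise
$\bar\eta_p$ at each abundance is a running mean over the 5% of proteins
nearest in $\log_{10}\mu$ — nearest-neighbour distance, self included, all
distance ties at the window edge included, which makes the definition exact
and lets an $O(N^2)$ oracle reproduce it bit-for-bit. Working in
$\log_{10}\mu$ rather than raw $\mu$ reflects that abundance spans decades.
**Deviating noise** is the ratio $\varepsilon_p = \eta_p/\bar\eta_p$,
reported both raw and as $\log_2 \varepsilon$ so that zero marks "exactly as
noisy as expected".

Enrichment of annotation sets (processes, TF targets) over any per-protein
score uses a permutation test: the observed set statistic (mean for general
sets, median for TF target sets) is compared to same-size random draws, with
the add-one correction $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$
so p-values are never zero. An iterative hypergeometric variant exists in
the literature but is not reproducible from its description; the permutation
test is the primary implementation here. Multiple testing uses Storey
q-values implemented in-package: $\hat\pi_0$ from the
$\lambda$-grid $0.05,\dots,0.95$, smoothed by a df-3 smoothing spline and
read at the grid maximum, clipped to $(0,1]$ (for fewer than 100 p-values
the grid minimum is used instead, as the spline extrapolation is unstable
there). TF enrichment additionally reports the Bonferroni threshold at the
conventional $10^{-4}$ level.

Protein-to-flux proportionality is plain OLS of flux on copy number across
conditions (at least three shared conditions required; seven is the typical
panel width), reporting slope, two-sided slope p-value and $R^2$.

## Pareto trade-off analysis

With phenotypes in hand, the trade-off analysis asks whether growth rate
and lag time are jointly bounded. A colony is **Pareto optimal** when no
other colony grows at least as fast *and* starts at least as early, one of
the two strictly better. The implementation is an $O(n \log n)$ sweep over
colonies sorted by growth rate, handling ties in groups (duplicated
phenotypes do not dominate each other); a quadratic dominance oracle checks
it on random instances in the tests.

Colony **fitness** is approximated as growth rate over lag time, computed on
min–max normalized axes (the plane in which isoclines of the ratio are
drawn); raw-axis fitness is available by flag. A small floor (`eps`, default
$10^{-3}$) keeps the shortest-lag colony finite after normalization. The
"expected by random choice" baseline is the fitness histogram of points
drawn uniformly over the normalized bounding rectangle (10,000 draws by
default, fixed seed). Band statistics (`fitness_band_correlation()`) select
colonies between two type-7 quantiles of the fitness distribution — default
0.7–0.8, near the front — and report the Spearman correlation (midrank
ties, large-sample p) between growth and respiratory rate inside the band.
The band-quantile mechanism is this package's declared operationalization of
"proximity to the front".

The equal-fitness reference curve comes from an exponential growth model:
cells reaching the same number of divisions $D$ in a fixed time $T$ satisfy
$\lambda (T - T_{lag}) = c$ with $c = D \ln 2$, hence
$T_{lag} = T - c/\lambda$ — an inverse relationship between growth rate and
lag.

Population variability is compared through a CV bootstrap: repeated draws of
400 colonies (1000 repetitions by default), CV = sd/mean per draw, and a
two-sided t-test between two strains' CV distributions. Trend lines use
local linear regression with tricube weights (`loess`, degree 1, direct
surface) on a grid.

## Metabolome statistics

Ions are annotated by accurate mass against a metabolite list: the default
adduct is [M−H]⁻ (expected m/z = monoisotopic mass − 1.007276), the
tolerance is a configurable ±5 ppm, and ions matching several metabolites
keep all matches flagged ambiguous — annotation is putative by design, and
neither the tolerance nor the adduct set is prescribed by upstream
conventions, so both are parameters with documented defaults. When several
ions map to one metabolite, the ion with the highest median intensity
represents it.

Differential abundance between two groups is the log2 ratio of group mean
intensities with a Welch two-tailed t-test on $\log_2(x+1)$ (the shift
keeps zeros finite; the transform choice is this package's default),
Storey-corrected across all metabolites; zero-variance rows are flagged, not
errors. Pathway enrichment delegates to the permutation machinery with
|log2 fold change| as the default score. Starvation time courses are
summarised as mean ± sd (with replicate counts) per strain and timepoint,
plus per-timepoint differential tests.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions under which the pipeline is
validated:

* **Plate time-lapse** (`gen_plate_timelapse()`): a 360-px plate imaged
  every 10 min for 88 frames (≈14.5 h), 50 colonies by default. Colonies are
  disks whose lattice pixel count follows each colony's Gompertz curve;
  growth parameters are log-normal across colonies ($A_{\min}$: mean 6 px²,
  CV 0.2; $A_\Delta$: mean 320 px², CV 0.25; $k$: mean 0.5/h, CV 0.2) with
  normal $t_m$ (7 ± 1.2 h) — dispersions of the order seen in real colony
  populations. The red channel rises at a colony-specific $\alpha$
  (log-normal, mean 0.02 intensity/h, CV 0.3, in arbitrary units as for any
  uncalibrated scanner signal) starting at the colony's lag time, since
  formazan accumulation accompanies active metabolism. A smooth radial
  illumination gradient (10%) and i.i.d. pixel noise (sd 0.02) are added.
  Colony placement is rejection sampling with a 10,000-attempt cap;
  non-overlap is enforced as centre separation beyond the sum of maximal
  radii.
* **Colony traces** (`gen_colony_timeseries()`): the same parameter
  distributions, with Gaussian area noise scaled to each colony's amplitude
  (5% default).
* **Protein tables** (`gen_protein_noise_table()`): log-normal abundances
  spanning decades; true noise $(a/\mu + b)\,\varepsilon^*$ with intrinsic
  coefficient $a = 200$, extrinsic floor $b = 0.05$, and log-normal
  deviation factors (log-sd 0.5).
* **Flux panels** (`gen_flux_protein_panel()`): 7 conditions, linear
  protein→flux scaling with a configurable null subset.
* **Metabolome matrices** (`gen_metabolome_matrix()`): log-normal
  intensities, one pathway shifted by a log2 effect in one group.

These emulate the structure the statistics rely on, not the physics: no 3D
colony morphology, nutrient diffusion, lid condensation or reflections; no
mass-spectral artifacts (isotopes, in-source fragments); no regulatory
correlation structure among proteins. Passing tests therefore demonstrate
that the estimators recover what they claim under controlled conditions —
not that real plates are free of the artifacts the QC filter exists for.

## Numerical choices and degenerate inputs

* Times are normalized to hours internally; minute-based inputs convert at
  the boundary (`frame_time_min`).
* The std projection uses the population divisor $n$.
* Otsu refuses constant rasters explicitly (degenerate threshold).
* `fit_gompertz()` stops early when a start reaches an essentially exact
  fit (relative RSS $\le 10^{-14}$); constant traces return
  `converged = FALSE` rather than an error.
* Enrichment p-values are bounded away from 0 and 1 by the add-one rule;
  q-values are monotone in p by the cumulative-minimum construction and
  never below $\hat\pi_0 p$.
* Pareto ties: identical phenotype pairs are both kept on the front (weak
  domination requires strict improvement somewhere).
* CV bootstrap draws with non-positive means are flagged `NA`, not dropped
  silently.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script run entirely on synthetic data
at sizes chosen to make Monte-Carlo error small relative to the margins
being checked: 1000 random parameter sets for the closed-form identities,
200 colonies for parameter recovery, one 50-colony default plate for
segmentation, 1000 proteins for noise recovery, 150 random sets × 2000
permutations for enrichment calibration, 5000 p-values for $\hat\pi_0$,
2000 points for the Pareto oracle, and the 1000 × 400 draw protocol for the
CV bootstrap.

## Known limitations

* The max-slope window estimator of $\alpha$ is upward-biased in absolute
  terms under noise (an extreme-value effect); rankings are unaffected.
* Tracking is greedy nearest-centroid; colonies that genuinely collide and
  merge late in an experiment are handled by the QC shrink rule rather than
  by mask splitting over time.
* The watershed tolerance `h` is expressed in std-projection intensity
  units and may need adjustment for stacks whose dynamic range differs
  substantially from the simulator's.
* `storey_qvalues()` assumes a reasonably dense p-value set; for very few
  tests the $\hat\pi_0$ estimate is conservative by construction.
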