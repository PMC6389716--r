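---
title: "Temporal variability of dynamic functional connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal variability of dynamic functional connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcvar)
```

## The statistic

Resting-state fMRI gives every brain region (node) a BOLD time series.
Static functional connectivity (FC) — the Pearson correlation between two
nodes over the whole scan — hides how the network reconfigures on the
scale of tens of seconds. This package quantifies that reconfiguration by
the *temporal variability* of connectivity profiles.

The series of `T` volumes is cut into `N = floor(T / l)` non-overlapping
windows of `l` volumes (anchored at the first volume, remainder
discarded), and an M × M Pearson correlation matrix is computed per
window — raw signed r, no Fisher transform, no thresholding. For node
`k`, the *connectivity profile* in window `i`, `F_ik`, is its vector of
FC values to all other nodes (the self-connection is excluded, so the
profile has M − 1 entries). The nodal temporal variability is

$$V_k = 1 - \frac{2}{N(N-1)} \sum_{i<j} \mathrm{corr}(F_{ik}, F_{jk}),$$

one minus the mean Pearson correlation of the node's profile over all
unordered window pairs. `V_k` lives in [0, 2]: 0 when the profile is
perfectly stable across windows, 1 when profiles are uncorrelated, 2 in
the degenerate perfectly anti-correlated case.

Module-level variants apply the same construction to unfolded blocks of
the windowed FC matrix given a node-to-module partition: intra-network
variability unfolds the upper triangle of the within-module block;
inter-network variability unfolds the full between-module block (each
cross pair once). The unfolding order is the fixed column-major order of
the sorted node indices, so results are bit-reproducible; the choice of
order cannot affect a Pearson correlation between identically-ordered
vectors. Intra and inter values are assembled into a K × K module
matrix (intra on the diagonal).

Because each profile correlation is location/scale invariant, every
variability value is unchanged by positive affine rescaling of any
node's signal — a property the test suite asserts to 1e-10. The
vectorized implementation standardizes each profile to zero mean and
unit sum of squares and uses
$\sum_{i<j} \langle z_i, z_j\rangle = (\lVert\sum_i z_i\rVert^2 - N)/2$,
and is checked against an independent loop-based reference to 1e-12.

## Inference

Group differences (patients minus controls, difference of means) are
tested by label permutation: subjects are reassigned to two groups of
the original sizes, the statistic recomputed, and tail proportions
reported. All units (nodes, modules, module pairs) share one set of
reassignments per iteration, as is standard when many network metrics
are tested on one cohort. The Monte-Carlo p-value uses the add-one
estimator `(k + 1) / (n_perm + 1)`, so it is never exactly zero, and tie
counting uses a relative tolerance of 1e-10 so a resample that
reproduces the observed labelling counts in both tails despite
floating-point summation-order noise. Within-group intra-vs-inter
comparisons use a paired sign-flip test on the per-subject difference
between a module's intra variability and its mean inter variability.

Clinical association uses Spearman rank correlation between per-patient
variability and a severity score, with a single-pass outlier screen:
values more than 3 sample SDs from the mean are removed (no iteration;
an SD of zero keeps everything), and the unscreened correlation is
reported alongside. The two-sided p is exact for n ≤ 9 and uses the
t-approximation otherwise. Demographic checks use a chi-square without
continuity correction for sex counts and a Welch t-test (also available
from printed mean/SD/n summaries) for age.

Default reporting thresholds follow common practice for this analysis:
nodal p < 0.005 uncorrected, module-level p < 0.05 with a stricter
p < 0.005 tier; Benjamini–Hochberg correction is available behind the
`fdr` flag but off by default. Both one-sided tails are always emitted.

## The synthetic cohort generator

No scan data ship with the package; the generator produces cohorts with
the statistical structure the analysis assumes, so the whole pipeline is
exercised and validated end to end. Defaults emulate a realistic
patient–control study: 40 controls and 42 patients, 264 nodes in 13
modules (the shipped synthetic partition follows the module sizes of the
published 264-ROI functional parcellation), 200 volumes at TR = 2 s.

Each subject's signal is multivariate normal around a modular baseline
connectome, switched between `n_states = 4` connectivity states:

1. **Baseline connectome.** A block matrix (`r_within = 0.4` inside
   modules, `r_between = 0.05` across) plus low-rank factor
   heterogeneity, renormalized to a correlation matrix. Heterogeneity
   has two layers: cohort-shared factors (entry SD `base_jitter_sd =
   0.2`, drawn from the cohort seed, identical for all subjects) and a
   smaller per-subject deviation (`subject_jitter_sd = 0.05`). Entry-level
   heterogeneity is load-bearing: a Pearson profile correlation ignores
   uniform shifts, so a block-constant baseline would leave within-block
   profiles with *no* stable across-entry variance and state
   reconfiguration would then *lower* observed variability (the stable
   term in `V = 1 - (b² + f a²)/(b² + a² + n²)` would vanish). The
   factor construction (base + L Lᵀ, q = 3 factors per layer) is used
   because it is positive definite by construction: a dense Gaussian
   jitter of useful size cannot survive eigenvalue clipping at M = 264,
   where its spectral radius (≈ 2·sd·√M) dwarfs the base spectrum.
   Making the large layer cohort-shared mirrors real cohorts, where most
   entry-level FC structure is common across subjects, and keeps the
   stable variance term nearly constant across subjects instead of
   swamping the group effect.

2. **Connectivity states.** Each state adds a zero-mean low-rank
   perturbation whose row/column amplitude is `amp_target = 0.25` for
   nodes in the target modules (subcortical, sensorimotor, visual,
   cerebellar analogues) and `amp_base = 0.08` elsewhere. Perturbation
   *directions* are cohort-level (drawn from the cohort seed and shared
   by all subjects, as k-means dFC states are in real cohorts); only the
   amplitude is subject-specific. The perturbation uses a Gram form
   `U Uᵀ` — its off-diagonal entries are zero-mean products of
   independent normals, and positive definiteness holds by construction,
   so no eigenvalue repair is needed, only unit-diagonal renormalization.

3. **Dynamics.** The state sequence has geometric (memoryless) dwell
   times with mean `mean_dwell = 25` volumes (50 s at TR = 2 s), so
   40-second analysis windows straddle state changes the way real dFC
   windows do. Volumes are drawn from the active state's multivariate
   normal and smoothed by an AR(1) recursion (`ar_phi = 0.3`), a stand-in
   for hemodynamic and band-pass smoothness chosen to keep the effective
   sample size of a 20-TR window reasonable.

4. **Group effect and severity.** A patient with latent severity
   s ∈ [0, 1] gets gain `1 + (group_gain − 1)(c·s + (1 − c))` on the
   target-module amplitude, with `group_gain = 1.8` and coupling
   `c = 0.7`; severities are Uniform(0, 1). The observed score emulates
   a 0–40 motor scale: `40·s` plus 10% Gaussian observation noise,
   truncated at zero; controls carry no score. The gain–severity
   coupling is what makes clinical correlation recoverable by design.

Everything is reproducible from the cohort seed alone: subject seeds,
severities, demographics, state sequences and written files are all
derived from it, and rerunning a simulation yields byte-identical files.

### What the generator does not emulate

No hemodynamic response convolution, no spatial smoothing or spatial
autocorrelation between neighbouring parcels, no head-motion artefacts,
no physiological noise spectra, no scanner drift, and no heterogeneity
of state *number* or dwell distribution across subjects. Passing tests
therefore show that the statistics and inference behave correctly on
data with the assumed covariance-switching structure — not that the
pipeline is robust to the full noise anatomy of real fMRI.

## Numerical and design choices

* Windows are anchored at volume 1 and the trailing remainder is
  discarded; `l ≥ 3` and `N ≥ 2` are enforced.
* A zero-variance node inside a window is a hard error by default;
  `skip_degenerate_windows` drops such windows for all nodes, keeping
  windows aligned across nodes. Silent NaN propagation into group
  statistics is never allowed.
* A profile with zero variance in some window yields `NA` for that unit
  with a diagnostic attribute; downstream group tests drop missing
  values pairwise with counts reported.
* Profiles are correlated on the raw Pearson scale; a `fisher_z` flag
  (atanh with |r| clipped at 1 − 1e-7) exists but is off by default.
* Averaging variability over window lengths is an elementwise mean; an
  entry missing at exactly one length is averaged over the present
  lengths (count recorded), an entry missing at two or more propagates
  as missing.
* The window-length sweep correlates per-subject variability vectors
  between lengths and averages each pair's correlation over subjects;
  the minimum off-diagonal entry is the headline robustness number.
* The "Uncertain" module is computed everywhere and only excluded from
  reports (restorable via `include_uncertain`).
* The sex-ratio check uses chi-square without continuity correction —
  the count-data equivalent of the pooled t on binary coding at these
  sample sizes.

## Problem sizes used by the test suite

Oracle-equivalence tests run 100 random stacks at M ≤ 10, N ≤ 6.
Calibration uses six null cohorts (group gain 1) at the full default
size, pooling about 2000 unit-level permutation tests at 999
permutations. Effect recovery uses 25 replicate default cohorts at 999
permutations, testing the four target modules' intra-network variability
and the Spearman correlation between each patient's mean target-module
intra variability (an aggregate severity index across the affected
systems) and the synthetic score. The window-length robustness check
runs the full default cohort across l = 10…20. Pipeline smoke and
determinism tests run micro-cohorts (11 nodes, 3 modules, 8 subjects,
199 permutations).

## Known limitations

* Modules with very few nodes give noisy intra-network variability: a
  4-node module has only 6 within-block pairs, so its estimator has
  several-fold the sampling noise of a 13-node module. In the synthetic
  recovery study the small cerebellar analogue is correspondingly hard
  to flag at conventional thresholds — consistent with module-level
  results on real cohorts, where small-module intra effects are
  likewise elusive.
* Non-overlapping windows make `N` small (10 windows at T = 200,
  l = 20); the variability estimate is unbiased in rank but noisy, and
  stabilizes as `N` grows (asserted by the test suite).
* The permutation test assumes exchangeability under the null; with
  covariate imbalance (age, sex, motion) a real analysis would need
  matched or covariate-adjusted designs, which this package deliberately
  does not provide.
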