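# dfcvar

Temporal variability of dynamic functional connectivity (dFC) for
resting-state fMRI cohort studies.

Whole-brain functional networks are not static: the correlation
structure between brain regions reorganizes on the scale of tens of
seconds, and several disorders — Parkinson's disease prominently among
them — show *excess* reconfiguration concentrated in specific
subnetworks. `dfcvar` implements the analysis that quantifies this: from
per-subject ROI time series to nodal, intra-network and inter-network
temporal variability, permutation-based group comparison, and
outlier-robust clinical correlation, plus a fully seeded synthetic
cohort generator so the entire pipeline runs and is validated without
any scan data.

## The statistic

Each subject's BOLD series (T volumes × M nodes) is cut into
N = ⌊T/l⌋ non-overlapping windows of l volumes, and an M × M Pearson
correlation network is computed per window. For node k with
connectivity profile F<sub>ik</sub> in window i (its FC values to all
other nodes), the temporal variability is

&nbsp;&nbsp;&nbsp;&nbsp;V<sub>k</sub> = 1 − 2/(N(N−1)) · Σ<sub>i&lt;j</sub> corr(F<sub>ik</sub>, F<sub>jk</sub>) ∈ [0, 2],

one minus the mean pairwise correlation of the node's profile across
windows: 0 for a perfectly stable profile, larger when the node's
functional fingerprint keeps reorganizing. Intra-network variability
applies the same construction to the unfolded upper triangle of a
module's within-block FC; inter-network variability to the full
between-module block. Group inference is by label permutation (shared
reassignments across units, add-one p estimator), within-group
intra-vs-inter contrasts by paired sign-flip tests, and
clinical association by Spearman correlation after a single-pass
3-SD outlier screen.

See `vignettes/temporal-variability.Rmd` for the full model, the
generator's design and its limitations.

## Worked example

Simulate a small cohort (12 controls, 12 patients with elevated
reconfiguration in the subcortical, sensorimotor, visual and cerebellar
analogues), compute variability at 20-TR windows, and test group
differences:

```r
library(dfcvar)
library(dplyr)

spec   <- cohort_spec(n_control = 12, n_patient = 12, seed = 7)
cohort <- simulate_cohort(spec)
vars   <- cohort_variability_mem(cohort, window_length = 20)

cmp <- group_compare(vars, n_perm = 999, seed = 7)
cmp |> filter(level == "intra") |> arrange(p_two_sided)
#>   level unit   mean_control mean_patient observed_diff p_greater p_smaller
#> 1 intra SMN           0.642        0.684       0.0419      0.001     1
#> 2 intra Visual        0.681        0.719       0.0375      0.001     1
#> 3 intra FPN           0.589        0.563      -0.0266      0.958     0.043
#> 4 intra CON           0.609        0.594      -0.0150      0.782     0.219
```

The two strongest elevations are in target modules (SMN, Visual), with
one-sided permutation p = 0.001 at 999 permutations — the injected
group effect, recovered. Clinical correlation against the synthetic
severity score:

```r
clinical_correlation(vars, cohort$manifest, score = "updrs3") |>
  filter(level == "intra") |> arrange(p)
#>   level unit        n_used n_outliers    rho      p
#> 1 intra Subcortical     12          0  0.657 0.0202
```

Higher subcortical intra-network variability goes with higher severity
scores (rho = 0.66), the association the generator builds in through
its severity–gain coupling.

For file-based cohorts, `simulate_cohort(spec, dir = ...)` writes
per-subject TSV time series, a manifest and a partition table;
`run_pipeline(parse_config(...))` then executes the full analysis
(variability → permutation comparison → intra-vs-inter → clinical
correlation → window-length sweep → cross-length averaging) into a run
directory of TSV/JSON artifacts, and `render_report()` produces
reportable-module summary tables. A thin command-line wrapper with the
same stages lives at `inst/cli/dfcvar.R`
(`Rscript inst/cli/dfcvar.R run-all --manifest ... --partition ... --out ...`).

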