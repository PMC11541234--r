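# msranet

Resting-state functional-connectivity analysis for two-group,
two-session symptom-provocation fMRI designs — multi-seed region
connectivity, density-thresholded connectome metrics with small-world
normalization, network-based statistics (including a control-adjusted
paired variant), and stability-selection machine learning — together with
a synthetic cohort generator that plants known effects so the entire chain
is testable without access to raw imaging data.

The package is aimed at researchers analysing region-wise BOLD time
series from studies that compare a patient group (e.g. anorexia nervosa,
AN) with healthy controls (HC) across sessions and conditions, and at
methodologists who want a calibrated, fully reproducible test bed for
connectome-level statistics.

## The analysis chain

1. **Temporal preprocessing** (`prep_pipeline`): OLS nuisance regression
   (white-matter/ventricle-type confounds) followed by a zero-phase
   forward–backward Butterworth band-pass, 0.009–0.08 Hz.
2. **Multi-seed region analysis** (`msra_matrix`): every atlas region
   seeds in turn; Pearson correlations with every target, exact t-based
   p-values, Benjamini–Hochberg FDR at *q* = 0.05 **per seed map**, and
   surviving correlations averaged per target region — an asymmetric
   R × R connectivity matrix.
3. **Graph metrics** (`threshold_to_density`, `global_metrics`,
   `node_metrics`, `sigma_curve`, `turning_point`): graphs thresholded to
   a target edge density *d*; clustering *C* and characteristic path
   length *L* normalized against 100 size-matched Erdős–Rényi digraphs,

   γ = C/⟨C_rand⟩, λ = L/⟨L_rand⟩, σ = γ/λ,

   evaluated over the 2–20 % density grid, with the analysis density
   selected at the curvature maximum (turning point) of σ(d); 14 global
   and 14 nodal metrics per graph.
4. **Network-based statistics** (`nbs_homoscedastic`,
   `nbs_paired_controlled`): edge-wise pooled-variance t on Fisher-z
   entries, supra-threshold components at edge-wise α = 0.05, and the
   largest component's family-wise p from permutation of subject labels,
   p_FWE = (1 + #{null ≥ obs}) / (1 + n_perm). For paired contrasts, a
   matched control contrast tightens α over a descending grid until the
   control is clean; the experimental component is read out at that α*.
5. **Stability-selection ML** (`build_feature_table`, `repeat_pipeline`):
   per resting state, 19 densities × 14 global metrics (GraphInfo, 266)
   plus regions × 14 nodal metrics (NodeParams; 2,870 at R = 205), 6,272
   features in total over two resting states; Boruta-style shadow-feature
   selection or sparse PLS-DA on the training rows of each of 100
   stratified 75/25 splits, an XGBoost classifier scored on the held-out
   rows, and per-feature selection frequencies (> 50 % = stable
   signature).
6. **Cohort statistics** (`independent_t`, `t_from_summary`): Levene-gated
   pooled/Welch t-tests for demographics and desire ratings, including a
   summary-statistics mode.

`run_study()` orchestrates everything from one configuration;
`inst/cli/msranet-cli.R` exposes the stages as shell verbs
(`simulate`, `prep`, `msra`, `metrics`, `stats`, `run-all`).

## Worked example

A desk-scale synthetic study: 8 subjects per cohort cell, 20 regions in 4
communities, and a connected 6-edge component whose correlations are
raised by Δr = 0.45 in the AN groups only.

```r
library(msranet)

spec <- cohort_spec(
  n_per_group = c(adult_HC = 8L, adult_AN = 8L, young_HC = 8L, young_AN = 8L),
  R = 20L, T = 150L, n_communities = 4L,
  effect_edges = data.frame(i = c(1, 6, 2, 7, 3, 8), j = c(6, 2, 7, 3, 8, 11),
                            delta = 0.45, diagnosis = "AN"),
  seed = 42L)
cfg <- study_config(spec = spec, densities = seq(0.04, 0.20, by = 0.04),
                    n_random = 10L, nbs_n_perm = 500L,
                    ml_algorithms = "splsda", ml_n_iter = 20L, seed = 42L)
res <- run_study(cfg, verbose = FALSE)
print(res)
```

```
Study pipeline result (config 7aa2c93f)
  scans analysed: 192  node density: 0.07
  NBS contrasts:
    baseline_AN_vs_HC_young                       significant (size 17, p_FWE=0.008)
    baseline_AN_vs_HC_adult                       not_significant (size 13, p_FWE=0.058)
    young_vs_adult_AN                             not_significant (size 8, p_FWE=0.250)
    young_vs_adult_HC                             not_significant (size 3, p_FWE=0.653)
    consumption_chips_vs_zucchini_control         not_significant (size 0)
  ML young_splsda         balanced accuracy 72.5%
  ML adult_splsda         balanced accuracy 95.0%
```

Reading the output: the planted AN-vs-HC component is recovered at
baseline — significant in the young cohort (17 supra-threshold edges,
p_FWE = 0.008), borderline in the smaller adult contrast — while the
contrasts with nothing planted (developmental comparisons, the
chips-vs-zucchini paired consumption contrast with its zucchini control)
correctly stay null. The classifier separates AN from HC above chance from
the graph features alone. At this demo scale a run takes about half a
minute on one CPU; the same code runs the full 205-region,
15/13/16/17-subject configuration unchanged.

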