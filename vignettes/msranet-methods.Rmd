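---
title: "Methods: from BOLD series to network statistics and stable biosignatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from BOLD series to network statistics and stable biosignatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

msranet implements a complete resting-state functional-connectivity
analysis for two-group, two-session symptom-provocation designs — the kind
of study that compares patients with anorexia nervosa (AN) against healthy
controls (HC) in two age classes, with three resting-state scans per
session bracketing a visual food-cue stimulation and a food consumption.
Because raw imaging data for such cohorts are rarely shareable, the package
pairs every analysis stage with a synthetic cohort generator that plants
known effects, so the whole chain is testable end to end.

This vignette explains each stage's model, its tunable parameters, and the
design decisions taken where the analysis recipe leaves genuine freedom.

## The synthetic cohort generator

Each scan is an $R \times T$ region-by-time matrix drawn from a stationary
multivariate AR(1) process. The population correlation $\Sigma$ has three
layers:

* a block community structure: regions in the same planted resting-state
  network correlate at `base_within_community_r` (default 0.3, a typical
  within-network resting correlation);
* planted effects: a table of edges $(i, j)$ with a correlation shift
  `delta` that applies only to scans matching the edge's selectors
  (diagnosis, age class, scan index, food condition). A correlation matrix
  is symmetric, so a planted edge shifts both $(i,j)$ and $(j,i)$;
  asymmetry enters later, through per-seed FDR thresholding;
* unit variances, so correlation and covariance coincide.

Temporal coloring uses $x_t = \phi\, x_{t-1} + \sqrt{1-\phi^2}\,
\varepsilon_t$ with $\varepsilon_t \sim N(0, \Sigma)$: the innovation
scaling keeps the zero-lag cross-correlation exactly $\Sigma$ at any
`ar1_phi` (default 0.3, in the range typical of BOLD at a 3 s repetition
time). On top of the signal the generator adds shared slow cosine drifts —
stand-ins for white-matter/ventricle confounds, stored with the scan so
preprocessing can be verified against exactly what was injected — and white
noise (`noise_sd`, default 0.2 against unit signal variance).

Defaults mirror the emulated study design: 205 atlas regions in 7
communities, 200 volumes at TR = 3 s, group sizes 15/13/16/17 (adult HC /
adult AN / young HC / young AN), two sessions of three scans (RS1–RS3),
and the food condition (chips vs zucchini) counterbalanced by deterministic
alternation over subject index — reproducibility was preferred over
simulated randomization. Positive definiteness of $\Sigma$ is checked at
build time; violations below $10^{-8}$ (floating-point dust from many
overlapping deltas) are repaired by eigenvalue clipping, anything larger
aborts with the offending edges named, because silently repairing a large
violation would corrupt the planted ground truth.

What the generator does *not* emulate: hemodynamic response shape, head
motion, physiological cycles, field inhomogeneity, spatial autocorrelation
within regions. Passing tests therefore show that the *analysis chain* is
correct and calibrated on plausible signal structure, not that it is robust
to every artifact of real acquisitions.

## Temporal preprocessing

The pipeline order is fixed: nuisance regression first, then band-pass.
Filtering first would leave the in-band projection of the confounds in the
data; a test demonstrates this with a confound that has both in-band and
out-of-band components.

* **Nuisance regression** is ordinary least squares of each region's series
  on an intercept plus the confound columns; residuals keep the region mean
  (correlations are mean-invariant, and the series stays on its original
  scale). Rank-deficient designs abort with the collinear columns named.
* **Band-pass** is a zero-phase forward–backward Butterworth filter,
  order 2 per pass, with corners 0.009–0.08 Hz — the conventional
  resting-state band. The analysis names only the band, not the filter
  family; any zero-phase realization meeting the attenuation contract
  (less than 10 % amplitude loss in-band, more than 90 % at twice the
  upper corner) would do, and the forward–backward Butterworth is the
  standard choice because zero phase preserves correlation timing.
* **Spatial smoothing** (voxel mode only) is a separable Gaussian with
  $\sigma = \mathrm{FWHM}/2.3548$ and reflective padding, which conserves
  per-volume total intensity on the small synthetic grids used in tests.

In region mode the temporal steps are applied to region-mean series
directly; linear operations commute with averaging, so this matches the
voxel-level pipeline up to smoothing, which only exists in voxel mode.

## Multi-seed region analysis (MSRA)

Every region seeds in turn: its (mean) time course is Pearson-correlated
with every target signal, p-values come from the exact t transform
$t = r\sqrt{(T-2)/(1-r^2)}$ on $T-2$ degrees of freedom, and
Benjamini–Hochberg FDR at $q = 0.05$ is applied *per seed*, over that
seed's own correlation map — the map is the multiple-testing family, not
the full $R^2$ matrix. Entry $(i, j)$ of the connectivity matrix is the
mean of the surviving correlations of seed $i$ within region $j$, zero when
none survive. Because each row has its own FDR family the matrix is
asymmetric; that asymmetry is a measurement artifact of the thresholding,
not evidence of directed influence, and downstream stages treat it
accordingly.

Two open choices are isolated behind switches: surviving *negative*
correlations are retained with their sign (`signed = TRUE`), and the
diagonal is stored but excluded from graph construction.

## Density-thresholded graphs and small-world normalization

A graph at density $d$ keeps the $k = \mathrm{round}(d\,R(R-1))$
algebraically largest off-diagonal entries (signed ranking, so strong
negative edges drop out first at sparse densities; ranking by $|r|$ is
available as an option since the original convention is not recoverable).
Ties break deterministically by row-then-column index. The binary
adjacency feeds topology metrics; a weighted twin keeps the retained
correlations for strength metrics.

Global metrics follow a fixed 14-metric schema: raw clustering $C$ and
characteristic path length $L$ (mean over ordered *reachable* pairs, which
keeps $L$ finite on disconnected graphs while preserving comparability);
their ratios $\gamma = C/\langle C_{\mathrm{rand}}\rangle$ and
$\lambda = L/\langle L_{\mathrm{rand}}\rangle$ against the mean of 100
Erdős–Rényi digraphs with identical node and edge counts (the stated
"random networks of the same size"; degree-preserving rewiring is offered
as a sensitivity option); the small-world index $\sigma = \gamma/\lambda$;
plus component structure, global efficiency, diameter, degree
assortativity, global transitivity, modularity of the undirected collapse,
mean strength and mean betweenness. The nodal schema likewise has 14
metrics per region (degrees, strengths, clustering, nodal path length,
HITS hub and authority scores — the natural reading of "hub scores" on a
directed graph — betweenness, closeness, eigenvector centrality, local
efficiency). The exact metric complements beyond the explicitly named ones
are fixed by the printed feature-count arithmetic: 19 densities × 14
global metrics = 266 "GraphInfo" features and 205 regions × 14 nodal
metrics = 2,870 "NodeParams" features per resting state, 6,272 in total
over two resting states. Nodal metrics are computed at a single selected
density with no density axis, which is what makes the arithmetic close.

The $\sigma(d)$ curve is evaluated on the 2–20 % grid in 1 % steps; the
analysis density is the point of maximum absolute discrete curvature
(second difference) of the curve, falling back to the conventional 7 %
when the curvature is flat. The hyperbolic decay of $\sigma$ with density
is asserted as a soft check only, since noisy matrices can violate it
locally.

## Network-based statistics

Edge-wise two-sample pooled-variance t statistics are computed on
Fisher-z-transformed entries (variance stabilization; raw-r testing is a
switch, since the original scale is not recoverable). Edges passing the
two-sided critical value at edge-wise $\alpha$ form a supra-threshold
graph; components are *weak* components — NBS conventionally treats the
graph as undirected, and the MSRA asymmetry is a thresholding artifact.
Component size is the edge count (the standard extent statistic), with
sign retained per edge so direction can be read post hoc.

The family-wise error of the largest component is controlled by permuting
subject labels: $p_{\mathrm{FWE}} = (1 + \#\{\text{null} \ge
\text{obs}\})/(1 + n_{\mathrm{perm}})$, 10,000 permutations by default.

For paired contrasts (the food-consumption design: post- vs pre-consumption
in the chips session) group-label permutation is unavailable, and the
package implements the control-adjusted variant: the same contrast in the
control session (zucchini) is scanned over a descending alpha grid
(default 0.05, 0.04, 0.03, 0.02, 0.01, 0.005, 0.001 — the original grid is
unstated, so a fixed documented grid keeps runs reproducible), and
$\alpha^\*$ is the largest value at which the control's largest
supra-threshold component has at most `max_control_component` edges
(default 0: the control must be entirely clean, the strictest reading of
"specific to the experimental manipulation"). The experimental contrast is
then read out at $\alpha^\*$; when no grid value qualifies the contrast is
`not_testable`. The exact adjustment rule of the original procedure is not
printed anywhere recoverable, so this scan-the-grid rule is a documented
assumption, isolated in `control_adjusted_alpha()`.

## Stability-selection classification

The feature table concatenates, per resting state (RS2 and RS3), the
GraphInfo block (density-major, then metric) and the NodeParams block
(region-major, then metric); column names follow
`<RS>_<GI|NP>_<density|region>_<metric>`, which makes frequency reporting
mechanical. For each of 100 iterations a stratified 75/25 split is drawn,
feature selection runs **on the training rows only** — re-run per split,
which is required for honest selection frequencies — and an XGBoost
classifier (300 trees, depth 3, learning rate 0.1; fixed defaults with an
override, since no tuning protocol is recoverable) is scored on the
held-out rows. AN is the positive class; balanced accuracy is the mean of
sensitivity and specificity, aggregated as the mean of per-iteration
balanced accuracies. Features selected in more than half the iterations
form the stable signature.

Two selectors are provided:

* **Boruta-style shadow features**: every candidate gets a shuffled shadow
  copy, a ranger random forest with permutation importance is fitted, and
  a feature scores a hit when it beats the best shadow. A two-sided
  binomial test on the running hit count (from round 3, at 0.05) confirms
  or rejects; rejected features leave the model; undecided features after
  `max_rounds` (default 10) are not selected. Permutation importance from
  a forest is the reference formulation; gradient-boosted gain importance
  is exposed as an option.
* **sPLS-DA** via mixOmics: one component, the 20 features with the
  largest sparse loadings — the minimal configuration consistent with a
  selector that reports 20 selected features; multi-component settings are
  exposed.

Zero-variance columns (computed on the training rows) are dropped inside
the selectors, which is also what guarantees a leakage canary — a feature
constant on train and informative only on test — can never be selected.

A small-sample caveat found while validating: with ~32 subjects (8 test
subjects per split) the label-permuted null sits systematically *below*
chance (balanced accuracy ≈ 43 %), the well-known anti-learning artifact
of per-split selection followed by out-of-sample scoring. The chance-level
sanity check is therefore run at 48 subjects, where it is measurable;
users applying the pipeline to cohorts of 30 should expect the same bias
in their permutation nulls and interpret accordingly.

## Cohort statistics

Demographics and desire ratings are compared with independent two-sample
t-tests gated by Levene's test (center = mean, implemented as the one-way
ANOVA on absolute deviations): pooled variance when Levene's p ≥ 0.05,
Welch otherwise — emulating common statistical-package practice since the
per-row choice is not recoverable. A summary-statistics mode recomputes t
and p from printed group means, SDs and sizes, and agrees exactly with the
sample mode fed its own summaries.

## Problem sizes and numerical tolerances used in validation

The test suite validates calibration properties at desk scale, chosen so
the full suite runs in about a minute: family-wise error over 200 null
replicates (30 regions, 10 subjects per group, 500 permutations); planted
10-edge component recovery over 50 replicates (15 regions, 15 subjects per
group, Δr = 0.4); small-world normalization over 20 Erdős–Rényi digraphs
(100 nodes, density 0.1, 20 reference graphs each); ML sanity over 100
split iterations on a 48 × 60 table. Oracle equivalences (BH-FDR versus a
threshold scan, component extraction versus flood fill, betweenness versus
exhaustive path enumeration, Monte-Carlo versus exhaustive 4-vs-4
permutation) run on instances small enough to enumerate. Monte-Carlo
assertions use 2–4 standard-error bands; exact algebraic identities (the
balanced-accuracy identity, the p-value definition) are asserted to
1e-12.

## Known limitations

* Region mode is the primary analysis path; voxel mode (six-voxel seeds at
  region centers of mass) is implemented and tested on small grids only.
* Correlation-level planting cannot express every covariance structure a
  real cohort has (e.g. subject-level variance heterogeneity beyond the
  planted deltas).
* The weighted-graph generalizations of γ/λ/σ, cluster-mass NBS variants,
  and any spatial preprocessing (motion, slice timing, registration) are
  out of scope.
* `simulate_ratings_demographics()` draws independent normals per
  variable; it reproduces group means/SDs, not the between-questionnaire
  correlation structure of real instruments.
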