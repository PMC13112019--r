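---
title: "Methods: connectome group comparison, prediction, and mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome group comparison, prediction, and mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectopipe)
```

## The problem

Chronic hematological disease in children — severe transfusion-dependent
anemia is the motivating case — can impair cognition through diffuse,
network-level disruption of brain function rather than through focal
lesions. Three questions follow naturally from resting-state fMRI in such
a cohort:

1. **Where is connectivity disrupted?** Compare patients and controls
   edge-by-edge over a whole-brain parcellation while controlling the
   family-wise error of the enormous multiple-comparison problem.
2. **Does connectivity predict cognition?** Build a cross-validated
   predictive model of a behavioral score (here a Wechsler-type composite,
   "WIS") from connectivity, and localize the predictive network.
3. **Is connectivity the pathway?** Test whether hematological exposures
   (hemoglobin concentration, red-cell distribution width) act on
   cognition *through* network connectivity (mediation), rather than
   directly.

`connectopipe` implements this chain — functional-connectivity
construction, Network-Based Statistics (NBS), Connectome-based Predictive
Modeling (CPM), and single-mediator bootstrap mediation — together with a
synthetic-cohort generator that plants known ground truth, so every stage
can be validated by recovery rather than by eyeballing.

## Functional connectivity

Input is a `T x N` matrix of region-averaged BOLD series over an
`N`-region parcellation (the packaged lookup table follows the AAL
116-region scheme: 78 cortical, 12 subcortical, 26 cerebellar labels).
Cleaning (`clean_timeseries()`) applies, in a fixed order:

1. **linear detrending** (per region, OLS on time);
2. **temporal bandpass**, default 0.01–0.08 Hz at TR = 2 s, as a 4-pole
   Butterworth applied forward–backward (`signal::filtfilt`) for zero
   phase;
3. **nuisance regression** (OLS with intercept) of confound series that
   have themselves been detrended and filtered identically, so the
   regression cannot reintroduce removed frequencies.

The order detrend → filter → regress is a convention; the literature
rarely states one, and filtering confounds to match the data (step 3) is
what makes the order essentially immaterial for the retained band.

Connectivity (`correlation_matrix()`) is pairwise Pearson correlation,
Fisher z-transformed (`atanh`), diagonal set to zero. Correlations at
`|r| >= 1 - 1e-7` (degenerate synthetic inputs, duplicated regions) are
clipped before the transform with a warning rather than propagating
infinities. The strict upper triangle is vectorized (`vectorize()`) in
**row-major order**; a 116-region matrix yields 6670 edge features. The
same edge-index convention is used everywhere in memory (1-based, R
style) and in every file export (0-based `i`, `j` columns); a silent
index-convention mismatch is the classic connectome bug, so the
convention is written into the output headers.

## Network-Based Statistics

NBS controls family-wise error at the level of *connected components* of
suprathreshold edges, exploiting the fact that real group differences
tend to form connected subnetworks while noise does not.

- **Prefilter.** An edge enters the analysis when a one-sample two-tailed
  t-test of its Fisher-z values against zero, within at least one group,
  survives Bonferroni correction over all E edges (`p < 0.05/E`). The
  filter is computed once, on the observed grouping, and the same
  retained set is reused inside every permutation.
- **Edge statistic.** Pooled-variance (Student) two-sample t per edge
  (Welch available via `var_equal = FALSE`), one-tailed by default in the
  patients-below-controls direction — the deficit hypothesis — and
  configurable.
- **Primary threshold.** Edges with `p < primary_alpha` (default `1e-4`)
  are suprathreshold; connected components are formed over them and a
  component's size is its **edge count** (not node count).
- **Null distribution.** Group labels are permuted (default 10000 times),
  the same threshold applied, and the maximal component size recorded.
  The corrected p-value of an observed component of size M is
  `(1 + #{null max >= M}) / (n_perm + 1)`. The `+1` estimator avoids
  p = 0 and counts ties as exceedances (conservative); it differs from
  the raw "proportion larger than M" by at most `1/n_perm`.

Two numerical notes. First, corrected p is monotone non-increasing in M
by construction. Second, the suprathreshold process must be
non-degenerate for the component-size null to be informative: at
`E * primary_alpha` well below 1 expected suprathreshold link per
permutation, the null is almost all zeros and corrected p-values are so
discrete that rejections become rare regardless of calibration. The
validation suite therefore runs its 40-node (780-edge) family-wise-error
simulation at a primary threshold of `1e-3` (≈0.8 expected suprathreshold
links per permutation), while the analysis default for 116-region data
remains `1e-4` (≈0.7 links). The threshold is scale bookkeeping, not a
tuning knob: error control holds at any threshold.

## Connectome-based Predictive Modeling

CPM predicts a behavioral score from connectivity with explicit
cross-validation:

1. **Selection** (training subjects only): Pearson correlation of every
   edge with behavior; p-values from the exact t-transform
   (`t = r sqrt((n-2)/(1-r^2))`, two-tailed — the positive/negative split
   captures sign separately); edges with `p < 0.005` form a positive
   (r > 0) and a negative (r < 0) set.
2. **Network strength**: the sum of a subject's Fisher-z values over a
   selected set — a weighted degree of the connectome restricted to the
   network.
3. **Models**: simple linear fits of behavior on positive and on negative
   strength, plus a combined two-predictor OLS model; applied to the
   held-out subject(s). A fold that selects no edges predicts the
   training mean (with a warning) — the model degrades gracefully
   instead of failing.
4. **Performance**: Pearson correlation between out-of-fold predictions
   and observed scores, with negative correlations reported as zero by
   default (a prediction that anticorrelates with the truth has no
   predictive value).
5. **Consensus network**: the intersection of the selected sets across
   folds; union and per-fold sets are retained for diagnostics.

Leave-one-out CV is the default (a fast-path computes each fold's
selection by downdating sufficient statistics, which also makes the
no-leakage property structural); stratified shuffled k-fold (k = 10) is
available and avoids all-patient folds at n = 60.

**Significance** is assessed by permutation: behavior is shuffled against
the connectomes (default 1000 times), the *entire* cross-validated
procedure is rerun, and the one-tailed p-value is
`(1 + #{null r >= observed r}) / (n_perm + 1)`. Parametric p-values are
wrong here because out-of-fold predictions share training data. One
calibration caveat is intrinsic: when no edge is selected in any fold,
out-of-fold predictions are the leave-one-out training means, which are a
decreasing affine function of the held-out value — the performance
statistic collapses to exactly −1. Under a sparse null many permutation
replicates tie at this degenerate value and the p-value acquires a
conservative atom at 1. The test suite therefore checks calibration of
`P(p <= t)` at decision-relevant thresholds rather than literal
uniformity; the atom can only make the test conservative, never
anticonservative.

**Localization.** Node degree within a selected network (`degree_table()`,
annotated from the atlas table), a high-degree-node follow-up
(`high_degree_followup()`: keep one hub and its incident edges, recompute
strength, partial-correlate with behavior controlling covariates,
Benjamini–Hochberg across the k hubs), and group-wise evaluation
(`groupwise_evaluation()`: within-group strength–behavior correlation,
asking whether the network is a patient-specific marker). Covariate
control is implemented as partial correlation — residualize both
variables on the covariates, correlate residuals, `df = n - 2 - k` —
matching "controlling for" without inventing a hierarchical model.

## Mediation

A single-mediator observed-variable model (the PROCESS "Model 4"
layout) with OLS paths and a common covariate set:

- `M ~ X + C` gives the a-path,
- `Y ~ X + M + C` gives b and the direct effect c′,
- `Y ~ X + C` gives the total effect c,

with continuous variables mean-centered. With identical covariate sets
the decomposition `c = c′ + a·b` is an algebraic identity of OLS and is
tested to `1e-10`. The indirect effect `a·b` gets a percentile bootstrap
CI (default 1000 resamples; subjects resampled with replacement;
degenerate resamples with constant exposure redrawn and counted;
bias-corrected-and-accelerated intervals available as an option —
percentile is the default because it is the modern PROCESS default and
has the more transparent finite-sample behavior). "Full mediation" is
flagged when the indirect CI excludes zero *and* c′ is non-significant at
0.05. Exposures (hemoglobin, RDW) are tested in separate models, on
patients only (hematology is not measured in controls), with BH-FDR over
the family of a-path tests; the mediator is the mean Fisher-z over the
CPM consensus positive network.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which every statistical claim in the test suite is evaluated.

A `cohort_spec()` fixes: 25 patients / 35 controls; 116 regions; 120
usable timepoints (a 130-volume acquisition minus 10 discarded
equilibration volumes at TR = 2 s); a planted **connected** 72-edge
disrupted component spanning 41 regions whose patient edge means are
lowered by `disruption_delta = 0.6` Fisher-z units; 30 of those edges
carry the behavioral score (`behavior = intercept + 2 × strength +
N(0, 8)` score units, intercept anchored to a control mean of 107.07);
and a patient-only mediation structure with hemoglobin ~ N(104.28,
13.31) g/L, RDW ~ N(42.06, 9.21), paths a = 0.43, b = 0.66, c′ = 0 and
residual SDs `sigma_m = 0.59`, `sigma_y = 0.43` chosen so that the
fitted path standard errors at n = 25 are ≈0.12 and ≈0.15 — i.e. the
planted effects carry the precision a cohort of this size reports, not
more. RDW is generated as a negatively mediator-correlated exposure
(`x_rdw = -a_rdw·m + noise`), so an observational fit recovers a
negative a-path of magnitude ≈0.48; its causal arrow is not modeled.

Two routes produce connectomes:

- **Time-series route** (`generate_timeseries_cohort()`): control edge
  correlation targets are drawn as Fisher-z ~ N(0.3, 0.15), patients'
  disrupted edges lowered by delta; each group's target matrix is
  projected to the nearest positive semi-definite correlation matrix by
  eigenvalue clipping (tolerance `1e-8`); subjects are stationary AR(1)
  Gaussian processes (lag-1 autocorrelation 0.3, 20 burn-in samples)
  colored by the group Cholesky factor, so detrending and filtering act
  on temporally autocorrelated input rather than white noise. The
  projection is not free: with dense random targets at N = 116 it
  absorbs roughly half of a 0.6-z planted contrast (the realized
  population contrast is ≈0.29 z, still an enormous per-edge effect at
  these sample sizes) and leaks small differences (≲0.1 z) onto
  unplanted edges. The generator measures the preserved contrast after
  projection and rejects the cohort specification as infeasible if less
  than a quarter
  survives on average or any planted edge loses its sign.
- **Matrix route** (`generate_matrix_cohort()`): subject edge vectors are
  drawn directly around the group Fisher-z targets with between-subject
  SD 0.1 plus the asymptotic correlation-sampling SD `1/sqrt(T-3)`. This
  route realizes planted deltas exactly and is used for the large
  replicate simulations (family-wise-error calibration, recovery power,
  coverage), where thousands of cohorts are needed.

What the generator does **not** emulate: head motion and scanner noise
spectra, voxel-level structure, spatially autocorrelated edge noise,
heavy-tailed subject effects, site/batch effects, and any realistic
distribution of edge weights (no such distribution is available to match;
the N(0.3, 0.15) z-targets are a convention). Passing recovery tests
therefore demonstrates that the *statistical machinery* is correct and
calibrated under the stated model — not that the pipeline is robust to
the full messiness of real pediatric fMRI.

## Validation design and problem sizes

The suite validates, among others: exact dual-route agreement of
components with an independent union-find oracle; edge t-statistics
against the hand pooled-variance formula; BH adjustment against the hand
step-up computation; NBS family-wise error on 500 exchangeable 40-node
cohorts (200 permutations each) within the binomial band [0.01, 0.09];
recovery of a planted 30-edge component (delta 0.6, n = 25/35) with
recall ≥ 0.8 in ≥ 90% of 50 replicates; noiseless CPM recovery
(consensus ⊇ planted network, out-of-fold r ≥ 0.95) with a structural
no-leakage check; permutation-p calibration over 200 permuted-behavior
cohorts; percentile-CI coverage for a·b within [90%, 98%] over 500
cohorts at n = 25; and a planted-full-mediation detection-rate check at
the generator defaults. These sizes were chosen so the whole suite runs
in minutes on one core while keeping binomial tolerances meaningful.

Two honest caveats surfaced by the validation are worth restating.
First, the CPM permutation p is conservatively mis-calibrated exactly on
the degenerate no-selection atom (above). Second, the planted-mediation
detection rate is structurally bounded: under a true c′ = 0 the
direct-path test false-positives 5% of the time, capping the joint
"indirect significant and direct non-significant" rate near 95% even at
perfect indirect power, and at the planted a-path precision (t ≈ 3.5 at
n = 25) normal-theory indirect power is itself well below 1 — so a ≥90%
joint detection-rate expectation is not attainable without planting a
stronger exposure–mediator coupling than the emulated study reports.
The corresponding check is allowed to fail rather than inflating the
planted effect.

## Limitations

- The atlas table carries labels and coarse network assignments only; no
  coordinates, no subject-specific parcellation.
- NBS and CPM operate on a fixed edge set per cohort; no
  threshold-free cluster enhancement, no node-count component statistic.
- Mediation is observed-variable, single-mediator, cross-sectional; it
  estimates path coefficients, not causal effects, and the generator's
  RDW pathway is explicitly observational.
- The pipeline's behavioral model is linear throughout, as in the
  methods it implements.
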