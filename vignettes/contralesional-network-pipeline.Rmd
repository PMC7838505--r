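---
title: "Methods: contralesional functional-network analysis and grade classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contralesional functional-network analysis and grade classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diffuse gliomas are graded low (WHO II, LGG) versus high (WHO III–IV, HGG),
and the grade drives treatment. Beyond the lesion itself, tumor growth
remodels the functional organization of the *structurally intact*
contralesional hemisphere, and that remodeling carries information about
tumor aggressiveness. `contranet` implements the full analysis that turns
parcellated resting-state fMRI node time series into an individual-level
grade classifier: Fisher-Z functional connectomes, sparsity-integrated graph
topology, repeated cross-validated AUC feature screening, and SMOTE-balanced
multivariate logistic regression with cross-hemisphere validation. Because
patient imaging data of this kind are rarely shareable, the package also
contains a first-class synthetic-cohort generator with recorded ground truth,
which is what the test suite and the acceptance script run on.

## The model, stage by stage

### Time-series cleaning

Input is an `N × T` matrix per subject (defaults `N = 123` parcels per
hemisphere, `T = 230` retained volumes at TR = 2 s, i.e. 240 acquired minus
10 discarded for scanner calibration). Cleaning is the fixed linear
composite:

1. **Linear detrending** — per-node OLS residual against intercept + slope·t.
2. **Nuisance regression** — OLS residual against an intercept plus the
   Friston 24-parameter motion expansion (`m`, `m` lagged one volume,
   and both squared) and any extra regressor rows (e.g. tissue signals).
3. **Band-pass filtering** — an ideal rectangular FFT filter on
   0.01–0.08 Hz. In-band components pass exactly; out-of-band components are
   removed exactly; the DC term is removed whenever the low edge is positive.

All three steps are linear projections. Detrending before regression is
absorbed by the regression intercept for the overlapping subspace, so the
composite is insensitive to reordering the first two steps; the order is
fixed anyway so that outputs are bit-reproducible. The ideal filter (rather
than an IIR design such as Butterworth) matches common resting-state practice
and makes the passthrough/rejection contracts exactly testable.

### Fisher-Z connectome

Edges are Pearson correlations between cleaned node series, transformed with
Fisher's Z = atanh(r). Correlations are clipped to |r| ≤ 1 − 1e−7 first: the
transform would otherwise map numerically perfect correlations to infinity
and poison every downstream statistic. The diagonal is fixed at 0 —
self-connections are not features. The upper triangle in row-major order
(1,2), (1,3), … is the canonical feature order everywhere; for `N = 123`
this is the 7,503-dimensional FC feature vector (`FC_<i>_<j>`, 1-based).

### Sparsity-integrated topology

Each FC matrix is binarized across the sparsity grid 0.01–0.34 (step 0.01):
at sparsity `s` the `round(s·N(N−1)/2)` strongest edges by signed Z are kept
(strongest positive first — standard thresholding practice; negative edges
can enter only after all positive ones). Ties break lexicographically by
(i, j) and rounding is half-away-from-zero, so graphs are platform-stable.

Per graph the package computes the standard metric set: clustering
coefficient `Cp`, characteristic path length `Lp` (unreachable pairs are
excluded from the mean and flagged — the least-distorting convention for
disconnected graphs), global efficiency `Eg`, local efficiency `Eloc`, and
the nodal metrics degree `Dc`, unnormalized Brandes betweenness `Bc`
(normalization is irrelevant after integration and standardization), nodal
global efficiency `NEg`, and nodal local efficiency `NEloc`. Small-world
indices come from degree-preserving Maslov–Sneppen rewiring: γ = Cp/⟨Cp⟩₀,
λ = Lp/⟨Lp⟩₀, σ = γ/λ, with ⟨·⟩₀ the mean over `n_null` rewired graphs
(default 20; the Monte-Carlo error of γ and λ shrinks as 1/√n_null, and 10
swap attempts per edge mixes the nulls well at these densities).

Every metric is then integrated over the sparsity grid by the trapezoid rule
(exact for linear curves), giving 7 global and 4·N nodal *area-under-curve*
features per subject (`aGamma … aEloc`, `aBc_<node>` …). Integration removes
the arbitrary choice of any single threshold. At the lowest sparsities both
the real and the rewired graphs can be triangle-free, leaving γ (and σ)
undefined as 0/0; such flagged points are imputed by linear interpolation
over the grid with nearest-finite extension at the ends before integration.
An entirely non-finite curve is an error, not a silent zero.

### Feature screening

Screening follows a three-step repeated inner-CV design on the training data
only:

1. A stratified 5-fold partition is drawn; each fold's *train-train* portion
   (the other four folds) is scored: every feature's ROC AUC is computed by
   the tie-corrected Mann–Whitney statistic.
2. A normal distribution is fitted to the AUC vector by its sample mean and
   SD, and features whose AUC exceeds the one-sided bound
   `mean + z(ci)·sd` become *candidates* for that draw.
3. The partition is re-randomized `n_repetitions` times (default 100; the
   study-scale suites in this package run 25) and each feature's selection
   frequency over all `n_repetitions × k_inner` draws is recorded. The
   predictive set is the top `top_pct` of features by frequency (zero-count
   features excluded), ties broken in canonical feature order.

Two design points deserve explanation:

* **Raw versus folded AUC in screening.** The exported `feature_auc()`
  defaults to the direction-folded value `max(a, 1 − a)`, which is the right
  summary when reporting a feature's discriminative strength regardless of
  direction. Screening, however, thresholds the *raw* one-sided AUC. Folding
  makes the null distribution half-normal, and the fraction of null features
  exceeding the fitted-normal one-sided bound would then be
  2·(1 − Φ(0.798 + 0.603·z)) instead of `1 − ci` — about four times the
  nominal rate at ci = 0.996. The raw one-sided rule keeps the screening
  calibrated: on pure-noise tables the candidate fraction per fold is
  `1 − ci` within binomial error, which the acceptance suite checks
  directly. It also matches selecting features "with high AUC" after
  estimating the normal distribution of AUCs.
* **Frequency base.** Counts are per fold (so 500 draws at the defaults),
  which is finer-grained and reduces ties compared with per-repetition
  counting. The top-percent base is the full feature count;
  `pick_predictive(of = "candidates")` restricts the base to the nonzero-
  frequency pool, which produces much smaller predictive sets when a few
  features dominate.

The inner train-test portions are deliberately unused by screening — the
procedure bases selection on train-train AUCs alone — and repetitions
re-randomize fold membership only (no subject resampling).

### Classification and cross-hemisphere validation

The classifier is a multivariate logistic regression over the predictive
features plus age. Age is force-included (it is a genuinely predictive
demographic in this setting: HGG patients are systematically older); sex and
location stay out of the default model but the machinery accepts any column.
Evaluation is stratified 10-fold outer CV where *everything* — screening,
SMOTE, standardization — happens inside each training fold:

1. screen the fold's training portion (repeated inner CV as above);
2. SMOTE-balance the training portion: synthetic minority points
   `x + u·(x_nn − x)` with `u ~ U(0,1)` and `x_nn` among the 5 nearest
   minority neighbors, until classes are exactly equal;
3. z-score the (augmented) training matrix, freeze the standardization in
   the model, and fit by damped Newton/IRLS with a small ridge (1e−4) on the
   slopes — SMOTE-balanced high-AUC feature sets are frequently linearly
   separable and the unpenalized MLE diverges;
4. report the ROC/AUC on the (original) training portion and on the held-out
   fold.

The per-fold AUC vector gives the "mean ± sd" summaries for the train and
validation contexts. Hemisphere specificity is tested by scoring all ten
fold models of one group on the *entire* feature table of the other group
(frozen standardization makes the models transportable); the two AUC
distributions are compared by a two-tailed pooled-variance t-test with
Benjamini–Hochberg correction across comparisons. Spec-level ambiguity —
whether a single refit model or all fold models cross-validate — is resolved
toward all fold models, which yields a distribution rather than a point.

## The synthetic-cohort generator

The generator emulates exactly the statistical structure the analysis
consumes, with realistic adult-glioma demographics as defaults:

* **Groups and sizes.** LH preset: 36 LGG / 44 HGG, ages 38.54 ± 10.88 and
  45.06 ± 13.21 years; RH preset: 32 LGG / 14 HGG, ages 39.48 ± 10.46 and
  51.25 ± 17.81; male fractions per group follow the same table. Ages are
  truncated at 18 (adult cohort).
* **Signal.** Node series are zero-mean multivariate normal draws. The HGG
  correlation matrix equals the LGG matrix except on a *planted edge set*,
  shifted by `effect_size` on the correlation scale and, when necessary,
  re-projected to the nearest positive-definite correlation matrix (Higham
  alternating projection, tolerance 1e−8). Topological group differences are
  therefore induced implicitly by the covariance shift, exactly as the real
  analysis derives topology from the same FC matrices. The planted set,
  effect size and both covariance matrices are recorded as ground truth.
* **Effect calibration.** What screening sees is the two-sample separation
  of the *cleaned* Fisher-Z features, and band-pass filtering inflates the
  Fisher-Z sampling SD from ~1/√T to roughly `1/sqrt(2(high − low)·tr·T)`
  (the filter keeps 28% of the spectrum at the defaults).
  `effect_for_separation()` converts a target separation into a
  correlation-scale effect: an analytic bandwidth-corrected start plus two
  fixed-point corrections measured on a pilot cohort under a dedicated
  calibration seed. The calibration targets the separation, never a
  downstream performance number.
* **What it does not emulate.** No hemodynamic response, scanner physics,
  head-motion artifacts (motion regressors are available synthetically but
  the simulated signal is motion-free), spatial autocorrelation of real
  parcellations, or between-subject covariance heterogeneity. Passing tests
  therefore demonstrate that the *procedure* is correct and calibrated — not
  that real gliomas are classifiable at any particular AUC.

## Problem sizes, determinism and numerics

The study-scale suites run n = 80 subjects (40/40) with 60-node networks:
1,770 edge features preserve the p ≫ n regime of the 123-node analysis
(7,503 features) while keeping repeated screening at desk scale; the
structural counts are verified at the full 123 nodes. Inner CV runs 25
repetitions in these suites (125 draws per screen); Monte-Carlo properties
sweep 10 seeds. The per-edge separations used are 1.0 SD (recovery of the
planted set) and 1.5 SD (classification performance), realized on the
cleaned features via `effect_for_separation()`.

Everything stochastic flows from explicit integer seeds through
`derive_seed(master, stage_label)`, a deterministic 32-bit hash, so every
stage is independently re-runnable and whole pipelines are bit-identical
under a fixed master seed; no function touches the global RNG state
(`withr::with_seed` everywhere). Degenerate inputs have defined behavior:
constant series detrend to zero; zero-variance nodes are an error naming the
node; zero-spread AUC vectors threshold at their mean with a degeneracy
flag; zero-variance t-test inputs with equal means return t = 0, p = 1;
empty graphs return zero metrics with a disconnection flag.

## Known limitations

* Graph metrics target binary undirected graphs only — no weighted variants,
  no modularity/rich-club/assortativity.
* The screening's fitted-normal threshold is a method-of-moments
  approximation; heavy-tailed AUC distributions (strong, many-featured
  effects) compress the candidate pool.
* Cross-hemisphere validation assumes both cohorts share the node count and
  feature naming; it does not re-register parcels.
* The generator's identity base correlation makes null FC features
  independent; real connectomes are spatially correlated, so real candidate
  pools will be effectively smaller than the feature count suggests.
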