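---
title: "Methods: biomimetic chromatography indices and GA-MLR QSRR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomimetic chromatography indices and GA-MLR QSRR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipochrom)
```

This vignette is the package's own account of the models and numerical
choices behind its functions: what is computed, under which assumptions,
which defaults were genuinely open choices, and what the shipped tests do
and do not demonstrate.

## 1. Index arithmetic

### CHI calibration

Fast-gradient reversed-phase retention times are placed on the
Chromatographic Hydrophobicity Index scale by an ordinary least-squares
line fitted to a calibration mixture of standards with known index values
(`fit_calibration`). The model is purely linear — no gradient-elution
physics is attempted — because in the fast-gradient protocol the
logarithmic dependence of retention on organic-modifier fraction is
absorbed into the standard values themselves. The CHI scale is nominally
0–100 but strongly retained analytes extrapolate beyond it; the package
returns such values unchanged and flags them via the `"extrapolated"`
attribute rather than truncating. An example standards file with
synthetic placeholder values ships under `extdata/`; real literature index
values must come from the user's calibration set, and the fit quality
(`r_squared`) should be inspected before use.

### CHI → CHI LogP

The conversion `CHI LogP = 0.054 × CHI − 1.467` maps CHI measured on the
nonionized form (for bases: at pH 10.6) onto the octanol–water LogP
scale. The slope and intercept are treated as given constants of the
method, not refit, and the unrounded value is returned by default; the
`round = TRUE` variant reproduces 2-decimal tabulations.

### HSA binding

Chromatographic HSA affinity interconverts between `logK_HSA` and percent
bound via `logK = log10(pct / (101 − pct))`, with inverse
`pct = 101·10^logK / (1 + 10^logK)`. The 101 denominator is deliberate:
on the shipped 26-compound fixture it reproduces every non-censored
logK/percent pair to ±0.01, whereas a 100 denominator misses the high
binders by about one percent (this verification is itself a shipped
test). The transform is monotone, so percent bound and logK order
compounds identically. Values of logK above ≈ 2 map above 100 % — outside
the invertible range — and are reported censored as "> 99.8"; compound 18
of the fixture (logK 2.27) is stored this way, with
`pct_HSA_censored = TRUE` rather than an invented number, preserving the
monotonicity invariant.

### Acid/base classification

Bases are ionized (and thus less retained) at low pH, acids at high pH,
so the CHI profile across pH 2.6 / 7.4 / 10.6 identifies character. With
`d_low = CHI(7.4) − CHI(2.6)` and `d_high = CHI(10.6) − CHI(7.4)`, the
implementation scores upward evidence `max(d_low, d_high, 0)` and
downward evidence `max(−d_low, −d_high, 0)` against a threshold
(default 10 CHI units, configurable — "significant" suppression has no
standard numeric criterion, and 10 units is comfortably above run-to-run
CHI reproducibility). Only upward evidence above threshold → basic; only
downward → acidic; neither → neutral; both → the dominant direction with
an `ambiguous` flag. The evidence formulation was chosen over a literal
two-branch rule ("acid-side delta large and basic-side delta small")
because a base whose ionization is incomplete at pH 7.4 keeps rising
between 7.4 and 10.6; both deltas are then positive and large, which is
unambiguous basic behaviour, not a conflict. On the shipped fixture 25 of
26 compounds classify basic; compound 8's profile is flat (its CHI at
pH 2.6, 97.99, is an outlier against every other compound's 38–73 and sits
3.4 units below its pH 7.4 value), so it classifies neutral at the default
threshold. The fixture stores measured values verbatim, so this is
reported as-is rather than patched.

## 2. Scale-comparison chemometrics

Correlation matrices use Pearson correlation (`stats::cor`). The
minimum-LogP census finds, per compound, which computed scale attains the
row minimum; exact ties are split fractionally so counts always sum to
the number of compounds. On the shipped library the census is MLogP 16 /
Silicos-IT 10, with three borderline rows (3, 20, 26) decided by margins
of 0.01–0.09 at the stored 2-decimal precision — counts computed from
unrounded source values could plausibly shift one of them.

Hierarchical clustering treats the index *columns* as objects (compounds
as features), standardizes them first so disparate native scales do not
dominate the metric, and applies Ward's rule in the Ward.D2 variant
(variance-minimizing update on Euclidean distances) — the common modern
convention. Merge heights are then guaranteed non-decreasing. Clustering
compounds instead is available via `cluster = "compounds"`. On the
combined fixture table the k = 2 cut cleanly separates the ten computed
LogP scales from the three experimental indices (CHI LogP, CHI_IAM,
logK_HSA) — computed and measured lipophilicity form distinct families.

PCA (`prcomp` on standardized columns) fixes the loading sign by making
each component's largest-magnitude element positive, so results are
reproducible across BLAS implementations.

## 3. Descriptor preparation

Descriptor matrices computed by external software are pruned before
modelling: zero-variance columns and columns whose modal value reaches a
fraction ≥ 0.95 ("almost constant"; 0.95 is the conventional default of
descriptor-generation software, configurable) are removed, then highly
correlated columns at |r| ≥ 0.95. Absolute correlation is used — an
anti-correlated duplicate carries the same information. Which member of a
correlated pair survives is inherently arbitrary; the package keeps the
first in column order, a deterministic, documented choice. After pruning,
no surviving pair violates the threshold (asserted by exhaustive pair
scan in the tests).

## 4. GA-MLR QSRR

The modelling core is ordinary least squares on a small, fixed-size
descriptor subset, with the subset chosen by a genetic algorithm:

* **Chromosomes** are descriptor subsets of exactly `model_size`
  (default 3, the typical size of interpretable retention models).
* **Fitness** is leave-one-out Q² of the OLS fit on the training split —
  the standard selection criterion for this protocol, preferred over R²
  because it resists overfitting at n ≈ 20; R² is available as an option.
* **Operators**: tournament selection (size 2), uniform crossover (the
  parents' union sampled back down to `model_size`), per-gene mutation
  with probability 0.20 — the protocol's "mutation rate of 20" read on
  the percent scale — and elitism, so best fitness is non-decreasing.
  Population 10, 500 generations per model size ("per size" read as per
  chromosome cardinality). The exact operators used by commercial
  QSAR-selection software are not published; these are reasonable,
  documented defaults, and on pools small enough to enumerate the GA
  reaches the exhaustive-search optimum in ≥ 95 % of seeds (a shipped
  acceptance property).
* **Fitness caching** by subset makes the 500-generation runs cheap: only
  distinct subsets are ever refit.

Singular fits (collinear subsets) receive fitness −∞ rather than an
error, so the GA simply selects away from them.

### Training/validation split

Compounds are split 19/7 (scaled proportionally for other library sizes).
The membership of the split used to produce any particular published
model is generally unpublished, so the default is a reconstruction:
systematic sampling by response rank (evenly spaced ranks go to
validation), which gives both groups full response-range coverage and is
deterministic. A seeded random strategy is provided.

### Validation battery and applicability domain

`qsrr()` reports R² and RMSE on the training set, leave-one-out Q²,
external R², external RMSE and Lin's concordance correlation coefficient
on the validation set. Conventions:

* **RMSE** uses the n denominator (not n − p − 1), matching the usual
  RMSE_tr / RMSE_P reporting of QSAR software; the degrees-of-freedom
  variant is available (`r2_rmse(..., df_adjust = TRUE)`). Which
  convention a given published table used cannot generally be determined
  without its raw data, hence both.
* **Q²_LOO** is implemented twice — literal refitting and the exact
  hat-matrix identity (PRESS residual = residual/(1 − leverage)) — and
  the two must agree to 1e-8, a two-oracle consistency test that guards
  the fast path used inside the GA. Q² ≤ R² always (PRESS ≥ SS_res for
  OLS).
* **CCC** uses sample (n-denominator) moments, the standard Lin
  definition; it penalizes location and scale shift, so CCC = 1 only for
  exact agreement.
* **Williams plot**: leverage `h = x'(X'X)⁻¹x` with intercept column,
  critical leverage `h* = 3(p + 1)/n`, residuals standardized by training
  RMSE, outside-domain iff `h > h*` or |standardized residual| > 3 — the
  conventional cut-offs.

## 5. Synthetic data

The generators provide inputs with the statistical structure the analysis
assumes, at a default shape of 26 compounds × 200 descriptors — the
fixture's library size, with the descriptor count kept small enough that
exhaustive-search oracles stay feasible while still swamping the signal
with decoys. Descriptor marginals are standard normal with optional
within-block correlation via a shared latent factor; the response is a
sparse linear combination (default 4·d3 − 2·d7) plus Gaussian noise
(default sd 0.5, a realistic index-unit noise level relative to
coefficient magnitudes of 2–4). Real descriptor blocks are
heavier-tailed, discrete or bounded; none of that is simulated, so
passing recovery tests shows the selection machinery works where its
assumptions hold, not that any particular real descriptor set yields a
good model. Calibration-run and index-family generators follow the same
pattern (uniform retention times on a line plus noise; column groups
sharing a latent factor). All generators are pure functions of their
specification including its seed.

## 6. Problem sizes and test design

The shipped suite exercises: exact reproduction of the fixture
conversions (26 rows); GA-vs-exhaustive equivalence on 12-descriptor
pools over 20 seeds; planted-signal recovery among 100 decoys at n = 26,
noise sd 0.5, over 20 seeds with the full default GA budget (population
10, 500 generations); and the closed-form identities for Q², CCC and
leverages. These sizes keep the whole suite around half a minute while
matching the study-scale geometry (n = 26, p = 3 models).

## 7. Known limitations

* Molecular descriptors are not computed here; the package consumes
  externally computed matrices.
* The 3170-descriptor matrix behind the fixture library's published
  models is not redistributable, so the package does not attempt to
  reproduce any specific fitted coefficients; its QSRR tests are
  structural and property-based (oracle equivalence, planted-signal
  recovery) instead.
* The calibration model is strictly linear; no peak-shape or gradient
  physics.
* Censored values are carried as flags, not imputed; downstream
  statistics exclude them explicitly.
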