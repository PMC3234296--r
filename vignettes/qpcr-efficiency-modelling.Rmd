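---
title: "Modelling qPCR amplification efficiency from sequence and curve data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling qPCR amplification efficiency from sequence and curve data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrEff)
```

## The problem

Relative quantification in qPCR compares amplification reactions, and the
comparison is only fair if the per-cycle amplification efficiency `E` of
each reaction is known: `E = 1` means no amplification, `E = 2` perfect
duplication, and empirical reactions mostly land between 1.65 and 1.90.
Efficiency can be *measured* from the fluorescence curve of a reaction
that has already been run, or *predicted* before any reagent is pipetted,
from properties of the amplicon and the primer pair. qpcrEff implements
both sides and the statistical machinery connecting them:

1. sequence features of an amplicon/primer-pair combination
   (`extract_features()`),
2. per-reaction efficiency from a fluorescence curve
   (`estimate_efficiency()`),
3. a generalized additive model predicting efficiency from features
   (`fit_gam()`, `predict_efficiency()`),
4. a univariate rank-test battery with effect-size conversions
   (`univariate_battery()`),
5. classifier-style validation of predictions (`roc_curve()`,
   `pr_curve()`, `threshold_sweep()`), and
6. a synthetic-data generator making all of it testable without
   laboratory data (`generate_dataset()`, `simulate_curve()`).

## Sequence features

Features are computed on plain `{A,C,G,T}` strings; lower case is
normalized and IUPAC ambiguity codes are rejected with an error rather
than silently scored, because every feature below is only defined on a
concrete base call.

**Hybridization scores.** A primer's tendency to self-anneal
(`primersSelfcom`) and a pair's tendency to form primer dimers
(`primerDimers`) are estimated by a k-mer device: each oligo is reduced
to its overlapping triplets (window 3, step 1), and the score is the
multiset-intersection size between the triplets of one strand and the
triplets of the reverse complement of the other (for self-complementarity,
of the primer itself). The raw integer count is the default covariate; a
normalized variant (count over the smaller triplet count) is available
via `normalize = TRUE` for cross-length comparison. The per-pair
`primersSelfcom` covariate is the sum of the two primers' self-scores.

**Aggregated primer covariates.** `primersLength` is the arithmetic mean
of the two primer lengths and `gcPrimers` the G+C fraction of the two
primers concatenated; both preserve the units and range of the per-primer
quantities. `gcImbalance` is the absolute difference of the two primers'
G+C fractions.

**Repeats and palindromes.** Homopolymer runs are summarized per base as
the longest run (`aCount`, ...) and a flag at the conventional N6 cutoff
(`aRepeats`, ...). `sequencePalindromes` counts reverse-complement
palindromes of length at least 6 (the same N6 convention; configurable but
even, since odd-length reverse-complement palindromes cannot exist),
counting each start position once at its maximal extent.

**Melting temperature.** The default is a nearest-neighbor duplex model
with the unified DNA/DNA parameter set, an entropic monovalent-salt
correction `0.368 (N-1) ln[Na+]`, and a two-state transition at total
oligo concentration `CT` (term `R ln(CT/4)` for non-self-complementary
strands). Defaults are 50 mM Na+ and 240 nM oligo, the concentration the
features are meant to model; the Wallace `2(A+T) + 4(G+C)` rule is kept as
a fast alternative. Units are degrees Celsius.

## Efficiency from an amplification curve

A reaction's curve is 40 fluorescence readings, one per cycle. The
estimator proceeds in four steps.

1. **Baseline correction** (`baseline_correct()`): `standard` subtracts
   the mean of cycles 1-5; `dynamic_tube` locates the take-off at the
   maximum of the smoothed finite-difference second derivative and
   subtracts the pre-take-off mean; `adaptive` subtracts the median of
   the lowest quartile. A constant trace under `dynamic_tube` falls back
   to `standard` with a warning; corrected values may be negative.
2. **Sigmoid fit** (`fit_sigmoid()`): least squares for the 4-parameter
   logistic `F(c) = F0 + a / (1 + exp(-(c - c½)/b))`, with the baseline
   `F0` kept free even on corrected curves so residual background cannot
   leak into later steps. Initialization is deterministic (amplitude and
   midpoint from the data, five fixed slope starts); a trace whose
   max/median ratio after background shift is below 1.2 raises a
   no-amplification condition that maps to `E = 1`.
3. **Anchor cycle**: the second-derivative maximum of the logistic has
   the closed form `cpD2 = c½ - b log(2 + sqrt(3))`; the anchor `n` is
   the real-valued cycle at which the fitted baseline-subtracted
   fluorescence equals 20% of its value at cpD2, inverted analytically on
   the rising limb and rounded to the nearest integer cycle. On any
   logistic the 20% point precedes cpD2, so `n < cpD2` always.
4. **The ratio** `E = F(n)/F(n-1)`: evaluated on an exponential-phase
   model `A E^c + d` fitted to the observed fluorescence over the cycles
   bracketing `n` (half-width 4, capped at cpD2). The free offset `d`
   absorbs whatever background the correction left behind, and the ratio
   of the exponential component *is* the per-cycle amplification factor.

Step 4 deserves its numerical footnote. Evaluating the ratio directly on
the fitted logistic would systematically understate the exponential-phase
ratio: at the 20% anchor the logistic's own consecutive-cycle ratio is
`(1 + uE)/(1 + u)` with `u = 5(3 + sqrt(3)) - 1 ≈ 22.66`, i.e. about
1.958 when the underlying chemistry doubles perfectly — a bias built into
the logistic's shape, not the data. Reading the ratio from a local
exponential fit instead recovers the true per-cycle factor exactly on
noise-free exponential-phase data, and the window (up to 9 points, fitted
with weights that shrink with fluorescence to mirror signal-proportional
noise, seeded multi-start) averages single-cycle noise. The box
constraint `E ∈ (1, 2.5]` guards the optimizer; a fit stuck at a bound is
discarded in favor of the offset-free difference-ratio seed.

## The efficiency GAM

The prediction model is a Gaussian additive model on the efficiency scale
itself (no link transform — the response is already a bounded, directly
interpretable number):

```
efficiency ~ s(lengthSequence, gcSequence)
           + s(primersLength,  gcPrimers)
           + s(gcImbalance,    primerDimers)
```

Each term is a bivariate thin-plate regression spline with basis
dimension 30 (configurable via `k`), and smoothing parameters are chosen
by GCV minimization (`method = "REML"` is available but not the default,
since the reported fit criterion is the GCV score
`n D / (n - edf_total)^2`, also exposed directly as `gcv_score()`).
Model comparison uses `AIC = -2 loglik + 2 edf_total`
(`compare_models_aic()`), with ties resolved toward fewer effective
degrees of freedom, and refuses to compare fits on different records.

Covariates that are univariately associated with efficiency but absent
from this formula — species, operator, template metadata, 3' termini,
palindromes, repeat flags, melting temperatures — are deliberately not
model terms: in multi-covariate fits their contribution dissolves into
covariation with the three interactions (each primer pair lives in one
project, one species, one operator), so the model keeps only the
sequence-intrinsic surfaces. All of them remain in the feature table for
user-defined refits.

Predictions are the intercept plus the three smooth evaluations, clamped
into the physical range [1, 2] with a per-record flag (the model itself
is unbounded; the quantity is not), and records with any covariate
outside the training range are flagged as extrapolation rather than
refused.

`save_model()`/`load_model()` serialize a fitted model to a versioned
JSON file holding the coefficient vector, each smooth's basis
construction (knots, projections, absorbed identifiability constraints)
and the training ranges; a loaded model predicts identically to its
source without requiring the training data. Unknown versions and
truncated files fail loudly.

## Univariate battery and effect sizes

Efficiency data are heavily tied, so the battery uses asymptotic rank
tests with explicit tie handling: quantitative covariates against
efficiency by a Spearman test (`rho` from ranks, `Z = rho sqrt(n-1)`,
two-sided normal p), categorical covariates by the tie-corrected
Kruskal-Wallis test, and two-group contrasts by the Wilcoxon-Mann-Whitney
Z with tie-corrected variance. Ties are midranked by default;
`tie_policy = "random"` draws distinct ranks within tie groups under a
seed ("random rank averaging"), and across seeds the resulting `rho`
values bracket the midrank value. Note that other asymptotic
formulations (e.g. linear-statistic frameworks) print slightly different
Z values on the same data; exactness is claimed for the conversion and
p-value formulas, not for reproducing any particular software's Z.

Effect sizes chain from the rank correlation by closed forms:
`d = 2 rho / sqrt(1 - rho^2)`, `logOdds = d pi / sqrt(3)`, and Hedges'
`g = d (1 - 3/(4n - 9))`. Raw p-values are reported against a 0.05
convention; no multiplicity correction is applied by default
(`adjust = "holm"` opts in).

## Classifier-style validation

A prediction is useful if it ranks reactions correctly, so predicted
efficiency is evaluated as a decision score for the binary outcome
"measured efficiency reaches the experimental threshold". A reaction at
exactly the threshold counts as a success (strictly below fails);
the conventional cutoff is 1.65, and `threshold_sweep()` defaults to
{1.60, 1.65, 1.80} — the last being the boundary often quoted for
optimized reactions. ROC points are swept over every distinct score with
ties grouped and endpoints (0,0), (1,1); AUC is trapezoidal and equals
the Mann-Whitney identity `U/(n1 n0)` exactly. PR curves use the
convention precision = 1 at zero predicted positives. Curves are
invariant under strictly monotone transforms of the scores; thresholds
yielding a single class are skipped with a warning.

## What the synthetic data does and does not emulate

`generate_dataset()` draws 90 amplicon/primer-pair combinations
(amplicons 74-907 bp, primers 18-25 nt, base composition from a
symmetric Beta(12, 12) so G+C mostly spans 0.3-0.7), computes covariates
with the package's own extractors — so covariate correlations arise from
sequence structure, not independent resampling — and replicates each
pair 44 times for about 3960 reaction rows, the scale of a
~4000-reaction study. True efficiency is a documented smooth surface
over the six model covariates (one Gaussian bump plus a linear tilt per
covariate pair, on within-dataset z-scores), centered at 1.738 and
scaled so the surface carries a target fraction (default 0.41) of row
variance given the residual SD (default `sqrt(0.0092293)`, the study's
residual scale); observations add Gaussian noise and are truncated to
[1, 2] (a minor distributional distortion near the boundaries, accepted
in preference to resampling). Every draw flows from one mandatory seed.

`simulate_curve()` builds a 40-cycle sigmoid whose rising limb grows by
*exactly* `true_E` per cycle — an exponential bent into its plateau by a
sharp Hill-type knee (exponent 8) — because an exact logistic never
carries the per-cycle ratio anywhere on its limb (see the numerical
footnote above), which would make "recover the true ratio" an
ill-posed test. The knee sits where a typical template load would put
it: take-off near cycle 18 for fast reactions, capped at `cycles - 6` so
slow reactions still plateau inside the window. Baseline defaults to 10
units, plateau amplitude to 100; noise is multiplicative Gaussian.

What this deliberately does **not** emulate: species/operator/template
batch effects (in real data these covary with the primer pair and were
dismissed as covariation, so the generator assigns metadata at random
and independent of efficiency), mispriming and melting-curve artifacts,
plate effects, and the drifting baselines of real optics. Consequently,
passing tests demonstrate correctness of the algorithms under the stated
data-generating assumptions — not field performance on any particular
instrument's output.

## Numerical choices and degenerate inputs

* Sizes used by the test suite are the package's own choice of
  desk-scale problems: 90 pairs x 5 replicates for unit-level GAM fits,
  20 replicates of the full 3960-row design for the
  deviance-explained recovery check, 200 curves for noisy estimator
  recovery, 1000 random primers for the hybridization-score oracle.
* All nonlinear fits are deterministic: fixed multi-starts, no random
  restarts; every stochastic generator requires a seed.
* Degenerate inputs fail with classed conditions: constant covariates
  (`qe_degenerate_design`), flat curves (`qe_no_amplification`, mapped
  to `E = 1`), constant vectors in correlation tests, single-class
  labels in curve evaluation, out-of-range efficiencies. A
  Kruskal-Wallis test on identically equal values returns `H = 0`
  rather than 0/0.
* Basis dimension is reduced automatically when a covariate pair has
  fewer distinct points than the requested `k`.

## Known limitations

* The curve estimator assumes one clean sigmoidal (or exponential)
  phase; biphasic curves, strong drift, or take-off before cycle 2 (too
  much template) raise estimation errors rather than guessing.
* Very slow reactions (E below roughly 1.1 under the default curve
  geometry) place most of their exponential phase outside the
  observation window; the estimator reports an error or `E = 1`, which
  is the honest reading of such a curve.
* The GAM predicts only from the six sequence covariates; reagent,
  instrument and operator effects are out of scope by design.
* The hybridization scores are alignment-free k-mer counts: they do not
  check that primers anneal to the template, nor compute hairpin free
  energies.
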