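---
title: "Pathway-informed prediction of apoptosis-inducing treatment responsiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-informed prediction of apoptosis-inducing treatment responsiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoptopredict)
```

## The model

`apoptopredict` predicts how glioma cell lines respond to apoptosis-inducing
treatment (TMZ, TRAIL, or both) from quantitative profiles of 19 core
apoptosis regulators. The central modeling idea is that the pathway's
known wiring can be encoded *before* any statistics are run: small sets of
proteins acting at the same control point are collapsed into single
features ("functional groups", FGs) by arithmetic that mirrors their
biological relationship. Redundant antagonists add (Bcl-2 + Bcl-xL +
Mcl-1; Bax + Bak; DR4 + DR5), obligatory partners multiply (Apaf-1 ×
caspase-9, so the apoptosome feature vanishes when either component is
absent; FADD as the obligatory DISC adaptor), direct inhibitor pairs form
ratios (caspase-8/cFLIP, caspase-3/XIAP), and proteins with distinct
individual roles stay single (Bid, Bim, Puma, Noxa, SMAC). This is
deliberately not a kinetic (ODE) model: no rate constants are assumed,
only stoichiometric-style interplay.

The 11 FG values per line are then z-scored and embedded by
correlation-scale PCA. Components with eigenvalue above 1 are retained
(Kaiser criterion), with a floor of one component and a `n_components`
override. Correlation-scale PCA (rather than covariance) is forced by two
facts: the Kaiser rule is defined on the correlation scale, and FG units
are heterogeneous (nM sums, dimensionless ratios, nM² products), so raw
covariances would be dominated by unit choices. Loading signs are fixed by
making the largest-magnitude coefficient of each component positive, so
projections and movement vectors are reproducible across platforms.

Survival relative to untreated control defines ordinal response classes:
highly responsive (survival ≤ 0.30), low responsive (0.30, 0.80],
resistant (> 0.80). "Up to 30%" is read as inclusive; the same
upper-inclusive convention is used at 0.80 and for synergy-class bins.
Classes with a single member are pooled into the adjacent class toward
lower responsiveness (a singleton resistant class, having no
less-responsive neighbor, joins the low responders); pooling repeats until
no singleton remains. Linear discriminant analysis with a pooled
within-class covariance segments the retained PC space into convex
response regions.

Prediction is leave-one-out: all model stages (standardization, PCA,
pooling, LDA) are refit without the held-out line, which is then projected
with the fold's frozen parameters and classified. The treatment
recommendation for a line is the arm with the more responsive predicted
class; equal predictions yield "either".

Combination effects are scored by Webb's fractional product (the Bliss
independence form): `CI = s_AB / (s_A s_B)`, with CI < 1 synergy, ≈ 1
additivity, > 1 antagonism. The method cited for this score does not fix
a direction convention, so we document ours in the output headers: lower
CI means more synergy.

ABT-737 sensitization is modeled as total in-silico depletion of Bcl-2 and
Bcl-xL: the target values are set to zero, FGs are recomputed, and the
line is re-projected into the PC space fitted on unperturbed data (nothing
is refit; the perturbed line is treated exactly like a held-out test
point). Because only the Bcl-2+Bcl-xL+Mcl-1 FG changes, the displacement
equals `-Δz × loadings[FG, 1:k]` with `Δz = (Bcl-2 + Bcl-xL)/SD(FG)` — the
"movement vector" formulation — and the package tests verify both
formulations agree to 10⁻¹⁰. The verdict is SENSITIZED when the
post-depletion class is strictly more responsive than the pre-depletion
class; crossing an LDA region boundary is the natural formalization of
"repositioning toward responders", since the LDA segmentation *is* the
response-region definition. A continuous secondary readout (reduction in
Mahalanobis distance to the most responsive class mean) is reported for
borderline cases.

## Parameters that matter

* `thresholds = c(0.30, 0.80)` — survival fractions separating the three
  response classes. Dimensionless fractions of untreated control.
* `fixed_k = 4` (pipeline default) — retained PC dimension. The general
  mode recomputes the Kaiser criterion inside every LOOCV fold
  (`fixed_k = NULL`); the fixed default reflects the 4-D working space the
  procedure was designed around and makes folds comparable.
* `ridge` — LDA covariance regularization, default `1e-6 · trace(Σ)/k`.
  With ~10 training points in 4 dimensions the pooled covariance can be
  ill-conditioned; the ridge is small enough to leave well-conditioned
  fits numerically unchanged.
* `priors = "uniform"` — no class-frequency weighting (none is implied by
  the procedure); `"empirical"` is available.
* `similar_tol = 0.10` — survival-fraction margin within which two arms
  count as "similar amounts of cell death" when scoring recommendations.
  The notion is inherently qualitative; 10 percentage points is our
  quantification, is exposed as configuration, and is recorded in output
  metadata. We additionally score an "either" recommendation as correct
  whenever one of its two readings is (it is only emitted on tied
  predictions).
* `ci_bins = c(0.5, 0.9)` — CI edges separating high synergy, moderate
  synergy and non-synergistic classes. These are a working convention for
  synthetic studies, not published values; any reproduction against real
  data must supply the grouping used there.
* `ratio_policy = "strict"` — a zero ratio denominator is an error, so
  data problems surface; `"floor"` substitutes a small epsilon
  (10⁻⁶ of the denominator's panel median) for exploratory runs.
* `mono_floor = 0.01` in `combination_index_table()` — detection floor on
  survival before CI formation: a monotherapy survival of exactly 0 leaves
  the CI undefined, and viability assays cannot measure exact zeros.

## Design choices where the design was open

* **DISC arithmetic.** The pathway logic says the DISC feature should
  vanish when an obligatory component is absent. The two death receptors
  are functionally redundant — either can seed the complex — while FADD is
  strictly required, so the default is `(DR4 + DR5) × FADD`. The strict
  triple product `DR4 × DR5 × FADD` is available via
  `disc_rule = "triple_product"`.
* **Ratio orientation.** Effector over inhibitor (caspase-8/cFLIP,
  caspase-3/XIAP), so larger FG values consistently mean greater death
  competence. Orientation only flips loading signs; class separability is
  unaffected. Configurable.
* **BH3-only proteins.** Kept as four separate variables by default; a
  merged single-FG variant (`merge_bh3 = TRUE`) exists for comparison.
* **Pooling direction.** Singletons merge toward the *less* responsive
  neighbor. Both documented instances of pooling in the procedure's
  original use follow this direction, and it is conservative: a lone
  highly-responsive line is treated as a low responder rather than the
  reverse.
* **Tie-breaks.** Equal discriminant scores classify as the less
  responsive class — conservative for treatment decisions.
* **Held-out labels under pooling.** When the held-out line's class is
  absent from a training fold, its observed label is mapped by the same
  pooling rule (toward the nearest less-responsive class present) before
  scoring.
* **LDA implementation.** Written in-package because the procedure fixes
  details (pooled covariance with ridge, uniform priors, conservative
  tie-break) that library implementations do not expose uniformly; tests
  cross-check predictions against an independent reference implementation
  and against the closed-form two-class boundary.

## The synthetic-data generator

The generator exists so every stage can be validated against known ground
truth. It emulates the statistical structure of a calibrated apoptosis
panel:

* Protein abundances are log-normal around plausible per-protein medians
  (≈ 0.1–500 nM across the panel; the death receptors in relative surface
  units), with between-line log-SD 0.5 (about 3-fold spread).
* All proteins share a line-level "apoptotic competence" factor (default
  loading 0.7, signed positive for pro-apoptotic and negative for
  anti-apoptotic proteins). This co-regulation gives the FG matrix a
  dominant variance direction, as real panels show (a handful of PCs
  carrying most of the variance). Without it, 11 independent FGs would
  have a flat eigenvalue spectrum and an unsupervised 4-D projection would
  have no reason to retain the class-relevant direction.
* Replicates (default 3 per measurement, as in a typical immunoblot
  design) scatter with a 15% coefficient of variation.
* Latent responsiveness per arm is a linear combination of standardized
  FG values (separate coefficient vectors for TMZ and TRAIL so arms can
  disagree), scaled to SD `separation` (default 3) in logit units; true
  survival is the logistic transform; observed survival adds Gaussian
  noise (SD 0.05) and is clipped to [0, 1.1], since relative-to-control
  assays can read slightly above 100%.
* Combination survival is `true_CI × s_TMZ × s_TRAIL` plus noise, with the
  true CI stored per line (scalar, vector, or a function of the FG
  z-scores).
* `class_means` optionally plants a Gaussian-mixture structure in the line
  factor (balanced assignment, unit component SD), for experiments that
  need well-separated classes with exact labels; the planted labels travel
  with the panel as an attribute.

What the generator does **not** emulate: real covariance structure beyond
one shared factor, heavy-tailed or censored measurements, batch effects
between blots, MGMT-status confounding, or any mechanistic link between
protein state and drug pharmacology. Passing tests on synthetic data
therefore demonstrate that the pipeline's machinery is correct and that
the method recovers structure *of the kind it assumes*; they are not
evidence about prediction accuracy on real tumor panels.

## Numerical choices and degenerate inputs

* Standardization guards: an FG whose SD is below 10⁻¹² of its mean
  magnitude is treated as constant and rejected with the FG named.
* Eigendecomposition of an 11×11 correlation matrix from n ≤ 11 lines has
  rank ≤ n − 1; trailing null-space eigenvectors are not identifiable and
  are never used (retention is capped by the Kaiser rule or `fixed_k`).
* LOOCV folds whose training labels collapse to a single class are marked
  unpredictable and count as incorrect by default (`skip_degenerate`
  excludes them from the denominator instead).
* All pipeline stages are deterministic given inputs and configuration;
  the only randomness in the package lives in the generator, which is
  fully determined by its seed (response and combination generation use
  fixed small offsets of the panel seed).

## Problem sizes used in the validation suite

The test suite validates the FG arithmetic against direct hand
computation on 100 random 5-line panels; PCA against brute-force
eigendecomposition on 8×11 matrices; LDA against the closed-form
two-class boundary (whitened classes, tolerance 10⁻⁶); LOOCV leakage by
bit-exact fold-model comparison; the permutation null on a 40-line panel
over 100 label permutations; parameter recovery on 24-line panels with
6-SD planted separation over 50 seeds (mean accuracy ≥ 0.9); Webb-CI
round trips in the noiseless limit; and the equivalence of the two
sensitization formulations on 100 random perturbation cases (10⁻¹⁰).
These sizes keep the full suite under half a minute while leaving each
statistical check well-powered.

## Known limitations

* With 11 cell lines, LOOCV accuracies are coarse (multiples of 1/11) and
  seed-to-seed variation on synthetic panels of that size is large.
* The CI class bins and the `similar_tol` margin are conventions that must
  be aligned with any external data set before comparison.
* The sensitization model treats depletion as total and instantaneous and
  ignores Mcl-1-mediated compensation beyond what the FG arithmetic
  captures; it predicts repositioning, not dose–response.
* Survival values are trusted as fractions of control; no assay error
  model is fit.
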