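---
title: "Methods: staged pump-speed NIRS analysis and severity classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged pump-speed NIRS analysis and severity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmonirs)
```

## The measurement model

`ecmonirs` analyses lower-limb NIRS recordings taken while the ECMO pump
speed is perturbed through a fixed six-stage protocol: a 15-minute baseline
at the clinical speed, four 10-minute stages at −1, 0, +1 and +2 speed units,
and a closing 15-minute stage back at the initial speed (4200 s in total).
One speed unit is 300 rpm for VV and 500 rpm for VA cannulation, so both
modes receive the same *relative* perturbation. The final stage is a
two-unit *reduction* from the preceding +2 stage, which is why
high-severity responses are expected to be most visible there: peripheral
tissue that depends on ECMO support desaturates when support drops.

Channels are relative concentration changes ΔHbO₂ and ΔHHb (and their sum
ΔHbT), plus the tissue saturation index (TSI, %). When only raw
dual-wavelength optical densities are available, `mbll_convert()` solves the
modified Beer–Lambert law system

$$\Delta OD(\lambda) = \big[\varepsilon_{HbO_2}(\lambda)\,\Delta HbO_2 +
\varepsilon_{HHb}(\lambda)\,\Delta HHb\big]\, d\, DPF(\lambda)$$

per sample. The extinction coefficients, source–detector distance
(3.0/3.5/4.0 cm) and differential pathlength factor are configurable
literature values in `mbll_params()`, not hard-coded constants: the vendor
processing chain that usually performs this step does not publish its
tables. The canonical entry point accepts concentration channels directly;
MBLL support exists for raw-intensity workflows and for the forward/inverse
round-trip tests (`make_optical_densities()` is the exact forward model, so
the inversion is testable to numerical precision).

## Preprocessing

Physiological interference concentrates in the respiration (0.15–0.4 Hz) and
cardiac (0.4–1.6 Hz) bands, well above the stage dynamics (a stage lasts
600–900 s). The filter is a fourth-order Butterworth low-pass with a 0.1 Hz
cutoff applied forward and backward, giving zero phase (stage boundaries are
not shifted) and the squared single-pass magnitude

$$|H_2(f)| = \frac{1}{1 + (f/0.1)^8},$$

so a 1 Hz cardiac tone is attenuated to ~10⁻⁸ and the 0.15 Hz respiration
band edge to below 4% of its input amplitude. Edge handling: odd-reflection
padding of length 3·(order+1) at both ends plus steady-state initial
conditions at the padded boundary value, so the slow filter starts settled
instead of relaxing from zero (with a 0.1 Hz cutoff the start-up transient
would otherwise outlast the padding by an order of magnitude).

HbT is computed **before** normalization — summation commutes with the
linear filter but not with per-channel rescaling. Each of the four channels
is then min–max normalized to [0, 1] independently over the full 70-minute
trace; the bounds are stored so the transform is invertible. TSI, although
already a percentage, is normalized like the others by default
(`normalize_tsi = FALSE` opts out) because the downstream features consume
normalized values uniformly. A constant channel is a degenerate input: it is
mapped to zeros with a warning rather than an error, since a flat channel can
legitimately occur in synthetic edge cases.

## Stage features

Four families over the six stages, computed per channel:

| family | definition | stages × signals | count |
|---|---|---|---|
| SM | stage mean | 6 × {HbO₂, HHb, HBT, TSI} | 24 |
| SA | stage mean − baseline mean | 5 × {HbO₂, HHb, HBT} | 15 |
| SD | stage mean − previous-stage mean | 5 × {HbO₂, HHb, HBT} | 15 |
| SS | within-stage slope | 6 × {HbO₂, HHb, HBT} | 18 |

TSI participates only in the stage means. Because Stage1's predecessor *is*
the baseline, SA and SD coincide at Stage1 for each of the three Hb signals —
the unique structural coincidence that reduces 72 features to 69. We resolve
it by dropping the SD Stage1 entries and keeping SA (the choice is arbitrary
and configurable via `keep = "SD"`); no other pair of features is
structurally identical, so this is the only defensible deduplication.

Slopes default to ordinary least squares against time within the stage;
"slope from beginning to end" could equally mean the endpoint difference, so
an `endpoints` method is provided and the choice is recorded in the feature
extraction call. Features are computed on the normalized signals, consistent
with treating the normalized trace as the analysis object throughout.

## Severity labels

Subjects are dichotomized on the APACHE II score at 24: the classical
score-to-mortality bands (4, 8, 15, 25, 40, 55, 75, 85% for scores 0–4, 5–9,
…, >34) cross 50% predicted mortality between 24 and 25, which is the
rationale for the threshold. The band table ships as a CSV under
`inst/extdata/` so alternative tabulations can be swapped in. The package
never computes APACHE II from physiology; scores are inputs.

## Screening and classification

Feature screening uses two-sided independent-samples t-tests between the L
and H groups, **training rows only**, for all 69 features plus age and BMI.
The pooled-variance (Student) variant is the default — the plain reading of
"independent-samples t-test" — with Welch available by argument. Raw
p-values are reported without multiple-testing correction, matching the
descriptive use of the screen; results are sorted by p with lexicographic
tie-breaks for determinism. The two top-ranked significant NIRS features
feed a C-classification SVM with RBF kernel. Hyperparameters: C = 1 and the
variance-scaled default γ = 1/(n_features · var(X)); no reweighting for
class imbalance by default (inverse-frequency weights are available).
Evaluation reports train/test accuracy, the confusion matrix with the
high-severity class positive, and stratified 5-fold cross-validation on the
training split (mean ± sample SD of fold accuracies). Folds are stratified
rather than fully random so that no fold loses a class at n ≈ 30.

Two analysis choices deserve a caveat. First, screening happens once on the
fixed training split, not per CV fold; CV scores therefore share the
selection information and are mildly optimistic — they measure classifier
stability, not fully nested generalization. Second, with clinical fusion the
four columns (2 NIRS features, age, BMI) are standardized and projected onto
the top two principal components (signs fixed by making each loading's
largest-magnitude entry positive); the projection is fitted on training rows
and applied to test rows.

## The synthetic cohort generator

Real recordings of this kind are not shareable, so `simulate_cohort()`
provides the test bed. Each subject's Hb channel follows first-order
exponential transitions (τ = 30 s) toward per-stage plateau targets — the
simplest response shape that produces both plateau-like stage means and
informative stage slopes — plus a linear drift (0.05 units/hr), one
respiration sinusoid (frequency drawn from 0.15–0.4 Hz), one cardiac
sinusoid (0.4–1.6 Hz) and white noise (sd 0.05). TSI is synthesized as
65% + 5·(ΔHbO₂ − ΔHHb) + noise. Between-subject variability enters through
per-subject Gaussian jitter on the plateau targets (sd 0.08); this is the
parameter that turns group plateau contrasts into finite effect sizes.

The default plateau matrices encode the qualitative group contrasts expected
for each mode: in VV cohorts the high-severity group has a larger HbO₂
Stage3-minus-Stage2 mean difference and a larger HbT Stage2 mean; in VA
cohorts the low-severity group has a steeper HbO₂ Stage2 rise and the
high-severity group a larger HHb Stage5 mean. The magnitudes were set once so
that the designated features separate the groups by at least 2 pooled SDs
(measured: ≈2.6–4.8 SD at n = 60 per group), the regime in which the full
pipeline should recover the planted structure almost perfectly; with
`effect = "null"` both groups share plateaus and covariate distributions,
giving the chance-level negative control. Clinical covariates mirror the
expected directions (younger low-severity patients in VA, higher BMI in the
low-severity VV group); APACHE scores are drawn per group and clipped to
0–24 / 25–71, so labels are consistent by construction.

What the generator does **not** emulate: motion artifacts, broadband
colored noise, inter-probe redundancy (two probes per calf are collapsed
into one effective channel set), cannulation-side perfusion asymmetry, and
any real biophysics of microcirculation. Passing tests on synthetic cohorts
therefore demonstrate the pipeline's correctness and statistical behaviour,
not clinical performance on patients.

## Numerical and design choices

- Stage boundaries: round-half-to-even on duration × sampling rate; 0-based
  half-open index intervals, so segments tile the recording exactly.
- Determinism: every stochastic step (subject draws, splits, folds) flows
  through one seeded generator; per-subject seeds derive from the cohort
  seed by a fixed integer hash kept below 2³¹. Identical configs reproduce
  byte-identical artifacts.
- Degenerate inputs have declared policies: constant channels normalize to
  zeros (warning); zero variance in both t-test groups reports t = 0, p = 1
  (warning); an empty selection after screening is a warning from
  `select_top()` and an error in `fit_severity()` unless features are given.
- Problem sizes: the examples and tests simulate at 4–5 Hz rather than the
  instrument's 25 Hz — the protocol timeline, noise bands and effect sizes
  are unchanged, only sample density drops (all bands stay below Nyquist at
  4 Hz). Statistical suites use 60-subject groups for effect recovery and
  500 twelve-subject null cohorts for type-I calibration.

## Limitations

The headline accuracies quoted by clinical studies of this design come from
private patient cohorts and are not reproducible here; synthetic-cohort
accuracies characterize the pipeline, not patients. CV numbers inherit the
screening-before-CV optimism discussed above. The SVM hyperparameters are
deliberately fixed defaults; an inner grid search would change reported
scores and is left to the user.
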