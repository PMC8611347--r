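---
title: "Model-based trial-by-trial RSA of social threat learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based trial-by-trial RSA of social threat learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threatrsa)
```

## The paradigm and the question

`threatrsa` implements a model-based, trial-by-trial representational
similarity analysis (RSA) for a social threat-learning experiment. Two
interaction partners repeatedly choose one of two images on behalf of a
participant; one image (the CS+) is sometimes followed by an electric shock,
the other (the CS−) never is. One partner is believed to deliver shocks
intentionally, the other unintentionally, crossing partner intentionality
(2) with CS type (2). The scientific question is how neural activation
patterns for these four conditions form and differentiate as learning
unfolds, and whether that formation carries the threat value of an action,
the intentionality of the actor, or their integration.

The analysis asks this at the level of *pattern similarity over trials*:
if a region gradually forms a stable representation of, say, threat, then
the spatial activation patterns of later CS+ trials should correlate more
strongly with one another than early ones do. The unit of analysis is a
trial-by-trial representational similarity matrix (RSM), and hypotheses
enter as *template matrices* of the same shape that are regressed jointly
onto the RSM.

## Trial schedule

The threat-learning phase has 52 trials (26 per partner; per partner 13 CS+
and 13 CS−). Each trial shows the partner's face (early anticipation, 3 s),
the two options (choice, 1 s), and the selected image (chosen option, 3 s),
followed by a fixed 13 s inter-trial fixation, so consecutive onsets are
20 s apart. The long fixed ITI is a design feature, not a nuisance: with
single-trial estimates, temporal autocorrelation between nearby trials
masquerades as pattern similarity, and 20 s spacing suppresses it. Shocks
arrive 2.8 s after chosen-option onset on reinforced trials — per partner 6
of the 13 CS+ trials (46%).

Analysis is restricted to *target* trials: 7 per condition (28 in all),
none reinforced, in fixed positions, so that shock delivery never
contaminates the similarity structure. The remaining 24 trials are fillers,
and all reinforced trials are CS+ fillers. The published description of the
layout is loose ("alternating blocks of filler and target trials" with
same-condition targets equidistant), so the generator commits to one layout
that satisfies both constraints: 7 rounds of 4 targets (one per condition,
fixed order) separated by 6 filler blocks of 4 (one per condition, order
randomized by the seed). Same-condition targets are then exactly 8 trials
apart, which the test suite asserts for every seed. The extinction phase is
identical but entirely unreinforced.

Trial indices are 1-based everywhere, the natural convention in R; "trial
2" in a ramp description means the second target of a condition's block.

## From patterns to the RSM

Each trial's voxel pattern (a single-trial GLM beta, below) is z-scored
across voxels, and all pairwise Pearson correlations between target-trial
patterns form the 28 × 28 RSM, with rows grouped by condition and ordered
chronologically within condition. Whether the original analysis z-scored
across voxels within trial or across trials within voxel is not decidable
from its description; across-voxel scoring is the only reading that is
well-defined "for each trial", so it is the default (and Pearson
correlation makes the within-trial affine normalization immaterial, which
the tests assert). Only the lower triangle (378 pairs, diagonal excluded)
enters the regression, after the Fisher transform `atanh`. Perfect
correlations transform to ±Inf and are replaced by ±0.999 *after* the
transform — a deliberate reproduction of the published rule, quirky as it
is (|z| for r = 0.99 is 2.65, larger than the clamp). The replacement
preserves sign by default; a flag (`signed = FALSE`) reproduces a literal
unsigned replacement.

## Template matrices

Templates are symmetric matrices in [0, 1] with zero diagonal, on exactly
the RSM's trial ordering (one shared pair indexer, asserted in tests).
For the chosen-option period of threat learning there are five:

* **category** — 1 where two trials show the same CS image (4 blocks of 7);
* **intentionality** — 1 where both trials are the intentional partner's;
* **cs** — 1 where both trials are CS+ choices;
* **csplus_intentional / csplus_unintentional** — learning ramps rising
  linearly from 0 to 1 within one condition's 7-trial block.

For the early-anticipation period (face viewing) there are four: category
over the two faces, intentionality, and one rising ramp per partner's face
(14 trials each, chronologically ordered). The extinction chosen-option
period has three alternative hypothesis sets: *decay* (ramps fall 1 → 0
across all 7 trials), *resistance* (the CS+ intentional block stays at a
constant 1 while CS+ unintentional decays), and *relearning* (rising ramps
as in threat learning).

Two choices here were genuinely open:

* **Pair-position rule.** A ramp assigns a value to a *pair* of trials, but
  is described per trial. The default takes the ramp at the earlier trial's
  position (a pair is only as "learned" as its earlier member), linearly
  from 0 at the first eligible pair to 1 at the last; a mean-position
  variant is available (`pair_rule = "mean"`). Both hit the printed
  endpoints 0 and 1 exactly.
* **Ramp start.** Threat-phase ramps start at within-block trial 2,
  excluding the first encounter of each CS when the shock contingency was
  still unknown; extinction decay ramps start at trial 1 (decay acts on an
  already-formed representation). The relearning set mirrors the threat
  ramps, start included. The resistance set's stable block is a constant 1;
  a constant at the threat-end value would also be defensible but is not
  printed anywhere, so the simpler reading was chosen.

Template predictors are Fisher-transformed exactly like the data (so a
binary template's ones become 0.999), with a flag to disable the transform
for sensitivity analysis. `assemble_templates()` warns when any two
predictors correlate beyond a configurable threshold; in the default sets
the maximum absolute predictor correlation is about 0.32.

## The regression and group inference

Per subject and region, the similarity vector is modelled as

z(i,j) = β0 + Σn βn · templaten(i,j) + ε(i,j),

fit by OLS (default) with per-coefficient t statistics; a robust
M-estimator (`estimator = "robust"`) is available since heavy-tailed
similarity values do occur with few voxels. Group inference is a two-sided
one-sample t-test of each coefficient's per-subject estimates against zero,
with Cohen's d = mean/sd. All (ROI × coefficient) tests of one model form
the multiple-comparison family — the intercept is excluded — and are
corrected with Benjamini–Hochberg FDR at q = 0.05. With the default
12-region chosen-option registry (ACC, amygdala, insula, hippocampus,
vmPFC, left/right TPJ, dmPFC, anterior and posterior STS, IFG, ITG) and 5
templates, the family has 60 tests; the early-anticipation registry adds
the FFA and its family size follows the same rule rather than being forced
to 60.

## The consecutive-trial analysis

As a bridge to the simpler legacy approach, `consecutive_series()` extracts
the within-condition superdiagonal of the RSM — the six correlations
between consecutive target trials 1–2 … 6–7 — Fisher-transformed, and
`rm_anova_2x2()` runs a within-subject 2 (CS) × 2 (intentionality) ANOVA on
the per-condition means (each effect on 1, n−1 degrees of freedom; partial
η² = SS_effect / (SS_effect + SS_error); with two-level factors sphericity
is trivially satisfied). Averaging the six pair values per condition is the
default aggregation; whether the original analysis averaged or modelled
pair as a factor is not stated. FDR across ROIs is applied within each
effect family. Cells that are constant within every subject yield a 0/0
F-ratio; these are reported as F = 0 rather than NaN, with a
scale-relative floor distinguishing true degeneracy from small variance.

## Synthetic data and what recovery tests show

The generators exist so that every stage is testable by parameter recovery
against *known* ground truth.

**Patterns.** Effects are planted on the Fisher-z similarity scale — the
scale the regression operates on — so the recovery target is exact: target
z(i,j) = atanh(c0) + Σ w·Tz(i,j). The implied correlation matrix (tanh of
the target, unit diagonal) is factorized by eigendecomposition; patterns
are that shared component plus independent voxel noise with variance 1/snr,
and the construction inflates the shared part so the *expected* correlation
equals the target at any snr. Non-positive-semidefinite plantings are
rejected naming the offending weight. Realized RSMs deviate from the target
by sampling error of order 1/√n_voxels. Defaults (200 voxels, snr 1,
baseline between-trial correlation 0.1) are typical of a mid-sized fMRI
ROI with moderate pattern reliability.

**BOLD.** Each trial's pattern enters through its HRF-convolved boxcar (a
canonical double-gamma, peak ≈ 5 s, unit peak; the published pipeline
delegates the HRF to its analysis software, so the canonical form is this
package's substitution) plus white noise at TR = 2 s; an AR(1) flag exists
to demonstrate why the 20 s trial spacing matters. The single-trial GLM is
least-squares-all: one regressor per trial in one model, plus a shock (US)
regressor in the threat phase, optional nuisance and discrete-cosine drift
columns, and an intercept. Scanner drift and prewhitening are not
simulated, so the drift basis is off by default. With zero noise the GLM
recovers the generating patterns to machine precision, which is an
identifiability statement about the design, not a claim about real data.

**Pupil.** Traces at 250 Hz with an event-locked dilation kernel (peak
~1.2 s) at each chosen-option onset, amplitude noise, slow drift, and
Poisson blink gaps. The deblinking rule widens every missing segment by
100 ms on each side and fills it with the linear trend between the nearest
valid neighbours; boundary segments stay missing. Per trial, baseline is
the mean over the 500 ms before the event and the response is the peak over
the following 2.5 s minus baseline ("peak" is the maximum — dilation
indexes arousal — not the maximum absolute deviation). Trials with > 50%
missing samples are discarded and imputed from same-condition neighbours;
a participant with > 33% discarded trials in any condition is excluded.
The window for the 50% rule is the 2.5 s response window by default (the
analysis window; the published description does not pin this down), with a
whole-trial option.

What passing recovery tests *do* show: the pipeline's algebra is right,
planted effects on the modelling scale come back with the right sign and
magnitude, and the error-rate machinery (BH-FDR, paired tests) controls
what it claims under the simulated noise model. What they do *not* show:
robustness to spatially smooth noise, motion, physiological artefacts,
haemodynamic variability across regions, or template mis-specification on
real data — the generators deliberately contain none of these.

## Numerical choices and problem sizes

Fisher clamping at ±0.999, the PSD tolerance (−1e-8 on the smallest
eigenvalue before rejection, with negative eigenvalues clipped at 0 in the
factorization), the symmetry tolerance of `lower_triangle()` (1e-10), and
the ANOVA degeneracy floor (1e-12 of the total sum of squares) are the only
magic numbers; each is asserted or exercised in the tests. Simulation-based
test blocks use sizes chosen to make Monte-Carlo error small relative to
the property being checked while keeping the default suite fast: 500
replicates for error-rate checks (MC se ≈ 0.01 at α = 0.05), 100 for
detection-rate checks, cohorts of 8–26 subjects, and 24–200 voxels
depending on whether the check targets rates or magnitudes. The pupil
error-rate simulation runs on a compact 20-trial schedule at 25 Hz — the
paired-contrast error rate does not depend on trace length or trial count,
and the full-size generator is exercised elsewhere.

## Limitations

The package analyses synthetic or user-supplied pattern tables; it does not
perform spatial preprocessing, atlas mask extraction, or whole-brain
inference. The filler/target interleaving is one concrete realization of a
loosely described layout. The ramp parameterization is one of several
consistent with the published figures; both implemented variants are
exposed, and conclusions that depend on the difference should be treated
with caution.
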