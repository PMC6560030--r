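---
title: "Decoding distal future-state representations: models, simulation, and inference"
author: "futurestates package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding distal future-state representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(futurestates)
```

## The scientific question

During goal-directed learning, does the brain come to represent states of
the world it will only encounter tens of seconds in the future?  The
paradigm this package models is a set of Y-maze episodes: at the first room
(state 1) the learner makes a left/right choice, passes through an
intermediate room (state 2), reaches one of two alternative third rooms
(state 3) — each marked by a unique face, scene, or object picture — and
finally receives reward or loss feedback, roughly 40 s after the initial
choice.  Eight mazes of interest are each repeated four times (plus two
always-loss mazes used for balancing), and half of the first exposures are
rewarded regardless of the choice, which both fixes first-repetition
performance at 50% and defines the "correct" action for every later
repetition.

The analysis asks whether multivoxel patterns evoked at state-1 onset carry
information about the *category of the correct state-3 room* — a stimulus
roughly 30 s in the future that has only been seen on earlier repetitions —
and whether that information grows with learning.

## Analysis pipeline

1. **Single-event GLM (least-squares-all).**  Every event of every maze
   trial (states 1–3, feedback, rest; durations 5/4/5/5/12 s) gets its own
   HRF-convolved regressor, yielding 200 regressors of interest for the
   learning phase and 155 for the localizer, plus block intercepts and any
   nuisance columns.  Ordinary least squares on the non-smoothed series
   gives one beta pattern per event (`buildLsaDesign()`, `fitBetas()`).
2. **Pairwise classifiers.**  Linear support-vector machines (cost C = 1)
   are trained on localizer betas under a fixed pairing — faces vs scenes,
   scenes vs faces, objects vs faces — with class counts equalized within
   each localizer mini-block by seeded random discard (`trainPairwise()`).
3. **Cross-phase decision values.**  The trained classifiers are applied to
   every learning-phase event.  Raw margins are mapped to \[0, 1\] decision
   values through a logistic (Platt-style) calibration fit on the training
   margins; the mapping is monotone, so margins and values carry the same
   ordering (`decisionValues()`).  Training in one phase and testing in the
   other avoids the inference problems of cross-validated information
   measures.
4. **Decision-value regressions.**  Per category, state-1 decision values
   are regressed on: a binary *current state* indicator (the on-screen
   category matches the model's category), a binary *future state*
   indicator (the correct state-3 category matches), the
   *correct-repetition* covariate, and the two interactions.  The covariate
   counts experience with the correct distal room: 0 until the repetition
   after it was first reached, then +1 per repetition
   (`buildCorrectRep()`).  Coefficients are averaged across the categories
   that pass a cross-phase generalization check and tested against zero
   across participants (`aggregateAndInfer()`).  The critical quantity is
   the future-state × correct-repetition interaction: does future-state
   evidence strengthen with learning?
5. **Controls.**  Per-bin models (current and future effects separately in
   each covariate bin), reduced models dropping the current- or
   future-state terms, variants at states 2/3/feedback, and a sweep over
   additional ROIs with uncorrected p values (`perBinModels()`,
   `stateVariantModels()`, `roiSweep()`).
6. **Univariate models.**  A geometric encoding-decay modulator (1, 0.50,
   0.25, 0.125 across repetitions) captures the initially-high-then-
   decaying response profile of rapid-encoding regions, and reward vs loss
   is coded +1/−1 at feedback and optionally the following rest period
   (`univariateDecayModel()`, `rewardFeedbackModel()`).
7. **Connectivity.**  A simplified psychophysiological interaction on ROI
   timecourses: the interaction regressor is the product of the centered
   seed timecourse and the HRF-convolved psychological term — either a
   state boxcar or the late-vs-early learning contrast (repetitions 3–4
   minus 1–2, never-learned mazes omitted).  The group-level covariate for
   the learning PPI is each participant's future × repetition effect
   (`generalPpi()`, `learningPpi()`).

## Equivalence testing and power

Null results are handled with the two-one-sided-tests (TOST) procedure:
an effect is declared equivalent to zero when it is significantly inside
symmetric bounds of ±d.  `requiredN()` computes minimum sample sizes by
integer search on exact noncentral-t power (for d = 0.47, 80% power,
α = 0.05 it returns 38 two-tailed and 30 one-tailed).  For the bound that
gives a TOST 80% power at a given n, `tostBoundForPower()` offers two
conventions:

* `method = "nct"` (default) root-finds on exact noncentral-t TOST power
  (0.529 at n = 32; 0.557 at n = 29);
* `method = "z"` reproduces the z-approximation with a √(n−1) denominator
  used by common TOST power calculators (0.53 at n = 32; 0.55 at n = 29).

The two differ by less than 0.01 in d at these sample sizes; published
two-decimal bounds typically follow the second convention, which is why it
is kept available and documented.  A Monte-Carlo check in the test suite
confirms the exact bound attains its designed rejection rate.

```{r power}
requiredN(0.47, 0.80, 0.05, tails = 2)
round(tostBoundForPower(32, 0.80, 0.05), 3)
round(tostBoundForPower(29, 0.80, 0.05, method = "z"), 2)
```

## The synthetic-data generator

Because the real dataset is not required, every analysis is exercised on
synthetic data with known ground truth (`simulateCohort()`).

**Design.**  `generateDesign()` reproduces the printed task structure: 8
mazes of interest + 2 always-loss mazes, 4 repetitions, 40 trials in 4
blocks of 10, staged introduction (the first four mazes cycle through three
repetitions before the second set is interleaved), half of the first
exposures rewarded.  Inter-state intervals are drawn uniformly so the mean
state-1→state-3 interval is ≈31 s and the mean maze duration ≈48 s; the
exact jitter distributions of the modeled experiment are unreported, so
uniform jitter over plausible ranges is used, and only the means are treated
as design targets.  `generateLocalizer()` reproduces the 155-trial localizer
(120 category, 20 scrambled, 15 motion; probes after 25% of category
trials; scrambled trials flanking motion at mini-block ends).

**Behavior.**  A two-parameter observe-then-exploit rule: after the correct
distal room has been observed, the correct action is chosen with
probability 0.821, before that with 0.714 — the reported repetition-2
accuracies after initial reward and loss in the modeled paradigm, which
anchors the synthetic learning curve to the published one.  No generative
behavioral model accompanies the paradigm; this rule is the simplest one
consistent with its design constraints (repetition-1 outcomes forced, learning driven by
observing the correct terminal room).

**Patterns.**  Orthonormal category templates T (QR of a seeded Gaussian
matrix) guarantee that planted current- and future-state signals cannot
confound each other.  State-1 patterns are

    aCurrent * T(on-screen) + gFuture * r * T(correct state 3) + noise

with r the correct-repetition covariate; localizer patterns are
`aLocalizer * T(category) + noise`.  The future signal is planted linearly
in r to match the linear interaction the analysis fits; optional extra
parameters plant signals for the control analyses (state-2 future signal,
state-3 suppression, past-state signal at feedback).  `simulateBold()`
additionally pushes any planted amplitudes through the forward HRF model
(double-gamma, peak 6 s, undershoot 16 s, ratio 6, TR 1.24 s, 16 microtime
bins) so the single-event GLM can be validated by exact inversion.

**Default parameters.**  The defaults (V = 100 voxels, aCurrent =
aLocalizer = 1, noiseSd = 1, gFuture = 0.8) were fixed once, before the
test suite was finalized, to give a clearly recoverable planted world: a
group-level future × repetition effect of d ≈ 0.9 at n = 30, detected in
essentially every cohort replication, with cross-phase AUC values
(≈ 10 chance-relative points) and a mean interaction coefficient (≈ 0.10 on
the decision-value scale) in the same regime reported for data of this kind.
Empirically reported effects of this kind (d ≈ 0.47) are weaker than this
planted default; recovering an effect that small reliably would need far
larger cohorts, and the recovery suite is meant to validate the estimator
chain, not to re-estimate an empirical effect size.

**What the generator does not emulate.**  No spatial autocorrelation,
physiological noise, motion artifacts, scanner drift in the pattern-level
path, attentional fluctuations, or nonlinear BOLD effects.  Passing
recovery tests therefore shows the pipeline is correct and calibrated under
its own assumptions — not that the original neural effect is real, nor that
the pipeline is robust to every artifact of real fMRI data.

## Numerical and design choices

* **Estimation** is plain OLS everywhere; AR(1) prewhitening belongs to
  preprocessing realism that is out of scope.  A
  `prewhiten` hook on `fitBetas()` accepts any whitening transform.
* **Parametric modulators** are mean-centered (SPM convention); regression
  predictors in the decision-value models are left uncentered (0/1
  indicators, 0–3 counts) with a `center` option — centering changes
  main-effect interpretation, never the interaction.
* **Margin → value mapping.**  The bounded decision value is obtained by a
  Platt-style logistic calibration on training margins (with regularized
  targets so perfect separation stays finite).  Any strictly monotone map
  would give identical rank-based results; the regressions use the bounded
  values.
* **AUC scale.**  Cross-phase classification is summarized as
  (AUC − 0.5) × 100, the chance-relative scale on which single-digit values
  like "9.9" are reported; the raw AUC is always returned alongside.
* **Exclusions.**  A category is invalid for a participant when its
  decision values at states 1 and 3 (concatenated — "both" states jointly)
  are not positively related to the true on-screen contrast; participants
  with no valid category are excluded.  A category whose regression design
  is degenerate (e.g., a covariate that never leaves zero) is likewise
  flagged invalid rather than aborting the cohort.
* **Future-state definition.**  The future indicator refers to the correct
  arm's state-3 category — the room the learner would visit under the
  correct policy — regardless of the arm actually visited on error trials;
  the alternative covariate coding (`"correct_only"`) increments only after
  correct repetitions.
* **Always-loss mazes** are excluded from the decision-value regressions
  (they have no correct arm), but their events are modeled in the GLM.
* **No joint value + decay model** is offered: with fixed reward
  contingencies, choice value and the decay modulator are strongly
  collinear by design, so a joint fit is not identifiable in any useful
  sense.
* **PPI without deconvolution.**  The interaction term multiplies the
  measured seed timecourse with the convolved psychological term.  This is
  a simplification relative to deconvolution-based PPI; with TR = 1.24 s
  and long block-like states it changes little, but interaction estimates
  should be read as approximations.
* **Degenerate inputs** (zero-variance samples, constant correlation
  input, single-class AUC, missing event states) are flagged or raised as
  errors, never silently converted to infinite statistics.

## Problem sizes

The test suite and the orchestration layer run everything at desk scale,
chosen to exercise the full pipeline in minutes on a single core: cohorts
of 30 participants with 100 voxels per ROI for recovery studies (100
replications per world), 20 voxels for unit-level worlds, and 10,000
replicates for the TOST power cross-check.  `runPipeline("all", config)`
with the default configuration performs the complete simulate → univariate
→ decode → regress → PPI chain and writes hashed, reproducible artifacts;
`pipelineReport()` then prints the group tables, the per-bin breakdown, and
the qualitative checks (future effect present and growing; current ×
repetition equivalent to null in signal worlds; everything equivalent in
null worlds).

## Known limitations

* Because each classifier scores its target *against a fixed contrast
  category*, a growing future-state signal belonging to the contrast
  category leaks, with negative sign, into the current × repetition term of
  strong signal worlds (the future indicator of, say, the face model does
  not span a scene-category future).  This is a property of the pairwise
  cross-classification scheme itself, visible only when the planted future
  signal is large; in null worlds the current × repetition term is centered
  on zero, which is the contrast the equivalence claims rest on.
* The pattern-level simulator bypasses BOLD sampling for speed; the
  BOLD-level path is validated separately by exact GLM inversion.
* Group inference is by one-sample t tests on participant means, matching
  the modeled analysis; no hierarchical model is provided.
* The localizer's probe/confidence sub-task is represented only as timing
  overhead, and no images are rendered — category labels are the stimulus.
* TOST is implemented for the one-sample case only, which covers every use
  in this analysis (coefficients and paired differences).
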