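# futurestates

Decoding distal future-state representations from fMRI multivoxel patterns
during goal-directed learning.

## What this package is for

In multi-step learning tasks — here, Y-maze episodes in which a state-1
choice leads, ~30 s and two rooms later, to a category-marked terminal room
and delayed reward — a central question is whether patterns of brain
activity at the *start* of an episode come to encode the distal state the
learner will only see much later.  `futurestates` implements the complete
analysis chain for that question, for methodologists and cognitive
neuroscientists who want to run, audit, or extend it:

* single-event (least-squares-all, LSA) GLM estimation of one beta pattern
  per event, with the canonical double-gamma HRF at TR = 1.24 s;
* pairwise linear SVM classifiers (cost *C* = 1) trained on localizer
  patterns — faces vs scenes, scenes vs faces, objects vs faces — with
  mini-block balancing, applied *across phases* to learning-phase patterns
  to yield bounded decision values in [0, 1];
* the core inference: per-category regressions of state-1 decision values

      dv = β₀ + β₁·current + β₂·future + β₃·r + β₄·current·r + β₅·future·r + ε

  where `current`/`future` indicate whether the on-screen (state-1) or
  correct distal (state-3) category matches the model's category, and `r`
  counts repetitions since the correct distal room was first observed.
  β₅ — the future × correct-repetition interaction — is the signature of a
  learned predictive representation.  Coefficients are averaged over
  categories that pass a cross-phase generalization check and tested with
  one-sample t tests across participants;
* control analyses: per-repetition-bin models, reduced models, variants at
  states 2/3/feedback, multi-ROI sweeps, chance-relative AUC
  ((AUC − 0.5) × 100);
* equivalence and power: exact noncentral-t sample-size search
  (`requiredN`), one-sample TOST (`tostTest`), and TOST equivalence bounds
  at a target power (`tostBoundForPower`);
* a simplified ROI-timecourse PPI, including the learning PPI whose
  group covariate is each participant's β₅;
* a synthetic-data generator (design, behavior, voxel patterns, BOLD) with
  planted ground truth, so the whole pipeline is validated by parameter
  recovery; and an orchestration layer (`runPipeline`, `pipelineReport`)
  writing hash-stamped artifacts.

## Worked example

Simulate a 12-participant cohort with a planted future-state slope, decode,
and run the group inference:

```r
library(futurestates)

cohort <- simulateCohort(nParticipants = 12, seed = 7, nVoxels = 60)
fits <- lapply(seq_along(cohort), function(i) {
  p   <- cohort[[i]]
  cls <- trainPairwise(p$localizer, seed = i)
  dvt <- decisionValues(cls, p$learning)
  fitParticipantModels(dvt, p$design, p$behavior)
})
agg <- aggregateAndInfer(fits)
print(agg$group, digits = 2)
```

```
      predictor   mean ci_low ci_high     t df       p cohen_d  n flag
1       current  0.269  0.154  0.3842  5.16 11 0.00032    1.49 12
2        future -0.021 -0.123  0.0800 -0.47 11 0.65051   -0.13 12
3   correct_rep -0.036 -0.079  0.0080 -1.80 11 0.09989   -0.52 12
4 current_x_rep -0.069 -0.134 -0.0037 -2.33 11 0.04012   -0.67 12
5  future_x_rep  0.165  0.083  0.2456  4.47 11 0.00095    1.29 12
```

The on-screen category is decodable throughout (`current` > 0), and the
critical `future_x_rep` interaction is strongly positive: evidence for the
to-be-visited distal category grows with experience of it, which is exactly
the signal that was planted (`gFuture = 0.8`).  Cross-phase generalization
on the same cohort averages about 14 chance-relative AUC points.  In a null
world (`gFuture = 0`) the same code leaves `future_x_rep` centered on zero
and declares it TOST-equivalent at the n-matched bound.

Power/equivalence calculators reproduce their printed reference values:

```r
requiredN(0.47, 0.80, 0.05, tails = 2)   # 38
requiredN(0.47, 0.80, 0.05, tails = 1)   # 30
round(tostBoundForPower(32, 0.80, 0.05), 2)                # 0.53
round(tostBoundForPower(29, 0.80, 0.05, method = "z"), 2)  # 0.55
```

The end-to-end pipeline with artifacts on disk:

```r
cfg <- pipelineConfig(seed = 1, nParticipants = 12, nVoxels = 60)
runPipeline("all", cfg, outDir = "artifacts")
pipelineReport("artifacts")
```

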