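# Synthetic voxel patterns and BOLD with planted, known ground truth.
#
# Generative model for learning-phase state-1 patterns:
#   pattern = aCurrent * T(on-screen category)
#           + gFuture * r * T(correct state-3 category) + noise,
# where r is the correct-repetition counter (0 until the repetition after
# the correct distal room was first observed) and T() are orthonormal
# category templates.  Localizer patterns are aLocalizer * T(category) +
# noise.  Optional extra signals support the control analyses: a
# future-state slope at state 2, a learning-dependent change of the
# on-screen amplitude at state 3, and past-state templates at feedback.

#' Simulate localizer and learning-phase voxel patterns
#'
#' Returns event-aligned beta matrices (as if estimated by a single-event
#' GLM) for the localizer and the learning phase, with ground truth
#' retained for parameter-recovery tests.  The generator is linear in the
#' planted amplitudes: doubling `aCurrent` and `gFuture` doubles the
#' noiseless patterns.
#'
#' @param design a `"mazeDesign"` from [generateDesign()].
#' @param behavior behavior table from [simulateBehavior()].
#' @param truth a [SimTruth-class] object.
#' @param roi ROI label attached to both pattern sets.
#' @return list with elements `localizer` and `learning`, both
#'   [VoxelPatternSet-class] objects.
#' @examples
#' d <- generateDesign(seed = 1)
#' b <- simulateBehavior(d, seed = 1)
#' ps <- simulatePatterns(d, b, simTruth(nVoxels = 20, seed = 1))
#' ps$learning
#' @export
simulatePatterns <- function(design, behavior, truth, roi = "OFC-VMPFC") {
  stopIfNot(is(truth, "SimTruth"), "truth must be a SimTruth object")
  tm <- templates(truth)
  V <- nrow(tm)
  ex <- truth@extras
  set.seed(childSeed(truth@seed, 11))

  loc <- generateLocalizer(design$mazes, seed = childSeed(truth@seed, 12))
  locB <- matrix(rnorm(nrow(loc) * V, sd = truth@noiseSd), nrow(loc), V)
  isCat <- loc$category %in% colnames(tm)
  if (any(isCat))
    locB[isCat, ] <- locB[isCat, ] +
      truth@aLocalizer * t(tm[, loc$category[isCat], drop = FALSE])

  ev <- makeLearningEvents(design, behavior)
  cr <- buildCorrectRep(behavior, coding = "observed")
  ev$correct_rep <- cr$correct_rep[match(paste(ev$maze_id, ev$repetition),
                                         paste(cr$maze_id, cr$repetition))]
  evB <- matrix(rnorm(nrow(ev) * V, sd = truth@noiseSd), nrow(ev), V)
  addSig <- function(rows, cats, amp) {
    use <- rows & cats %in% colnames(tm) & amp != 0
    if (any(use))
      evB[use, ] <<- evB[use, ] + amp[use] * t(tm[, cats[use], drop = FALSE])
  }
  r <- ev$correct_rep
  addSig(ev$state == "S1", ev$onscreen_category,
         rep(truth@aCurrent, nrow(ev)))
  addSig(ev$state == "S1", ev$future_category, truth@gFuture * r)
  addSig(ev$state == "S2", ev$future_category,
         (ex$gFutureS2 %||% 0) * r)
  addSig(ev$state == "S3", ev$onscreen_category,
         truth@aCurrent + (ex$s3DecaySlope %||% 0) * r)
  addSig(ev$state == "FEEDBACK", ev$s1_category,
         rep(ex$pastFeedbackGain %||% 0, nrow(ev)))
  addSig(ev$state == "FEEDBACK", ev$visited_s3_category,
         rep(ex$pastFeedbackGain %||% 0, nrow(ev)))

  list(localizer = VoxelPatternSet(locB, loc, roi = roi, truth = truth),
       learning = VoxelPatternSet(evB, ev, roi = roi, truth = truth))
}

#' Simulate a BOLD time series from event amplitudes
#'
#' Forward model: each event's boxcar (at its modeled duration) is convolved
#' with the canonical double-gamma HRF and scaled by the event's voxel
#' amplitudes; drifts and Gaussian scanner noise are added on top.  Inverting
#' this series with [buildLsaDesign()] and [fitBetas()] recovers the planted
#' amplitudes exactly in the noiseless case.
#'
#' @param events data.frame with `onset` and `duration` columns (seconds),
#'   one row per event, all within a single run.
#' @param amplitudes events x voxels matrix of planted response amplitudes.
#' @param truth a [SimTruth-class] (supplies TR and HRF parameters).
#' @param nScans number of scans; defaults to cover the last event plus 20 s.
#' @param noiseSd scanner noise standard deviation (default 0).
#' @param drift optional time x voxels nuisance matrix (e.g. motion-like
#'   drifts) added to the series.
#' @return time x voxels matrix of simulated BOLD.
#' @export
simulateBold <- function(events, amplitudes, truth, nScans = NULL,
                         noiseSd = 0, drift = NULL) {
  amplitudes <- as.matrix(amplitudes)
  stopIfNot(nrow(amplitudes) == nrow(events),
            "one amplitude row per event is required")
  tr <- truth@tr
  if (is.null(nScans))
    nScans <- ceiling((max(events$onset + events$duration) + 20) / tr)
  X <- convolveEvents(events$onset, events$duration, nScans, tr,
                      hrfParams = truth@hrfParams)
  Y <- X %*% amplitudes
  if (!is.null(drift)) {
    drift <- as.matrix(drift)
    stopIfNot(all(dim(drift) == dim(Y)), "drift must be time x voxels")
    Y <- Y + drift
  }
  if (noiseSd > 0) {
    set.seed(childSeed(truth@seed, 13))
    Y <- Y + matrix(rnorm(length(Y), sd = noiseSd), nrow(Y), ncol(Y))
  }
  Y
}

#' Simulate a cohort of participants
#'
#' Generates, per participant, a maze design, behavior, and localizer plus
#' learning-phase pattern sets under a shared set of generative parameters,
#' with all randomness derived from one master seed.
#'
#' @param nParticipants cohort size.
#' @param seed master seed; per-participant seeds are derived from it.
#' @param nVoxels,aCurrent,aLocalizer,gFuture,noiseSd,... forwarded to
#'   [simTruth()].
#' @param pLearnAfterReward,pLearnAfterLoss forwarded to
#'   [simulateBehavior()].
#' @param roi ROI label.
#' @return list of participants, each a list with `design`, `behavior`,
#'   `localizer`, `learning`, and `truth`.
#' @export
simulateCohort <- function(nParticipants = 30, seed = 1, nVoxels = 100,
                           aCurrent = 1, aLocalizer = 1, gFuture = 0.8,
                           noiseSd = 1, pLearnAfterReward = 0.821,
                           pLearnAfterLoss = 0.714, roi = "OFC-VMPFC", ...) {
  lapply(seq_len(nParticipants), function(p) {
    ps <- childSeed(seed, 100 + p)
    d <- generateDesign(seed = ps)
    b <- simulateBehavior(d, pLearnAfterReward, pLearnAfterLoss, seed = ps)
    truth <- simTruth(nVoxels = nVoxels, aCurrent = aCurrent,
                      aLocalizer = aLocalizer, gFuture = gFuture,
                      noiseSd = noiseSd, seed = ps, ...)
    c(list(design = d, behavior = b, truth = truth),
      simulatePatterns(d, b, truth, roi = roi))
  })
}
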