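# Design-matrix construction and beta estimation: single-event (LSA)
# betas for multivariate analysis, and condition-level univariate models
# with the decaying-encoding modulator and the reward/loss contrast.

#' Geometric encoding-decay modulator
#'
#' Parametric modulator capturing an initially high and then exponentially
#' decreasing response across maze repetitions: a geometric decay of 50%
#' per repetition, i.e. values 1, 0.50, 0.25, 0.125 for repetitions 1-4.
#'
#' @param repetition integer repetition number(s), 1-based.
#' @return numeric vector `0.5^(repetition - 1)`.
#' @examples
#' decayModulator(1:4)   # 1.000 0.500 0.250 0.125
#' @export
decayModulator <- function(repetition = 1:4) 0.5^(repetition - 1)

#' Build a least-squares-all (LSA) design matrix
#'
#' One convolved regressor per event (at the modeled state durations), so
#' every event gets its own beta pattern.  Block intercepts (one per
#' concatenated run) and any nuisance columns (e.g. six motion parameters)
#' are appended as regressors of no interest.  For the default learning
#' phase this yields 200 regressors of interest (40 trials x 5 states);
#' for a full localizer run, 155.
#'
#' @param events data.frame with `onset` and `duration` (seconds) and
#'   optionally `block`; onsets are interpreted within the concatenated
#'   run unless `block` splits them.
#' @param nScans total number of scans (per block if `block` is present,
#'   in which case a vector).
#' @param tr repetition time in seconds.
#' @param nuisance optional time x k nuisance matrix.
#' @param hrfParams double-gamma HRF parameters.
#' @return list of class `"lsaDesign"`: `X` (time x regressors), `labels`,
#'   `interest` (column indices of the event regressors), `events`.
#' @export
buildLsaDesign <- function(events, nScans, tr = 1.24, nuisance = NULL,
                           hrfParams = c(peak = 6, undershoot = 16,
                                         ratio = 6)) {
  events <- as.data.frame(events)
  blocks <- if ("block" %in% names(events)) events$block else
    rep(1L, nrow(events))
  ub <- sort(unique(blocks))
  if (!length(ub)) ub <- 1L  # empty event list: nuisance-only matrix
  if (length(nScans) == 1) nScans <- rep(nScans, length(ub))
  stopIfNot(length(nScans) == length(ub),
            "need one nScans per block (or a single value)")
  nT <- sum(nScans)
  X <- matrix(0, nT, nrow(events))
  off <- 0L
  blockCols <- matrix(0, nT, length(ub))
  for (i in seq_along(ub)) {
    idx <- which(blocks == ub[i])
    rows <- off + seq_len(nScans[i])
    if (length(idx))
      X[rows, idx] <- convolveEvents(events$onset[idx], events$duration[idx],
                                     nScans[i], tr, hrfParams = hrfParams)
    blockCols[rows, i] <- 1
    off <- off + nScans[i]
  }
  labels <- if (!is.null(events$label)) as.character(events$label) else
    sprintf("ev%03d", seq_len(nrow(events)))
  Xfull <- X
  nuisLab <- character(0)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopIfNot(nrow(nuisance) == nT, "nuisance rows must match total scans")
    Xfull <- cbind(Xfull, nuisance)
    nuisLab <- sprintf("nuisance%02d", seq_len(ncol(nuisance)))
  }
  Xfull <- cbind(Xfull, blockCols)
  colnames(Xfull) <- c(labels, nuisLab,
                       sprintf("block%02d", seq_along(ub)))
  structure(list(X = Xfull, labels = labels,
                 interest = seq_len(nrow(events)), events = events,
                 tr = tr, nScans = nScans),
            class = "lsaDesign")
}

#' Estimate single-event betas by ordinary least squares
#'
#' Mass-univariate OLS of the (non-smoothed) BOLD series on an LSA design;
#' one beta per event per voxel.  Estimation is plain OLS; an optional
#' `prewhiten` hook accepts a function applied to both sides of the model
#' before fitting (AR(1) prewhitening belongs to preprocessing
#' realism and is intentionally not reimplemented).
#'
#' @param bold time x voxels matrix.
#' @param design an `"lsaDesign"` from [buildLsaDesign()].
#' @param roi ROI label for the returned pattern set.
#' @param truth optional [SimTruth-class] carried through.
#' @param prewhiten optional function `(matrix) -> matrix` applied to the
#'   BOLD and design columns.
#' @return a [VoxelPatternSet-class] of the event (interest) betas with the
#'   event metadata attached.
#' @export
fitBetas <- function(bold, design, roi = "ROI", truth = NULL,
                     prewhiten = NULL) {
  stopIfNot(inherits(design, "lsaDesign"), "design must be an lsaDesign")
  bold <- as.matrix(bold)
  X <- design$X
  stopIfNot(nrow(bold) == nrow(X), "design rows must match time points")
  if (!is.null(prewhiten)) {
    bold <- prewhiten(bold)
    X <- prewhiten(X)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  B <- qr.coef(qx, bold)
  VoxelPatternSet(B[design$interest, , drop = FALSE], design$events,
                  roi = roi, truth = truth)
}

# per-participant parametric-modulator effect on a univariate ROI response
modulatorEffect <- function(amp, modulator, center = TRUE) {
  m <- if (center) modulator - mean(modulator) else modulator
  if (sd(m) == 0) return(NA_real_)
  unname(coef(lm(amp ~ m))[2])
}

#' Decaying-encoding model of the univariate ROI response
#'
#' Regresses the mean ROI amplitude of each state-1 (optionally state-2/3)
#' event on the geometric decay modulator (mean-centered, SPM convention),
#' per participant, and tests the modulator effect at the group level.
#' A region whose response is initially high and then decays across
#' repetitions yields a positive effect.
#'
#' @param patternSets list of [VoxelPatternSet-class] objects (one per
#'   participant) holding learning-phase event betas.
#' @param state which state's events to model (default `"S1"`).
#' @return list with `perParticipant` effects and a `group` one-sample t
#'   row ([groupTTest] format).  Mazes lacking all four repetitions are
#'   dropped with a message.
#' @export
univariateDecayModel <- function(patternSets, state = "S1") {
  eff <- vapply(patternSets, function(vps) {
    ev <- eventData(vps)
    amp <- rowMeans(betas(vps))
    use <- ev$state == state
    ev <- ev[use, ]; amp <- amp[use]
    full <- names(which(table(ev$maze_id) == 4))
    if (length(full) < length(unique(ev$maze_id)))
      message("dropping maze(s) without all four repetitions")
    keep <- ev$maze_id %in% full
    stopIfNot(any(keep), "no maze with four repetitions at this state")
    modulatorEffect(amp[keep], decayModulator(ev$repetition[keep]))
  }, numeric(1))
  list(perParticipant = eff, group = groupTTest(eff))
}

#' Reward-versus-loss feedback model
#'
#' Parametric effect of feedback valence on the univariate ROI response at
#' the feedback state (and, optionally, the subsequent rest period), with
#' reward and loss coded +1 and -1.
#'
#' @param patternSets list of [VoxelPatternSet-class] objects.
#' @param includeRest also estimate the effect at the rest-period events.
#' @return list with `perParticipant` (matrix participants x states) and
#'   `group` rows per modeled state.
#' @export
rewardFeedbackModel <- function(patternSets, includeRest = FALSE) {
  states <- c("FEEDBACK", if (includeRest) "REST")
  eff <- t(vapply(patternSets, function(vps) {
    ev <- eventData(vps)
    amp <- rowMeans(betas(vps))
    vapply(states, function(st) {
      use <- ev$state == st & ev$outcome %in% c("reward", "loss")
      stopIfNot(length(unique(ev$outcome[use])) == 2,
                "both reward and loss outcomes are required")
      x <- ifelse(ev$outcome[use] == "reward", 1, -1)
      modulatorEffect(amp[use], x)
    }, numeric(1))
  }, numeric(length(states))))
  if (length(states) == 1) eff <- matrix(eff, ncol = 1,
                                         dimnames = list(NULL, states))
  group <- do.call(rbind, lapply(states, function(st)
    cbind(data.frame(state = st), groupTTest(eff[, st]))))
  list(perParticipant = eff, group = group)
}
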