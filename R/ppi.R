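# Simplified ROI-timecourse psychophysiological interaction (PPI).
#
# No BOLD deconvolution is attempted: the psychological term (a state
# boxcar or a late-versus-early learning contrast) is convolved with the
# canonical HRF and multiplied element-wise with the centered, measured
# seed timecourse.  This is a stated simplification relative to
# deconvolution-based PPI formulations.

buildPsych <- function(events, weights, nScans, tr, hrfParams) {
  keep <- weights != 0
  stopIfNot(any(keep), "psychological term has no events")
  X <- convolveEvents(events$onset[keep], events$duration[keep], nScans, tr,
                      hrfParams = hrfParams)
  drop(X %*% weights[keep])
}

#' General PPI at one maze state
#'
#' Regression of a target ROI timecourse on the seed timecourse
#' (physiological term), the HRF-convolved state boxcar (psychological
#' term), and their product (interaction), plus optional nuisance columns.
#' Both main-effect terms are mean-centered before the product is formed,
#' so the interaction coefficient is invariant to affine rescaling of the
#' seed.
#'
#' @param seedTc,targetTc equal-length ROI timecourses (one run).
#' @param events event table with `onset`, `duration`, `state`.
#' @param state which state's events form the psychological term
#'   (`"S1"`, `"FEEDBACK"`, or `"REST"` in the primary use).
#' @param tr repetition time (s).
#' @param nuisance optional time x k matrix.
#' @param hrfParams double-gamma HRF parameters.
#' @return one-row data.frame: interaction `estimate`, `t`, `p`, `df`.
#' @export
generalPpi <- function(seedTc, targetTc, events, state, tr = 1.24,
                       nuisance = NULL,
                       hrfParams = c(peak = 6, undershoot = 16, ratio = 6)) {
  stopIfNot(length(seedTc) == length(targetTc),
            "seed and target timecourses must have equal length")
  use <- events$state == state
  stopIfNot(any(use), paste("no events at state", state))
  psy <- buildPsych(events[use, ], rep(1, sum(use)), length(seedTc), tr,
                    hrfParams)
  if (sd(psy) == 0) stop("psychological regressor has zero variance")
  ppiFit(seedTc, targetTc, psy, nuisance)
}

ppiFit <- function(seedTc, targetTc, psy, nuisance = NULL) {
  phys <- seedTc - mean(seedTc)
  psy <- psy - mean(psy)
  inter <- phys * psy
  X <- cbind(phys = phys, psy = psy, inter = inter)
  if (!is.null(nuisance)) X <- cbind(X, as.matrix(nuisance))
  fit <- lm(targetTc ~ X)
  sm <- summary(fit)$coefficients
  row <- grep("inter$", rownames(sm))
  data.frame(estimate = sm[row, 1], t = sm[row, 3], p = sm[row, 4],
             df = fit$df.residual)
}

#' Min-statistic conjunction over PPI states
#'
#' @param results list of [generalPpi()] rows (e.g. S1, FEEDBACK, REST).
#' @return one-row data.frame with the minimum interaction t statistic and
#'   the corresponding (largest) p value.
#' @export
ppiConjunction <- function(results) {
  t <- vapply(results, function(r) r$t, numeric(1))
  p <- vapply(results, function(r) r$p, numeric(1))
  data.frame(t_conjunction = min(t), p_conjunction = max(p))
}

#' Learning PPI with an individual-differences covariate
#'
#' Per participant, the psychological term is the late-versus-early
#' learning contrast at the given state: repetitions 3-4 weighted +1 and
#' repetitions 1-2 weighted -1 (the "repetitions 2 and 3 versus 0 and 1"
#' contrast in 0-indexed terms), restricted to mazes where above-chance
#' performance was achieved (at least 2 of 3 post-first repetitions
#' correct) when `dropUnlearned` is TRUE.  The per-participant interaction
#' coefficients are tested at the group level and correlated (Pearson)
#' with the supplied covariate — typically each participant's
#' future-by-correct-repetition decision-value effect.
#'
#' @param participants list; each element needs `seedTc`, `targetTc`,
#'   `events` (learning events for the same run), and `behavior`.
#' @param covariate numeric vector, one value per participant.
#' @param state maze state for the contrast (default `"S1"`; `"S2"`,
#'   `"S3"`, `"FEEDBACK"` give the control variants).
#' @param dropUnlearned omit never-learned mazes from the contrast.
#' @param tr repetition time (s).
#' @param hrfParams double-gamma HRF parameters.
#' @return list: `perParticipant` interaction coefficients, `group` t-test
#'   row, and `covariateCorrelation` from [correlate()].
#' @export
learningPpi <- function(participants, covariate, state = "S1",
                        dropUnlearned = TRUE, tr = 1.24,
                        hrfParams = c(peak = 6, undershoot = 16, ratio = 6)) {
  stopIfNot(length(participants) >= 3, "need at least 3 participants")
  stopIfNot(length(covariate) == length(participants),
            "one covariate value per participant is required")
  eff <- vapply(participants, function(p) {
    ev <- p$events
    use <- ev$state == state & ev$of_interest
    evS <- ev[use, ]
    learned <- vapply(split(p$behavior, p$behavior$maze_id), function(b)
      isTRUE(sum(b$correct[b$repetition >= 2], na.rm = TRUE) >= 2),
      logical(1))
    if (dropUnlearned) {
      ok <- evS$maze_id %in% as.integer(names(learned)[learned])
      stopIfNot(any(ok), "no learned maze available for the contrast")
      evS <- evS[ok, ]
    }
    w <- ifelse(evS$repetition >= 3, 1, -1)
    if (length(unique(w)) < 2)
      stop("late-vs-early contrast is degenerate for a participant")
    psy <- buildPsych(evS, w, length(p$seedTc), tr, hrfParams)
    ppiFit(p$seedTc, p$targetTc, psy)$estimate
  }, numeric(1))
  list(perParticipant = eff, group = groupTTest(eff),
       covariateCorrelation = correlate(eff, covariate))
}
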