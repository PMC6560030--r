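# Core inference: regressions of state-1 decision values on current-state,
# future-state, and correct-repetition predictors; category aggregation;
# group inference; and the control models (per-bin, reduced, other states,
# multi-ROI sweep).

DV_PREDICTORS <- c("current", "future", "correct_rep",
                   "current_x_rep", "future_x_rep")

#' Correct-repetition covariate
#'
#' Per maze, the count of experience with the correct distal (state-3)
#' room.  Under the primary `"observed"` coding the value is 0 on the first
#' repetition and stays 0 until the repetition *after* the correct state-3
#' room was first reached, then increments by 1 on every subsequent
#' repetition (regardless of later choices).  The alternative
#' `"correct_only"` coding increments only following correct repetitions.
#'
#' @param behavior behavior table from [simulateBehavior()] (needs
#'   `maze_id`, `repetition`, `reached_correct_s3`).
#' @param coding `"observed"` (primary) or `"correct_only"`.
#' @return data.frame `maze_id`, `repetition`, `correct_rep` (0-3).
#' @examples
#' b <- data.frame(maze_id = 1, repetition = 1:4,
#'                 reached_correct_s3 = c(TRUE, TRUE, TRUE, TRUE))
#' buildCorrectRep(b)$correct_rep          # 0 1 2 3
#' b$reached_correct_s3 <- c(FALSE, FALSE, TRUE, TRUE)
#' buildCorrectRep(b)$correct_rep          # 0 0 0 1
#' @export
buildCorrectRep <- function(behavior, coding = c("observed", "correct_only")) {
  coding <- match.arg(coding)
  out <- lapply(split(behavior, behavior$maze_id), function(b) {
    b <- b[order(b$repetition), ]
    stopIfNot(all(b$repetition == seq_len(nrow(b))),
              "each maze needs consecutive repetitions starting at 1")
    reached <- b$reached_correct_s3
    cr <- if (coding == "observed") {
      j <- match(TRUE, reached)
      if (is.na(j)) rep(0L, nrow(b)) else pmax(0L, b$repetition - j)
    } else {
      cumsum(c(0L, reached[-nrow(b)]))
    }
    data.frame(maze_id = b$maze_id, repetition = b$repetition,
               correct_rep = as.integer(cr))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build the state-1 predictor design for one category model
#'
#' Binary current- and future-state indicators (1 when the state-1, resp.
#' correct state-3, category of the event's maze matches the model's
#' target category), the correct-repetition covariate, and the two
#' element-wise interaction columns.  Predictors are left uncentered (0/1
#' indicators and 0-3 counts); a centered variant is available since only
#' main-effect interpretation, not the interaction, depends on it.
#'
#' @param events state-1 event records (rows of a learning event table
#'   with `state == "S1"`).
#' @param mazes maze specification data.frame.
#' @param covariate output of [buildCorrectRep()].
#' @param targetCategory the model's category of interest.
#' @param center mean-center the columns before forming interactions.
#' @return data.frame with columns `current`, `future`, `correct_rep`,
#'   `current_x_rep`, `future_x_rep`; attribute `"reducedRank"` is TRUE
#'   when the covariate has no variance (interactions vanish).
#' @export
buildState1Predictors <- function(events, mazes, covariate, targetCategory,
                                  center = FALSE) {
  mix <- match(events$maze_id, mazes$maze_id)
  stopIfNot(!anyNA(mix), "event references an unknown maze")
  cr <- covariate$correct_rep[match(paste(events$maze_id, events$repetition),
                                    paste(covariate$maze_id,
                                          covariate$repetition))]
  stopIfNot(!anyNA(cr), "covariate does not cover all events")
  cur <- as.numeric(mazes$s1_category[mix] == targetCategory)
  fut <- as.numeric(mazes$s3_correct_category[mix] == targetCategory)
  if (center) {
    cur <- cur - mean(cur); fut <- fut - mean(fut); cr <- cr - mean(cr)
  }
  X <- data.frame(current = cur, future = fut, correct_rep = cr,
                  current_x_rep = cur * cr, future_x_rep = fut * cr)
  attr(X, "reducedRank") <- sd(cr) == 0
  X
}

#' Fit one category's decision-value regression
#'
#' Ordinary least squares of the category's state-1 decision values on the
#' five predictors (with intercept).  Coefficients are exactly the
#' normal-equations solution.
#'
#' @param values numeric vector of decision values for the target category
#'   at the state-1 events (same order as the predictor rows).
#' @param predictors design from [buildState1Predictors()] (or a reduced
#'   version of it).
#' @return one-row data.frame of coefficients plus `sigma` (residual SD)
#'   and `n`.
#' @export
fitDecisionRegression <- function(values, predictors) {
  X <- as.matrix(predictors)
  stopIfNot(length(values) == nrow(X),
            "one decision value per predictor row is required")
  stopIfNot(nrow(X) >= ncol(X) + 1 && nrow(X) >= 6,
            "too few observations for the regression")
  Xi <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xi)
  if (qx$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qx$pivot[(qx$rank + 1):ncol(Xi)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  cf <- qr.coef(qx, values)
  res <- values - drop(Xi %*% cf)
  out <- as.data.frame(as.list(cf[-1]))
  names(out) <- colnames(X)
  out$intercept <- unname(cf[1])
  out$sigma <- sqrt(sum(res^2) / (nrow(X) - ncol(Xi)))
  out$n <- nrow(X)
  out
}

#' Fit the three category models for one participant
#'
#' Builds the correct-repetition covariate from behavior, restricts to
#' state-1 events of the mazes of interest (always-loss mazes are
#' excluded), fits one regression per category on that category's decision
#' values, and attaches the cross-phase validity flags from
#' [exclusionCheck()].
#'
#' @param dvt a [DecisionValueTable-class] for the learning phase.
#' @param design the participant's `"mazeDesign"`.
#' @param behavior the participant's behavior table.
#' @param coding covariate coding, see [buildCorrectRep()].
#' @param drop optionally drop the `"current"` or `"future"` terms (main
#'   effect and interaction) to obtain the reduced control models.
#' @param center mean-center predictors (default FALSE).
#' @return list: `fits` (category x coefficient data.frame), `valid`
#'   (named logical), `include` (participant-level inclusion).
#' @export
fitParticipantModels <- function(dvt, design, behavior,
                                 coding = c("observed", "correct_only"),
                                 drop = NULL, center = FALSE) {
  coding <- match.arg(coding)
  if (!is.null(drop)) {
    drop <- match.arg(drop, c("current", "future"))
  }
  cov <- buildCorrectRep(behavior, coding)
  ev <- dvEvents(dvt)
  use <- ev$state == "S1" & ev$of_interest
  vals <- decisionValueMatrix(dvt)
  excl <- exclusionCheck(dvt)
  fitOK <- setNames(rep(TRUE, length(PAIR_SCHEME)), names(PAIR_SCHEME))
  fits <- lapply(names(PAIR_SCHEME), function(target) {
    X <- buildState1Predictors(ev[use, ], design$mazes, cov, target,
                               center = center)
    if (!is.null(drop))
      X <- X[, setdiff(names(X), paste0(drop, c("", "_x_rep"))), drop = FALSE]
    fit <- tryCatch(fitDecisionRegression(vals[use, target], X),
                    error = function(e) {
                      # degenerate design for this category (e.g. the
                      # covariate never varies): flag instead of aborting
                      fitOK[target] <<- FALSE
                      out <- as.data.frame(as.list(
                        setNames(rep(NA_real_, ncol(X)), names(X))))
                      out$intercept <- NA_real_
                      out$sigma <- NA_real_
                      out$n <- nrow(X)
                      out
                    })
    cbind(data.frame(category = target), fit)
  })
  fits <- do.call(rbind, fits)
  valid <- setNames(excl$categories$valid, excl$categories$category) & fitOK
  list(fits = fits, valid = valid, include = excl$includeParticipant)
}

#' Aggregate category fits and run group inference
#'
#' Within participant, coefficients are averaged across the valid
#' categories only; participants with no valid category are dropped (with
#' a message).  Each predictor's participant-level means are then tested
#' against zero with a one-sample two-sided t test, reported with Cohen's
#' d.  Zero-variance samples are flagged instead of yielding an infinite
#' statistic.
#'
#' @param participantFits list of results from [fitParticipantModels()].
#' @param predictors which coefficients to test (defaults to all five).
#' @return list: `group` (one row per predictor), `participantMeans`
#'   (participants x predictors matrix), `nDropped`.
#' @export
aggregateAndInfer <- function(participantFits, predictors = NULL) {
  stopIfNot(length(participantFits) >= 3, "need at least 3 participants")
  predictors <- predictors %||%
    intersect(DV_PREDICTORS, names(participantFits[[1]]$fits))
  means <- do.call(rbind, lapply(participantFits, function(pf) {
    v <- pf$valid[pf$fits$category]
    if (!any(v)) return(rep(NA_real_, length(predictors)))
    colMeans(pf$fits[v, predictors, drop = FALSE])
  }))
  colnames(means) <- predictors
  dropped <- !complete.cases(means)
  if (any(dropped))
    message(sum(dropped), " participant(s) with no valid category dropped")
  means <- means[!dropped, , drop = FALSE]
  stopIfNot(nrow(means) >= 3, "fewer than 3 participants remain")
  group <- do.call(rbind, lapply(predictors, function(p)
    cbind(data.frame(predictor = p), groupTTest(means[, p]))))
  list(group = group, participantMeans = means, nDropped = sum(dropped))
}

#' Per-correct-repetition-bin control models
#'
#' For each correct-repetition bin (0-3) separately, regresses the state-1
#' decision values on current- and future-state indicators only, averaging
#' coefficients across valid categories.  This gives the learning-curve
#' breakdown of how current and future state information evolve, without
#' an interaction term.  Empty bins are skipped with a message.
#'
#' @inheritParams fitParticipantModels
#' @param bins bins to fit (default 0:3).
#' @return data.frame: one row per bin with averaged `current` and
#'   `future` coefficients and the bin's event count.
#' @export
perBinModels <- function(dvt, design, behavior,
                         coding = c("observed", "correct_only"),
                         bins = 0:3) {
  coding <- match.arg(coding)
  cov <- buildCorrectRep(behavior, coding)
  ev <- dvEvents(dvt)
  use <- ev$state == "S1" & ev$of_interest
  vals <- decisionValueMatrix(dvt)
  excl <- exclusionCheck(dvt)
  valid <- setNames(excl$categories$valid, excl$categories$category)
  evS1 <- ev[use, ]
  crv <- cov$correct_rep[match(paste(evS1$maze_id, evS1$repetition),
                               paste(cov$maze_id, cov$repetition))]
  out <- lapply(bins, function(b) {
    res <- sapply(names(PAIR_SCHEME), function(target) {
      X <- buildState1Predictors(evS1, design$mazes, cov, target)
      inBin <- X$correct_rep == b
      if (sum(inBin) < 3 ||
          sd(X$current[inBin]) == 0 || sd(X$future[inBin]) == 0)
        return(c(current = NA_real_, future = NA_real_))
      cf <- coef(lm(vals[use, target][inBin] ~ current + future,
                    data = X[inBin, ]))
      c(current = unname(cf["current"]), future = unname(cf["future"]))
    })
    v <- valid[colnames(res)] & !is.na(res["current", ]) &
      !is.na(res["future", ])
    if (!any(v)) {
      message("bin ", b, " empty or degenerate; skipped")
      return(NULL)
    }
    data.frame(bin = b, current = mean(res["current", v]),
               future = mean(res["future", v]),
               n_events = sum(crv == b), n_categories = sum(v))
  })
  do.call(rbind, out)
}

#' Control models at later maze states
#'
#' Variants of the decision-value regression at states without (state 2)
#' or with different (state 3, feedback) on-screen information:
#' \describe{
#'   \item{S2}{future-state indicator, correct repetition, and their
#'     interaction (no stimulus is on screen).}
#'   \item{S3}{current (visited state-3) indicator, correct repetition,
#'     their interaction, plus past-state (state-1 category) main effect
#'     and interaction.}
#'   \item{FEEDBACK}{past-state terms only: state-1 category indicator,
#'     correct repetition, and their interaction.}
#' }
#'
#' @inheritParams fitParticipantModels
#' @param state `"S2"`, `"S3"`, or `"FEEDBACK"`.
#' @return list as [fitParticipantModels()]: per-category fits, validity,
#'   inclusion.
#' @export
stateVariantModels <- function(dvt, design, behavior,
                               state = c("S2", "S3", "FEEDBACK"),
                               coding = c("observed", "correct_only")) {
  state <- match.arg(state)
  coding <- match.arg(coding)
  cov <- buildCorrectRep(behavior, coding)
  ev <- dvEvents(dvt)
  use <- ev$state == state & ev$of_interest
  stopIfNot(any(use), paste("no events at state", state))
  vals <- decisionValueMatrix(dvt)
  excl <- exclusionCheck(dvt)
  evS <- ev[use, ]
  mix <- match(evS$maze_id, design$mazes$maze_id)
  cr <- cov$correct_rep[match(paste(evS$maze_id, evS$repetition),
                              paste(cov$maze_id, cov$repetition))]
  fits <- lapply(names(PAIR_SCHEME), function(target) {
    past <- as.numeric(design$mazes$s1_category[mix] == target)
    X <- switch(state,
      S2 = data.frame(
        future = as.numeric(design$mazes$s3_correct_category[mix] == target),
        correct_rep = cr),
      S3 = data.frame(
        current = as.numeric(evS$onscreen_category == target),
        correct_rep = cr, past = past),
      FEEDBACK = data.frame(correct_rep = cr, past = past))
    if (!is.null(X$future)) X$future_x_rep <- X$future * cr
    if (!is.null(X$current)) X$current_x_rep <- X$current * cr
    X$past_x_rep <- if (!is.null(X$past)) X$past * cr else NULL
    cbind(data.frame(category = target),
          fitDecisionRegression(vals[use, target], X))
  })
  list(fits = do.call(rbind, fits),
       valid = setNames(excl$categories$valid, excl$categories$category),
       include = excl$includeParticipant)
}

#' Future-by-repetition effect across multiple ROIs
#'
#' Runs the full decode-and-regress pipeline per ROI and reports the group
#' future x correct-repetition effect for each, with uncorrected p values
#' (no multiple-comparison correction is applied, matching how exploratory
#' region sweeps are usually reported) and the count of nominally
#' significant regions.
#'
#' @param cohortByRoi named list: for each ROI, a list of participants,
#'   each with `design`, `behavior`, `localizer`, `learning` (as produced
#'   by [simulateCohort()]).
#' @param seed seed for classifier training.
#' @param alpha nominal level for the significance count.
#' @return list: `table` (one row per ROI, ordered as given) and
#'   `nSignificant`.
#' @export
roiSweep <- function(cohortByRoi, seed = 1, alpha = 0.05) {
  stopIfNot(length(cohortByRoi) >= 1, "need at least one ROI")
  rows <- lapply(names(cohortByRoi), function(roi) {
    cohort <- cohortByRoi[[roi]]
    fits <- lapply(cohort, function(p) {
      cls <- trainPairwise(p$localizer, seed = seed)
      dvt <- decisionValues(cls, p$learning)
      fitParticipantModels(dvt, p$design, p$behavior)
    })
    agg <- suppressMessages(aggregateAndInfer(fits,
                                              predictors = "future_x_rep"))
    g <- agg$group
    data.frame(roi = roi, estimate = g$mean, t = g$t, df = g$df,
               p = g$p, n = g$n)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, nSignificant = sum(tab$p < alpha, na.rm = TRUE))
}
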