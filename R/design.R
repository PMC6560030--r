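# Experimental-design generation: Y-maze learning phase and localizer.
#
# The learning phase presents nInterest Y-mazes of interest (half assigned
# reward on first exposure regardless of choice) plus nExtra always-loss
# mazes, four repetitions each, with staged introduction: the first four
# mazes cycle through three repetitions (each shown once per round), their
# fourth repetition is interleaved with the introduction of the second set,
# and the always-loss mazes are interleaved with the second set's fourth
# repetition.  Forty trials are split into four blocks of ten.

STATE_DURATIONS <- c(S1 = 5, S2 = 4, S3 = 5, FEEDBACK = 5, REST = 12)

#' Event durations used for GLM modeling
#'
#' States 1 and 3 and the feedback state are modeled as 5 s events, state 2
#' as 4 s, and the post-feedback rest period as 12 s.
#' @return named numeric vector of durations in seconds.
#' @export
stateDurations <- function() STATE_DURATIONS

shuf <- function(x) x[sample.int(length(x))]

# alternate rows of two data.frames until both are exhausted
weaveRows <- function(d1, d2) {
  if (is.null(d1)) return(d2)
  if (is.null(d2)) return(d1)
  out <- vector("list", nrow(d1) + nrow(d2))
  i <- 1L; j <- 1L; k <- 1L
  while (i <= nrow(d1) || j <= nrow(d2)) {
    if (i <= nrow(d1)) { out[[k]] <- d1[i, ]; i <- i + 1L; k <- k + 1L }
    if (j <= nrow(d2)) { out[[k]] <- d2[j, ]; j <- j + 1L; k <- k + 1L }
  }
  do.call(rbind, out)
}

#' Generate the maze learning-phase design
#'
#' Builds maze specifications (stimulus categories at state 1 and the two
#' state-3 arms, the correct action, and the forced first-exposure outcome)
#' and the staged, blocked trial order with jittered state onset times.
#' Category triplets are assigned by cycling through the six orderings of
#' face/scene/object, so each category appears at state 1 and state 3 in
#' near-equal numbers, and the state-1 and state-3 categories of a maze
#' always differ.
#'
#' Exactly half of the mazes of interest are assigned reward on their first
#' exposure (independent of the participant's choice), so expected
#' first-repetition performance is 50% by construction.  Always-loss extra
#' mazes end in a loss on every repetition.
#'
#' Inter-state intervals are drawn uniformly so that the mean state-1 to
#' state-3 onset interval is ~31 s and the mean maze duration ~48 s.
#'
#' @param nInterest number of mazes of interest (default 8).
#' @param nExtra number of always-loss extra mazes (default 2).
#' @param seed integer seed.
#' @return a list of class `"mazeDesign"` with elements `mazes` (one row per
#'   maze), `trials` (ordered trial list with block assignment and per-state
#'   onsets, block-relative seconds), `nBlocks`, and `seed`.
#' @examples
#' d <- generateDesign(seed = 1)
#' nrow(d$trials)                       # 40 trials
#' table(d$trials$block)                # 4 blocks of 10
#' sum(d$mazes$initial_reward[d$mazes$of_interest])  # 4 of 8 rewarded
#' @export
generateDesign <- function(nInterest = 8, nExtra = 2, seed = 1) {
  if (nInterest < 1 || nExtra < 0)
    stop("impossible counterbalancing request: need nInterest >= 1, nExtra >= 0")
  set.seed(childSeed(seed, 1))
  n <- nInterest + nExtra

  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2),
                c(1, 3, 2), c(2, 1, 3), c(3, 2, 1))
  catIdx <- do.call(rbind, perms[((seq_len(n) - 1) %% 6) + 1])
  mazes <- data.frame(
    maze_id = seq_len(n),
    s1_category = CATEGORIES[catIdx[, 1]],
    s3_correct_category = CATEGORIES[catIdx[, 2]],
    s3_incorrect_category = CATEGORIES[catIdx[, 3]],
    correct_action = sample(c("left", "right"), n, replace = TRUE),
    of_interest = seq_len(n) <= nInterest,
    stringsAsFactors = FALSE)
  mazes$s1_stimulus <- sprintf("%s_m%02d_s1", mazes$s1_category, mazes$maze_id)
  mazes$s3_correct_stimulus <- sprintf("%s_m%02d_s3c",
                                       mazes$s3_correct_category, mazes$maze_id)
  mazes$s3_incorrect_stimulus <- sprintf("%s_m%02d_s3i",
                                         mazes$s3_incorrect_category, mazes$maze_id)
  # half of the mazes of interest end their first exposure in reward
  nRew <- floor(nInterest / 2)
  rewarded <- shuf(seq_len(nInterest))[seq_len(nRew)]
  if (nInterest %% 2 == 1 && runif(1) < 0.5)
    rewarded <- c(rewarded, setdiff(seq_len(nInterest), rewarded)[1])
  mazes$initial_reward <- mazes$maze_id %in% rewarded & mazes$of_interest

  # staged trial order
  A <- mazes$maze_id[mazes$of_interest][seq_len(min(4, nInterest))]
  B <- setdiff(mazes$maze_id[mazes$of_interest], A)
  E <- mazes$maze_id[!mazes$of_interest]
  mk <- function(ids, r) if (length(ids)) data.frame(maze_id = ids,
                                                     repetition = r) else NULL
  segs <- lapply(1:3, function(r) mk(shuf(A), r))
  if (length(B)) {
    segs <- c(segs, list(weaveRows(mk(shuf(A), 4L), mk(shuf(B), 1L))))
    segs <- c(segs, lapply(2:3, function(r) mk(shuf(B), r)))
    segs <- c(segs, list(weaveRows(mk(shuf(B), 4L), mk(shuf(E), 1L))))
  } else {
    segs <- c(segs, list(weaveRows(mk(shuf(A), 4L), mk(shuf(E), 1L))))
  }
  if (length(E))
    segs <- c(segs, lapply(2:4, function(r) mk(shuf(E), r)))
  trials <- do.call(rbind, segs)
  rownames(trials) <- NULL
  trials$trial_index <- seq_len(nrow(trials))
  trials$block <- rep(seq_len(4), each = nrow(trials) / 4)

  # jittered state onsets, block-relative
  d12 <- runif(nrow(trials), 11, 19)     # state 1 -> state 2 onset
  d23 <- runif(nrow(trials), 12, 20)     # state 2 -> state 3 onset
  d3f <- runif(nrow(trials), 8.6, 14.6)  # state 3 -> feedback onset
  iti <- runif(nrow(trials), 15, 18.5)   # feedback offset -> next state 1
  onset <- numeric(nrow(trials))
  for (b in seq_len(4)) {
    idx <- which(trials$block == b)
    t0 <- 2
    for (i in idx) {
      onset[i] <- t0
      t0 <- onset[i] + d12[i] + d23[i] + d3f[i] + STATE_DURATIONS["FEEDBACK"] + iti[i]
    }
  }
  trials$onset_s1 <- onset
  trials$onset_s2 <- onset + d12
  trials$onset_s3 <- onset + d12 + d23
  trials$onset_feedback <- trials$onset_s3 + d3f
  trials$onset_rest <- trials$onset_feedback + STATE_DURATIONS["FEEDBACK"] + 0.25

  structure(list(mazes = mazes, trials = trials, nBlocks = 4L,
                 seed = as.integer(seed)),
            class = "mazeDesign")
}

#' @export
print.mazeDesign <- function(x, ...) {
  cat("mazeDesign:", nrow(x$mazes), "mazes (",
      sum(x$mazes$of_interest), "of interest ),",
      nrow(x$trials), "trials in", x$nBlocks, "blocks\n")
  invisible(x)
}

#' Simulate maze-learning behavior
#'
#' A two-parameter observe-then-exploit rule.  The first exposure's outcome
#' is forced by the design (half of the mazes of interest are rewarded
#' regardless of choice), which also fixes which action counts as correct
#' thereafter.  From the second repetition on, the correct action is chosen
#' with probability `pLearnAfterReward` once the correct state-3 room has
#' been observed on any earlier repetition, and with `pLearnAfterLoss`
#' before that.  The defaults are the reported repetition-2
#' accuracies of the modeled paradigm, conditional on initial reward
#' versus initial loss.
#'
#' @param design a `"mazeDesign"` from [generateDesign()].
#' @param pLearnAfterReward probability of a correct choice once the correct
#'   distal state has been observed.
#' @param pLearnAfterLoss probability of a correct choice before the correct
#'   distal state has been observed.
#' @param seed integer seed.
#' @return data.frame with one row per maze x repetition: `maze_id`,
#'   `repetition`, `of_interest`, `chosen_action`, `correct` (NA for
#'   always-loss mazes), `reached_correct_s3`, `outcome`.
#' @examples
#' d <- generateDesign(seed = 1)
#' b <- simulateBehavior(d, seed = 1)
#' mean(b$outcome[b$repetition == 1 & b$of_interest] == "reward")  # 0.5
#' @export
simulateBehavior <- function(design, pLearnAfterReward = 0.821,
                             pLearnAfterLoss = 0.714, seed = 1) {
  stopIfNot(inherits(design, "mazeDesign"), "design must be a mazeDesign")
  stopIfNot(all(c(pLearnAfterReward, pLearnAfterLoss) >= 0) &&
            all(c(pLearnAfterReward, pLearnAfterLoss) <= 1),
            "learning probabilities must lie in [0, 1]")
  set.seed(childSeed(seed, 2))
  mz <- design$mazes
  out <- vector("list", nrow(mz))
  for (i in seq_len(nrow(mz))) {
    m <- mz[i, ]
    chosen <- character(4); correct <- rep(NA, 4)
    reached <- logical(4); outc <- character(4)
    chosen[1] <- sample(c("left", "right"), 1)
    if (m$of_interest) {
      correct[1] <- m$initial_reward
      reached[1] <- m$initial_reward
      outc[1] <- if (m$initial_reward) "reward" else "loss"
      for (k in 2:4) {
        p <- if (any(reached[seq_len(k - 1)])) pLearnAfterReward else pLearnAfterLoss
        correct[k] <- runif(1) < p
        chosen[k] <- if (correct[k]) m$correct_action else
          setdiff(c("left", "right"), m$correct_action)
        reached[k] <- correct[k]
        outc[k] <- if (correct[k]) "reward" else "loss"
      }
    } else {
      # always-loss mazes: both actions lose, no correct choice is defined
      outc[] <- "loss"
      chosen[2:4] <- sample(c("left", "right"), 3, replace = TRUE)
    }
    out[[i]] <- data.frame(maze_id = m$maze_id, repetition = 1:4,
                           of_interest = m$of_interest,
                           chosen_action = chosen, correct = correct,
                           reached_correct_s3 = reached, outcome = outc,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Expand design and behavior into a per-event table
#'
#' One row per trial and state (S1, S2, S3, FEEDBACK, REST) with modeled
#' onset and duration, the category on screen (none at S2, feedback and
#' rest), and the behavioral outcome.  The visited state-3 room follows the
#' choice: the correct arm's room on correct trials, the incorrect arm's
#' otherwise (always-loss mazes visit the incorrect arm by convention).
#'
#' @param design a `"mazeDesign"`.
#' @param behavior behavior table from [simulateBehavior()].
#' @return data.frame of event records, ordered by block and onset.
#' @export
makeLearningEvents <- function(design, behavior) {
  tr <- design$trials
  mz <- design$mazes
  key <- paste(behavior$maze_id, behavior$repetition)
  bix <- match(paste(tr$maze_id, tr$repetition), key)
  stopIfNot(!anyNA(bix), "behavior table does not cover all design trials")
  bh <- behavior[bix, ]
  mix <- match(tr$maze_id, mz$maze_id)
  visited <- ifelse(!is.na(bh$correct) & bh$correct,
                    mz$s3_correct_category[mix], mz$s3_incorrect_category[mix])
  states <- names(STATE_DURATIONS)
  onsets <- cbind(tr$onset_s1, tr$onset_s2, tr$onset_s3,
                  tr$onset_feedback, tr$onset_rest)
  rows <- vector("list", length(states))
  for (s in seq_along(states)) {
    st <- states[s]
    rows[[s]] <- data.frame(
      block = tr$block, trial_index = tr$trial_index,
      maze_id = tr$maze_id, repetition = tr$repetition,
      state = st, onset = onsets[, s],
      duration = unname(STATE_DURATIONS[st]),
      onscreen_category = switch(st, S1 = mz$s1_category[mix],
                                 S3 = visited, rep("none", nrow(tr))),
      s1_category = mz$s1_category[mix],
      future_category = mz$s3_correct_category[mix],
      visited_s3_category = visited,
      of_interest = mz$of_interest[mix],
      outcome = if (st %in% c("FEEDBACK", "REST")) bh$outcome else
        rep("none", nrow(tr)),
      chosen_action = bh$chosen_action,
      stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$block, ev$onset), ]
  rownames(ev) <- NULL
  ev
}

#' Generate the localizer-phase trial list
#'
#' Three mini-blocks, each presenting every learning-phase stimulus with a
#' category-trial total of four appearances per stimulus, 20 scrambled
#' trials split 4-8 per mini-block, and 5 motion trials per mini-block.
#' Scrambled trials flank the motion trials at the end of each mini-block.
#' Memory probes follow 25% of the face/scene/object trials.  With the
#' default 10-maze design this yields 155 trials: 120 category, 20
#' scrambled, 15 motion.
#'
#' @param mazes maze specification data.frame (`$mazes` of a design).
#' @param allSeen were all stimuli seen during learning?  If `FALSE`,
#'   trials for unseen stimuli are dropped and each contributes 2 s of
#'   additional inter-trial interval.
#' @param seenStimuli character vector of seen stimulus ids (used when
#'   `allSeen = FALSE`).
#' @param seed integer seed.
#' @return data.frame of localizer trials: `index`, `category`, `stimulus`,
#'   `miniblock`, `probe`, `onset`, `duration`.
#' @examples
#' d <- generateDesign(seed = 1)
#' loc <- generateLocalizer(d$mazes, seed = 1)
#' table(ifelse(loc$category %in% c("face","scene","object"),
#'              "category", loc$category))
#' @export
generateLocalizer <- function(mazes, allSeen = TRUE, seenStimuli = NULL,
                              seed = 1) {
  set.seed(childSeed(seed, 3))
  inv <- data.frame(
    stimulus = c(mazes$s1_stimulus, mazes$s3_correct_stimulus,
                 mazes$s3_incorrect_stimulus),
    category = c(mazes$s1_category, mazes$s3_correct_category,
                 mazes$s3_incorrect_category),
    stringsAsFactors = FALSE)
  nStim <- nrow(inv)
  seen <- if (allSeen) rep(TRUE, nStim) else inv$stimulus %in% seenStimuli

  # each stimulus appears once per mini-block plus once extra in one block
  extraBlock <- integer(nStim)
  if (nStim) extraBlock <- rep(1:3, length.out = nStim)[sample.int(nStim)]
  scrCounts <- scrambledSplit(20L, 4L, 8L)

  blocks <- vector("list", 3)
  for (b in 1:3) {
    catIdx <- c(seq_len(nStim), which(extraBlock == b))
    catTrials <- if (length(catIdx))
      data.frame(category = inv$category[catIdx],
                 stimulus = inv$stimulus[catIdx],
                 seen = seen[catIdx], stringsAsFactors = FALSE) else NULL
    if (!is.null(catTrials)) catTrials <- catTrials[sample.int(nrow(catTrials)), ]
    k <- scrCounts[b]
    scr1 <- ceiling(k / 2)
    scrRow <- function(n, off) if (n) data.frame(
      category = "scrambled", stimulus = sprintf("scrambled_%02d_b%d", off + seq_len(n), b),
      seen = TRUE, stringsAsFactors = FALSE) else NULL
    mot <- data.frame(category = "motion",
                      stimulus = sprintf("motion_%02d_b%d", 1:5, b),
                      seen = TRUE, stringsAsFactors = FALSE)
    blk <- rbind(catTrials, scrRow(scr1, 0L), mot, scrRow(k - scr1, scr1))
    blk$miniblock <- b
    blocks[[b]] <- blk
  }
  trials <- do.call(rbind, blocks)
  rownames(trials) <- NULL
  trials$duration <- ifelse(trials$category == "motion", 3, 2)

  isCat <- trials$category %in% CATEGORIES
  trials$probe <- FALSE
  probeable <- which(isCat & trials$seen)
  nProbe <- round(0.25 * sum(isCat))
  trials$probe[sample(probeable, min(nProbe, length(probeable)))] <- TRUE

  # sequential onsets; dropped (unseen) trials leave 2 s of extra ITI behind
  gap <- runif(nrow(trials), 1.5, 4.5) + ifelse(trials$probe, 5, 0)
  t0 <- 2; onset <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    if (trials$seen[i]) {
      onset[i] <- t0
      t0 <- t0 + trials$duration[i] + gap[i]
    } else {
      onset[i] <- NA
      t0 <- t0 + 2
    }
  }
  trials$onset <- onset
  trials <- trials[trials$seen, setdiff(names(trials), "seen")]
  trials$index <- seq_len(nrow(trials))
  rownames(trials) <- NULL
  trials[, c("index", "category", "stimulus", "miniblock", "probe",
             "onset", "duration")]
}

# split `total` scrambled trials over 3 mini-blocks with per-block bounds
scrambledSplit <- function(total, lo, hi) {
  comps <- expand.grid(b1 = lo:hi, b2 = lo:hi, b3 = lo:hi)
  comps <- comps[rowSums(comps) == total, , drop = FALSE]
  stopIfNot(nrow(comps) > 0, "no valid scrambled-trial split exists")
  unlist(comps[sample.int(nrow(comps), 1), ], use.names = FALSE)
}
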