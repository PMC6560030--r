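test_that("default design reproduces the printed learning-phase structure", {
  d <- generateDesign(seed = 7)
  expect_equal(nrow(d$trials), 40)
  expect_equal(as.integer(table(d$trials$block)), rep(10L, 4))
  expect_equal(sum(d$mazes$initial_reward[d$mazes$of_interest]), 4)
  expect_false(any(d$mazes$initial_reward[!d$mazes$of_interest]))
  # each maze seen exactly four times
  expect_equal(as.integer(table(d$trials$maze_id)), rep(4L, 10))
  # staged introduction: the first four trials are four distinct mazes,
  # each shown once before any is repeated
  expect_equal(length(unique(d$trials$maze_id[1:4])), 4)
  firstRep2 <- min(which(d$trials$repetition == 2))
  expect_true(all(d$trials$repetition[1:(firstRep2 - 1)] == 1))
  # maze categories: state 1 and state 3 always differ within a maze
  expect_true(all(d$mazes$s1_category != d$mazes$s3_correct_category))
  expect_true(all(d$mazes$s1_category != d$mazes$s3_incorrect_category))
  # stimuli unique across mazes and slots
  stim <- c(d$mazes$s1_stimulus, d$mazes$s3_correct_stimulus,
            d$mazes$s3_incorrect_stimulus)
  expect_equal(anyDuplicated(stim), 0L)
})

test_that("trial timings have the designed means and ordering", {
  d <- generateDesign(seed = 3)
  s13 <- d$trials$onset_s3 - d$trials$onset_s1
  expect_true(abs(mean(s13) - 31) < 2)
  dur <- d$trials$onset_feedback + 5 - d$trials$onset_s1
  expect_true(abs(mean(dur) - 48.5) < 3)
  ev <- makeLearningEvents(d, simulateBehavior(d, seed = 3))
  for (b in 1:4)
    expect_true(all(diff(ev$onset[ev$block == b]) > 0))
})

test_that("degenerate and invalid design requests behave as specified", {
  d1 <- generateDesign(nInterest = 1, nExtra = 0, seed = 2)
  expect_equal(nrow(d1$trials), 4)
  expect_error(generateDesign(nInterest = 0), "impossible")
})

test_that("event records carry the modeled durations and screen content", {
  d <- generateDesign(seed = 5)
  b <- simulateBehavior(d, seed = 5)
  ev <- makeLearningEvents(d, b)
  expect_equal(nrow(ev), 200)
  durs <- stateDurations()
  for (s in names(durs))
    expect_true(all(ev$duration[ev$state == s] == durs[[s]]))
  expect_true(all(ev$onscreen_category[
    ev$state %in% c("S2", "FEEDBACK", "REST")] == "none"))
  expect_true(all(ev$onscreen_category[ev$state == "S1"] %in%
                    c("face", "scene", "object")))
  # visited state-3 room follows the choice
  s3 <- ev[ev$state == "S3" & ev$of_interest, ]
  bh <- b[match(paste(s3$maze_id, s3$repetition),
                paste(b$maze_id, b$repetition)), ]
  mz <- d$mazes[match(s3$maze_id, d$mazes$maze_id), ]
  expect_equal(s3$onscreen_category,
               ifelse(bh$correct, mz$s3_correct_category,
                      mz$s3_incorrect_category))
})

test_that("localizer composition matches the printed trial counts", {
  d <- generateDesign(seed = 11)
  loc <- generateLocalizer(d$mazes, seed = 11)
  expect_equal(nrow(loc), 155)
  expect_equal(sum(loc$category %in% c("face", "scene", "object")), 120)
  expect_equal(sum(loc$category == "scrambled"), 20)
  expect_equal(sum(loc$category == "motion"), 15)
  expect_equal(sum(loc$probe), 30)          # 25% of the category trials
  expect_false(any(loc$probe[loc$category %in% c("scrambled", "motion")]))
  # per mini-block: 40 category, 4-8 scrambled flanking 5 motion at the end
  for (b in 1:3) {
    blk <- loc[loc$miniblock == b, ]
    expect_equal(sum(blk$category %in% c("face", "scene", "object")), 40)
    expect_true(sum(blk$category == "scrambled") %in% 4:8)
    mot <- which(blk$category == "motion")
    expect_equal(length(mot), 5)
    expect_equal(mot, seq(min(mot), length.out = 5))  # contiguous
    expect_equal(blk$category[min(mot) - 1], "scrambled")
    expect_equal(blk$category[max(mot) + 1], "scrambled")
  }
  expect_true(all(diff(loc$onset) > 0))
})

test_that("unseen stimuli are dropped and a 0-maze localizer degenerates", {
  d <- generateDesign(seed = 4)
  seen <- c(d$mazes$s1_stimulus, d$mazes$s3_correct_stimulus)
  loc <- generateLocalizer(d$mazes, allSeen = FALSE, seenStimuli = seen,
                           seed = 4)
  expect_true(all(loc$stimulus[loc$category %in%
                                 c("face", "scene", "object")] %in% seen))
  expect_equal(sum(loc$category == "scrambled"), 20)
  loc0 <- generateLocalizer(d$mazes[0, ], seed = 4)
  expect_setequal(unique(loc0$category), c("scrambled", "motion"))
})

test_that("behavioral rule honors forced feedback and learning probabilities", {
  d <- generateDesign(seed = 9)
  b <- simulateBehavior(d, 1, 1, seed = 9)
  expect_true(all(b$correct[b$repetition > 1 & b$of_interest]))
  # repetition-1 outcome equals the design assignment, choice-independent
  r1 <- b[b$repetition == 1 & b$of_interest, ]
  expect_equal(r1$outcome == "reward",
               d$mazes$initial_reward[match(r1$maze_id, d$mazes$maze_id)])
  expect_equal(mean(r1$outcome == "reward"), 0.5)
  # always-loss mazes lose on every repetition
  expect_true(all(b$outcome[!b$of_interest] == "loss"))
})

test_that("repetition-2 accuracy tracks the learning probability", {
  d <- generateDesign(seed = 1)
  acc <- vapply(1:1000, function(i) {
    b <- simulateBehavior(d, 0.5, 0.5, seed = i)
    mean(b$correct[b$repetition == 2 & b$of_interest])
  }, numeric(1))
  expect_true(abs(mean(acc) - 0.5) < 0.02)
})

test_that("pattern generator is linear and exact in the noiseless limit", {
  d <- generateDesign(seed = 6)
  b <- simulateBehavior(d, seed = 6)
  t0 <- simTruth(nVoxels = 12, aCurrent = 0.7, gFuture = 0, noiseSd = 0,
                 seed = 6)
  ps <- simulatePatterns(d, b, t0)
  ev <- eventData(ps$learning)
  B <- betas(ps$learning)
  tm <- templates(t0)
  i <- which(ev$state == "S1")[5]
  expect_equal(B[i, ], 0.7 * tm[, ev$onscreen_category[i]],
               ignore_attr = TRUE)
  # with a future slope, the projection onto the future template is g * r
  t1 <- simTruth(nVoxels = 12, aCurrent = 0.7, gFuture = 0.25, noiseSd = 0,
                 seed = 6)
  ps1 <- simulatePatterns(d, b, t1)
  ev1 <- eventData(ps1$learning)
  B1 <- betas(ps1$learning)
  s1 <- which(ev1$state == "S1" & ev1$onscreen_category !=
                ev1$future_category)
  proj <- vapply(s1, function(i)
    sum(B1[i, ] * templates(t1)[, ev1$future_category[i]]), numeric(1))
  expect_equal(proj, 0.25 * ev1$correct_rep[s1], ignore_attr = TRUE)
  # linearity: doubling the amplitudes doubles the noiseless patterns
  t2 <- simTruth(nVoxels = 12, aCurrent = 1.4, gFuture = 0.5, noiseSd = 0,
                 seed = 6)
  ps2 <- simulatePatterns(d, b, t2)
  expect_equal(betas(ps2$learning), 2 * B1, tolerance = 1e-12)
})

test_that("all generators are bit-reproducible under a fixed seed", {
  w1 <- tinyWorld(seed = 31)
  w2 <- tinyWorld(seed = 31)
  expect_identical(w1$design, w2$design)
  expect_identical(w1$behavior, w2$behavior)
  expect_identical(betas(w1$learning), betas(w2$learning))
  expect_identical(betas(w1$localizer), betas(w2$localizer))
})
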