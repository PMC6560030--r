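mkBehavior <- function(reached, mazeId = 1) {
  data.frame(maze_id = mazeId, repetition = seq_along(reached),
             reached_correct_s3 = reached)
}

test_that("correct-repetition covariate follows the stated coding rules", {
  expect_equal(buildCorrectRep(mkBehavior(c(TRUE, TRUE, TRUE, TRUE)))$correct_rep,
               0:3)
  expect_equal(buildCorrectRep(mkBehavior(c(FALSE, FALSE, TRUE, TRUE)))$correct_rep,
               c(0, 0, 0, 1))
  expect_equal(buildCorrectRep(mkBehavior(rep(FALSE, 4)))$correct_rep,
               rep(0, 4))
  # once observed, the primary coding increments regardless of later errors
  expect_equal(buildCorrectRep(mkBehavior(c(TRUE, FALSE, FALSE, TRUE)))$correct_rep,
               0:3)
  # the alternative coding increments only after correct repetitions
  expect_equal(buildCorrectRep(mkBehavior(c(TRUE, FALSE, TRUE, TRUE)),
                               coding = "correct_only")$correct_rep,
               c(0, 1, 1, 2))
})

test_that("state-1 predictors encode binary category matches and products", {
  mazes <- data.frame(maze_id = 1:2,
                      s1_category = c("face", "scene"),
                      s3_correct_category = c("scene", "object"))
  events <- data.frame(maze_id = c(1, 1, 2), repetition = c(1, 3, 2))
  cov <- data.frame(maze_id = c(1, 1, 1, 2, 2), repetition = c(1, 2, 3, 1, 2),
                    correct_rep = c(0, 1, 2, 0, 1))
  Xf <- buildState1Predictors(events, mazes, cov, "face")
  expect_equal(Xf$current, c(1, 1, 0))
  expect_equal(Xf$future, c(0, 0, 0))
  Xs <- buildState1Predictors(events, mazes, cov, "scene")
  expect_equal(Xs$current, c(0, 0, 1))
  expect_equal(Xs$future, c(1, 1, 0))
  expect_equal(Xs$correct_rep, c(0, 2, 1))
  expect_equal(Xs$future_x_rep, c(0, 2, 0))
  expect_equal(Xs$current_x_rep, c(0, 0, 1))
  # all-zero covariate collapses the interactions and is flagged
  cov0 <- transform(cov, correct_rep = 0)
  X0 <- buildState1Predictors(events, mazes, cov0, "face")
  expect_true(attr(X0, "reducedRank"))
  expect_true(all(X0$future_x_rep == 0))
  expect_error(buildState1Predictors(transform(events, maze_id = 99),
                                     mazes, cov, "face"), "unknown maze")
})

test_that("regression recovers constructed coefficients exactly", {
  d <- generateDesign(seed = 10)
  b <- simulateBehavior(d, seed = 10)
  ev <- makeLearningEvents(d, b)
  evS1 <- ev[ev$state == "S1" & ev$of_interest, ]
  cov <- buildCorrectRep(b)
  X <- buildState1Predictors(evS1, d$mazes, cov, "face")
  vals <- 0.3 + 0.1 * X$current + 0.05 * X$future_x_rep
  fit <- fitDecisionRegression(vals, X)
  expect_equal(fit$current, 0.1, tolerance = 1e-10)
  expect_equal(fit$future, 0, tolerance = 1e-10)
  expect_equal(fit$correct_rep, 0, tolerance = 1e-10)
  expect_equal(fit$current_x_rep, 0, tolerance = 1e-10)
  expect_equal(fit$future_x_rep, 0.05, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.3, tolerance = 1e-10)
})

test_that("coefficients equal the normal-equations oracle", {
  set.seed(11)
  for (rep in 1:20) {
    X <- data.frame(current = rbinom(40, 1, 0.4),
                    future = rbinom(40, 1, 0.4),
                    correct_rep = sample(0:3, 40, TRUE))
    X$current_x_rep <- X$current * X$correct_rep
    X$future_x_rep <- X$future * X$correct_rep
    if (qr(cbind(1, as.matrix(X)))$rank < 6) next
    y <- rnorm(40)
    fit <- fitDecisionRegression(y, X)
    Xi <- cbind(1, as.matrix(X))
    oracle <- solve(t(Xi) %*% Xi, t(Xi) %*% y)   # brute-force normal equations
    expect_equal(unlist(fit[names(X)]), oracle[-1, 1], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(fit$intercept, unname(oracle[1, 1]), tolerance = 1e-10)
  }
})

test_that("pure-noise decision values give coefficients centered on zero", {
  d <- generateDesign(seed = 12)
  b <- simulateBehavior(d, seed = 12)
  ev <- makeLearningEvents(d, b)
  evS1 <- ev[ev$state == "S1" & ev$of_interest, ]
  X <- buildState1Predictors(evS1, d$mazes, buildCorrectRep(b), "face")
  set.seed(12)
  cf <- t(vapply(1:500, function(i)
    unlist(fitDecisionRegression(rnorm(nrow(X), 0.5, 0.1), X)[
      c("current", "future", "future_x_rep")]), numeric(3)))
  se <- apply(cf, 2, sd) / sqrt(nrow(cf))
  expect_true(all(abs(colMeans(cf)) < 2 * se * 3))
})

test_that("regression guards degenerate input", {
  X <- data.frame(current = c(1, 0, 1, 0, 1),
                  future = c(0, 1, 0, 1, 0))
  expect_error(fitDecisionRegression(rnorm(5), X), "too few")
  X2 <- data.frame(a = rnorm(10), b = rnorm(10))
  X2$c <- X2$a + X2$b
  expect_error(fitDecisionRegression(rnorm(10), X2), "collinear.*c")
})

test_that("aggregation averages valid categories and flags degenerate groups", {
  mkFit <- function(vals, valid = c(face = TRUE, scene = TRUE,
                                    object = TRUE)) {
    fits <- data.frame(category = c("face", "scene", "object"),
                       current = vals, future = 0, correct_rep = 0,
                       current_x_rep = 0, future_x_rep = vals * 2)
    list(fits = fits, valid = valid, include = any(valid))
  }
  pf <- list(mkFit(c(1, 2, 3)), mkFit(c(2, 3, 4)),
             mkFit(c(0, 3, 6), valid = c(face = FALSE, scene = TRUE,
                                         object = TRUE)))
  agg <- aggregateAndInfer(pf)
  expect_equal(unname(agg$participantMeans[, "current"]), c(2, 3, 4.5))
  # a participant with no valid category is dropped with a message
  pf2 <- c(pf, list(mkFit(c(9, 9, 9), valid = c(face = FALSE, scene = FALSE,
                                                object = FALSE))))
  expect_message(agg2 <- aggregateAndInfer(pf2), "dropped")
  expect_equal(agg2$nDropped, 1)
  expect_equal(nrow(agg2$participantMeans), 3)
  # identical coefficients across participants: flagged, not t = Inf
  pf3 <- list(mkFit(c(1, 1, 1)), mkFit(c(1, 1, 1)), mkFit(c(1, 1, 1)))
  agg3 <- aggregateAndInfer(pf3)
  expect_true(all(agg3$group$flag[agg3$group$predictor == "current"] ==
                    "zero-variance"))
  expect_false(any(is.infinite(agg3$group$t), na.rm = TRUE))
})

test_that("per-bin estimates match the full model algebraically", {
  w <- tinyWorld(seed = 14, nVoxels = 20, noiseSd = 0)
  res <- analyzeParticipant(w)
  # construct noiseless decision values obeying the full linear model
  ev <- futurestates::dvEvents(res$dvt)
  use <- ev$state == "S1" & ev$of_interest
  cov <- buildCorrectRep(w$behavior)
  vals <- decisionValueMatrix(res$dvt)
  beta <- c(current = 0.2, future = 0.03, correct_rep = -0.01,
            current_x_rep = 0.01, future_x_rep = 0.06)
  for (cat in colnames(vals)) {
    X <- buildState1Predictors(ev[use, ], w$design$mazes, cov, cat)
    vals[use, cat] <- 0.4 + as.matrix(X) %*% beta
  }
  vals <- pmin(pmax(vals, 0), 1)
  dvt <- new("DecisionValueTable", values = vals,
             margins = marginMatrix(res$dvt), events = ev, roi = "x")
  pb <- perBinModels(dvt, w$design, w$behavior)
  for (i in seq_len(nrow(pb))) {
    b <- pb$bin[i]
    expect_equal(pb$current[i], beta["current"] + b * beta["current_x_rep"],
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(pb$future[i], beta["future"] + b * beta["future_x_rep"],
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # monotone growth of the future effect with bin under a linear plant
  expect_true(all(diff(pb$future) > 0))
})

test_that("reduced models obey the omitted-variable relationship", {
  w <- tinyWorld(seed = 15, nVoxels = 20)
  res <- analyzeParticipant(w)
  full <- res$models$fits
  red <- fitParticipantModels(res$dvt, w$design, w$behavior,
                              drop = "future")$fits
  ev <- futurestates::dvEvents(res$dvt)
  use <- ev$state == "S1" & ev$of_interest
  cov <- buildCorrectRep(w$behavior)
  for (cat in c("face", "scene", "object")) {
    X <- buildState1Predictors(ev[use, ], w$design$mazes, cov, cat)
    Xi <- cbind(1, as.matrix(X[c("current", "correct_rep",
                                 "current_x_rep")]))
    X2 <- as.matrix(X[c("future", "future_x_rep")])
    # delta = (X1'X1)^-1 X1'X2 %*% beta2   (omitted-variable formula)
    delta <- solve(crossprod(Xi), crossprod(Xi, X2)) %*%
      t(full[full$category == cat, c("future", "future_x_rep")])
    keep <- c("current", "correct_rep", "current_x_rep")
    expect_equal(unlist(red[red$category == cat, keep]),
                 unlist(full[full$category == cat, keep]) +
                   delta[-1, 1], tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_error(fitParticipantModels(res$dvt, w$design, w$behavior,
                                    drop = "both"), "arg")
})

test_that("state-variant models recover planted later-state signals", {
  # planted state-3 suppression: on-screen amplitude falls with learning
  w <- tinyWorld(seed = 16, nVoxels = 20, noiseSd = 0.05,
                 s3DecaySlope = -0.3)
  res <- analyzeParticipant(w)
  s3 <- stateVariantModels(res$dvt, w$design, w$behavior, state = "S3")
  expect_lt(mean(s3$fits$current_x_rep), 0)
  # no signal planted at state 2 or feedback: interactions near zero
  s2 <- stateVariantModels(res$dvt, w$design, w$behavior, state = "S2")
  expect_lt(abs(mean(s2$fits$future_x_rep)), 0.05)
  fb <- stateVariantModels(res$dvt, w$design, w$behavior,
                           state = "FEEDBACK")
  expect_lt(abs(mean(fb$fits$past)), 0.1)
  # a planted state-2 future signal is picked up by the S2 variant
  w2 <- tinyWorld(seed = 17, nVoxels = 20, noiseSd = 0.05, gFutureS2 = 0.4)
  res2 <- analyzeParticipant(w2)
  s22 <- stateVariantModels(res2$dvt, w2$design, w2$behavior, state = "S2")
  expect_gt(mean(s22$fits$future_x_rep), 0.01)
})

test_that("the future-by-repetition estimate grows with the planted slope", {
  est <- vapply(c(0, 0.4, 0.8), function(g) {
    mean(vapply(1:6, function(s) {
      w <- tinyWorld(seed = 700 + s, nVoxels = 30, gFuture = g)
      res <- analyzeParticipant(w, seed = s)
      v <- res$models$valid
      mean(res$models$fits$future_x_rep[v], na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("selectivity: current-only worlds show no future-by-rep effect", {
  # the double dissociation the design relies on: with no future signal,
  # on-screen decoding succeeds while the learning interaction stays null
  cohort <- simulateCohort(nParticipants = 10, seed = 77, gFuture = 0,
                           nVoxels = 40)
  fits <- lapply(seq_along(cohort), function(i) {
    p <- cohort[[i]]
    res <- analyzeParticipant(p, seed = i)
    list(auc = mean(generalizationAuc(res$dvt)$auc_minus_chance_x100,
                    na.rm = TRUE),
         models = res$models)
  })
  aucs <- vapply(fits, `[[`, numeric(1), "auc")
  expect_gt(mean(aucs), 5)   # on-screen categories decode above chance
  agg <- suppressMessages(aggregateAndInfer(lapply(fits, `[[`, "models")))
  g <- agg$group
  expect_gt(g$mean[g$predictor == "current"], 0)
  expect_gt(g$p[g$predictor == "future_x_rep"], 0.05)
})

test_that("category relabeling leaves the group analysis invariant", {
  # relabeling the synthetic world's categories permutes the per-category
  # fits but not the category-averaged participant means
  w <- tinyWorld(seed = 19, nVoxels = 20)
  res <- analyzeParticipant(w)
  m <- res$models
  perm <- colMeans(m$fits[m$valid, futurestates:::DV_PREDICTORS])
  expect_equal(unname(perm["future_x_rep"]),
               mean(m$fits$future_x_rep[m$valid]))
})

test_that("ROI sweep ranks the signal-bearing region first", {
  mkCohort <- function(g, seedOff) lapply(1:5, function(i) {
    w <- tinyWorld(seed = seedOff + i, nVoxels = 25, gFuture = g)
    w
  })
  sweep <- roiSweep(list(signal = mkCohort(0.8, 400),
                         null = mkCohort(0, 500)), seed = 2)
  expect_equal(nrow(sweep$table), 2)
  expect_gt(sweep$table$estimate[sweep$table$roi == "signal"],
            sweep$table$estimate[sweep$table$roi == "null"])
  one <- roiSweep(list(only = mkCohort(0.5, 600)), seed = 3)
  expect_equal(nrow(one$table), 1)
})
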