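orthoTemplates <- function(V = 20, seed = 1) {
  set.seed(seed)
  tm <- qr.Q(qr(matrix(rnorm(V * 3), V, 3)))
  colnames(tm) <- c("face", "scene", "object")
  tm
}

test_that("noiseless orthogonal templates are classified perfectly", {
  tm <- orthoTemplates()
  loc <- templateLocalizer(tm, noiseSd = 0.01, seed = 2)
  cls <- trainPairwise(loc, seed = 1)
  expect_named(cls, c("face", "scene", "object"))
  for (cl in cls) {
    ev <- eventData(loc)
    pair <- ev$category %in% c(cl@target, cl@contrast)
    m <- betas(loc)[pair, ] %*% cl@w + cl@b
    expect_true(all((m > 0) == (ev$category[pair] == cl@target)))
  }
})

test_that("imbalanced mini-blocks are equalized by seeded discard", {
  tm <- orthoTemplates()
  set.seed(3)
  ev <- data.frame(
    category = c(rep("face", 40), rep("scene", 37), rep("object", 10)),
    miniblock = 1)
  ev <- rbind(ev, transform(ev, miniblock = 2),
              transform(ev, miniblock = 3))
  B <- t(tm[, ev$category]) + matrix(rnorm(nrow(ev) * 20, sd = 0.5),
                                     nrow(ev), 20)
  loc <- VoxelPatternSet(B, ev)
  cls <- trainPairwise(loc, seed = 9)
  expect_equal(as.integer(cls$face@trainInfo$balancedPerBlock),
               rep(37L, 3))
  expect_equal(cls$face@trainInfo$nTrain, 2L * 37L * 3L)
})

test_that("a class missing from the localizer is a hard failure", {
  tm <- orthoTemplates()
  loc <- templateLocalizer(tm[, c("face", "scene")], noiseSd = 0.1,
                           categories = c("face", "scene"))
  expect_error(trainPairwise(loc), "class absent")
})

test_that("decision values are bounded, rank-preserving, and centered", {
  tm <- orthoTemplates()
  loc <- templateLocalizer(tm, noiseSd = 0.3, seed = 4)
  cls <- trainPairwise(loc, seed = 1)
  # test events: boundary pattern plus an amplitude ramp on the target
  amps <- seq(-2, 2, by = 0.5)
  B <- rbind(matrix(0, 1, 20), t(sapply(amps, function(a) a * tm[, "face"])))
  ev <- data.frame(state = "S1",
                   onscreen_category = c("none", rep("face", length(amps))))
  dvt <- decisionValues(cls, VoxelPatternSet(B, ev))
  vals <- decisionValueMatrix(dvt)
  expect_true(all(vals >= 0 & vals <= 1))
  # boundary pattern maps to ~0.5 under symmetric balanced calibration
  expect_equal(unname(vals[1, "face"]), 0.5, tolerance = 0.05)
  # strictly increasing in planted target amplitude
  expect_true(all(diff(vals[-1, "face"]) > 0))
  # identical rank order for margins and mapped values
  mg <- marginMatrix(dvt)
  for (k in colnames(vals))
    expect_equal(cor(mg[, k], vals[, k], method = "spearman"), 1)
  # voxel-dimension mismatch is an error
  expect_error(decisionValues(cls, VoxelPatternSet(matrix(0, 2, 5),
                                                   ev[1:2, , drop = FALSE])),
               "dimension")
})

test_that("decision values are invariant to a common voxel-space rotation", {
  w <- tinyWorld(seed = 8, nVoxels = 20)
  set.seed(8)
  Q <- qr.Q(qr(matrix(rnorm(400), 20, 20)))
  rot <- function(vps) VoxelPatternSet(betas(vps) %*% Q, eventData(vps))
  v1 <- decisionValueMatrix(decisionValues(trainPairwise(w$localizer, 1),
                                           w$learning))
  v2 <- decisionValueMatrix(decisionValues(trainPairwise(rot(w$localizer), 1),
                                           rot(w$learning)))
  expect_equal(v1, v2, tolerance = 1e-6)
})

test_that("generalization AUC is perfect, antisymmetric, and null-calibrated", {
  w <- tinyWorld(seed = 5, nVoxels = 20, noiseSd = 0.01, gFuture = 0)
  res <- analyzeParticipant(w)
  auc <- generalizationAuc(res$dvt)
  expect_equal(auc$auc_minus_chance_x100, rep(50, 3))  # perfect separation
  # antisymmetry: swapping the pair labels mirrors the AUC around chance
  dvt <- res$dvt
  ev <- futurestates::dvEvents(dvt)
  swap <- ev
  swap$onscreen_category[ev$onscreen_category == "face"] <- "scene"
  swap$onscreen_category[ev$onscreen_category == "scene"] <- "face"
  dvtSwap <- new("DecisionValueTable", values = decisionValueMatrix(dvt),
                 margins = marginMatrix(dvt), events = swap, roi = "x")
  aucSwap <- generalizationAuc(dvtSwap)
  expect_equal(aucSwap$auc_minus_chance_x100[1],
               -auc$auc_minus_chance_x100[1], tolerance = 1e-9)
  # single-class input is flagged undefined
  one <- ev
  one$onscreen_category[one$state %in% c("S1", "S3")] <- "face"
  dvtOne <- new("DecisionValueTable", values = decisionValueMatrix(dvt),
                margins = marginMatrix(dvt), events = one, roi = "x")
  expect_equal(generalizationAuc(dvtOne)$flag, rep("single-class", 3))
})

test_that("label permutation centers the AUC on chance", {
  w <- tinyWorld(seed = 12, nVoxels = 20)
  res <- analyzeParticipant(w)
  ev <- futurestates::dvEvents(res$dvt)
  vals <- decisionValueMatrix(res$dvt)
  set.seed(12)
  null <- vapply(1:1000, function(i) {
    evp <- ev
    s13 <- ev$state %in% c("S1", "S3")
    evp$onscreen_category[s13] <- sample(ev$onscreen_category[s13])
    dvtp <- new("DecisionValueTable", values = vals,
                margins = marginMatrix(res$dvt), events = evp, roi = "x")
    generalizationAuc(dvtp)$auc_minus_chance_x100[1]
  }, numeric(1))
  expect_lt(abs(mean(null)), 1)
})

test_that("noise-only patterns decode at chance", {
  aucs <- vapply(1:100, function(s) {
    w <- tinyWorld(seed = 5000 + s, nVoxels = 15, aCurrent = 0,
                   aLocalizer = 0, gFuture = 0)
    res <- analyzeParticipant(w, seed = s)
    mean(generalizationAuc(res$dvt)$auc, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("exclusion rule tracks cross-phase generalization", {
  w <- tinyWorld(seed = 6, nVoxels = 20, noiseSd = 0.2)
  res <- analyzeParticipant(w)
  chk <- exclusionCheck(res$dvt)
  expect_true(all(chk$categories$valid))
  expect_true(chk$includeParticipant)
  # anti-learned patterns: flip the learning-phase signal
  flip <- VoxelPatternSet(-betas(w$learning), eventData(w$learning))
  dvtF <- decisionValues(res$classifiers, flip)
  chkF <- exclusionCheck(dvtF)
  expect_false(any(chkF$categories$valid))
  expect_false(chkF$includeParticipant)
})

test_that("chance-level generalization excludes about half per category", {
  flags <- vapply(1:60, function(s) {
    w <- tinyWorld(seed = 9000 + s, nVoxels = 12, aCurrent = 0,
                   aLocalizer = 0.5, gFuture = 0)
    chk <- exclusionCheck(analyzeParticipant(w, seed = s)$dvt)
    mean(chk$categories$valid)
  }, numeric(1))
  # per-category exclusion should hover around 50% under the null
  expect_gt(mean(flags), 0.3)
  expect_lt(mean(flags), 0.7)
})
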