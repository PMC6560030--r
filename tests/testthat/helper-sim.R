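# shared fixtures: all synthetic, built in code at test time

# one participant's full world at reduced voxel count
tinyWorld <- function(seed = 1, nVoxels = 20, gFuture = 0.8, noiseSd = 1,
                      aCurrent = 1, aLocalizer = 1, ...) {
  d <- generateDesign(seed = seed)
  b <- simulateBehavior(d, seed = seed)
  tr <- simTruth(nVoxels = nVoxels, aCurrent = aCurrent,
                 aLocalizer = aLocalizer, gFuture = gFuture,
                 noiseSd = noiseSd, seed = seed, ...)
  c(list(design = d, behavior = b, truth = tr),
    simulatePatterns(d, b, tr))
}

# train, decode, and fit the category models for one simulated participant
analyzeParticipant <- function(world, seed = 1, ...) {
  cl <- trainPairwise(world$localizer, seed = seed)
  dvt <- decisionValues(cl, world$learning)
  list(classifiers = cl, dvt = dvt,
       models = fitParticipantModels(dvt, world$design, world$behavior, ...))
}

# one full cohort replication: group inference on the future x rep effect
cohortReplication <- function(seed, gFuture, n = 30, nVoxels = 100) {
  cohort <- simulateCohort(nParticipants = n, seed = seed,
                           gFuture = gFuture, nVoxels = nVoxels)
  fits <- lapply(seq_along(cohort), function(i) {
    p <- cohort[[i]]
    cl <- trainPairwise(p$localizer, seed = childSeed(seed, 300 + i))
    dvt <- decisionValues(cl, p$learning)
    fitParticipantModels(dvt, p$design, p$behavior)
  })
  agg <- suppressMessages(aggregateAndInfer(fits))
  g <- agg$group
  row <- g[g$predictor == "future_x_rep", ]
  x <- agg$participantMeans[, "future_x_rep"]
  bound <- tostBoundForPower(length(x), 0.80, 0.05)
  list(p = row$p, estimate = row$mean, d = row$cohen_d,
       tostEquivalent = isTRUE(tostTest(x, bound)$equivalent),
       participantMeans = agg$participantMeans, group = g)
}

childSeed <- futurestates:::childSeed

# synthetic localizer pattern set built directly from templates
templateLocalizer <- function(tm, perBlock = 10, noiseSd = 0, seed = 1,
                              categories = colnames(tm)) {
  set.seed(seed)
  ev <- expand.grid(rep = seq_len(perBlock), category = categories,
                    miniblock = 1:3, stringsAsFactors = FALSE)
  B <- t(tm[, ev$category]) +
    matrix(rnorm(nrow(ev) * nrow(tm), sd = noiseSd), nrow(ev), nrow(tm))
  VoxelPatternSet(B, ev[c("category", "miniblock")], roi = "synthetic")
}
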