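# Orchestration: configuration, staged execution with provenance, and
# report generation for the end-to-end parameter-recovery analysis.

#' Pipeline configuration
#'
#' A single serializable list from which every stage derives its
#' parameters; all randomness flows from the one master seed through named
#' sub-streams.  Re-running a stage with an identical configuration is
#' bit-reproducible.
#'
#' @param seed master seed.
#' @param nParticipants cohort size.
#' @param nVoxels,aCurrent,aLocalizer,gFuture,noiseSd generative
#'   parameters, see [simTruth()].
#' @param pLearnAfterReward,pLearnAfterLoss behavioral parameters.
#' @param covariateCoding `"observed"` or `"correct_only"`.
#' @param center mean-center regression predictors.
#' @param roi ROI label.
#' @param tostPowerTarget,alpha group-inference settings; the equivalence
#'   bound is derived from the realized sample size at this power.
#' @return list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1, nParticipants = 30, nVoxels = 100,
                           aCurrent = 1, aLocalizer = 1, gFuture = 0.8,
                           noiseSd = 1, pLearnAfterReward = 0.821,
                           pLearnAfterLoss = 0.714,
                           covariateCoding = "observed", center = FALSE,
                           roi = "OFC-VMPFC", tostPowerTarget = 0.80,
                           alpha = 0.05) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipelineConfig")
}

#' @export
print.pipelineConfig <- function(x, ...) {
  cat("pipelineConfig (hash", configHash(x), ")\n")
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Configuration hash used for artifact provenance
#' @param config a `"pipelineConfig"`.
#' @return md5 string of the serialized configuration.
#' @export
configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

stageFiles <- list(
  simulate = c("behavior.tsv", "learning_events.tsv", "localizer_events.tsv",
               "learning_betas.tsv", "localizer_betas.tsv", "truth.json"),
  behavior = "behavior_stats.json",
  glm = "univariate.json",
  decode = "decision_values.tsv",
  dvreg = c("fits.tsv", "group.json", "per_bin.tsv"),
  ppi = "ppi.json")

rebuildCohort <- function(config) {
  simulateCohort(nParticipants = config$nParticipants, seed = config$seed,
                 nVoxels = config$nVoxels, aCurrent = config$aCurrent,
                 aLocalizer = config$aLocalizer, gFuture = config$gFuture,
                 noiseSd = config$noiseSd,
                 pLearnAfterReward = config$pLearnAfterReward,
                 pLearnAfterLoss = config$pLearnAfterLoss,
                 roi = config$roi)
}

#' Run pipeline stages
#'
#' Executes one stage (or `"all"`: simulate, behavior, glm, decode, dvreg,
#' ppi) and writes its artifacts to `outDir`.  Every artifact embeds the
#' configuration hash; stages refuse to consume artifacts produced under a
#' different configuration, and report which stage to run first when an
#' upstream artifact is missing.
#'
#' @param stage one of `"simulate"`, `"behavior"`, `"glm"`, `"decode"`,
#'   `"dvreg"`, `"ppi"`, `"all"`.
#' @param config a [pipelineConfig()].
#' @param outDir artifact directory (created if needed).
#' @return invisibly, the vector of artifact paths written.
#' @export
runPipeline <- function(stage = c("all", "simulate", "behavior", "glm",
                                  "decode", "dvreg", "ppi"),
                        config = pipelineConfig(), outDir = tempdir()) {
  stage <- match.arg(stage)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  stages <- if (stage == "all")
    c("simulate", "behavior", "glm", "decode", "dvreg", "ppi") else stage
  written <- character(0)
  for (s in stages)
    written <- c(written, runStage(s, config, outDir, hash))
  writeArtifactJson(unclass(config), file.path(outDir, "config.json"), hash)
  invisible(written)
}

runStage <- function(stage, config, outDir, hash) {
  p <- function(f) file.path(outDir, f)
  switch(stage,
    simulate = {
      cohort <- rebuildCohort(config)
      bindP <- function(field) do.call(rbind, lapply(seq_along(cohort),
        function(i) cbind(participant = i, cohort[[i]][[field]])))
      writeArtifactTsv(bindP("behavior"), p("behavior.tsv"), hash)
      ev <- do.call(rbind, lapply(seq_along(cohort), function(i)
        cbind(participant = i, eventData(cohort[[i]]$learning))))
      writeArtifactTsv(ev, p("learning_events.tsv"), hash)
      loc <- do.call(rbind, lapply(seq_along(cohort), function(i)
        cbind(participant = i, eventData(cohort[[i]]$localizer))))
      writeArtifactTsv(loc, p("localizer_events.tsv"), hash)
      bmat <- function(field) do.call(rbind, lapply(seq_along(cohort),
        function(i) {
          b <- betas(cohort[[i]][[field]])
          colnames(b) <- sprintf("v%04d", seq_len(ncol(b)))
          cbind(data.frame(participant = i, event = seq_len(nrow(b))),
                as.data.frame(b))
        }))
      writeArtifactTsv(bmat("learning"), p("learning_betas.tsv"), hash)
      writeArtifactTsv(bmat("localizer"), p("localizer_betas.tsv"), hash)
      tr <- cohort[[1]]$truth
      writeArtifactJson(list(aCurrent = tr@aCurrent,
                             aLocalizer = tr@aLocalizer,
                             gFuture = tr@gFuture, noiseSd = tr@noiseSd,
                             tr = tr@tr, nVoxels = nrow(templates(tr)),
                             seed = config$seed),
                        p("truth.json"), hash)
      unlist(lapply(stageFiles$simulate, p))
    },
    behavior = {
      bh <- readArtifactTsv(p("behavior.tsv"), hash, "simulate")
      bl <- split(bh, bh$participant)
      acc <- accuracyByRepetition(bl)
      spl <- suppressMessages(initialFeedbackSplit(bl))
      writeArtifactJson(list(accuracy_by_repetition = acc,
                             initial_feedback_split = spl[1:3],
                             n_excluded_from_split = spl$nExcluded),
                        p("behavior_stats.json"), hash)
      p("behavior_stats.json")
    },
    glm = {
      cohort <- cohortFromArtifacts(config, outDir, hash)
      dec <- univariateDecayModel(lapply(cohort, `[[`, "learning"))
      rew <- rewardFeedbackModel(lapply(cohort, `[[`, "learning"),
                                 includeRest = TRUE)
      writeArtifactJson(list(decay_modulator = decayModulator(1:4),
                             decay_effect = dec$group,
                             reward_effect = rew$group),
                        p("univariate.json"), hash)
      p("univariate.json")
    },
    decode = {
      cohort <- cohortFromArtifacts(config, outDir, hash)
      rows <- lapply(seq_along(cohort), function(i) {
        cl <- trainPairwise(cohort[[i]]$localizer,
                            seed = childSeed(config$seed, 300 + i))
        dvt <- decisionValues(cl, cohort[[i]]$learning)
        vals <- decisionValueMatrix(dvt)
        colnames(vals) <- paste0("value_", colnames(vals))
        mg <- marginMatrix(dvt)
        colnames(mg) <- paste0("margin_", colnames(mg))
        cbind(data.frame(participant = i, event = seq_len(nrow(vals))),
              as.data.frame(vals), as.data.frame(mg))
      })
      writeArtifactTsv(do.call(rbind, rows), p("decision_values.tsv"), hash)
      p("decision_values.tsv")
    },
    dvreg = {
      cohort <- cohortFromArtifacts(config, outDir, hash)
      dv <- readArtifactTsv(p("decision_values.tsv"), hash, "decode")
      fits <- lapply(seq_along(cohort), function(i) {
        dvt <- dvTableFromArtifact(dv, i, cohort[[i]]$learning)
        fitParticipantModels(dvt, cohort[[i]]$design,
                             cohort[[i]]$behavior,
                             coding = config$covariateCoding,
                             center = config$center)
      })
      agg <- suppressMessages(aggregateAndInfer(fits))
      nInc <- agg$group$n[1]
      bound <- tostBoundForPower(nInc, config$tostPowerTarget, config$alpha)
      tostCur <- tostTest(agg$participantMeans[, "current_x_rep"], bound,
                          config$alpha)
      tostFut <- tostTest(agg$participantMeans[, "future_x_rep"], bound,
                          config$alpha)
      fitTab <- do.call(rbind, lapply(seq_along(fits), function(i)
        cbind(participant = i, fits[[i]]$fits,
              valid = fits[[i]]$valid[fits[[i]]$fits$category])))
      writeArtifactTsv(fitTab, p("fits.tsv"), hash)
      perBin <- lapply(seq_along(cohort), function(i) {
        dvt <- dvTableFromArtifact(dv, i, cohort[[i]]$learning)
        pb <- suppressMessages(perBinModels(dvt, cohort[[i]]$design,
                                            cohort[[i]]$behavior,
                                            coding = config$covariateCoding))
        if (!is.null(pb)) cbind(participant = i, pb) else NULL
      })
      writeArtifactTsv(do.call(rbind, perBin), p("per_bin.tsv"), hash)
      writeArtifactJson(list(group = agg$group, n_dropped = agg$nDropped,
                             tost_bound_d = bound,
                             tost_current_x_rep = tostCur,
                             tost_future_x_rep = tostFut),
                        p("group.json"), hash)
      unlist(lapply(stageFiles$dvreg, p))
    },
    ppi = {
      grp <- readArtifactJson(p("group.json"), hash, "dvreg")
      fits <- readArtifactTsv(p("fits.tsv"), hash, "dvreg")
      covar <- tapply(fits$future_x_rep[fits$valid],
                      fits$participant[fits$valid], mean)
      cohort <- cohortFromArtifacts(config, outDir, hash)
      parts <- lapply(seq_along(cohort), function(i)
        simulatePpiTimecourses(cohort[[i]], gain = config$gFuture,
                               seed = childSeed(config$seed, 400 + i)))
      res <- learningPpi(parts, as.numeric(covar[as.character(
        seq_along(cohort))]))
      writeArtifactJson(list(group = res$group,
                             covariate_correlation =
                               res$covariateCorrelation),
                        p("ppi.json"), hash)
      p("ppi.json")
    },
    stop("unknown stage: ", stage))
}

# reconstitute per-participant VoxelPatternSets from simulate artifacts
cohortFromArtifacts <- function(config, outDir, hash) {
  p <- function(f) file.path(outDir, f)
  for (f in stageFiles$simulate)
    if (!file.exists(p(f)))
      stop("missing artifact '", f, "'; run stage 'simulate' first",
           call. = FALSE)
  bh <- readArtifactTsv(p("behavior.tsv"), hash, "simulate")
  ev <- readArtifactTsv(p("learning_events.tsv"), hash, "simulate")
  loc <- readArtifactTsv(p("localizer_events.tsv"), hash, "simulate")
  lb <- readArtifactTsv(p("learning_betas.tsv"), hash, "simulate")
  cb <- readArtifactTsv(p("localizer_betas.tsv"), hash, "simulate")
  vcols <- grep("^v[0-9]+$", names(lb))
  lapply(sort(unique(bh$participant)), function(i) {
    # designs are deterministic given the per-participant derived seed
    ps <- childSeed(config$seed, 100 + i)
    list(design = generateDesign(seed = ps),
         behavior = bh[bh$participant == i, -1],
         localizer = VoxelPatternSet(
           as.matrix(cb[cb$participant == i, vcols]),
           loc[loc$participant == i, -1], roi = config$roi),
         learning = VoxelPatternSet(
           as.matrix(lb[lb$participant == i, vcols]),
           ev[ev$participant == i, -1], roi = config$roi))
  })
}

dvTableFromArtifact <- function(dv, i, learning) {
  d <- dv[dv$participant == i, ]
  d <- d[order(d$event), ]
  vals <- as.matrix(d[, grep("^value_", names(d))])
  mg <- as.matrix(d[, grep("^margin_", names(d))])
  colnames(vals) <- sub("^value_", "", colnames(vals))
  colnames(mg) <- sub("^margin_", "", colnames(mg))
  new("DecisionValueTable", values = vals, margins = mg,
      events = eventData(learning), roi = roiLabel(learning))
}

# synthetic seed/target ROI timecourses whose state-1 coupling grows with
# learning in proportion to `gain`; used by the ppi stage.  Blocks are
# concatenated onto one run so that early and late repetitions share a
# timecourse.
simulatePpiTimecourses <- function(participant, gain, seed, blockLen = 700,
                                   tr = 1.24) {
  set.seed(seed)
  ev <- eventData(participant$learning)
  ev$onset <- ev$onset + (ev$block - 1) * blockLen
  nScans <- ceiling(4 * blockLen / tr)
  seedTc <- rnorm(nScans)
  w <- ifelse(ev$state == "S1" & ev$repetition >= 3, 1,
              ifelse(ev$state == "S1", -1, 0))
  mod <- if (any(w != 0))
    buildPsych(ev[w != 0, ], w[w != 0], nScans, tr,
               c(peak = 6, undershoot = 16, ratio = 6)) else numeric(nScans)
  target <- 0.5 * seedTc + gain * mod * seedTc + rnorm(nScans, sd = 0.5)
  list(seedTc = seedTc, targetTc = target, events = ev,
       behavior = participant$behavior)
}

#' Summarize pipeline artifacts
#'
#' Prints a human-readable summary of whatever artifacts exist in
#' `outDir` — behavioral learning curve, univariate effects, the group
#' decision-value regression table with its equivalence tests, and the
#' per-bin current/future breakdown — and flags the qualitative checks the
#' analysis is designed around (is the future-by-repetition effect
#' present? is the current-by-repetition effect equivalent to null? does
#' the per-bin future effect increase?).  An empty directory yields an
#' empty report rather than an error.
#'
#' @param outDir artifact directory used by [runPipeline()].
#' @param config the configuration the artifacts were produced under; when
#'   NULL, the stored `config.json` is used.
#' @return invisibly, a list with the collected tables and check flags.
#' @export
pipelineReport <- function(outDir, config = NULL) {
  cfgPath <- file.path(outDir, "config.json")
  if (is.null(config)) {
    if (!file.exists(cfgPath)) {
      cat("pipeline report: no artifacts found in", outDir, "\n")
      return(invisible(list()))
    }
    config <- do.call(pipelineConfig, within(
      jsonlite::read_json(cfgPath, simplifyVector = TRUE),
      rm(config_hash)))
  }
  hash <- configHash(config)
  out <- list()
  rd <- function(f, reader) {
    path <- file.path(outDir, f)
    if (file.exists(path)) reader(path, hash, "?") else NULL
  }
  out$behavior <- rd("behavior_stats.json", readArtifactJson)
  out$univariate <- rd("univariate.json", readArtifactJson)
  out$group <- rd("group.json", readArtifactJson)
  out$perBin <- rd("per_bin.tsv", readArtifactTsv)
  out$ppi <- rd("ppi.json", readArtifactJson)

  cat("== pipeline report (config", hash, ") ==\n")
  if (!is.null(out$behavior)) {
    cat("\nLearning accuracy by repetition:\n")
    print(out$behavior$accuracy_by_repetition, digits = 3)
  }
  if (!is.null(out$group)) {
    cat("\nGroup decision-value regression:\n")
    print(out$group$group, digits = 3)
    cat(sprintf("\nTOST bound d = %.3f\n", out$group$tost_bound_d))
    checks <- list(
      future_x_rep_significant =
        isTRUE(out$group$group$p[out$group$group$predictor ==
                                   "future_x_rep"] < config$alpha),
      current_x_rep_equivalent =
        isTRUE(out$group$tost_current_x_rep$equivalent),
      future_x_rep_equivalent =
        isTRUE(out$group$tost_future_x_rep$equivalent))
    out$checks <- checks
    cat("checks:",
        paste(names(checks), unlist(checks), sep = "=", collapse = ", "),
        "\n")
  }
  if (!is.null(out$perBin)) {
    pb <- aggregate(cbind(current, future) ~ bin, out$perBin, mean)
    out$perBinGroup <- pb
    cat("\nPer-bin mean coefficients (across participants):\n")
    print(pb, digits = 3)
    if (nrow(pb) >= 2) {
      inc <- coef(lm(future ~ bin, pb))[2] > 0
      out$checks$per_bin_future_increasing <- unname(inc)
      cat("per-bin future effect increasing:", unname(inc), "\n")
    }
  }
  if (!is.null(out$ppi)) {
    cat("\nLearning PPI: group estimate",
        sprintf("%.4f (p=%.3g);", out$ppi$group$mean, out$ppi$group$p),
        "covariate r =",
        sprintf("%.3f (p=%.3g)\n", out$ppi$covariate_correlation$r,
                out$ppi$covariate_correlation$p))
  }
  if (!length(out)) cat("no artifacts found\n")
  invisible(out)
}
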