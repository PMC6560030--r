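# Pairwise linear-SVM training on localizer betas, cross-phase application
# to learning-phase betas, decision-value extraction, AUC generalization,
# and the per-category / per-participant exclusion rules.

PAIR_SCHEME <- list(face = "scene", scene = "face", object = "face")

# equalize class counts within each mini-block by seeded random discard
balanceMiniBlocks <- function(idxA, idxB, miniblock) {
  keep <- integer(0)
  for (b in unique(miniblock)) {
    a <- idxA[miniblock[idxA] == b]
    bb <- idxB[miniblock[idxB] == b]
    k <- min(length(a), length(bb))
    keep <- c(keep, sample(a)[seq_len(k)], sample(bb)[seq_len(k)])
  }
  sort(keep)
}

#' Train the three pairwise category classifiers
#'
#' Linear L2-regularized support-vector machines (LIBSVM via \pkg{e1071})
#' with a fixed cost C = 1, trained on localizer-phase betas under the
#' fixed pairing scheme: faces vs scenes, scenes vs faces, and objects vs
#' faces.  Class counts are equalized within each localizer mini-block by
#' seeded random discard before training.  A logistic (Platt-style)
#' calibration of the training margins is fitted alongside each classifier
#' so that test margins can be mapped to decision values in \[0, 1\].
#'
#' @param localizer a [VoxelPatternSet-class] of localizer betas whose
#'   event metadata has `category` and `miniblock` columns.
#' @param seed integer seed for the balancing discard.
#' @return named list of three [PairwiseClassifier-class] objects.
#' @export
trainPairwise <- function(localizer, seed = 1) {
  ev <- eventData(localizer)
  B <- betas(localizer)
  stopIfNot(all(c("category", "miniblock") %in% names(ev)),
            "localizer events need 'category' and 'miniblock' columns")
  set.seed(childSeed(seed, 21))
  out <- lapply(names(PAIR_SCHEME), function(target) {
    contrast <- PAIR_SCHEME[[target]]
    iT <- which(ev$category == target)
    iC <- which(ev$category == contrast)
    if (!length(iT) || !length(iC))
      stop("class absent from localizer: ",
           if (!length(iT)) target else contrast)
    mb <- ev$miniblock
    stopIfNot(length(intersect(unique(mb[iT]), unique(mb[iC]))) >= 2,
              "need both pair classes in at least 2 mini-blocks")
    keep <- balanceMiniBlocks(iT, iC, mb)
    x <- B[keep, , drop = FALSE]
    y <- factor(ifelse(ev$category[keep] == target, "target", "contrast"),
                levels = c("target", "contrast"))
    fit <- e1071::svm(x, y, kernel = "linear", cost = 1, scale = FALSE)
    w <- drop(crossprod(fit$coefs, fit$SV))
    b <- -fit$rho
    # orient so that a larger margin means more target-like
    dvName <- colnames(attr(predict(fit, x[1, , drop = FALSE],
                                    decision.values = TRUE),
                            "decision.values"))
    if (identical(dvName, paste0(contrast, "/", target)) ||
        identical(dvName, "contrast/target")) { w <- -w; b <- -b }
    margins <- drop(x %*% w + b)
    platt <- fitPlatt(margins, y == "target")
    counts <- table(mb[keep]) / 2
    new("PairwiseClassifier", target = target, contrast = contrast,
        w = w, b = b, cost = 1, platt = platt,
        trainInfo = list(balancedPerBlock = counts, seed = seed,
                         nTrain = length(keep)))
  })
  names(out) <- names(PAIR_SCHEME)
  out
}

# logistic calibration of margins; regularized targets as in Platt (1999)
# keep the fit finite under perfect separation
fitPlatt <- function(margins, isTarget) {
  nP <- sum(isTarget); nN <- sum(!isTarget)
  yReg <- ifelse(isTarget, (nP + 1) / (nP + 2), 1 / (nN + 2))
  fit <- suppressWarnings(glm(yReg ~ margins, family = binomial()))
  cf <- coef(fit)
  if (any(!is.finite(cf))) cf <- c(0, 1)
  setNames(unname(cf), c("a", "b"))
}

#' Derive decision values for learning-phase events
#'
#' Applies trained pairwise classifiers to every learning-phase event
#' pattern: the raw margin is the linear decision function, and the
#' decision value maps that margin through the classifier's localizer-fit
#' logistic link into \[0, 1\], preserving rank order.  A pattern on the
#' decision boundary maps to 0.5 when the calibration is symmetric.
#'
#' @param classifiers list of [PairwiseClassifier-class] from
#'   [trainPairwise()].
#' @param learning a [VoxelPatternSet-class] of learning-phase betas with
#'   the same voxel dimension as the training data.
#' @return a [DecisionValueTable-class].
#' @export
decisionValues <- function(classifiers, learning) {
  B <- betas(learning)
  margins <- sapply(classifiers, function(cl) {
    stopIfNot(length(cl@w) == ncol(B),
              "voxel dimension mismatch between classifier and patterns")
    drop(B %*% cl@w + cl@b)
  })
  values <- sapply(seq_along(classifiers), function(i) {
    p <- classifiers[[i]]@platt
    plogis(p["a"] + p["b"] * margins[, i])
  })
  colnames(values) <- colnames(margins) <- names(classifiers)
  new("DecisionValueTable", values = values, margins = margins,
      events = eventData(learning), roi = roiLabel(learning))
}

#' Cross-phase generalization AUC
#'
#' For each category classifier, the area under the ROC curve of its
#' decision values for state-1 and state-3 events whose on-screen stimulus
#' was the target versus the contrast category.  Reported chance-relative
#' and scaled, as (AUC - 0.5) x 100, alongside the raw AUC.
#'
#' @param dvt a [DecisionValueTable-class].
#' @param states which learning states to evaluate (default S1 and S3, the
#'   states with a stimulus on screen).
#' @return data.frame per category: `auc`, `auc_minus_chance_x100`, event
#'   counts, and a flag when only one class is present (AUC undefined).
#' @export
generalizationAuc <- function(dvt, states = c("S1", "S3")) {
  ev <- dvEvents(dvt)
  vals <- decisionValueMatrix(dvt)
  out <- lapply(names(PAIR_SCHEME), function(target) {
    contrast <- PAIR_SCHEME[[target]]
    use <- ev$state %in% states & ev$onscreen_category %in% c(target, contrast)
    y <- ev$onscreen_category[use] == target
    if (length(unique(y)) < 2)
      return(data.frame(category = target, auc = NA_real_,
                        auc_minus_chance_x100 = NA_real_,
                        n_target = sum(y), n_contrast = sum(!y),
                        flag = "single-class"))
    a <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = vals[use, target],
      direction = "<", quiet = TRUE)))
    data.frame(category = target, auc = a,
               auc_minus_chance_x100 = (a - 0.5) * 100,
               n_target = sum(y), n_contrast = sum(!y), flag = "")
  })
  do.call(rbind, out)
}

#' Cross-phase generalization check and exclusion rule
#'
#' A category's classifier must generalize across task phases: its decision
#' values at state 1 and state 3 (concatenated) must be positively related
#' to whether the on-screen stimulus was the target versus the contrast
#' category.  The per-category performance score is that regression
#' coefficient; a category with a non-positive coefficient is flagged
#' invalid, and a participant with no valid category is excluded entirely.
#'
#' @param dvt a [DecisionValueTable-class].
#' @return list with `categories` (data.frame of coefficients and validity
#'   flags) and `includeParticipant`.
#' @export
exclusionCheck <- function(dvt) {
  ev <- dvEvents(dvt)
  vals <- decisionValueMatrix(dvt)
  rows <- lapply(names(PAIR_SCHEME), function(target) {
    contrast <- PAIR_SCHEME[[target]]
    use <- ev$state %in% c("S1", "S3") &
      ev$onscreen_category %in% c(target, contrast)
    x <- as.numeric(ev$onscreen_category[use] == target)
    if (length(unique(x)) < 2 || sd(vals[use, target]) == 0)
      return(data.frame(category = target, coefficient = NA_real_,
                        valid = FALSE))
    cf <- unname(coef(lm(vals[use, target] ~ x))[2])
    data.frame(category = target, coefficient = cf, valid = cf > 0)
  })
  cats <- do.call(rbind, rows)
  list(categories = cats, includeParticipant = any(cats$valid))
}
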