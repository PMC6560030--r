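#' @import methods
#' @importFrom stats coef cor fitted lm pnorm pt qnorm qt rbinom rnorm runif
#'   sd setNames t.test cor.test glm binomial plogis uniroot integrate dgamma
#'   predict aggregate complete.cases convolve
#' @importFrom utils read.delim write.table head modifyList str
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

CATEGORIES <- c("face", "scene", "object")

#' Events-by-voxels pattern container
#'
#' `VoxelPatternSet` holds single-event beta patterns for one participant and
#' one region of interest, as a [SummarizedExperiment::SummarizedExperiment]
#' with voxels as rows and events as columns.  Per-event metadata (maze,
#' repetition, state, on-screen category, outcome, ...) lives in `colData`;
#' the ROI label and, for simulated data, the planted ground truth live in
#' `metadata`.
#'
#' @slot ... inherited from `SummarizedExperiment`; the single assay
#'   `"betas"` is a voxels x events numeric matrix.
#'
#' @seealso [VoxelPatternSet()], [betas()], [eventData()], [roiLabel()]
#' @export
setClass("VoxelPatternSet", contains = "SummarizedExperiment")

setValidity("VoxelPatternSet", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!("betas" %in% a))
    return("assay 'betas' is required")
  if (any(!is.finite(SummarizedExperiment::assay(object, "betas"))))
    return("beta matrix must be finite")
  TRUE
})

#' Construct a VoxelPatternSet
#'
#' @param betas numeric matrix of single-event beta estimates,
#'   events x voxels (one row per modeled event).
#' @param events data.frame of per-event metadata, one row per event.
#' @param roi character ROI label.
#' @param truth optional [SimTruth-class] object retained for
#'   parameter-recovery tests.
#' @return a [VoxelPatternSet-class] object.
#' @examples
#' vps <- VoxelPatternSet(matrix(rnorm(20), 4, 5),
#'                        data.frame(state = c("S1","S2","S3","FEEDBACK")),
#'                        roi = "OFC-VMPFC")
#' nEvents(vps)
#' @export
VoxelPatternSet <- function(betas, events, roi = "ROI", truth = NULL) {
  betas <- as.matrix(betas)
  events <- as.data.frame(events)
  if (nrow(betas) != nrow(events))
    stop("number of beta rows (events) must equal number of event records")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(betas = t(betas)),
    colData = S4Vectors::DataFrame(events))
  md <- list(roi = roi)
  if (!is.null(truth)) md$truth <- truth
  S4Vectors::metadata(se) <- md
  new("VoxelPatternSet", se)
}

#' @describeIn VoxelPatternSet events x voxels beta matrix.
#' @param x a `VoxelPatternSet`.
#' @export
betas <- function(x) t(SummarizedExperiment::assay(x, "betas"))

#' @describeIn VoxelPatternSet per-event metadata as a base data.frame.
#' @export
eventData <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn VoxelPatternSet ROI label.
#' @export
roiLabel <- function(x) S4Vectors::metadata(x)$roi

#' @describeIn VoxelPatternSet planted ground truth (or NULL).
#' @export
simTruthOf <- function(x) S4Vectors::metadata(x)$truth

#' @describeIn VoxelPatternSet number of modeled events.
#' @export
nEvents <- function(x) ncol(x)

#' @describeIn VoxelPatternSet number of voxels.
#' @export
nVoxels <- function(x) nrow(x)

setMethod("show", "VoxelPatternSet", function(object) {
  cat("VoxelPatternSet:", nVoxels(object), "voxels x",
      nEvents(object), "events; ROI:", roiLabel(object), "\n")
  st <- eventData(object)$state
  if (!is.null(st)) {
    tab <- table(st)
    cat("  states:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(simTruthOf(object))) cat("  carries planted simulation truth\n")
})

#' Planted simulation ground truth
#'
#' Parameters of the generative model behind the synthetic voxel patterns:
#' orthonormal category templates, the amplitude of the on-screen (current
#' state) signal, the localizer amplitude, the slope with which evidence for
#' the correct distal state grows per correct repetition, and pattern noise.
#'
#' @slot templates V x 3 matrix of mutually orthonormal category templates
#'   (columns named face/scene/object).
#' @slot aCurrent amplitude of the on-screen category signal during learning.
#' @slot aLocalizer amplitude of the category signal in localizer patterns.
#' @slot gFuture slope of the future-state signal per correct repetition
#'   (0 gives a null world).
#' @slot noiseSd standard deviation of i.i.d. Gaussian pattern noise.
#' @slot tr repetition time in seconds (1.24 by default).
#' @slot hrfParams double-gamma HRF parameters (peak, undershoot, ratio).
#' @slot seed integer seed from which all pattern noise derives.
#' @slot extras optional planted signals for control analyses
#'   (`gFutureS2`, `s3DecaySlope`, `pastFeedbackGain`).
#' @export
setClass("SimTruth",
  representation(templates = "matrix", aCurrent = "numeric",
                 aLocalizer = "numeric", gFuture = "numeric",
                 noiseSd = "numeric", tr = "numeric", hrfParams = "numeric",
                 seed = "integer", extras = "list"))

setValidity("SimTruth", function(object) {
  tm <- object@templates
  if (ncol(tm) < 3 || nrow(tm) < ncol(tm))
    return("need at least as many voxels as categories (>= 3)")
  g <- crossprod(tm)
  if (max(abs(g - diag(ncol(tm)))) > 1e-8)
    return("category templates must be orthonormal")
  if (object@gFuture < 0) return("gFuture must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' Create planted simulation parameters
#'
#' Category templates are drawn orthonormal via QR decomposition of a seeded
#' Gaussian matrix, so planted current- and future-state signals are exactly
#' orthogonal and cannot confound one another.
#'
#' @param nVoxels number of voxels V in the simulated ROI.
#' @param aCurrent,aLocalizer,gFuture,noiseSd generative amplitudes; see
#'   [SimTruth-class].
#' @param tr repetition time in seconds.
#' @param hrfParams named numeric vector `c(peak=, undershoot=, ratio=)` of
#'   double-gamma HRF parameters.
#' @param seed integer seed.
#' @param gFutureS2 future-state slope planted at state 2 (default 0).
#' @param s3DecaySlope change of the on-screen state-3 amplitude per correct
#'   repetition (negative values plant suppression; default 0).
#' @param pastFeedbackGain amplitude of past-state (state 1/state 3)
#'   templates planted at feedback (default 0).
#' @return a [SimTruth-class] object.
#' @examples
#' tr <- simTruth(nVoxels = 20, seed = 1)
#' crossprod(templates(tr))[1:3, 1:3]  # identity: orthonormal templates
#' @export
simTruth <- function(nVoxels = 100, aCurrent = 1, aLocalizer = 1,
                     gFuture = 0.8, noiseSd = 1, tr = 1.24,
                     hrfParams = c(peak = 6, undershoot = 16, ratio = 6),
                     seed = 1L, gFutureS2 = 0, s3DecaySlope = 0,
                     pastFeedbackGain = 0) {
  if (nVoxels < 3)
    stop("nVoxels must be at least the number of categories (3)")
  set.seed(seed)
  tm <- qr.Q(qr(matrix(rnorm(nVoxels * 3), nVoxels, 3)))
  colnames(tm) <- CATEGORIES
  new("SimTruth", templates = tm, aCurrent = aCurrent,
      aLocalizer = aLocalizer, gFuture = gFuture, noiseSd = noiseSd,
      tr = tr, hrfParams = hrfParams, seed = as.integer(seed),
      extras = list(gFutureS2 = gFutureS2, s3DecaySlope = s3DecaySlope,
                    pastFeedbackGain = pastFeedbackGain))
}

#' @describeIn simTruth the V x 3 orthonormal template matrix.
#' @param x a `SimTruth` object.
#' @export
templates <- function(x) x@templates

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@templates), "voxels;",
      "aCurrent =", object@aCurrent, "| aLocalizer =", object@aLocalizer,
      "| gFuture =", object@gFuture, "| noiseSd =", object@noiseSd, "\n")
})

#' Pairwise linear classifier
#'
#' One linear support-vector classifier discriminating a target category
#' from its fixed contrast category (faces vs scenes, scenes vs faces,
#' objects vs faces), trained on localizer patterns with a fixed cost C = 1,
#' plus the logistic (Platt-style) calibration that maps raw margins to
#' decision values in \[0, 1\].
#'
#' @slot target,contrast category names.
#' @slot w voxel weight vector of the linear decision function.
#' @slot b intercept of the decision function.
#' @slot cost SVM cost parameter (fixed at 1).
#' @slot platt intercept and slope of the margin-to-value logistic link.
#' @slot trainInfo list with balanced per-mini-block counts and the seed
#'   used for the random discard.
#' @export
setClass("PairwiseClassifier",
  representation(target = "character", contrast = "character",
                 w = "numeric", b = "numeric", cost = "numeric",
                 platt = "numeric", trainInfo = "list"))

setMethod("show", "PairwiseClassifier", function(object) {
  cat(sprintf("PairwiseClassifier: %s vs %s (C = %g, %d voxels)\n",
              object@target, object@contrast, object@cost, length(object@w)))
})

#' Per-event decision values
#'
#' Decision values in \[0, 1\] for each learning-phase event under each
#' category classifier, together with the raw margins and the event metadata
#' the values align with.
#'
#' @slot values events x categories matrix of calibrated decision values.
#' @slot margins events x categories matrix of raw SVM margins.
#' @slot events per-event metadata (one row per event).
#' @slot roi ROI label carried through from the pattern set.
#' @export
setClass("DecisionValueTable",
  representation(values = "matrix", margins = "matrix",
                 events = "data.frame", roi = "character"))

setValidity("DecisionValueTable", function(object) {
  if (any(object@values < -1e-9 | object@values > 1 + 1e-9))
    return("decision values must lie in [0, 1]")
  if (!identical(dim(object@values), dim(object@margins)))
    return("values and margins must have identical dimensions")
  if (nrow(object@values) != nrow(object@events))
    return("one event record per value row is required")
  TRUE
})

#' @describeIn DecisionValueTable decision-value matrix.
#' @param x a `DecisionValueTable`.
#' @export
decisionValueMatrix <- function(x) x@values

#' @describeIn DecisionValueTable raw margin matrix.
#' @export
marginMatrix <- function(x) x@margins

#' @describeIn DecisionValueTable aligned event metadata.
#' @export
dvEvents <- function(x) x@events

setMethod("show", "DecisionValueTable", function(object) {
  cat("DecisionValueTable:", nrow(object@values), "events x",
      ncol(object@values), "categories; ROI:", object@roi, "\n")
})
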