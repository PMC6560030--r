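# Canonical double-gamma HRF and event-regressor convolution.
#
# Regressors are built at a microtime resolution of 16 bins per TR:
# a boxcar of the event duration is convolved with the HRF sampled on the
# microtime grid and then down-sampled at scan times (0-based scan
# indexing, onsets in seconds).

#' Canonical double-gamma hemodynamic response function
#'
#' The SPM-style canonical shape: a gamma density peaking at `peak` seconds
#' minus an undershoot gamma peaking at `undershoot` seconds scaled by
#' 1/`ratio`, normalized to unit peak.
#'
#' @param t time in seconds (vector).
#' @param peak time-to-peak of the positive lobe (s).
#' @param undershoot time-to-peak of the undershoot (s).
#' @param ratio peak-to-undershoot amplitude ratio.
#' @return numeric vector of HRF values at `t`.
#' @examples
#' t <- seq(0, 30, by = 0.1)
#' t[which.max(canonicalHRF(t))]   # peaks near 5 s
#' @export
canonicalHRF <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  # shape/scale chosen as in the common double-gamma parameterization
  h <- dgamma(t, shape = peak, rate = 1) -
    dgamma(t, shape = undershoot, rate = 1) / ratio
  h[t < 0] <- 0
  m <- max(h)
  if (m > 0) h <- h / m
  h
}

# time x events matrix of convolved regressors
# onsets/durations in seconds; nScans scans at the given TR
convolveEvents <- function(onsets, durations, nScans, tr,
                           oversample = 16, hrfParams = c(peak = 6,
                                                          undershoot = 16,
                                                          ratio = 6)) {
  stopIfNot(length(onsets) == length(durations),
            "onsets and durations must have equal length")
  runEnd <- nScans * tr
  if (length(onsets) && any(onsets + durations > runEnd))
    stop("event extends beyond the end of the run (",
         sprintf("%.1f s > %.1f s", max(onsets + durations), runEnd), ")")
  dt <- tr / oversample
  nFine <- nScans * oversample
  hrf <- canonicalHRF(seq(0, 32, by = dt), hrfParams["peak"],
                      hrfParams["undershoot"], hrfParams["ratio"])
  X <- matrix(0, nScans, length(onsets))
  scanIdx <- seq(1, by = oversample, length.out = nScans)  # 0-based scan times
  for (j in seq_along(onsets)) {
    box <- numeric(nFine)
    i0 <- floor(onsets[j] / dt) + 1
    i1 <- min(nFine, ceiling((onsets[j] + durations[j]) / dt))
    box[i0:i1] <- 1
    conv <- convolve(box, rev(hrf), type = "open")[seq_len(nFine)]
    X[, j] <- conv[scanIdx]
  }
  X
}
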