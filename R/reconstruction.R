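#' Apply the calibration corrections to a light record
#'
#' The corrected light is \code{qc = q * k1 * k2}: the lateral correction of
#' the leaf's ROI times the output-drift correction of the frame's time.
#' The corrected light is then accumulated into per-projection sums S and
#' per-frame means meanS, which the open/closed threshold is compared
#' against.  With \code{method = "gated"} (default) frames fully inside a
#' projection are attributed whole, and the light of a frame straddling a
#' projection boundary is split by a forward sweep that exploits the gating
#' structure (leaf openings are centred within their projection, so the
#' straddling frame holds at most the tail of the earlier opening and the
#' head of the later one; the tail is fixed by the earlier projection's
#' already-resolved open time, the head is whatever light remains).
#' \code{method = "overlap"} splits boundary frames by plain time overlap;
#' \code{method = "midpoint"} assigns whole frames to the projection
#' containing their midpoint.
#'
#' @param record A [LightRecord-class].
#' @param cal A [CalibrationSet-class]; its k1 must cover every observed
#'   leaf (an empty k1/k2 means no correction).
#' @param nProjections Number of projections of the delivery (default: as
#'   many as the record's time span covers).
#' @param method Frame-to-projection accumulation: "gated", "overlap" or
#'   "midpoint".
#' @param startTime Delivery start time (seconds).
#' @return A [CorrectedLight-class].
#' @export
applyCorrections <- function(record, cal, nProjections = NULL,
                             method = c("gated", "overlap", "midpoint"),
                             startTime = 0) {
  method <- match.arg(method)
  stopifnot(is(record, "LightRecord"), is(cal, "CalibrationSet"))
  g <- record@geometry
  leaves <- observedLeaves(record)
  k1 <- if (length(cal@k1)) {
    if (!all(as.character(leaves) %in% names(cal@k1)))
      stop("k1 is missing for some observed leaves")
    cal@k1[as.character(leaves)]
  } else rep(1, length(leaves))
  k2 <- k2At(cal, frameMidpoints(record))
  qc <- record@q * k1 * rep(k2, each = nrow(record@q))
  Tp <- projectionDuration(g) / 1000
  if (is.null(nProjections))
    nProjections <- max(1L, ceiling((max(frameMidpoints(record)) - startTime) / Tp))
  if (method %in% c("gated", "overlap")) {
    W <- frameProjectionOverlap(record@timestamps, g, nProjections, startTime)
    S <- W %*% t(qc)
    nEff <- attr(W, "effectiveFrames")
    if (method == "gated") {
      if (!length(cal@timeSlope) || cal@timeSlope <= 0)
        stop("gated accumulation needs a fitted time calibration")
      S <- gatedProjectionLight(qc, record@timestamps, g, nProjections,
                                startTime, cal@timeSlope)
    }
  } else {
    pr <- binFramesToProjections(record@timestamps, g, startTime)
    pr[pr > nProjections] <- nProjections
    S <- matrix(0, nProjections, length(leaves))
    cnt <- numeric(nProjections)
    for (p in unique(pr)) {
      S[p, ] <- rowSums(qc[, pr == p, drop = FALSE])
      cnt[p] <- sum(pr == p)
    }
    nEff <- cnt
  }
  colnames(S) <- leaves
  meanS <- S / pmax(nEff, .Machine$double.eps)
  new("CorrectedLight", qc = qc, S = S, meanS = meanS,
      framesPerProjection = nEff, method = method,
      timestamps = record@timestamps, geometry = g)
}

## Gated attribution of per-frame light to projections (forward sweep).
## Leaf openings are centred within their projection, so a frame straddling
## a projection boundary can only hold the tail of the earlier opening and
## the head of the later one.  Frames fully inside a projection give the
## interior open time I exactly; when an opening also intrudes into its
## boundary frames, the intrusions are deterministic functions of the open
## time tau (tau = I + lambda + rho with lambda/rho the intrusions into the
## start/end boundary frames).  Sweeping forward, the tail rho of
## projection p-1 is already resolved when frame L (straddling the p-1/p
## boundary) is split: lambda_p is the frame's measured open time minus
## rho_{p-1}.  Noise-free this recovers every open time exactly up to
## quantization; light is conserved per frame.  All open-time bookkeeping
## is in ms via the calibration slope; the returned S is in accumulated
## pixel values, comparable to plain overlap sums.
gatedProjectionLight <- function(qc, ts, g, nProjections, startTime, slope) {
  dtms <- framePeriod(g) * 1000
  Tms <- projectionDuration(g)
  nL <- nrow(qc)
  a <- (ts - startTime) * 1000
  b <- a + dtms
  pStart <- floor(a / Tms + 1e-9) + 1L
  pEnd <- floor((b - 1e-6) / Tms) + 1L
  S <- matrix(0, nProjections, nL)
  ## interior frames: attributed whole
  int <- which(pStart == pEnd & pStart >= 1L & pStart <= nProjections)
  if (length(int)) {
    M <- rowsum(t(qc[, int, drop = FALSE]), pStart[int])
    S[as.integer(rownames(M)), ] <- M
  }
  Ims <- S / slope                      # interior open time, ms
  ## frame straddling the boundary at the start of each projection
  Lidx <- rep(NA_integer_, nProjections + 1L)
  sf <- which(pEnd == pStart + 1L)
  Lidx[pmin(pEnd[sf], nProjections + 1L)] <- sf
  rho <- numeric(nL)                    # resolved tail of previous projection
  for (p in seq_len(nProjections)) {
    iL <- Lidx[p]
    lambda <- numeric(nL)
    if (!is.na(iL)) {
      oL <- pmin(pmax(qc[, iL] / slope, 0), dtms)
      capL <- b[iL] - (p - 1) * Tms
      lambda <- pmin(pmax(oL - rho, 0), capL)
    }
    iR <- Lidx[p + 1L]
    if (!is.na(iR)) {
      w <- a[iR] - (p - 0.5) * Tms      # centre-to-interior-edge distance
      capR <- p * Tms - a[iR]
      tau <- Ims[p, ] + lambda
      tau <- ifelse(tau > 2 * w, 2 * (tau - w), tau)
      tau <- pmin(tau, Tms)
      rho <- pmin(pmax(tau / 2 - w, 0), capR)
    } else rho <- numeric(nL)
    S[p, ] <- S[p, ] + (lambda + rho) * slope
  }
  S
}

setMethod("show", "CorrectedLight", function(object) {
  cat("CorrectedLight:", nrow(object@S), "projections x", ncol(object@S),
      "leaves (", object@method, "binning );",
      sprintf("mean per-frame light %.1f pv", mean(object@meanS)), "\n")
})

#' Open/closed classification against a threshold
#'
#' A leaf-projection bin is classified open when its light is strictly
#' greater than the threshold Th; a value equal to Th is closed.
#'
#' @param x A [CorrectedLight-class] (its per-projection mean per-frame
#'   light is used, making Th directly comparable to the per-frame anchor
#'   values) or a numeric matrix of light values.
#' @param th Threshold in pixel values (>= 0).
#' @param scope For a [CorrectedLight-class]: "projection" compares the
#'   per-projection mean per-frame light (default), "frame" classifies
#'   individual frames of qc.
#' @return Logical matrix of open calls.
#' @export
classifyOpen <- function(x, th, scope = c("projection", "frame")) {
  scope <- match.arg(scope)
  if (th < 0) stop("threshold must be >= 0")
  v <- if (is(x, "CorrectedLight")) {
    if (scope == "projection") x@meanS else t(x@qc)
  } else x
  v > th
}

#' Youden index
#'
#' \code{sensitivity + specificity - 1}; the criterion used to pick the
#' open/closed threshold.
#'
#' @param sensitivity,specificity Classification rates in [0, 1].
#' @return The Youden index.
#' @examples
#' youdenIndex(0.998, 0.989)  # 0.987
#' @export
youdenIndex <- function(sensitivity, specificity) sensitivity + specificity - 1

#' ROC analysis over a threshold grid
#'
#' Sweeps the open/closed threshold over \code{thGrid} and computes, against
#' the planned sinogram restricted to the observed leaves, the sensitivity
#' (open bins detected open), specificity (closed bins detected closed) and
#' Youden index at each threshold.
#'
#' @param x A [CorrectedLight-class] or a numeric light matrix
#'   (projections x observed leaves).
#' @param truth The planned [Sinogram-class] (or an open-fraction matrix
#'   over the same bins).
#' @param thGrid Thresholds to evaluate (default integers 0-100 pv).
#' @param geometry Geometry used to restrict a full sinogram to its
#'   observed leaves.
#' @return data.frame with columns th, sensitivity, specificity, youden.
#' @export
rocAnalysis <- function(x, truth, thGrid = 0:100,
                        geometry = tomoGeometry()) {
  score <- if (is(x, "CorrectedLight")) { geometry <- x@geometry; x@meanS } else x
  tv <- truthMatrix(truth, geometry, ncol(score))
  if (!all(dim(tv) == dim(score)))
    stop("truth and light matrices must align on projections x leaves")
  open <- tv > 0
  nOpen <- sum(open); nClosed <- sum(!open)
  if (nOpen == 0L || nClosed == 0L)
    warning("truth is all-", if (nOpen == 0L) "closed" else "open",
            ": the undefined rate is reported as NaN")
  out <- do.call(rbind, lapply(thGrid, function(th) {
    call <- score > th
    data.frame(th = th,
               sensitivity = sum(call & open) / nOpen,
               specificity = sum(!call & !open) / nClosed)
  }))
  out$youden <- youdenIndex(out$sensitivity, out$specificity)
  out
}

truthMatrix <- function(truth, geometry, nLeavesExpected) {
  tv <- if (is(truth, "Sinogram")) sinogramValues(truth) else as.matrix(truth)
  if (ncol(tv) == geometry@nLeaves && nLeavesExpected < ncol(tv))
    tv <- tv[, observedLeaves(geometry), drop = FALSE]
  tv
}

#' Threshold maximizing the Youden index
#'
#' Ties are broken toward the smallest threshold, which favours detecting
#' single-leaf openings (their light is far below that of wide fields).
#'
#' @param roc data.frame from [rocAnalysis()].
#' @return The optimal threshold (same units as the grid).
#' @export
youdenThreshold <- function(roc) {
  y <- round(roc$youden, 12)  # guard against FP noise breaking ties
  if (all(is.nan(y)))
    stop("Youden index is undefined: the truth has no open or no closed ",
         "bins; choose a threshold explicitly")
  roc$th[which.max(y)]
}

#' Reconstruct a sinogram from corrected light
#'
#' Per projection and leaf: bins whose per-frame light is at or below the
#' threshold are closed (0.0); open bins convert their accumulated
#' corrected light to a leaf open time through the inverse calibration
#' line, expressed as a fraction of the projection duration and clipped to
#' [0, 1] (scattered light can push the light of a wide open field above
#' the full-open calibration).
#'
#' @param corrected A [CorrectedLight-class].
#' @param cal A [CalibrationSet-class] with a fitted time calibration.
#' @param th Open/closed threshold in pixel values (compared against the
#'   per-projection mean per-frame light).
#' @param geometry A [TomoGeometry-class].
#' @return The reconstructed [Sinogram-class] (closed leaves outside the
#'   observed range are 0).
#' @export
reconstructSinogram <- function(corrected, cal, th,
                                geometry = corrected@geometry) {
  stopifnot(is(corrected, "CorrectedLight"))
  if (!length(cal@timeSlope) || cal@timeSlope <= 0)
    stop("calibration has no fitted time-calibration line")
  Tp <- projectionDuration(geometry)
  tau <- predictOpenTime(cal, corrected@S)
  frac <- pmin(tau / Tp, 1)  # matrix first: pmin keeps its attributes
  frac[!classifyOpen(corrected, th)] <- 0
  v <- matrix(0, nrow(frac), geometry@nLeaves)
  v[, as.integer(colnames(corrected@S))] <- frac
  sinogram(v, geometry)
}
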