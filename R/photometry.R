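#' ROI table for the observed leaves
#'
#' One square ROI per observed leaf, centred on the leaf's strip on the
#' horizontal diameter of the scintillator image at gantry 0 degrees.  ROIs
#' must lie fully inside the image and are pairwise disjoint (the leaf pitch
#' of ~13.35 px comfortably exceeds the 5 px ROI).
#'
#' @param geometry A [TomoGeometry-class].
#' @return data.frame with columns \code{leaf}, \code{cx}, \code{cy} (pixel
#'   centres).
#' @export
roiTable <- function(geometry = tomoGeometry()) {
  ol <- observedLeaves(geometry)
  cx <- round(leafCenterPx(geometry, ol))
  cy <- rep(round(geometry@isocenterPx[2]), length(ol))
  half <- geometry@roiSize %/% 2
  if (any(cx - half < 1 | cx + half > geometry@imageSize[1] |
          cy - half < 1 | cy + half > geometry@imageSize[2]))
    stop("ROIs fall outside the image for this geometry")
  if (any(diff(cx) < geometry@roiSize))
    stop("ROIs overlap for this geometry")
  data.frame(leaf = ol, cx = cx, cy = cy)
}

## ROI sample points (one row per pixel of every ROI) plus the leaf id
roiPoints <- function(geometry, rois) {
  half <- geometry@roiSize %/% 2
  off <- seq(-half, half)
  grid <- expand.grid(dx = off, dy = off)
  pts <- do.call(rbind, lapply(seq_len(nrow(rois)), function(k)
    cbind(rois$cx[k] + grid$dx, rois$cy[k] + grid$dy)))
  list(pts = pts, leaf = rep(rois$leaf, each = nrow(grid)))
}

#' Extract per-frame, per-leaf light from a stack
#'
#' The mean raw pixel value of each leaf's ROI in each frame (qraw) and the
#' background-subtracted light q = qraw - BG.  With
#' \code{backRotate = TRUE} each frame is first rotated back to the 0 degree
#' reference by its recorded gantry angle (bilinear interpolation about the
#' isocenter; pixels from outside the image read as the background), which
#' is how a rotating delivery is measured with ROIs that do not rotate.
#' q is deliberately not clipped at zero, so noise can make it negative.
#'
#' @param stack A [FrameStack-class].
#' @param rois ROI table from [roiTable()].
#' @param bg Background pixel value BG (default 0.36, the measured dark
#'   level).
#' @param backRotate Rotate frames back by their gantry angles first.
#' @return A [LightRecord-class].
#' @export
extractLight <- function(stack, rois = roiTable(stack@geometry), bg = 0.36,
                         backRotate = FALSE) {
  stopifnot(is(stack, "FrameStack"), bg >= 0)
  g <- stack@geometry
  angles <- if (backRotate) {
    if (anyNA(stack@gantryAngles))
      stop("back-rotation requires per-frame gantry angles")
    stack@gantryAngles * pi / 180
  } else numeric(nFrames(stack))
  rp <- roiPoints(g, rois)
  sm <- cpp_sample_stack(stack@frames, rp$pts, angles,
                         g@isocenterPx[1], g@isocenterPx[2], bg)
  qraw <- rowsum(sm, rp$leaf) / tabulate(factor(rp$leaf))[1]
  rownames(qraw) <- sort(unique(rp$leaf))
  new("LightRecord", qraw = qraw, q = qraw - bg, bg = bg,
      timestamps = stack@timestamps, gantryAngles = stack@gantryAngles,
      geometry = g)
}

#' Estimate the background pixel value
#'
#' BG is the mean raw ROI pixel value of a beam-off recording, averaged over
#' all ROIs and frames.
#'
#' @param stack A beam-off [FrameStack-class].
#' @param rois ROI table.
#' @return Background pixel value.
#' @export
estimateBackground <- function(stack, rois = roiTable(stack@geometry)) {
  if (nFrames(stack) < 1L) stop("cannot estimate background from an empty stack")
  rec <- extractLight(stack, rois, bg = 0)
  mean(rec@qraw)
}

#' @rdname accumulatedLight
#' @export
setMethod("accumulatedLight", "LightRecord", function(x) rowSums(x@q))

#' @rdname observedLeaves
#' @export
setMethod("observedLeaves", "LightRecord",
          function(x) as.integer(rownames(x@qraw)))

#' @rdname gantryAngles
#' @export
setMethod("gantryAngles", "LightRecord", function(x) x@gantryAngles)

#' @rdname timestamps
#' @export
setMethod("timestamps", "LightRecord", function(x) x@timestamps)

setMethod("show", "LightRecord", function(object) {
  cat("LightRecord:", nrow(object@q), "leaves x", ncol(object@q),
      "frames; BG =", object@bg, "\n  Qcenter =",
      sprintf("%.1f pv", tryCatch(qCenter(object), error = function(e) NA)),
      "\n")
})

#' Centre-of-field light
#'
#' The isocenter sits between leaves 32 and 33, so the centre reference is
#' the mean of their accumulated light, \code{(Q32 + Q33)/2}.
#' \code{qCenterPerFrame} is the per-frame analogue used by the drift
#' analysis.
#'
#' @param record A [LightRecord-class] covering leaves 32 and 33.
#' @return \code{qCenter}: one pixel value; \code{qCenterPerFrame}: one per
#'   frame.
#' @export
qCenter <- function(record) {
  Q <- accumulatedLight(record)
  if (!all(c("32", "33") %in% names(Q)))
    stop("centre leaves 32 and 33 are not observed in this record")
  (Q[["32"]] + Q[["33"]]) / 2
}

#' @rdname qCenter
#' @export
qCenterPerFrame <- function(record) {
  if (!all(c("32", "33") %in% rownames(record@q)))
    stop("centre leaves 32 and 33 are not observed in this record")
  (record@q["32", ] + record@q["33", ]) / 2
}

#' Assign frames to projections by their midpoint
#'
#' Frame i belongs to the projection whose half-open time window
#' \code{[p*T, (p+1)*T)} contains the frame's midpoint (a frame exactly on a
#' boundary goes to the later projection).  Every frame is assigned to
#' exactly one projection.
#'
#' @param x A [FrameStack-class], [LightRecord-class] or numeric vector of
#'   frame start times (seconds).
#' @param geometry A [TomoGeometry-class].
#' @param startTime Delivery start time (seconds); frames with midpoints
#'   before it are an error.
#' @return Integer vector of 1-based projection indices, one per frame.
#' @export
binFramesToProjections <- function(x, geometry = tomoGeometry(),
                                   startTime = 0) {
  ts <- if (is.numeric(x)) x else timestamps(x)
  if (!is.numeric(x)) geometry <- x@geometry
  mid <- ts + framePeriod(geometry) / 2
  if (any(mid < startTime))
    stop("frames before the delivery start time")
  Tp <- projectionDuration(geometry) / 1000
  as.integer(floor((mid - startTime) / Tp)) + 1L
}

#' Overlap weights between frames and projections
#'
#' The fraction of each frame's exposure window falling into each
#' projection's time window.  A frame fully inside a projection contributes
#' weight 1 to it; a frame straddling a boundary is split between the two
#' projections in proportion to the time overlap.  Used to accumulate
#' per-frame light into per-projection light without the double-counting a
#' whole-frame assignment would entail.
#'
#' @param ts Frame start times (seconds).
#' @param geometry A [TomoGeometry-class].
#' @param nProjections Number of projections of the delivery.
#' @param startTime Delivery start time (seconds).
#' Weights are normalized per frame by the frame's overlap with the whole
#' delivery window, so that a frame extending beyond the delivery end (when
#' the beam is already off) still assigns all of its light to the last
#' projection it saw.
#'
#' @return Matrix W of size \code{nProjections} x frames with unit column
#'   sums for frames intersecting the delivery.  The attribute
#'   \code{"effectiveFrames"} carries each projection's time span in frame
#'   periods (the divisor for per-frame mean light).
#' @export
frameProjectionOverlap <- function(ts, geometry = tomoGeometry(),
                                   nProjections, startTime = 0) {
  dt <- framePeriod(geometry)
  Tp <- projectionDuration(geometry) / 1000
  O <- matrix(0, nrow = nProjections, ncol = length(ts))
  s <- ts - startTime
  for (p in seq_len(nProjections)) {
    ov <- pmax(0, pmin(p * Tp, s + dt) - pmax((p - 1) * Tp, s)) / dt
    O[p, ] <- ov
  }
  cover <- colSums(O)  # frame's overlap with the delivery, in frame periods
  W <- O / rep(pmax(cover, .Machine$double.eps), each = nProjections)
  attr(W, "effectiveFrames") <- rowSums(O)
  W
}
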