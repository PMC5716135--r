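#' Fit the light-to-open-time calibration line
#'
#' Ordinary least squares of accumulated centre light Q against leaf open
#' time.  The measured relation is linear over 29.41-294.12 ms; an intercept
#' is kept since the measurement does not force the line through the origin.
#'
#' @param openTimesMs Leaf open times in milliseconds (>= 2 distinct values).
#' @param Q Accumulated centre light (pixel values), one per open time.
#' @return List with \code{slope} (pv/ms), \code{intercept} (pv) and the
#'   underlying \code{lm} fit.
#' @examples
#' fitTimeCalibration(c(50, 100, 200), c(10, 20, 40))$slope  # 0.2
#' @export
fitTimeCalibration <- function(openTimesMs, Q) {
  if (length(openTimesMs) < 2L || length(unique(openTimesMs)) < 2L)
    stop("need at least two distinct open times")
  if (length(openTimesMs) != length(Q)) stop("length mismatch")
  fit <- lm(Q ~ openTimesMs)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("time calibration has a non-positive slope")
  list(slope = slope, intercept = unname(coef(fit)[1]), fit = fit)
}

#' Predict leaf open time from accumulated light
#'
#' Inverts the calibration line; negative predictions are clipped to zero
#' (light below the intercept cannot correspond to a negative open time).
#'
#' @param cal A [CalibrationSet-class] or the list from
#'   [fitTimeCalibration()].
#' @param Q Accumulated light (pixel values), any numeric shape.
#' @return Open times in milliseconds, same shape as \code{Q}.
#' @export
predictOpenTime <- function(cal, Q) {
  if (is(cal, "CalibrationSet")) {
    slope <- cal@timeSlope; intercept <- cal@timeIntercept
  } else {
    slope <- cal$slope; intercept <- cal$intercept
  }
  out <- (Q - intercept) / slope
  out[out < 0] <- 0
  out
}

#' Lateral correction factors from single-leaf exposures
#'
#' Each observed leaf is opened alone for the same open time; the relative
#' profile is the accumulated light normalized to leaf 32, and k1 is its
#' inverse, so that multiplying a leaf's light by k1 flattens the lateral
#' response.
#'
#' @param perLeafQ Named numeric vector of accumulated light per leaf (names
#'   are leaf numbers; must include the reference leaf 32).
#' @return Named numeric vector k1 (k1[leaf 32] = 1).
#' @examples
#' measureLateralProfile(c("31" = 0.95, "32" = 1, "33" = 0.95))
#' @export
measureLateralProfile <- function(perLeafQ) {
  if (!"32" %in% names(perLeafQ))
    stop("the reference leaf 32 must be measured")
  if (any(perLeafQ <= 0))
    stop("non-positive light at leaves ",
         paste(names(perLeafQ)[perLeafQ <= 0], collapse = ", "),
         ": profile is undefined")
  k1 <- perLeafQ[["32"]] / perLeafQ
  k1
}

#' Output-drift correction from a long static exposure
#'
#' The per-frame centre light of a long constant exposure is averaged in
#' \code{window}-second bins and normalized by the bin at
#' \code{normalizeAt} seconds, giving the relative beam output over time;
#' k2 is its inverse, piecewise constant over the bins (frames beyond the
#' calibrated range use the nearest bin).
#'
#' @param record [LightRecord-class] of a static exposure at least
#'   \code{normalizeAt} seconds long.
#' @param window Averaging window in seconds (default 10).
#' @param normalizeAt Normalization time in seconds (default 100).
#' @return data.frame with columns tStart, tEnd, relOutput, k2.
#' @export
measureDriftCorrection <- function(record, window = 10, normalizeAt = 100) {
  tm <- frameMidpoints(record)
  if (max(tm) < normalizeAt)
    stop("exposure shorter than the ", normalizeAt, " s normalization point")
  qc <- qCenterPerFrame(record)
  bin <- floor(tm / window)
  means <- tapply(qc, bin, mean)
  bins <- as.integer(names(means))
  refBin <- floor(normalizeAt / window)
  ## Fig-style normalization: the bin containing the normalization time
  if (!refBin %in% bins) refBin <- bins[which.min(abs(bins - refBin))]
  rel <- as.numeric(means) / means[[as.character(refBin)]]
  if (any(rel <= 0)) stop("non-positive windowed output; cannot form k2")
  data.frame(tStart = bins * window, tEnd = (bins + 1) * window,
             relOutput = rel, k2 = 1 / rel)
}

#' Look up k2 at given times
#'
#' @param cal A [CalibrationSet-class] (or a k2 data.frame).
#' @param t Times in seconds.
#' @return k2 values (1 when no drift calibration is present).
#' @export
k2At <- function(cal, t) {
  bins <- if (is(cal, "CalibrationSet")) cal@k2Bins else cal
  if (is.null(bins) || !nrow(bins)) return(rep(1, length(t)))
  idx <- findInterval(t, bins$tStart)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(bins)] <- nrow(bins)
  bins$k2[idx]
}

#' Field-size output factors from centred-aperture exposures
#'
#' For each aperture of n contiguous open leaves (fixed open time) the
#' centre per-frame light (leaf 32 when one leaf is open at the centre, the
#' 32/33 mean otherwise) and the field-edge per-frame light, defined as the
#' mean of the two closed-leaf ROIs flanking the aperture.  When a flank
#' falls outside the observed range that edge is omitted with a warning.
#'
#' @param exposures List of entries, each with elements \code{record} (a
#'   [LightRecord-class]), \code{leaves} (the open aperture) and
#'   \code{openTimeMs}.
#' @param geometry A [TomoGeometry-class].
#' @return data.frame with columns nOpen, center, edge (pixel values per
#'   frame).
#' @export
measureFieldFactors <- function(exposures, geometry = tomoGeometry()) {
  out <- lapply(exposures, function(e) {
    Q <- accumulatedLight(e$record)
    nEff <- e$openTimeMs / (framePeriod(geometry) * 1000)
    leaves <- sort(e$leaves)
    n <- length(leaves)
    centerLeaves <- if (n %% 2L == 1L) leaves[(n + 1L) %/% 2L] else
      leaves[c(n %/% 2L, n %/% 2L + 1L)]
    center <- mean(Q[as.character(centerLeaves)]) / nEff
    flank <- c(leaves[1] - 1L, leaves[n] + 1L)
    ok <- flank >= geometry@observedLeaves[1] & flank <= geometry@observedLeaves[2]
    if (!all(ok))
      warning("aperture of ", n, " leaves touches the observed range; ",
              "edge uses the available flank only")
    edge <- if (any(ok)) mean(Q[as.character(flank[ok])]) / nEff else NA_real_
    data.frame(nOpen = n, center = center, edge = edge)
  })
  do.call(rbind, out)
}

#' Build a calibration set from its components
#'
#' @param timeFit List from [fitTimeCalibration()].
#' @param k1 Named numeric vector of lateral corrections (default: none,
#'   treated as 1 everywhere).
#' @param k2Bins Drift-correction table from [measureDriftCorrection()]
#'   (default: no drift correction).
#' @param k2Window Drift window in seconds.
#' @param fieldFactors Output-factor table from [measureFieldFactors()].
#' @param meta Provenance list.
#' @return A [CalibrationSet-class].
#' @export
calibrationSet <- function(timeFit, k1 = numeric(), k2Bins = data.frame(),
                           k2Window = 10, fieldFactors = data.frame(),
                           meta = list()) {
  new("CalibrationSet", timeSlope = timeFit$slope,
      timeIntercept = timeFit$intercept, k1 = k1, k2Bins = k2Bins,
      k2Window = k2Window, fieldFactors = fieldFactors, meta = meta)
}

setMethod("show", "CalibrationSet", function(object) {
  cat(sprintf("CalibrationSet: Q = %.4f pv/ms * t %+.3f pv\n",
              object@timeSlope, object@timeIntercept))
  if (length(object@k1))
    cat(sprintf("  k1 over %d leaves in [%.3f, %.3f]\n", length(object@k1),
                min(object@k1), max(object@k1)))
  if (nrow(object@k2Bins))
    cat(sprintf("  k2 over %d x %g s bins in [%.4f, %.4f]\n",
                nrow(object@k2Bins), object@k2Window, min(object@k2Bins$k2),
                max(object@k2Bins$k2)))
  if (nrow(object@fieldFactors))
    cat(sprintf("  field factors for n = %d..%d open leaves\n",
                min(object@fieldFactors$nOpen), max(object@fieldFactors$nOpen)))
})

#' Simulate the full calibration session
#'
#' Reproduces the QA measurement chain on simulated data: (1) static
#' centre-field exposures (leaves 25-40) over a sweep of open times for the
#' light-to-open-time line, (2) one single-leaf exposure per observed leaf
#' for the lateral profile k1, (3) a long constant exposure for the output
#' -drift correction k2, and (4) optional centred-aperture exposures for the
#' field-size output factors.  The drift exposure is simulated in chunks so
#' that arbitrarily long recordings need only bounded memory.
#'
#' @param model An [OpticalModel-class] (the "machine" being measured).
#' @param geometry A [TomoGeometry-class].
#' @param seed Integer seed for the simulated exposures.
#' @param openTimesMs Open-time sweep for the line fit.
#' @param profileOpenTimeMs Open time of the single-leaf profile exposures.
#' @param driftDuration Length (s) of the drift exposure; must reach the
#'   100 s normalization point, 0 skips the drift correction.
#' @param fieldSizes Aperture sizes (open-leaf counts) for the output
#'   factors, NULL to skip.
#' @param driftWindow Drift averaging window (s).
#' @return A [CalibrationSet-class].
#' @export
simulateCalibrationSession <- function(model, geometry = tomoGeometry(),
                                       seed = 1L,
                                       openTimesMs = seq(29.41, 294.12,
                                                         length.out = 10),
                                       profileOpenTimeMs = 294.12,
                                       driftDuration = 300,
                                       fieldSizes = NULL,
                                       driftWindow = 10) {
  dtMs <- framePeriod(geometry) * 1000
  pad <- 3 * dtMs / 1000
  centreField <- 25:40
  ## (1) open-time sweep
  Q <- vapply(seq_along(openTimesMs), function(k) {
    stk <- simulateStaticExposure(centreField, openTimesMs[k] / 1000 + pad,
                                  model, geometry, seed = seed + k,
                                  openTime = openTimesMs[k] / 1000)
    qCenter(extractLight(stk, bg = model@backgroundMean))
  }, numeric(1))
  timeFit <- fitTimeCalibration(openTimesMs, Q)
  ## (2) lateral profile
  ol <- observedLeaves(geometry)
  perLeafQ <- vapply(seq_along(ol), function(k) {
    stk <- simulateStaticExposure(ol[k], profileOpenTimeMs / 1000 + pad,
                                  model, geometry, seed = seed + 1000L + k,
                                  openTime = profileOpenTimeMs / 1000)
    accumulatedLight(extractLight(stk, bg = model@backgroundMean))[[as.character(ol[k])]]
  }, numeric(1))
  names(perLeafQ) <- ol
  k1 <- measureLateralProfile(perLeafQ)
  ## (3) output drift, chunked
  k2Bins <- data.frame()
  if (driftDuration > 0) {
    k2Bins <- measureDriftChunked(model, geometry, seed + 2000L,
                                  driftDuration, driftWindow, centreField)
  }
  ## (4) field-size output factors
  ff <- data.frame()
  if (!is.null(fieldSizes)) {
    centre <- (geometry@nLeaves + 1) / 2   # 32.5: apertures centred there
    exposures <- lapply(fieldSizes, function(n) {
      lo <- ceiling(centre - n / 2)
      leaves <- lo:(lo + n - 1L)
      stk <- simulateStaticExposure(leaves, profileOpenTimeMs / 1000 + pad,
                                    model, geometry, seed = seed + 3000L + n,
                                    openTime = profileOpenTimeMs / 1000)
      list(record = extractLight(stk, bg = model@backgroundMean),
           leaves = leaves, openTimeMs = profileOpenTimeMs)
    })
    ff <- suppressWarnings(measureFieldFactors(exposures, geometry))
  }
  calibrationSet(timeFit, k1 = k1, k2Bins = k2Bins, k2Window = driftWindow,
                 fieldFactors = ff,
                 meta = list(seed = seed, openTimesMs = openTimesMs,
                             driftDuration = driftDuration))
}

## drift exposure in chunks of ~30 s to bound memory on long recordings
measureDriftChunked <- function(model, geometry, seed, duration, window,
                                leaves) {
  dt <- framePeriod(geometry)
  nF <- floor(duration / dt + 1e-9)
  chunk <- max(1L, floor(30 / dt))
  set.seed(seed)
  ts <- (seq_len(nF) - 1) * dt
  qc <- numeric(nF)
  fops1 <- matrix(0, geometry@nLeaves, 1L)
  fops1[leaves, 1L] <- 1
  done <- 0L
  rois <- roiTable(geometry)
  while (done < nF) {
    idx <- (done + 1L):min(nF, done + chunk)
    mid <- ts[idx] + dt / 2
    amp <- leafAmplitudes(fops1[, rep(1L, length(idx)), drop = FALSE], mid,
                          model, geometry)
    fr <- renderStack(amp, numeric(length(idx)), model, geometry)
    fr <- injectTransients(fr, model@transientProb, model@transientRadius)
    stk <- frameStack(fr, ts[idx], numeric(length(idx)), geometry)
    qc[idx] <- qCenterPerFrame(extractLight(stk, rois,
                                            bg = model@backgroundMean))
    done <- idx[length(idx)]
  }
  ## qc is already the centre light; apply the windowed estimator directly
  tm <- ts + dt / 2
  bin <- floor(tm / window)
  means <- tapply(qc, bin, mean)
  bins <- as.integer(names(means))
  refBin <- floor(100 / window)
  if (!refBin %in% bins) refBin <- bins[which.min(abs(bins - refBin))]
  rel <- as.numeric(means) / means[[as.character(refBin)]]
  data.frame(tStart = bins * window, tEnd = (bins + 1) * window,
             relOutput = rel, k2 = 1 / rel)
}

#' Serialize / load a calibration set as JSON
#'
#' @param cal A [CalibrationSet-class].
#' @param path JSON file path.
#' @return \code{writeCalibration} returns \code{path} invisibly;
#'   \code{readCalibration} returns a [CalibrationSet-class].
#' @export
writeCalibration <- function(cal, path) {
  jsonlite::write_json(
    list(timeSlope = cal@timeSlope, timeIntercept = cal@timeIntercept,
         k1 = as.list(cal@k1), k2Bins = cal@k2Bins, k2Window = cal@k2Window,
         fieldFactors = cal@fieldFactors, meta = cal@meta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  z <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CalibrationSet", timeSlope = z$timeSlope,
      timeIntercept = z$timeIntercept, k1 = unlist(z$k1),
      k2Bins = as.data.frame(z$k2Bins), k2Window = z$k2Window,
      fieldFactors = as.data.frame(z$fieldFactors),
      meta = if (is.null(z$meta)) list() else as.list(z$meta))
}
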