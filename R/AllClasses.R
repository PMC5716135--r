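#' @import methods
#' @importFrom stats lm coef sd rnorm runif median residuals
#' @importFrom graphics hist
#' @importFrom tools md5sum
#' @importFrom utils read.table write.table packageVersion head tail
#' @useDynLib scintQA, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Machine and imaging geometry of the verification unit
#'
#' Describes the treatment-machine side (binary MLC with 64 leaves, 51
#' projections per gantry rotation) and the measurement side (cylindrical
#' scintillator filmed by a camcorder) of the QA setup.  All leaf indices are
#' 1-based; only leaves inside \code{observedLeaves} are visible on the
#' scintillator disc.
#'
#' @slot nLeaves Number of binary MLC leaves (64).
#' @slot observedLeaves Inclusive leaf-index pair monitored by the detector,
#'   default \code{c(18, 47)}: the 20 cm scintillator only covers the central
#'   part of the 40 cm leaf bank.
#' @slot nProjPerRotation Projections delivered per gantry rotation (51).
#' @slot rotationPeriod Gantry rotation period in seconds (default 15).
#' @slot leafWidthIso Leaf width at isocenter in cm (0.625).
#' @slot scintDiameter,scintLength Scintillator diameter and length in cm.
#' @slot pixelPitch Image scale in mm per pixel (0.468).
#' @slot imageSize Frame size in pixels, \code{c(width, height)}.
#' @slot frameRate Camcorder frame rate in frames per second (29.97).
#' @slot roiSize Side of the square photometry ROI in pixels (5).
#' @slot isocenterPx Pixel coordinates \code{c(x, y)} of the isocenter /
#'   rotation center in the image.
#' @seealso [tomoGeometry()], [projectionDuration()]
#' @export
setClass("TomoGeometry", representation(
  nLeaves = "integer",
  observedLeaves = "integer",
  nProjPerRotation = "integer",
  rotationPeriod = "numeric",
  leafWidthIso = "numeric",
  scintDiameter = "numeric",
  scintLength = "numeric",
  pixelPitch = "numeric",
  imageSize = "integer",
  frameRate = "numeric",
  roiSize = "integer",
  isocenterPx = "numeric"
))

setValidity("TomoGeometry", function(object) {
  msg <- character()
  if (object@rotationPeriod <= 0)
    msg <- c(msg, "rotationPeriod must be positive")
  if (object@nProjPerRotation < 1L)
    msg <- c(msg, "nProjPerRotation must be >= 1")
  if (abs(object@leafWidthIso * object@nLeaves - 40) > 1e-6)
    msg <- c(msg, "leafWidthIso * nLeaves must equal the 40 cm field width")
  ol <- object@observedLeaves
  if (length(ol) != 2L || ol[1] > ol[2] || ol[1] < 1L || ol[2] > object@nLeaves)
    msg <- c(msg, "observedLeaves must be an increasing pair inside [1, nLeaves]")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
  if (object@roiSize < 1L) msg <- c(msg, "roiSize must be >= 1 pixel")
  if (length(object@imageSize) != 2L || any(object@imageSize < 8L))
    msg <- c(msg, "imageSize must be two pixel counts >= 8")
  if (length(msg)) msg else TRUE
})

#' Delivery sinogram: planned or reconstructed leaf-open fractions
#'
#' A sinogram is a P x 64 matrix of leaf-open fractions in [0, 1]; row p,
#' column j gives the fraction of projection p for which leaf j is open
#' (0 = closed for the whole projection, 1 = open for the whole projection).
#'
#' @slot values Numeric matrix of open fractions, one row per projection.
#' @slot geometry The [TomoGeometry-class] the plan refers to.
#' @seealso [sinogram()], [simplePattern()], [clinicalPattern()],
#'   [modulationFactor()]
#' @export
setClass("Sinogram", representation(
  values = "matrix",
  geometry = "TomoGeometry"
))

setValidity("Sinogram", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (nrow(v) < 1L) return("a sinogram needs at least one projection")
  if (ncol(v) != object@geometry@nLeaves)
    return("sinogram must have one column per leaf")
  if (anyNA(v) || any(v < 0) || any(v > 1))
    return("open fractions must lie in [0, 1]")
  TRUE
})

#' Phenomenological optical model of the scintillator-camcorder chain
#'
#' Parameters of the forward light model used by the simulator.  The expected
#' ROI amplitude (pixel value per frame at a leaf's own ROI, centre row) for
#' leaf j is \code{gain * profile(j) * drift(t) * sum_m kernel(j - m) f_m},
#' where \code{f_m} is the fraction of the frame for which leaf m was open.
#' The scatter kernel is a two-sided exponential over leaf-index offsets,
#' \code{kernel(0) = 1}, \code{kernel(d) = scatterAmp * exp(-|d|/scatterLambda)},
#' capturing in-medium light scatter and Cherenkov contamination that light up
#' ROIs of closed leaves near an open field.
#'
#' @slot gain Pixel value per frame for a single fully open leaf at its own
#'   ROI (before lateral-profile and drift factors).
#' @slot scatterAmp,scatterLambda Amplitude and decay length (in leaf indices)
#'   of the scatter kernel; \code{scatterAmp = 0} switches scatter off.
#' @slot profileDrop Relative drop of the symmetric quadratic lateral profile
#'   at the ends of the observed leaf range (profile = 1 at the leaf-bank
#'   centre, \code{1 - profileDrop} at the range ends).
#' @slot driftStart,driftRate Linac output-drift line: relative output is
#'   \code{driftStart + driftRate * t} with t the beam-on time in seconds.
#'   \code{driftStart = 1, driftRate = 0} is a drift-free beam.
#' @slot backgroundMean Mean dark pixel value of the camcorder (0.36).
#' @slot pixelNoiseSd Gaussian pixel-noise standard deviation in pixel values.
#' @slot transientProb Per-frame probability of a transient bright artifact
#'   from a scattered photon hitting the sensor (0.002).
#' @slot transientRadius Range (pixels) of the saturated artifact disc radius.
#' @slot attenuationMu Effective attenuation coefficient (1/cm) of the beam
#'   along its path through the scintillator; breaks the entry/exit symmetry
#'   used by the gantry-angle tracker.
#' @slot anchors,fitResiduals Calibration anchors and their fit residuals
#'   when the model was produced by [calibrateOpticalModel()].
#' @seealso [opticalModel()], [calibrateOpticalModel()], [simulateDelivery()]
#' @export
setClass("OpticalModel", representation(
  gain = "numeric",
  scatterAmp = "numeric",
  scatterLambda = "numeric",
  profileDrop = "numeric",
  driftStart = "numeric",
  driftRate = "numeric",
  backgroundMean = "numeric",
  pixelNoiseSd = "numeric",
  transientProb = "numeric",
  transientRadius = "numeric",
  attenuationMu = "numeric",
  anchors = "list",
  fitResiduals = "numeric"
))

setValidity("OpticalModel", function(object) {
  msg <- character()
  if (object@gain <= 0) msg <- c(msg, "gain must be positive")
  if (object@scatterAmp < 0) msg <- c(msg, "scatter weights must be >= 0")
  if (object@scatterLambda <= 0) msg <- c(msg, "scatterLambda must be positive")
  if (object@scatterAmp * exp(-1 / object@scatterLambda) > 1)
    msg <- c(msg, "central kernel weight must be the maximum")
  if (object@transientProb < 0 || object@transientProb > 1)
    msg <- c(msg, "transientProb must be in [0, 1]")
  if (object@profileDrop < 0 || object@profileDrop >= 1)
    msg <- c(msg, "profileDrop must be in [0, 1)")
  if (object@driftStart + object@driftRate * 600 <= 0 || object@driftStart <= 0)
    msg <- c(msg, "drift curve must stay positive over deliveries")
  if (object@pixelNoiseSd < 0) msg <- c(msg, "pixelNoiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Stack of recorded (or simulated) camcorder frames
#'
#' Ordered 8-bit grayscale frames with per-frame timestamps and gantry
#' angles; the raw measurement of a delivery.  Frames are stored as a raw
#' array of dimension \code{c(width, height, nFrames)}; pixel values are
#' 0-255.  Timestamps are frame start times in seconds from delivery start,
#' spaced at the nominal frame period.
#'
#' @slot frames Raw array \code{c(nx, ny, nFrames)} of 8-bit pixel values.
#' @slot timestamps Frame start times (seconds), strictly increasing.
#' @slot gantryAngles Gantry angle (degrees) at each frame midpoint.
#' @slot geometry The [TomoGeometry-class] of the acquisition.
#' @slot seed Integer seed the stack was simulated with (NA for loaded data).
#' @seealso [simulateDelivery()], [simulateStaticExposure()], [extractLight()]
#' @export
setClass("FrameStack", representation(
  frames = "array",
  timestamps = "numeric",
  gantryAngles = "numeric",
  geometry = "TomoGeometry",
  seed = "integer"
))

setValidity("FrameStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3-d array (nx, ny, nFrames)")
  if (!is.raw(object@frames)) return("frames must be an 8-bit raw array")
  n <- d[3]
  if (length(object@timestamps) != n || length(object@gantryAngles) != n)
    return("timestamps and gantryAngles must have one entry per frame")
  if (n > 1L && any(diff(object@timestamps) <= 0))
    return("timestamps must be strictly increasing")
  TRUE
})

#' Per-frame, per-leaf light measurements extracted from a frame stack
#'
#' Holds the ROI photometry of a stack: the mean raw pixel value of each
#' leaf's ROI in each frame (qraw), the background-subtracted light
#' q = qraw - BG (not clipped at zero; noise may make it negative), and the
#' acquisition timing needed to bin frames into projections.
#'
#' @slot qraw,q Numeric matrices, observed leaves x frames.
#' @slot bg Background pixel value subtracted.
#' @slot timestamps,gantryAngles Copied from the source stack.
#' @slot geometry The acquisition [TomoGeometry-class].
#' @seealso [extractLight()], [accumulatedLight()], [qCenter()]
#' @export
setClass("LightRecord", representation(
  qraw = "matrix",
  q = "matrix",
  bg = "numeric",
  timestamps = "numeric",
  gantryAngles = "numeric",
  geometry = "TomoGeometry"
))

setValidity("LightRecord", function(object) {
  if (!identical(dim(object@qraw), dim(object@q)))
    return("qraw and q must have the same shape")
  if (ncol(object@q) != length(object@timestamps))
    return("one column per frame required")
  if (max(abs(object@qraw - object@bg - object@q)) > 1e-9)
    return("q must equal qraw - bg")
  TRUE
})

#' Calibration of the light-to-open-time conversion
#'
#' The fitted calibration used to reconstruct a sinogram: the straight line
#' relating accumulated light Q to leaf open time, the per-leaf lateral
#' correction k1 (inverse of the single-leaf profile normalized at leaf 32),
#' the per-time drift correction k2 (inverse of the windowed relative output,
#' normalized at the 100 s bin, piecewise constant over bins), and per-field
#' -size output factors.
#'
#' @slot timeSlope,timeIntercept Q (pixel value) per ms and offset of the
#'   open-time calibration line.
#' @slot k1 Named numeric vector of lateral corrections per observed leaf.
#' @slot k2Bins data.frame with columns tStart, tEnd, relOutput, k2.
#' @slot k2Window Drift averaging window in seconds.
#' @slot fieldFactors data.frame with per-aperture center/edge per-frame
#'   light (columns nOpen, center, edge).
#' @slot meta List of provenance details (seeds, exposure settings).
#' @seealso [simulateCalibrationSession()], [fitTimeCalibration()],
#'   [predictOpenTime()], [applyCorrections()]
#' @export
setClass("CalibrationSet", representation(
  timeSlope = "numeric",
  timeIntercept = "numeric",
  k1 = "numeric",
  k2Bins = "data.frame",
  k2Window = "numeric",
  fieldFactors = "data.frame",
  meta = "list"
))

setValidity("CalibrationSet", function(object) {
  msg <- character()
  if (length(object@timeSlope) && object@timeSlope <= 0)
    msg <- c(msg, "time-calibration slope must be positive")
  if (length(object@k1)) {
    if (is.null(names(object@k1))) msg <- c(msg, "k1 must be named by leaf")
    if ("32" %in% names(object@k1) && abs(object@k1[["32"]] - 1) > 1e-9)
      msg <- c(msg, "k1 must be 1 at the reference leaf 32")
  }
  if (length(msg)) msg else TRUE
})

#' Corrected light and its per-projection accumulation
#'
#' The background-subtracted light after the two calibration corrections,
#' qc = q * k1 * k2, together with its accumulation into projections:
#' S[p, j] is the corrected light of leaf j summed over projection p, and
#' meanS the per-frame average (S divided by the frames contributing to the
#' projection), the quantity the open/closed threshold is compared against.
#'
#' @slot qc Corrected per-frame light, observed leaves x frames.
#' @slot S,meanS Projection sums and per-frame means, projections x leaves.
#' @slot framesPerProjection Effective frames contributing to each projection.
#' @slot method Frame-to-projection accumulation method used.
#' @slot timestamps,geometry Acquisition timing/geometry.
#' @seealso [applyCorrections()], [classifyOpen()], [reconstructSinogram()]
#' @export
setClass("CorrectedLight", representation(
  qc = "matrix",
  S = "matrix",
  meanS = "matrix",
  framesPerProjection = "numeric",
  method = "character",
  timestamps = "numeric",
  geometry = "TomoGeometry"
))

#' Verification scorecard of a reconstructed sinogram against the plan
#'
#' @slot sensitivity Fraction of truly open leaf-projection bins detected
#'   open.
#' @slot specificity Fraction of truly closed bins detected closed.
#' @slot youden sensitivity + specificity - 1.
#' @slot threshold Open/closed threshold used (pixel value).
#' @slot relativeError Percent error map, projections x observed leaves,
#'   normalized per projection by that projection's maximum planned fraction.
#' @slot leafOpenErrorMean,leafOpenErrorSd Mean and (population) SD of the
#'   relative errors, in percent: the "leaf open error".
#' @slot fractionWithin3pct Fraction of observed bins within +/- 3 percent.
#' @slot histogram data.frame of binned relative errors (1 percent bins).
#' @slot counts Confusion-matrix counts.
#' @slot meta Provenance list.
#' @seealso [verificationReport()], [confusionMetrics()], [leafOpenError()]
#' @export
setClass("VerificationReport", representation(
  sensitivity = "numeric",
  specificity = "numeric",
  youden = "numeric",
  threshold = "numeric",
  relativeError = "matrix",
  leafOpenErrorMean = "numeric",
  leafOpenErrorSd = "numeric",
  fractionWithin3pct = "numeric",
  histogram = "data.frame",
  counts = "list",
  meta = "list"
))

#' Gantry rotation trace and constant-speed fit
#'
#' Angular position of the narrow-beam edge tracked frame by frame, with the
#' least-squares speed fit and residuals against the theoretical
#' constant-speed line (360 / nominal period deg/s).
#'
#' @slot trace data.frame with columns time (s) and angle (degrees, unwrapped).
#' @slot speed,intercept Fitted angular speed (deg/s) and phase offset.
#' @slot nominalPeriod Nominal rotation period (s), NA if not supplied.
#' @slot residuals Residuals (degrees) against the theoretical line (against
#'   the fitted line when no nominal period is given).
#' @seealso [trackBeamEdge()], [fitRotation()]
#' @export
setClass("RotationTrace", representation(
  trace = "data.frame",
  speed = "numeric",
  intercept = "numeric",
  nominalPeriod = "numeric",
  residuals = "numeric"
))
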