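## Shared fixtures for the test suite.  Pipeline tests run on a reduced
## geometry (smaller image, narrower observed leaf range) so that rendered
## stacks stay cheap; the machine-side timing (64 leaves, 51 projections,
## 15 s rotation) is unchanged.

smallGeometry <- function(...) {
  tomoGeometry(imageSize = c(200L, 200L), observedLeaves = c(26L, 39L), ...)
}

## tiny canvas for tests that never read ROIs (e.g. artifact counting)
tinyGeometry <- function() tomoGeometry(imageSize = c(64L, 48L))

noiseFreeModel <- function(...) {
  opticalModel(pixelNoiseSd = 0, transientProb = 0, scatterAmp = 0,
               driftStart = 1, driftRate = 0, ...)
}

## memoised noise-free calibration on the small geometry (reused across
## reconstruction tests)
.cache <- new.env(parent = emptyenv())
smallNoiseFreeCal <- function() {
  if (is.null(.cache$cal))
    .cache$cal <- simulateCalibrationSession(noiseFreeModel(), smallGeometry(),
                                             seed = 97L, driftDuration = 0)
  .cache$cal
}

## FrameStack from an integer pixel array (synthetic measurement)
rawStack <- function(values, geometry, angles = NULL) {
  values <- array(as.raw(values), dim = dim(values))
  n <- dim(values)[3]
  ts <- (seq_len(n) - 1) / geometry@frameRate
  if (is.null(angles)) angles <- numeric(n)
  scintQA:::frameStack(values, ts, angles, geometry)
}

## constant-pixel stack
constantStack <- function(value, nFrames, geometry) {
  d <- c(geometry@imageSize, nFrames)
  rawStack(array(value, dim = d), geometry)
}

## synthetic LightRecord with given background-subtracted light
lightRecord <- function(q, geometry, bg = 0.36, leaves = NULL) {
  if (is.null(leaves)) leaves <- observedLeaves(geometry)[seq_len(nrow(q))]
  rownames(q) <- leaves
  n <- ncol(q)
  new("LightRecord", qraw = q + bg, q = q, bg = bg,
      timestamps = (seq_len(n) - 1) / geometry@frameRate,
      gantryAngles = numeric(n), geometry = geometry)
}
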