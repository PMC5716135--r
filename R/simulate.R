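## Per-frame open fraction of every leaf for a delivery of `sino`.
## Within each projection a leaf's open interval is centred: a fraction f
## maps to [(1-f)/2, (1+f)/2] of the projection window, mirroring how the
## binary MLC symmetrically gates the beam inside the projection.  Each
## frame's entry is the fraction of the frame period the leaf was open.
frameOpenFractions <- function(sino, geometry = sino@geometry) {
  v <- sinogramValues(sino)
  P <- nrow(v)
  Tp <- projectionDuration(geometry) / 1000
  dt <- framePeriod(geometry)
  nF <- ceiling(P * Tp / dt - 1e-9)
  fops <- matrix(0, nrow = geometry@nLeaves, ncol = nF)
  for (p in seq_len(P)) {
    js <- which(v[p, ] > 0)
    if (!length(js)) next
    f <- v[p, js]
    t0 <- (p - 1) * Tp + (1 - f) / 2 * Tp
    t1 <- (p - 1) * Tp + (1 + f) / 2 * Tp
    i0 <- floor(min(t0) / dt) + 1L
    i1 <- min(nF, floor(max(t1) / dt - 1e-12) + 1L)
    fr <- i0:i1
    starts <- (fr - 1) * dt
    ends <- fr * dt
    ov <- pmax(outer(t1, ends, pmin) - outer(t0, starts, pmax), 0) / dt
    fops[js, fr] <- fops[js, fr] + ov
  }
  list(fops = fops, timestamps = (seq_len(nF) - 1) * dt, nFrames = nF)
}

## Expected ROI amplitude (pv/frame) per leaf and frame: gain x lateral
## profile x drift x scatter-accumulated open fraction.
leafAmplitudes <- function(fops, midpoints, model, geometry) {
  K <- scatterMatrix(model, geometry@nLeaves)
  prof <- lateralProfileAt(model, seq_len(geometry@nLeaves), geometry)
  amp <- (K %*% fops) * prof
  sweep(amp, 2L, model@gain * driftAt(model, midpoints), "*")
}

renderStack <- function(amp, anglesDeg, model, geometry) {
  cpp_render_stack(amp, anglesDeg * pi / 180,
                   geometry@imageSize[1], geometry@imageSize[2],
                   geometry@isocenterPx[1], geometry@isocenterPx[2],
                   discRadiusPx(geometry), leafPitchPx(geometry),
                   (geometry@nLeaves + 1) / 2,
                   model@attenuationMu * geometry@pixelPitch / 10,
                   model@backgroundMean, model@pixelNoiseSd)
}

## Saturated-disc artifacts from scattered photons hitting the sensor:
## each frame is hit with probability `prob`; a hit saturates a disc of
## radius uniform in `radiusRange` at a uniform random position.
injectTransients <- function(frames, prob, radiusRange) {
  d <- dim(frames)
  if (prob <= 0 || d[3] == 0L) return(frames)
  hit <- which(runif(d[3]) < prob)
  for (i in hit) {
    r <- runif(1, radiusRange[1], radiusRange[2])
    px <- runif(1, 1, d[1])
    py <- runif(1, 1, d[2])
    xs <- max(1, floor(px - r)):min(d[1], ceiling(px + r))
    ys <- max(1, floor(py - r)):min(d[2], ceiling(py + r))
    msk <- outer(xs - px, ys - py, function(a, b) a^2 + b^2 <= r^2)
    sub <- frames[xs, ys, i, drop = FALSE]
    dim(sub) <- dim(msk)
    sub[msk] <- as.raw(255)
    frames[xs, ys, i] <- sub
  }
  frames
}

#' Count frames carrying a transient artifact
#'
#' Scans a stack for frames containing any pixel at or above \code{level};
#' with the default optical model the saturated transient discs (255) stand
#' far above beam light and noise, so this recovers the artifact count.
#'
#' @param stack A [FrameStack-class].
#' @param level Detection level in pixel values (default 200).
#' @return Integer number of affected frames.
#' @export
countTransientFrames <- function(stack, level = 200) {
  d <- dim(stack@frames)
  lvl <- as.raw(level)
  sum(vapply(seq_len(d[3]), function(i) any(stack@frames[, , i] >= lvl),
             logical(1)))
}

#' Simulate the camcorder recording of a delivery
#'
#' Renders one 8-bit frame per camera period over the whole delivery.  Each
#' leaf contributes light proportional to the fraction of the frame window
#' it was open, spread over neighbouring ROI positions by the scatter
#' kernel, scaled by the lateral profile and output drift, attenuated along
#' the beam path, rotated to the frame's gantry angle (constant angular
#' speed), with background and Gaussian pixel noise added, transient
#' artifacts injected, and the result quantized to 8 bits.
#'
#' @param sino The delivery [Sinogram-class].
#' @param model An [OpticalModel-class].
#' @param geometry A [TomoGeometry-class]; must agree with the sinogram's
#'   leaf count.
#' @param seed Integer seed; identical seeds give identical stacks.
#' @param rotateGantry If FALSE the gantry is held at 0 degrees.
#' @return A [FrameStack-class].
#' @examples
#' g <- tomoGeometry(imageSize = c(192L, 144L))
#' s <- simplePattern(g, nProjections = 2)
#' stk <- simulateDelivery(s, opticalModel(), g, seed = 1)
#' @export
simulateDelivery <- function(sino, model = opticalModel(),
                             geometry = sino@geometry, seed = 1L,
                             rotateGantry = TRUE) {
  stopifnot(is(sino, "Sinogram"), is(model, "OpticalModel"))
  if (ncol(sinogramValues(sino)) != geometry@nLeaves)
    stop("sinogram and geometry disagree on the number of leaves")
  set.seed(seed)
  fo <- frameOpenFractions(sino, geometry)
  mid <- fo$timestamps + framePeriod(geometry) / 2
  angles <- if (rotateGantry) 360 * mid / geometry@rotationPeriod else
    numeric(fo$nFrames)
  amp <- leafAmplitudes(fo$fops, mid, model, geometry)
  fr <- renderStack(amp, angles, model, geometry)
  fr <- injectTransients(fr, model@transientProb, model@transientRadius)
  frameStack(fr, fo$timestamps, angles, geometry, seed)
}

#' Simulate a static exposure
#'
#' Fixed gantry at 0 degrees with a given set of leaves opened for
#' \code{openTime} seconds from recording start, recorded for
#' \code{duration} seconds.  Used for the calibration measurements (open
#' -time linearity, lateral profile, field-size factors, output drift).
#'
#' @param openLeaves Integer leaf indices held open.
#' @param duration Recording length in seconds; the stack holds
#'   \code{floor(duration * frameRate)} frames (a warning is given when that
#'   is zero frames).
#' @param model,geometry,seed As in [simulateDelivery()].
#' @param openTime Beam-on time in seconds (default: the whole recording).
#'   Choose \code{duration > openTime} to capture all emitted light.
#' @return A [FrameStack-class].
#' @export
simulateStaticExposure <- function(openLeaves, duration,
                                   model = opticalModel(),
                                   geometry = tomoGeometry(), seed = 1L,
                                   openTime = duration) {
  stopifnot(duration > 0, openTime > 0)
  set.seed(seed)
  dt <- framePeriod(geometry)
  nF <- floor(duration / dt + 1e-9)
  if (nF == 0L)
    warning("recording shorter than one frame period: empty stack")
  ts <- (seq_len(nF) - 1) * dt
  fops <- matrix(0, geometry@nLeaves, nF)
  if (nF > 0L)
    fops[openLeaves, ] <- rep(pmax(0, pmin(openTime, ts + dt) - ts) / dt,
                              each = length(openLeaves))
  mid <- ts + dt / 2
  amp <- leafAmplitudes(fops, mid, model, geometry)
  fr <- renderStack(amp, numeric(nF), model, geometry)
  fr <- injectTransients(fr, model@transientProb, model@transientRadius)
  frameStack(fr, ts, numeric(nF), geometry, seed)
}

#' Simulate a rotating narrow-beam recording
#'
#' Single central leaf open continuously while the gantry rotates at a
#' constant nominal speed (optionally with an injected sinusoidal speed
#' fault), the measurement behind the rotational-stability check.
#'
#' @param period Rotation period in seconds.
#' @param duration Recording length in seconds (default one full rotation).
#' @param model,geometry,seed As in [simulateDelivery()].
#' @param leaf Open leaf (32 or 33 for a beam edge through the isocenter).
#' @param wobbleAmp Amplitude (degrees) of an injected angular fault.
#' @param wobbleCycles Fault cycles per rotation.
#' @return A [FrameStack-class].
#' @export
simulateRotation <- function(period, duration = period,
                             model = opticalModel(),
                             geometry = tomoGeometry(), seed = 1L,
                             leaf = 32L, wobbleAmp = 0, wobbleCycles = 1) {
  stopifnot(period > 0, duration > 0)
  set.seed(seed)
  dt <- framePeriod(geometry)
  nF <- floor(duration / dt + 1e-9)
  ts <- (seq_len(nF) - 1) * dt
  mid <- ts + dt / 2
  angles <- 360 * mid / period +
    wobbleAmp * sin(2 * pi * wobbleCycles * mid / period)
  fops <- matrix(0, geometry@nLeaves, nF)
  fops[leaf, ] <- 1
  amp <- leafAmplitudes(fops, mid, model, geometry)
  fr <- renderStack(amp, angles, model, geometry)
  fr <- injectTransients(fr, model@transientProb, model@transientRadius)
  frameStack(fr, ts, angles, geometry, seed)
}

#' Noise-free light pattern of an open-leaf configuration
#'
#' Evaluates the un-quantized forward light model (no background, no noise)
#' for one frame, mainly to check model-level properties such as
#' superposition of disjoint open-leaf sets.
#'
#' @param openFractions Numeric vector of per-leaf open fractions.
#' @param model,geometry As in [simulateDelivery()].
#' @param angle Gantry angle in degrees.
#' @param time Beam-on time (seconds) for the drift factor.
#' @return Numeric pixel matrix (width x height).
#' @export
lightPattern <- function(openFractions, model = opticalModel(),
                         geometry = tomoGeometry(), angle = 0, time = 0) {
  stopifnot(length(openFractions) == geometry@nLeaves)
  amp <- leafAmplitudes(matrix(openFractions, ncol = 1), time, model, geometry)
  cpp_render_frame_values(amp[, 1], angle * pi / 180,
                          geometry@imageSize[1], geometry@imageSize[2],
                          geometry@isocenterPx[1], geometry@isocenterPx[2],
                          discRadiusPx(geometry), leafPitchPx(geometry),
                          (geometry@nLeaves + 1) / 2,
                          model@attenuationMu * geometry@pixelPitch / 10)
}
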