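#' Track the narrow-beam edge angle across frames
#'
#' For a recording with a single central leaf open while the gantry
#' rotates, each frame shows a narrow stripe through the isocenter.  The
#' intensity profile is sampled on a circle of radius \code{radius} pixels
#' around the isocenter; the edge of the stripe that passes through the
#' isocenter is located as the 50 percent-of-maximum crossing on the
#' trailing side of the brightest lobe (the beam-entry side, which
#' attenuation makes brighter than the exit side, fixing the half-turn
#' ambiguity of a diameter-shaped stripe).  Frames without a detectable
#' beam are skipped with a warning.  Angles are unwrapped assuming less
#' than a half turn between consecutive frames.
#'
#' @param stack A [FrameStack-class] of a rotating narrow-beam delivery.
#' @param radius Sampling-ring radius in pixels; the default uses
#'   three-quarters of the largest ring that fits the image (180 px on the
#'   default 640 x 480 geometry).
#' @param phiStep Angular sampling step in degrees (default 0.2).
#' @param minSignal Minimum peak height (pixel values above background) for
#'   a frame to count as "beam on".
#' @return A [RotationTrace-class] with the per-frame times and unwrapped
#'   edge angles (fit slots empty until [fitRotation()] is called).
#' @export
trackBeamEdge <- function(stack, radius = NULL, phiStep = 0.2,
                          minSignal = 5) {
  g <- stack@geometry
  maxR <- min(g@isocenterPx, g@imageSize - g@isocenterPx)
  if (is.null(radius)) radius <- floor(0.75 * maxR / 10) * 10
  if (radius >= maxR)
    stop("sampling ring does not fit inside the image")
  phi <- seq(0, 360 - phiStep, by = phiStep)
  pts <- cbind(g@isocenterPx[1] + radius * sin(phi * pi / 180),
               g@isocenterPx[2] - radius * cos(phi * pi / 180))
  prof <- cpp_sample_stack(stack@frames, pts,
                           numeric(nFrames(stack)),
                           g@isocenterPx[1], g@isocenterPx[2], 0)
  n <- length(phi)
  angles <- rep(NA_real_, nFrames(stack))
  for (f in seq_len(nFrames(stack))) {
    y <- prof[, f] - median(prof[, f])
    pk <- which.max(y)
    if (y[pk] < minSignal) next
    level <- y[pk] / 2
    ## walk clockwise (increasing phi, circular) to the 50% crossing of the
    ## lobe's leading edge
    for (stp in seq_len(n - 1L)) {
      i <- (pk + stp - 1L) %% n + 1L
      if (y[i] < level) {
        j <- (pk + stp - 2L) %% n + 1L  # last index still above level
        frac <- (y[j] - level) / (y[j] - y[i])
        angles[f] <- (phi[j] + frac * phiStep) %% 360
        break
      }
    }
  }
  bad <- is.na(angles)
  if (any(bad))
    warning(sum(bad), " frame(s) without a detectable beam were skipped")
  t <- frameMidpoints(stack)[!bad]
  a <- angles[!bad]
  ## unwrap: < 180 degrees between consecutive tracked frames
  if (length(a) > 1L) {
    d <- diff(a)
    jump <- cumsum(c(0, ifelse(d < -180, 360, ifelse(d > 180, -360, 0))))
    a <- a + jump
  }
  new("RotationTrace", trace = data.frame(time = t, angle = a),
      speed = numeric(), intercept = numeric(),
      nominalPeriod = NA_real_, residuals = numeric())
}

#' Fit a constant rotation speed to a trace
#'
#' Least-squares line angle = speed * t + offset through the unwrapped
#' trace.  When a nominal period is given, residuals are computed against
#' the theoretical constant-speed line (slope 360/nominalPeriod deg/s, with
#' a free phase offset); otherwise against the fitted line.
#'
#' @param trace A [RotationTrace-class] from [trackBeamEdge()].
#' @param nominalPeriod Nominal rotation period in seconds (optional).
#' @return The trace with \code{speed} (deg/s), \code{intercept} and
#'   \code{residuals} (degrees) filled in.
#' @export
fitRotation <- function(trace, nominalPeriod = NA_real_) {
  tr <- trace@trace
  if (nrow(tr) < 3L) stop("need at least three tracked frames")
  if (any(abs(diff(tr$angle)) > 180))
    stop("unwrapping failure: gaps above a half turn between frames")
  fit <- lm(angle ~ time, data = tr)
  speed <- unname(coef(fit)[2])
  if (is.na(nominalPeriod)) {
    res <- unname(residuals(fit))
  } else {
    slope0 <- 360 / nominalPeriod
    offs <- mean(tr$angle - slope0 * tr$time)
    res <- tr$angle - (slope0 * tr$time + offs)
  }
  new("RotationTrace", trace = tr, speed = speed,
      intercept = unname(coef(fit)[1]),
      nominalPeriod = as.numeric(nominalPeriod), residuals = res)
}

setMethod("show", "RotationTrace", function(object) {
  cat("RotationTrace:", nrow(object@trace), "tracked frames")
  if (length(object@speed)) {
    cat(sprintf("; fitted speed %.3f deg/s", object@speed))
    if (!is.na(object@nominalPeriod))
      cat(sprintf(" (nominal %.3f)", 360 / object@nominalPeriod))
    cat(sprintf("; max |residual| %.2f deg", max(abs(object@residuals))))
  }
  cat("\n")
})

#' Maximum residual of a fitted rotation trace
#' @param trace A fitted [RotationTrace-class].
#' @return Degrees.
#' @export
maxResidual <- function(trace) {
  if (!length(trace@residuals)) stop("trace has not been fitted")
  max(abs(trace@residuals))
}

#' Write a rotation trace as CSV
#' @param trace A [RotationTrace-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeTrace <- function(trace, path) {
  df <- trace@trace
  if (length(trace@residuals) == nrow(df)) df$residual <- trace@residuals
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
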