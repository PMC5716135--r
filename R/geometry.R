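#' Construct the machine/imaging geometry
#'
#' Builds a [TomoGeometry-class] with the defaults of the verification unit:
#' a 64-leaf binary MLC (0.625 cm leaf width, 40 cm field), 51 projections
#' per rotation at a 15 s rotation period, a 20 cm diameter scintillator
#' imaged at 0.468 mm/pixel on 640 x 480 8-bit frames at 29.97 fps, with
#' 5 x 5 pixel photometry ROIs and leaves 18-47 observable.
#'
#' @param nLeaves,observedLeaves,nProjPerRotation,rotationPeriod,leafWidthIso
#'   Machine-side parameters; see [TomoGeometry-class].
#' @param scintDiameter,scintLength,pixelPitch,imageSize,frameRate,roiSize
#'   Measurement-side parameters; see [TomoGeometry-class].
#' @param isocenterPx Rotation-center pixel; defaults to the image center.
#' @return A validated [TomoGeometry-class] object.
#' @examples
#' g <- tomoGeometry()
#' projectionDuration(g)  # 294.12 ms
#' @export
tomoGeometry <- function(nLeaves = 64L,
                         observedLeaves = c(18L, 47L),
                         nProjPerRotation = 51L,
                         rotationPeriod = 15,
                         leafWidthIso = 0.625,
                         scintDiameter = 20,
                         scintLength = 10,
                         pixelPitch = 0.468,
                         imageSize = c(640L, 480L),
                         frameRate = 29.97,
                         roiSize = 5L,
                         isocenterPx = imageSize / 2) {
  new("TomoGeometry",
      nLeaves = as.integer(nLeaves),
      observedLeaves = as.integer(observedLeaves),
      nProjPerRotation = as.integer(nProjPerRotation),
      rotationPeriod = as.numeric(rotationPeriod),
      leafWidthIso = as.numeric(leafWidthIso),
      scintDiameter = as.numeric(scintDiameter),
      scintLength = as.numeric(scintLength),
      pixelPitch = as.numeric(pixelPitch),
      imageSize = as.integer(imageSize),
      frameRate = as.numeric(frameRate),
      roiSize = as.integer(roiSize),
      isocenterPx = as.numeric(isocenterPx))
}

#' @describeIn tomoGeometry observed leaf indices of a geometry
#' @param x A [TomoGeometry-class].
#' @export
setMethod("observedLeaves", "TomoGeometry", function(x) {
  seq.int(x@observedLeaves[1], x@observedLeaves[2])
})

#' Duration of one projection
#'
#' One gantry rotation delivers \code{nProjPerRotation} equal projections, so
#' each projection lasts \code{rotationPeriod / nProjPerRotation}: 294.12 ms
#' for the default 15 s / 51 projections.
#'
#' @param geometry A [TomoGeometry-class].
#' @return Projection duration in milliseconds (unrounded).
#' @examples
#' round(projectionDuration(tomoGeometry()), 2)                       # 294.12
#' round(projectionDuration(tomoGeometry(rotationPeriod = 60)), 2)    # 1176.47
#' @export
projectionDuration <- function(geometry) {
  stopifnot(is(geometry, "TomoGeometry"))
  if (geometry@rotationPeriod <= 0 || geometry@nProjPerRotation < 1L)
    stop("invalid geometry: rotation period must be positive and ",
         "projections per rotation >= 1")
  geometry@rotationPeriod / geometry@nProjPerRotation * 1000
}

#' Leaf open time of a sinogram fraction
#'
#' A sinogram entry is the fraction of the projection duration for which the
#' leaf is open; 0.5 at the default geometry is 147.06 ms.
#'
#' @param fraction Open fraction(s) in [0, 1].
#' @param geometry A [TomoGeometry-class].
#' @return Open time(s) in milliseconds.
#' @examples
#' round(openTimeMs(0.5, tomoGeometry()), 2)  # 147.06
#' @export
openTimeMs <- function(fraction, geometry) {
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE) || anyNA(fraction))
    stop("open fractions must lie in [0, 1]")
  fraction * projectionDuration(geometry)
}

#' Nominal frame period
#' @param geometry A [TomoGeometry-class].
#' @return Frame period in seconds (1/29.97 s by default).
#' @export
framePeriod <- function(geometry) 1 / geometry@frameRate

## pixels per leaf width (6.25 mm / 0.468 mm px^-1 = 13.35 px by default)
leafPitchPx <- function(geometry) geometry@leafWidthIso * 10 / geometry@pixelPitch

## scintillator radius in pixels
discRadiusPx <- function(geometry) geometry@scintDiameter / 2 * 10 / geometry@pixelPitch

## x position (pixels) of the centre of leaf j; the boundary between the two
## central leaves sits at the isocenter column
leafCenterPx <- function(geometry, j) {
  geometry@isocenterPx[1] + (j - (geometry@nLeaves + 1) / 2) * leafPitchPx(geometry)
}

setMethod("show", "TomoGeometry", function(object) {
  cat("TomoGeometry:", object@nLeaves, "leaves x", object@leafWidthIso,
      "cm; observed", object@observedLeaves[1], "-", object@observedLeaves[2],
      "\n  ", object@nProjPerRotation, "projections per",
      object@rotationPeriod, "s rotation (",
      sprintf("%.2f", projectionDuration(object)), "ms/projection)\n",
      "  image", object@imageSize[1], "x", object@imageSize[2], "px @",
      object@frameRate, "fps,", object@pixelPitch, "mm/px, ROI",
      object@roiSize, "x", object@roiSize, "px\n")
})
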