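#' Number of projections of a sinogram
#' @param x A [Sinogram-class].
#' @return Integer projection count.
#' @export
setGeneric("nProjections", function(x) standardGeneric("nProjections"))

#' Open-fraction matrix of a sinogram
#' @param x A [Sinogram-class].
#' @return Numeric matrix, projections x leaves.
#' @export
setGeneric("sinogramValues", function(x) standardGeneric("sinogramValues"))

#' Modulation factor of a delivery plan
#'
#' Maximum leaf open time divided by the average leaf open time.  By default
#' the average runs over the nonzero open times only, so that leaves that
#' never open do not make the factor depend on the plan size; set
#' \code{population = "all"} to average over every leaf-projection bin.
#'
#' @param x A [Sinogram-class].
#' @param population Either "nonzero" (default) or "all".
#' @return The modulation factor, a unitless number >= 1 for "nonzero".
#' @examples
#' g <- tomoGeometry()
#' modulationFactor(simplePattern(g, nProjections = 5))  # constant plan -> 1
#' @export
setGeneric("modulationFactor",
           function(x, population = c("nonzero", "all"))
             standardGeneric("modulationFactor"))

#' Number of frames in a stack
#' @param x A [FrameStack-class].
#' @return Integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Extract one frame as a numeric pixel matrix
#' @param x A [FrameStack-class].
#' @param i Frame index.
#' @return Numeric matrix (width x height) of pixel values 0-255.
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' Per-frame gantry angles
#' @param x A [FrameStack-class] or [LightRecord-class].
#' @return Numeric vector of degrees.
#' @export
setGeneric("gantryAngles", function(x) standardGeneric("gantryAngles"))

#' Frame timestamps
#' @param x A [FrameStack-class] or [LightRecord-class].
#' @return Numeric vector of frame start times in seconds.
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' Accumulated light per leaf (Q)
#'
#' Sums the background-subtracted per-frame light over all frames of the
#' record, giving the accumulated light Q for each observed leaf.
#'
#' @param x A [LightRecord-class].
#' @return Named numeric vector, one value per observed leaf.
#' @export
setGeneric("accumulatedLight", function(x) standardGeneric("accumulatedLight"))

#' Leaves covered by a record or geometry
#' @param x A [TomoGeometry-class] or [LightRecord-class].
#' @return Integer vector of observed leaf indices.
#' @export
setGeneric("observedLeaves", function(x) standardGeneric("observedLeaves"))
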