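frameStack <- function(frames, timestamps, gantryAngles, geometry,
                       seed = NA_integer_) {
  new("FrameStack", frames = frames, timestamps = timestamps,
      gantryAngles = gantryAngles, geometry = geometry,
      seed = as.integer(seed))
}

#' @rdname nFrames
#' @export
setMethod("nFrames", "FrameStack", function(x) dim(x@frames)[3])

#' @rdname getFrame
#' @export
setMethod("getFrame", "FrameStack", function(x, i) {
  d <- dim(x@frames)
  if (i < 1L || i > d[3]) stop("frame index out of range")
  matrix(as.integer(x@frames[, , i]), nrow = d[1], ncol = d[2])
})

#' @rdname gantryAngles
#' @export
setMethod("gantryAngles", "FrameStack", function(x) x@gantryAngles)

#' @rdname timestamps
#' @export
setMethod("timestamps", "FrameStack", function(x) x@timestamps)

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat("FrameStack:", d[3], "frames of", d[1], "x", d[2], "px, t =",
      sprintf("%.3f", object@timestamps[1]), "..",
      sprintf("%.3f s", object@timestamps[d[3]] + framePeriod(object@geometry)),
      "\n  gantry", sprintf("%.1f", min(object@gantryAngles)), "-",
      sprintf("%.1f deg", max(object@gantryAngles)),
      if (!is.na(object@seed)) paste("; seed", object@seed) else "", "\n")
})

#' Frame midpoint times
#'
#' Midpoint time of each frame's exposure window, the time used for
#' projection binning and drift lookups.
#'
#' @param x A [FrameStack-class] or [LightRecord-class].
#' @return Numeric vector of seconds.
#' @export
frameMidpoints <- function(x) {
  g <- if (is(x, "FrameStack")) x@geometry else x@geometry
  timestamps(x) + framePeriod(g) / 2
}

#' Write / read a frame stack on disk
#'
#' Two dialects are supported.  \code{format = "png"} writes a directory of
#' 8-bit grayscale PNG images (\code{frame_00001.png}, ...) with a
#' \code{frames.csv} sidecar (frame index, timestamp, gantry angle) and a
#' \code{meta.json}; \code{format = "rds"} writes a single compressed array
#' archive.  \code{readFrameStack} auto-detects the dialect.
#'
#' @param x A [FrameStack-class].
#' @param path Directory (png) or file path (rds).
#' @param format "png" or "rds".
#' @return \code{writeFrameStack} returns \code{path} invisibly;
#'   \code{readFrameStack} returns a [FrameStack-class].
#' @export
writeFrameStack <- function(x, path, format = c("png", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(list(frames = x@frames, timestamps = x@timestamps,
                 gantryAngles = x@gantryAngles,
                 geometry = geometryToList(x@geometry), seed = x@seed),
            path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(x@frames)
  for (i in seq_len(d[3])) {
    ## png images are row-major from the top: transpose our (x, y) layout
    img <- t(matrix(as.integer(x@frames[, , i]), d[1], d[2])) / 255
    png::writePNG(img, file.path(path, sprintf("frame_%05d.png", i)))
  }
  sidecar <- data.frame(frame = seq_len(d[3]), timestamp = x@timestamps,
                        gantry_angle = x@gantryAngles)
  write.table(sidecar, file.path(path, "frames.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(geometryToList(x@geometry), list(seed = x@seed)),
                       file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeFrameStack
#' @export
readFrameStack <- function(path) {
  if (!dir.exists(path)) {
    z <- readRDS(path)
    return(frameStack(z$frames, z$timestamps, z$gantryAngles,
                      do.call(tomoGeometry, z$geometry), z$seed))
  }
  sidecar <- read.table(file.path(path, "frames.csv"), sep = ",", header = TRUE)
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  seed <- meta$seed
  meta$seed <- NULL
  geometry <- do.call(tomoGeometry, meta)
  files <- file.path(path, sprintf("frame_%05d.png", sidecar$frame))
  first <- png::readPNG(files[1])
  nx <- ncol(first); ny <- nrow(first)
  fr <- array(as.raw(0), dim = c(nx, ny, length(files)))
  for (i in seq_along(files)) {
    img <- if (i == 1L) first else png::readPNG(files[i])
    fr[, , i] <- as.raw(round(t(img) * 255))
  }
  frameStack(fr, sidecar$timestamp, sidecar$gantry_angle, geometry,
             if (is.null(seed) || is.na(seed)) NA_integer_ else seed)
}

geometryToList <- function(g) {
  list(nLeaves = g@nLeaves, observedLeaves = g@observedLeaves,
       nProjPerRotation = g@nProjPerRotation,
       rotationPeriod = g@rotationPeriod, leafWidthIso = g@leafWidthIso,
       scintDiameter = g@scintDiameter, scintLength = g@scintLength,
       pixelPitch = g@pixelPitch, imageSize = g@imageSize,
       frameRate = g@frameRate, roiSize = g@roiSize,
       isocenterPx = g@isocenterPx)
}

#' Rotate a frame about the isocenter
#'
#' Bilinear rotation of a pixel matrix by \code{angle} degrees (clockwise,
#' the gantry convention) about the isocenter pixel; out-of-bounds source
#' pixels are filled with \code{fill}.  Rotating by the recorded gantry
#' angle's negative brings a frame back to the 0 degree reference.
#'
#' @param frame Numeric pixel matrix (width x height) or a
#'   [FrameStack-class] with \code{i} given.
#' @param angle Degrees.
#' @param geometry A [TomoGeometry-class] fixing the rotation centre.
#' @param fill Fill value for pixels from outside the image.
#' @param i Frame index when \code{frame} is a stack.
#' @return Numeric pixel matrix.
#' @export
rotateFrame <- function(frame, angle, geometry = tomoGeometry(), fill = 0,
                        i = 1L) {
  if (is(frame, "FrameStack")) {
    geometry <- frame@geometry
    frame <- getFrame(frame, i)
  }
  cpp_rotate_frame(frame, angle * pi / 180, geometry@isocenterPx[1],
                   geometry@isocenterPx[2], fill)
}
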