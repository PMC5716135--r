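#' Construct a sinogram from an open-fraction matrix
#'
#' @param values Numeric matrix, projections x leaves, entries in [0, 1].
#' @param geometry A [TomoGeometry-class]; the column count must match its
#'   leaf count.
#' @return A [Sinogram-class].
#' @export
sinogram <- function(values, geometry = tomoGeometry()) {
  values <- as.matrix(values)
  dimnames(values) <- NULL
  new("Sinogram", values = values, geometry = geometry)
}

#' @rdname nProjections
#' @export
setMethod("nProjections", "Sinogram", function(x) nrow(x@values))

#' @rdname sinogramValues
#' @export
setMethod("sinogramValues", "Sinogram", function(x) x@values)

#' @rdname modulationFactor
#' @export
setMethod("modulationFactor", "Sinogram", function(x, population = c("nonzero", "all")) {
  population <- match.arg(population)
  v <- x@values
  open <- v[v > 0]
  if (!length(open)) stop("modulation factor is undefined for an all-zero sinogram")
  if (population == "nonzero") max(open) / mean(open) else max(v) / mean(v)
})

setMethod("show", "Sinogram", function(object) {
  v <- object@values
  mf <- if (any(v > 0)) sprintf("%.3f", max(v[v > 0]) / mean(v[v > 0])) else "NA"
  cat("Sinogram:", nrow(v), "projections x", ncol(v), "leaves;",
      sum(v > 0), "open bins; modulation factor", mf, "\n")
})

#' Simple all-open verification pattern
#'
#' Every observed leaf open for the whole projection duration, repeated for
#' \code{nProjections} projections (default 133); leaves outside the
#' observed range stay closed.  This is the constant pattern used to probe
#' the system at its widest monitored field.
#'
#' @param geometry A [TomoGeometry-class].
#' @param nProjections Number of projections (default 133).
#' @return A [Sinogram-class].
#' @export
simplePattern <- function(geometry = tomoGeometry(), nProjections = 133L) {
  if (nProjections < 1L) stop("nProjections must be >= 1")
  v <- matrix(0, nrow = nProjections, ncol = geometry@nLeaves)
  v[, observedLeaves(geometry)] <- 1
  sinogram(v, geometry)
}

#' Clinical-like modulated pattern
#'
#' Statistical stand-in for a clinical prostate plan: a per-projection
#' contiguous open aperture whose centre drifts sinusoidally across the
#' observed range, with log-normal per-leaf jitter on the open fractions,
#' clipped to [0.07, 1] (a 0.07 fraction is about the 20 ms clinical minimum
#' leaf open time), then affinely rescaled so the modulation factor matches
#' \code{targetModulation} within 1 percent.
#'
#' @param geometry A [TomoGeometry-class].
#' @param nProjections Number of projections (default 643).
#' @param targetModulation Target modulation factor (default 1.649).
#' @param seed Integer seed; the same seed reproduces the same plan.
#' @param jitterSd Log-normal sdlog of the per-leaf fraction jitter; 0 gives
#'   a deterministic aperture with constant fractions (then only
#'   \code{targetModulation = } the unscaled factor is attainable).
#' @return A [Sinogram-class].
#' @examples
#' s <- clinicalPattern(nProjections = 40, seed = 1)
#' modulationFactor(s)
#' @export
clinicalPattern <- function(geometry = tomoGeometry(), nProjections = 643L,
                            targetModulation = 1.649, seed = 1L,
                            jitterSd = 0.35) {
  if (nProjections < 1L) stop("nProjections must be >= 1")
  if (targetModulation < 1) stop("modulation factor targets must be >= 1")
  set.seed(seed)
  ol <- observedLeaves(geometry)
  nL <- geometry@nLeaves
  v <- matrix(0, nrow = nProjections, ncol = nL)
  mid <- mean(ol)
  span <- diff(range(ol))
  phase <- runif(1, 0, 2 * pi)
  for (p in seq_len(nProjections)) {
    centre <- mid + span / 5 * sin(2 * pi * p / geometry@nProjPerRotation + phase)
    halfw <- span / 4 * (1 + 0.4 * sin(2 * pi * p / (3.1 * geometry@nProjPerRotation)))
    leaves <- ol[ol >= centre - halfw & ol <= centre + halfw]
    if (!length(leaves)) leaves <- round(centre)
    shape <- 0.6 + 0.4 * cos((leaves - centre) / (halfw + 0.5) * pi / 2)
    jit <- if (jitterSd > 0) exp(rnorm(length(leaves), 0, jitterSd)) else 1
    v[p, leaves] <- pmin(1, pmax(0.07, shape * jit))
  }
  if (jitterSd == 0 && targetModulation == 1) {
    v[v > 0] <- 1
    return(sinogram(v, geometry))
  }
  ## affine rescale of the open fractions so max/mean hits the target:
  ## f' = (f + rho) / (fmax + rho) has modulation (fmax + rho)/(fmean + rho);
  ## clipping to [0.07, 1] perturbs it slightly, so iterate a few times.
  for (it in 1:40) {
    open <- v > 0
    f <- v[open]
    fmax <- max(f); fmean <- mean(f)
    m0 <- fmax / fmean
    if (abs(m0 - targetModulation) / targetModulation < 0.005) break
    rho <- (fmax - targetModulation * fmean) / (targetModulation - 1)
    if (!is.finite(rho) || fmax + rho <= 0)
      stop("target modulation unattainable for this pattern")
    v[open] <- pmin(1, pmax(0.07, (f + rho) / (fmax + rho)))
  }
  mf <- modulationFactor(sinogram(v, geometry))
  if (abs(mf - targetModulation) / targetModulation > 0.01)
    stop(sprintf("could not reach target modulation %.3f (got %.3f)",
                 targetModulation, mf))
  sinogram(v, geometry)
}

#' Read / write sinogram CSV files
#'
#' The on-disk format is a headerless CSV with one row per projection and one
#' comma-separated open fraction per leaf; lines starting with "#" are
#' comments.  A write followed by a read reproduces the values exactly.
#'
#' @param path File path.
#' @param geometry Geometry for the read sinogram.
#' @return \code{readSinogram} returns a [Sinogram-class];
#'   \code{writeSinogram} returns \code{path} invisibly.
#' @export
readSinogram <- function(path, geometry = tomoGeometry()) {
  v <- as.matrix(read.table(path, sep = ",", comment.char = "#",
                            header = FALSE))
  sinogram(v, geometry)
}

#' @rdname readSinogram
#' @param x A [Sinogram-class] to write.
#' @export
writeSinogram <- function(x, path) {
  stopifnot(is(x, "Sinogram"))
  ## full precision so that the round trip is bit-identical
  lines <- apply(x@values, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
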