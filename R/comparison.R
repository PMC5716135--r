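#' Confusion metrics between plan and reconstruction
#'
#' A leaf-projection bin is "open" when its fraction is greater than zero.
#' Sensitivity is the fraction of truly open bins detected open;
#' specificity the fraction of truly closed bins detected closed.  Both are
#' computed over the observed leaves only (the detector cannot see the
#' rest).  When the truth has no open (or no closed) bins the corresponding
#' rate is NaN with a warning.
#'
#' @param truth,reconstructed [Sinogram-class] objects (or matrices over the
#'   same bins) of identical shape.
#' @param geometry Geometry fixing the observed leaf range.
#' @return List with sensitivity, specificity and the confusion counts.
#' @export
confusionMetrics <- function(truth, reconstructed,
                             geometry = if (is(truth, "Sinogram"))
                               truth@geometry else tomoGeometry()) {
  tv <- restrictToObserved(truth, geometry)
  rv <- restrictToObserved(reconstructed, geometry)
  if (!all(dim(tv) == dim(rv))) stop("sinogram shapes differ")
  open <- tv > 0
  call <- rv > 0
  tp <- sum(open & call); fn <- sum(open & !call)
  tn <- sum(!open & !call); fp <- sum(!open & call)
  if (tp + fn == 0L) warning("no open bins in truth: sensitivity is NaN")
  if (tn + fp == 0L) warning("no closed bins in truth: specificity is NaN")
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       counts = list(tp = tp, fn = fn, tn = tn, fp = fp))
}

restrictToObserved <- function(x, geometry) {
  v <- if (is(x, "Sinogram")) sinogramValues(x) else as.matrix(x)
  if (ncol(v) == geometry@nLeaves)
    v <- v[, observedLeaves(geometry), drop = FALSE]
  v
}

#' Relative-error map between plan and reconstruction
#'
#' Per bin: \code{(reconstructed - truth) / max(truth over the projection's
#' leaves) * 100}, i.e. the difference normalized by each projection's
#' maximum planned fraction, in percent.  Projections whose truth row is
#' all zero yield a zero row with a warning.
#'
#' @inheritParams confusionMetrics
#' @return Percent error matrix, projections x observed leaves.
#' @export
relativeErrorMap <- function(truth, reconstructed,
                             geometry = if (is(truth, "Sinogram"))
                               truth@geometry else tomoGeometry()) {
  tv <- restrictToObserved(truth, geometry)
  rv <- restrictToObserved(reconstructed, geometry)
  if (!all(dim(tv) == dim(rv))) stop("sinogram shapes differ")
  rowMax <- apply(tv, 1L, max)
  if (any(rowMax == 0)) {
    warning(sum(rowMax == 0), " projection(s) with all-zero truth: ",
            "their error rows are reported as 0")
  }
  err <- (rv - tv) / ifelse(rowMax > 0, rowMax, Inf) * 100
  err
}

#' Leaf-open-error statistics of a relative-error map
#'
#' The "leaf open error" is the mean and (population) standard deviation of
#' the per-bin relative errors over all observed bins, together with the
#' fraction of bins within +/- \code{tolerancePct}.
#'
#' @param relErr Percent error matrix from [relativeErrorMap()].
#' @param tolerancePct Tolerance for the within-fraction (default 3).
#' @return List with mean, sd and fractionWithin.
#' @examples
#' leafOpenError(matrix(c(-3, 0, 3, 6), 2))  # mean 1.5, 3/4 within 3 pct
#' @export
leafOpenError <- function(relErr, tolerancePct = 3) {
  if (!length(relErr)) stop("empty error map")
  n <- length(relErr)
  m <- mean(relErr)
  list(mean = m,
       sd = sqrt(sum((relErr - m)^2) / n),
       fractionWithin = mean(abs(relErr) <= tolerancePct))
}

#' Full verification report
#'
#' Scores a reconstructed sinogram against the plan: confusion metrics and
#' Youden index, the relative-error map, the leaf-open-error statistics,
#' the within +/- 3 percent fraction, and a signed histogram of the relative
#' errors in \code{binWidth}-percent bins.
#'
#' @inheritParams confusionMetrics
#' @param threshold The open/closed threshold used (pixel value), recorded
#'   in the report.
#' @param binWidth Histogram bin width in percent (default 1).
#' @param meta Provenance list stored in the report.
#' @return A [VerificationReport-class].
#' @export
verificationReport <- function(truth, reconstructed, threshold = NA_real_,
                               geometry = if (is(truth, "Sinogram"))
                                 truth@geometry else tomoGeometry(),
                               binWidth = 1, meta = list()) {
  cm <- confusionMetrics(truth, reconstructed, geometry)
  relErr <- relativeErrorMap(truth, reconstructed, geometry)
  loe <- leafOpenError(relErr)
  breaks <- seq(floor(min(relErr, -1)) - 0.5 * binWidth,
                ceiling(max(relErr, 1)) + 1.5 * binWidth, by = binWidth)
  h <- hist(as.numeric(relErr), breaks = breaks, plot = FALSE)
  new("VerificationReport",
      sensitivity = cm$sensitivity, specificity = cm$specificity,
      youden = youdenIndex(cm$sensitivity, cm$specificity),
      threshold = as.numeric(threshold), relativeError = relErr,
      leafOpenErrorMean = loe$mean, leafOpenErrorSd = loe$sd,
      fractionWithin3pct = loe$fractionWithin,
      histogram = data.frame(mid = h$mids, count = h$counts,
                             density = h$density),
      counts = cm$counts, meta = meta)
}

setMethod("show", "VerificationReport", function(object) {
  cat("VerificationReport\n")
  cat(sprintf("  threshold        : %s pv\n",
              ifelse(is.na(object@threshold), "-", object@threshold)))
  cat(sprintf("  sensitivity      : %.3f\n", object@sensitivity))
  cat(sprintf("  specificity      : %.3f\n", object@specificity))
  cat(sprintf("  Youden index     : %.3f\n", object@youden))
  cat(sprintf("  leaf open error  : %.1f +/- %.1f %%\n",
              object@leafOpenErrorMean, object@leafOpenErrorSd))
  cat(sprintf("  within +/-3%%     : %.1f %%\n",
              100 * object@fractionWithin3pct))
})

#' Write a verification report as JSON
#'
#' @param report A [VerificationReport-class].
#' @param path Output path.
#' @param includeMap Include the full relative-error map (default FALSE:
#'   only the summary statistics and histogram are written).
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path, includeMap = FALSE) {
  out <- list(sensitivity = report@sensitivity,
              specificity = report@specificity,
              youden = report@youden,
              threshold = report@threshold,
              leaf_open_error_mean_pct = report@leafOpenErrorMean,
              leaf_open_error_sd_pct = report@leafOpenErrorSd,
              fraction_within_3pct = report@fractionWithin3pct,
              counts = report@counts,
              histogram = report@histogram,
              meta = report@meta)
  if (includeMap) out$relative_error_pct <- report@relativeError
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
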