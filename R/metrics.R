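# Reconstruction-quality metrics: min-max standardization, standardized
# difference images, per-channel colour differences, the root-summed
# benchmark, and histogram distinguishability statistics.

#' Min-max standardization
#'
#' Rescales the whole input (global minimum and maximum, not per channel)
#' onto [0,1]: \code{(x - min) / (max - min)}. A constant input — a
#' legitimate case for difference images of identical frames — maps to
#' all zeros rather than raising.
#'
#' @param x non-empty numeric vector, matrix or array.
#' @return object of the same shape with values in [0,1].
#' @export
standardizeImage <- function(x) {
  if (length(x) == 0L) stop("cannot standardize an empty input")
  mn <- min(x); mx <- max(x)
  if (!is.finite(mn) || !is.finite(mx))
    stop("input contains non-finite values")
  if (mx == mn) {
    x[] <- 0
    return(x)
  }
  (x - mn) / (mx - mn)
}

#' Standardized difference image (DIFF)
#'
#' The min-max standardized subtraction of two same-shape images,
#' guaranteeing all pixel values lie in [0,1]. This is the image that
#' reveals subject contours the reconstruction smooths away.
#'
#' @param x,y image arrays of identical shape.
#' @return array of the same shape, values in [0,1].
#' @export
imageDiff <- function(x, y) {
  if (!identical(dim(x), dim(y)))
    stop("imageDiff requires images of identical shape")
  standardizeImage(x - y)
}

#' Per-channel colour difference
#'
#' Mean over pixels of the squared difference between one colour plane of
#' two images. The mean (rather than the sum) keeps the statistic
#' independent of image area; pass \code{aggregate = "sum"} to audit the
#' unnormalized variant.
#'
#' @param x,y image arrays of identical shape.
#' @param channel channel index in 1..3.
#' @param aggregate "mean" (default) or "sum" over pixels.
#' @return a non-negative scalar.
#' @export
colorDiff <- function(x, y, channel, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (!identical(dim(x), dim(y)))
    stop("colorDiff requires images of identical shape")
  if (length(channel) != 1L || !channel %in% 1:3)
    stop("channel must be a single index in 1..3")
  d2 <- (x[, , channel] - y[, , channel])^2
  if (aggregate == "mean") mean(d2) else sum(d2)
}

#' Reconstruction benchmark value
#'
#' Square root of the summed per-channel colour differences:
#' \code{sqrt(sum_c colorDiff(x, y, c))}. Zero iff the images are equal;
#' the larger the value, the higher the visual contrast between the two
#' images. Bounded by \code{sqrt(3)} for inputs in [0,1].
#'
#' @inheritParams colorDiff
#' @return a scalar in [0, sqrt(3)] for [0,1] inputs.
#' @examples
#' x <- array(0.5, c(4, 4, 3))
#' y <- x + 0.1
#' benchmarkValue(x, y)  # sqrt(3 * 0.01)
#' @export
benchmarkValue <- function(x, y, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (!identical(dim(x), dim(y)) || dim(x)[3] != 3L)
    stop("benchmarkValue requires two RGB images of identical shape")
  sqrt(sum(vapply(1:3, function(c) colorDiff(x, y, c, aggregate),
                  numeric(1))))
}

#' Per-channel histograms of an RGB image
#'
#' Counts over \code{bins} equal-width bins spanning [0,1]; the value 1.0
#' falls in the last bin. 256 bins (the 8-bit convention) by default.
#'
#' @param img H x W x 3 array with values in [0,1].
#' @param bins number of bins (>= 2).
#' @return a [ChannelHistogram-class] object.
#' @export
channelHistograms <- function(img, bins = 256L) {
  if (bins < 2L) stop("bins must be >= 2")
  bins <- as.integer(bins)
  counts <- vapply(1:3, function(c) {
    idx <- pmin(floor(img[, , c] * bins), bins - 1L) + 1L
    tabulate(idx, nbins = bins)
  }, integer(bins))
  new("ChannelHistogram", bins = bins, counts = counts)
}

#' Pooled histogram distinguishability statistics
#'
#' Pools every count vector of the supplied histograms into one sequence
#' and summarizes it: minimum, maximum, population standard deviation
#' (divide by N), scale (max - min) and coefficient of variation
#' (std dev / mean). Large scale, standard deviation and COV indicate a
#' strongly structured (distinguishable) colour distribution.
#'
#' @param hists a [ChannelHistogram-class] object or a list of them.
#' @return a [HistogramStats-class] object.
#' @export
histogramStats <- function(hists) {
  if (is(hists, "ChannelHistogram")) hists <- list(hists)
  if (length(hists) == 0L) stop("histogramStats needs at least one histogram")
  pooled <- unlist(lapply(hists, function(h) {
    stopifnot(is(h, "ChannelHistogram"))
    as.vector(h@counts)
  }))
  m <- mean(pooled)
  sdev <- sqrt(mean((pooled - m)^2))
  new("HistogramStats",
      min = min(pooled), max = max(pooled), stdDev = sdev,
      scale = max(pooled) - min(pooled),
      cov = if (m == 0) 0 else sdev / m)
}

#' @describeIn histogramStats display of the pooled summaries.
#' @param object a \code{HistogramStats} object.
#' @export
setMethod("show", "HistogramStats", function(object) {
  cat(sprintf(
    "HistogramStats | min=%.4g max=%.4g sd=%.4g scale=%.4g cov=%.4g\n",
    object@min, object@max, object@stdDev, object@scale, object@cov))
})
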