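#' Adaptive Wiener filter
#'
#' Local adaptive (Lee-style) Wiener filtering for speckle reduction. With
#' local mean \eqn{\mu} and local variance \eqn{\sigma^2} over the window and
#' noise power \eqn{\nu^2} estimated as the image-wide mean of
#' \eqn{\sigma^2}, the output is
#' \deqn{\mu + \frac{\max(\sigma^2 - \nu^2, 0)}{\max(\sigma^2, \nu^2)}
#'   (I - \mu),}
#' clipped to \[0, 1\]. Smooth regions collapse to their local mean while
#' high-variance structure (edges) is preserved. Borders use reflect padding.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param window Odd window size >= 3.
#' @return Filtered matrix, same shape.
#' @export
wiener_filter <- function(img, window = 5L) {
  stopifnot_odd_window(window)
  if (window > min(dim(img)))
    stop("window exceeds image size", call. = FALSE)
  mu <- local_mean(img, window)
  sig2 <- pmax(local_mean(img * img, window) - mu * mu, 0)
  nu2 <- mean(sig2)
  gain <- pmax(sig2 - nu2, 0) / pmax(sig2, nu2)
  gain[pmax(sig2, nu2) == 0] <- 0
  clamp01(mu + gain * (img - mu))
}

#' Global histogram equalization
#'
#' Redistributes intensities via the 256-bin empirical CDF: each pixel maps to
#' the fraction of pixels at or below its intensity bin. The mapping is
#' monotone non-decreasing, so intensity ordering is preserved.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @return Equalized matrix in \[0, 1\], same shape.
#' @export
equalize <- function(img) {
  idx <- pmin(floor(img * 256), 255)
  counts <- tabulate(idx + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(img)
  matrix(cdf[idx + 1L], nrow(img), ncol(img))
}

#' Median filter
#'
#' Replaces each pixel by the median of its `window` x `window`
#' neighbourhood, with reflect padding at the borders. Removes salt-type
#' speckle outliers while preserving edges.
#'
#' @param img Numeric matrix.
#' @param window Odd window size >= 3.
#' @return Filtered matrix, same shape.
#' @export
median_filter <- function(img, window = 3L) {
  stopifnot_odd_window(window)
  median_filter_cpp(img, as.integer(window))
}

#' Full preprocessing chain
#'
#' Applies, in order: adaptive Wiener filter, global histogram equalization,
#' median filter. This chain precedes every segmenter except the active
#' contour, which operates on the raw ROI.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param cfg A [pipeline_config()] supplying the window sizes.
#' @return Preprocessed matrix in \[0, 1\].
#' @export
preprocess <- function(img, cfg = pipeline_config()) {
  median_filter(equalize(wiener_filter(img, cfg$preprocess_window)),
                cfg$median_window)
}
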