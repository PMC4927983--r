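# Internal raster helpers shared by the preprocessing chain and the phantom
# renderer. All window/kernel operations use reflect padding so borders are
# not darkened, which matters for segmenters that key on intensity.

# mirror-pad a matrix by `r` pixels on every side
pad_reflect <- function(img, r) {
  H <- nrow(img); W <- ncol(img)
  ri <- c(rev(seq_len(min(r, H - 1)) + 1L), seq_len(H),
          H - seq_len(min(r, H - 1)))
  if (r >= H) ri <- rep(ri, length.out = H + 2L * r) # tiny-image fallback
  ci <- c(rev(seq_len(min(r, W - 1)) + 1L), seq_len(W),
          W - seq_len(min(r, W - 1)))
  img[ri, ci, drop = FALSE]
}

# local windowed mean via shift-and-accumulate on the padded image
local_mean <- function(img, window) {
  r <- window %/% 2L
  p <- pad_reflect(img, r)
  H <- nrow(img); W <- ncol(img)
  acc <- matrix(0, H, W)
  for (di in -r:r) for (dj in -r:r)
    acc <- acc + p[(1 + r + di):(H + r + di), (1 + r + dj):(W + r + dj)]
  acc / (window * window)
}

# separable convolution with a symmetric 1-D kernel, reflect padding
conv_sep <- function(img, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  p <- pad_reflect(img, r)
  tmp <- matrix(0, H, W + 2L * r)
  for (di in -r:r)
    tmp <- tmp + kernel[di + r + 1L] * p[(1 + r + di):(H + r + di), , drop = FALSE]
  out <- matrix(0, H, W)
  for (dj in -r:r)
    out <- out + kernel[dj + r + 1L] * tmp[, (1 + r + dj):(W + r + dj), drop = FALSE]
  out
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  conv_sep(img, gaussian_kernel(sigma))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stopifnot_odd_window <- function(window, name = "window") {
  if (length(window) != 1L || is.na(window) || window %% 2L != 1L || window < 3L)
    stop(sprintf("`%s` must be an odd integer >= 3, got %s", name,
                 paste(window, collapse = ",")), call. = FALSE)
  invisible(as.integer(window))
}

# shoelace area of a closed polygon given as a 2-col (row, col) matrix
polygon_area <- function(poly) {
  x <- poly[, 2]; y <- poly[, 1]
  n <- nrow(poly)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_perimeter <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1L)
  sum(sqrt((poly[j, 1] - poly[, 1])^2 + (poly[j, 2] - poly[, 2])^2))
}

polygon_centroid <- function(poly) {
  x <- poly[, 2]; y <- poly[, 1]
  n <- nrow(poly)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(y), mean(x)))
  cx <- sum((x + x[j]) * cr) / (6 * a)
  cy <- sum((y + y[j]) * cr) / (6 * a)
  c(cy, cx)
}
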