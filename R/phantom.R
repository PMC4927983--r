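#' Lesion shape specification
#'
#' Describes one simulated hypoechoic lesion as a radial-harmonic closed
#' contour: \eqn{r(\theta) = r_0 (1 + \sum_k a_k \sin(k\theta + \phi_k))},
#' anisotropically scaled by `aspect_ratio` along a random orientation.
#' Benign lesions are near-elliptical (small harmonic energy); malignant
#' lesions carry substantial energy in harmonics of order three and above,
#' producing the spiculated, irregular margins that characterise malignancy
#' on B-mode ultrasound.
#'
#' @param label `"benign"` or `"malignant"`.
#' @param center Lesion centre as `(row, col)` in pixels (1-based).
#' @param r0 Base radius in pixels.
#' @param aspect_ratio Axis ratio \eqn{\ge 1}; area-preserving stretch.
#' @param amps Harmonic amplitudes \eqn{a_k} for \eqn{k = 1, \dots}.
#' @param phases Harmonic phases \eqn{\phi_k} in radians, same length as
#'   `amps`.
#' @param echo_contrast Lesion mean intensity divided by background mean
#'   intensity, in (0, 1) (hypoechoic).
#' @return A validated `bus_lesion_spec` list.
#' @export
lesion_spec <- function(label, center, r0, aspect_ratio = 1,
                        amps = numeric(0), phases = numeric(0),
                        echo_contrast = 0.35) {
  label <- match.arg(label, c("benign", "malignant"))
  stopifnot(length(center) == 2L, r0 > 0, aspect_ratio >= 1,
            length(amps) == length(phases))
  if (echo_contrast <= 0 || echo_contrast >= 1)
    stop("echo_contrast must be in (0, 1)", call. = FALSE)
  if (label == "benign") {
    if (aspect_ratio > 2)
      stop("benign lesions must have aspect_ratio <= 2", call. = FALSE)
    if (sum(abs(amps)) > 0.08)
      stop("benign lesions must have total harmonic amplitude <= 0.08",
           call. = FALSE)
  } else {
    hi <- sum(abs(amps[seq_along(amps) >= 3L]))
    if (hi < 0.15 || hi > 0.45)
      stop("malignant lesions need total |a_k| over harmonics k >= 3 in ",
           "[0.15, 0.45], got ", signif(hi, 3), call. = FALSE)
  }
  theta <- seq(0, 2 * pi, length.out = 720L)
  if (length(amps) && min(radial_profile(theta, amps, phases)) <= 0)
    stop("harmonic amplitudes drive r(theta) <= 0", call. = FALSE)
  structure(list(label = label, center = as.numeric(center), r0 = r0,
                 aspect_ratio = aspect_ratio, amps = amps, phases = phases,
                 echo_contrast = echo_contrast),
            class = "bus_lesion_spec")
}

radial_profile <- function(theta, amps, phases) {
  r <- rep(1, length(theta))
  for (k in seq_along(amps))
    r <- r + amps[k] * sin(k * theta + phases[k])
  r
}

#' Speckle rendering parameters
#'
#' Parameters of the B-mode appearance model: an echogenicity template
#' modulated by multiplicative Rayleigh speckle, blurred by a Gaussian
#' point-spread function and perturbed by additive sensor noise. The default
#' Rayleigh scale \eqn{\sqrt{2/\pi}} gives the speckle field unit mean, so
#' the template sets the local mean brightness.
#'
#' @param background_mean Mean background intensity in (0, 1).
#' @param rayleigh_scale Rayleigh scale of the multiplicative speckle (> 0).
#' @param psf_sigma Gaussian point-spread sigma in pixels.
#' @param additive_noise_sd Standard deviation of additive Gaussian noise.
#' @return A `bus_speckle_params` list.
#' @export
speckle_params <- function(background_mean = 0.5,
                           rayleigh_scale = sqrt(2 / pi),
                           psf_sigma = 1.5, additive_noise_sd = 0.02) {
  stopifnot(background_mean > 0, background_mean < 1, rayleigh_scale > 0,
            psf_sigma > 0, additive_noise_sd >= 0)
  structure(list(background_mean = background_mean,
                 rayleigh_scale = rayleigh_scale, psf_sigma = psf_sigma,
                 additive_noise_sd = additive_noise_sd),
            class = "bus_speckle_params")
}

#' Build the closed lesion contour for a specification
#'
#' Evaluates the radial-harmonic profile on a dense angular grid, applies the
#' area-preserving aspect stretch along a random orientation, and returns the
#' resulting simple polygon. Being a radial function about the centre, the
#' contour is star-shaped and therefore non-self-intersecting.
#'
#' @param spec A [lesion_spec()].
#' @param n_vertices Number of polygon vertices (>= 64).
#' @return A `n_vertices` x 2 matrix of `(row, col)` vertices.
#' @export
make_lesion_contour <- function(spec, n_vertices = 128L) {
  stopifnot(inherits(spec, "bus_lesion_spec"), n_vertices >= 64L)
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- spec$r0 * radial_profile(theta, spec$amps, spec$phases)
  if (min(r) <= 0) stop("r(theta) <= 0: invalid lesion spec", call. = FALSE)
  alpha <- runif(1, 0, pi)
  sa <- sqrt(spec$aspect_ratio)
  u <- r * cos(theta) * sa
  v <- r * sin(theta) / sa
  rows <- spec$center[1] + u * cos(alpha) - v * sin(alpha)
  cols <- spec$center[2] + u * sin(alpha) + v * cos(alpha)
  cbind(row = rows, col = cols)
}

#' Rasterize a closed contour into a binary mask
#'
#' Scanline fill: a pixel is lesion iff its (integer-coordinate) centre lies
#' strictly inside the polygon, by the even-odd rule.
#'
#' @param contour A closed polygon as an n x 2 `(row, col)` matrix.
#' @param shape Image dimensions `c(H, W)`.
#' @return A logical `H` x `W` mask.
#' @export
rasterize_contour <- function(contour, shape) {
  H <- shape[1]; W <- shape[2]
  if (min(contour[, 1]) < 3 || max(contour[, 1]) > H - 2 ||
      min(contour[, 2]) < 3 || max(contour[, 2]) > W - 2)
    stop("contour must fit inside the image with a 2 px margin",
         call. = FALSE)
  mask <- matrix(FALSE, H, W)
  y1 <- contour[, 1]; x1 <- contour[, 2]
  n <- nrow(contour)
  j <- c(2:n, 1L)
  y2 <- y1[j]; x2 <- x1[j]
  for (row in seq_len(H)) {
    # half-open rule: the edge spans [min(y), max(y)); avoids double-counting
    # vertices that sit exactly on a scan line
    crosses <- (y1 <= row & y2 > row) | (y2 <= row & y1 > row)
    if (!any(crosses)) next
    t <- (row - y1[crosses]) / (y2[crosses] - y1[crosses])
    xs <- sort(x1[crosses] + t * (x2[crosses] - x1[crosses]))
    for (p in seq(1L, length(xs) - 1L, by = 2L)) {
      lo <- floor(xs[p]) + 1L
      hi <- ceiling(xs[p + 1L]) - 1L
      if (lo <= hi) mask[row, lo:hi] <- TRUE
    }
  }
  if (!any(mask))
    stop("contour encloses no pixel centres (empty mask)", call. = FALSE)
  mask
}

#' Render a B-mode-like image from a lesion mask
#'
#' Produces `clip(blur(T * R) + eps)` where `T` is the echogenicity template
#' (background mean outside the mask, `echo_contrast` times that inside),
#' `R` is i.i.d. Rayleigh multiplicative speckle, the blur is Gaussian with
#' `psf_sigma`, and `eps` is i.i.d. additive Gaussian noise. With
#' `deterministic = TRUE` the speckle field is replaced by its mean and the
#' additive noise suppressed, exposing the noise-free template response.
#'
#' @param mask Logical lesion mask.
#' @param sp A [speckle_params()].
#' @param spec The [lesion_spec()] supplying `echo_contrast`.
#' @param deterministic Replace noise sources by their means.
#' @return A numeric matrix in \[0, 1\], same shape as `mask`.
#' @export
render_ultrasound <- function(mask, sp = speckle_params(), spec,
                              deterministic = FALSE) {
  stopifnot(is.matrix(mask), is.logical(mask),
            inherits(sp, "bus_speckle_params"))
  contrast <- if (missing(spec)) 0.35 else spec$echo_contrast
  H <- nrow(mask); W <- ncol(mask)
  templ <- matrix(sp$background_mean, H, W)
  templ[mask] <- contrast * sp$background_mean
  ray_mean <- sp$rayleigh_scale * sqrt(pi / 2)
  if (deterministic) {
    speckle <- matrix(ray_mean, H, W)
    eps <- 0
  } else {
    speckle <- matrix(sp$rayleigh_scale * sqrt(-2 * log(runif(H * W))), H, W)
    eps <- matrix(rnorm(H * W, 0, sp$additive_noise_sd), H, W)
  }
  # normalise by the speckle mean so the template sets local mean brightness
  clamp01(gaussian_blur(templ * speckle / ray_mean, sp$psf_sigma) + eps)
}

# class-conditional random lesion specification; the parameter ranges encode
# the benign = smooth / malignant = spiculated contrast and keep the contour
# inside the frame with margin
random_lesion_spec <- function(label, shape) {
  H <- shape[1]; W <- shape[2]
  # ROIs are drawn tightly around the lesion plus a band of surrounding
  # tissue, so the lesion occupies a substantial fraction of the frame
  center <- c(H / 2 + runif(1, -0.02, 0.02) * H,
              W / 2 + runif(1, -0.02, 0.02) * W)
  r0 <- runif(1, 0.26, 0.32) * min(H, W)
  # phantom inclusions are rounded: same mild ellipticity for both classes,
  # so that margin irregularity (not elongation) separates them
  if (label == "benign") {
    aspect <- runif(1, 1, 1.25)
    n_h <- 3L
    raw <- abs(rnorm(n_h))
    amps <- raw / sum(raw) * runif(1, 0.01, 0.07)
  } else {
    aspect <- runif(1, 1, 1.25)
    n_h <- 8L
    raw <- c(abs(rnorm(2)) * 0.02, abs(rnorm(6)))
    hi_total <- runif(1, 0.15, 0.35)
    amps <- raw
    amps[3:8] <- raw[3:8] / sum(raw[3:8]) * hi_total
  }
  phases <- runif(n_h, 0, 2 * pi)
  lesion_spec(label, center, r0, aspect, amps, phases, echo_contrast = 0.35)
}

#' Generate a synthetic phantom dataset
#'
#' Draws class-conditional lesion shapes, rasterizes ground-truth masks and
#' renders speckled B-mode-like images, emulating a balanced phantom study
#' (e.g. 72 benign + 72 malignant rectangular ROIs). Deterministic under
#' `seed`.
#'
#' @param n_benign,n_malignant Number of images per class.
#' @param shape Image dimensions `c(H, W)`; default 128 x 128.
#' @param seed Integer RNG seed.
#' @param sp A [speckle_params()].
#' @return A tibble with columns `id`, `label`, and list-columns `image`
#'   (numeric matrix), `mask` (logical matrix) and `spec`
#'   ([lesion_spec()]).
#' @examples
#' ds <- generate_dataset(3, 3, shape = c(64, 64), seed = 1)
#' table(ds$label)
#' @export
generate_dataset <- function(n_benign, n_malignant, shape = c(128L, 128L),
                             seed = 1L, sp = speckle_params()) {
  stopifnot(n_benign >= 0, n_malignant >= 0)
  set.seed(seed)
  labels <- rep(c("benign", "malignant"), c(n_benign, n_malignant))
  rows <- lapply(seq_along(labels), function(i) {
    for (attempt in 1:20) {
      spec <- random_lesion_spec(labels[i], shape)
      mask <- tryCatch(
        rasterize_contour(make_lesion_contour(spec), shape),
        error = function(e) NULL)
      if (is.null(mask)) next
      # ground truth must be one hole-free component; extreme spicule draws
      # that pinch off at pixel resolution are redrawn
      lab <- label_components_cpp(mask, 8L)
      if (max(lab) == 1L && !any(fill_holes(mask) != mask)) break
    }
    if (is.null(mask))
      stop("could not draw a lesion fitting the frame; enlarge `shape`",
           call. = FALSE)
    img <- render_ultrasound(mask, sp, spec)
    list(id = sprintf("%03d", i), label = labels[i], image = img,
         mask = mask, spec = spec)
  })
  tibble(
    id = vapply(rows, `[[`, "", "id"),
    label = vapply(rows, `[[`, "", "label"),
    image = lapply(rows, `[[`, "image"),
    mask = lapply(rows, `[[`, "mask"),
    spec = lapply(rows, `[[`, "spec")
  )
}

#' Write a generated dataset to a directory
#'
#' Writes `images/NNN.png`, `masks/NNN.png` and `labels.csv` (columns
#' `id,label`) under `dir`.
#'
#' @param dataset A tibble from [generate_dataset()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(dataset))) {
    write_gray_image(dataset$image[[i]],
                     file.path(dir, "images", paste0(dataset$id[i], ".png")))
    write_mask(dataset$mask[[i]],
               file.path(dir, "masks", paste0(dataset$id[i], ".png")))
  }
  utils::write.csv(dataset[, c("id", "label")],
                   file.path(dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
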