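#' Region-growing segmentation
#'
#' 8-connected flood fill from a seed pixel: a neighbouring pixel joins the
#' region when its intensity lies within `tol` of the current region mean,
#' which is updated incrementally as pixels are admitted (FIFO order).
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param seed_px Seed `(row, col)`, 1-based; defaults to the image centre
#'   (lesions are centred in the rectangular ROI).
#' @param tol Intensity tolerance > 0; default 0.15 of the intensity range.
#' @return Logical mask of the grown region.
#' @export
seg_region_growing <- function(img, seed_px = NULL, tol = 0.15) {
  if (is.null(seed_px)) seed_px <- round(dim(img) / 2)
  if (seed_px[1] < 1 || seed_px[1] > nrow(img) ||
      seed_px[2] < 1 || seed_px[2] > ncol(img))
    stop("seed pixel outside the image", call. = FALSE)
  if (tol < 0) stop("tol must be >= 0", call. = FALSE)
  region_grow_cpp(img, as.integer(seed_px[1]), as.integer(seed_px[2]), tol)
}

# seeded initial centres: a random draw of k distinct intensities
init_centres <- function(img, k, seed) {
  vals <- unique(as.vector(img))
  if (k > length(vals))
    stop("k exceeds the number of distinct intensities (", length(vals), ")",
         call. = FALSE)
  set.seed(seed)
  sort(sample(vals, k))
}

#' k-means intensity segmentation
#'
#' Lloyd iterations on the pixel intensities (up to 300, until assignments
#' stabilise), started from a seeded draw of `k` distinct intensities. The
#' lesion cluster is chosen by [select_lesion_cluster()].
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed; the result is deterministic given `seed`.
#' @param details If `TRUE`, also return labels and the fitted centres.
#' @return Logical lesion mask, or a list when `details = TRUE`.
#' @export
seg_kmeans <- function(img, k = 2L, seed = 1L, details = FALSE) {
  stopifnot(k >= 2L)
  centres <- init_centres(img, k, seed)
  km <- suppressWarnings(
    kmeans(as.vector(img), centers = matrix(centres), iter.max = 300L,
           algorithm = "Lloyd"))
  labels <- matrix(km$cluster, nrow(img), ncol(img))
  mask <- select_lesion_cluster(labels, img)
  if (details)
    list(mask = mask, labels = labels, centres = as.vector(km$centers),
         tot_withinss = km$tot.withinss, init_centres = centres)
  else mask
}

#' Fuzzy c-means intensity segmentation
#'
#' Standard FCM on pixel intensities (memberships proportional to
#' \eqn{d^{-2/(m-1)}}, centroids as membership-weighted means), started from
#' a seeded draw of `c` distinct intensities and defuzzified by maximum
#' membership. The lesion cluster is chosen by [select_lesion_cluster()].
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param c Number of clusters (>= 2).
#' @param m Fuzzifier > 1 (default 2).
#' @param seed Integer seed.
#' @param details If `TRUE`, also return labels, memberships and centres.
#' @return Logical lesion mask, or a list when `details = TRUE`.
#' @export
seg_fuzzy_cmeans <- function(img, c = 2L, m = 2, seed = 1L,
                             details = FALSE) {
  stopifnot(c >= 2L)
  if (m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)
  centres <- init_centres(img, c, seed)
  fit <- e1071::cmeans(matrix(as.vector(img), ncol = 1),
                       centers = matrix(centres), m = m, iter.max = 300L,
                       method = "cmeans")
  labels <- matrix(fit$cluster, nrow(img), ncol(img))
  mask <- select_lesion_cluster(labels, img)
  if (details)
    list(mask = mask, labels = labels, membership = fit$membership,
         centres = as.vector(fit$centers))
  else mask
}

# per-pixel SOM features: intensity, 3x3 local mean, 3x3 local std
som_pixel_features <- function(img) {
  mu <- local_mean(img, 3L)
  sd3 <- sqrt(pmax(local_mean(img * img, 3L) - mu * mu, 0))
  cbind(as.vector(img), as.vector(mu), as.vector(sd3))
}

#' Self-organizing-map pixel segmentation
#'
#' Trains a one-dimensional SOM on per-pixel feature vectors (intensity,
#' 3x3 local mean, 3x3 local std), then labels each pixel by its final
#' best-matching unit. Learning rate and Gaussian-neighbourhood radius decay
#' linearly over the epochs; the pixel presentation order is reshuffled every
#' epoch under the given seed. The lesion unit is chosen by
#' [select_lesion_cluster()].
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param n_units Number of SOM units on the chain (default 4). After global
#'   equalization the intensity marginal is nearly uniform, so a 2-unit chain
#'   can only split at the mass median; with 4 units the chain quantizes the
#'   axis into mass bands and the darkest band isolates a hypoechoic lesion
#'   occupying up to about a quarter of the ROI.
#' @param n_epochs Training epochs (default 10).
#' @param lr Learning-rate schedule `c(initial, final)`, default 0.5 to 0.01.
#' @param radius Neighbourhood-radius schedule `c(initial, final)`, default
#'   1 to 0.
#' @param seed Integer seed.
#' @param details If `TRUE`, also return labels, unit weights and the
#'   quantization-error trace.
#' @return Logical lesion mask, or a list when `details = TRUE`.
#' @export
seg_som <- function(img, n_units = 4L, n_epochs = 10L, lr = c(0.5, 0.01),
                    radius = c(1, 0), seed = 1L, details = FALSE) {
  stopifnot(n_units >= 2L, n_epochs >= 1L, all(lr > 0), diff(lr) < 0,
            diff(radius) <= 0)
  if (diff(range(img)) == 0)
    stop("no contrast: all pixels are equal", call. = FALSE)
  X <- som_pixel_features(img)
  # deterministic init: units spread along the intensity axis from the 2nd to
  # the 98th percentile, so the chain spans the hypoechoic-to-echogenic range
  # and converges to the tissue-class partition rather than the median mass
  # split of the (near-uniform) equalized histogram
  ord <- order(X[, 1])
  qs <- if (n_units == 1L) 0.5
        else 0.02 + 0.96 * (seq_len(n_units) - 1L) / (n_units - 1L)
  pos <- ord[pmax(1L, round(qs * nrow(X)))]
  init_w <- X[pos, , drop = FALSE]
  set.seed(seed)
  fit <- som_fit_cpp(X, init_w, as.integer(n_epochs), lr[1], lr[2],
                     radius[1], radius[2])
  labels <- matrix(fit$labels, nrow(img), ncol(img))
  if (length(unique(fit$labels)) < 2L)
    stop("SOM collapsed to a single unit; no lesion/background partition",
         call. = FALSE)
  mask <- select_lesion_cluster(labels, img)
  if (details)
    list(mask = mask, labels = labels, weights = fit$weights, qe = fit$qe)
  else mask
}

#' Active-contour (two-phase level-set) segmentation
#'
#' Region-based evolution minimising the two-phase piecewise-constant energy
#' (sum of squared deviations from the inside/outside means). The level-set
#' function starts as a centred circle of radius `min(H, W) / 4`, is advected
#' by the pointwise energy-competition force and regularised by Gaussian
#' smoothing each iteration. Runs on the raw (unpreprocessed) ROI. Iteration
#' stops when the implied mask changes by fewer than 0.1% of the pixels, or
#' at `max_iter` (then the current mask is returned with
#' `attr(, "converged") = FALSE` and a warning). The darker phase is taken as
#' the lesion (hypoechoic), and morphological opening then closing with a
#' disc of radius `smoothing` polishes the boundary.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param max_iter Maximum iterations (default 200).
#' @param smoothing Disc radius (px) of the opening/closing element.
#' @param details If `TRUE`, also return the energy trace.
#' @return Logical lesion mask (with a `converged` attribute), or a list when
#'   `details = TRUE`.
#' @export
seg_active_contour <- function(img, max_iter = 200L, smoothing = 2L,
                               details = FALSE) {
  stopifnot(max_iter >= 1L)
  H <- nrow(img); W <- ncol(img)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  r0 <- min(H, W) / 4
  phi <- r0 - sqrt((rr - (H + 1) / 2)^2 + (cc - (W + 1) / 2)^2)
  inside <- phi > 0
  energy <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    c1 <- mean(img[inside]); c2 <- mean(img[!inside])
    energy <- c(energy, sum((img[inside] - c1)^2) +
                        sum((img[!inside] - c2)^2))
    force <- (img - c2)^2 - (img - c1)^2
    phi <- phi / max(abs(phi)) + force / max(abs(force), 1e-12)
    phi <- gaussian_blur(phi, 0.8)
    new_inside <- phi > 0
    if (!any(new_inside) || all(new_inside)) {
      warning("active contour collapsed to one phase")
      break
    }
    changed <- sum(new_inside != inside)
    inside <- new_inside
    if (it > 5L && changed < 0.001 * H * W) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("active contour did not converge within max_iter")
  c1 <- mean(img[inside]); c2 <- mean(img[!inside])
  mask <- if (c1 <= c2) inside else !inside
  mask <- morph_open_close(mask, smoothing)
  attr(mask, "converged") <- converged
  if (details) list(mask = mask, energy = energy, converged = converged)
  else mask
}

# opening then closing with a disc structuring element of radius r
morph_open_close <- function(mask, r) {
  if (r < 1) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
  m <- EBImage::closing(EBImage::opening(mask * 1, brush), brush)
  matrix(m > 0.5, nrow(mask), ncol(mask))
}

#' Pick the lesion cluster from a pixel labelling
#'
#' Among clusters whose nearest pixel lies within `max_center_dist` of the
#' expected lesion centre, selects the one with the lowest mean intensity
#' (lesions are hypoechoic; set `hypoechoic = FALSE` to select the brightest
#' instead). Ties on mean intensity go to the cluster containing the centre.
#' If no cluster reaches the centre neighbourhood, the spatially nearest
#' cluster is used.
#'
#' @param labels Integer matrix of per-pixel cluster ids (>= 1).
#' @param img The intensity image the labels were computed from.
#' @param center Expected lesion centre `(row, col)`; defaults to the image
#'   centre.
#' @param hypoechoic If `TRUE` (default) pick the darkest candidate cluster.
#' @param max_center_dist Radius (px) of the centre neighbourhood; default
#'   `min(H, W) / 4`.
#' @return Logical mask of the selected cluster.
#' @export
select_lesion_cluster <- function(labels, img, center = NULL,
                                  hypoechoic = TRUE,
                                  max_center_dist = NULL) {
  ids <- sort(unique(as.vector(labels)))
  if (length(ids) < 2L)
    stop("need at least two clusters", call. = FALSE)
  H <- nrow(labels); W <- ncol(labels)
  if (is.null(center)) center <- c((H + 1) / 2, (W + 1) / 2)
  if (is.null(max_center_dist)) max_center_dist <- min(H, W) / 4
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  d2 <- (rr - center[1])^2 + (cc - center[2])^2
  stats_tbl <- t(vapply(ids, function(id) {
    sel <- labels == id
    c(mean_int = mean(img[sel]), min_dist = sqrt(min(d2[sel])))
  }, numeric(2)))
  cand <- which(stats_tbl[, "min_dist"] <= max_center_dist)
  if (!length(cand)) cand <- which.min(stats_tbl[, "min_dist"])
  key <- if (hypoechoic) stats_tbl[cand, "mean_int"]
         else -stats_tbl[cand, "mean_int"]
  best <- cand[order(key, stats_tbl[cand, "min_dist"])][1]
  labels == ids[best]
}

# fill interior holes: background components (4-connected) not touching the
# image border are holes
fill_holes <- function(mask) {
  comp <- label_components_cpp(!mask, 4L)
  border <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1],
                     comp[, ncol(comp)]))
  border <- border[border > 0]
  mask | (comp > 0 & !(comp %in% border))
}

#' Postprocess a raw segmentation mask
#'
#' Keeps only the largest 8-connected component (ties broken by the component
#' whose centroid is nearest the image centre) and fills all interior holes,
#' removing disconnected artifacts and internal valleys.
#'
#' @param mask Logical matrix; must contain at least one `TRUE` pixel.
#' @return Logical mask with one hole-free component.
#' @export
postprocess_mask <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("segmentation produced no region", call. = FALSE)
  comp <- label_components_cpp(mask, 8L)
  n <- max(comp)
  if (n > 1L) {
    areas <- tabulate(comp[comp > 0], nbins = n)
    best <- which(areas == max(areas))
    if (length(best) > 1L) {
      centre <- (dim(mask) + 1) / 2
      d <- vapply(best, function(id) {
        idx <- which(comp == id, arr.ind = TRUE)
        sum((colMeans(idx) - centre)^2)
      }, numeric(1))
      best <- best[which.min(d)]
    }
    mask <- comp == best
  }
  fill_holes(mask)
}

#' Segment one ROI with a named method
#'
#' Dispatcher used by the CLI and the benchmark: applies the preprocessing
#' chain (except for the active contour, which runs on the raw ROI), the
#' chosen segmenter, and [postprocess_mask()].
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param method One of `"som"`, `"active_contour"`, `"region_growing"`,
#'   `"fuzzy_cmeans"`, `"kmeans"`.
#' @param cfg A [pipeline_config()].
#' @param ... Passed on to the individual segmenter.
#' @return Logical lesion mask (one hole-free component).
#' @export
segment_lesion <- function(img, method = c("som", "active_contour",
                                           "region_growing", "fuzzy_cmeans",
                                           "kmeans"),
                           cfg = pipeline_config(), ...) {
  method <- match.arg(method)
  if (method == "active_contour") {
    mask <- suppressWarnings(seg_active_contour(img, ...))
  } else {
    pre <- preprocess(img, cfg)
    mask <- switch(method,
      region_growing = seg_region_growing(pre, ...),
      fuzzy_cmeans = seg_fuzzy_cmeans(pre, seed = cfg$rng_seed, ...),
      kmeans = seg_kmeans(pre, seed = cfg$rng_seed, ...),
      som = seg_som(pre, seed = cfg$rng_seed, ...)
    )
  }
  postprocess_mask(mask)
}
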