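#' Trace the sub-pixel outer contour of a lesion mask
#'
#' Extracts the 0.5-level contour of the binary mask by marching squares
#' (via [grDevices::contourLines()] on the zero-padded mask), giving a
#' sub-pixel closed polygon. Perimeter, area and centroid come from the
#' polygon (arc length, shoelace, polygon centroid), which keeps
#' \eqn{P^2/A}-type descriptors stable; pixel-edge perimeters would
#' overestimate `P` substantially and break the form-factor bound.
#'
#' @param mask Logical matrix with exactly one hole-free component (e.g. the
#'   output of [postprocess_mask()]).
#' @return A `bus_contour_geometry` list: `boundary` (n x 2 `(row, col)`
#'   polygon, counter-clockwise), `centroid`, `radial_lengths`, `area`,
#'   `perimeter`, `hull_area`, `hull_perimeter`, `bbox_area`, `bbox_extent`
#'   (`c(height, width)`), `r_max`, `r_mean`, `r_sd`, and the polygon second
#'   moments.
#' @export
trace_contour <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  comp <- label_components_cpp(mask, 8L)
  if (max(comp) != 1L)
    stop("mask must be a single connected component", call. = FALSE)
  if (any(fill_holes(mask) != mask))
    stop("mask must be hole-free", call. = FALSE)
  H <- nrow(mask); W <- ncol(mask)
  z <- matrix(0, H + 2L, W + 2L)
  z[2:(H + 1), 2:(W + 1)] <- mask * 1
  cl <- grDevices::contourLines(x = 0:(H + 1), y = 0:(W + 1), z = z,
                                levels = 0.5)
  if (!length(cl)) stop("no contour found", call. = FALSE)
  lens <- vapply(cl, function(p) length(p$x), integer(1))
  p <- cl[[which.max(lens)]]
  poly <- cbind(row = p$x, col = p$y)
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  poly <- smooth_staircase(poly)
  # orient counter-clockwise (positive shoelace area in (col, row) axes)
  if (signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ,
                                          drop = FALSE]
  centroid <- polygon_centroid(poly)
  r <- sqrt((poly[, 1] - centroid[1])^2 + (poly[, 2] - centroid[2])^2)
  hull_idx <- grDevices::chull(poly[, 2], poly[, 1])
  hull <- poly[hull_idx, , drop = FALSE]
  ext <- c(height = diff(range(poly[, 1])), width = diff(range(poly[, 2])))
  mom <- polygon_moments(poly)
  structure(list(
    boundary = poly,
    centroid = centroid,
    radial_lengths = r,
    area = polygon_area(poly),
    perimeter = polygon_perimeter(poly),
    hull_area = polygon_area(hull),
    hull_perimeter = polygon_perimeter(hull),
    bbox_area = prod(ext),
    bbox_extent = ext,
    r_max = max(r), r_mean = mean(r), r_sd = stats::sd(r),
    moments = mom
  ), class = "bus_contour_geometry")
}

# Corner-preserving removal of marching-squares staircase jitter. On binary
# input the 0.5-level polygon zig-zags along oblique boundaries, inflating
# perimeter estimates by up to ~6%; a circular moving average removes the
# jitter but would also round true corners (and spicule tips), biasing P the
# other way. Vertices whose net direction change across the window exceeds
# 60 degrees -- genuine corners, not jitter, whose alternating turns cancel --
# are therefore left untouched, along with their window-width neighbourhood.
smooth_staircase <- function(poly, r = 3L) {
  n <- nrow(poly)
  if (n < 6L * r) return(poly)
  idx <- function(k) ((k - 1L) %% n) + 1L
  v_in <- poly - poly[idx(seq_len(n) - r), , drop = FALSE]
  v_out <- poly[idx(seq_len(n) + r), , drop = FALSE] - poly
  cosang <- rowSums(v_in * v_out) /
    pmax(sqrt(rowSums(v_in^2) * rowSums(v_out^2)), 1e-12)
  protect <- cosang < 0.5
  for (d in c(-r:-1, 1:r))
    protect <- protect | (cosang < 0.5)[idx(seq_len(n) + d)]
  sm <- poly
  for (d in c(-r:-1, 1:r)) sm <- sm + poly[idx(seq_len(n) + d), , drop = FALSE]
  sm <- sm / (2L * r + 1L)
  poly[!protect, ] <- sm[!protect, ]
  reconstruct_corners(poly, protect, r)
}

# Marching squares chamfers a true corner with a short diagonal. For every
# protected run, extend the two adjacent edge lines and, when they meet close
# to the run, collapse the run to their intersection, restoring the corner
# apex. Ill-conditioned (near-parallel or distant) intersections leave the
# run unchanged.
reconstruct_corners <- function(poly, protect, r) {
  n <- nrow(poly)
  if (!any(protect) || all(protect)) return(poly)
  idx <- function(k) ((k - 1L) %% n) + 1L
  runs <- protected_runs(protect)
  keep <- rep(TRUE, n)
  for (run in runs) {
    a <- run[1]; b <- run[2]
    p1 <- poly[idx(a - 1L), ]; p0 <- poly[idx(a - 1L - r), ]
    q1 <- poly[idx(b + 1L), ]; q0 <- poly[idx(b + 1L + r), ]
    d1 <- p1 - p0; d2 <- q1 - q0
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-9 * sqrt(sum(d1^2) * sum(d2^2))) next
    t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
    apex <- p1 + t * d1
    run_len <- if (b >= a) b - a + 1L else n - a + b + 1L
    mid <- poly[idx(a + run_len %/% 2L), ]
    if (sqrt(sum((apex - mid)^2)) > 2 * r) next
    members <- idx(seq.int(a, a + run_len - 1L))
    poly[members[1], ] <- apex
    keep[members[-1]] <- FALSE
  }
  poly[keep, , drop = FALSE]
}

# maximal circular runs of TRUE, as (start, end) index pairs
protected_runs <- function(protect) {
  n <- length(protect)
  d <- diff(c(protect[n], protect))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  if (!length(starts)) return(list())
  ends[ends == 0L] <- n
  # pair each start with the first end at or after it (circularly)
  lapply(starts, function(s) {
    e <- ends[ends >= s]
    if (length(e)) c(s, e[1]) else c(s, ends[1])
  })
}

signed_area <- function(poly) {
  x <- poly[, 2]; y <- poly[, 1]
  n <- nrow(poly)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# central second moments of a polygon (x = col, y = row), shoelace form
polygon_moments <- function(poly) {
  x <- poly[, 2]; y <- poly[, 1]
  n <- nrow(poly)
  j <- c(2:n, 1L)
  a <- x * y[j] - x[j] * y
  A <- sum(a) / 2
  cx <- sum((x + x[j]) * a) / (6 * A)
  cy <- sum((y + y[j]) * a) / (6 * A)
  ixx <- sum((y^2 + y * y[j] + y[j]^2) * a) / 12 - A * cy^2
  iyy <- sum((x^2 + x * x[j] + x[j]^2) * a) / 12 - A * cx^2
  ixy <- sum((x * y[j] + 2 * x * y + 2 * x[j] * y[j] + x[j] * y) * a) / 24 -
    A * cx * cy
  list(ixx = ixx / A, iyy = iyy / A, ixy = ixy / A)
}

#' Morphological shape descriptors of a lesion contour
#'
#' Computes the 24 shape descriptors used for benign/malignant
#' discrimination. The core dimensionless descriptors follow the
#' breast-lesion shape-analysis conventions: form factor \eqn{4\pi A/P^2},
#' compactness \eqn{P^2/(4\pi A)}, circularity \eqn{A/(\pi R_{max}^2)},
#' convexity \eqn{P_h/P}, solidity \eqn{A/A_h}, rectangularity
#' \eqn{A/A_{bb}}, residue \eqn{(A_h - A)/A_h}, and area ratio
#' \eqn{\frac{1}{m\,\mu_R}\sum_{R_i>\mu_R}(R_i-\mu_R)} over the `m` boundary
#' radii. The remainder are normalized-radial-length (NRL) statistics and
#' absolute-size/geometry auxiliaries (see the vignette for the full list).
#' Smooth round lesions score near 1 on form factor, circularity and
#' solidity; spiculated ones score lower.
#'
#' @param geom A [trace_contour()] result.
#' @return A named numeric vector of 24 features.
#' @export
extract_features <- function(geom) {
  stopifnot(inherits(geom, "bus_contour_geometry"))
  A <- geom$area; P <- geom$perimeter
  if (A <= 0 || P <= 0) stop("degenerate contour (zero area or perimeter)",
                             call. = FALSE)
  r <- geom$radial_lengths
  m <- length(r)
  mu_r <- geom$r_mean
  nrl <- r / geom$r_max
  dev <- r - mu_r
  # sign changes of (R_i - mean) around the closed boundary
  s <- sign(dev)[sign(dev) != 0]
  zc <- if (length(s) > 1L) sum(s != c(s[-1], s[1])) else 0L
  h <- tabulate(pmin(floor(nrl * 32) + 1L, 32L), nbins = 32L)
  ph <- h[h > 0] / m
  mom <- geom$moments
  tr <- mom$ixx + mom$iyy
  det <- mom$ixx * mom$iyy - mom$ixy^2
  l1 <- tr / 2 + sqrt(pmax(tr^2 / 4 - det, 0))
  l2 <- tr / 2 - sqrt(pmax(tr^2 / 4 - det, 0))
  c(
    form_factor = 4 * pi * A / P^2,
    compactness = P^2 / (4 * pi * A),
    circularity = A / (pi * geom$r_max^2),
    convexity = geom$hull_perimeter / P,
    solidity = A / geom$hull_area,
    rectangularity = A / geom$bbox_area,
    residue = (geom$hull_area - A) / geom$hull_area,
    area_ratio = sum(dev[dev > 0]) / (m * mu_r),
    perimeter = P,
    eccentricity = sqrt(1 - pmin(l2 / l1, 1)),
    extent_ratio = geom$bbox_extent[["width"]] / geom$bbox_extent[["height"]],
    orientation = 0.5 * atan2(2 * mom$ixy, mom$iyy - mom$ixx),
    equivalent_diameter = sqrt(4 * A / pi),
    nrl_mean = mean(nrl),
    nrl_sd = stats::sd(nrl),
    nrl_entropy = -sum(ph * log(ph)),
    nrl_zero_crossings = zc,
    roughness = mean(abs(dev - c(dev[-1], dev[1]))) / mu_r,
    radial_variance_ratio = geom$r_sd / mu_r,
    hull_perimeter = geom$hull_perimeter,
    hull_area = geom$hull_area,
    bbox_aspect = max(geom$bbox_extent) / min(geom$bbox_extent),
    area = A,
    max_radial = geom$r_max
  )
}

#' @rdname extract_features
#' @param mask Logical lesion mask (single hole-free component).
#' @export
compute_features <- function(mask) extract_features(trace_contour(mask))

#' Morphological feature table for a dataset
#'
#' Computes the 24 descriptors for every ground-truth or segmented mask in a
#' dataset tibble.
#'
#' @param dataset Tibble with columns `id`, `label` and a list-column of
#'   masks (named by `mask_col`).
#' @param mask_col Name of the list-column holding the masks.
#' @return A tibble with `id`, `label` and 24 feature columns.
#' @export
feature_table <- function(dataset, mask_col = "mask") {
  stopifnot(mask_col %in% names(dataset))
  feats <- purrr::map(dataset[[mask_col]], compute_features)
  dplyr::bind_cols(dataset[, c("id", "label")],
                   as_tibble(do.call(rbind, feats)))
}
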