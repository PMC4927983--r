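# geometric fixtures shared across the suite

make_disc_mask <- function(shape, center, radius) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  sqrt((rr - center[1])^2 + (cc - center[2])^2) <= radius
}

make_square_mask <- function(shape, top_left, side) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[top_left[1]:(top_left[1] + side - 1L),
    top_left[2]:(top_left[2] + side - 1L)] <- TRUE
  m
}

# two-level image: dark disc on a bright background
make_two_level_disc <- function(shape = c(40L, 40L), radius = 9,
                                dark = 0.2, bright = 0.8) {
  disc <- make_disc_mask(shape, (shape + 1) / 2, radius)
  img <- matrix(bright, shape[1], shape[2])
  img[disc] <- dark
  list(img = img, mask = disc)
}

# analytic circle geometry (no rasterization): regular n-gon on a circle
analytic_circle_geometry <- function(r = 10, n = 360L, center = c(50, 50)) {
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  poly <- cbind(row = center[1] + r * sin(theta),
                col = center[2] + r * cos(theta))
  geometry_from_polygon(poly)
}

analytic_square_geometry <- function(s = 10, center = c(50, 50)) {
  h <- s / 2
  poly <- cbind(row = center[1] + c(-h, -h, h, h),
                col = center[2] + c(-h, h, h, -h))
  geometry_from_polygon(poly)
}

# build a bus_contour_geometry from an explicit polygon (test-side
# constructor mirroring the exported type, independent of trace_contour)
geometry_from_polygon <- function(poly) {
  centroid <- buscad:::polygon_centroid(poly)
  r <- sqrt((poly[, 1] - centroid[1])^2 + (poly[, 2] - centroid[2])^2)
  hull <- poly[grDevices::chull(poly[, 2], poly[, 1]), , drop = FALSE]
  ext <- c(height = diff(range(poly[, 1])), width = diff(range(poly[, 2])))
  structure(list(
    boundary = poly, centroid = centroid, radial_lengths = r,
    area = buscad:::polygon_area(poly),
    perimeter = buscad:::polygon_perimeter(poly),
    hull_area = buscad:::polygon_area(hull),
    hull_perimeter = buscad:::polygon_perimeter(hull),
    bbox_area = prod(ext), bbox_extent = ext,
    r_max = max(r), r_mean = mean(r), r_sd = stats::sd(r),
    moments = buscad:::polygon_moments(poly)
  ), class = "bus_contour_geometry")
}

# naive 8-connected BFS labeling, used as an independent oracle
naive_label <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (j0 in seq_len(W)) for (i0 in seq_len(H)) {
    if (!mask[i0, j0] || lab[i0, j0] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i0, j0)); lab[i0, j0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        if (connectivity == 4L && di != 0 && dj != 0) next
        i <- p[1] + di; j <- p[2] + dj
        if (i < 1 || i > H || j < 1 || j > W) next
        if (mask[i, j] && lab[i, j] == 0L) {
          lab[i, j] <- nxt
          queue <- c(queue, list(c(i, j)))
        }
      }
    }
  }
  lab
}
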