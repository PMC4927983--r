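test_that("region growing recovers a disc exactly on a two-level image", {
  tl <- make_two_level_disc()
  mask <- seg_region_growing(tl$img, tol = 0.3)
  expect_identical(mask, tl$mask)
  # tol = 0: only pixels equal to the seed value and reachable from it
  # (levels exactly representable so the running mean stays exact)
  tl0 <- make_two_level_disc(dark = 0.25, bright = 0.75)
  m0 <- seg_region_growing(tl0$img, tol = 0)
  expect_identical(m0, tl0$mask)
  expect_error(seg_region_growing(tl$img, seed_px = c(0, 5)), "outside")
})

test_that("region growing matches a queue-based flood-fill oracle", {
  set.seed(11)
  img <- matrix(sample(c(0.2, 0.8), 256, replace = TRUE), 16, 16)
  seed <- c(8, 8)
  mask <- seg_region_growing(img, seed, tol = 0.1)
  # oracle: BFS over the same-level pixels connected to the seed
  level <- img[seed[1], seed[2]]
  comp <- naive_label(abs(img - level) <= 0.1, 8L)
  expect_identical(mask, comp == comp[seed[1], seed[2]])
})

test_that("k-means segments a two-level image exactly and descends in WSS", {
  tl <- make_two_level_disc()
  km <- seg_kmeans(tl$img, k = 2, seed = 1, details = TRUE)
  expect_identical(km$mask, tl$mask)
  expect_identical(km$mask, seg_kmeans(tl$img, k = 2, seed = 1))
  # monotone descent: final WSS no worse than the seeded initial assignment
  x <- as.vector(tl$img)
  assign0 <- apply(abs(outer(x, km$init_centres, "-")), 1, which.min)
  wss0 <- sum((x - km$init_centres[assign0])^2)
  expect_lte(km$tot_withinss, wss0 + 1e-12)
  expect_error(seg_kmeans(tl$img, k = 5), "distinct")
})

test_that("fuzzy c-means agrees with k-means on separable data", {
  tl <- make_two_level_disc()
  fc <- seg_fuzzy_cmeans(tl$img, c = 2, m = 2, seed = 1, details = TRUE)
  expect_identical(fc$mask, seg_kmeans(tl$img, k = 2, seed = 1))
  expect_equal(rowSums(fc$membership), rep(1, nrow(fc$membership)),
               tolerance = 1e-9)
  expect_error(seg_fuzzy_cmeans(tl$img, m = 1), "m must be > 1")
})

test_that("the SOM partitions a two-level image exactly with two units", {
  tl <- make_two_level_disc()
  m1 <- seg_som(tl$img, n_units = 2, seed = 1)
  expect_identical(m1, tl$mask)
  expect_identical(m1, seg_som(tl$img, n_units = 2, seed = 1))
  expect_error(seg_som(matrix(0.5, 10, 10)), "no contrast")
})

test_that("SOM training reduces the quantization error overall", {
  set.seed(4)
  tl <- make_two_level_disc()
  noisy <- buscad:::clamp01(tl$img + matrix(rnorm(1600, 0, 0.05), 40, 40))
  fit <- seg_som(noisy, n_units = 2, seed = 2, details = TRUE)
  expect_lt(fit$qe[length(fit$qe)], fit$qe[1])
})

test_that("clustering segmenters are invariant to affine intensity rescaling", {
  tl <- make_two_level_disc()
  rescaled <- 0.15 + 0.6 * tl$img
  expect_identical(seg_kmeans(tl$img, seed = 3), seg_kmeans(rescaled, seed = 3))
  expect_identical(seg_fuzzy_cmeans(tl$img, seed = 3),
                   seg_fuzzy_cmeans(rescaled, seed = 3))
  expect_identical(seg_som(tl$img, n_units = 2, seed = 3),
                   seg_som(rescaled, n_units = 2, seed = 3))
})

test_that("the active contour recovers a noise-free disc almost perfectly", {
  tl <- make_two_level_disc(shape = c(64, 64), radius = 14)
  fit <- seg_active_contour(tl$img, details = TRUE)
  q <- region_metrics(pixel_confusion(fit$mask, tl$mask))
  expect_gte(q$AOM, 99)
  expect_true(fit$converged)
  # two-phase energy is non-increasing along the evolution
  expect_true(all(diff(fit$energy) <= 1e-9 * fit$energy[1]))
})

test_that("opening/closing barely changes an already smooth disc", {
  disc <- make_disc_mask(c(64, 64), c(32, 32), 15)
  sm <- buscad:::morph_open_close(disc, 2L)
  expect_lt(sum(sm != disc) / sum(disc), 0.01)
})

test_that("the lesion cluster is the darkest cluster near the centre", {
  img <- matrix(0.8, 12, 12)
  labels <- matrix(1L, 12, 12)
  img[5:8, 5:8] <- 0.3; labels[5:8, 5:8] <- 2L
  expect_identical(select_lesion_cluster(labels, img), labels == 2L)
  # darkest cluster is a far-corner artifact: the darker central cluster wins
  img3 <- matrix(0.8, 12, 12)
  lab3 <- matrix(1L, 12, 12)
  img3[5:8, 5:8] <- 0.3; lab3[5:8, 5:8] <- 2L
  img3[1, 12] <- 0.05; lab3[1, 12] <- 3L
  expect_identical(select_lesion_cluster(lab3, img3), lab3 == 2L)
  # exact tie on mean intensity: the cluster containing the centre wins
  img4 <- matrix(0.8, 12, 12)
  lab4 <- matrix(1L, 12, 12)
  img4[5:8, 5:8] <- 0.3; lab4[5:8, 5:8] <- 2L
  img4[10:12, 10:12] <- 0.3; lab4[10:12, 10:12] <- 3L
  expect_identical(select_lesion_cluster(lab4, img4), lab4 == 2L)
  # hyperechoic flag inverts the choice
  expect_identical(select_lesion_cluster(labels, img, hypoechoic = FALSE),
                   labels == 1L)
  expect_error(select_lesion_cluster(matrix(1L, 5, 5), matrix(0.5, 5, 5)),
               "two clusters")
})

test_that("postprocessing keeps the largest component and fills holes", {
  mask <- make_disc_mask(c(40, 40), c(20, 20), 9)
  mask[2, 2] <- TRUE; mask[3, 38] <- TRUE; mask[38, 3] <- TRUE
  out <- postprocess_mask(mask)
  expect_identical(out, make_disc_mask(c(40, 40), c(20, 20), 9))
  # annulus becomes a filled disc
  ann <- make_disc_mask(c(40, 40), c(20, 20), 10) &
    !make_disc_mask(c(40, 40), c(20, 20), 6)
  expect_identical(postprocess_mask(ann),
                   make_disc_mask(c(40, 40), c(20, 20), 10))
  expect_error(postprocess_mask(matrix(FALSE, 5, 5)), "no region")
})

test_that("postprocessing agrees with a naive labeling + border-flood oracle", {
  set.seed(9)
  for (rep in 1:5) {
    mask <- matrix(runif(144) < 0.35, 12, 12)
    if (!any(mask)) next
    out <- postprocess_mask(mask)
    lab <- naive_label(mask, 8L)
    areas <- tabulate(lab[lab > 0])
    big <- which(areas == max(areas))
    if (length(big) > 1L) next  # tie-break covered elsewhere
    keep <- lab == big
    # fill holes: flood the complement from the border (4-connected)
    bg <- naive_label(!keep, 4L)
    border_ids <- setdiff(unique(c(bg[1, ], bg[12, ], bg[, 1], bg[, 12])), 0L)
    oracle <- keep | (bg > 0 & !(bg %in% border_ids))
    expect_identical(out, oracle)
  }
})

test_that("EBImage independently confirms the component labeling", {
  set.seed(13)
  mask <- matrix(runif(400) < 0.3, 20, 20)
  ours <- buscad:::label_components_cpp(mask, 4L)
  theirs <- EBImage::bwlabel(mask)  # 4-connected labeling
  # same partition up to label permutation
  expect_equal(max(ours), max(theirs))
  expect_true(all(tapply(theirs[mask], ours[mask],
                         function(v) length(unique(v))) == 1L))
})

test_that("every segmenter's dispatched output is one hole-free component", {
  ds <- generate_dataset(1, 1, shape = c(96, 96), seed = 5)
  for (m in c("som", "region_growing", "kmeans", "fuzzy_cmeans",
              "active_contour")) {
    S <- segment_lesion(ds$image[[1]], method = m)
    expect_equal(max(buscad:::label_components_cpp(S, 8L)), 1L)
    expect_identical(buscad:::fill_holes(S), S)
  }
})
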