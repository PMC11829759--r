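test_that("equalisation window converts physical kernel to voxels", {
  expect_equal(ahe_window_voxels(10, c(1, 1, 1)), c(10L, 10L, 10L))
  expect_equal(ahe_window_voxels(10, c(2, 0.5, 0.5)), c(5L, 20L, 20L))
  expect_error(ahe_window_voxels(3, c(2, 0.5, 0.5)), "twice the largest")
})

test_that("adaptive equalisation flattens local histograms", {
  # constant stack: no contrast to equalise
  const <- array(0.3, c(8, 12, 12))
  out <- equalize_adaptive(const, kernel_um = 4, voxel_size_um = c(1, 1, 1))
  expect_true(all(out == 0.5))
  expect_true(all(out >= 0 & out <= 1))

  # dim/bright halves: equalisation removes the global contrast between the
  # regions (interior voxels of both halves end up with the same local-rank
  # distribution) while preserving contrast within each window
  set.seed(42)
  img <- array(0, c(6, 20, 40))
  img[, , 1:20] <- 0.2 + 0.02 * array(runif(6 * 20 * 20), c(6, 20, 20))
  img[, , 21:40] <- 0.8 + 0.02 * array(runif(6 * 20 * 20), c(6, 20, 20))
  eq <- equalize_adaptive(img, kernel_um = 6, voxel_size_um = c(1, 1, 1))
  dim_in <- as.vector(img[, , 5:15]); bright_in <- as.vector(img[, , 25:35])
  dim_eq <- as.vector(eq[, , 5:15]); bright_eq <- as.vector(eq[, , 25:35])
  expect_gt(abs(mean(bright_in) - mean(dim_in)), 0.5)  # strong input contrast
  expect_lt(abs(mean(bright_eq) - mean(dim_eq)), 0.05) # equalised away
  # local variation survives: the output is not collapsed to a constant
  expect_gt(sd(dim_eq), 0.1)
})

test_that("difference of Gaussians matches the analytic kernel response", {
  # constant input: zero up to floating-point cancellation
  const <- array(1, c(8, 10, 10))
  expect_true(all(abs(dog_filter(const, voxel_size_um = c(1, 1, 1))) < 1e-12))

  # single impulse: response equals the clipped difference of the two
  # separable Gaussian kernels evaluated at each offset
  imp <- array(0, c(27, 27, 27))
  imp[14, 14, 14] <- 1
  got <- dog_filter(imp, low_sigma = 1, high_sigma = 3,
                    voxel_size_um = c(1, 1, 1))
  g1d <- function(s) {
    r <- max(1L, ceiling(4 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k / sum(k)
  }
  pad <- function(k, half) {
    out <- numeric(2 * half + 1)
    r <- (length(k) - 1) / 2
    out[(half + 1 - r):(half + 1 + r)] <- k
    out
  }
  k1 <- pad(g1d(1), 13); k3 <- pad(g1d(3), 13)
  expected <- outer(outer(k1, k1), k1) - outer(outer(k3, k3), k3)
  expected[expected < 0] <- 0
  expect_equal(got, expected, tolerance = 1e-10)

  expect_error(dog_filter(const, low_sigma = 3, high_sigma = 1,
                          voxel_size_um = c(1, 1, 1)), "low_sigma")
  # non-negativity on arbitrary input
  set.seed(1)
  noisy <- array(runif(8 * 16 * 16), c(8, 16, 16))
  expect_true(all(dog_filter(noisy, voxel_size_um = c(1, 1, 1)) >= 0))
})

test_that("2D labelling finds separated nuclei cross-sections", {
  blank <- matrix(0, 64, 64)
  expect_equal(sum(label_2d(blank, spacing_um = c(0.5, 0.5)) > 0), 0)

  # two well-separated disks of nuclear size
  disks <- matrix(0, 80, 80)
  for (c1 in list(c(22, 22), c(60, 60))) {
    for (i in 1:80) for (j in 1:80) {
      if ((i - c1[1])^2 + (j - c1[2])^2 <= 12^2) disks[i, j] <- 1
    }
  }
  lab <- label_2d(disks, spacing_um = c(0.5, 0.5))
  expect_equal(length(setdiff(unique(as.integer(lab)), 0L)), 2)

  # phantom slice through several nuclei: one label per plausible-area
  # cross-section (the same footprint filter defines "plausible" both for
  # the expectation and for the labeller)
  sim <- small_phantom(n_nuclei = 6, seed = 13, shape = c(48, 96, 96))
  pre <- dog_filter(equalize_adaptive(sim$stack))
  vol <- get_channel(pre, "nuclear")
  thr <- otsu_threshold(vol)
  min_area_px <- 0.5 * pi * 25 / 0.25
  for (z_pick in unique(round(sim$truth$z_um / 0.5))) {
    truth_slice <- sim$labels[z_pick, , ]
    areas <- table(truth_slice[truth_slice > 0])
    n_possible <- sum(areas >= min_area_px)       # plausible footprints
    n_certain <- sum(areas >= 1.6 * min_area_px)  # comfortably plausible
    lab2 <- label_2d(vol[z_pick, , ], spacing_um = c(0.5, 0.5),
                     threshold = thr)
    n_got <- length(setdiff(unique(as.integer(lab2)), 0L))
    expect_gte(n_got, n_certain)
    expect_lte(n_got, n_possible)
  }
})

test_that("IoU stitching follows the 0.6 threshold arithmetic", {
  # identical footprints: IoU 1, one 3D label
  a <- matrix(0L, 20, 20); a[5:14, 5:14] <- 1L # 100 px
  stack2 <- array(0L, c(2, 20, 20))
  stack2[1, , ] <- a; stack2[2, , ] <- a
  expect_equal(max(join_labels_3d(stack2)), 1L)

  # 100 px footprints overlapping by 60: IoU 60/140 < 0.6, two labels
  b60 <- matrix(0L, 30, 30); b60[5:14, 9:18] <- 1L
  s60 <- array(0L, c(2, 30, 30))
  a30 <- matrix(0L, 30, 30); a30[5:14, 5:14] <- 1L
  s60[1, , ] <- a30; s60[2, , ] <- b60
  expect_equal(max(join_labels_3d(s60)), 2L)

  # overlapping by 80: IoU 80/120 >= 0.6, one label
  b80 <- matrix(0L, 30, 30); b80[5:14, 7:16] <- 1L
  s80 <- array(0L, c(2, 30, 30))
  s80[1, , ] <- a30; s80[2, , ] <- b80
  expect_equal(max(join_labels_3d(s80)), 1L)

  expect_error(join_labels_3d(list(matrix(0L, 4, 4), matrix(0L, 5, 5))),
               "same 2D grid")
  expect_error(join_labels_3d(s80, iou_threshold = 1.5), "0, 1")
})

test_that("stitching conserves label counts and is monotone in the threshold", {
  sim <- small_phantom(n_nuclei = 5, seed = 21)
  lab2d <- slice_labels_from_truth(sim$labels,
                                   min_area_px = 0.5 * pi * 25 / 0.25)
  total_2d <- sum(vapply(seq_len(dim(lab2d)[1]), function(z) {
    length(setdiff(unique(as.integer(lab2d[z, , ])), 0L))
  }, integer(1)))
  counts <- vapply(c(0.3, 0.6, 0.9), function(thr) {
    max(join_labels_3d(lab2d, iou_threshold = thr))
  }, integer(1))
  expect_true(all(counts <= total_2d))
  expect_true(all(diff(counts) >= 0)) # raising the threshold never merges more
})

test_that("stitched labels equal 3D connected components on a phantom", {
  sim <- small_phantom(n_nuclei = 5, seed = 31)
  lab2d <- slice_labels_from_truth(sim$labels,
                                   min_area_px = 0.5 * pi * 25 / 0.25)
  joined <- join_labels_3d(lab2d, iou_threshold = 0.6)
  oracle <- cc_label_3d(lab2d > 0)
  expect_identical(label_partition(joined), label_partition(oracle))
  expect_equal(max(joined), 5L)
})

test_that("nucleus measurement applies spacing and averages channels exactly", {
  labels <- array(0L, c(10, 10, 10))
  labels[3:7, 2:6, 4:8] <- 1L # 5x5x5 cube
  vox <- array(0, c(10, 10, 10, 2))
  vox[, , , 1] <- 0.25 # uniform channel
  vox[, , , 2] <- array(seq(0, 1, length.out = 1000), c(10, 10, 10))
  iso <- image_stack(vox, c(1, 1, 1), c("uniform", "grad"))
  tab <- extract_nuclei(labels, iso)
  expect_equal(tab$volume_um3, 125)
  expect_equal(c(tab$z_um, tab$y_um, tab$x_um), c(4.5, 3.5, 5.5))
  expect_equal(tab$mean_uniform, 0.25)

  # anisotropic z doubles the volume and scales the z centroid
  aniso <- image_stack(vox, c(2, 1, 1), c("uniform", "grad"))
  tab2 <- extract_nuclei(labels, aniso)
  expect_equal(tab2$volume_um3, 250)
  expect_equal(tab2$z_um, 9)

  empty <- extract_nuclei(array(0L, c(10, 10, 10)), iso)
  expect_equal(nrow(empty), 0)
})

test_that("full chain recovers a noiseless phantom", {
  sim <- small_phantom(n_nuclei = 5, seed = 17)
  seg <- segment_stack(sim$stack)
  expect_equal(seg$n_nuclei, 5)
  # matched centroids within half a nucleus radius
  truth_pos <- as.matrix(sim$truth[, c("z_um", "y_um", "x_um")])
  got_pos <- as.matrix(seg$nuclei[, c("z_um", "y_um", "x_um")])
  d <- as.matrix(dist(rbind(truth_pos, got_pos)))[seq_len(5), 5 + seq_len(5)]
  expect_true(all(apply(d, 1, min) < 2.5))
})
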