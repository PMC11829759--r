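test_that("phantom generation conserves counts and handles degenerate input", {
  # degenerate: no nuclei
  empty <- generate_nuclear_stack(embryo_phantom_spec(
    shape_voxels = c(16, 24, 24), n_nuclei = 0, seed = 1))
  expect_equal(nrow(empty$truth), 0)
  expect_true(all(empty$labels == 0L))

  sim <- small_phantom(n_nuclei = 6, seed = 3)
  expect_equal(nrow(sim$truth), 6)
  expect_setequal(setdiff(unique(as.integer(sim$labels)), 0L), 1:6)
  expect_equal(sim$stack$channels, c("nuclear", "sox2", "tbxta"))
})

test_that("phantom generation is a pure function of its spec", {
  spec <- embryo_phantom_spec(shape_voxels = c(32, 64, 64), n_nuclei = 4,
                              noise_sd = 0.05, seed = 7)
  a <- generate_nuclear_stack(spec)
  b <- generate_nuclear_stack(spec)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth, b$truth)
})

test_that("phantom respects packing, domain and gradient invariants", {
  sim <- small_phantom(n_nuclei = 8, seed = 11, shape = c(48, 96, 96))
  tr <- sim$truth
  pos <- as.matrix(tr[, c("z_um", "y_um", "x_um")])
  dmat <- as.matrix(dist(pos))
  diag(dmat) <- Inf
  expect_true(min(dmat) >= 1.3 * 10) # separation_factor * diameter
  extent <- c(48, 96, 96) * 0.5
  expect_true(all(pos >= 0 & pos <= rep(extent, each = nrow(pos))))
  expect_true(all(tr$gradient_coord >= 0 & tr$gradient_coord <= 1))
  # class truth tracks the coexpression band of the DV coordinate
  band <- c(0.35, 0.65)
  expect_equal(tr$class,
               ifelse(tr$gradient_coord < band[1], "sox2_only",
                      ifelse(tr$gradient_coord > band[2], "tbxta_only",
                             "double_positive")))
  # opposing monotone amplitude profiles
  ord <- order(tr$gradient_coord)
  expect_true(all(diff(tr$amp_sox2[ord]) <= 1e-12))
  expect_true(all(diff(tr$amp_tbxta[ord]) >= -1e-12))
})

test_that("infeasible packing fails with the achievable count", {
  spec <- embryo_phantom_spec(shape_voxels = c(48, 64, 64), n_nuclei = 40,
                              seed = 1)
  expect_error(generate_nuclear_stack(spec), "placed only")
})

test_that("ablated nuclei become unlabelled bright debris", {
  box <- rbind(c(0, 0, 0), c(24, 48, 48)) # left half of the domain, um
  spec <- embryo_phantom_spec(shape_voxels = c(48, 96, 96), n_nuclei = 8,
                              separation_factor = 1.3,
                              ablation_box_um = box, seed = 5)
  sim <- generate_nuclear_stack(spec)
  inside <- sim$truth$x_um < 48 & sim$truth$y_um < 48 & sim$truth$z_um < 24
  expect_equal(sim$truth$ablated, inside)
  # ablated nuclei carry no label
  expect_true(all(is.na(sim$truth$id[sim$truth$ablated])))
  expect_equal(sum(!sim$truth$ablated),
               length(setdiff(unique(as.integer(sim$labels)), 0L)))
  if (any(sim$truth$ablated)) {
    # debris exists: bright unlabelled voxels in the nuclear channel
    nuc <- get_channel(sim$stack, "nuclear")
    expect_true(any(nuc > 0.5 & sim$labels == 0L))
  }
})

test_that("track generators honour their per-kind step statistics", {
  # ballistic, zero noise: collinear with constant per-step displacement
  bal <- generate_tracks(track_sim_spec("ballistic", n_tracks = 2,
                                        n_steps = 12, step_sd_um = 0,
                                        speed_um_per_frame = 1.5, seed = 2))
  one <- bal[bal$track_id == 1, ]
  steps <- diff(as.matrix(one[, c("x_um", "y_um", "z_um")]))
  expect_equal(sqrt(rowSums(steps^2)), rep(1.5, nrow(steps)), tolerance = 1e-12)
  # all steps identical: the motion is collinear (rank-1 step matrix)
  expect_true(all(abs(sweep(steps, 2, steps[1, ])) < 1e-10))

  # diffusive with zero step sd: stationary
  still <- generate_tracks(track_sim_spec("diffusive", n_tracks = 1,
                                          n_steps = 10, step_sd_um = 0, seed = 1))
  expect_equal(var(still$x_um), 0)

  # confined: never escapes the reflecting sphere
  conf <- generate_tracks(track_sim_spec("confined", n_tracks = 3, n_steps = 50,
                                         step_sd_um = 1,
                                         confinement_radius_um = 5, seed = 4))
  for (id in unique(conf$track_id)) {
    g <- conf[conf$track_id == id, ]
    r <- sqrt((g$x_um - g$x_um[1])^2 + (g$y_um - g$y_um[1])^2 +
                (g$z_um - g$z_um[1])^2)
    expect_true(all(r <= 5 + 1e-9))
  }

  expect_error(track_sim_spec("levitating", 10, 20), "unknown track kind")
  expect_error(track_sim_spec("diffusive", 10, 5), "n_steps")
})

test_that("diffusive ensemble recovers exponent 1 through the MSD fit", {
  tr <- generate_tracks(track_sim_spec("diffusive", n_tracks = 200,
                                       n_steps = 100, step_sd_um = 1, seed = 9))
  alphas <- vapply(split(tr, tr$track_id), function(g) {
    msd_exponent(msd_curve(g))$alpha
  }, numeric(1))
  expect_equal(mean(alphas), 1.0, tolerance = 0.1)
  # cross-check: ensemble MSD regressed against lag is linear with slope
  # 3 * sd^2 per frame (independent of the per-track log-log fit)
  lags <- 1:10
  ens <- vapply(lags, function(lag) {
    mean(unlist(lapply(split(tr, tr$track_id), function(g) {
      p <- as.matrix(g[, c("x_um", "y_um", "z_um")])
      n <- nrow(p)
      rowSums((p[(1 + lag):n, , drop = FALSE] - p[1:(n - lag), , drop = FALSE])^2)
    })))
  }, numeric(1))
  fit <- lm(ens ~ lags)
  expect_equal(unname(coef(fit)[2]), 3, tolerance = 0.1)
})

test_that("point-cloud generator records exact transforms and noise scale", {
  pcs <- generate_point_clouds(n_embryos = 2, n_points = 30,
                               noise_sd_um = 0, seed = 3)
  emb <- pcs$embryos[[1]]
  back <- transform_points(invert_transform(emb$transform), emb$cloud)
  expect_equal(as.matrix(back[, c("x_um", "y_um", "z_um")]),
               as.matrix(pcs$reference), tolerance = 1e-10)

  # identity-range transforms with zero noise reproduce the reference
  ident <- generate_point_clouds(2, 20, transform_ranges = list(
    rotation_deg = 0, translation_um = 0), noise_sd_um = 0, seed = 1)
  expect_equal(as.matrix(ident$embryos[[1]]$cloud[, c("x_um", "y_um", "z_um")]),
               as.matrix(ident$reference), tolerance = 1e-12)

  # Monte-Carlo: residual RMS after applying the true transform ~ sd * sqrt(3)
  rms <- vapply(1:20, function(s) {
    pc <- generate_point_clouds(1, 200, noise_sd_um = 0.5, seed = s)
    pred <- transform_points(pc$embryos[[1]]$transform, as.matrix(pc$reference))
    sqrt(mean(rowSums((as.matrix(pc$embryos[[1]]$cloud[, 1:3]) - pred)^2)))
  }, numeric(1))
  expect_equal(mean(rms), 0.5 * sqrt(3), tolerance = 0.03)

  flat <- cbind(runif(10), runif(10), 0)
  colnames(flat) <- c("x_um", "y_um", "z_um")
  expect_error(generate_point_clouds(1, 10, reference = flat), "degenerate")
})

test_that("tail polylines reproduce somite lengths exactly", {
  tp <- generate_tail_polylines(3, c(50, 50, 50), psm_length_um = 0,
                                curvature = 0, seed = 1)
  len <- polyline_length(tp$paraxial_mesoderm)
  expect_equal(len$total_um, 150)
  # straight polyline: length equals the Euclidean endpoint distance
  pts <- tp$paraxial_mesoderm$points_um
  expect_equal(len$total_um,
               sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2)), tolerance = 1e-9)

  # curved polyline: per-somite chord sums equal the requested lengths and
  # match a dense numerical arc-length computation of the same vertices
  somites <- c(42, 38.5, 35, 31)
  tp2 <- generate_tail_polylines(4, somites, psm_length_um = 80,
                                 curvature = 0.15, seed = 6)
  len2 <- polyline_length(tp2$paraxial_mesoderm)
  expect_equal(len2$per_segment_um, c(somites, 80), tolerance = 1e-9)
  pts2 <- tp2$paraxial_mesoderm$points_um
  arc <- sum(sqrt(rowSums(diff(pts2)^2)))
  expect_equal(len2$total_um, arc, tolerance = 1e-12)

  expect_error(generate_tail_polylines(2, c(50, 50, 50)), "n_somites")
})
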