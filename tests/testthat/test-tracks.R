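make_track <- function(pos, dt = 30, id = 1L, intensity = NULL) {
  n <- nrow(pos)
  out <- tibble::tibble(track_id = id, frame = 0:(n - 1), t_s = (0:(n - 1)) * dt,
                        x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3])
  if (!is.null(intensity)) out$intensity <- intensity
  out
}

test_that("track tables parse both column dialects and enforce gap limits", {
  generic <- data.frame(id = rep(1:2, each = 12), t = rep(0:11 * 30, 2),
                        x = rnorm(24), y = rnorm(24), z = rnorm(24))
  ts <- read_tracks(generic)
  expect_equal(length(unique(ts$track_id)), 2)
  expect_true(all(c("track_id", "frame", "t_s", "x_um") %in% names(ts)))

  trackmate <- data.frame(TRACK_ID = 1, POSITION_T = 0:11 * 30,
                          POSITION_X = 1:12, POSITION_Y = 0, POSITION_Z = 0,
                          MEAN_INTENSITY = 12:1)
  tm <- read_tracks(trackmate)
  expect_equal(tm$intensity, as.numeric(12:1))

  expect_error(read_tracks(data.frame(t = 1, x = 1, y = 1, z = 1)), "track id")
  expect_error(read_tracks(data.frame(id = 1, t = 1, x = 1, y = 1)), "z")

  # a 2-frame gap is legal, a 3-frame gap is not
  gap2 <- data.frame(id = 1, t = c(0:3, 6:12) * 30, x = 0, y = 0, z = 0)
  expect_s3_class(read_tracks(gap2), "track_set")
  gap3 <- data.frame(id = 1, t = c(0:3, 7:13) * 30, x = 0, y = 0, z = 0)
  expect_error(read_tracks(gap3), "missing frames")

  # non-monotone times are rejected
  bad <- data.frame(id = 1, t = c(0, 30, 30, 60), x = 0, y = 0, z = 0)
  expect_error(read_tracks(bad), "non-monotone")

  empty <- read_tracks(data.frame(id = integer(), t = numeric(),
                                  x = numeric(), y = numeric(), z = numeric()))
  expect_equal(nrow(empty), 0)
})

test_that("track selection filters on start window and length", {
  tr <- dplyr::bind_rows(
    make_track(matrix(rnorm(36), 12, 3), id = 1L),            # starts at 0 s
    dplyr::mutate(make_track(matrix(rnorm(36), 12, 3), id = 2L),
                  t_s = t_s + 300),                           # starts at 300 s
    dplyr::mutate(make_track(matrix(rnorm(36), 12, 3), id = 3L),
                  t_s = t_s + 700),                           # starts at 700 s
    make_track(matrix(rnorm(15), 5, 3), id = 4L)              # too short
  )
  sel <- select_tracks(tr, start_window_s = c(0, 600), min_length = 10)
  expect_setequal(unique(sel$track_id), c(1L, 2L))
  none <- select_tracks(tr, min_length = 1000)
  expect_equal(nrow(none), 0)
})

test_that("MSD of a ballistic track is exactly quadratic with exponent 2", {
  v <- c(1.2, -0.4, 0.3)
  pos <- outer(0:19, v)
  curve <- msd_curve(make_track(pos))
  expect_equal(curve$msd_um2, sum(v^2) * curve$lag_frames^2, tolerance = 1e-12)
  fit <- msd_exponent(curve)
  expect_equal(fit$alpha, 2, tolerance = 1e-10)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-12)
  # convexity in lag for ballistic motion
  expect_true(all(diff(diff(curve$msd_um2)) > 0))

  # stationary track: MSD identically zero, exponent undefined
  still <- msd_curve(make_track(matrix(0, 15, 3)))
  expect_true(all(still$msd_um2 == 0))
  expect_true(is.na(msd_exponent(still)$alpha))

  expect_error(msd_curve(make_track(matrix(0, 5, 3))), "at least 10")

  # an exactly linear MSD curve has exponent 1
  lin <- tibble::tibble(lag_frames = 1:10, lag_s = 1:10 * 30,
                        msd_um2 = 2.5 * (1:10), n_pairs = 10)
  expect_equal(msd_exponent(lin)$alpha, 1, tolerance = 1e-12)
})

test_that("MSD pairs spanning frame gaps are skipped not interpolated", {
  pos <- outer(0:14, c(1, 0, 0))
  tr <- make_track(pos)
  tr <- tr[tr$frame != 7, ] # knock out one frame
  curve <- msd_curve(tr)
  full <- msd_curve(make_track(pos))
  expect_true(all(curve$n_pairs <= full$n_pairs[seq_len(nrow(curve))]))
  # positions still exact so MSD values are unchanged where pairs exist
  expect_equal(curve$msd_um2, full$msd_um2[seq_len(nrow(curve))],
               tolerance = 1e-12)
})

test_that("directional classification is strict at the 1.1 boundary", {
  expect_false(classify_directional(1.05))
  expect_true(classify_directional(1.2))
  expect_false(classify_directional(1.1)) # boundary is not directional
  expect_true(is.na(classify_directional(NA_real_)))
  # monotone: increasing alpha never flips true -> false
  alphas <- sort(runif(50, 0.5, 2))
  cls <- classify_directional(alphas)
  expect_true(all(diff(as.integer(cls)) >= 0))
})

test_that("straightness and angular alignment follow their definitions", {
  straight <- make_track(outer(0:15, c(1, 1, 0)))
  expect_equal(straightness_corrected(straight), sqrt(15), tolerance = 1e-12)
  expect_equal(mean_angular_alignment(straight), 1, tolerance = 1e-12)

  # out-and-back: returns to origin, straightness 0, alignment -1
  out_back <- make_track(rbind(outer(0:5, c(1, 0, 0)), outer(4:0, c(1, 0, 0))))
  expect_equal(straightness_corrected(out_back), 0)
  zigzag <- make_track(outer(c(0, 1, 0, 1, 0, 1), c(1, 0, 0)))
  expect_equal(mean_angular_alignment(zigzag), -1, tolerance = 1e-12)

  # stationary: 0 by convention; alignment undefined
  still <- make_track(matrix(1, 8, 3))
  expect_equal(straightness_corrected(still), 0)
  expect_true(is.na(mean_angular_alignment(still)))

  # isotropic random walk: mean alignment near 0, and diffusive straightness
  # below ballistic straightness at equal duration
  set.seed(12)
  walks <- replicate(100, apply(matrix(rnorm(60), 20, 3), 2, cumsum),
                     simplify = FALSE)
  aligns <- vapply(walks, function(p) mean_angular_alignment(make_track(p)),
                   numeric(1))
  expect_lt(abs(mean(aligns)), 0.05)
  diff_str <- mean(vapply(walks, function(p)
    straightness_corrected(make_track(p)), numeric(1)))
  bal_str <- straightness_corrected(make_track(outer(0:19, c(1, 0, 0))))
  expect_lt(diff_str, bal_str)
})

test_that("dorsoventral displacement projects onto the ventral axis", {
  dv <- c(0, -1, 0) # ventral = -y
  down <- make_track(cbind(0, seq(0, -5, length.out = 12), 0))
  expect_equal(dv_displacement(down, dv), 5)
  ortho <- make_track(cbind(seq(0, 7, length.out = 12), 0, 0))
  expect_equal(dv_displacement(ortho, dv), 0)

  # synthetic embryo: 80% of near-ablation tracks drift ventrally
  set.seed(13)
  mk <- function(id, ventral) {
    drift <- if (ventral) c(0, -0.8, 0) else c(0, 0.8, 0)
    pos <- sweep(apply(matrix(rnorm(36, sd = 0.2), 12, 3), 2, cumsum), 2,
                 drift, function(a, b) a + b * seq_len(12))
    start <- runif(3, -20, 20)
    make_track(sweep(pos, 2, start, `+`), id = id)
  }
  tr <- dplyr::bind_rows(lapply(1:50, function(i) mk(i, i <= 40)))
  frac <- fraction_displaced_ventrally(tr, dv, c(0, 0, 0), cutoff_um = 60)
  expect_equal(frac$n_eligible, 50)
  expect_equal(frac$fraction_ventral, 0.8, tolerance = 0.05)

  none <- fraction_displaced_ventrally(tr, dv, c(1e5, 0, 0), cutoff_um = 60)
  expect_true(is.na(none$fraction_ventral))
})

test_that("intensity dynamics are z-scored and telescoping", {
  tr <- make_track(matrix(rnorm(36), 12, 3), intensity = rep(2, 12))
  # embryo distribution {1,2,3}: mean 2, a track starting at 2 has z = 0
  dyn <- intensity_dynamics(tr, embryo_mean = 2, embryo_sd = 1)
  expect_equal(dyn$start_intensity_z, 0)
  expect_equal(dyn$mean_intensity_change, 0)

  arith <- make_track(matrix(rnorm(36), 12, 3),
                      intensity = seq(1, by = 0.25, length.out = 12))
  expect_equal(intensity_dynamics(arith, 0, 1)$mean_intensity_change, 0.25,
               tolerance = 1e-12)
  expect_error(intensity_dynamics(tr, 0, 0), "embryo_sd")
})

test_that("metrics are invariant under global rigid motion of the track set", {
  set.seed(14)
  tr <- generate_tracks(track_sim_spec("persistent", n_tracks = 5, n_steps = 30,
                                       step_sd_um = 1, seed = 15))
  dv <- c(0, -1, 0)
  refp <- c(10, 10, 10)
  m1 <- track_metrics(tr, dv, refp)
  r <- tailbudkit:::.rotation_about_axis(c(1, 1, 1) / sqrt(3), 0.6)
  tf <- rigid_transform(r, c(30, -12, 4))
  moved <- transform_points(tf, tr)
  dv2 <- as.numeric(r %*% dv)
  refp2 <- as.numeric(r %*% refp + tf$translation_um)
  m2 <- track_metrics(moved, dv2, refp2)
  for (col in c("alpha", "straightness_corrected", "mean_angular_alignment",
                "dv_displacement_um", "start_distance_um")) {
    expect_equal(m2[[col]], m1[[col]], tolerance = 1e-8)
  }
})

test_that("per-kind exponent recovery holds across the motion spectrum", {
  fit_alphas <- function(spec) {
    tr <- generate_tracks(spec)
    vapply(split(tr, tr$track_id),
           function(g) msd_exponent(msd_curve(g))$alpha, numeric(1))
  }
  a_diff <- fit_alphas(track_sim_spec("diffusive", 60, 100, seed = 16))
  expect_equal(mean(a_diff), 1, tolerance = 0.1)
  a_conf <- fit_alphas(track_sim_spec("confined", 60, 100, step_sd_um = 2,
                                      confinement_radius_um = 4, seed = 17))
  expect_lt(mean(a_conf), 1)
  a_pers <- fit_alphas(track_sim_spec("persistent", 60, 100,
                                      persistence = 0.8, seed = 18))
  expect_gt(mean(a_pers), 1)
  a_bal <- fit_alphas(track_sim_spec("ballistic", 20, 100, step_sd_um = 0,
                                     seed = 19))
  expect_equal(unname(a_bal), rep(2, 20), tolerance = 1e-9)
})
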