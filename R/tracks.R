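#' Read a cell-track table
#'
#' Parses an exported track table into a tidy `track_set`. Two column
#' dialects are accepted: generic (`id`/`track_id`, `t`/`t_s`/`time`,
#' `x`/`x_um`, `y`, `z`, optional `intensity`, optional `parent`/
#' `parent_id`) and the common tracker export layout (`TRACK_ID`,
#' `POSITION_X`, `POSITION_Y`, `POSITION_Z`, `POSITION_T` or `FRAME`,
#' optional `MEAN_INTENSITY`). Times must be strictly increasing within a
#' track; frame gaps of at most `max_frame_gap` missing frames are accepted
#' (matching the linking setting used at acquisition), longer gaps are an
#' error. Gaps are left absent — never interpolated.
#'
#' @param path CSV file path (or a data frame already in memory).
#' @param max_frame_gap Maximum number of consecutive missing frames.
#' @return A `track_set` tibble: `track_id`, `frame`, `t_s`, `x_um`, `y_um`,
#'   `z_um`, plus `intensity` and `parent_id` when present.
#' @export
read_tracks <- function(path, max_frame_gap = 2) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path, check.names = FALSE)
  names(df) <- tolower(names(df))
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(df)) return(df[[nm]])
    NULL
  }
  id <- pick("track_id", "id")
  tt <- pick("t_s", "position_t", "t", "time")
  fr <- pick("frame")
  x <- pick("x_um", "position_x", "x")
  y <- pick("y_um", "position_y", "y")
  z <- pick("z_um", "position_z", "z")
  for (need in list(c("track id", is.null(id)), c("time", is.null(tt) && is.null(fr)),
                    c("x", is.null(x)), c("y", is.null(y)), c("z", is.null(z)))) {
    if (isTRUE(as.logical(need[2]))) {
      stop(sprintf("track table is missing a mandatory %s column", need[1]),
           call. = FALSE)
    }
  }
  out <- tibble::tibble(track_id = id,
                        t_s = if (!is.null(tt)) as.numeric(tt) else as.numeric(fr),
                        x_um = as.numeric(x), y_um = as.numeric(y),
                        z_um = as.numeric(z))
  inten <- pick("intensity", "mean_intensity")
  if (!is.null(inten)) out$intensity <- as.numeric(inten)
  parent <- pick("parent_id", "parent")
  if (!is.null(parent)) out$parent_id <- parent
  if (nrow(out)) {
    # times must already be strictly increasing within each track
    mono <- tapply(out$t_s, out$track_id,
                   function(t) length(t) < 2 || all(diff(t) > 0))
    if (!all(unlist(mono))) {
      stop(sprintf("non-monotone times within track(s): %s",
                   paste(utils::head(names(mono)[!unlist(mono)], 5),
                         collapse = ", ")), call. = FALSE)
    }
    # frame index from the smallest sampling interval across the table
    dts <- unlist(tapply(out$t_s, out$track_id, diff, simplify = FALSE))
    dt <- if (length(dts)) min(dts) else 1
    out$frame <- as.integer(round(out$t_s / dt))
    gaps <- tapply(out$frame, out$track_id, function(f) max(c(1L, diff(f))) - 1L)
    too_big <- names(gaps)[gaps > max_frame_gap]
    if (length(too_big)) {
      stop(sprintf("track(s) %s have more than %d consecutive missing frames",
                   paste(utils::head(too_big, 5), collapse = ", "),
                   max_frame_gap), call. = FALSE)
    }
  } else {
    out$frame <- integer()
  }
  out <- dplyr::relocate(out, "track_id", "frame", "t_s")
  class(out) <- c("track_set", class(out))
  out
}

#' Filter tracks by start time and length
#'
#' Keeps tracks whose first sample lies in `start_window_s` (default: the
#' first 10 minutes) and which have at least `min_length` samples.
#'
#' @param tracks A `track_set` tibble.
#' @param start_window_s Closed interval of allowed start times (s).
#' @param min_length Minimum number of samples.
#' @return The filtered `track_set`.
#' @export
select_tracks <- function(tracks, start_window_s = c(0, 600), min_length = 10) {
  keep <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(start = min(.data$t_s), n = dplyr::n()) |>
    dplyr::filter(.data$start >= start_window_s[1],
                  .data$start <= start_window_s[2],
                  .data$n >= min_length)
  out <- dplyr::filter(tracks, .data$track_id %in% keep$track_id)
  class(out) <- unique(c("track_set", class(out)))
  out
}

.track_positions <- function(track) {
  stopifnot(all(c("frame", "x_um", "y_um", "z_um") %in% names(track)))
  track <- track[order(track$frame), ]
  list(frames = track$frame, pos = as.matrix(track[, c("x_um", "y_um", "z_um")]),
       t_s = track$t_s, intensity = track[["intensity"]])
}

#' Time-averaged mean squared displacement of one track
#'
#' `MSD(tau)` is the mean over all start frames `t` of
#' `||r(t + tau) - r(t)||^2`, for lags of 1 up to
#' `floor(max_lag_fraction * (n - 1))` frames. Pairs spanning a missing
#' frame are skipped, never interpolated.
#'
#' @param track Samples of one track (rows of a `track_set`).
#' @param max_lag_fraction Largest lag as a fraction of the track length.
#' @return A tibble: `lag_frames`, `lag_s`, `msd_um2`, `n_pairs`.
#' @export
msd_curve <- function(track, max_lag_fraction = 0.5) {
  tp <- .track_positions(track)
  n <- nrow(tp$pos)
  if (n < 10) stop("MSD needs at least 10 samples", call. = FALSE)
  max_lag <- floor(max_lag_fraction * (n - 1))
  if (max_lag < 1) stop("track too short for the requested lag range", call. = FALSE)
  dt <- min(diff(tp$t_s))
  frame_of <- match(seq(min(tp$frames), max(tp$frames)), tp$frames)
  purrr::map_dfr(seq_len(max_lag), function(lag) {
    i <- seq_len(length(frame_of) - lag)
    a <- frame_of[i]
    b <- frame_of[i + lag]
    ok <- !is.na(a) & !is.na(b)
    disp2 <- rowSums((tp$pos[b[ok], , drop = FALSE] -
                        tp$pos[a[ok], , drop = FALSE])^2)
    tibble::tibble(lag_frames = lag, lag_s = lag * dt,
                   msd_um2 = if (length(disp2)) mean(disp2) else NA_real_,
                   n_pairs = sum(ok))
  })
}

#' MSD exponent from a log-log fit
#'
#' The exponent alpha is the ordinary least-squares slope of `log MSD`
#' against `log lag` over the curve's retained lags; alpha near 1 indicates
#' diffusive motion, above 1 directional, 2 ballistic. Zero MSD values are
#' dropped from the fit; if fewer than 3 lags remain, alpha is undefined
#' (`NA`).
#'
#' @param curve A tibble from [msd_curve()].
#' @return An object of class `msd_fit`: `alpha`, `fit_r2`, `n_lags`.
#' @export
msd_exponent <- function(curve) {
  ok <- is.finite(curve$msd_um2) & curve$msd_um2 > 0
  out <- list(alpha = NA_real_, fit_r2 = NA_real_, n_lags = sum(ok))
  if (sum(ok) >= 3) {
    lx <- log(curve$lag_frames[ok])
    ly <- log(curve$msd_um2[ok])
    fit <- stats::lm.fit(cbind(1, lx), ly)
    out$alpha <- unname(fit$coefficients[2])
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((ly - mean(ly))^2)
    out$fit_r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  }
  structure(out, class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("<msd_fit> alpha = %.3f (R2 = %.3f, %d lags)\n",
              x$alpha, x$fit_r2, x$n_lags))
  invisible(x)
}

#' @rdname msd_exponent
#' @param x An `msd_fit`.
#' @param ... Unused.
#' @method glance msd_fit
#' @export
glance.msd_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, fit_r2 = x$fit_r2, n_lags = x$n_lags)
}

#' Classify a track as directional from its MSD exponent
#'
#' Directional means alpha strictly above the threshold (printed value 1.1);
#' an exponent of exactly 1.1 is not directional. Undefined exponents
#' propagate as `NA`.
#'
#' @param alpha MSD exponent(s).
#' @param threshold Directionality threshold.
#' @return Logical vector.
#' @export
classify_directional <- function(alpha, threshold = 1.1) {
  ifelse(is.na(alpha), NA, alpha > threshold)
}

#' Duration-corrected straightness of a track
#'
#' Net displacement over total path length, multiplied by the square root of
#' the duration in frames to correct for the length bias of plain
#' straightness. A stationary track (zero path length) returns 0.
#'
#' @param track Samples of one track.
#' @return Non-negative scalar.
#' @export
straightness_corrected <- function(track) {
  tp <- .track_positions(track)
  n <- nrow(tp$pos)
  if (n < 2) stop("straightness needs at least 2 samples", call. = FALSE)
  steps <- diff(tp$pos)
  path <- sum(sqrt(rowSums(steps^2)))
  if (path == 0) return(0)
  net <- sqrt(sum((tp$pos[n, ] - tp$pos[1, ])^2))
  duration <- tp$frames[n] - tp$frames[1]
  (net / path) * sqrt(duration)
}

#' Mean angular alignment of consecutive steps
#'
#' Mean cosine of the turning angle between consecutive steps: +1 for a
#' straight track, -1 for perfect reversals, about 0 for an isotropic random
#' walk. Zero-length steps are skipped; if all steps are zero-length the
#' result is undefined (`NA`).
#'
#' @param track Samples of one track (at least 3).
#' @return Scalar in `[-1, 1]`, or `NA`.
#' @export
mean_angular_alignment <- function(track) {
  tp <- .track_positions(track)
  if (nrow(tp$pos) < 3) stop("angular alignment needs at least 3 samples",
                             call. = FALSE)
  steps <- diff(tp$pos)
  lens <- sqrt(rowSums(steps^2))
  keep <- lens > 0
  steps <- steps[keep, , drop = FALSE]
  lens <- lens[keep]
  if (nrow(steps) < 2) return(NA_real_)
  a <- steps[-nrow(steps), , drop = FALSE]
  b <- steps[-1, , drop = FALSE]
  mean(rowSums(a * b) / (lens[-length(lens)] * lens[-1]))
}

#' Dorsoventral displacement of a track
#'
#' Signed displacement of the track endpoint relative to its start along the
#' dorsoventral axis, ventral-positive by convention.
#'
#' @param track Samples of one track.
#' @param dv_axis Unit vector `(x, y, z)` pointing ventrally.
#' @return Signed displacement in um.
#' @export
dv_displacement <- function(track, dv_axis) {
  .assert_unit_vector(dv_axis, "dv_axis")
  tp <- .track_positions(track)
  n <- nrow(tp$pos)
  sum((tp$pos[n, ] - tp$pos[1, ]) * dv_axis)
}

#' Fraction of near-ablation tracks displaced ventrally
#'
#' Among tracks whose first position lies within `cutoff_um` (default 60 um)
#' of the reference point (the ablation centre or its control equivalent),
#' the fraction with a positive (ventral) dorsoventral displacement. With no
#' eligible tracks the fraction is undefined (`NA`).
#'
#' @param tracks A `track_set`.
#' @param dv_axis Ventral-positive unit vector `(x, y, z)`.
#' @param reference_point Reference position `(x, y, z)` in um.
#' @param cutoff_um Start-distance cutoff.
#' @return A one-row tibble: `n_eligible`, `n_ventral`, `fraction_ventral`.
#' @export
fraction_displaced_ventrally <- function(tracks, dv_axis, reference_point,
                                         cutoff_um = 60) {
  .assert_unit_vector(dv_axis, "dv_axis")
  stopifnot(length(reference_point) == 3)
  per <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_map(function(g, key) {
      g <- g[order(g$frame), ]
      start <- c(g$x_um[1], g$y_um[1], g$z_um[1])
      tibble::tibble(
        track_id = key$track_id,
        start_distance_um = sqrt(sum((start - reference_point)^2)),
        dv_um = dv_displacement(g, dv_axis)
      )
    }) |>
    dplyr::bind_rows()
  elig <- dplyr::filter(per, .data$start_distance_um <= cutoff_um)
  tibble::tibble(
    n_eligible = nrow(elig),
    n_ventral = sum(elig$dv_um > 0),
    fraction_ventral = if (nrow(elig)) sum(elig$dv_um > 0) / nrow(elig)
    else NA_real_
  )
}

#' Reporter-intensity dynamics of a track
#'
#' Start intensity as a z-score against the embryo-wide intensity
#' distribution, and the mean per-frame intensity change over the track
#' (for gap-free tracks this equals `(I_last - I_first) / (n - 1)`).
#'
#' @param track Samples of one track with an `intensity` column.
#' @param embryo_mean,embryo_sd Embryo-wide intensity mean and sd
#'   (`embryo_sd > 0`).
#' @return A one-row tibble: `start_intensity_z`, `mean_intensity_change`.
#' @export
intensity_dynamics <- function(track, embryo_mean, embryo_sd) {
  stopifnot(embryo_sd > 0)
  tp <- .track_positions(track)
  if (is.null(tp$intensity)) stop("track has no intensity column", call. = FALSE)
  z <- (tp$intensity[1] - embryo_mean) / embryo_sd
  change <- if (length(tp$intensity) >= 2) mean(diff(tp$intensity)) else NA_real_
  tibble::tibble(start_intensity_z = z, mean_intensity_change = change)
}

#' Per-track motion metrics table
#'
#' Computes, for every track: the MSD exponent and fit quality, the
#' directional classification (threshold 1.1), corrected straightness, mean
#' angular alignment, dorsoventral displacement and start distance to the
#' reference point, plus intensity dynamics when an `intensity` column and
#' embryo statistics are available.
#'
#' @param tracks A `track_set`.
#' @param dv_axis Ventral-positive unit vector `(x, y, z)`.
#' @param reference_point Ablation centre (or control point), `(x, y, z)` um.
#' @param alpha_threshold Directionality threshold on alpha.
#' @param max_lag_fraction Passed to [msd_curve()].
#' @param embryo_mean,embryo_sd Optional embryo-wide intensity statistics.
#' @return A tibble with one row per track.
#' @export
track_metrics <- function(tracks, dv_axis = c(0, -1, 0),
                          reference_point = c(0, 0, 0), alpha_threshold = 1.1,
                          max_lag_fraction = 0.5, embryo_mean = NULL,
                          embryo_sd = NULL) {
  .assert_unit_vector(dv_axis, "dv_axis")
  have_intensity <- "intensity" %in% names(tracks) &&
    !is.null(embryo_mean) && !is.null(embryo_sd)
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_map(function(g, key) {
      g <- g[order(g$frame), ]
      fit <- tryCatch(msd_exponent(msd_curve(g, max_lag_fraction)),
                      error = function(e) list(alpha = NA_real_,
                                               fit_r2 = NA_real_))
      start <- c(g$x_um[1], g$y_um[1], g$z_um[1])
      row <- tibble::tibble(
        track_id = key$track_id,
        n_samples = nrow(g),
        alpha = fit$alpha,
        fit_r2 = fit$fit_r2,
        directional = classify_directional(fit$alpha, alpha_threshold),
        straightness_corrected = straightness_corrected(g),
        mean_angular_alignment = if (nrow(g) >= 3) mean_angular_alignment(g)
        else NA_real_,
        dv_displacement_um = dv_displacement(g, dv_axis),
        start_distance_um = sqrt(sum((start - reference_point)^2))
      )
      if (have_intensity) {
        row <- dplyr::bind_cols(row,
                                intensity_dynamics(g, embryo_mean, embryo_sd))
      }
      row
    }) |>
    dplyr::bind_rows()
}
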