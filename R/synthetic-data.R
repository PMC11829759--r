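#' Specification of a synthetic tailbud phantom
#'
#' Describes a two-gene tailbud phantom: ellipsoidal ~10 um nuclei packed in
#' a voxel domain, opposing dorsoventral expression profiles for the two HCR
#' channels with a co-expression band in the middle, optional ablated region
#' rendered as pyknotic debris, and additive noise. Every generated output
#' carries its ground truth so downstream recovery error is measurable.
#'
#' The two channel amplitudes follow opposing piecewise-linear profiles of
#' the dorsoventral coordinate `g` in `[0, 1]`: `sox2` is high dorsally and
#' falls to zero beyond the co-expression band; `tbxta` mirrors it
#' ventrally. Nuclei with `g` inside `coexpression_band` express
#' both channels above background (the neuromesodermal-competent state).
#'
#' @param shape_voxels Integer length-3 `(z, y, x)` grid size.
#' @param voxel_size_um Positive length-3 spacing in um (z, y, x).
#' @param n_nuclei Number of nuclei.
#' @param nucleus_diameter_um Nominal nucleus diameter (default 10 um).
#' @param gradient_axis Unit vector (z, y, x) of the dorsoventral axis.
#' @param coexpression_band Interval in `[0, 1]` of the gradient coordinate
#'   where nuclei co-express both genes.
#' @param noise_sd Additive Gaussian noise scale; the per-voxel sd is
#'   `noise_sd * sqrt(1 + I)` (Poisson-like signal scaling).
#' @param ablation_box_um Optional 2x3 matrix `rbind(lo, hi)` of an
#'   axis-aligned box in um (z, y, x); nuclei whose centre falls inside are
#'   replaced by bright 1-3 um debris fragments.
#' @param separation_factor Minimum centre separation as a multiple of the
#'   nucleus diameter (at least the packing invariant 0.8).
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return A validated list of class `embryo_phantom_spec`.
#' @export
embryo_phantom_spec <- function(shape_voxels, voxel_size_um = c(0.5, 0.5, 0.5),
                                n_nuclei, nucleus_diameter_um = 10,
                                gradient_axis = c(0, 1, 0),
                                coexpression_band = c(0.35, 0.65),
                                noise_sd = 0, ablation_box_um = NULL,
                                separation_factor = 0.8, seed = 1) {
  shape_voxels <- as.integer(shape_voxels)
  stopifnot(length(shape_voxels) == 3L, all(shape_voxels >= 1L))
  stopifnot(length(voxel_size_um) == 3L, all(voxel_size_um > 0))
  stopifnot(n_nuclei >= 0, nucleus_diameter_um > 0, noise_sd >= 0)
  .assert_unit_vector(gradient_axis, "gradient_axis")
  stopifnot(length(coexpression_band) == 2L,
            coexpression_band[1] >= 0, coexpression_band[2] <= 1,
            coexpression_band[1] < coexpression_band[2])
  if (separation_factor < 0.8) {
    stop("`separation_factor` must be >= 0.8 (packing invariant)", call. = FALSE)
  }
  if (!is.null(ablation_box_um)) {
    ablation_box_um <- matrix(as.numeric(ablation_box_um), 2, 3)
    stopifnot(all(ablation_box_um[2, ] >= ablation_box_um[1, ]))
  }
  structure(
    list(shape_voxels = shape_voxels, voxel_size_um = as.numeric(voxel_size_um),
         n_nuclei = as.integer(n_nuclei),
         nucleus_diameter_um = nucleus_diameter_um,
         gradient_axis = as.numeric(gradient_axis),
         coexpression_band = as.numeric(coexpression_band),
         noise_sd = noise_sd, ablation_box_um = ablation_box_um,
         separation_factor = separation_factor, seed = as.integer(seed)),
    class = "embryo_phantom_spec"
  )
}

# Expression amplitude profiles along the DV coordinate g in [0,1]:
# opposing piecewise-linear ramps that fall to zero outside each gene's
# expression domain, so a non-expressing nucleus renders no signal and
# background-region medians estimate the true (zero) background exactly.
.amp_profiles <- function(g, band, peak_amp = 0.7) {
  sox2 <- ifelse(g <= band[2], peak_amp * (1 - 0.5 * g / band[2]), 0)
  tbxta <- ifelse(g >= band[1],
                  peak_amp * (1 - 0.5 * (1 - g) / (1 - band[1])), 0)
  list(sox2 = sox2, tbxta = tbxta)
}

.truth_class <- function(g, band) {
  dplyr::case_when(
    g < band[1] ~ "sox2_only",
    g > band[2] ~ "tbxta_only",
    TRUE ~ "double_positive"
  )
}

#' Generate a two-gene nuclear phantom stack with ground truth
#'
#' Renders `n_nuclei` Gaussian-tapered ellipsoids (axis jitter +/- 10%) into
#' a three-channel stack (`nuclear`, `sox2`, `tbxta`), together with the
#' ground-truth 3D label image and a truth table giving each nucleus's
#' centre, dorsoventral coordinate, expression class and channel amplitudes.
#' Nuclei inside `ablation_box_um` are replaced by small bright fragments
#' (pyknotic debris) carrying no label.
#'
#' @param spec An [embryo_phantom_spec].
#' @return A list: `stack` ([image_stack] with channels `nuclear`, `sox2`,
#'   `tbxta`), `labels` (3D integer array), `truth` (tibble with columns
#'   `id`, `z_um`, `y_um`, `x_um`, `gradient_coord`, `class`, `amp_sox2`,
#'   `amp_tbxta`, `ablated`).
#' @export
generate_nuclear_stack <- function(spec) {
  stopifnot(inherits(spec, "embryo_phantom_spec"))
  .with_seed(spec$seed, .generate_nuclear_stack_impl(spec))
}

.generate_nuclear_stack_impl <- function(spec) {
  d <- spec$shape_voxels
  sp <- spec$voxel_size_um
  extent <- d * sp
  diam <- spec$nucleus_diameter_um
  r_max <- diam / 2 * 1.1
  n <- spec$n_nuclei

  empty_truth <- tibble::tibble(
    id = integer(), z_um = double(), y_um = double(), x_um = double(),
    gradient_coord = double(), class = character(),
    amp_sox2 = double(), amp_tbxta = double(), ablated = logical()
  )
  make_stack <- function(vox) {
    image_stack(vox, sp, channels = c("nuclear", "sox2", "tbxta"))
  }
  if (n == 0L) {
    vox <- array(0, c(d, 3L))
    vox <- .add_phantom_noise(vox, spec$noise_sd)
    return(list(stack = make_stack(vox), labels = array(0L, d),
                truth = empty_truth))
  }

  # dart-throwing placement with minimum separation
  min_sep <- spec$separation_factor * diam
  margin <- pmin(r_max + max(sp), extent / 2)
  if (any(extent - 2 * margin <= 0)) {
    stop("domain too small to contain any nucleus", call. = FALSE)
  }
  centers <- matrix(NA_real_, n, 3)
  placed <- 0L
  tries <- 0L
  max_tries <- 4000L * n
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    p <- margin + stats::runif(3) * (extent - 2 * margin)
    ok <- placed == 0L ||
      min(sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE], 2, p)^2))) >= min_sep
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- p
    }
  }
  if (placed < n) {
    stop(sprintf(
      "infeasible packing: placed only %d of %d nuclei at separation %.1f um; reduce n_nuclei to <= %d or enlarge the domain",
      placed, n, min_sep, placed), call. = FALSE)
  }

  # dorsoventral coordinate: projection onto gradient_axis, scaled to [0,1]
  u <- spec$gradient_axis
  corners <- as.matrix(expand.grid(c(0, extent[1]), c(0, extent[2]), c(0, extent[3])))
  pr <- corners %*% u
  g <- as.numeric((centers %*% u - min(pr)) / (max(pr) - min(pr)))

  amps <- .amp_profiles(g, spec$coexpression_band)
  amp_nuc <- stats::runif(n, 0.8, 1.0)
  semiaxes <- matrix(stats::runif(3L * n, 0.9, 1.1) * diam / 2, n, 3)
  ablated <- rep(FALSE, n)
  if (!is.null(spec$ablation_box_um)) {
    b <- spec$ablation_box_um
    ablated <- centers[, 1] >= b[1, 1] & centers[, 1] < b[2, 1] &
      centers[, 2] >= b[1, 2] & centers[, 2] < b[2, 2] &
      centers[, 3] >= b[1, 3] & centers[, 3] < b[2, 3]
  }

  vox <- array(0, c(d, 3L))
  labels <- array(0L, d)
  best_rho <- array(Inf, d)
  taper_sigma2 <- 1 / (2 * log(5)) # intensity falls to 0.2 at the surface

  axes_um <- list(( seq_len(d[1]) - 0.5) * sp[1],
                  (seq_len(d[2]) - 0.5) * sp[2],
                  (seq_len(d[3]) - 0.5) * sp[3])

  render_blob <- function(center, semi, add_to, amp3, label_id = 0L) {
    # bounding voxel ranges per axis
    rng <- lapply(1:3, function(ax) {
      lo <- max(1L, ceiling((center[ax] - semi[ax]) / sp[ax] - 0.5))
      hi <- min(d[ax], floor((center[ax] + semi[ax]) / sp[ax] + 1.5))
      if (lo > hi) integer(0) else lo:hi
    })
    if (any(lengths(rng) == 0)) return(invisible())
    nz <- length(rng[[1]]); ny <- length(rng[[2]]); nx <- length(rng[[3]])
    dz <- (axes_um[[1]][rng[[1]]] - center[1]) / semi[1]
    dy <- (axes_um[[2]][rng[[2]]] - center[2]) / semi[2]
    dx <- (axes_um[[3]][rng[[3]]] - center[3]) / semi[3]
    rho2 <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`)
    inside <- rho2 <= 1
    if (!any(inside)) return(invisible())
    tp <- exp(-rho2 / (2 * taper_sigma2))
    for (ch in 1:3) {
      if (amp3[ch] <= 0) next
      sub <- vox[rng[[1]], rng[[2]], rng[[3]], ch]
      sub[inside] <- sub[inside] + amp3[ch] * tp[inside]
      vox[rng[[1]], rng[[2]], rng[[3]], ch] <<- sub
    }
    if (label_id > 0L) {
      lsub <- labels[rng[[1]], rng[[2]], rng[[3]]]
      bsub <- best_rho[rng[[1]], rng[[2]], rng[[3]]]
      take <- inside & rho2 < bsub
      lsub[take] <- label_id
      bsub[take] <- rho2[take]
      labels[rng[[1]], rng[[2]], rng[[3]]] <<- lsub
      best_rho[rng[[1]], rng[[2]], rng[[3]]] <<- bsub
    }
    invisible()
  }

  next_label <- 0L
  label_of <- integer(n)
  for (i in seq_len(n)) {
    if (ablated[i]) {
      # pyknotic debris: a few condensed bright 1-3 um fragments
      n_frag <- sample(2:4, 1)
      for (f in seq_len(n_frag)) {
        off <- stats::rnorm(3)
        off <- off / sqrt(sum(off^2)) * stats::runif(1, 0, 0.6) * semiaxes[i, ]
        frag_r <- stats::runif(1, 0.5, 1.5) # radius in um (1-3 um diameter)
        render_blob(centers[i, ] + off, rep(frag_r, 3),
                    amp3 = c(1.3 * amp_nuc[i], 0, 0))
      }
    } else {
      next_label <- next_label + 1L
      label_of[i] <- next_label
      render_blob(centers[i, ], semiaxes[i, ],
                  amp3 = c(amp_nuc[i], amps$sox2[i], amps$tbxta[i]),
                  label_id = next_label)
    }
  }

  vox <- .add_phantom_noise(vox, spec$noise_sd)
  truth <- tibble::tibble(
    id = ifelse(label_of > 0L, label_of, NA_integer_),
    z_um = centers[, 1], y_um = centers[, 2], x_um = centers[, 3],
    gradient_coord = g,
    class = .truth_class(g, spec$coexpression_band),
    amp_sox2 = amps$sox2, amp_tbxta = amps$tbxta,
    ablated = ablated
  )
  list(stack = make_stack(vox), labels = labels, truth = truth)
}

.add_phantom_noise <- function(vox, noise_sd) {
  if (noise_sd <= 0) return(vox)
  noise <- stats::rnorm(length(vox), sd = noise_sd * sqrt(1 + as.double(vox)))
  vox <- vox + array(noise, dim(vox))
  vox[vox < 0] <- 0
  vox
}

#' Specification of simulated 3D cell tracks
#'
#' @param kind One of `"diffusive"` (i.i.d. Gaussian steps), `"persistent"`
#'   (AR(1)-correlated steps), `"ballistic"` (constant velocity plus optional
#'   positional noise) or `"confined"` (diffusion in a reflecting sphere).
#' @param n_tracks,n_steps Number of tracks and steps per track
#'   (`n_steps >= 10`).
#' @param step_sd_um Per-axis step (or positional noise) sd in um.
#' @param frame_interval_s Frame interval in seconds (default 30 s).
#' @param persistence AR(1) step correlation in `[0, 1]` (persistent only).
#' @param speed_um_per_frame Speed in um/frame (ballistic only).
#' @param confinement_radius_um Reflecting-sphere radius (confined only).
#' @param seed RNG seed.
#' @return A validated list of class `track_sim_spec`.
#' @export
track_sim_spec <- function(kind, n_tracks, n_steps, step_sd_um = 1,
                           frame_interval_s = 30, persistence = 0.7,
                           speed_um_per_frame = 1, confinement_radius_um = 5,
                           seed = 1) {
  kinds <- c("diffusive", "persistent", "ballistic", "confined")
  if (!(is.character(kind) && length(kind) == 1L && kind %in% kinds)) {
    stop(sprintf("unknown track kind; use one of: %s",
                 paste(kinds, collapse = ", ")), call. = FALSE)
  }
  stopifnot(n_tracks >= 1, n_steps >= 10, step_sd_um >= 0,
            frame_interval_s > 0, persistence >= 0, persistence <= 1,
            speed_um_per_frame > 0, confinement_radius_um > 0)
  structure(
    list(kind = kind, n_tracks = as.integer(n_tracks),
         n_steps = as.integer(n_steps), step_sd_um = step_sd_um,
         frame_interval_s = frame_interval_s, persistence = persistence,
         speed_um_per_frame = speed_um_per_frame,
         confinement_radius_um = confinement_radius_um, seed = as.integer(seed)),
    class = "track_sim_spec"
  )
}

#' Generate simulated 3D tracks with ground-truth motion class
#'
#' Positions are in um at uniform frame intervals. The ground-truth MSD
#' exponent is attached per track: 1 for diffusive, 2 for ballistic, below 1
#' at long lags for confined, and between 1 and 2 for persistent motion
#' (`NA` where no single exponent applies).
#'
#' @param spec A [track_sim_spec].
#' @return A tidy track table (class `track_set`): columns `track_id`,
#'   `frame`, `t_s`, `x_um`, `y_um`, `z_um`, with a `truth` attribute tibble
#'   (`track_id`, `kind`, `alpha_true`).
#' @export
generate_tracks <- function(spec) {
  stopifnot(inherits(spec, "track_sim_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_tracks
    m <- spec$n_steps
    tracks <- purrr::map(seq_len(n), function(i) {
      start <- stats::runif(3, 0, 100)
      pos <- switch(
        spec$kind,
        diffusive = apply(matrix(stats::rnorm(3 * m, sd = spec$step_sd_um), m, 3),
                          2, cumsum),
        ballistic = {
          dir <- stats::rnorm(3)
          dir <- dir / sqrt(sum(dir^2))
          base <- outer(seq_len(m), dir * spec$speed_um_per_frame)
          if (spec$step_sd_um > 0) {
            base + matrix(stats::rnorm(3 * m, sd = spec$step_sd_um), m, 3)
          } else base
        },
        persistent = {
          p <- spec$persistence
          steps <- matrix(0, m, 3)
          prev <- stats::rnorm(3, sd = spec$step_sd_um)
          for (t in seq_len(m)) {
            prev <- p * prev +
              sqrt(1 - p^2) * stats::rnorm(3, sd = spec$step_sd_um)
            steps[t, ] <- prev
          }
          apply(steps, 2, cumsum)
        },
        confined = {
          r <- spec$confinement_radius_um
          cur <- c(0, 0, 0)
          out <- matrix(0, m, 3)
          for (t in seq_len(m)) {
            cur <- cur + stats::rnorm(3, sd = spec$step_sd_um)
            nrm <- sqrt(sum(cur^2))
            if (nrm > r) cur <- cur * (2 * r - nrm) / nrm # radial reflection
            out[t, ] <- cur
          }
          out
        }
      )
      pos <- rbind(c(0, 0, 0), pos)
      tibble::tibble(
        track_id = i, frame = 0:m, t_s = (0:m) * spec$frame_interval_s,
        x_um = start[1] + pos[, 1], y_um = start[2] + pos[, 2],
        z_um = start[3] + pos[, 3]
      )
    })
    out <- dplyr::bind_rows(tracks)
    alpha_true <- switch(spec$kind, diffusive = 1, ballistic = 2,
                         persistent = NA_real_, confined = NA_real_)
    attr(out, "truth") <- tibble::tibble(
      track_id = seq_len(n), kind = spec$kind, alpha_true = alpha_true
    )
    class(out) <- c("track_set", class(out))
    out
  })
}

#' Generate embryo point clouds related by known rigid transforms
#'
#' Draws a reference cloud (or takes one), applies a random recorded rigid
#' transform per embryo and adds isotropic Gaussian jitter, emulating
#' independently mounted embryos to be registered back onto the reference.
#'
#' @param n_embryos Number of transformed clouds.
#' @param n_points Points per cloud (`>= 4`).
#' @param transform_ranges List with `rotation_deg` (max absolute rotation
#'   angle) and `translation_um` (max absolute translation per axis).
#' @param noise_sd_um Isotropic per-axis jitter sd in um.
#' @param seed RNG seed.
#' @param reference Optional reference cloud (matrix or tibble with
#'   `x_um`, `y_um`, `z_um`); drawn uniformly in a 100 um box if missing.
#' @return A list: `reference` (tibble `x_um`, `y_um`, `z_um`) and `embryos`,
#'   a list of lists with `cloud` (tibble, `embryo_id` attached) and
#'   `transform` (the true [rigid_transform]).
#' @export
generate_point_clouds <- function(n_embryos, n_points,
                                  transform_ranges = list(rotation_deg = 30,
                                                          translation_um = 20),
                                  noise_sd_um = 0, seed = 1, reference = NULL) {
  stopifnot(n_embryos >= 1, n_points >= 4)
  .with_seed(seed, {
    ref <- if (is.null(reference)) {
      matrix(stats::runif(3 * n_points, 0, 100), n_points, 3)
    } else {
      m <- if (is.data.frame(reference)) {
        as.matrix(reference[, c("x_um", "y_um", "z_um")])
      } else as.matrix(reference)
      stopifnot(ncol(m) == 3)
      m
    }
    centered <- sweep(ref, 2, colMeans(ref))
    if (qr(centered)$rank < 3) {
      stop("degenerate reference cloud: points are collinear or coplanar",
           call. = FALSE)
    }
    embryos <- purrr::map(seq_len(n_embryos), function(i) {
      ang <- stats::runif(1, -transform_ranges$rotation_deg,
                          transform_ranges$rotation_deg) * pi / 180
      axis <- stats::rnorm(3)
      axis <- axis / sqrt(sum(axis^2))
      tr <- stats::runif(3, -transform_ranges$translation_um,
                         transform_ranges$translation_um)
      tf <- rigid_transform(rotation = .rotation_about_axis(axis, ang),
                            translation_um = tr)
      pts <- transform_points(tf, ref)
      if (noise_sd_um > 0) {
        pts <- pts + matrix(stats::rnorm(length(pts), sd = noise_sd_um),
                            nrow(pts), 3)
      }
      cloud <- tibble::tibble(x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3])
      attr(cloud, "embryo_id") <- i
      list(cloud = cloud, transform = tf)
    })
    list(reference = tibble::tibble(x_um = ref[, 1], y_um = ref[, 2],
                                    z_um = ref[, 3]),
         embryos = embryos)
  })
}

# Rodrigues rotation matrix about a unit axis
.rotation_about_axis <- function(axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle) * kx + (1 - cos(angle)) * (kx %*% kx)
}

#' Generate tail tissue polylines with known per-somite lengths
#'
#' Builds a curved paraxial-mesoderm polyline whose landmark-to-landmark arc
#' lengths reproduce `somite_lengths_um` exactly (each somite is a chain of
#' equal-length chords), followed by a pre-somitic mesoderm segment, plus a
#' spinal-cord polyline of known total length.
#'
#' @param n_somites Number of somites; must equal
#'   `length(somite_lengths_um)`.
#' @param somite_lengths_um Positive per-somite lengths in um.
#' @param sc_profile List with `length_um`, the spinal-cord polyline length.
#' @param psm_length_um Length of the PSM segment appended after the last
#'   somite (0 for none).
#' @param curvature Maximum heading change per chord in radians (0 gives
#'   straight lines).
#' @param seed RNG seed.
#' @return A list: `spinal_cord` and `paraxial_mesoderm`
#'   ([measured_polyline] objects) and `truth` (list with
#'   `somite_lengths_um`, `psm_length_um`, `sc_length_um`, `pm_total_um`).
#' @export
generate_tail_polylines <- function(n_somites, somite_lengths_um,
                                    sc_profile = list(length_um = 400),
                                    psm_length_um = 100, curvature = 0.05,
                                    seed = 1) {
  if (length(somite_lengths_um) != n_somites) {
    stop(sprintf("`somite_lengths_um` has %d entries but n_somites = %d",
                 length(somite_lengths_um), n_somites), call. = FALSE)
  }
  stopifnot(all(somite_lengths_um > 0), psm_length_um >= 0)
  .with_seed(seed, {
    chords_per_seg <- 8L
    build_path <- function(seg_lengths, start, heading0) {
      pts <- matrix(start, 1, 2)
      heading <- heading0
      idx <- 1L
      landmark_indices <- 1L
      for (L in seg_lengths) {
        step <- L / chords_per_seg
        for (k in seq_len(chords_per_seg)) {
          heading <- heading + stats::runif(1, -curvature, curvature)
          pts <- rbind(pts, pts[nrow(pts), ] +
                         step * c(cos(heading), sin(heading)))
          idx <- idx + 1L
        }
        landmark_indices <- c(landmark_indices, idx)
      }
      list(pts = pts, landmarks = landmark_indices)
    }
    pm_segs <- c(somite_lengths_um, if (psm_length_um > 0) psm_length_um)
    pm <- build_path(pm_segs, c(0, 0), 0)
    sc <- build_path(sc_profile$length_um, c(0, 12), 0)
    list(
      spinal_cord = measured_polyline(sc$pts, sc$landmarks, tissue = "spinal_cord"),
      paraxial_mesoderm = measured_polyline(pm$pts, pm$landmarks,
                                            tissue = "paraxial_mesoderm"),
      truth = list(somite_lengths_um = as.numeric(somite_lengths_um),
                   psm_length_um = psm_length_um,
                   sc_length_um = sc_profile$length_um,
                   pm_total_um = sum(pm_segs))
    )
  })
}
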