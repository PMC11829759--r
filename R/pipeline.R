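#' Pipeline configuration
#'
#' One flat, validated configuration object holding every stage parameter.
#' The defaults are the printed analysis values: 10 um equalisation kernel,
#' DoG sigmas 1 and 3, IoU stitching threshold 0.6, two rounds of 0.8 um
#' median filtering, 11 um neighbourhood radius, MSD directionality
#' threshold 1.1, 60 um start-distance cutoff, and significance tiers
#' 0.05/0.01/0.001/0.0001. Configurations round-trip losslessly through
#' YAML.
#'
#' @param kernel_um Adaptive-equalisation kernel (um).
#' @param dog_low_sigma,dog_high_sigma DoG sigmas (voxel units).
#' @param iou_threshold 2D-to-3D stitching threshold, in `(0, 1]`.
#' @param hcr_kernel_um,hcr_rounds HCR median-filter window (um) and passes.
#' @param radius_um Neighbourhood-averaging radius (um).
#' @param alpha_threshold MSD directionality threshold.
#' @param distance_cutoff_um Start-distance cutoff for track fractions (um).
#' @param tier_thresholds Significance tiers, largest first.
#' @param nucleus_diameter_um Nominal nucleus diameter (um).
#' @param min_area_frac,min_volume_frac Segmentation plausibility filters.
#' @param dv_axis Ventral-positive dorsoventral axis `(x, y, z)`.
#' @param seed Seed governing every stochastic stage.
#' @param paths Named list of input paths used by `run_pipeline()`
#'   subcommands.
#' @param phantom Named list of phantom settings for the `simulate`
#'   subcommand (`shape_voxels`, `voxel_size_um`, `n_nuclei`, `noise_sd`).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(kernel_um = 10, dog_low_sigma = 1,
                            dog_high_sigma = 3, iou_threshold = 0.6,
                            hcr_kernel_um = 0.8, hcr_rounds = 2,
                            radius_um = 11, alpha_threshold = 1.1,
                            distance_cutoff_um = 60,
                            tier_thresholds = c(0.05, 0.01, 0.001, 0.0001),
                            nucleus_diameter_um = 10, min_area_frac = 0.5,
                            min_volume_frac = 0.1, dv_axis = c(0, -1, 0),
                            seed = 1, paths = list(), phantom = list()) {
  cfg <- list(
    kernel_um = kernel_um, dog_low_sigma = dog_low_sigma,
    dog_high_sigma = dog_high_sigma, iou_threshold = iou_threshold,
    hcr_kernel_um = hcr_kernel_um, hcr_rounds = hcr_rounds,
    radius_um = radius_um, alpha_threshold = alpha_threshold,
    distance_cutoff_um = distance_cutoff_um,
    tier_thresholds = as.numeric(tier_thresholds),
    nucleus_diameter_um = nucleus_diameter_um,
    min_area_frac = min_area_frac, min_volume_frac = min_volume_frac,
    dv_axis = as.numeric(dv_axis), seed = as.integer(seed),
    paths = paths, phantom = phantom
  )
  if (!(cfg$iou_threshold > 0 && cfg$iou_threshold <= 1)) {
    stop("invalid config: `iou_threshold` must lie in (0, 1]", call. = FALSE)
  }
  if (!(cfg$dog_low_sigma > 0 && cfg$dog_high_sigma > cfg$dog_low_sigma)) {
    stop("invalid config: DoG sigmas must satisfy 0 < low < high", call. = FALSE)
  }
  stopifnot(cfg$kernel_um > 0, cfg$hcr_kernel_um > 0, cfg$hcr_rounds >= 1,
            cfg$radius_um > 0, cfg$distance_cutoff_um > 0,
            all(diff(cfg$tier_thresholds) < 0))
  .assert_unit_vector(cfg$dv_axis, "dv_axis")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

.write_manifest <- function(out_dir, cfg, subcommand, outputs) {
  manifest <- list(
    subcommand = subcommand,
    config_hash = rlang::hash(unclass(cfg)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("tailbudkit")),
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run one pipeline stage
#'
#' Chains the package's stages under a single configuration. Subcommands:
#' `simulate` (write a phantom stack, truth labels and truth table),
#' `segment` (stack to label volume and nucleus table), `quantify`
#' (classify expression and compute the relative-level index), `register`
#' (align a moving cloud to a fixed cloud), `tracks` (per-track motion
#' metrics), `morphometry` (polyline lengths and normalisation). Every
#' stochastic stage is governed by the config seed, so identical config and
#' seed give identical outputs; a manifest with the config hash is written
#' alongside them.
#'
#' @param cfg A [pipeline_config].
#' @param subcommand One of `simulate`, `segment`, `quantify`, `register`,
#'   `tracks`, `morphometry`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(cfg, subcommand, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  subcommands <- c("simulate", "segment", "quantify", "register", "tracks",
                   "morphometry")
  if (!(is.character(subcommand) && length(subcommand) == 1L &&
        subcommand %in% subcommands)) {
    stop(sprintf("usage: unknown subcommand; expected one of %s",
                 paste(subcommands, collapse = ", ")), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  outputs <- switch(
    subcommand,
    simulate = {
      ph <- cfg$phantom
      spec <- embryo_phantom_spec(
        shape_voxels = ph$shape_voxels %||% c(40, 96, 96),
        voxel_size_um = ph$voxel_size_um %||% c(0.5, 0.5, 0.5),
        n_nuclei = ph$n_nuclei %||% 30,
        nucleus_diameter_um = cfg$nucleus_diameter_um,
        noise_sd = ph$noise_sd %||% 0,
        separation_factor = ph$separation_factor %||% 0.8,
        seed = cfg$seed
      )
      sim <- generate_nuclear_stack(spec)
      write_stack(sim$stack, p("stack.tif"))
      write_labels(sim$labels, p("labels_truth.tif"), spec$voxel_size_um)
      utils::write.csv(sim$truth, p("truth.csv"), row.names = FALSE)
      list(stack = p("stack.tif"), labels_truth = p("labels_truth.tif"),
           truth = p("truth.csv"))
    },
    segment = {
      stack <- load_stack(cfg$paths$stack %||% p("stack.tif"))
      seg <- segment_stack(
        stack, kernel_um = cfg$kernel_um, low_sigma = cfg$dog_low_sigma,
        high_sigma = cfg$dog_high_sigma, iou_threshold = cfg$iou_threshold,
        nucleus_diameter_um = cfg$nucleus_diameter_um,
        min_area_frac = cfg$min_area_frac,
        min_volume_frac = cfg$min_volume_frac
      )
      write_labels(seg$labels, p("labels.tif"), stack$voxel_size_um)
      utils::write.csv(seg$nuclei, p("nuclei.csv"), row.names = FALSE)
      jsonlite::write_json(list(n_nuclei = seg$n_nuclei), p("counts.json"),
                           auto_unbox = TRUE)
      list(labels = p("labels.tif"), nuclei = p("nuclei.csv"),
           counts = p("counts.json"))
    },
    quantify = {
      nuclei <- tibble::as_tibble(utils::read.csv(cfg$paths$nuclei))
      regions <- utils::read.csv(cfg$paths$regions)
      exclusions <- if (!is.null(cfg$paths$exclusions)) {
        utils::read.csv(cfg$paths$exclusions)
      } else NULL
      bg <- estimate_background(nuclei, regions)
      cls <- classify_expression(nuclei, bg, manual_exclusions = exclusions)
      cls <- nmc_relative_level(cls, bg)
      utils::write.csv(bg, p("backgrounds.csv"), row.names = FALSE)
      utils::write.csv(cls, p("nuclei_classified.csv"), row.names = FALSE)
      utils::write.csv(region_counts(cls), p("class_counts.csv"),
                       row.names = FALSE)
      list(backgrounds = p("backgrounds.csv"),
           nuclei_classified = p("nuclei_classified.csv"),
           class_counts = p("class_counts.csv"))
    },
    register = {
      moving <- utils::read.csv(cfg$paths$moving)
      fixed <- utils::read.csv(cfg$paths$fixed)
      fit <- register_point_clouds(moving, fixed,
                                   mode = cfg$paths$mode %||% "landmark")
      write_transform(fit$transform, p("transform.json"))
      utils::write.csv(tidy(fit), p("residuals.csv"), row.names = FALSE)
      list(transform = p("transform.json"), residuals = p("residuals.csv"))
    },
    tracks = {
      ts <- read_tracks(cfg$paths$tracks)
      ref <- as.numeric(cfg$paths$reference_point %||% c(0, 0, 0))
      tm <- track_metrics(ts, dv_axis = cfg$dv_axis, reference_point = ref,
                          alpha_threshold = cfg$alpha_threshold)
      utils::write.csv(tm, p("track_metrics.csv"), row.names = FALSE)
      frac <- fraction_displaced_ventrally(ts, cfg$dv_axis, ref,
                                           cutoff_um = cfg$distance_cutoff_um)
      utils::write.csv(frac, p("dv_fractions.csv"), row.names = FALSE)
      list(track_metrics = p("track_metrics.csv"),
           dv_fractions = p("dv_fractions.csv"))
    },
    morphometry = {
      read_poly <- function(path, tissue) {
        df <- utils::read.csv(path)
        landmarks <- which(as.logical(df$landmark %||% rep(TRUE, nrow(df))))
        measured_polyline(as.matrix(df[, c("x_um", "y_um")]),
                          if (length(landmarks)) landmarks else NULL, tissue)
      }
      sc <- read_poly(cfg$paths$spinal_cord, "spinal_cord")
      pm <- read_poly(cfg$paths$paraxial_mesoderm, "paraxial_mesoderm")
      n_somites <- cfg$paths$total_somites %||% NULL
      sc_len <- polyline_length(sc, n_somites)
      pm_len <- polyline_length(pm, n_somites)
      res <- tibble::tibble(
        tissue = c("spinal_cord", "paraxial_mesoderm"),
        total_um = c(sc_len$total_um, pm_len$total_um),
        relative_um_per_somite = c(sc_len$relative_um_per_somite,
                                   pm_len$relative_um_per_somite),
        ratio_sc_pm = tissue_ratio(sc_len, pm_len)
      )
      utils::write.csv(res, p("tissue_lengths.csv"), row.names = FALSE)
      list(tissue_lengths = p("tissue_lengths.csv"))
    }
  )
  .write_manifest(out_dir, cfg, subcommand, outputs)
  invisible(outputs)
}
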