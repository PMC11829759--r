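#' Adaptive histogram equalisation with a physical-size kernel
#'
#' Equalises local contrast with an exact sliding-window rank transform: each
#' voxel is replaced by its mid-rank within a box window whose side is
#' `kernel_um` converted to voxels per axis (`round(kernel_um /
#' voxel_size_um)`), so anisotropic stacks get anisotropic windows. The
#' default 10 um matches the average nuclear diameter. Output intensities lie
#' in `[0, 1]`.
#'
#' @param stack An [image_stack], or a bare 3D `(z, y, x)` array (then
#'   `voxel_size_um` must be given).
#' @param kernel_um Side of the cubic kernel in um; must be at least twice
#'   the largest voxel spacing.
#' @param channel Channel to equalise when `stack` is an [image_stack].
#' @param voxel_size_um Spacing for bare arrays.
#' @return Same form as the input (stack with the channel replaced, or array).
#' @export
equalize_adaptive <- function(stack, kernel_um = 10, channel = "nuclear",
                              voxel_size_um = NULL) {
  v <- .resolve_volume(stack, channel, voxel_size_um)
  win <- ahe_window_voxels(kernel_um, v$spacing)
  out <- .cpp_ahe3d(as.double(v$arr), dim(v$arr),
                    as.integer((win - 1L) %/% 2L), as.integer(win %/% 2L))
  dim(out) <- dim(v$arr)
  if (is.null(v$stack)) out else set_channel(v$stack, channel, out)
}

#' @rdname equalize_adaptive
#' @details `ahe_window_voxels()` exposes the um-to-voxel window conversion.
#' @export
ahe_window_voxels <- function(kernel_um, voxel_size_um) {
  stopifnot(length(voxel_size_um) == 3L, all(voxel_size_um > 0))
  if (kernel_um < 2 * max(voxel_size_um)) {
    stop("`kernel_um` must be at least twice the largest voxel spacing",
         call. = FALSE)
  }
  win <- as.integer(round(kernel_um / voxel_size_um))
  if (any(win < 1L)) {
    stop("equalisation kernel smaller than one voxel on some axis", call. = FALSE)
  }
  win
}

.gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

.gauss3d <- function(arr, sigma_vox) {
  out <- as.double(arr)
  d <- dim(arr)
  for (ax in 0:2) {
    s <- sigma_vox[ax + 1]
    if (s > 0) out <- .cpp_conv1d_axis(out, d, .gauss_kernel(s), ax)
  }
  dim(out) <- d
  out
}

#' Difference-of-Gaussians band-pass filter
#'
#' Subtracts a wide Gaussian blur from a narrow one and clips negative values
#' to zero, enhancing blob-like structures at the nuclear scale. The printed
#' defaults are sigma 1 (narrow) and 3 (wide); sigmas are interpreted in
#' voxel units by default, with a um option for physically calibrated use
#' (each axis then gets `sigma_um / spacing` voxels).
#'
#' @inheritParams equalize_adaptive
#' @param low_sigma,high_sigma Gaussian standard deviations, `0 < low < high`.
#' @param sigma_units `"voxel"` (default) or `"um"`.
#' @return Same form as the input; values are everywhere `>= 0`.
#' @export
dog_filter <- function(stack, low_sigma = 1, high_sigma = 3,
                       sigma_units = c("voxel", "um"), channel = "nuclear",
                       voxel_size_um = NULL) {
  sigma_units <- match.arg(sigma_units)
  if (!(low_sigma > 0 && high_sigma > low_sigma)) {
    stop("require 0 < low_sigma < high_sigma", call. = FALSE)
  }
  v <- .resolve_volume(stack, channel, voxel_size_um)
  lo <- if (sigma_units == "um") low_sigma / v$spacing else rep(low_sigma, 3)
  hi <- if (sigma_units == "um") high_sigma / v$spacing else rep(high_sigma, 3)
  out <- .gauss3d(v$arr, lo) - .gauss3d(v$arr, hi)
  out[out < 0] <- 0
  if (is.null(v$stack)) out else set_channel(v$stack, channel, out)
}

#' Segment nuclei in a single 2D slice
#'
#' Labels bright blobs of plausible nuclear footprint area in one
#' pre-processed slice. The reference backend is classical: Gaussian
#' smoothing, Otsu thresholding, connected-component labelling and a
#' distance-transform watershed split of touching blobs. The backend is
#' pluggable: pass a function `(slice) -> integer label matrix` to adapt a
#' trained 2D model in place of the classical labeller; the footprint-area
#' filter is applied either way.
#'
#' Footprints smaller than `min_area_frac` times the equatorial
#' cross-section of a nominal nucleus (`pi * (nucleus_diameter_um/2)^2`) are
#' discarded: such footprints are pole caps of a nucleus or debris fragments,
#' and their slice-to-slice overlap is too unstable to stitch reliably.
#'
#' @param slice 2D numeric matrix `(y, x)`.
#' @param spacing_um Pixel spacing `(y, x)` in um.
#' @param nucleus_diameter_um Nominal nucleus diameter (default 10 um).
#' @param min_area_frac Minimum footprint area as a fraction of the nominal
#'   equatorial area.
#' @param backend `"classical"` or a labelling function.
#' @param smooth_sigma_px Smoothing sigma (pixels) for the classical backend.
#' @param split_touching Run the watershed split (classical backend).
#' @param threshold Optional global intensity threshold (same units as the
#'   slice); when missing, a per-slice Otsu threshold is used. A volume-wide
#'   threshold (see [otsu_threshold()]) is more robust on slices that carry
#'   no nuclei.
#' @return Integer label matrix, background 0.
#' @export
label_2d <- function(slice, spacing_um, nucleus_diameter_um = 10,
                     min_area_frac = 0.5, backend = "classical",
                     smooth_sigma_px = 2, split_touching = TRUE,
                     threshold = NULL) {
  stopifnot(is.matrix(slice), length(spacing_um) == 2L, all(spacing_um > 0))
  labels <- if (is.function(backend)) {
    res <- tryCatch(backend(slice), error = function(e) {
      stop(sprintf("2D labelling backend failed: %s", conditionMessage(e)),
           call. = FALSE)
    })
    storage.mode(res) <- "integer"
    res
  } else if (identical(backend, "classical")) {
    .label_2d_classical(slice, smooth_sigma_px, split_touching, threshold)
  } else {
    stop("`backend` must be \"classical\" or a function", call. = FALSE)
  }
  min_area_px <- min_area_frac * pi * (nucleus_diameter_um / 2)^2 /
    prod(spacing_um)
  filter_small_footprints(labels, min_area_px)
}

.label_2d_classical <- function(slice, smooth_sigma_px, split_touching,
                                threshold = NULL) {
  if (is.null(threshold)) {
    rng <- range(slice)
    if (rng[2] <= rng[1]) return(matrix(0L, nrow(slice), ncol(slice)))
    img <- (slice - rng[1]) / (rng[2] - rng[1])
    if (smooth_sigma_px > 0) img <- EBImage::gblur(img, sigma = smooth_sigma_px)
    threshold <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
    mask <- img > threshold
  } else {
    img <- if (smooth_sigma_px > 0) EBImage::gblur(slice, sigma = smooth_sigma_px)
    else slice
    mask <- img > threshold
  }
  if (!any(mask)) return(matrix(0L, nrow(slice), ncol(slice)))
  labels <- if (split_touching) {
    EBImage::watershed(EBImage::distmap(mask), tolerance = 1)
  } else {
    EBImage::bwlabel(mask)
  }
  out <- as.integer(EBImage::imageData(labels))
  dim(out) <- dim(slice)
  out
}

#' Volume-wide Otsu threshold
#'
#' Otsu's threshold computed from the intensity histogram of an entire
#' array, used to binarise the band-passed nuclear channel consistently
#' across slices.
#'
#' @param x Numeric array or vector.
#' @param n_bins Histogram resolution.
#' @return Threshold on the scale of `x`.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  v <- as.double(x)
  rng <- range(v)
  if (rng[2] <= rng[1]) return(rng[1])
  h <- as.double(tabulate(pmin(n_bins, 1L + as.integer(
    (v - rng[1]) / (rng[2] - rng[1]) * n_bins)), n_bins))
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * (rng[2] - rng[1])
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(between)]
}

#' Remove small label footprints
#'
#' Zeroes out labels whose pixel count is below `min_area_px`; remaining
#' label ids are kept as-is.
#'
#' @param labels Integer label matrix (or array).
#' @param min_area_px Minimum retained size in pixels.
#' @return Filtered labels, same shape.
#' @export
filter_small_footprints <- function(labels, min_area_px) {
  if (!any(labels > 0)) return(labels)
  sizes <- tabulate(labels[labels > 0])
  drop <- which(sizes > 0 & sizes < min_area_px)
  if (length(drop)) labels[labels %in% drop] <- 0L
  labels
}

#' Join per-slice 2D labels into 3D nuclei
#'
#' Stitches a z-series of 2D label images into 3D labels by footprint
#' overlap. Scanning slices in increasing z, each 2D label is matched to at
#' most one 3D label from the previous slice by greedy one-to-one matching
#' in order of descending intersection-over-union (IoU); ties broken by
#' larger intersection, then lower 2D label id. Pairs with IoU at or above
#' `iou_threshold` (printed value 0.6) continue the 3D label; everything
#' else seeds a new one. No gap bridging: a nucleus absent from one slice
#' restarts as a new label.
#'
#' @param labels_2d 3D integer array `(z, y, x)` of per-slice 2D labels, or a
#'   list of 2D matrices sharing one grid.
#' @param iou_threshold IoU threshold in `(0, 1]`.
#' @return 3D integer label array with consecutive labels `1..K`.
#' @export
join_labels_3d <- function(labels_2d, iou_threshold = 0.6) {
  if (!(iou_threshold > 0 && iou_threshold <= 1)) {
    stop("`iou_threshold` must lie in (0, 1]", call. = FALSE)
  }
  if (is.list(labels_2d)) {
    dims <- unique(lapply(labels_2d, dim))
    if (length(dims) != 1L) stop("all slices must share the same 2D grid", call. = FALSE)
    arr <- array(0L, c(length(labels_2d), dims[[1]]))
    for (z in seq_along(labels_2d)) arr[z, , ] <- as.integer(labels_2d[[z]])
    labels_2d <- arr
  }
  stopifnot(is.array(labels_2d), length(dim(labels_2d)) == 3L)
  storage.mode(labels_2d) <- "integer"
  nz <- dim(labels_2d)[1]
  out <- array(0L, dim(labels_2d))
  next_id <- 1L

  relabel_slice <- function(cur, assignment) {
    # assignment: named map 2D id -> 3D id; unmapped ids get fresh 3D ids
    slice <- array(0L, dim(cur))
    ids <- sort(unique(as.integer(cur)))
    ids <- ids[ids > 0]
    for (id in ids) {
      key <- as.character(id)
      if (!is.null(assignment[[key]])) {
        slice[cur == id] <- assignment[[key]]
      } else {
        slice[cur == id] <- next_id
        next_id <<- next_id + 1L
      }
    }
    slice
  }

  out[1, , ] <- relabel_slice(labels_2d[1, , ], list())
  if (nz >= 2L) {
    for (z in 2:nz) {
      prev <- out[z - 1, , ]
      cur <- labels_2d[z, , ]
      assignment <- list()
      ov <- .cpp_label_overlaps(as.integer(prev), as.integer(cur))
      if (nrow(ov)) {
        area_prev <- tabulate(prev[prev > 0])
        area_cur <- tabulate(cur[cur > 0])
        inter <- ov[, 3]
        iou <- inter / (area_prev[ov[, 1]] + area_cur[ov[, 2]] - inter)
        keep <- iou >= iou_threshold
        if (any(keep)) {
          cand <- data.frame(p = ov[keep, 1], c = ov[keep, 2],
                             inter = inter[keep], iou = iou[keep])
          cand <- cand[order(-cand$iou, -cand$inter, cand$c, cand$p), ]
          used_p <- integer(0)
          for (r in seq_len(nrow(cand))) {
            key <- as.character(cand$c[r])
            if (cand$p[r] %in% used_p || !is.null(assignment[[key]])) next
            assignment[[key]] <- cand$p[r]
            used_p <- c(used_p, cand$p[r])
          }
        }
      }
      out[z, , ] <- relabel_slice(cur, assignment)
    }
  }
  # relabel consecutively (ids are already 1..K by construction, but a
  # matched id can skip generations; normalise defensively)
  ids <- sort(unique(as.integer(out)))
  ids <- ids[ids > 0]
  if (length(ids) && !identical(ids, seq_along(ids))) {
    remap <- integer(max(ids))
    remap[ids] <- seq_along(ids)
    pos <- out > 0
    out[pos] <- remap[out[pos]]
  }
  out
}

#' Measure segmented nuclei
#'
#' Builds the per-nucleus table from a 3D label image and the intensity
#' stack: centroid in um (voxel-centre convention, per-axis spacing applied),
#' volume in um^3 (voxel count times voxel volume), and the mean intensity of
#' every channel within the nucleus.
#'
#' @param labels_3d 3D integer label array on the stack's grid.
#' @param stack The source [image_stack].
#' @return A tibble with columns `id`, `z_um`, `y_um`, `x_um`, `volume_um3`
#'   and one `mean_<channel>` column per channel; empty (zero-row) for an
#'   empty label image.
#' @export
extract_nuclei <- function(labels_3d, stack) {
  stopifnot(inherits(stack, "image_stack"))
  stopifnot(identical(dim(labels_3d), dim(stack$voxels)[1:3]))
  spacing <- stack$voxel_size_um
  mean_cols <- paste0("mean_", stack$channels)
  pos <- which(labels_3d > 0)
  if (!length(pos)) {
    out <- tibble::tibble(id = integer(), z_um = double(), y_um = double(),
                          x_um = double(), volume_um3 = double())
    for (mc in mean_cols) out[[mc]] <- double()
    return(out)
  }
  lab <- as.integer(labels_3d[pos])
  n_vox <- tabulate(lab)
  ids <- which(n_vox > 0)
  coord <- arrayInd(pos, dim(labels_3d))
  cz <- unname(rowsum(coord[, 1] - 0.5, lab)[, 1]) / n_vox[ids] * spacing[1]
  cy <- unname(rowsum(coord[, 2] - 0.5, lab)[, 1]) / n_vox[ids] * spacing[2]
  cx <- unname(rowsum(coord[, 3] - 0.5, lab)[, 1]) / n_vox[ids] * spacing[3]
  out <- tibble::tibble(
    id = ids, z_um = cz, y_um = cy, x_um = cx,
    volume_um3 = n_vox[ids] * prod(spacing)
  )
  for (k in seq_along(stack$channels)) {
    ch <- stack$voxels[, , , k, drop = FALSE]
    dim(ch) <- dim(labels_3d)
    out[[mean_cols[k]]] <- unname(rowsum(as.double(ch[pos]), lab)[, 1]) / n_vox[ids]
  }
  out
}

#' Full 3D nuclear segmentation chain
#'
#' Runs the whole pipeline on the nuclear channel: adaptive equalisation
#' (10 um kernel), difference-of-Gaussians (sigmas 1/3, clipped at 0),
#' per-slice 2D labelling, IoU stitching into 3D (threshold 0.6), a minimum
#' 3D volume filter, and per-nucleus measurement.
#'
#' @inheritParams equalize_adaptive
#' @inheritParams label_2d
#' @inheritParams join_labels_3d
#' @param low_sigma,high_sigma DoG sigmas (voxel units).
#' @param min_volume_frac Minimum 3D object volume as a fraction of the
#'   nominal nucleus volume `(4/3) * pi * (d/2)^3`; smaller objects are
#'   discarded as debris.
#' @return A list of class `segmentation_result`: `labels` (3D array),
#'   `nuclei` (tibble from [extract_nuclei()]), `n_nuclei`.
#' @export
segment_stack <- function(stack, channel = "nuclear", kernel_um = 10,
                          low_sigma = 1, high_sigma = 3, iou_threshold = 0.6,
                          nucleus_diameter_um = 10, min_area_frac = 0.5,
                          min_volume_frac = 0.1, backend = "classical",
                          split_touching = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  eq <- equalize_adaptive(stack, kernel_um = kernel_um, channel = channel)
  band <- dog_filter(eq, low_sigma, high_sigma, channel = channel)
  vol <- get_channel(band, channel)
  thr <- if (identical(backend, "classical")) otsu_threshold(vol) else NULL
  nz <- dim(vol)[1]
  lab2d <- array(0L, dim(vol))
  for (z in seq_len(nz)) {
    lab2d[z, , ] <- tryCatch(
      label_2d(vol[z, , ], spacing_um = stack$voxel_size_um[2:3],
               nucleus_diameter_um = nucleus_diameter_um,
               min_area_frac = min_area_frac, backend = backend,
               smooth_sigma_px = 0, split_touching = split_touching,
               threshold = thr),
      error = function(e) stop(sprintf("slice %d: %s", z, conditionMessage(e)),
                               call. = FALSE)
    )
  }
  labels <- join_labels_3d(lab2d, iou_threshold = iou_threshold)
  min_vox <- min_volume_frac * (4 / 3) * pi * (nucleus_diameter_um / 2)^3 /
    prod(stack$voxel_size_um)
  labels <- filter_small_footprints(labels, min_vox)
  ids <- sort(unique(as.integer(labels)))
  ids <- ids[ids > 0]
  if (length(ids) && !identical(ids, seq_along(ids))) {
    remap <- integer(max(ids))
    remap[ids] <- seq_along(ids)
    pos <- labels > 0
    labels[pos] <- remap[labels[pos]]
  }
  nuclei <- extract_nuclei(labels, stack)
  structure(list(labels = labels, nuclei = nuclei, n_nuclei = nrow(nuclei)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d nuclei in a %s-voxel volume\n",
              x$n_nuclei, paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}
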