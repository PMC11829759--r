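#' Write and read image stacks as TIFF with a sidecar
#'
#' Stacks are written as a multi-page 32-bit float TIFF (channel-major, then
#' z) together with a JSON sidecar (`<path>.json`) recording the grid shape,
#' voxel size in um, channel names and the intensity scale. Reading requires
#' the sidecar: voxel size is never silently assumed.
#'
#' @param stack An [image_stack].
#' @param path Output TIFF path (sidecar written next to it).
#' @return `write_stack()` returns `path` invisibly; `load_stack()` returns
#'   an [image_stack].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  mx <- max(stack$voxels, 1e-12)
  slices <- vector("list", d[1] * d[4])
  k <- 1L
  for (ch in seq_len(d[4])) {
    for (z in seq_len(d[1])) {
      slices[[k]] <- stack$voxels[z, , , ch] / mx
      k <- k + 1L
    }
  }
  tiff::writeTIFF(slices, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  sidecar <- list(shape_voxels = d[1:3], voxel_size_um = stack$voxel_size_um,
                  channels = stack$channels, intensity_scale = mx,
                  axis_order = "channel,z,y,x")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
load_stack <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop(sprintf(
      "no voxel-size metadata: sidecar '%s' not found (voxel size is never assumed)",
      sidecar_path), call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  d <- as.integer(meta$shape_voxels)
  if (length(d) != 3L) {
    stop("sidecar must record a 3D shape (z, y, x); missing z extent",
         call. = FALSE)
  }
  nc <- length(meta$channels)
  if (length(slices) != d[1] * nc) {
    stop(sprintf("expected %d pages (%d channels x %d z-slices), found %d",
                 d[1] * nc, nc, d[1], length(slices)), call. = FALSE)
  }
  vox <- array(0, c(d, nc))
  k <- 1L
  for (ch in seq_len(nc)) {
    for (z in seq_len(d[1])) {
      vox[z, , , ch] <- slices[[k]] * meta$intensity_scale
      k <- k + 1L
    }
  }
  image_stack(vox, voxel_size_um = as.numeric(meta$voxel_size_um),
              channels = as.character(meta$channels))
}

#' Write and read 3D label volumes as TIFF
#'
#' Labels are stored as 16-bit pages with a JSON sidecar for shape and
#' spacing.
#'
#' @param labels 3D integer label array `(z, y, x)`.
#' @param path TIFF path.
#' @param voxel_size_um Spacing recorded in the sidecar.
#' @return `write_labels()` returns `path` invisibly; `load_labels()` a list
#'   with `labels` and `voxel_size_um`.
#' @export
write_labels <- function(labels, path, voxel_size_um) {
  stopifnot(length(dim(labels)) == 3L)
  mx <- max(labels, 1L)
  if (mx > 65535) stop("more than 65535 labels not supported", call. = FALSE)
  slices <- lapply(seq_len(dim(labels)[1]), function(z) labels[z, , ] / 65535)
  tiff::writeTIFF(slices, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(shape_voxels = dim(labels), voxel_size_um = voxel_size_um,
         kind = "labels"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_labels
#' @export
load_labels <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  d <- as.integer(meta$shape_voxels)
  labels <- array(0L, d)
  for (z in seq_len(d[1])) labels[z, , ] <- as.integer(round(slices[[z]] * 65535))
  list(labels = labels, voxel_size_um = as.numeric(meta$voxel_size_um))
}

#' Write and read rigid transforms as JSON
#'
#' @param tf A [rigid_transform].
#' @param path JSON path.
#' @return `write_transform()` returns `path` invisibly; `read_transform()`
#'   a [rigid_transform].
#' @export
write_transform <- function(tf, path) {
  stopifnot(inherits(tf, "rigid_transform"))
  jsonlite::write_json(
    list(rotation = unclass(tf$rotation), translation_um = tf$translation_um,
         scale = tf$scale),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(rotation = j$rotation, translation_um = j$translation_um,
                  scale = j$scale %||% 1)
}
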