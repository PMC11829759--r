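#' Multi-channel 3D image stack
#'
#' A light container for a voxel grid with physical spacing and named
#' channels. Voxels are stored as a 4D array with axis order `(z, y, x,
#' channel)`; a 3D array is accepted and treated as a single channel.
#' Physical positions use the voxel-centre convention: the centre of voxel
#' `i` (1-based) along an axis with spacing `s` lies at `(i - 0.5) * s` um.
#'
#' @param voxels Numeric array, 3D `(z, y, x)` or 4D `(z, y, x, channel)`,
#'   non-negative intensities.
#' @param voxel_size_um Positive numeric length-3, spacing in um for
#'   `(z, y, x)`.
#' @param channels Character vector of unique channel names, one per
#'   channel; defaults to `"ch1"`, `"ch2"`, ...
#' @return An object of class `image_stack`.
#' @examples
#' st <- image_stack(array(0, c(4, 8, 8)), voxel_size_um = c(1, 0.5, 0.5))
#' dim(get_channel(st, "ch1"))
#' @export
image_stack <- function(voxels, voxel_size_um, channels = NULL) {
  if (!is.array(voxels) || !(length(dim(voxels)) %in% c(3L, 4L))) {
    stop("`voxels` must be a 3D (z,y,x) or 4D (z,y,x,channel) array", call. = FALSE)
  }
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  nc <- dim(voxels)[4]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  if (length(channels) != nc) stop("`channels` must name every channel", call. = FALSE)
  if (anyDuplicated(channels)) stop("channel names must be unique", call. = FALSE)
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0)) {
    stop("`voxel_size_um` must be 3 positive reals (z, y, x)", call. = FALSE)
  }
  structure(
    list(voxels = voxels, voxel_size_um = voxel_size_um,
         channels = as.character(channels)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %d x %d x %d voxels (z,y,x), spacing %s um, channels: %s\n",
    d[1], d[2], d[3], paste(signif(x$voxel_size_um, 3), collapse = " x "),
    paste(x$channels, collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Extract or replace one channel of an image stack
#'
#' @param stack An [image_stack].
#' @param channel Channel name.
#' @param value 3D array replacing the channel's voxels.
#' @return `get_channel()` returns the channel's 3D `(z, y, x)` array;
#'   `set_channel()` returns the modified stack.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  i <- match(channel, stack$channels)
  if (is.na(i)) {
    stop(sprintf("unknown channel '%s' (have: %s)", channel,
                 paste(stack$channels, collapse = ", ")), call. = FALSE)
  }
  arr <- stack$voxels[, , , i, drop = FALSE]
  dim(arr) <- dim(stack$voxels)[1:3]
  arr
}

#' @rdname get_channel
#' @export
set_channel <- function(stack, channel, value) {
  stopifnot(inherits(stack, "image_stack"))
  i <- match(channel, stack$channels)
  if (is.na(i)) {
    i <- length(stack$channels) + 1L
    stack$channels <- c(stack$channels, channel)
    d <- dim(stack$voxels)
    new <- array(0, c(d[1:3], i))
    new[, , , seq_len(i - 1L)] <- stack$voxels
    stack$voxels <- new
  }
  stopifnot(identical(dim(value), dim(stack$voxels)[1:3]))
  stack$voxels[, , , i] <- value
  stack
}

# resolve (stack, channel) or bare 3D array into list(arr, spacing, stack?)
.resolve_volume <- function(stack, channel, voxel_size_um = NULL) {
  if (inherits(stack, "image_stack")) {
    list(arr = get_channel(stack, channel), spacing = stack$voxel_size_um,
         stack = stack)
  } else if (is.array(stack) && length(dim(stack)) == 3L) {
    if (is.null(voxel_size_um)) {
      stop("`voxel_size_um` is required when passing a bare array", call. = FALSE)
    }
    list(arr = stack, spacing = as.numeric(voxel_size_um), stack = NULL)
  } else {
    stop("expected an image_stack or a 3D array", call. = FALSE)
  }
}

# physical µm coordinates (z,y,x) of voxel centres for 1-based indices
.voxel_centers_um <- function(idx_zyx, spacing) {
  sweep(idx_zyx - 0.5, 2, spacing, `*`)
}
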