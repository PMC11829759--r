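#' Rigid (proper) 3D transform
#'
#' A rotation (orthonormal, determinant +1), translation in um, and an
#' optional isotropic scale (default 1, i.e. strictly rigid).
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation_um Numeric length-3 translation.
#' @param scale Positive isotropic scale.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation_um = c(0, 0, 0),
                            scale = 1) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("`rotation` must be orthonormal (R'R = I within 1e-8)", call. = FALSE)
  }
  if (det(rotation) < 0) {
    stop("`rotation` must be proper (det = +1), not a reflection", call. = FALSE)
  }
  stopifnot(length(translation_um) == 3L, scale > 0)
  structure(list(rotation = rotation,
                 translation_um = as.numeric(translation_um),
                 scale = scale),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%s) um, scale %g\n",
              ang, paste(signif(x$translation_um, 4), collapse = ", "), x$scale))
  invisible(x)
}

#' Apply, invert and compose rigid transforms
#'
#' `transform_points()` maps an `n x 3` matrix (or tibble with `x_um`,
#' `y_um`, `z_um`) through `p' = s * R p + t`. `invert_transform()` and
#' `compose_transforms()` obey `compose(invert(tf), tf) = identity`.
#'
#' @param tf,a,b [rigid_transform] objects.
#' @param points Point matrix or tibble.
#' @return Transformed points (same form as input), or a [rigid_transform].
#' @export
transform_points <- function(tf, points) {
  stopifnot(inherits(tf, "rigid_transform"))
  is_df <- is.data.frame(points)
  m <- if (is_df) as.matrix(points[, c("x_um", "y_um", "z_um")]) else as.matrix(points)
  stopifnot(ncol(m) == 3)
  out <- tf$scale * (m %*% t(tf$rotation))
  out <- sweep(out, 2, tf$translation_um, `+`)
  if (is_df) {
    points$x_um <- out[, 1]; points$y_um <- out[, 2]; points$z_um <- out[, 3]
    points
  } else out
}

#' @rdname transform_points
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  rinv <- t(tf$rotation)
  rigid_transform(rotation = rinv,
                  translation_um = -(rinv %*% tf$translation_um) / tf$scale,
                  scale = 1 / tf$scale)
}

#' @rdname transform_points
#' @export
compose_transforms <- function(a, b) {
  # applies b first, then a
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(rotation = a$rotation %*% b$rotation,
                  translation_um = a$scale * (a$rotation %*% b$translation_um) +
                    a$translation_um,
                  scale = a$scale * b$scale)
}

.as_points_matrix <- function(cloud) {
  if (is.data.frame(cloud)) as.matrix(cloud[, c("x_um", "y_um", "z_um")])
  else as.matrix(cloud)
}

# closed-form least-squares rigid alignment (Kabsch) of matched point sets
.kabsch <- function(moving, fixed, allow_scale = FALSE) {
  mc <- colMeans(moving); fc <- colMeans(fixed)
  a <- sweep(moving, 2, mc); b <- sweep(fixed, 2, fc)
  if (qr(a)$rank < 3) {
    stop("degenerate geometry: moving cloud has rank < 3 after centering",
         call. = FALSE)
  }
  h <- crossprod(a, b)
  sv <- svd(h)
  s <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  r <- sv$v %*% s %*% t(sv$u)
  sc <- if (allow_scale) sum(diag(t(b) %*% a %*% t(r))) / sum(a^2) else 1
  rigid_transform(rotation = r, translation_um = fc - sc * (r %*% mc), scale = sc)
}

#' Register two embryo point clouds
#'
#' Estimates the rigid transform mapping `moving` onto `fixed`. In
#' `landmark` mode the clouds are matched row-by-row and the least-squares
#' rigid alignment is solved in closed form (SVD). In `icp` mode
#' correspondences are unknown: the solver alternates nearest-neighbour
#' matching with the closed-form update until the mean residual changes by
#' less than `tol` or `max_iter` is reached (non-convergence is flagged, not
#' an error).
#'
#' @param moving,fixed Point matrices or tibbles (`x_um`, `y_um`, `z_um`);
#'   at least 4 non-degenerate points, matched rows in landmark mode.
#' @param mode `"landmark"` or `"icp"`.
#' @param allow_scale Also estimate an isotropic scale (default rigid).
#' @param max_iter,tol ICP iteration controls.
#' @return An object of class `registration_fit`: `transform`
#'   ([rigid_transform]), `residuals_um` (per-point distances after
#'   transformation), `rmse_um`, `converged`, `iterations`, `mode`.
#' @export
register_point_clouds <- function(moving, fixed, mode = c("landmark", "icp"),
                                  allow_scale = FALSE, max_iter = 50,
                                  tol = 1e-9) {
  mode <- match.arg(mode)
  mv <- .as_points_matrix(moving)
  fx <- .as_points_matrix(fixed)
  if (nrow(mv) < 4 || nrow(fx) < 4) {
    stop("registration needs at least 4 points per cloud", call. = FALSE)
  }
  if (mode == "landmark") {
    if (nrow(mv) != nrow(fx)) {
      stop("landmark mode requires matched correspondences (equal row counts)",
           call. = FALSE)
    }
    tf <- .kabsch(mv, fx, allow_scale)
    res <- sqrt(rowSums((transform_points(tf, mv) - fx)^2))
    fit <- list(transform = tf, residuals_um = res,
                rmse_um = sqrt(mean(res^2)), converged = TRUE,
                iterations = 0L, mode = mode)
  } else {
    tf <- rigid_transform()
    prev <- Inf
    converged <- FALSE
    it <- 0L
    res <- NULL
    while (it < max_iter) {
      it <- it + 1L
      cur <- transform_points(tf, mv)
      nn <- .nearest_neighbour(cur, fx)
      tf <- .kabsch(mv, fx[nn$index, , drop = FALSE], allow_scale)
      cur <- transform_points(tf, mv)
      res <- sqrt(rowSums((cur - fx[nn$index, , drop = FALSE])^2))
      m <- mean(res)
      if (abs(prev - m) < tol) { converged <- TRUE; break }
      prev <- m
    }
    fit <- list(transform = tf, residuals_um = res, rmse_um = sqrt(mean(res^2)),
                converged = converged, iterations = it, mode = mode)
  }
  structure(fit, class = "registration_fit")
}

# brute-force nearest neighbours of each row of `a` among rows of `b`
.nearest_neighbour <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  idx <- max.col(-d2, ties.method = "first")
  list(index = idx, dist_um = sqrt(pmax(0, d2[cbind(seq_len(nrow(a)), idx)])))
}

#' @export
print.registration_fit <- function(x, ...) {
  cat(sprintf("<registration_fit> mode %s, rmse %.4g um, %s\n", x$mode,
              x$rmse_um,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-point residuals of a registration fit
#'
#' @param x A `registration_fit`.
#' @param ... Unused.
#' @return A tibble with one row per moving point (`point`, `residual_um`).
#' @method tidy registration_fit
#' @export
tidy.registration_fit <- function(x, ...) {
  tibble::tibble(point = seq_along(x$residuals_um),
                 residual_um = x$residuals_um)
}

#' One-row summary of a registration fit
#'
#' @inheritParams tidy.registration_fit
#' @return A one-row tibble: `mode`, `rmse_um`, `rotation_deg`,
#'   `translation_um`, `scale`, `converged`, `iterations`.
#' @method glance registration_fit
#' @export
glance.registration_fit <- function(x, ...) {
  tf <- x$transform
  ang <- acos(pmin(1, pmax(-1, (sum(diag(tf$rotation)) - 1) / 2))) * 180 / pi
  tibble::tibble(mode = x$mode, rmse_um = x$rmse_um, rotation_deg = ang,
                 translation_um = sqrt(sum(tf$translation_um^2)),
                 scale = tf$scale, converged = x$converged,
                 iterations = x$iterations)
}

#' Average an attribute over local neighbourhoods across embryos
#'
#' For every reference point, averages `attribute` over all pooled points
#' strictly within `radius_um` (default 11 um, which in a perfect lattice
#' collects 14 nearest neighbours). A pooled point at exactly the reference
#' position (distance 0) is treated as the point itself and excluded when
#' `exclude_self` is set. Reference sites with no support are flagged with
#' `NA` rather than a value.
#'
#' @param reference Tibble/matrix of reference positions (`x_um`, `y_um`,
#'   `z_um`).
#' @param pooled Tibble of pooled (already registered) points with the
#'   attribute column.
#' @param attribute Name of the attribute column in `pooled`.
#' @param radius_um Neighbourhood radius in um.
#' @param exclude_self Drop distance-0 pooled points.
#' @return A tibble of class `neighborhood_map`: reference coordinates,
#'   `value` (mean attribute, `NA` if unsupported), `support` (point count),
#'   with the radius in attribute `radius_um`.
#' @export
average_neighborhood <- function(reference, pooled, attribute, radius_um = 11,
                                 exclude_self = TRUE) {
  stopifnot(radius_um > 0)
  if (!attribute %in% names(pooled)) {
    stop(sprintf("unknown attribute '%s' in pooled cloud", attribute),
         call. = FALSE)
  }
  ref <- .as_points_matrix(reference)
  pm <- .as_points_matrix(pooled)
  vals <- pooled[[attribute]]
  n <- nrow(ref)
  value <- rep(NA_real_, n)
  support <- integer(n)
  # chunked distance computation keeps memory flat for large clouds
  chunk <- max(1L, floor(2e6 / max(1L, nrow(pm))))
  for (s in seq(1L, n, by = chunk)) {
    rows <- s:min(n, s + chunk - 1L)
    d2 <- outer(rowSums(ref[rows, , drop = FALSE]^2), rowSums(pm^2), `+`) -
      2 * tcrossprod(ref[rows, , drop = FALSE], pm)
    d2[d2 < 0] <- 0
    within <- d2 < radius_um^2
    if (exclude_self) within[d2 < 1e-16] <- FALSE
    for (k in seq_along(rows)) {
      idx <- which(within[k, ] & !is.na(vals))
      support[rows[k]] <- length(idx)
      if (length(idx)) value[rows[k]] <- mean(vals[idx])
    }
  }
  out <- tibble::tibble(
    x_um = ref[, 1], y_um = ref[, 2], z_um = ref[, 3],
    value = value, support = support
  )
  attr(out, "radius_um") <- radius_um
  attr(out, "attribute") <- attribute
  class(out) <- c("neighborhood_map", class(out))
  out
}

#' Count nuclei inside an axis-aligned region of interest
#'
#' Counts table rows whose centroid lies in the box, inclusive on the low
#' edge and exclusive on the high edge. A zero-volume ROI returns 0 with a
#' warning.
#'
#' @param table Nucleus table with centroid columns `z_um`, `y_um`, `x_um`.
#' @param roi_um 2x3 matrix `rbind(lo, hi)` in um, axes `(z, y, x)`.
#' @return Integer count.
#' @export
count_nuclei_in_roi <- function(table, roi_um) {
  roi_um <- matrix(as.numeric(roi_um), 2, 3)
  if (any(roi_um[2, ] <= roi_um[1, ])) {
    warning("ROI has zero volume; returning 0")
    return(0L)
  }
  if (!nrow(table)) return(0L)
  pos <- as.matrix(table[, c("z_um", "y_um", "x_um")])
  inside <- pos[, 1] >= roi_um[1, 1] & pos[, 1] < roi_um[2, 1] &
    pos[, 2] >= roi_um[1, 2] & pos[, 2] < roi_um[2, 2] &
    pos[, 3] >= roi_um[1, 3] & pos[, 3] < roi_um[2, 3]
  sum(inside)
}

#' Voxel-wise overlap frequency of registered ablation ROIs
#'
#' Rasterises each registered ROI onto a common grid and counts, per voxel,
#' how many ROIs cover it — the ablation-precision heatmap across embryos.
#'
#' @param rois List of ROIs: each either a 2x3 box `rbind(lo, hi)` in um
#'   (axes z, y, x) or a logical/integer mask already on the target grid.
#' @param grid_spacing_um Grid spacing (scalar or length-3).
#' @param extent_um Length-3 grid extent in um; inferred from box ROIs when
#'   missing.
#' @return Integer 3D array of coverage counts (max value is the number of
#'   ROIs), with the spacing attached as attribute `grid_spacing_um`.
#' @export
roi_overlap_map <- function(rois, grid_spacing_um = 1, extent_um = NULL) {
  stopifnot(is.list(rois), length(rois) >= 1)
  sp <- rep(as.numeric(grid_spacing_um), length.out = 3)
  is_box <- vapply(rois, function(r) is.matrix(r) && all(dim(r) == c(2, 3)) &&
                     !is.logical(r), logical(1))
  masks <- vapply(rois, function(r) is.array(r) && (is.logical(r) || max(r) <= 1),
                  logical(1)) & !is_box
  if (is.null(extent_um)) {
    if (!all(is_box)) stop("`extent_um` is required when ROIs are masks",
                           call. = FALSE)
    extent_um <- apply(do.call(rbind, lapply(rois, function(r) r[2, ])), 2, max)
  }
  d <- pmax(1L, as.integer(ceiling(extent_um / sp)))
  freq <- array(0L, d)
  centers <- lapply(1:3, function(ax) (seq_len(d[ax]) - 0.5) * sp[ax])
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    if (is_box[i]) {
      inz <- centers[[1]] >= r[1, 1] & centers[[1]] < r[2, 1]
      iny <- centers[[2]] >= r[1, 2] & centers[[2]] < r[2, 2]
      inx <- centers[[3]] >= r[1, 3] & centers[[3]] < r[2, 3]
      cover <- outer(outer(inz, iny, `&`), inx, `&`)
    } else {
      stopifnot(identical(dim(r), dim(freq)))
      cover <- r > 0
    }
    freq <- freq + cover
  }
  storage.mode(freq) <- "integer"
  attr(freq, "grid_spacing_um") <- sp
  freq
}
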