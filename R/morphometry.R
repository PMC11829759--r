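#' Measured tissue polyline
#'
#' An ordered 2D polyline traced along a tissue in image coordinates, with
#' landmark indices marking somite boundaries (and the PSM start/end).
#'
#' @param points_um n x 2 matrix (or data frame) of ordered positions in um.
#' @param landmark_indices Strictly increasing indices into the points
#'   marking segment boundaries (default: the endpoints).
#' @param tissue One of `"spinal_cord"`, `"paraxial_mesoderm"`, `"other"`.
#' @return An object of class `measured_polyline`.
#' @export
measured_polyline <- function(points_um, landmark_indices = NULL,
                              tissue = c("other", "spinal_cord",
                                         "paraxial_mesoderm")) {
  tissue <- match.arg(tissue)
  pts <- as.matrix(points_um)
  if (nrow(pts) < 2 || ncol(pts) != 2) {
    stop("a polyline needs at least 2 points with 2 coordinates", call. = FALSE)
  }
  if (is.null(landmark_indices)) landmark_indices <- c(1L, nrow(pts))
  landmark_indices <- as.integer(landmark_indices)
  if (any(diff(landmark_indices) <= 0) || min(landmark_indices) < 1 ||
      max(landmark_indices) > nrow(pts)) {
    stop("landmark indices must be strictly increasing and within range",
         call. = FALSE)
  }
  structure(list(points_um = pts, landmark_indices = landmark_indices,
                 tissue = tissue),
            class = "measured_polyline")
}

#' @export
print.measured_polyline <- function(x, ...) {
  cat(sprintf("<measured_polyline> %s: %d points, %d landmark segments\n",
              x$tissue, nrow(x$points_um), length(x$landmark_indices) - 1L))
  invisible(x)
}

#' Polyline tissue lengths
#'
#' Total length is the sum of Euclidean chord lengths between consecutive
#' points; per-segment lengths are measured between consecutive landmark
#' indices, exactly as with a segmented-line measurement tool. Total length
#' always equals the sum of its landmark segments.
#'
#' @param polyline A [measured_polyline].
#' @param total_somites Optional somite count for the um/somite
#'   normalisation.
#' @return An object of class `tissue_lengths`: `total_um`,
#'   `per_segment_um`, `tissue`, plus `total_somites` and
#'   `relative_um_per_somite` when a somite count is given.
#' @export
polyline_length <- function(polyline, total_somites = NULL) {
  stopifnot(inherits(polyline, "measured_polyline"))
  pts <- polyline$points_um
  chords <- sqrt(rowSums(diff(pts)^2))
  li <- polyline$landmark_indices
  per_segment <- vapply(seq_len(length(li) - 1L), function(k) {
    sum(chords[li[k]:(li[k + 1] - 1L)])
  }, numeric(1))
  out <- list(total_um = sum(chords), per_segment_um = per_segment,
              tissue = polyline$tissue, total_somites = total_somites,
              relative_um_per_somite = if (!is.null(total_somites)) {
                relative_length(sum(chords), total_somites)
              } else NA_real_)
  structure(out, class = "tissue_lengths")
}

#' @export
print.tissue_lengths <- function(x, ...) {
  cat(sprintf("<tissue_lengths> %s: total %.2f um over %d segments",
              x$tissue, x$total_um, length(x$per_segment_um)))
  if (!is.null(x$total_somites)) {
    cat(sprintf(", %.2f um/somite", x$relative_um_per_somite))
  }
  cat("\n")
  invisible(x)
}

#' @rdname polyline_length
#' @param x A `tissue_lengths`.
#' @param ... Unused.
#' @method tidy tissue_lengths
#' @export
tidy.tissue_lengths <- function(x, ...) {
  tibble::tibble(tissue = x$tissue,
                 segment = seq_along(x$per_segment_um),
                 length_um = x$per_segment_um)
}

#' Length normalised by somite number
#'
#' Divides a tissue length by the total somite count to adjust for small
#' differences in developmental timing. The result has units of um/somite.
#'
#' @param total_um Tissue length in um.
#' @param total_somites Somite count (>= 1).
#' @return Length in um/somite.
#' @export
relative_length <- function(total_um, total_somites) {
  if (is.null(total_somites) || total_somites < 1) {
    stop("`total_somites` must be at least 1", call. = FALSE)
  }
  total_um / total_somites
}

#' Spinal cord to paraxial mesoderm length ratio
#'
#' Ratio of the two tissue lengths measured from the same anterior landmark
#' (the 22nd somite in the tail measurements); dimensionless.
#'
#' @param sc,pm `tissue_lengths` objects (or bare lengths in um).
#' @return `sc / pm`.
#' @export
tissue_ratio <- function(sc, pm) {
  sc_um <- if (inherits(sc, "tissue_lengths")) sc$total_um else as.numeric(sc)
  pm_um <- if (inherits(pm, "tissue_lengths")) pm$total_um else as.numeric(pm)
  if (!(pm_um > 0) || !(sc_um > 0)) {
    stop("tissue lengths must be positive", call. = FALSE)
  }
  sc_um / pm_um
}

#' Apoptotic fraction
#'
#' Percentage of nuclei positive for the apoptosis marker (activated
#' Caspase 3) relative to the nuclear count of the region.
#'
#' @param positive_count Marker-positive nuclei.
#' @param nuclei_count Total nuclei (>= 1, and >= `positive_count`).
#' @return Percentage in `[0, 100]`.
#' @export
apoptosis_fraction <- function(positive_count, nuclei_count) {
  if (nuclei_count < 1 || positive_count < 0 || positive_count > nuclei_count) {
    stop("need 0 <= positive_count <= nuclei_count and nuclei_count >= 1",
         call. = FALSE)
  }
  100 * positive_count / nuclei_count
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
.mw_exact <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  n <- length(pooled)
  r <- rank(pooled)
  combs <- utils::combn(n, na)
  # U statistic for each assignment of na pooled values to group a
  u_all <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

.p_tier <- function(p, tiers = c(0.05, 0.01, 0.001, 0.0001)) {
  labels <- c("*", "**", "***", "****")
  hit <- which(p <= tiers)
  if (!length(hit)) "ns" else labels[max(hit)]
}

#' Compare two groups with the Mann-Whitney-Wilcoxon test
#'
#' Two-sided rank-sum comparison as used for all condition contrasts. For a
#' combined sample size up to `exact_max_n` the p-value is exact, by full
#' enumeration of all group assignments of the pooled ranks (ties handled by
#' mid-ranks); above that, the normal approximation with tie correction and
#' continuity correction is used. Significance tiers follow the legend
#' convention: `*` P<=0.05, `**` P<=0.01, `***` P<=0.001, `****` P<=0.0001
#' (boundaries inclusive).
#'
#' @param a,b Numeric value vectors, each non-empty.
#' @param tiers Tier thresholds, largest first.
#' @param exact_max_n Combined size at or below which the exact enumeration
#'   is used.
#' @return A one-row tibble of class `group_comparison`: `u_statistic`,
#'   `p_value`, `tier`, `n_a`, `n_b`, `method`.
#' @export
compare_groups <- function(a, b, tiers = c(0.05, 0.01, 0.001, 0.0001),
                           exact_max_n = 20) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  if (n <= exact_max_n) {
    p <- .mw_exact(a, b)
    method <- "exact enumeration"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    )
    method <- "normal approximation"
  }
  out <- tibble::tibble(u_statistic = u, p_value = p,
                        tier = .p_tier(p, tiers),
                        n_a = length(a), n_b = length(b), method = method)
  class(out) <- c("group_comparison", class(out))
  out
}
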