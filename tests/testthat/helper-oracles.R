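# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# brute-force 26-connected 3D component labelling by iterative minimum-label
# propagation over all neighbour shifts
cc_label_3d <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- seq_len(sum(mask))
  shift <- function(arr, off) {
    out <- array(Inf, d)
    src <- lapply(1:3, function(ax) {
      i <- seq_len(d[ax])
      i[i + off[ax] >= 1 & i + off[ax] <= d[ax]]
    })
    dst <- lapply(1:3, function(ax) src[[ax]] + off[ax])
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
  }
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  work <- array(Inf, d)
  work[mask] <- lab[mask]
  repeat {
    new <- work
    for (r in seq_len(nrow(offs))) {
      sh <- shift(work, offs[r, ])
      new <- pmin(new, sh)
    }
    new[!mask] <- Inf
    if (identical(new, work)) break
    work <- new
  }
  out <- array(0L, d)
  out[mask] <- as.integer(match(work[mask], sort(unique(work[mask]))))
  out
}

# canonical component signature: sorted list of sorted voxel-index sets,
# used to compare two labelings up to relabelling
label_partition <- function(labels) {
  pos <- which(labels > 0)
  sets <- split(pos, labels[pos])
  unname(sets[order(vapply(sets, min, numeric(1)))])
}

# per-slice 2D labels from a ground-truth 3D label image (footprints keep
# their nucleus identity within a slice but ids are slice-local)
slice_labels_from_truth <- function(labels3d, min_area_px = 0) {
  nz <- dim(labels3d)[1]
  out <- array(0L, dim(labels3d))
  for (z in seq_len(nz)) {
    sl <- labels3d[z, , ]
    if (min_area_px > 0) sl <- filter_small_footprints(sl, min_area_px)
    ids <- sort(unique(as.integer(sl)))
    ids <- ids[ids > 0]
    if (length(ids)) out[z, , ] <- match(sl, ids, nomatch = 0L)
  }
  out
}

# exhaustive two-sided Mann-Whitney p-value by enumerating every assignment
# of the pooled observations to the two groups; U computed by direct pair
# counting (not via ranks) to stay independent of the implementation
mw_perm_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(ga, gb) sum(outer(ga, gb, `>`)) + 0.5 * sum(outer(ga, gb, `==`))
  combs <- utils::combn(length(pooled), na)
  u_all <- apply(combs, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  u_obs <- u_of(a, b)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# body-centred cubic lattice with conventional cell side `cell`, as a point
# tibble spanning `reps` cells per axis
bcc_lattice <- function(reps = 4, cell = 1) {
  corners <- expand.grid(x = 0:reps, y = 0:reps, z = 0:reps) * cell
  centers <- expand.grid(x = seq_len(reps) - 0.5, y = seq_len(reps) - 0.5,
                         z = seq_len(reps) - 0.5) * cell
  pts <- rbind(corners, centers)
  tibble::tibble(x_um = pts$x, y_um = pts$y, z_um = pts$z)
}

# small phantom used in several segmentation tests
small_phantom <- function(n_nuclei = 5, seed = 1, shape = c(48, 96, 96),
                          separation_factor = 1.3, noise_sd = 0) {
  generate_nuclear_stack(embryo_phantom_spec(
    shape_voxels = shape, n_nuclei = n_nuclei, noise_sd = noise_sd,
    separation_factor = separation_factor, seed = seed
  ))
}
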