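# phantom builders shared across test files

const_volume <- function(value = 1, dims = c(8, 8, 8), spacing = c(2, 2, 2)) {
  pet_volume(array(value, dims), spacing = spacing)
}

full_mask <- function(dims = c(8, 8, 8), spacing = c(2, 2, 2), role = "boost") {
  binary_mask(array(TRUE, dims), spacing = spacing, role = role)
}

box_mask <- function(dims, from, to, spacing = c(2, 2, 2), role = "HSV") {
  v <- array(FALSE, dims)
  v[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  binary_mask(v, spacing = spacing, role = role)
}

# sphere of given radius (voxels) centered in the grid
voxel_sphere <- function(dims, center, radius, spacing = c(2, 2, 2),
                         role = "HSV") {
  ax <- lapply(1:3, function(a) seq_len(dims[a]) - center[a])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  binary_mask(d2 <= radius^2, spacing = spacing, role = role)
}

# a nested pair: baseline of n_ref voxels plus a superset with extra voxels,
# filled in a fixed deterministic order so volumes are exact
nested_masks <- function(n_ref, n_new, dims = c(24, 24, 24)) {
  stopifnot(n_new >= n_ref, n_new <= prod(dims))
  ctr <- dims / 2
  ax <- lapply(1:3, function(a) seq_len(dims[a]) - ctr[a])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  ord <- order(as.vector(d2))
  ref <- array(FALSE, dims); ref[ord[seq_len(n_ref)]] <- TRUE
  new <- array(FALSE, dims); new[ord[seq_len(n_new)]] <- TRUE
  list(ref = binary_mask(ref), new = binary_mask(new))
}

# random small discretized grid for oracle comparisons
random_disc <- function(dims = c(5, 5, 5), n_levels = 3,
                        p_mask = 0.8) {
  lv <- array(sample.int(n_levels, prod(dims), replace = TRUE), dims)
  m <- array(runif(prod(dims)) < p_mask, dims)
  if (!any(m)) m[1] <- TRUE
  lv[!m] <- NA_integer_
  structure(list(levels = lv, n_levels = n_levels,
                 scheme = "fixed_bin_width", bin_width = 1),
            class = "discretized_volume")
}

# textured phantom: in-plane checkerboard (constant along z, so its energy
# sits in the mixed wavelet sub-bands) plus a smooth ramp
textured_volume <- function(dims = c(16, 16, 16), spacing = c(2, 2, 2)) {
  co <- arrayInd(seq_len(prod(dims)), dims)
  chk <- (co[, 1] + co[, 2]) %% 2
  ramp <- co[, 1] / dims[1]
  pet_volume(array(1 + 0.5 * chk + 0.3 * ramp, dims), spacing = spacing)
}

# gradient lesion: background 1.0, spherical lesion ramping linearly from
# SUV 1.0 at the rim to peak at the center
gradient_lesion <- function(dims = c(64, 64, 64), spacing = c(2, 2, 2),
                            radius_mm = 20, peak = 2.0) {
  ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - 1) - (dims[a] - 1) / 2) *
                 spacing[a])
  r <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`))
  v <- array(1, dims)
  inside <- r <= radius_mm
  v[inside] <- 1 + (peak - 1) * (1 - r[inside] / radius_mm)
  pet_volume(v, spacing = spacing)
}
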