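# Orthogonal wavelet filter banks (decomposition low-pass; the rest follow
# by quadrature-mirror relations). coif1 is the default basis: compactly
# supported, 6 taps.
wavelet_filters <- function(basis = c("coif1", "haar")) {
  basis <- match.arg(basis)
  h <- switch(basis,
    coif1 = c(-0.015655728135791993, -0.07273261951252645,
              0.38486484686485783, 0.85257202021160054,
              0.33789766245748185, -0.07273261951252645),
    haar  = c(1, 1) / sqrt(2))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # dec_hi from dec_lo
  list(h = h, g = g, length = L)
}

# Dense one-level periodized analysis matrix (N x N, orthogonal for
# orthogonal filters and even N >= filter length). Rows 1..N/2 are the
# low-pass (approximation) outputs, rows N/2+1..N the high-pass details.
dwt_matrix <- function(n, filt) {
  stopifnot(n %% 2 == 0, n >= filt$length)
  half <- n / 2
  W <- matrix(0, n, n)
  for (k in seq_len(half)) {
    idx <- ((2 * (k - 1) + seq_len(filt$length) - 1) %% n) + 1
    for (j in seq_along(idx)) {
      W[k, idx[j]] <- W[k, idx[j]] + filt$h[j]
      W[half + k, idx[j]] <- W[half + k, idx[j]] + filt$g[j]
    }
  }
  W
}

apply_axis <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  a <- matrix(a, nrow = d[axis])
  a <- M %*% a
  a <- array(a, dim = d[perm])
  aperm(a, order(perm))
}

#' Wavelet band-pass filter of a PET volume
#'
#' One-level 3D discrete wavelet decomposition (orthogonal basis, periodized
#' boundary on an edge-replicated even-sized grid) followed by
#' reconstruction with re-weighted sub-bands: the six band-pass sub-bands
#' (mixed low/high along the three axes) receive weight `bp_weight`, the
#' pure approximation (LLL) and pure detail (HHH) sub-bands receive weight
#' `other_weight` — a 1:2 band-pass-to-other ratio by default. The result is
#' normalized by `other_weight` so a constant volume is returned unchanged
#' (the DC component lives in LLL). Radiomic features are then computed on
#' the filtered values.
#'
#' @param volume a [pet_volume()].
#' @param mask [binary_mask()] whose bounding box must reach the filter
#'   support (checked); filtering itself is applied to the whole grid.
#' @param basis `"coif1"` (default) or `"haar"`.
#' @param bp_weight,other_weight sub-band weights (defaults 1 and 2).
#' @return A `filtered_volume` (same grid, possibly negative values).
#' @export
wavelet_bandpass <- function(volume, mask = NULL, basis = "coif1",
                             bp_weight = 1, other_weight = 2) {
  filt <- wavelet_filters(basis)
  v <- volume$values
  d0 <- dim(v)
  if (!is.null(mask)) {
    check_disc_inputs(volume, mask)
    bb <- apply(which(mask$values, arr.ind = TRUE), 2, range)
    if (any(bb[2, ] - bb[1, ] + 1L < filt$length))
      stop("mask bounding box smaller than the wavelet filter support (",
           filt$length, " voxels)")
  }
  # pad to even length >= filter length on each axis by edge replication
  target <- pmax(d0 + d0 %% 2, filt$length + filt$length %% 2)
  idx <- lapply(1:3, function(a) pmin(seq_len(target[a]), d0[a]))
  vp <- v[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  dim(vp) <- target
  Ws <- lapply(1:3, function(a) dwt_matrix(target[a], filt))
  cf <- vp
  for (a in 1:3) cf <- apply_axis(cf, Ws[[a]], a)
  # weight octants: low = first half of each axis, high = second half
  w <- array(bp_weight, dim = target)
  lo <- lapply(target, function(n) seq_len(n / 2))
  hi <- lapply(target, function(n) seq.int(n / 2 + 1, n))
  w[lo[[1]], lo[[2]], lo[[3]]] <- other_weight
  w[hi[[1]], hi[[2]], hi[[3]]] <- other_weight
  cf <- cf * w / other_weight
  for (a in 1:3) cf <- apply_axis(cf, t(Ws[[a]]), a)
  out <- cf[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
  dim(out) <- d0
  structure(list(values = out, spacing = volume$spacing,
                 origin = volume$origin, time_point = volume$time_point,
                 basis = basis), class = "filtered_volume")
}
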