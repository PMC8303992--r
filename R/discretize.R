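#' Fixed-bin-width discretization
#'
#' SUV values inside the mask are binned with a fixed bin width
#' (default W = 0.01 g/mL) anchored at the in-mask minimum:
#' \deqn{g = \lfloor (s - s_{min}) / W \rfloor + 1.}
#' The voxel at the maximum falls in the top bin, so `n_levels =
#' floor((max - min)/W) + 1`.
#'
#' @param volume a [pet_volume()] (or any object with a `values` array,
#'   e.g. the output of [wavelet_bandpass()]).
#' @param mask nonempty [binary_mask()] on the same grid.
#' @param bin_width bin width in SUV units; default 0.01.
#' @return A `discretized_volume`: `levels` (3D integer array, `NA` outside
#'   the mask), `n_levels`, `scheme = "fixed_bin_width"`, `bin_width`.
#' @export
discretize_fixed <- function(volume, mask, bin_width = 0.01) {
  if (bin_width <= 0) stop("'bin_width' must be positive")
  check_disc_inputs(volume, mask)
  s <- volume$values[mask$values]
  g <- as.integer(floor((s - min(s)) / bin_width)) + 1L
  lv <- array(NA_integer_, dim(volume$values))
  lv[mask$values] <- g
  structure(list(levels = lv, n_levels = max(g), scheme = "fixed_bin_width",
                 bin_width = bin_width), class = "discretized_volume")
}

#' Equal-probability quantization
#'
#' Histogram-equalizing discretization: level boundaries sit at empirical
#' quantiles of the in-mask values so each of `n_levels` bins holds as equal
#' a voxel count as ties permit (the behaviour of classical histogram
#' equalization on continuous data).
#'
#' @param volume as in [discretize_fixed()].
#' @param mask nonempty [binary_mask()].
#' @param n_levels number of gray levels, >= 2 (default 64).
#' @return A `discretized_volume` with `scheme = "equal_probability"`.
#' @export
discretize_equal_probability <- function(volume, mask, n_levels = 64L) {
  if (n_levels < 2L) stop("'n_levels' must be >= 2")
  check_disc_inputs(volume, mask)
  s <- volume$values[mask$values]
  br <- unique(quantile(s, probs = seq_len(n_levels - 1L) / n_levels,
                        names = FALSE, type = 7))
  g <- findInterval(s, br, left.open = TRUE) + 1L
  lv <- array(NA_integer_, dim(volume$values))
  lv[mask$values] <- g
  structure(list(levels = lv, n_levels = max(g), scheme = "equal_probability",
                 bin_width = NA_real_), class = "discretized_volume")
}

check_disc_inputs <- function(volume, mask) {
  if (!identical(dim(volume$values), dim(mask$values)))
    stop("volume and mask grids differ")
  if (!any(mask$values)) stop("mask is empty")
  invisible(TRUE)
}
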