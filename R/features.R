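# ---- texture feature formulas -------------------------------------------
# All operate on count matrices from build_matrices(). Features that are
# undefined on degenerate input (e.g. a single occupied gray level) return
# NA rather than a fabricated value, so the gap propagates into the
# delta-radiomics instead of a spurious 0.

glcm_features <- function(glcm) {
  tot <- sum(glcm)
  if (tot == 0)
    return(setNames(rep(NA_real_, 9), paste0("glcm_", GLCM_NAMES)))
  p <- glcm / tot
  G <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mu_x <- sum(seq_len(G) * px)
  var_x <- sum((seq_len(G) - mu_x)^2 * px)
  # symmetric matrix: marginals coincide
  corr <- if (var_x > 0)
    sum((i - mu_x) * (j - mu_x) * p) / var_x else NA_real_
  pos <- p > 0
  c(glcm_energy = sum(p^2),
    glcm_contrast = sum((i - j)^2 * p),
    glcm_correlation = corr,
    glcm_homogeneity = sum(p / (1 + abs(i - j))),
    glcm_entropy = -sum(p[pos] * log2(p[pos])),
    glcm_dissimilarity = sum(abs(i - j) * p),
    glcm_autocorrelation = sum(i * j * p),
    glcm_cluster_shade = sum((i + j - 2 * mu_x)^3 * p),
    glcm_cluster_prominence = sum((i + j - 2 * mu_x)^4 * p))
}

#' Correlation of the gray-level co-occurrence matrix
#'
#' \deqn{C_{CM} = \sum_{i,j} (i-\mu)(j-\mu) p(i,j) / \sigma^2}
#' with \eqn{p} the normalized symmetric GLCM and \eqn{\mu,\sigma} its
#' marginal mean and standard deviation. `NA` when only one gray level
#' occurs (zero marginal variance).
#'
#' @param glcm co-occurrence count matrix (as in [build_matrices()]).
#' @return scalar in `[-1, 1]`, or `NA`.
#' @export
glcm_correlation <- function(glcm) unname(glcm_features(glcm)["glcm_correlation"])

rlm_style_features <- function(m, n_voxels, prefix, names11) {
  nr <- sum(m)
  if (nr == 0)
    return(setNames(rep(NA_real_, 11), paste0(prefix, names11)))
  g <- row(m); l <- col(m)
  out <- c(
    sum(m / l^2) / nr,               # short run / small zone emphasis
    sum(m * l^2) / nr,               # long run / large zone emphasis
    sum(rowSums(m)^2) / nr,          # gray-level non-uniformity
    sum(colSums(m)^2) / nr,          # run-length / zone-size non-uniformity
    nr / n_voxels,                   # run / zone percentage
    sum(m / g^2) / nr,               # low gray-level emphasis
    sum(m * g^2) / nr,               # high gray-level emphasis
    sum(m / (g^2 * l^2)) / nr,
    sum(m * g^2 / l^2) / nr,
    sum(m * l^2 / g^2) / nr,
    sum(m * g^2 * l^2) / nr)
  setNames(out, paste0(prefix, names11))
}

GLCM_NAMES <- c("energy", "contrast", "correlation", "homogeneity",
                "entropy", "dissimilarity", "autocorrelation",
                "cluster_shade", "cluster_prominence")
GLRLM_NAMES <- c("sre", "lre", "gln", "rln", "rp",
                 "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge")
GLSZM_NAMES <- c("sze", "lze", "gln", "zsn", "zp",
                 "lgze", "hgze", "szlge", "szhge", "lzlge", "lzhge")
NGTDM_NAMES <- c("coarseness", "contrast", "busyness", "complexity",
                 "strength")

glrlm_features <- function(glrlm, n_voxels)
  rlm_style_features(glrlm, n_voxels, "glrlm_", GLRLM_NAMES)

glszm_features <- function(glszm, n_voxels)
  rlm_style_features(glszm, n_voxels, "glszm_", GLSZM_NAMES)

#' Low gray-level zone emphasis (LGZE)
#'
#' \deqn{LGZE = \frac{1}{N_z} \sum_g \sum_s n(g,s) / g^2}
#' where \eqn{n(g,s)} counts 26-connected zones of gray level \eqn{g} and
#' size \eqn{s} and \eqn{N_z} is the total zone count. LGZE emphasizes
#' regions of low tracer concentration: it is 1 when every zone sits at the
#' lowest level and decreases toward 0 as zones concentrate at high levels,
#' so it quantifies uptake heterogeneity through the abundance of
#' low-intensity zones.
#'
#' @param glszm size-zone count matrix (levels x sizes).
#' @return scalar in `(0, 1]`.
#' @export
lgze <- function(glszm) {
  if (sum(glszm) == 0) stop("empty size-zone matrix")
  unname(sum(glszm / row(glszm)^2) / sum(glszm))
}

ngtdm_features <- function(ngtdm) {
  nm <- paste0("ngtdm_", NGTDM_NAMES)
  N <- sum(ngtdm$n)
  if (N == 0) return(setNames(rep(NA_real_, 5), nm))
  pres <- which(ngtdm$n > 0)
  p <- ngtdm$n / N
  s <- ngtdm$s
  Ngl <- length(pres)
  ps <- sum(p * s)
  coarseness <- if (ps > 0) 1 / ps else NA_real_
  if (Ngl > 1) {
    ii <- rep(pres, times = Ngl); jj <- rep(pres, each = Ngl)
    pi_ <- p[ii]; pj <- p[jj]
    contrast <- sum(pi_ * pj * (ii - jj)^2) / (Ngl * (Ngl - 1)) * sum(s) / N
    denom_b <- sum(abs(ii * pi_ - jj * pj))
    busyness <- if (denom_b > 0) ps / denom_b else NA_real_
    complexity <- sum(abs(ii - jj) * (pi_ * s[ii] + pj * s[jj]) /
                        (pi_ + pj)) / N
    strength <- if (sum(s) > 0)
      sum((pi_ + pj) * (ii - jj)^2) / sum(s) else NA_real_
  } else {
    contrast <- NA_real_; busyness <- NA_real_
    complexity <- NA_real_; strength <- NA_real_
  }
  setNames(c(coarseness, contrast, busyness, complexity, strength), nm)
}

texture_block <- function(mats, prefix = "") {
  v <- c(glcm_features(mats$glcm),
         glrlm_features(mats$glrlm, mats$n_voxels),
         glszm_features(mats$glszm, mats$n_voxels),
         ngtdm_features(mats$ngtdm))
  setNames(v, paste0(prefix, names(v)))
}

# ---- first-order, histogram and shape blocks ----------------------------

firstorder_features <- function(suv) {
  n <- length(suv)
  m <- mean(suv)
  s <- if (n > 1) sd(suv) else NA_real_
  ctr <- suv - m
  c(fo_mean = m, fo_sd = s, fo_variance = s^2,
    fo_cv = if (!is.na(s) && m != 0) s / m else NA_real_,
    fo_skewness = if (!is.na(s) && s > 0)
      mean(ctr^3) / (mean(ctr^2))^1.5 else NA_real_,
    fo_kurtosis = if (!is.na(s) && s > 0)
      mean(ctr^4) / (mean(ctr^2))^2 else NA_real_,
    fo_min = min(suv), fo_max = max(suv), fo_range = max(suv) - min(suv),
    fo_median = median(suv), fo_energy = sum(suv^2),
    fo_rms = sqrt(mean(suv^2)))
}

histogram_features <- function(disc) {
  g <- disc$levels[!is.na(disc$levels)]
  p <- tabulate(g, nbins = disc$n_levels) / length(g)
  pos <- p > 0
  c(hist_entropy = -sum(p[pos] * log2(p[pos])),
    hist_uniformity = sum(p^2),
    hist_max_probability = max(p),
    hist_mode_level = which.max(p))
}

shape_features <- function(mask) {
  vals <- mask$values
  sp <- mask$spacing
  n <- sum(vals)
  vol_mm3 <- n * prod(sp)
  # exposed-face area, corrected by the mean staircase factor 3/2 (exact in
  # expectation for an isotropically oriented smooth surface)
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  d <- dim(vals)
  area <- 0
  for (ax in 1:3) {
    shift_lo <- shift_logical(vals, ax, 1L)
    shift_hi <- shift_logical(vals, ax, -1L)
    area <- area + (sum(vals & !shift_lo) + sum(vals & !shift_hi)) * face_area[ax]
  }
  area <- area / 1.5
  sph <- if (area > 0) pi^(1 / 3) * (6 * vol_mm3)^(2 / 3) / area else NA_real_
  comp <- if (area > 0) vol_mm3 / (sqrt(pi) * area^1.5) else NA_real_
  # max diameter over boundary voxels (interior voxels cannot be extremal)
  idx <- which(vals, arr.ind = TRUE)
  interior <- shift_logical(vals, 1, 1L) & shift_logical(vals, 1, -1L) &
    shift_logical(vals, 2, 1L) & shift_logical(vals, 2, -1L) &
    shift_logical(vals, 3, 1L) & shift_logical(vals, 3, -1L)
  bnd <- which(vals & !interior, arr.ind = TRUE)
  if (nrow(bnd) == 0L) bnd <- idx
  pts <- sweep(bnd, 2, sp, `*`)
  dia <- if (nrow(pts) > 1) max(dist(pts)) else 0
  c(shape_voxel_count = n, shape_volume_ml = vol_mm3 / 1000,
    shape_surface_mm2 = area, shape_sphericity = sph,
    shape_compactness = comp, shape_max_diameter_mm = dia)
}

# neighbor occupancy after shifting the mask by one voxel along an axis
# (out-of-grid treated as empty)
shift_logical <- function(vals, axis, by) {
  d <- dim(vals)
  out <- array(FALSE, d)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  if (by > 0) {
    dst[[axis]] <- seq.int(1L + by, d[axis])
    src[[axis]] <- seq.int(1L, d[axis] - by)
  } else {
    dst[[axis]] <- seq.int(1L, d[axis] + by)
    src[[axis]] <- seq.int(1L - by, d[axis])
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vals[src[[1]], src[[2]], src[[3]]]
  out
}

# ---- the frozen 130-feature list ----------------------------------------

#' Names of the 130 radiomic features
#'
#' The frozen feature list: 12 first-order statistics, 4 histogram features
#' (fixed-bin), 6 shape features, and 36 texture features (9 GLCM, 11
#' GLRLM, 11 GLSZM, 5 NGTDM) computed under three discretization/filter
#' variants — plain fixed-bin-width, wavelet band-pass filtered (`wf_`
#' prefix), and equal-probability quantized (`q_` prefix). 22 + 3 x 36 =
#' 130. `glszm_lgze` and `glcm_correlation` are always present.
#'
#' @return character vector of length 130, in stable order.
#' @export
radiomics_feature_names <- function() {
  tex <- c(paste0("glcm_", GLCM_NAMES), paste0("glrlm_", GLRLM_NAMES),
           paste0("glszm_", GLSZM_NAMES), paste0("ngtdm_", NGTDM_NAMES))
  c(paste0("fo_", c("mean", "sd", "variance", "cv", "skewness", "kurtosis",
                    "min", "max", "range", "median", "energy", "rms")),
    c("hist_entropy", "hist_uniformity", "hist_max_probability",
      "hist_mode_level"),
    paste0("shape_", c("voxel_count", "volume_ml", "surface_mm2",
                       "sphericity", "compactness", "max_diameter_mm")),
    tex, paste0("wf_", tex), paste0("q_", tex))
}

#' Default radiomics configuration
#'
#' @param bin_width fixed bin width in SUV (default 0.01).
#' @param q_levels levels for equal-probability quantization (default 64).
#' @param wavelet wavelet basis for the band-pass variant (default
#'   `"coif1"`).
#' @param bp_weight,other_weight wavelet sub-band weights (1:2 default).
#' @return named list of configuration values.
#' @export
radiomics_config <- function(bin_width = 0.01, q_levels = 64L,
                             wavelet = "coif1", bp_weight = 1,
                             other_weight = 2) {
  list(bin_width = bin_width, q_levels = q_levels, wavelet = wavelet,
       bp_weight = bp_weight, other_weight = other_weight)
}

#' Compute the 130-feature radiomic vector
#'
#' Features are computed on the raw SUV values inside the mask (first
#' order, histogram, shape) and on three discretized variants for the
#' texture families: fixed bin width W = 0.01 anchored at the in-mask
#' minimum; the wavelet band-pass filtered volume, fixed-bin discretized;
#' and equal-probability quantization. Features undefined on degenerate
#' regions are `NA`, never fabricated.
#'
#' @param volume a [pet_volume()].
#' @param mask nonempty [binary_mask()]; by convention the baseline HSV,
#'   transferred unchanged to later time-points.
#' @param config see [radiomics_config()].
#' @return A `feature_vector`: named numeric of length 130 with attributes
#'   `time_point` and `config`.
#' @export
feature_vector <- function(volume, mask, config = radiomics_config()) {
  check_disc_inputs(volume, mask)
  suv <- volume$values[mask$values]
  disc_fb <- discretize_fixed(volume, mask, config$bin_width)
  out <- c(firstorder_features(suv),
           histogram_features(disc_fb),
           shape_features(mask),
           texture_block(build_matrices(disc_fb)))
  wf <- wavelet_bandpass(volume, mask, basis = config$wavelet,
                         bp_weight = config$bp_weight,
                         other_weight = config$other_weight)
  disc_wf <- discretize_fixed(wf, mask, config$bin_width)
  out <- c(out, texture_block(build_matrices(disc_wf), prefix = "wf_"))
  disc_q <- discretize_equal_probability(volume, mask, config$q_levels)
  out <- c(out, texture_block(build_matrices(disc_q), prefix = "q_"))
  expected <- radiomics_feature_names()
  stopifnot(identical(names(out), expected))
  structure(out, time_point = volume$time_point, config = config,
            class = c("feature_vector", "numeric"))
}

#' Relative feature deviations (delta-radiomics)
#'
#' \deqn{\Delta RF = (RF_{Wk} - RF_{W0}) / |RF_{W0}|,} per feature; `NA`
#' when the baseline value is 0 or either value is missing.
#'
#' @param fv0 baseline [feature_vector()] (W0).
#' @param fvk follow-up feature vector on the transferred W0 mask.
#' @return A `delta_features` named numeric of length 130 with attribute
#'   `pair`.
#' @export
delta_features <- function(fv0, fvk) {
  stopifnot(identical(names(fv0), names(fvk)))
  v0 <- as.numeric(fv0); vk <- as.numeric(fvk)
  d <- ifelse(!is.na(v0) & !is.na(vk) & v0 != 0,
              (vk - v0) / abs(v0), NA_real_)
  structure(setNames(d, names(fv0)),
            pair = c(attr(fv0, "time_point") %||% "W0",
                     attr(fvk, "time_point") %||% "Wk"),
            class = c("delta_features", "numeric"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
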