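#' Estimate the background uptake level
#'
#' The hypoxia threshold is defined relative to a background (BG) region of
#' normoxic tissue: every boost voxel whose SUV reaches `tbr` times the BG
#' mean is called hypoxic. The BG statistic is the arithmetic mean over the
#' ROI by default (configurable to the median).
#'
#' @param volume a [pet_volume()].
#' @param roi a nonempty [binary_mask()] on the volume's grid.
#' @param statistic `"mean"` (default) or `"median"`.
#' @return An object of class `background_estimate` with fields `mean_suv`,
#'   `sd_suv`, `n_voxels`, `roi_role`, `statistic`.
#' @export
estimate_background <- function(volume, roi, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stop_if_grid_mismatch(roi, volume, "background ROI")
  vals <- volume$values[roi$values]
  if (length(vals) == 0L) stop("background ROI is empty")
  m <- if (statistic == "mean") mean(vals) else median(vals)
  if (m <= 0) stop("background mean is 0; TBR undefined")
  structure(list(mean_suv = m,
                 sd_suv = if (length(vals) > 1L) sd(vals) else 0,
                 n_voxels = length(vals), roi_role = roi$role,
                 statistic = statistic),
            class = "background_estimate")
}

#' Segment the hypoxic sub-volume by target-to-background ratio
#'
#' The hypoxic sub-volume (HSV) is the set of boost voxels whose SUV is at
#' least `tbr` times the background mean (threshold 1.4 by default). The
#' comparison is inclusive (`>=`). An empty HSV is a valid outcome (patients
#' without hypoxic volume), not an error. No post-processing is applied by
#' default; a minimum connected-component size can be requested.
#'
#' @param volume a [pet_volume()].
#' @param boost boost-volume [binary_mask()] delineating the tumor region.
#' @param bg a [estimate_background()] result (or a positive scalar SUV).
#' @param tbr target-to-background ratio threshold, > 1. Default 1.4.
#' @param inclusive include voxels exactly at the threshold (default TRUE).
#' @param min_component_voxels drop 26-connected HSV components smaller than
#'   this many voxels; 0 (default) disables filtering.
#' @return a [binary_mask()] with role `"HSV"`.
#' @export
segment_hsv <- function(volume, boost, bg, tbr = 1.4, inclusive = TRUE,
                        min_component_voxels = 0L) {
  if (tbr <= 1) stop("'tbr' must exceed 1")
  bg_mean <- if (inherits(bg, "background_estimate")) bg$mean_suv else as.numeric(bg)
  if (!is.finite(bg_mean) || bg_mean <= 0) stop("background mean must be > 0")
  stop_if_grid_mismatch(boost, volume, "boost mask")
  thr <- tbr * bg_mean
  hsv <- if (inclusive) volume$values >= thr else volume$values > thr
  hsv <- hsv & boost$values
  if (min_component_voxels > 0L && any(hsv)) {
    lab <- label_components_26(array(ifelse(hsv, 1L, NA_integer_), dim(hsv)))
    keep <- as.integer(names(which(table(lab$zone_id) >= min_component_voxels)))
    hsv[] <- FALSE
    hsv[lab$index[lab$zone_id %in% keep]] <- TRUE
  }
  binary_mask(hsv, spacing = volume$spacing, origin = volume$origin,
              role = "HSV")
}

#' Transfer a contour to a co-registered time-point
#'
#' Radiomic features are always computed inside the baseline HSV: the W0
#' segmentation is re-bound, voxel for voxel, to each later co-registered
#' scan. The voxel set is unchanged.
#'
#' @param mask_w0 the baseline [binary_mask()].
#' @param target the [pet_volume()] of the destination time-point.
#' @return a [binary_mask()] with identical voxel set on the target grid.
#' @export
transfer_contour <- function(mask_w0, target) {
  stop_if_grid_mismatch(mask_w0, target, "contour")
  binary_mask(mask_w0$values, spacing = target$spacing,
              origin = target$origin, role = mask_w0$role)
}

#' Build a cuboid background ROI automatically
#'
#' Optional helper for studies without a delineated background region:
#' takes an axis-aligned box in a corner of the grid, eroded away from the
#' faces, far from the boost volume. The recommended practice remains a
#' user-supplied ROI over normoxic tissue.
#'
#' @param volume a [pet_volume()].
#' @param boost boost mask to stay clear of.
#' @param margin_voxels distance from the grid faces (default 4).
#' @param size_voxels box edge length in voxels (default 8).
#' @return a [binary_mask()] with role `"background"`.
#' @export
auto_background_roi <- function(volume, boost, margin_voxels = 4L,
                                size_voxels = 8L) {
  d <- dim(volume$values)
  if (any(d < margin_voxels + size_voxels))
    stop("grid too small for the requested background box")
  roi <- array(FALSE, d)
  idx <- lapply(d, function(n) seq.int(margin_voxels + 1L,
                                       margin_voxels + size_voxels))
  roi[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  roi <- roi & !boost$values
  if (!any(roi)) stop("auto background box fully inside the boost volume")
  binary_mask(roi, spacing = volume$spacing, origin = volume$origin,
              role = "background")
}
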