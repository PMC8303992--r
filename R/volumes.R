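#' @importFrom stats sd median quantile rnorm runif rbinom rexp pnorm setNames
#'   p.adjust wilcox.test cor pchisq binomial glm.fit plogis qlogis qnorm dnorm
#'   uniroot as.formula dist
#' @importFrom utils read.csv write.csv
NULL

# geometry tolerance (mm) for declaring two grids "the same"; co-registration
# is upstream, the package only verifies alignment
GRID_TOL <- 1e-3

TIME_POINTS <- c("W0", "W2", "W5")

#' Construct a PET volume
#'
#' A `pet_volume` is a 3D grid of standardized-uptake values (SUV, g/mL)
#' with voxel geometry, the unit every pipeline stage consumes. Values must
#' be finite and non-negative; spacing strictly positive.
#'
#' @param values 3D numeric array of SUV (g/mL).
#' @param spacing numeric length-3, voxel edge lengths in mm per axis.
#' @param origin numeric length-3, world coordinate (mm) of voxel (1,1,1).
#' @param time_point one of `"W0"`, `"W2"`, `"W5"`.
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(values, spacing = c(2, 2, 2), origin = c(0, 0, 0),
                       time_point = "W0") {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3D array, got ", length(dim(values)), " dims")
  bad <- which(!is.finite(values))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(values))
    stop(sprintf("non-finite SUV at voxel (%d,%d,%d)%s",
                 idx[1], idx[2], idx[3],
                 if (length(bad) > 1L)
                   sprintf(" and %d more", length(bad) - 1L) else ""))
  }
  if (any(values < 0))
    stop("negative SUV values are not allowed")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive lengths (mm)")
  time_point <- match.arg(time_point, TIME_POINTS)
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin), time_point = time_point),
            class = "pet_volume")
}

#' Construct a binary mask
#'
#' A voxel-aligned region on the same grid as a [pet_volume()]: the boost
#' volume, a hypoxic sub-volume (HSV), or a background ROI. Masks are
#' inclusive voxel sets; no fractional membership.
#'
#' @param values 3D logical (or 0/1 numeric) array.
#' @param spacing,origin grid geometry, as in [pet_volume()].
#' @param role one of `"HSV"`, `"boost"`, `"background"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing = c(2, 2, 2), origin = c(0, 0, 0),
                        role = "HSV") {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (!is.logical(values)) {
    if (any(!is.finite(values))) stop("non-finite mask values")
    values <- array(values >= 0.5, dim = dim(values))
  }
  role <- match.arg(role, c("HSV", "boost", "background"))
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), role = role),
            class = "binary_mask")
}

#' Voxel volume in mL
#'
#' Product of the voxel edge lengths, converted from mm^3 to mL.
#' @param x a `pet_volume` or `binary_mask`.
#' @return scalar, mL per voxel.
#' @export
voxel_volume_ml <- function(x) prod(x$spacing) / 1000

#' Mask volume in mL
#' @param mask a `binary_mask`.
#' @return voxel count times voxel volume, mL.
#' @export
mask_volume_ml <- function(mask) sum(mask$values) * voxel_volume_ml(mask)

#' Do two objects share one grid?
#'
#' Shape must match exactly; spacing and origin within a 1e-3 mm tolerance
#' (registration is upstream, this only verifies alignment).
#' @param a,b `pet_volume` or `binary_mask` objects.
#' @return logical scalar.
#' @export
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) <= GRID_TOL) &&
    all(abs(a$origin - b$origin) <= GRID_TOL)
}

stop_if_grid_mismatch <- function(a, b, what = "mask") {
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("grid mismatch: %s shape (%s) vs reference (%s)", what,
                 paste(dim(a$values), collapse = "x"),
                 paste(dim(b$values), collapse = "x")))
  if (any(abs(a$spacing - b$spacing) > GRID_TOL))
    stop(sprintf("grid mismatch: %s spacing differs beyond %g mm", what, GRID_TOL))
  if (any(abs(a$origin - b$origin) > GRID_TOL))
    stop(sprintf("grid mismatch: %s origin differs beyond %g mm", what, GRID_TOL))
  invisible(TRUE)
}

#' Bundle one patient's longitudinal study
#'
#' @param patient_id character scalar.
#' @param volumes named list of `pet_volume` per time-point; `W0` mandatory.
#' @param boost_mask,background_mask `binary_mask` objects on the same grid.
#' @param outcome an [outcome_record()], or `NULL`.
#' @return An object of class `patient_study`.
#' @export
patient_study <- function(patient_id, volumes, boost_mask,
                          background_mask = NULL, outcome = NULL) {
  if (!"W0" %in% names(volumes)) stop("baseline volume 'W0' is mandatory")
  ref <- volumes$W0
  for (tp in names(volumes)) stop_if_grid_mismatch(volumes[[tp]], ref, tp)
  stop_if_grid_mismatch(boost_mask, ref, "boost mask")
  if (!is.null(background_mask))
    stop_if_grid_mismatch(background_mask, ref, "background mask")
  structure(list(patient_id = as.character(patient_id), volumes = volumes,
                 boost_mask = boost_mask, background_mask = background_mask,
                 outcome = outcome),
            class = "patient_study")
}

#' Read a PET volume from a NIfTI file
#'
#' The carrier is NIfTI-1 with SUV normalization already applied upstream;
#' the package never computes SUV from raw activity.
#'
#' @param path path to a `.nii`/`.nii.gz` file holding a 3D scalar image.
#' @param time_point time-point label to attach.
#' @return a [pet_volume()].
#' @export
read_volume <- function(path, time_point = "W0") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), dim = d[1:3])
    attr_pix <- RNifti::pixdim(img)[1:3]
    return(pet_volume(img2, spacing = attr_pix,
                      origin = nifti_origin(img), time_point = time_point))
  }
  if (length(d) != 3L)
    stop("expected a 3D single-channel image, got ", length(d), " dims")
  pet_volume(array(as.numeric(img), dim = d),
             spacing = RNifti::pixdim(img)[1:3],
             origin = nifti_origin(img), time_point = time_point)
}

nifti_origin <- function(img) {
  xf <- RNifti::xform(img)
  as.numeric(xf[1:3, 4])
}

#' Write a PET volume or mask to NIfTI
#' @param x a `pet_volume` or `binary_mask`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  vals <- if (is.logical(x$values))
    array(as.numeric(x$values), dim = dim(x$values)) else x$values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- x$spacing
  xf <- diag(4)
  diag(xf)[1:3] <- x$spacing
  xf[1:3, 4] <- x$origin
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI, verified against a reference grid
#'
#' Nonzero voxels (threshold 0.5) become `TRUE`; grid metadata is copied
#' from the reference after shape/spacing/origin verification. Values other
#' than 0/1 trigger a warning.
#'
#' @param path NIfTI file path.
#' @param reference the `pet_volume` whose grid the mask must match.
#' @param role mask role label.
#' @return a [binary_mask()].
#' @export
read_mask <- function(path, reference, role = "HSV") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("mask must be a 3D image")
  vals <- array(as.numeric(img), dim = d)
  probe <- structure(list(values = vals,
                          spacing = RNifti::pixdim(img)[1:3],
                          origin = nifti_origin(img)), class = "binary_mask")
  stop_if_grid_mismatch(probe, reference, "mask")
  if (any(!vals %in% c(0, 1)))
    warning("mask values other than {0,1}; thresholding at 0.5")
  binary_mask(vals, spacing = reference$spacing, origin = reference$origin,
              role = role)
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<pet_volume %s> %s voxels @ %s mm, SUV range [%.3f, %.3f]\n",
              x$time_point, paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %s> %d voxels (%.3f mL) on %s grid\n",
              x$role, sum(x$values), mask_volume_ml(x),
              paste(dim(x$values), collapse = "x")))
  invisible(x)
}
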