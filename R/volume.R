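#' Scalar volume on a regular 3D grid
#'
#' A `scalar_volume` is the basic image container of the package: a 3D array
#' of voxel values together with the physical grid geometry.  Voxel index
#' `(i, j, k)` (1-based) has its center at
#' `origin + (c(i, j, k) - 1) * spacing` in millimetres; all distances and
#' volumes are computed in physical units.  Units are one of `"SUV"`
#' (body-weight standardized uptake value, dimensionless), `"Bq_per_ml"`
#' (activity concentration) or `"binary"` (mask, values in \{0, 1\}).
#'
#' @param values Numeric 3D array of voxel values.
#' @param spacing_mm Positive numeric vector of length 3, voxel pitch in mm.
#' @param origin_mm Numeric vector of length 3, physical position (mm) of the
#'   center of voxel `(1, 1, 1)`.
#' @param units One of `"SUV"`, `"Bq_per_ml"`, `"binary"`.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                          units = c("SUV", "Bq_per_ml", "binary")) {
  units <- match.arg(units)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(dim(values) < 1L))
    stop("volume must have extent >= 1 along every axis", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive finite numbers", call. = FALSE)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be 3 finite numbers", call. = FALSE)
  storage.mode(values) <- "double"
  if (units == "binary" && !all(values %in% c(0, 1)))
    stop("binary volume must contain only 0 and 1", call. = FALSE)
  structure(
    list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm,
         units = units),
    class = "scalar_volume"
  )
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s, dim %s, spacing %s mm, origin %s mm\n",
              x$units, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              paste(signif(x$origin_mm, 4), collapse = ", ")))
  invisible(x)
}

#' Do two volumes share the same grid?
#'
#' Grids match when shapes are identical and spacing and origin agree within
#' `tol` millimetres.
#'
#' @param a,b `scalar_volume` objects.
#' @param tol Tolerance in mm.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing_mm - b$spacing_mm) <= tol) &&
    all(abs(a$origin_mm - b$origin_mm) <= tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not on the same grid (shape/spacing/origin differ)",
                 what), call. = FALSE)
  invisible(TRUE)
}

#' Physical coordinates of voxel centers
#'
#' @param vol A `scalar_volume`.
#' @param index Integer matrix (n x 3) of 1-based voxel indices; defaults to
#'   all voxels in array order.
#' @return Numeric n x 3 matrix of coordinates in mm.
#' @export
voxel_centers <- function(vol, index = NULL) {
  if (is.null(index))
    index <- arrayInd(seq_along(vol$values), dim(vol$values))
  index <- matrix(as.numeric(index), ncol = 3)
  sweep(sweep(index - 1, 2, vol$spacing_mm, "*"), 2, vol$origin_mm, "+")
}

#' Voxel volume in millilitres
#' @param vol A `scalar_volume`.
#' @return Scalar, ml per voxel.
#' @export
voxel_volume_ml <- function(vol) prod(vol$spacing_mm) / 1000

#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI-1 image.  The affine must be an axis-aligned scaling plus
#' translation (the default pipeline never produces oblique grids); oblique
#' affines are rejected with an explicit error rather than silently
#' reoriented.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param units Unit tag to attach (the file format does not carry one).
#' @return A `scalar_volume`.
#' @export
read_volume <- function(path, units = c("SUV", "Bq_per_ml", "binary")) {
  units <- match.arg(units)
  if (!file.exists(path))
    stop(sprintf("volume file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L)
    stop(sprintf("expected a 3D image, got %dD: %s", length(dm), path),
         call. = FALSE)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-6 * max(abs(diag(rot)))) || any(diag(rot) <= 0))
    stop(sprintf("oblique or flipped affine not supported: %s", path),
         call. = FALSE)
  vals <- array(as.numeric(img), dim = dm)
  scalar_volume(vals, spacing_mm = diag(rot), origin_mm = xf[1:3, 4],
                units = units)
}

#' Write a volume as NIfTI-1
#'
#' The affine encodes spacing and origin (qform and sform, code 2).  SUV and
#' activity images are stored as 32-bit float, masks as 8-bit unsigned
#' integers.
#'
#' @param vol A `scalar_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "scalar_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing_mm
  aff <- rbind(cbind(diag(vol$spacing_mm), vol$origin_mm), c(0, 0, 0, 1))
  aff <- structure(aff, code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  dtype <- if (vol$units == "binary") "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Convert activity concentration to body-weight SUV
#'
#' SUV = activity concentration (kBq/ml) x body weight (g) / injected dose
#' (kBq), i.e. `value_Bq_per_ml * weight_kg * 1000 / (dose_MBq * 1e6)`.
#' Decay correction is assumed to have been applied upstream by the scanner.
#'
#' @param activity `scalar_volume` in `Bq_per_ml`.
#' @param weight_kg Body weight in kg (> 0).
#' @param injected_dose_MBq Injected activity in MBq (> 0).
#' @return `scalar_volume` in SUV units.
#' @export
to_suv <- function(activity, weight_kg, injected_dose_MBq) {
  stopifnot(inherits(activity, "scalar_volume"))
  if (activity$units != "Bq_per_ml")
    stop("`activity` must be in Bq_per_ml units", call. = FALSE)
  if (!is.finite(weight_kg) || weight_kg <= 0)
    stop("`weight_kg` must be > 0", call. = FALSE)
  if (!is.finite(injected_dose_MBq) || injected_dose_MBq <= 0)
    stop("`injected_dose_MBq` must be > 0", call. = FALSE)
  scalar_volume(activity$values * (weight_kg * 1000) /
                  (injected_dose_MBq * 1e6),
                activity$spacing_mm, activity$origin_mm, units = "SUV")
}

#' Rigid spatial transform
#'
#' Maps source-space physical coordinates to target space:
#' `x_target = rotation %*% x_source + translation_mm`.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, determinant +1).
#' @param translation_mm Numeric length-3 translation in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation_mm = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation_mm <- as.numeric(translation_mm)
  stopifnot(length(translation_mm) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("`rotation` must be orthonormal with determinant +1", call. = FALSE)
  structure(list(rotation = rotation, translation_mm = translation_mm),
            class = "rigid_transform")
}

#' Resample a binary mask onto a target grid
#'
#' Nearest-neighbor resampling: each target voxel center is mapped back
#' through the inverse of `transform` into source space and takes the value
#' of the nearest source voxel (0 outside the source grid).  Output is
#' binary on the target grid.  With the identity transform on identical
#' grids the mask is returned unchanged, so the operation is idempotent.
#'
#' @param mask Binary `scalar_volume` (source).
#' @param target `scalar_volume` defining the output grid.
#' @param transform A `rigid_transform` mapping source to target space
#'   (default identity).
#' @return Binary `scalar_volume` on the target grid.
#' @export
resample_mask <- function(mask, target, transform = rigid_transform()) {
  stopifnot(inherits(mask, "scalar_volume"), inherits(target, "scalar_volume"))
  if (mask$units != "binary" || !all(mask$values %in% c(0, 1)))
    stop("`mask` must be a binary volume", call. = FALSE)
  identity_tf <- max(abs(transform$rotation - diag(3))) == 0 &&
    all(transform$translation_mm == 0)
  if (identity_tf && same_grid(mask, target)) return(mask)
  dm_t <- dim(target$values)
  pts <- voxel_centers(target)                     # target voxel centers (mm)
  # invert: x_source = R^T (x_target - t)
  pts <- sweep(pts, 2, transform$translation_mm, "-") %*% transform$rotation
  idx <- round(sweep(sweep(pts, 2, mask$origin_mm, "-"), 2,
                     mask$spacing_mm, "/")) + 1
  dm_s <- dim(mask$values)
  inside <- idx[, 1] >= 1 & idx[, 1] <= dm_s[1] &
    idx[, 2] >= 1 & idx[, 2] <= dm_s[2] &
    idx[, 3] >= 1 & idx[, 3] <= dm_s[3]
  out <- numeric(prod(dm_t))
  lin <- (idx[inside, 3] - 1) * dm_s[1] * dm_s[2] +
    (idx[inside, 2] - 1) * dm_s[1] + idx[inside, 1]
  out[inside] <- mask$values[lin]
  scalar_volume(array(out, dm_t), target$spacing_mm, target$origin_mm,
                units = "binary")
}
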