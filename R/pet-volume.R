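#' PET volume in SUV units
#'
#' Container for a 3D PET image whose voxel values are standardized uptake
#' values (SUV, body-weight normalized, dimensionless). The grid lives in a
#' physical coordinate system in millimetres: the origin is the corner of
#' voxel (1,1,1), so the centre of voxel `(i,j,k)` sits at
#' `origin + (c(i,j,k) - 0.5) * spacing`. Axis order is x, y, z and matches
#' the array dimensions.
#'
#' @param voxels Numeric 3D array of SUV values; all finite and `>= 0`.
#' @param spacing Numeric length-3 vector of voxel edge lengths in mm, all
#'   `> 0`.
#' @param origin Physical coordinate (mm) of the corner of the first voxel.
#'   Default `c(0, 0, 0)`.
#'
#' @return An object of class `pet_volume`: the voxel array with `spacing`
#'   and `origin` attributes.
#' @examples
#' vol <- pet_volume(array(1, dim = c(4, 4, 4)), spacing = c(2, 2, 2))
#' voxel_volume_ml(vol)
#' @export
pet_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3D array.", class = "mtvsurv_invalid_argument")
  }
  storage.mode(voxels) <- "double"
  if (anyNA(voxels) || any(!is.finite(voxels))) {
    abort("All SUV values must be finite.", class = "mtvsurv_invalid_argument")
  }
  if (any(voxels < 0)) {
    abort("SUV values must be >= 0.", class = "mtvsurv_invalid_argument")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive voxel edge lengths (mm).",
      class = "mtvsurv_invalid_argument")
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin))) {
    abort("`origin` must be a finite length-3 coordinate (mm).",
      class = "mtvsurv_invalid_argument")
  }
  structure(voxels, spacing = spacing, origin = origin, class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x)
  sp <- attr(x, "spacing")
  cat(sprintf("<pet_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  cat(sprintf("  SUV range [%.3g, %.3g]; voxel volume %.4g ml\n",
    min(x), max(x), voxel_volume_ml(x)))
  invisible(x)
}

#' Volume of a single voxel in millilitres
#'
#' @param volume A [pet_volume()].
#' @return Voxel volume in ml (`prod(spacing) / 1000`).
#' @export
voxel_volume_ml <- function(volume) {
  stopifnot(inherits(volume, "pet_volume"))
  prod(attr(volume, "spacing")) / 1000
}

#' Body-weight standardized uptake value
#'
#' SUV normalizes a tissue activity concentration by the injected activity
#' per unit body weight, taking tissue density as 1 g/ml, so the result is
#' dimensionless:
#' `SUV = conc (kBq/ml) / (injected (MBq) * 1000 / (weight (kg) * 1000))
#'      = conc * weight / injected`.
#' Inputs are assumed decay-corrected, as scanner software reports them.
#'
#' @param activity_conc Tissue activity concentration, kBq/ml. Vectorized.
#' @param injected_activity Injected activity, MBq (`> 0`).
#' @param body_weight Body weight, kg (`> 0`).
#' @return SUV values, same length as `activity_conc`.
#' @examples
#' suv_from_activity(8, injected_activity = 140, body_weight = 70) # 4
#' @export
suv_from_activity <- function(activity_conc, injected_activity, body_weight) {
  if (any(!is.finite(activity_conc)) || any(activity_conc < 0)) {
    abort("`activity_conc` must be finite and >= 0.",
      class = "mtvsurv_invalid_argument")
  }
  for (nm in c("injected_activity", "body_weight")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive number.", nm),
        class = "mtvsurv_invalid_argument")
    }
  }
  activity_conc * body_weight / injected_activity
}

#' Read and write PET volumes as NIfTI-1
#'
#' `read_pet_nifti()` loads a `.nii`/`.nii.gz` image, taking the voxel
#' spacing from the header (`pixdim`). `write_pet_nifti()` writes a
#' [pet_volume()]; `write_mask_nifti()` writes a logical voxel mask as uint8
#' on the grid of a reference volume.
#'
#' @param path File path.
#' @param volume A [pet_volume()] (for writing) or reference volume whose
#'   grid a mask shares.
#' @param mask Logical array, same dimensions as `volume`.
#' @return `read_pet_nifti()` returns a [pet_volume()]; the writers return
#'   the path invisibly.
#' @export
read_pet_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  sp <- RNifti::pixdim(img)[1:3]
  arr[arr < 0] <- 0 # clip reconstruction negatives
  pet_volume(arr, spacing = sp)
}

#' @rdname read_pet_nifti
#' @export
write_pet_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  img <- RNifti::asNifti(unclass(volume) + 0)
  RNifti::pixdim(img) <- attr(volume, "spacing")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_pet_nifti
#' @export
write_mask_nifti <- function(mask, volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  if (!identical(dim(mask), dim(volume))) {
    abort("Mask and volume grids differ.", class = "mtvsurv_shape_error")
  }
  arr <- array(as.integer(mask), dim = dim(mask))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- attr(volume, "spacing")
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

# Physical coordinates (mm) of all voxel centres, as an n-by-3 matrix in
# array order. Internal.
voxel_centers <- function(volume) {
  d <- dim(volume)
  sp <- attr(volume, "spacing")
  or <- attr(volume, "origin")
  list(
    x = or[1] + (seq_len(d[1]) - 0.5) * sp[1],
    y = or[2] + (seq_len(d[2]) - 0.5) * sp[2],
    z = or[3] + (seq_len(d[3]) - 0.5) * sp[3]
  )
}
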