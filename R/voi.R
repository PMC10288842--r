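#' Spherical reference volume of interest
#'
#' Fixed-volume spheres placed in reference tissues (left liver lobe,
#' fifth lumbar vertebra, spleen) to read off background SUV statistics.
#' The radius follows from the nominal volume:
#' `radius_mm = (3 * volume_ml * 1000 / (4 * pi))^(1/3)`.
#'
#' @param center Physical coordinate of the sphere centre, mm (length 3).
#' @param volume_ml Nominal VOI volume in ml (`> 0`); clinical practice uses
#'   5 ml in liver and spleen, 3 ml in bone.
#' @param label Reference tissue tag: one of `"liver"`, `"bone"`,
#'   `"spleen"`, `"other"`.
#' @return An object of class `sphere_voi` with a derived `radius_mm`.
#' @examples
#' sphere_voi(c(40, 64, 64), volume_ml = 5, label = "liver")
#' @export
sphere_voi <- function(center, volume_ml, label = c("liver", "bone", "spleen", "other")) {
  label <- match.arg(label)
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center))) {
    abort("`center` must be a finite length-3 coordinate (mm).",
      class = "mtvsurv_invalid_argument")
  }
  if (length(volume_ml) != 1L || !is.finite(volume_ml) || volume_ml <= 0) {
    abort("`volume_ml` must be a single positive volume.",
      class = "mtvsurv_invalid_argument")
  }
  structure(
    list(
      center = center,
      volume_ml = volume_ml,
      radius_mm = (3 * volume_ml * 1000 / (4 * pi))^(1 / 3),
      label = label
    ),
    class = "sphere_voi"
  )
}

#' @export
print.sphere_voi <- function(x, ...) {
  cat(sprintf("<sphere_voi> %s, %.3g ml (radius %.3f mm) at (%.1f, %.1f, %.1f) mm\n",
    x$label, x$volume_ml, x$radius_mm, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Rasterize a spherical VOI on a volume grid
#'
#' Selects exactly the voxels whose centre lies within the sphere radius of
#' the VOI centre (voxel-centre membership, no partial-volume weighting).
#'
#' @param volume A [pet_volume()].
#' @param voi A [sphere_voi()].
#' @return Logical array of the volume's dimensions, `TRUE` inside the VOI.
#' @seealso [reference_stats()]
#' @export
voi_mask <- function(volume, voi) {
  stopifnot(inherits(volume, "pet_volume"), inherits(voi, "sphere_voi"))
  ctr <- voxel_centers(volume)
  dx2 <- (ctr$x - voi$center[1])^2
  dy2 <- (ctr$y - voi$center[2])^2
  dz2 <- (ctr$z - voi$center[3])^2
  r2 <- voi$radius_mm^2
  mask <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r2
  if (!any(mask)) {
    abort("VOI sphere contains no voxel centre on this grid.",
      class = "mtvsurv_empty_voi")
  }
  mask
}

#' Reference-tissue SUV statistics inside a spherical VOI
#'
#' Mean, maximum and sample standard deviation (n - 1 denominator, the
#' workstation convention adopted here) of the SUV values whose voxel
#' centres fall inside the VOI. The liver statistics feed the MTV
#' segmentation threshold (see [segmentation_threshold()]).
#'
#' @inheritParams voi_mask
#' @param sd_type `"sample"` (default, n - 1) or `"population"` (n).
#' @return One-row tibble with `label`, `suv_mean`, `suv_max`, `suv_sd`,
#'   `n_voxels`, `sd_type`.
#' @examples
#' vol <- pet_volume(array(4.41, dim = c(20, 20, 20)), spacing = c(2, 2, 2))
#' reference_stats(vol, sphere_voi(c(20, 20, 20), 5, "liver"))
#' @export
reference_stats <- function(volume, voi, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  mask <- voi_mask(volume, voi)
  vals <- volume[mask]
  n <- length(vals)
  s <- if (n < 2L) 0 else sd(vals)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  tibble(
    label = voi$label,
    suv_mean = mean(vals),
    suv_max = max(vals),
    suv_sd = s,
    n_voxels = n,
    sd_type = sd_type
  )
}
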