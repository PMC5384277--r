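# Voxel stand-in for CBCT segmentation.
#
# The phantom is rasterized into a 3D Hounsfield-unit volume (air -1000 HU
# inside the lumen, soft tissue +40 HU outside) and segmented with the same
# two-sided HU threshold used on clinical scans.

#' Rasterize a phantom into a Hounsfield-unit voxel volume
#'
#' @param phantom an `airway_phantom`
#' @param voxel_mm cubic voxel edge length, mm
#' @param air_hu,tissue_hu HU values assigned inside/outside the lumen
#' @param margin_mm lateral padding of tissue around the widest slice, mm
#' @return a `voxel_volume`: 3D array `hu` (x, y, z), voxel size, origin
#' @export
voxelize_phantom <- function(phantom, voxel_mm = 0.4, air_hu = -1000,
                             tissue_hu = 40, margin_mm = 3) {
  stopifnot(inherits(phantom, "airway_phantom"), voxel_mm > 0)
  rmax <- max(phantom$radius)
  half <- rmax + margin_mm
  nxy <- max(3L, as.integer(ceiling(2 * half / voxel_mm)))
  nz <- max(1L, as.integer(ceiling(phantom$length / voxel_mm)))
  # voxel-center coordinates, origin at the axis
  xc <- (seq_len(nxy) - 0.5) * voxel_mm - half
  zc <- (seq_len(nz) - 0.5) * voxel_mm
  r2 <- outer(xc^2, xc^2, "+")
  hu <- array(tissue_hu, dim = c(nxy, nxy, nz))
  Rz <- phantom$radius_fun(pmin(zc, phantom$length))
  for (k in seq_len(nz)) {
    hu[, , k][r2 <= Rz[k]^2] <- air_hu
  }
  structure(list(hu = hu, voxel_mm = voxel_mm,
                 origin = c(-half, -half, 0)),
            class = "voxel_volume")
}

#' Segment a voxel volume by Hounsfield-unit thresholding
#'
#' Voxels with `lo_hu <= HU <= hi_hu` form the airway mask; the default
#' window (-1024, -480) selects air against soft tissue.
#'
#' @param vol a `voxel_volume` from [voxelize_phantom()]
#' @param lo_hu,hi_hu threshold window, HU (lo < hi)
#' @return list with `mask` (logical 3D array) and `volume_cm3`
#' @export
segment_hu <- function(vol, lo_hu = -1024, hi_hu = -480) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (lo_hu >= hi_hu) stop("segment_hu: need lo_hu < hi_hu")
  mask <- vol$hu >= lo_hu & vol$hu <= hi_hu
  n <- sum(mask)
  if (n == 0) {
    warning("segment_hu: no voxels inside the threshold window; ",
            "segmented volume is zero")
  }
  list(mask = mask, volume_cm3 = mm3_to_cm3(n * vol$voxel_mm^3))
}

#' Voxelize and segment in one step
#'
#' @inheritParams voxelize_phantom
#' @inheritParams segment_hu
#' @param phantom an `airway_phantom`
#' @return list with `mask` and `volume_cm3`
#' @export
voxelize_and_segment <- function(phantom, voxel_mm = 0.4,
                                 lo_hu = -1024, hi_hu = -480) {
  segment_hu(voxelize_phantom(phantom, voxel_mm), lo_hu, hi_hu)
}
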