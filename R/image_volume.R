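#' Construct an image volume
#'
#' A minimal container for a 3D scalar grid with physical voxel spacing, the
#' working stand-in for a micro-CT scan. The voxel array is stored in R's
#' native layout, `voxels[ix, iy, iz]` with `ix` varying fastest; equivalently
#' the slowest-to-fastest storage order is z, y, x. Indices are 0-based in the
#' world-coordinate convention: the centre of voxel `(i, j, k)` (0-based) sits
#' at `origin + c(i, j, k) * spacing` millimetres.
#'
#' @param voxels 3D numeric (or logical) array of voxel values.
#' @param spacing numeric length-3, mm per voxel along (x, y, z); all > 0.
#' @param origin numeric length-3, world position (mm) of the centre of voxel
#'   (0, 0, 0). Default `c(0, 0, 0)`.
#' @return An object of class `image_volume`.
#' @examples
#' v <- image_volume(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5))
#' dim(v$voxels)
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must be length 3 (mm)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

#' World coordinates of voxel centres
#'
#' @param vol an `image_volume`.
#' @param idx integer matrix (n x 3) of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Axis coordinate vectors (mm) of voxel centres along each axis
#' @param vol an `image_volume`
#' @return list with elements x, y, z
#' @export
voxel_axes <- function(vol) {
  d <- dim(vol$voxels)
  list(x = vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1],
       y = vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2],
       z = vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3])
}

#' Write / read a volume as NIfTI with a JSON sidecar
#'
#' The voxel array goes to a `.nii` file (via RNifti, which stores the spacing
#' in the header as well); spacing and origin are additionally echoed to a
#' human-readable JSON sidecar so downstream tools need no NIfTI reader.
#'
#' @param vol an `image_volume`.
#' @param path output path ending in `.nii`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$voxels, pixdim = vol$spacing)
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(spacing_mm = vol$spacing, origin_mm = vol$origin,
                            dim = dim(vol$voxels)),
                       sidecar, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    image_volume(array(as.numeric(img), dim = dim(img)),
                 spacing = meta$spacing_mm, origin = meta$origin_mm)
  } else {
    image_volume(array(as.numeric(img), dim = dim(img)),
                 spacing = RNifti::pixdim(img))
  }
}
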