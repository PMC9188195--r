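#' 2D intensity plane with physical pixel size
#'
#' Lightweight container for a single-channel section image: an intensity
#' matrix plus the pixel size in micrometres per pixel.
#'
#' @param data numeric matrix of intensities.
#' @param pixel_size pixel edge length, um/px (> 0).
#' @return an object of class `plane2d`.
#' @export
plane2d <- function(data, pixel_size) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric matrix")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    abort("`pixel_size` must be a single positive number (um/px)")
  }
  structure(list(data = data, pixel_size = pixel_size), class = "plane2d")
}

#' @export
print.plane2d <- function(x, ...) {
  cat(sprintf("<plane2d> %d x %d px @ %g um/px, range [%g, %g]\n",
              nrow(x$data), ncol(x$data), x$pixel_size,
              min(x$data), max(x$data)))
  invisible(x)
}

#' 3D intensity volume with per-axis voxel size
#'
#' @param data numeric 3D array.
#' @param voxel_size voxel edge lengths in um, length 1 (isotropic) or 3.
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(data, voxel_size) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3D array")
  }
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    abort("`voxel_size` must be positive (um)")
  }
  structure(list(data = data, voxel_size = voxel_size), class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels @ [%s] um\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$voxel_size, 4), collapse = ", ")))
  invisible(x)
}

is_isotropic <- function(vol, tol = 1e-8) {
  diff(range(vol$voxel_size)) <= tol * mean(vol$voxel_size)
}

as_plane_matrix <- function(img) {
  if (inherits(img, "plane2d")) img$data else img
}
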