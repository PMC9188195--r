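#' Label connected components of a binary mask
#'
#' Components are defined either by face adjacency (4-connectivity in 2D,
#' 6-connectivity in 3D, i.e. "adjacent and orthogonally adjacent") or by
#' full adjacency including diagonals (8 in 2D, 26 in 3D). Labels are dense
#' integers starting at 1, assigned in column-major order of each
#' component's first pixel, so the labelling is deterministic.
#'
#' @param mask logical matrix (2D) or 3D array.
#' @param connectivity `"full"` (8/26, the usual imaging-software default for
#'   2D object counting) or `"face"` (4/6, orthogonal adjacency only).
#' @return integer array of the same shape; 0 is background.
#' @export
label_components <- function(mask, connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  d <- mask_dims(mask)
  lab <- cpp_label_components(as.logical(mask), d, connectivity == "full")
  array(lab, dim = dim(mask) %||% length(mask))
}

#' Squared Euclidean distance to the nearest foreground pixel/voxel
#'
#' Distances are measured between pixel/voxel centres, in physical units
#' when `spacing` is given. Positions with no reachable foreground are `Inf`.
#'
#' @param mask logical matrix or 3D array; `TRUE` marks foreground.
#' @param spacing physical size of one pixel/voxel per axis (recycled).
#' @return numeric array of squared distances, same shape as `mask`.
#' @export
distance_sq_to <- function(mask, spacing = 1) {
  d <- mask_dims(mask)
  sp <- rep_len(as.numeric(spacing), 3L)
  out <- cpp_edt_sq(as.logical(mask), d, sp)
  array(out, dim = dim(mask) %||% length(mask))
}

#' Euclidean binary dilation
#'
#' A pixel is positive in the output iff its centre lies within `radius` of
#' the centre of any positive input pixel; radius 0 is the identity.
#'
#' @param mask logical matrix or 3D array.
#' @param radius dilation radius, in the units of `spacing`.
#' @param spacing pixel/voxel size per axis (default 1: radius in pixels).
#' @return logical array, same shape.
#' @export
dilate_mask <- function(mask, radius, spacing = 1) {
  stopifnot(radius >= 0)
  if (radius == 0) {
    return(array(as.logical(mask), dim = dim(mask) %||% length(mask)))
  }
  d2 <- distance_sq_to(mask, spacing)
  # small tolerance so exact integer radii include boundary pixels
  d2 <= radius^2 * (1 + 1e-12)
}

# shared shape handling: everything is run as a 3D grid, 2D gets nz = 1
mask_dims <- function(mask) {
  dm <- dim(mask)
  if (is.null(dm)) abort("mask must be a matrix or a 3D array")
  if (length(dm) == 2L) dm <- c(dm, 1L)
  if (length(dm) != 3L) abort("mask must be 2D or 3D")
  as.integer(dm)
}
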