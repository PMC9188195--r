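#' Write / read a 2D plane as TIFF with a metadata sidecar
#'
#' Intensities are stored as 32-bit float TIFF scaled into `[0, 1]`; the
#' scale and the pixel size travel in a small CSV sidecar
#' (`<path>.meta.csv`) so the plane is restored on read (at float32
#' precision).
#'
#' @param plane a [plane2d()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_plane_tiff <- function(plane, path) {
  stopifnot(inherits(plane, "plane2d"))
  scale <- max(plane$data, 1)
  tiff::writeTIFF(plane$data / scale, path, bits.per.sample = 32L)
  readr::write_csv(tibble(pixel_size = plane$pixel_size, scale = scale),
                   paste0(path, ".meta.csv"))
  invisible(path)
}

#' @rdname write_plane_tiff
#' @export
read_plane_tiff <- function(path) {
  meta <- readr::read_csv(paste0(path, ".meta.csv"),
                          col_types = readr::cols())
  x <- tiff::readTIFF(path)
  plane2d(x * meta$scale[1], meta$pixel_size[1])
}

#' Write / read a 3D volume as NIfTI
#'
#' Voxel sizes (um) are stored in the NIfTI pixdim fields. Integer label
#' volumes survive the round trip exactly.
#'
#' @param vol a [volume3d()] or a bare 3D array (then `voxel_size` is
#'   required).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size voxel edges in um when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path, voxel_size = NULL) {
  if (inherits(vol, "volume3d")) {
    arr <- vol$data
    voxel_size <- vol$voxel_size
  } else {
    arr <- vol
    if (is.null(voxel_size)) abort("voxel_size required for bare arrays")
    voxel_size <- rep_len(voxel_size, 3L)
  }
  if (is.logical(arr)) {
    arr <- array(as.integer(arr), dim(arr))
  }
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- voxel_size
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  volume3d(array(as.numeric(nii), dim(nii)), RNifti::pixdim(nii)[1:3])
}

#' Write / read metadata tables with lossless column types
#'
#' Plain CSV with a leading `# coltypes:` comment carrying the readr
#' column-type codes, so integer/double/character/logical columns
#' round-trip exactly.
#'
#' @param df a data frame (list-columns are not supported; factor columns
#'   are written as character).
#' @param path CSV path.
#' @return `path` invisibly; `read_metadata_csv()` returns a tibble.
#' @export
write_metadata_csv <- function(df, path) {
  codes <- vapply(df, function(col) {
    if (is.integer(col)) "i"
    else if (is.numeric(col)) "d"
    else if (is.logical(col)) "l"
    else "c"
  }, character(1))
  writeLines(paste0("# coltypes: ", paste(codes, collapse = "")), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  first <- readLines(path, n = 1)
  codes <- sub("^# coltypes: ", "", first)
  readr::read_csv(path, comment = "#", col_types = codes)
}
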