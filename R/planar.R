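#' Parameters for 2D section quantification
#'
#' Bundles every tunable of the 2D pipeline. The defaults follow common
#' slide-scanner macro practice: median smoothing with a 1 px radius,
#' rolling-ball style local background subtraction with a 50 um radius,
#' per-channel Otsu thresholds (override with a fixed number per channel),
#' removal of objects smaller than 10 px, and a 10 um plaque dilation ring.
#'
#' @param median_radius median filter radius in px (0 disables smoothing).
#' @param background_method `"rolling_ball"` (grayscale opening with a flat
#'   disc; the classical local background estimate) or `"gaussian_highpass"`
#'   (subtract a Gaussian blur).
#' @param background_radius background structuring radius / sigma, um.
#' @param threshold per-channel binarization threshold: a single number, a
#'   named numeric vector (per channel), or `"otsu"`.
#' @param min_object_px objects smaller than this many pixels are removed
#'   (strictly smaller: an object of exactly `min_object_px` survives).
#' @param dilation_radius plaque dilation ring radius, um.
#' @param connectivity object connectivity, `"full"` (8) or `"face"` (4).
#' @return a list of class `planar_params`.
#' @export
planar_params <- function(median_radius = 1,
                          background_method = c("rolling_ball",
                                                "gaussian_highpass"),
                          background_radius = 50,
                          threshold = "otsu",
                          min_object_px = 10,
                          dilation_radius = 10,
                          connectivity = c("full", "face")) {
  background_method <- match.arg(background_method)
  connectivity <- match.arg(connectivity)
  stopifnot(median_radius >= 0, background_radius > 0,
            min_object_px >= 1, dilation_radius >= 0)
  structure(list(median_radius = median_radius,
                 background_method = background_method,
                 background_radius = background_radius,
                 threshold = threshold,
                 min_object_px = min_object_px,
                 dilation_radius = dilation_radius,
                 connectivity = connectivity),
            class = "planar_params")
}

#' Median smoothing plus local background subtraction
#'
#' Applies a median filter of the configured radius, estimates the local
#' background (grayscale opening with a flat disc for `rolling_ball`, or a
#' Gaussian blur for `gaussian_highpass`), subtracts it, and clips at zero.
#' A constant image therefore maps to all zeros, and slowly varying
#' backgrounds (e.g. a linear ramp) are removed while compact bright
#' objects survive.
#'
#' @param img a [plane2d()] (pixel size is required to convert the
#'   background radius from um to px).
#' @param params a [planar_params()].
#' @return a `plane2d` of the same shape, values >= 0.
#' @export
preprocess_channel <- function(img, params = planar_params()) {
  if (!inherits(img, "plane2d")) {
    abort("`img` must be a plane2d (intensity matrix + pixel size)")
  }
  x <- img$data
  if (params$median_radius >= 1) {
    mx <- max(x)
    if (mx > 0) {
      # EBImage's constant-time median filter expects values in [0, 1]
      x <- EBImage::medianFilter(x / mx, round(params$median_radius)) * mx
    }
  }
  r_px <- params$background_radius / img$pixel_size
  bg <- estimate_background(x, r_px, params$background_method)
  out <- pmax(x - bg, 0)
  plane2d(matrix(out, nrow(x), ncol(x)), img$pixel_size)
}

estimate_background <- function(x, r_px, method) {
  # EBImage's grayscale morphology expects intensities in [0, 1]
  mx <- max(x)
  if (mx <= 0) return(x * 0)
  if (method == "rolling_ball") {
    size <- 2L * max(1L, as.integer(floor(r_px))) + 1L
    brush <- EBImage::makeBrush(size, shape = "disc")
    as.matrix(EBImage::opening(x / mx, brush)) * mx
  } else {
    as.matrix(EBImage::gblur(x / mx, sigma = r_px)) * mx
  }
}

#' Binarize an intensity image
#'
#' A pixel is positive iff its value is strictly greater than the
#' threshold. With `threshold = "otsu"` the threshold is computed by Otsu's
#' method over a 256-bin histogram of the image range; the resolved value is
#' recorded in the `"threshold"` attribute so every run is reproducible.
#'
#' @param img a [plane2d()] or numeric matrix.
#' @param threshold a finite number, or `"otsu"`.
#' @return logical matrix with attribute `threshold` (the value used).
#' @export
binarize <- function(img, threshold = "otsu") {
  x <- as_plane_matrix(img)
  thr <- resolve_threshold(x, threshold)
  out <- x > thr
  attr(out, "threshold") <- thr
  out
}

resolve_threshold <- function(x, threshold) {
  if (identical(threshold, "otsu")) {
    rng <- range(x)
    if (diff(rng) == 0) {
      return(rng[1]) # flat image: strict '>' yields an empty mask
    }
    x01 <- (x - rng[1]) / diff(rng)
    EBImage::otsu(x01, range = c(0, 1), levels = 256) * diff(rng) + rng[1]
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L,
              is.finite(threshold))
    threshold
  }
}

#' Remove small objects from a binary mask
#'
#' Connected components (8-connectivity by default) with strictly fewer
#' than `min_px` pixels are removed as staining artifacts; components of
#' exactly `min_px` pixels survive. Idempotent.
#'
#' @param mask logical matrix.
#' @param min_px minimum surviving object size in pixels (>= 1).
#' @param connectivity `"full"` or `"face"`.
#' @return logical matrix.
#' @export
filter_small_objects <- function(mask, min_px = 10,
                                 connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  stopifnot(min_px >= 1)
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes >= min_px)
  out <- array(lab %in% keep, dim = dim(mask))
  out
}

#' Dilate plaque objects to a surrounding region
#'
#' Euclidean dilation of the mask by a physical radius: an output pixel is
#' positive iff its centre lies within `radius_um` of any positive input
#' pixel centre. Radius 0 is the identity. Used to build the region
#' "surrounding and including" plaques within which plaque-adjacent
#' microglial signal is measured.
#'
#' @param mask logical matrix.
#' @param radius_um dilation radius in um (>= 0).
#' @param pixel_size um per pixel.
#' @return logical matrix.
#' @export
dilate_objects <- function(mask, radius_um, pixel_size) {
  stopifnot(radius_um >= 0, pixel_size > 0)
  dilate_mask(mask, radius_um, spacing = pixel_size)
}

#' Per-ROI marker and plaque statistics for one section
#'
#' All statistics are computed strictly within the ROI. For each marker:
#' percent positivity (100 * positive area / ROI area), the percentage of
#' marker signal falling inside the dilated plaque region, and the
#' percentage of plaque area overlapped by the marker. Plaques are counted
#' as connected components of the plaque mask inside the ROI. Overlap
#' percentages with an empty denominator (no marker signal, or no plaques)
#' are reported as 0 with the corresponding `empty_*` flag set, so batch
#' runs over sparse sections complete.
#'
#' @param channel_masks named list of logical matrices, one per marker
#'   (e.g. `iba1`, `cd68`), already binarized and artifact-filtered.
#' @param plaque_mask logical matrix of plaque (amyloid) objects.
#' @param roi logical matrix; must be non-empty.
#' @param params a [planar_params()]; supplies the dilation radius and
#'   object connectivity.
#' @param pixel_size um per pixel.
#' @param intensity optional named list of intensity matrices; when a
#'   marker's name matches, the mean intensity over `mask & roi` is
#'   reported (`mean_intensity`), covering masked-intensity readouts.
#' @return a tibble with one row per marker; section-level columns
#'   (`roi_area_px`, `roi_area_mm2`, `plaque_count`, `plaque_pct_area`,
#'   `plaque_areas_px` list-column) are repeated on each row.
#' @export
quantify_roi <- function(channel_masks, plaque_mask, roi,
                         params = planar_params(), pixel_size,
                         intensity = NULL) {
  stopifnot(is.list(channel_masks), length(channel_masks) >= 1,
            !is.null(names(channel_masks)))
  shp <- dim(plaque_mask)
  ok <- vapply(channel_masks, function(m) identical(dim(m), shp), logical(1))
  if (!all(ok) || !identical(dim(roi), shp)) {
    abort("all masks and the ROI must share the same shape")
  }
  roi <- roi & TRUE
  roi_area <- sum(roi)
  if (roi_area == 0) abort("ROI is empty")

  plaque_in <- plaque_mask & roi
  lab <- label_components(plaque_in, params$connectivity)
  n_plaques <- max(lab)
  plaque_areas <- if (n_plaques > 0) {
    tabulate(lab[lab > 0L], nbins = n_plaques)
  } else {
    integer(0)
  }
  dil <- dilate_objects(plaque_in, params$dilation_radius, pixel_size) & roi
  plaque_area <- sum(plaque_in)

  rows <- purrr::imap(channel_masks, function(m, nm) {
    pos <- m & roi
    pos_area <- sum(pos)
    in_ring <- sum(pos & dil)
    in_marker <- sum(plaque_in & pos)
    tibble(
      marker = nm,
      positive_px = pos_area,
      positive_mm2 = px_to_mm2(pos_area, pixel_size),
      percent_positive = 100 * pos_area / roi_area,
      pct_marker_in_plaque_region =
        if (pos_area > 0) 100 * in_ring / pos_area else 0,
      empty_marker = pos_area == 0,
      pct_plaque_in_marker =
        if (plaque_area > 0) 100 * in_marker / plaque_area else 0,
      empty_plaque = plaque_area == 0,
      mean_intensity = masked_mean(intensity[[nm]], pos)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$roi_area_px <- roi_area
  out$roi_area_mm2 <- px_to_mm2(roi_area, pixel_size)
  out$plaque_count <- n_plaques
  out$plaque_pct_area <- 100 * plaque_area / roi_area
  out$plaque_areas_px <- rep(list(plaque_areas), nrow(out))
  out$dilation_radius_um <- params$dilation_radius
  as_tibble(out)
}

px_to_mm2 <- function(n_px, pixel_size) n_px * pixel_size^2 / 1e6

masked_mean <- function(intensity, mask) {
  if (is.null(intensity) || sum(mask) == 0) return(NA_real_)
  mean(intensity[mask])
}

#' Average per-section quantification records into a per-mouse summary
#'
#' Sections are averaged with equal weight (the unweighted arithmetic mean
#' of every percentage and count metric), per marker; the order of sections
#' does not matter. The input (per-section) table is attached as the
#' `"sections"` attribute of the result.
#'
#' @param records tibble of [quantify_roi()] rows from one mouse, typically
#'   `dplyr::bind_rows()` over sections (add a `section` column if you want
#'   to keep track of provenance).
#' @return a tibble with one row per marker of mean metrics.
#' @export
aggregate_mouse <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("`records` must contain at least one section record")
  }
  num_cols <- setdiff(
    names(records)[vapply(records, is.numeric, logical(1))],
    c("section")
  )
  out <- records |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(
      n_sections = dplyr::n(),
      dplyr::across(dplyr::all_of(num_cols), ~ mean(.x)),
      .groups = "drop"
    )
  attr(out, "sections") <- records
  out
}
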