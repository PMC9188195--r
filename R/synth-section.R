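#' Ground truth for a synthetic stained section
#'
#' Describes a 2D phantom: plaques and microglia as discs (positions and
#' radii in um), a smooth background (constant plus linear gradient),
#' additive Gaussian noise clipped at zero, and an optional polygonal ROI.
#' Geometry that falls outside the image bounds is rejected.
#'
#' @param width_um,height_um image extent, um.
#' @param pixel_size um per pixel (> 0).
#' @param plaque_centers,microglia_centers n x 2 matrices of (x, y) um
#'   (may have zero rows).
#' @param plaque_radii,microglia_radii radii in um (> 0), recycled.
#' @param background_level constant background intensity.
#' @param background_gradient `c(gx, gy)`: intensity change per um.
#' @param foreground_level intensity added inside objects.
#' @param noise_sd Gaussian noise standard deviation.
#' @param roi_polygon optional m x 2 matrix of (x, y) um vertices; `NULL`
#'   means the whole image.
#' @return a list of class `section_truth`.
#' @export
section_truth <- function(width_um, height_um, pixel_size,
                          plaque_centers = matrix(numeric(0), 0, 2),
                          plaque_radii = numeric(0),
                          microglia_centers = matrix(numeric(0), 0, 2),
                          microglia_radii = numeric(0),
                          background_level = 0,
                          background_gradient = c(0, 0),
                          foreground_level = 100,
                          noise_sd = 0,
                          roi_polygon = NULL) {
  stopifnot(width_um > 0, height_um > 0, pixel_size > 0, noise_sd >= 0)
  plaque_centers <- as_center_matrix(plaque_centers)
  microglia_centers <- as_center_matrix(microglia_centers)
  plaque_radii <- rep_len(plaque_radii, nrow(plaque_centers))
  microglia_radii <- rep_len(microglia_radii, nrow(microglia_centers))
  if (any(plaque_radii <= 0) || any(microglia_radii <= 0)) {
    abort("all radii must be > 0")
  }
  check_in_bounds(plaque_centers, plaque_radii, width_um, height_um,
                  "plaques")
  check_in_bounds(microglia_centers, microglia_radii, width_um, height_um,
                  "microglia")
  structure(list(width_um = width_um, height_um = height_um,
                 pixel_size = pixel_size,
                 plaque_centers = plaque_centers,
                 plaque_radii = plaque_radii,
                 microglia_centers = microglia_centers,
                 microglia_radii = microglia_radii,
                 background_level = background_level,
                 background_gradient = background_gradient,
                 foreground_level = foreground_level,
                 noise_sd = noise_sd,
                 roi_polygon = roi_polygon),
            class = "section_truth")
}

as_center_matrix <- function(x) {
  if (is.null(x) || length(x) == 0) return(matrix(numeric(0), 0, 2))
  x <- as.matrix(x)
  if (ncol(x) < 2) abort("centres must have two (or three) columns")
  x
}

check_in_bounds <- function(centers, radii, w, h, what) {
  if (nrow(centers) == 0) return(invisible())
  bad <- centers[, 1] - radii < 0 | centers[, 1] + radii > w |
    centers[, 2] - radii < 0 | centers[, 2] + radii > h
  if (any(bad)) {
    abort(sprintf("%s %s extend outside the image bounds", what,
                  paste(which(bad), collapse = ", ")))
  }
  invisible()
}

#' Random section truth with plaque-associated microglia
#'
#' Places `n_plaques` plaques uniformly (non-overlapping) and `n_microglia`
#' microglia, a fraction `frac_near` of which are placed within `near_dist`
#' um of a plaque boundary, emulating plaque-adjacent microgliosis.
#'
#' @param n_plaques,n_microglia object counts.
#' @param frac_near fraction of microglia placed near plaques.
#' @param near_dist maximum centre-to-boundary distance for "near", um.
#' @param plaque_radius,microglia_radius radii, um (recycled).
#' @param seed integer seed.
#' @inheritParams section_truth
#' @return a [section_truth()].
#' @export
random_section_truth <- function(n_plaques = 5, n_microglia = 12,
                                 frac_near = 0.5, near_dist = 15,
                                 plaque_radius = 12, microglia_radius = 5,
                                 width_um = 400, height_um = 400,
                                 pixel_size = 1, background_level = 10,
                                 background_gradient = c(0.01, 0),
                                 noise_sd = 2, seed = 1) {
  with_seed(seed, {
    pr <- rep_len(plaque_radius, n_plaques)
    pc <- place_discs(n_plaques, pr, width_um, height_um, min_gap = 4)
    mr <- rep_len(microglia_radius, n_microglia)
    n_near <- round(frac_near * n_microglia)
    mc <- matrix(NA_real_, n_microglia, 2)
    for (i in seq_len(n_microglia)) {
      if (i <= n_near && n_plaques > 0) {
        p <- sample.int(n_plaques, 1)
        repeat {
          ang <- runif(1, 0, 2 * pi)
          d <- pr[p] + runif(1, 0, near_dist)
          cand <- pc[p, ] + d * c(cos(ang), sin(ang))
          if (all(cand - mr[i] >= 0) && cand[1] + mr[i] <= width_um &&
              cand[2] + mr[i] <= height_um) break
        }
        mc[i, ] <- cand
      } else {
        mc[i, ] <- c(runif(1, mr[i], width_um - mr[i]),
                     runif(1, mr[i], height_um - mr[i]))
      }
    }
    section_truth(width_um, height_um, pixel_size,
                  plaque_centers = pc, plaque_radii = pr,
                  microglia_centers = mc, microglia_radii = mr,
                  background_level = background_level,
                  background_gradient = background_gradient,
                  noise_sd = noise_sd)
  })
}

place_discs <- function(n, radii, w, h, min_gap = 0) {
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    for (try in 1:1000) {
      cand <- c(runif(1, radii[i], w - radii[i]),
                runif(1, radii[i], h - radii[i]))
      if (i == 1) break
      prev <- centers[seq_len(i - 1), , drop = FALSE]
      dd <- sqrt(rowSums((prev - matrix(cand, i - 1, 2, byrow = TRUE))^2))
      if (all(dd >= radii[seq_len(i - 1)] + radii[i] + min_gap)) break
      if (try == 1000) abort("could not place discs without overlap")
    }
    centers[i, ] <- cand
  }
  centers
}

#' Render a synthetic multichannel section with ground-truth masks
#'
#' Rasterization rule: a pixel is foreground iff its centre lies inside
#' (<= radius from the centre of) a disc, which makes truth areas
#' integer-exact. Plaques appear in the amyloid channel, microglia in the
#' Iba1/CD68 channels; each channel is foreground signal plus the smooth
#' background plus Gaussian noise clipped at zero.
#'
#' @param truth a [section_truth()].
#' @param channels channel names to render; `"abeta"` carries plaques, any
#'   other name carries microglia.
#' @param seed integer seed (noise only).
#' @return a list of class `synthetic_section`: `channels` (named list of
#'   [plane2d()]), `masks` (named list of ground-truth logical matrices,
#'   incl. `abeta` and `microglia`), `roi` (logical matrix), and `truth`
#'   (a tibble of per-plaque pixel areas plus the truth object itself as
#'   an attribute).
#' @export
make_section <- function(truth,
                         channels = c("abeta", "iba1", "cd68"),
                         seed = 1) {
  stopifnot(inherits(truth, "section_truth"))
  nx <- round(truth$width_um / truth$pixel_size)
  ny <- round(truth$height_um / truth$pixel_size)
  cx <- (seq_len(nx) - 0.5) * truth$pixel_size
  cy <- (seq_len(ny) - 0.5) * truth$pixel_size

  disc_mask <- function(centers, radii) {
    m <- matrix(FALSE, nx, ny)
    for (i in seq_len(nrow(centers))) {
      m <- m | outer(cx, cy, function(x, y) {
        (x - centers[i, 1])^2 + (y - centers[i, 2])^2 <= radii[i]^2
      })
    }
    m
  }
  plaque_mask <- disc_mask(truth$plaque_centers, truth$plaque_radii)
  micro_mask <- disc_mask(truth$microglia_centers, truth$microglia_radii)
  plaque_areas <- vapply(seq_len(nrow(truth$plaque_centers)), function(i) {
    sum(disc_mask(truth$plaque_centers[i, , drop = FALSE],
                  truth$plaque_radii[i]))
  }, numeric(1))

  bg <- truth$background_level +
    outer(cx, cy, function(x, y) {
      truth$background_gradient[1] * x + truth$background_gradient[2] * y
    })
  roi <- if (is.null(truth$roi_polygon)) {
    matrix(TRUE, nx, ny)
  } else {
    grid <- expand.grid(x = cx, y = cy)
    matrix(points_in_polygon(grid$x, grid$y, truth$roi_polygon), nx, ny)
  }

  ch <- with_seed(seed, {
    lapply(setNames(channels, channels), function(nm) {
      fg <- if (nm == "abeta") plaque_mask else micro_mask
      noise <- if (truth$noise_sd > 0) {
        matrix(rnorm(nx * ny, 0, truth$noise_sd), nx, ny)
      } else {
        0
      }
      plane2d(clip0(bg + truth$foreground_level * fg + noise),
              truth$pixel_size)
    })
  })

  masks <- lapply(setNames(channels, channels),
                  function(nm) if (nm == "abeta") plaque_mask else micro_mask)
  masks$microglia <- micro_mask
  truth_tbl <- tibble(
    plaque_id = seq_along(plaque_areas),
    area_px = as.integer(plaque_areas),
    area_um2 = plaque_areas * truth$pixel_size^2
  )
  structure(list(channels = ch, masks = masks, roi = roi,
                 truth = truth_tbl,
                 pct_plaque_area = 100 * sum(plaque_mask & roi) / sum(roi),
                 section_truth = truth),
            class = "synthetic_section")
}
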