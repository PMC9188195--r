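#' Ground truth for a synthetic confocal volume
#'
#' A 3D phantom of microglia (spherical somata plus capsule-shaped
#' processes), amyloid plaques (spheres), and per-cell methoxy-X04 content
#' (the fraction of each soma's volume occupied by dye signal). All
#' positions and sizes are in um.
#'
#' @param extent_um volume extent `c(x, y, z)`, um.
#' @param voxel_size voxel edges, um (length 1 or 3; may be anisotropic).
#' @param soma_centers n x 3 matrix, um.
#' @param soma_diameters diameters, um (> 0, recycled).
#' @param process_segments list of `list(start, end, radius)` capsules, um.
#' @param plaque_centers m x 3 matrix, um.
#' @param plaque_radii radii, um.
#' @param methoxy_fraction_per_cell per-cell fraction in `[0, 1]`.
#' @param background_level,foreground_level,noise_sd intensity model.
#' @return a list of class `volume_truth`.
#' @export
volume_truth <- function(extent_um, voxel_size,
                         soma_centers = matrix(numeric(0), 0, 3),
                         soma_diameters = numeric(0),
                         process_segments = list(),
                         plaque_centers = matrix(numeric(0), 0, 3),
                         plaque_radii = numeric(0),
                         methoxy_fraction_per_cell = 0,
                         background_level = 0, foreground_level = 100,
                         noise_sd = 0) {
  extent_um <- rep_len(extent_um, 3L)
  voxel_size <- rep_len(voxel_size, 3L)
  stopifnot(all(extent_um > 0), all(voxel_size > 0), noise_sd >= 0)
  soma_centers <- as.matrix(soma_centers)
  plaque_centers <- as.matrix(plaque_centers)
  soma_diameters <- rep_len(soma_diameters, nrow(soma_centers))
  plaque_radii <- rep_len(plaque_radii, nrow(plaque_centers))
  mfrac <- rep_len(methoxy_fraction_per_cell, nrow(soma_centers))
  if (any(soma_diameters <= 0)) abort("soma diameters must be > 0")
  if (any(mfrac < 0 | mfrac > 1)) {
    abort("methoxy fractions must lie in [0, 1]")
  }
  structure(list(extent_um = extent_um, voxel_size = voxel_size,
                 soma_centers = soma_centers,
                 soma_diameters = soma_diameters,
                 process_segments = process_segments,
                 plaque_centers = plaque_centers,
                 plaque_radii = plaque_radii,
                 methoxy_fraction_per_cell = mfrac,
                 background_level = background_level,
                 foreground_level = foreground_level,
                 noise_sd = noise_sd),
            class = "volume_truth")
}

#' Render a synthetic three-channel confocal volume with ground truth
#'
#' Somata are rasterized as spheres (voxel centre within the radius),
#' processes as capsules; the methoxy channel fills a concentric sphere
#' covering the requested volume fraction of each designated cell's soma;
#' plaques fill the amyloid channel. The returned truth table records the
#' exact rasterized per-cell methoxy overlap (in voxels) and the analytic
#' centre-to-plaque-surface distance.
#'
#' @param truth a [volume_truth()].
#' @param seed integer seed (noise only).
#' @return a list of class `synthetic_volume`: `channels` (named
#'   [volume3d()]s: `iba1`, `methoxy`, `abeta`), `masks` (logical arrays),
#'   and `cells` (per-cell truth tibble).
#' @export
make_volume <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "volume_truth"))
  dims <- pmax(1L, round(truth$extent_um / truth$voxel_size))
  cc <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * truth$voxel_size[a])
  # voxel-centre coordinate arrays
  X <- array(rep(cc[[1]], times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(cc[[2]], each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(cc[[3]], each = dims[1] * dims[2]), dims)

  sphere <- function(ctr, r) {
    (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <= r^2
  }
  capsule <- function(s, e, r) {
    v <- e - s
    len2 <- sum(v^2)
    t <- ((X - s[1]) * v[1] + (Y - s[2]) * v[2] + (Z - s[3]) * v[3]) /
      max(len2, 1e-12)
    t <- pmin(pmax(t, 0), 1)
    (X - s[1] - t * v[1])^2 + (Y - s[2] - t * v[2])^2 +
      (Z - s[3] - t * v[3])^2 <= r^2
  }

  n_cells <- nrow(truth$soma_centers)
  iba1 <- array(FALSE, dims)
  methoxy <- array(FALSE, dims)
  soma_masks <- vector("list", n_cells)
  methoxy_vox <- integer(n_cells)
  for (i in seq_len(n_cells)) {
    r <- truth$soma_diameters[i] / 2
    sm <- sphere(truth$soma_centers[i, ], r)
    soma_masks[[i]] <- sm
    iba1 <- iba1 | sm
    f <- truth$methoxy_fraction_per_cell[i]
    if (f > 0) {
      mm <- sphere(truth$soma_centers[i, ], r * f^(1 / 3))
      methoxy_vox[i] <- sum(mm & sm)
      methoxy <- methoxy | (mm & sm)
    }
  }
  for (seg in truth$process_segments) {
    iba1 <- iba1 | capsule(seg$start, seg$end, seg$radius)
  }
  abeta <- array(FALSE, dims)
  for (i in seq_len(nrow(truth$plaque_centers))) {
    abeta <- abeta | sphere(truth$plaque_centers[i, ], truth$plaque_radii[i])
  }

  render <- with_seed(seed, {
    lapply(list(iba1 = iba1, methoxy = methoxy, abeta = abeta), function(m) {
      noise <- if (truth$noise_sd > 0) {
        array(rnorm(prod(dims), 0, truth$noise_sd), dims)
      } else {
        0
      }
      volume3d(clip0(truth$background_level +
                       truth$foreground_level * m + noise),
               truth$voxel_size)
    })
  })

  plaque_dist <- function(ctr) {
    if (nrow(truth$plaque_centers) == 0) return(Inf)
    d <- sqrt(rowSums((truth$plaque_centers -
                         matrix(ctr, nrow(truth$plaque_centers), 3,
                                byrow = TRUE))^2)) - truth$plaque_radii
    max(min(d), 0)
  }
  cells <- tibble(
    cell_id = seq_len(n_cells),
    x = truth$soma_centers[, 1], y = truth$soma_centers[, 2],
    z = truth$soma_centers[, 3],
    diameter_um = truth$soma_diameters,
    soma_voxels = vapply(soma_masks, sum, numeric(1)),
    methoxy_fraction = truth$methoxy_fraction_per_cell,
    methoxy_voxels = methoxy_vox,
    methoxy_positive = methoxy_vox >= 1L,
    center_to_plaque_surface_um =
      vapply(seq_len(n_cells),
             function(i) plaque_dist(truth$soma_centers[i, ]), numeric(1))
  )
  structure(list(channels = render,
                 masks = list(iba1 = iba1, methoxy = methoxy, abeta = abeta),
                 cells = cells, volume_truth = truth),
            class = "synthetic_volume")
}
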