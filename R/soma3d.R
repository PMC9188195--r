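#' Parameters for 3D microglia soma segmentation
#'
#' Defaults follow the conventional confocal workflow this module
#' implements: resampling to 0.5 um isotropic voxels, Gaussian background
#' estimation with a 10 um kernel, a bipartite Iba1 threshold completed by
#' random-walker diffusion (diffusion constant 10), soma seeds where local
#' surface thickness reaches at least 7 um spaced at least 10 um apart, and
#' a configurable plaque-proximity cutoff (10 um by default; reported in
#' all outputs since it is a reporting choice, not a measurement).
#'
#' @param iso_voxel target isotropic voxel size, um.
#' @param bg_kernel Gaussian background kernel (sigma), um.
#' @param iba1_low_threshold,iba1_high_threshold bipartite threshold: below
#'   low is background, above high is microglia, in between is decided by
#'   the random walker. Must satisfy `low < high`.
#' @param methoxy_threshold,abeta_threshold manual surface thresholds for
#'   the methoxy-X04 and amyloid channels.
#' @param rw_diffusion random-walker diffusion constant (edge-weight
#'   sharpness beta; see [segment_microglia()]).
#' @param min_soma_diameter minimum soma diameter, um.
#' @param min_soma_spacing minimum spacing between soma peaks, um.
#' @param proximity_um plaque-proximity cutoff, um.
#' @param methoxy_min_voxels minimum overlap (voxels) for a cell to be
#'   called methoxy-X04 positive.
#' @return a list of class `soma3d_params`.
#' @export
soma3d_params <- function(iso_voxel = 0.5, bg_kernel = 10,
                          iba1_low_threshold = NULL,
                          iba1_high_threshold = NULL,
                          methoxy_threshold = NULL, abeta_threshold = NULL,
                          rw_diffusion = 10, min_soma_diameter = 7,
                          min_soma_spacing = 10, proximity_um = 10,
                          methoxy_min_voxels = 1) {
  stopifnot(iso_voxel > 0, bg_kernel > 0, min_soma_spacing > 0,
            min_soma_diameter > 0, proximity_um >= 0, methoxy_min_voxels >= 1)
  if (!is.null(iba1_low_threshold) && !is.null(iba1_high_threshold)) {
    stopifnot(iba1_low_threshold < iba1_high_threshold)
  }
  structure(list(iso_voxel = iso_voxel, bg_kernel = bg_kernel,
                 iba1_low_threshold = iba1_low_threshold,
                 iba1_high_threshold = iba1_high_threshold,
                 methoxy_threshold = methoxy_threshold,
                 abeta_threshold = abeta_threshold,
                 rw_diffusion = rw_diffusion,
                 min_soma_diameter = min_soma_diameter,
                 min_soma_spacing = min_soma_spacing,
                 proximity_um = proximity_um,
                 methoxy_min_voxels = methoxy_min_voxels),
            class = "soma3d_params")
}

#' Local-mean resampling to an isotropic voxel grid
#'
#' Each output voxel is the (area-weighted) mean of the input voxels it
#' covers: exact block means for integer pooling factors, box averaging for
#' rational factors. A trailing partial output voxel (when the axis length
#' is not divisible by the pooling factor) is dropped.
#'
#' @param vol a [volume3d()].
#' @param iso_voxel target voxel size, um.
#' @return a `volume3d` with `voxel_size = c(iso, iso, iso)`.
#' @export
resample_isotropic <- function(vol, iso_voxel = 0.5) {
  stopifnot(inherits(vol, "volume3d"), iso_voxel > 0)
  x <- vol$data
  for (ax in 1:3) {
    f <- iso_voxel / vol$voxel_size[ax]
    if (abs(f - 1) < 1e-12) next
    W <- box_weights(dim(x)[ax], f)
    x <- axis_matmul(x, W, ax)
  }
  volume3d(x, iso_voxel)
}

# Row o of the output covers input-cell interval [(o-1)*f, o*f);
# weights are overlap lengths normalized to f (rows sum to 1).
box_weights <- function(n_in, f) {
  n_out <- floor(n_in / f + 1e-9)
  if (n_out < 1) abort("resampling factor larger than the axis extent")
  W <- matrix(0, n_out, n_in)
  for (o in seq_len(n_out)) {
    lo <- (o - 1) * f
    hi <- o * f
    cells <- seq.int(floor(lo + 1e-12) + 1L, min(ceiling(hi - 1e-12), n_in))
    W[o, cells] <- (pmin(hi, cells) - pmax(lo, cells - 1)) / f
  }
  W
}

# multiply a (possibly non-square) matrix along one axis of a 3D array
axis_matmul <- function(x, W, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- W %*% matrix(xp, dp[1], dp[2] * dp[3])
  out <- array(m, c(nrow(W), dp[2], dp[3]))
  aperm(out, order(perm))
}

#' Gaussian background subtraction for isotropic volumes
#'
#' The background is estimated by isotropic Gaussian smoothing with the
#' stated kernel (sigma, in um) and subtracted; the result is clipped at 0.
#' Edge rows of the separable kernel are renormalized, so a constant volume
#' maps exactly to zeros.
#'
#' @param vol an isotropic [volume3d()] (resample first if needed).
#' @param kernel_um Gaussian sigma in um.
#' @return a `volume3d`, everywhere >= 0.
#' @export
subtract_background <- function(vol, kernel_um = 10) {
  stopifnot(inherits(vol, "volume3d"), kernel_um > 0)
  if (!is_isotropic(vol)) {
    abort("volume is anisotropic; run resample_isotropic() first")
  }
  sigma <- kernel_um / vol$voxel_size[1]
  x <- vol$data
  for (ax in 1:3) {
    if (dim(x)[ax] > 1) x <- axis_matmul(x, gauss_weights(dim(x)[ax], sigma), ax)
  }
  volume3d(pmax(vol$data - x, 0), vol$voxel_size)
}

gauss_weights <- function(n, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  i <- seq_len(n)
  W <- outer(i, i, function(a, b) {
    d <- a - b
    ifelse(abs(d) <= half, exp(-d^2 / (2 * sigma^2)), 0)
  })
  W / rowSums(W)
}

#' Threshold a volume into a binary surface
#'
#' Voxel positive iff value is strictly greater than `thr` (same strict
#' convention as [binarize()] in the 2D pipeline).
#'
#' @param vol a [volume3d()].
#' @param thr finite threshold.
#' @return a `volume3d` with logical data.
#' @export
surface_threshold <- function(vol, thr) {
  stopifnot(inherits(vol, "volume3d"), is.finite(thr))
  volume3d(array(vol$data > thr, dim(vol$data)), vol$voxel_size)
}

#' Bipartite-threshold random-walker microglia segmentation
#'
#' Voxels above `high` are microglia, voxels below `low` (strictly) are
#' background, and the intermediate voxels are assigned by the random
#' walker: the combinatorial Dirichlet problem on the voxel lattice with
#' intensity-difference edge weights `w = exp(-beta * (g_i - g_j)^2)`
#' (intensities `g` normalized to the volume range), seeded by the two
#' decided classes. `rw_diffusion` is the sharpness `beta`. An intermediate
#' voxel joins the microglia mask when its foreground probability is
#' >= 0.5, so a symmetric phantom splits at its midplane.
#'
#' @param vol a [volume3d()] of Iba1 intensity.
#' @param low,high bipartite thresholds, `low < high`.
#' @param rw_diffusion diffusion constant (beta).
#' @return a `volume3d` with logical data. If there is no foreground seed
#'   the mask is empty (with a warning); if no background seed, full (with
#'   a warning).
#' @export
segment_microglia <- function(vol, low, high, rw_diffusion = 10) {
  stopifnot(inherits(vol, "volume3d"), low < high)
  x <- vol$data
  fg <- x > high
  bg <- x < low
  if (!any(fg)) {
    warn("no voxel above the high threshold; returning an empty mask")
    return(volume3d(array(FALSE, dim(x)), vol$voxel_size))
  }
  if (!any(bg)) {
    warn("no voxel below the low threshold; returning a full mask")
    return(volume3d(array(TRUE, dim(x)), vol$voxel_size))
  }
  und <- !fg & !bg
  if (any(und)) {
    prob <- rw_probability(x, fg, bg, rw_diffusion)
    fg <- fg | (und & prob >= 0.5)
  }
  volume3d(array(fg, dim(x)), vol$voxel_size)
}

# Solve the combinatorial Dirichlet problem for the unseeded voxels.
rw_probability <- function(x, fg, bg, beta) {
  dm <- dim(x)
  n <- length(x)
  rng <- range(x)
  g <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) else array(0, dm)

  # 6-neighbour lattice edges via index shifts
  edges_i <- integer(0); edges_j <- integer(0)
  idx <- array(seq_len(n), dm)
  for (ax in 1:3) {
    if (dm[ax] < 2) next
    take_lo <- lapply(dm, seq_len)
    take_hi <- take_lo
    take_lo[[ax]] <- seq_len(dm[ax] - 1L)
    take_hi[[ax]] <- seq.int(2L, dm[ax])
    a <- do.call(`[`, c(list(idx), take_lo, list(drop = FALSE)))
    b <- do.call(`[`, c(list(idx), take_hi, list(drop = FALSE)))
    edges_i <- c(edges_i, as.integer(a))
    edges_j <- c(edges_j, as.integer(b))
  }
  w <- exp(-beta * (g[edges_i] - g[edges_j])^2)

  unknown <- which(!fg & !bg)
  uid <- integer(n)
  uid[unknown] <- seq_along(unknown)
  seedval <- numeric(n)
  seedval[fg] <- 1

  iu <- uid[edges_i]; ju <- uid[edges_j]
  both <- iu > 0L & ju > 0L
  # off-diagonal blocks among unknowns (symmetric)
  Wuu <- Matrix::sparseMatrix(
    i = c(iu[both], ju[both]), j = c(ju[both], iu[both]),
    x = c(w[both], w[both]),
    dims = c(length(unknown), length(unknown))
  )
  # boundary load from seeded neighbours
  b_rhs <- numeric(length(unknown))
  lo_seed <- iu > 0L & ju == 0L
  hi_seed <- ju > 0L & iu == 0L
  if (any(lo_seed)) {
    add <- tapply(w[lo_seed] * seedval[edges_j[lo_seed]], iu[lo_seed], sum)
    b_rhs[as.integer(names(add))] <- b_rhs[as.integer(names(add))] + add
  }
  if (any(hi_seed)) {
    add <- tapply(w[hi_seed] * seedval[edges_i[hi_seed]], ju[hi_seed], sum)
    b_rhs[as.integer(names(add))] <- b_rhs[as.integer(names(add))] + add
  }
  # degree includes edges to seeds
  deg <- numeric(length(unknown))
  d_add <- tapply(w[iu > 0L], iu[iu > 0L], sum)
  deg[as.integer(names(d_add))] <- deg[as.integer(names(d_add))] + d_add
  d_add <- tapply(w[ju > 0L], ju[ju > 0L], sum)
  deg[as.integer(names(d_add))] <- deg[as.integer(names(d_add))] + d_add

  L <- Matrix::Diagonal(x = deg) - Wuu
  sol <- as.numeric(Matrix::solve(L, b_rhs))
  prob <- array(NA_real_, dm)
  prob[unknown] <- sol
  prob[fg] <- 1
  prob[bg] <- 0
  prob
}

#' Detect soma peaks from surface thickness
#'
#' Local thickness is twice the Euclidean distance from a mask voxel to
#' the object boundary: the distance transform to the nearest background
#' voxel centre, plus the half-voxel boundary correction (the boundary
#' lies half a voxel nearer than that centre), doubled. This calibrates
#' the discrete measurement so a rasterized sphere reads out its true
#' diameter to within a voxel. Candidate voxels have thickness at least
#' `min_diameter_um` and are local maxima of the thickness map (no
#' 26-neighbour strictly thicker; plateaus count); peaks are then selected
#' by greedy non-maximum suppression: candidates in descending thickness
#' (ties broken by column-major voxel order), accepting a candidate iff it
#' lies at least `min_spacing_um` (Euclidean, voxel centres) from every
#' already-accepted peak.
#'
#' @param mask a binary [volume3d()] (isotropic).
#' @param min_diameter_um minimum soma diameter, um.
#' @param min_spacing_um minimum peak spacing, um.
#' @return tibble with one row per peak: voxel indices `i, j, k`, physical
#'   centre `x, y, z` (um), and `thickness_um`; zero rows for an empty mask.
#' @export
detect_somata <- function(mask, min_diameter_um = 7, min_spacing_um = 10) {
  stopifnot(inherits(mask, "volume3d"))
  if (!is_isotropic(mask)) abort("mask must be isotropic")
  m <- mask$data > 0
  empty <- tibble(i = integer(0), j = integer(0), k = integer(0),
                  x = numeric(0), y = numeric(0), z = numeric(0),
                  thickness_um = numeric(0))
  if (!any(m)) return(empty)
  h <- mask$voxel_size[1]
  thick <- 2 * (sqrt(distance_sq_to(!m, spacing = mask$voxel_size)) + h / 2)
  thick[!m] <- 0
  cand <- which(thick >= min_diameter_um & local_max_26(thick))
  if (length(cand) == 0) return(empty)
  ord <- cand[order(-thick[cand], cand)]
  coords <- arrayInd(ord, dim(m))
  pos <- (coords - 0.5) * h # voxel centres, um
  sel <- integer(0)
  for (r in seq_len(nrow(coords))) {
    if (length(sel) == 0) {
      sel <- r
      next
    }
    d2 <- rowSums((pos[sel, , drop = FALSE] -
                     matrix(pos[r, ], length(sel), 3, byrow = TRUE))^2)
    if (all(d2 >= min_spacing_um^2)) sel <- c(sel, r)
  }
  tibble(
    i = coords[sel, 1], j = coords[sel, 2], k = coords[sel, 3],
    x = pos[sel, 1], y = pos[sel, 2], z = pos[sel, 3],
    thickness_um = thick[ord[sel]]
  )
}

# TRUE where no 26-neighbour is strictly larger (plateaus count as maxima)
local_max_26 <- function(x) {
  d <- dim(x)
  nbr_max <- array(-Inf, d)
  rng <- function(n, off) {
    lo <- max(1, 1 - off)
    hi <- min(n, n - off)
    if (lo > hi) integer(0) else lo:hi
  }
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    sh <- array(-Inf, d)
    si <- rng(d[1], di)
    sj <- rng(d[2], dj)
    sk <- rng(d[3], dk)
    if (length(si) && length(sj) && length(sk)) {
      sh[si + di, sj + dj, sk + dk] <- x[si, sj, sk]
    }
    nbr_max <- pmax(nbr_max, sh)
  }
  x >= nbr_max
}

#' Watershed assignment of mask voxels to soma peaks
#'
#' Every mask voxel is assigned to its geodesically nearest peak: paths run
#' through face-adjacent mask voxels with per-axis physical step costs, the
#' watershed of the distance-to-peak landscape. Ties go to the lower peak
#' id. Labels partition the mask; background stays 0; mask voxels not
#' connected to any peak also stay 0 (unassigned).
#'
#' @param mask a binary [volume3d()].
#' @param peaks tibble from [detect_somata()] (columns `i, j, k`).
#' @return integer label array of the mask's shape.
#' @export
assign_cells <- function(mask, peaks) {
  stopifnot(inherits(mask, "volume3d"))
  m <- mask$data > 0
  if (nrow(peaks) == 0) {
    if (any(m)) warn("no peaks: all mask voxels left unassigned (label 0)")
    return(array(0L, dim(m)))
  }
  pk <- as.matrix(peaks[, c("i", "j", "k")])
  storage.mode(pk) <- "integer"
  lab <- cpp_geodesic_labels(m, mask_dims(m), pk, mask$voxel_size)
  array(lab, dim(m))
}

#' Per-cell methoxy-X04 content and plaque proximity
#'
#' For every labelled cell: voxel count and volume, overlap with the
#' methoxy-X04 surface (methoxy-positive iff overlap >= the configured
#' minimum voxel count), and the minimum distance from the cell to the
#' nearest plaque voxel (0 when the cell touches a plaque; `Inf` when the
#' plaque mask is empty). A cell is proximal iff that distance is at most
#' `proximity_um`.
#'
#' @param cells integer label array from [assign_cells()].
#' @param methoxy,plaques logical arrays of the same shape (or binary
#'   [volume3d()]).
#' @param params a [soma3d_params()].
#' @param voxel_size voxel edge lengths in um (taken from `methoxy` if it is
#'   a `volume3d`).
#' @return a list of class `soma_classification` with `cells` (one row per
#'   cell: `soma_id`, `cell_voxels`, `cell_volume_um3`,
#'   `methoxy_overlap_voxels`, `methoxy_positive`,
#'   `distance_to_nearest_plaque_um`, `proximal_to_plaque`) and `summary`
#'   (fraction methoxy-positive, fraction of methoxy-positive cells
#'   proximal to a plaque, and the proximity cutoff used).
#' @export
classify_cells <- function(cells, methoxy, plaques,
                           params = soma3d_params(), voxel_size = NULL) {
  if (inherits(methoxy, "volume3d")) {
    voxel_size <- voxel_size %||% methoxy$voxel_size
    methoxy <- methoxy$data > 0
  }
  if (inherits(plaques, "volume3d")) plaques <- plaques$data > 0
  voxel_size <- rep_len(voxel_size %||% 1, 3L)
  if (!identical(dim(cells), dim(methoxy)) ||
      !identical(dim(cells), dim(plaques))) {
    abort("cells, methoxy and plaques must share the same shape")
  }
  ids <- sort(unique(cells[cells > 0L]))
  dplq <- if (any(plaques)) {
    sqrt(distance_sq_to(plaques, spacing = voxel_size))
  } else {
    array(Inf, dim(cells))
  }
  vox_vol <- prod(voxel_size)
  rows <- purrr::map(ids, function(id) {
    inc <- cells == id
    nv <- sum(inc)
    ov <- sum(inc & methoxy)
    dmin <- min(dplq[inc])
    tibble(
      soma_id = id,
      cell_voxels = nv,
      cell_volume_um3 = nv * vox_vol,
      methoxy_overlap_voxels = ov,
      methoxy_positive = ov >= params$methoxy_min_voxels,
      distance_to_nearest_plaque_um = dmin,
      proximal_to_plaque = dmin <= params$proximity_um
    )
  })
  cell_tbl <- dplyr::bind_rows(rows)
  n_pos <- sum(cell_tbl$methoxy_positive)
  summary <- tibble(
    n_cells = nrow(cell_tbl),
    n_methoxy_positive = n_pos,
    frac_methoxy_positive =
      if (nrow(cell_tbl) > 0) n_pos / nrow(cell_tbl) else NA_real_,
    frac_positive_proximal = if (n_pos > 0) {
      sum(cell_tbl$methoxy_positive & cell_tbl$proximal_to_plaque) / n_pos
    } else {
      NA_real_
    },
    proximity_um = params$proximity_um
  )
  structure(list(cells = cell_tbl, summary = summary),
            class = "soma_classification")
}

#' @export
print.soma_classification <- function(x, ...) {
  cat(sprintf("<soma_classification> %d cells, %.1f%% methoxy-X04(+)\n",
              x$summary$n_cells, 100 * x$summary$frac_methoxy_positive))
  print(x$cells, ...)
  invisible(x)
}
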