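#' Ground truth for a synthetic atlas-registered brain
#'
#' A toy stand-in for an annotated reference volume: an integer label
#' volume at summary-grid resolution, a rooted structure ontology, and
#' plaques planted on sampled section planes only (depths that are
#' multiples of the sectioning interval).
#'
#' @param label_volume integer 3D array of structure ids at grid
#'   resolution (0 = outside the brain).
#' @param ontology tibble with `id`, `parent_id` (`NA` at the root),
#'   `name`, and optionally `acronym` and `hemisphere`.
#' @param planted_plaques tibble with one row per plaque: `plaque_id`,
#'   `structure_id`, voxel indices `i`, `j`, `k` (anchor corner) and
#'   in-plane `extent` (square side, grid voxels).
#' @param section_interval um between imaged sections.
#' @param lateral_pixel_size full-resolution pixel size, um.
#' @param grid_voxel summary grid voxel edge, um.
#' @return a list of class `atlas_truth`.
#' @export
atlas_truth <- function(label_volume, ontology, planted_plaques,
                        section_interval = 100, lateral_pixel_size = 0.5,
                        grid_voxel = 10) {
  stopifnot(length(dim(label_volume)) == 3L, section_interval >= grid_voxel,
            lateral_pixel_size < grid_voxel)
  labs <- setdiff(unique(as.integer(label_volume)), 0L)
  if (!all(labs %in% ontology$id)) {
    abort("every nonzero label in the volume must appear in the ontology")
  }
  check_rooted_tree(ontology)
  z_um <- (planted_plaques$k - 1L) * grid_voxel
  if (any(z_um %% section_interval != 0)) {
    abort("planted plaques must lie on sampled section planes")
  }
  structure(list(label_volume = label_volume, ontology = ontology,
                 planted_plaques = planted_plaques,
                 section_interval = section_interval,
                 lateral_pixel_size = lateral_pixel_size,
                 grid_voxel = grid_voxel),
            class = "atlas_truth")
}

check_rooted_tree <- function(ontology) {
  root <- is.na(ontology$parent_id)
  if (sum(root) != 1) abort("ontology must have exactly one root")
  if (!all(ontology$parent_id[!root] %in% ontology$id)) {
    abort("ontology parent links must point at known ids")
  }
  # walk up from every node; a cycle would never reach the root
  for (id in ontology$id) {
    seen <- integer(0)
    cur <- id
    while (!is.na(cur)) {
      if (cur %in% seen) abort("ontology contains a cycle")
      seen <- c(seen, cur)
      cur <- ontology$parent_id[match(cur, ontology$id)]
    }
  }
  invisible()
}

#' Random toy atlas with planted plaques
#'
#' Builds a block-structured label volume: the x-axis splits into left and
#' right hemispheres, each subdivided into `n_structures_per_hemisphere`
#' leaf structures along y, under a three-level ontology (root ->
#' hemispheres -> leaves). Plaques are planted as `extent` x `extent`
#' voxel squares on sampled section planes, spaced so that distinct
#' plaques never touch.
#'
#' @param dims grid dimensions `c(nx, ny, nz)`.
#' @param n_structures_per_hemisphere leaf structures per hemisphere.
#' @param n_plaques total number of planted plaques.
#' @param extent in-plane plaque side, grid voxels.
#' @param section_interval,lateral_pixel_size,grid_voxel geometry (um).
#' @param seed integer seed.
#' @return an [atlas_truth()].
#' @export
random_atlas_truth <- function(dims = c(20, 20, 30),
                               n_structures_per_hemisphere = 3,
                               n_plaques = 8, extent = 2,
                               section_interval = 100,
                               lateral_pixel_size = 0.5, grid_voxel = 10,
                               seed = 1) {
  nsh <- n_structures_per_hemisphere
  leaf_ids <- seq_len(2 * nsh) + 3L
  ontology <- tibble(
    id = c(1L, 2L, 3L, leaf_ids),
    parent_id = c(NA_integer_, 1L, 1L,
                  rep(c(2L, 3L), each = nsh)),
    name = c("root", "left hemisphere", "right hemisphere",
             paste0("structure ", rep(c("L", "R"), each = nsh),
                    rep(seq_len(nsh), 2))),
    acronym = c("root", "LH", "RH",
                paste0(rep(c("L", "R"), each = nsh), rep(seq_len(nsh), 2))),
    hemisphere = c(NA, "left", "right", rep(c("left", "right"), each = nsh))
  )
  lab <- array(0L, dims)
  half <- dims[1] %/% 2
  ybreaks <- floor(seq(0, dims[2], length.out = nsh + 1))
  for (s in seq_len(nsh)) {
    yy <- (ybreaks[s] + 1):ybreaks[s + 1]
    lab[1:half, yy, ] <- leaf_ids[s]
    lab[(half + 1):dims[1], yy, ] <- leaf_ids[nsh + s]
  }
  step <- as.integer(section_interval / grid_voxel)
  planes <- seq.int(1L, dims[3], by = step)
  with_seed(seed, {
    placed <- tibble(plaque_id = integer(0), structure_id = integer(0),
                     i = integer(0), j = integer(0), k = integer(0),
                     extent = integer(0))
    for (p in seq_len(n_plaques)) {
      for (try in 1:2000) {
        k <- sample(planes, 1)
        i <- sample.int(dims[1] - extent, 1)
        j <- sample.int(dims[2] - extent, 1)
        # keep a 1-voxel moat so separate plaques never touch in-plane,
        # and keep each plaque inside a single structure so the planted
        # per-structure assignment is unambiguous
        clash <- placed$k == k &
          abs(placed$i - i) <= extent & abs(placed$j - j) <= extent
        foot <- lab[i:(i + extent - 1L), j:(j + extent - 1L), k]
        if (!any(clash) && length(unique(as.integer(foot))) == 1L &&
            foot[1] != 0L) {
          break
        }
        if (try == 2000) abort("could not place plaques without contact")
      }
      placed <- dplyr::bind_rows(placed, tibble(
        plaque_id = p, structure_id = lab[i, j, k],
        i = i, j = j, k = k, extent = as.integer(extent)
      ))
    }
    atlas_truth(lab, ontology, placed, section_interval,
                lateral_pixel_size, grid_voxel)
  })
}

#' Render full-resolution section masks from an atlas truth
#'
#' Each sampled section plane becomes a full-resolution binary mask in
#' which every pixel mapping into a planted plaque's grid-voxel footprint
#' is positive, so voxelization recovers the planted objects exactly.
#'
#' @param truth an [atlas_truth()].
#' @param seed integer seed (kept for interface symmetry; rendering is
#'   deterministic).
#' @return a list of class `synthetic_atlas_sections`: `sections` (list of
#'   `list(mask, z)`), `label_volume`, `ontology`, `params` (a matching
#'   [grid_params()]), and `truth` (per-plaque and per-structure tables).
#' @export
make_atlas_sections <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "atlas_truth"))
  dims <- dim(truth$label_volume)
  ratio <- truth$lateral_pixel_size / truth$grid_voxel
  npx <- ceiling(dims[1] / ratio)
  npy <- ceiling(dims[2] / ratio)
  # pixel -> grid-voxel map, identical to the one voxelization applies
  pix2vox_x <- floor((seq_len(npx) - 1L) * ratio) + 1L
  pix2vox_y <- floor((seq_len(npy) - 1L) * ratio) + 1L
  step <- as.integer(truth$section_interval / truth$grid_voxel)
  planes <- seq.int(1L, dims[3], by = step)
  sections <- lapply(planes, function(k) {
    mask <- matrix(FALSE, npx, npy)
    pp <- truth$planted_plaques
    pp <- pp[pp$k == k, , drop = FALSE]
    for (r in seq_len(nrow(pp))) {
      px <- which(pix2vox_x %in% (pp$i[r]:(pp$i[r] + pp$extent[r] - 1L)))
      py <- which(pix2vox_y %in% (pp$j[r]:(pp$j[r] + pp$extent[r] - 1L)))
      mask[px, py] <- TRUE
    }
    list(mask = mask, z = (k - 1L) * truth$grid_voxel)
  })
  per_structure <- truth$planted_plaques |>
    dplyr::count(.data$structure_id, name = "plaque_count")
  params <- grid_params(grid_voxel = truth$grid_voxel,
                        lateral_pixel = truth$lateral_pixel_size,
                        section_interval = truth$section_interval)
  structure(list(sections = sections,
                 label_volume = truth$label_volume,
                 ontology = truth$ontology,
                 params = params,
                 truth = list(plaques = truth$planted_plaques,
                              per_structure = per_structure)),
            class = "synthetic_atlas_sections")
}
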