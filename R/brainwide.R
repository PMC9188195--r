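#' Parameters for brain-wide plaque gridding
#'
#' Defaults mirror standard serial block-face acquisition: 0.35 um lateral
#' pixels, a 100 um sectioning interval, and a 10 um isotropic summary
#' grid. Because the sectioning interval exceeds the grid voxel, plaque
#' objects can never span two sections: the z resolution limit for
#' separating plaques equals the sectioning interval.
#'
#' @param grid_voxel summary grid voxel edge, um.
#' @param lateral_pixel full-resolution lateral pixel size, um.
#' @param section_interval spacing between imaged sections, um
#'   (>= `grid_voxel`).
#' @param connectivity `"face6"` (adjacent and orthogonally adjacent voxels,
#'   the default) or `"full26"`.
#' @param hemisphere `"both"`, `"left"` or `"right"`; restricts
#'   summarization to structures of one hemisphere when the ontology
#'   carries a `hemisphere` column.
#' @return a list of class `grid_params`.
#' @export
grid_params <- function(grid_voxel = 10, lateral_pixel = 0.35,
                        section_interval = 100,
                        connectivity = c("face6", "full26"),
                        hemisphere = c("both", "left", "right")) {
  connectivity <- match.arg(connectivity)
  hemisphere <- match.arg(hemisphere)
  stopifnot(grid_voxel > 0, section_interval >= grid_voxel,
            lateral_pixel < grid_voxel)
  structure(list(grid_voxel = grid_voxel, lateral_pixel = lateral_pixel,
                 section_interval = section_interval,
                 connectivity = connectivity, hemisphere = hemisphere),
            class = "grid_params")
}

#' Voxelize per-section segmentation masks onto an isotropic grid
#'
#' Full-resolution pixel `(i, j)` (0-based) of the section at depth `z`
#' maps to grid voxel `(floor(i * lateral / grid), floor(j * lateral /
#' grid), floor(z / grid))`; each grid voxel stores the number of
#' signal-positive pixels mapped into it, so total signal is conserved.
#'
#' @param sections list of `list(mask = <logical matrix>, z = <um>)`;
#'   section depths must be multiples of the sectioning interval.
#' @param params a [grid_params()].
#' @param dims optional grid dimensions `c(nx, ny, nz)`; defaults to the
#'   smallest grid covering all sections.
#' @return a list of class `signal_grid`: `counts` (3D integer array),
#'   `grid_voxel`, and `z_sections` (tibble mapping grid z-planes to
#'   section depths).
#' @export
voxelize_sections <- function(sections, params = grid_params(), dims = NULL) {
  stopifnot(length(sections) >= 1)
  zs <- vapply(sections, function(s) s$z, numeric(1))
  if (any(zs %% params$section_interval != 0)) {
    abort("section z positions must be multiples of the section interval")
  }
  shp <- dim(sections[[1]]$mask)
  if (!all(vapply(sections, function(s) identical(dim(s$mask), shp),
                  logical(1)))) {
    abort("all section masks must share the same shape")
  }
  ratio <- params$lateral_pixel / params$grid_voxel
  if (is.null(dims)) {
    dims <- c(floor((shp[1] - 1) * ratio) + 1L,
              floor((shp[2] - 1) * ratio) + 1L,
              max(floor(zs / params$grid_voxel)) + 1L)
  }
  counts <- array(0L, dims)
  for (s in sections) {
    pos <- which(s$mask, arr.ind = TRUE)
    if (nrow(pos) == 0) next
    gi <- floor((pos[, 1] - 1L) * ratio) + 1L
    gj <- floor((pos[, 2] - 1L) * ratio) + 1L
    gk <- floor(s$z / params$grid_voxel) + 1L
    lin <- gi + dims[1] * (gj - 1L) + dims[1] * dims[2] * (gk - 1L)
    tab <- table(lin)
    ii <- as.integer(names(tab))
    counts[ii] <- counts[ii] + as.integer(tab)
  }
  structure(list(counts = counts, grid_voxel = params$grid_voxel,
                 z_sections = tibble(z_plane = floor(zs / params$grid_voxel) + 1L,
                                     z_um = zs)),
            class = "signal_grid")
}

#' @export
print.signal_grid <- function(x, ...) {
  cat(sprintf("<signal_grid> %s voxels @ %g um, %d positive, %d signal px\n",
              paste(dim(x$counts), collapse = " x "), x$grid_voxel,
              sum(x$counts > 0), sum(x$counts)))
  invisible(x)
}

#' Group signal voxels into plaque objects
#'
#' Connected components of the signal-positive grid voxels under the
#' configured connectivity ("adjacent and orthogonally adjacent" = face
#' adjacency by default). With default geometry the sectioning interval
#' exceeds the grid voxel, so components never span sections.
#'
#' @param grid a [voxelize_sections()] result.
#' @param params a [grid_params()].
#' @return tibble with one row per object: `object_id`, `n_voxels`,
#'   `summed_signal` (positive pixels), centroid voxel indices
#'   `ci, cj, ck`, and a `voxels` list-column of linear voxel indices.
#' @export
label_plaques <- function(grid, params = grid_params()) {
  conn <- if (params$connectivity == "face6") "face" else "full"
  lab <- label_components(grid$counts > 0L, conn)
  n <- max(lab)
  if (n == 0) {
    return(tibble(object_id = integer(0), n_voxels = integer(0),
                  summed_signal = integer(0), ci = integer(0),
                  cj = integer(0), ck = integer(0), voxels = list()))
  }
  pos <- which(lab > 0L)
  coords <- arrayInd(pos, dim(lab))
  lv <- lab[pos]
  tibble(
    object_id = seq_len(n),
    n_voxels = as.integer(tabulate(lv, n)),
    summed_signal = as.integer(
      vapply(split(grid$counts[pos], lv), sum, numeric(1))),
    ci = as.integer(round(vapply(split(coords[, 1], lv), mean, numeric(1)))),
    cj = as.integer(round(vapply(split(coords[, 2], lv), mean, numeric(1)))),
    ck = as.integer(round(vapply(split(coords[, 3], lv), mean, numeric(1)))),
    voxels = split(pos, lv)
  )
}

#' Per-structure signal, plaque counts and densities
#'
#' Signal and volume are summed per atlas structure; each plaque object is
#' assigned to one structure, by the atlas label under its centroid voxel
#' (default) or by majority vote over its voxels. Density is reported both
#' raw (`plaques_per_mm3 = count / structure volume`) and with the
#' z-sampling correction factor `section_interval / grid_voxel`
#' (`plaques_per_mm3_corrected`), since only a fraction `grid /
#' section_interval` of each structure's depth is sampled by the sections.
#' Objects whose assigned label is 0 are reported under `structure_id = 0`
#' ("unassigned").
#'
#' @param grid a [voxelize_sections()] result.
#' @param objects a [label_plaques()] table.
#' @param atlas integer label array, grid-aligned with `grid$counts`.
#' @param ontology tibble with columns `id`, `parent_id`, `name` (optional
#'   `acronym`, `hemisphere`).
#' @param params a [grid_params()].
#' @param assign `"centroid"` or `"majority"`.
#' @return tibble with one row per structure present in the atlas (plus an
#'   unassigned bucket when needed), `rolled_up = FALSE`.
#' @export
structure_summary <- function(grid, objects, atlas, ontology,
                              params = grid_params(),
                              assign = c("centroid", "majority")) {
  assign <- match.arg(assign)
  if (!identical(dim(atlas), dim(grid$counts))) {
    abort("atlas must be grid-aligned (same dimensions as the signal grid)")
  }
  atlas <- restrict_hemisphere(atlas, ontology, params$hemisphere)
  ids <- sort(setdiff(unique(as.integer(atlas)), 0L))

  obj_struct <- if (nrow(objects) == 0) {
    integer(0)
  } else if (assign == "centroid") {
    atlas[cbind(objects$ci, objects$cj, objects$ck)]
  } else {
    vapply(objects$voxels, function(v) {
      labs <- atlas[v]
      as.integer(names(which.max(table(labs))))
    }, integer(1))
  }
  vox_mm3 <- (grid$grid_voxel / 1e3)^3
  corr <- params$section_interval / params$grid_voxel

  all_ids <- ids
  if (any(obj_struct == 0L)) all_ids <- c(0L, all_ids)
  rows <- purrr::map(all_ids, function(id) {
    in_s <- atlas == id
    nvox <- sum(in_s)
    vol <- nvox * vox_mm3
    cnt <- sum(obj_struct == id)
    tibble(
      structure_id = id,
      structure_name = structure_name(id, ontology),
      signal_voxels = sum(in_s & grid$counts > 0L),
      summed_signal = sum(grid$counts[in_s]),
      structure_volume_mm3 = vol,
      plaque_count = cnt,
      plaques_per_mm3 = if (vol > 0) cnt / vol else NA_real_,
      plaques_per_mm3_corrected = if (vol > 0) cnt / vol * corr else NA_real_,
      sampling_corrected_factor = corr,
      rolled_up = FALSE
    )
  })
  dplyr::bind_rows(rows)
}

structure_name <- function(id, ontology) {
  if (id == 0L) return("unassigned")
  nm <- ontology$name[match(id, ontology$id)]
  if (is.na(nm)) paste0("structure_", id) else nm
}

restrict_hemisphere <- function(atlas, ontology, hemisphere) {
  if (hemisphere == "both" || is.null(ontology$hemisphere)) return(atlas)
  keep <- ontology$id[!is.na(ontology$hemisphere) &
                        ontology$hemisphere == hemisphere]
  atlas[!(atlas %in% keep)] <- 0L
  atlas
}

#' Roll structure summaries up an atlas ontology
#'
#' Every internal node of the ontology tree receives the sums of signal,
#' volume and plaque count over its descendant structures that appear in
#' the leaf summaries, and its densities are recomputed from those sums.
#' Leaf rows are returned unchanged (`rolled_up = FALSE`); ancestor rows
#' are appended with `rolled_up = TRUE`.
#'
#' @param summaries a [structure_summary()] table (leaf level).
#' @param ontology tibble with `id`, `parent_id`, `name`; `parent_id` is
#'   `NA` at the root. Links must form a rooted tree.
#' @return tibble of leaf plus ancestor rows.
#' @export
rollup_ontology <- function(summaries, ontology) {
  kids <- split(ontology$id, factor(ontology$parent_id,
                                    levels = ontology$id))
  desc_leaves <- function(id) {
    ch <- kids[[as.character(id)]]
    if (is.null(ch) || length(ch) == 0) return(id)
    unlist(lapply(ch, desc_leaves))
  }
  leaf_ids <- summaries$structure_id
  internal <- ontology$id[vapply(as.character(ontology$id),
                                 function(k) length(kids[[k]]) > 0,
                                 logical(1))]
  corr <- if (nrow(summaries) > 0) summaries$sampling_corrected_factor[1] else 1
  rows <- purrr::map(internal, function(id) {
    lv <- intersect(desc_leaves(id), leaf_ids)
    sub <- summaries[summaries$structure_id %in% lv, ]
    vol <- sum(sub$structure_volume_mm3)
    cnt <- sum(sub$plaque_count)
    tibble(
      structure_id = id,
      structure_name = structure_name(id, ontology),
      signal_voxels = sum(sub$signal_voxels),
      summed_signal = sum(sub$summed_signal),
      structure_volume_mm3 = vol,
      plaque_count = cnt,
      plaques_per_mm3 = if (vol > 0) cnt / vol else NA_real_,
      plaques_per_mm3_corrected = if (vol > 0) cnt / vol * corr else NA_real_,
      sampling_corrected_factor = corr,
      rolled_up = TRUE
    )
  })
  dplyr::bind_rows(c(list(summaries), rows))
}
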