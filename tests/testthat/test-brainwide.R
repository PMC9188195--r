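make_grid <- function(counts, grid_voxel = 10) {
  structure(list(counts = counts, grid_voxel = grid_voxel,
                 z_sections = tibble::tibble()), class = "signal_grid")
}

test_that("voxelization bins pixels and conserves total signal", {
  p <- grid_params(grid_voxel = 10, lateral_pixel = 0.5,
                   section_interval = 100)
  mask <- matrix(FALSE, 60, 60)
  mask[1:10, 1:10] <- TRUE # 100 px inside voxel (1,1)
  g <- voxelize_sections(list(list(mask = mask, z = 0)), p)
  expect_equal(g$counts[1, 1, 1], 100L)
  expect_equal(sum(g$counts), 100L)

  # conservation and agreement with a direct per-pixel binning oracle
  set.seed(3)
  m1 <- matrix(runif(3600) < 0.01, 60, 60)
  m2 <- matrix(runif(3600) < 0.02, 60, 60)
  g2 <- voxelize_sections(list(list(mask = m1, z = 0),
                               list(mask = m2, z = 100)), p)
  expect_equal(sum(g2$counts), sum(m1) + sum(m2))
  oracle <- array(0L, dim(g2$counts))
  for (s in list(list(m = m1, z = 0), list(m = m2, z = 100))) {
    pos <- which(s$m, arr.ind = TRUE)
    for (r in seq_len(nrow(pos))) {
      i <- floor((pos[r, 1] - 1) * 0.5 / 10) + 1
      j <- floor((pos[r, 2] - 1) * 0.5 / 10) + 1
      k <- floor(s$z / 10) + 1
      oracle[i, j, k] <- oracle[i, j, k] + 1L
    }
  }
  expect_identical(g2$counts, oracle)
  expect_error(voxelize_sections(list(list(mask = m1, z = 37)), p),
               "multiples")
})

test_that("plaque objects follow the connectivity and z-resolution rules", {
  cnt <- array(0L, c(12, 12, 21))
  # two face-adjacent voxels in one plane: one object
  cnt[3, 3, 1] <- 5L
  cnt[4, 3, 1] <- 2L
  # signal on consecutive sampled sections (10 layers apart): two objects
  cnt[8, 8, 1] <- 1L
  cnt[8, 8, 11] <- 1L
  obj <- label_plaques(make_grid(cnt), grid_params(lateral_pixel = 0.5))
  expect_equal(nrow(obj), 3)
  expect_setequal(obj$summed_signal, c(7L, 1L, 1L))

  # diagonal voxels: separate under face6, merged under full26
  cnt2 <- array(0L, c(5, 5, 1))
  cnt2[2, 2, 1] <- 1L
  cnt2[3, 3, 1] <- 1L
  expect_equal(nrow(label_plaques(make_grid(cnt2),
                                  grid_params(lateral_pixel = 0.5,
                                              connectivity = "face6"))), 2)
  expect_equal(nrow(label_plaques(make_grid(cnt2),
                                  grid_params(lateral_pixel = 0.5,
                                              connectivity = "full26"))), 1)
})

test_that("component count equals the flood-fill oracle on random grids", {
  set.seed(13)
  for (rep in 1:5) {
    cnt <- array(as.integer(runif(8 * 7 * 6) < 0.3), c(8, 7, 6))
    for (conn in c("face6", "full26")) {
      obj <- label_plaques(make_grid(cnt),
                           grid_params(lateral_pixel = 0.5,
                                       connectivity = conn))
      want <- max(oracle_label_components(cnt > 0, full = conn == "full26"))
      expect_equal(nrow(obj), want)
    }
  }
})

test_that("per-structure summaries compute volumes and densities", {
  atlas <- array(1L, c(10, 10, 10)) # one structure, 1000 voxels = 1e-3 mm3
  ont <- tibble::tibble(id = 1L, parent_id = NA_integer_, name = "s")
  cnt <- array(0L, c(10, 10, 10))
  cnt[2, 2, 1] <- 1L
  cnt[8, 8, 1] <- 1L
  g <- make_grid(cnt)
  p <- grid_params(lateral_pixel = 0.5)
  obj <- label_plaques(g, p)
  ss <- structure_summary(g, obj, atlas, ont, p)
  expect_equal(ss$plaque_count, 2)
  expect_equal(ss$structure_volume_mm3, 1e-3)
  expect_equal(ss$plaques_per_mm3, 2000)
  expect_equal(ss$plaques_per_mm3_corrected, 2000 * 10)
  # empty grid: zeros everywhere
  ss0 <- structure_summary(make_grid(array(0L, c(10, 10, 10))),
                           label_plaques(make_grid(array(0L, c(10, 10, 10))),
                                         p),
                           atlas, ont, p)
  expect_equal(ss0$plaque_count, 0)
  expect_equal(ss0$summed_signal, 0L)
})

test_that("ontology rollup sums descendants and recomputes density", {
  ont <- tibble::tibble(
    id = c(1L, 2L, 3L, 4L, 5L),
    parent_id = c(NA, 1L, 1L, 3L, 3L),
    name = c("root", "leafA", "mid", "leafB", "leafC")
  )
  leaves <- tibble::tibble(
    structure_id = c(2L, 4L, 5L),
    structure_name = c("leafA", "leafB", "leafC"),
    signal_voxels = c(1L, 2L, 0L),
    summed_signal = c(10L, 20L, 0L),
    structure_volume_mm3 = c(0.001, 0.002, 0.001),
    plaque_count = c(1L, 2L, 0L),
    plaques_per_mm3 = c(1000, 1000, 0),
    plaques_per_mm3_corrected = c(10000, 10000, 0),
    sampling_corrected_factor = 10,
    rolled_up = FALSE
  )
  ru <- rollup_ontology(leaves, ont)
  mid <- ru[ru$structure_id == 3L, ]
  expect_equal(mid$plaque_count, 2L)
  expect_equal(mid$structure_volume_mm3, 0.003)
  expect_equal(mid$plaques_per_mm3, 2 / 0.003)
  root <- ru[ru$structure_id == 1L, ]
  expect_equal(root$plaque_count, 3L)
  expect_equal(root$summed_signal, 30L)
  # brute-force descendant summation oracle over the whole tree
  desc <- list(`1` = c(2L, 4L, 5L), `3` = c(4L, 5L))
  for (id in names(desc)) {
    want <- sum(leaves$plaque_count[leaves$structure_id %in% desc[[id]]])
    expect_equal(ru$plaque_count[ru$structure_id == as.integer(id)], want)
  }
})

test_that("single-leaf trees roll up to an identical parent", {
  ont <- tibble::tibble(id = c(1L, 2L), parent_id = c(NA, 1L),
                        name = c("root", "leaf"))
  leaves <- tibble::tibble(
    structure_id = 2L, structure_name = "leaf", signal_voxels = 3L,
    summed_signal = 30L, structure_volume_mm3 = 0.004, plaque_count = 3L,
    plaques_per_mm3 = 750, plaques_per_mm3_corrected = 7500,
    sampling_corrected_factor = 10, rolled_up = FALSE
  )
  ru <- rollup_ontology(leaves, ont)
  root <- ru[ru$structure_id == 1L, ]
  for (col in c("signal_voxels", "summed_signal", "structure_volume_mm3",
                "plaque_count", "plaques_per_mm3")) {
    expect_equal(root[[col]], leaves[[col]])
  }
})

test_that("planted plaques are recovered per structure, end to end", {
  at <- random_atlas_truth(dims = c(20, 20, 30), n_plaques = 8, seed = 5)
  sa <- make_atlas_sections(at)
  g <- voxelize_sections(sa$sections, sa$params,
                         dims = dim(sa$label_volume))
  obj <- label_plaques(g, sa$params)
  expect_equal(nrow(obj), 8)
  ss <- structure_summary(g, obj, sa$label_volume, sa$ontology, sa$params)
  got <- ss[ss$plaque_count > 0, c("structure_id", "plaque_count")]
  want <- sa$truth$per_structure
  expect_equal(dplyr::arrange(got, structure_id)$plaque_count,
               dplyr::arrange(want, structure_id)$plaque_count)
  # density equals planted count / known structure volume
  vox_mm3 <- (sa$params$grid_voxel / 1e3)^3
  for (r in seq_len(nrow(want))) {
    vol <- sum(sa$label_volume == want$structure_id[r]) * vox_mm3
    expect_equal(
      ss$plaques_per_mm3[ss$structure_id == want$structure_id[r]],
      want$plaque_count[r] / vol
    )
  }
  # conservation: leaf counts total the object count
  expect_equal(sum(ss$plaque_count), nrow(obj))
  # no object spans two sections under default geometry
  ks <- vapply(obj$voxels, function(v) {
    length(unique(arrayInd(v, dim(g$counts))[, 3]))
  }, numeric(1))
  expect_true(all(ks == 1))
})

test_that("hemisphere masking commutes with summarization", {
  at <- random_atlas_truth(dims = c(20, 20, 30), n_plaques = 8, seed = 8)
  sa <- make_atlas_sections(at)
  g <- voxelize_sections(sa$sections, sa$params,
                         dims = dim(sa$label_volume))
  obj <- label_plaques(g, sa$params)
  p_left <- grid_params(lateral_pixel = sa$params$lateral_pixel,
                        hemisphere = "left")
  # route 1: restrict during summarization
  ss_left <- structure_summary(g, obj, sa$label_volume, sa$ontology, p_left)
  # route 2: summarize everything, then filter structures by hemisphere
  ss_all <- structure_summary(g, obj, sa$label_volume, sa$ontology,
                              sa$params)
  left_ids <- sa$ontology$id[!is.na(sa$ontology$hemisphere) &
                               sa$ontology$hemisphere == "left"]
  a <- ss_left[ss_left$structure_id %in% left_ids,
               c("structure_id", "plaque_count", "summed_signal")]
  b <- ss_all[ss_all$structure_id %in% left_ids,
              c("structure_id", "plaque_count", "summed_signal")]
  expect_equal(as.data.frame(a), as.data.frame(b))
})
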