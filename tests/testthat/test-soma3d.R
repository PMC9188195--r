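test_that("local-mean resampling pools blocks exactly", {
  # identity when already at the target
  v <- volume3d(array(runif(8 * 8 * 4), c(8, 8, 4)), 0.5)
  expect_equal(resample_isotropic(v, 0.5)$data, v$data)

  # 2x2x2 block of 1..8 pools to its mean, 4.5
  v2 <- volume3d(array(1:8, c(2, 2, 2)), 1)
  out <- resample_isotropic(v2, 2)
  expect_equal(dim(out$data), c(1, 1, 1))
  expect_equal(out$data[1, 1, 1], 4.5)

  # conservation: means agree exactly for integer pooling factors
  set.seed(2)
  v3 <- volume3d(array(runif(6 * 4 * 8), c(6, 4, 8)), c(1, 1, 0.5))
  out3 <- resample_isotropic(v3, 2)
  expect_equal(dim(out3$data), c(3, 2, 2))
  expect_equal(mean(out3$data), mean(v3$data))
})

test_that("gaussian background subtraction behaves on flats and spheres", {
  flat <- volume3d(array(42, c(12, 12, 12)), 1)
  expect_lt(max(subtract_background(flat, 4)$data), 1e-9)

  # bright sphere on a flat offset: sphere survives, background ~ 0
  d <- 20
  ctr <- (1:d) - 0.5
  X <- array(rep(ctr, d * d), c(d, d, d))
  Y <- array(rep(rep(ctr, each = d), d), c(d, d, d))
  Z <- array(rep(ctr, each = d * d), c(d, d, d))
  sph <- (X - 10)^2 + (Y - 10)^2 + (Z - 10)^2 <= 9
  vol <- volume3d(20 + 100 * sph, 1)
  out <- subtract_background(vol, 5)
  expect_true(all(out$data >= 0))
  far <- (X - 10)^2 + (Y - 10)^2 + (Z - 10)^2 > 64
  expect_lt(max(out$data[far]), 10)
  expect_gt(max(out$data[sph]), 50)
  expect_error(subtract_background(volume3d(array(0, c(4, 4, 4)),
                                            c(1, 1, 2)), 4),
               "anisotropic")
})

test_that("random walker respects seeds and reduces to thresholding", {
  # no intermediate voxels: equals the simple high threshold
  x <- array(sample(c(0, 100), 125, TRUE), c(5, 5, 5))
  v <- volume3d(x, 1)
  seg <- segment_microglia(v, low = 10, high = 90)
  expect_identical(seg$data, array(x > 90, dim(x)))

  # seed preservation on a noisy volume with intermediates
  set.seed(9)
  x2 <- array(runif(6^3, 0, 1), c(6, 6, 6))
  v2 <- volume3d(x2, 1)
  seg2 <- segment_microglia(v2, low = 0.2, high = 0.8)
  expect_true(all(seg2$data[x2 > 0.8]))
  expect_true(!any(seg2$data[x2 < 0.2]))

  expect_warning(segment_microglia(volume3d(array(0, c(3, 3, 3)), 1),
                                   0.2, 0.8),
                 "empty mask")
  expect_warning(segment_microglia(volume3d(array(1, c(3, 3, 3)), 1),
                                   0.2, 0.8),
                 "full mask")
})

test_that("random walker splits a linear ramp at its midpoint", {
  # even number of unseeded voxels, so the midplane falls between voxels
  # and no probability sits exactly on the 0.5 decision boundary
  n <- 20
  ramp <- array(seq(0, 1, length.out = n), c(n, 1, 1))
  v <- volume3d(ramp, 1)
  seg <- segment_microglia(v, low = 0.04, high = 0.96, rw_diffusion = 10)
  got <- as.logical(seg$data[, 1, 1])
  expect_identical(got, (1:n) >= 11)

  # the interior probabilities solve the 1D Dirichlet problem: compare
  # against the exact solution of the small tridiagonal system
  x <- as.numeric(ramp)
  g <- (x - min(x)) / diff(range(x))
  w <- exp(-10 * diff(g)^2)
  und <- 2:(n - 1)
  A <- matrix(0, length(und), length(und))
  b <- numeric(length(und))
  for (ii in seq_along(und)) {
    i <- und[ii]
    A[ii, ii] <- w[i - 1] + w[i]
    if (ii > 1) A[ii, ii - 1] <- -w[i - 1]
    if (ii < length(und)) A[ii, ii + 1] <- -w[i]
  }
  b[length(und)] <- w[n - 1] * 1
  prob <- solve(A, b)
  got_fg <- got[und]
  expect_identical(got_fg, prob >= 0.5)
  # symmetry: the solution is antisymmetric about the midpoint
  expect_equal(prob + rev(prob), rep(1, length(prob)), tolerance = 1e-10)
})

test_that("soma detection follows the diameter and spacing rules", {
  mk <- function(centers, diam = 8) {
    vt <- volume_truth(c(40, 40, 20), 1, soma_centers = centers,
                       soma_diameters = diam)
    surface_threshold(make_volume(vt, seed = 1)$channels$iba1, 50)
  }
  # one 8 um sphere (centred on a voxel centre): one peak at its centre
  pk <- detect_somata(mk(rbind(c(20.5, 20.5, 10.5))), 7, 10)
  expect_equal(nrow(pk), 1)
  expect_equal(unlist(pk[1, c("x", "y", "z")]), c(x = 20.5, y = 20.5,
                                                  z = 10.5))
  # a 5 um sphere is below the 7 um diameter rule
  expect_equal(nrow(detect_somata(mk(rbind(c(20.5, 20.5, 10.5)), diam = 5),
                                  7, 10)), 0)
  # spacing: 9 um apart -> 1 peak; 15 um apart -> 2 peaks
  expect_equal(nrow(detect_somata(mk(rbind(c(14.5, 20.5, 10.5),
                                           c(23.5, 20.5, 10.5))),
                                  7, 10)), 1)
  expect_equal(nrow(detect_somata(mk(rbind(c(12.5, 20.5, 10.5),
                                           c(27.5, 20.5, 10.5))),
                                  7, 10)), 2)
  # empty mask -> empty list
  expect_equal(nrow(detect_somata(volume3d(array(0, c(5, 5, 5)), 1))), 0)
})

test_that("peak count is monotone in diameter and spacing", {
  vt <- volume_truth(c(60, 60, 20), 1,
                     soma_centers = rbind(c(12, 12, 10), c(25, 14, 10),
                                          c(40, 40, 10), c(50, 20, 10)),
                     soma_diameters = c(8, 9, 10, 8))
  mask <- surface_threshold(make_volume(vt, seed = 1)$channels$iba1, 50)
  n_by_diam <- vapply(c(5, 7, 9, 11),
                      function(d) nrow(detect_somata(mask, d, 10)),
                      numeric(1))
  expect_true(all(diff(n_by_diam) <= 0))
  n_by_space <- vapply(c(5, 10, 20, 40),
                       function(s) nrow(detect_somata(mask, 7, s)),
                       numeric(1))
  expect_true(all(diff(n_by_space) <= 0))
})

test_that("cell assignment partitions the mask", {
  # single peak: everything connected takes label 1; two disconnected
  # blobs with their own peaks keep their own labels
  vt <- volume_truth(c(40, 20, 16), 1,
                     soma_centers = rbind(c(10, 10, 8), c(30, 10, 8)),
                     soma_diameters = 8)
  mask <- surface_threshold(make_volume(vt, seed = 1)$channels$iba1, 50)
  pk <- detect_somata(mask, 7, 10)
  lab <- assign_cells(mask, pk)
  m <- mask$data > 0
  expect_true(all(lab[m] > 0))
  expect_true(all(lab[!m] == 0))
  blobs <- label_components(m, "face")
  for (b in 1:2) {
    expect_equal(length(unique(lab[blobs == b])), 1)
  }
  expect_warning(out <- assign_cells(mask, pk[0, ]), "no peaks")
  expect_true(all(out == 0L))
})

test_that("methoxy content and plaque proximity recover planted truth", {
  vt <- volume_truth(c(60, 30, 24), 1,
                     soma_centers = rbind(c(12, 15, 12), c(30, 15, 12),
                                          c(48, 15, 12)),
                     soma_diameters = 8,
                     methoxy_fraction_per_cell = c(0.5, 0, 0.3),
                     plaque_centers = rbind(c(12, 25, 12)),
                     plaque_radii = 4)
  sv <- make_volume(vt, seed = 2)
  mask <- surface_threshold(sv$channels$iba1, 50)
  pk <- detect_somata(mask, 7, 10)
  lab <- assign_cells(mask, pk)
  cls <- classify_cells(lab, sv$masks$methoxy, sv$masks$abeta,
                        soma3d_params(proximity_um = 10), voxel_size = 1)
  expect_equal(cls$summary$n_cells, 3)
  expect_equal(cls$summary$frac_methoxy_positive, 2 / 3)
  # cell 1 sits ~2 um from the plaque surface: proximal; others are not
  ord <- order(cls$cells$soma_id)
  pos <- cls$cells$methoxy_positive[ord]
  expect_equal(sum(pos), 2)
  prox <- cls$cells$proximal_to_plaque[ord]
  expect_equal(sum(prox), 1)
  expect_equal(cls$summary$frac_positive_proximal, 1 / 2)
  # methoxy overlap is a plain voxel intersection per cell
  expect_equal(sort(cls$cells$methoxy_overlap_voxels),
               sort(sv$cells$methoxy_voxels))
  # empty methoxy mask -> 0% positive
  cls0 <- classify_cells(lab, array(FALSE, dim(lab)), sv$masks$abeta,
                         soma3d_params(), voxel_size = 1)
  expect_equal(cls0$summary$frac_methoxy_positive, 0)
})
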