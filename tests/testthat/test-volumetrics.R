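test_that("noiseless three-level phantom segments to exact indicator volumes", {
  sp <- structural_phantom_spec(dims = c(48, 48, 48), voxel_size = c(4, 4, 4),
                                semiaxes_mm = c(78, 88, 72), noise_sd = 0,
                                edge_mm = 0)
  pair <- generate_structural_pair(sp)
  seg <- segment_tissues(pair$vol1, pair$brain_mask)
  tv <- tissue_volumes(seg, prod(sp$voxel_size))
  tru <- pair$truth$volumes
  expect_equal(tv$csf_ml, tru$volume_ml[tru$session == "pre" & tru$tissue == "csf"])
  expect_equal(tv$gm_ml, tru$volume_ml[tru$session == "pre" & tru$tissue == "gm"])
  expect_equal(tv$wm_ml, tru$volume_ml[tru$session == "pre" & tru$tissue == "wm"])
})

test_that("1% intensity noise keeps per-tissue volume error under 1%", {
  sp <- structural_phantom_spec(noise_sd = 10, edge_mm = 0)
  pair <- generate_structural_pair(sp, seed = 4)
  seg <- segment_tissues(pair$vol1, pair$brain_mask)
  tv <- tissue_volumes(seg, prod(sp$voxel_size))
  tru <- pair$truth$volumes
  for (tis in c("csf", "gm", "wm")) {
    t_ml <- tru$volume_ml[tru$session == "pre" & tru$tissue == tis]
    e_ml <- tv[[paste0(tis, "_ml")]]
    expect_lt(abs(e_ml - t_ml) / t_ml, 0.01)
  }
})

test_that("segmentation rejects degenerate intensity distributions", {
  two <- array(rep(c(1, 2), 500), c(10, 10, 10))
  expect_error(segment_tissues(two, array(TRUE, dim(two))), "three intensity")
  expect_error(segment_tissues(two, array(FALSE, dim(two))), "empty")
})

test_that("tissue volumes are linear in partial volumes and intensity-invariant", {
  sp <- structural_phantom_spec(dims = c(48, 48, 48), voxel_size = c(4, 4, 4),
                                semiaxes_mm = c(78, 88, 72), noise_sd = 8)
  pair <- generate_structural_pair(sp, seed = 2)
  seg <- segment_tissues(pair$vol1, pair$brain_mask)
  tv <- tissue_volumes(seg, 64)
  # halving the GM fractions halves gm_ml
  seg2 <- seg
  seg2$gm <- seg$gm / 2
  expect_equal(tissue_volumes(seg2, 64)$gm_ml, tv$gm_ml / 2)
  # 1000 pure voxels of 27 mm^3 are 27 mL
  pure <- structure(list(csf = array(0, c(10, 10, 10)),
                         gm = array(1, c(10, 10, 10)),
                         wm = array(0, c(10, 10, 10)),
                         mask = array(TRUE, c(10, 10, 10))),
                    class = "tissue_segmentation")
  expect_equal(tissue_volumes(pure, 27)$gm_ml, 27)
  # affine intensity rescaling leaves volumes unchanged
  seg3 <- segment_tissues(pair$vol1 * 2.5 + 40, pair$brain_mask)
  tv3 <- tissue_volumes(seg3, 64)
  expect_equal(tv3$gm_ml, tv$gm_ml, tolerance = 5e-3)
  expect_equal(tv3$wm_ml, tv$wm_ml, tolerance = 5e-3)
})

test_that("identical volumes give exactly zero displacement and PBVC", {
  sp <- structural_phantom_spec(dims = c(40, 40, 40), voxel_size = c(3, 3, 3),
                                semiaxes_mm = 50, noise_sd = 0)
  pair <- generate_structural_pair(sp)
  ed <- edge_displacement(pair$vol1, pair$vol1, pair$brain_mask,
                          pair$voxel_size)
  expect_true(all(ed$points$displacement_mm == 0))
  expect_equal(pbvc(ed, sum(pair$brain_mask) * 27)$pbvc, 0)
})

test_that("uniform erosion of a sphere matches the analytic shell volume", {
  sp <- structural_phantom_spec(dims = c(50, 50, 50), voxel_size = c(3, 3, 3),
                                semiaxes_mm = 60, noise_sd = 0)
  pair <- generate_structural_pair(sp, atrophy_spec(boundary_shift_mm = -1.5))
  ed <- edge_displacement(pair$vol1, pair$vol2, pair$brain_mask,
                          pair$voxel_size)
  # sphere eroded by half a voxel: mean perpendicular displacement -1.5 mm
  expect_equal(mean(ed$points$displacement_mm), -1.5, tolerance = 0.1)
  res <- pbvc(ed, sum(pair$brain_mask) * prod(pair$voxel_size))
  analytic <- ((58.5 / 60)^3 - 1) * 100
  expect_equal(analytic, -7.31, tolerance = 1e-3)
  expect_lt(abs(res$pbvc - analytic), 0.5)
  # uniform growth is positive
  grow <- generate_structural_pair(sp, atrophy_spec(boundary_shift_mm = 1.5))
  ed_g <- edge_displacement(grow$vol1, grow$vol2, grow$brain_mask,
                            grow$voxel_size)
  expect_gt(pbvc(ed_g, sum(grow$brain_mask) * 27)$pbvc, 0)
})

test_that("pure translation of the object yields near-zero net displacement", {
  sp <- structural_phantom_spec(dims = c(40, 40, 40), voxel_size = c(3, 3, 3),
                                semiaxes_mm = 45, noise_sd = 0)
  pair <- generate_structural_pair(sp)
  shifted <- array(0, dim(pair$vol1))
  shifted[2:40, , ] <- pair$vol1[1:39, , ]  # 3 mm shift along x
  ed <- edge_displacement(pair$vol1, shifted, pair$brain_mask,
                          pair$voxel_size)
  res <- pbvc(ed, sum(pair$brain_mask) * 27)
  # opposite faces cancel
  expect_lt(abs(res$mean_displacement_mm), 0.12)
})

test_that("PBVC is antisymmetric under swapping the time points", {
  sp <- structural_phantom_spec(dims = c(50, 50, 50), voxel_size = c(3, 3, 3),
                                semiaxes_mm = 60, noise_sd = 0)
  pair <- generate_structural_pair(sp, atrophy_spec(boundary_shift_mm = -0.75))
  sp2 <- structural_phantom_spec(dims = c(50, 50, 50), voxel_size = c(3, 3, 3),
                                 semiaxes_mm = 60 - 0.75, noise_sd = 0)
  mask2 <- generate_structural_pair(sp2)$brain_mask
  fwd <- pbvc(edge_displacement(pair$vol1, pair$vol2, pair$brain_mask, c(3, 3, 3)),
              sum(pair$brain_mask) * 27)$pbvc
  rev <- pbvc(edge_displacement(pair$vol2, pair$vol1, mask2, c(3, 3, 3)),
              sum(mask2) * 27)$pbvc
  expect_lt(fwd, 0)
  expect_gt(rev, 0)
  expect_equal(abs(rev) / abs(fwd), 1, tolerance = 0.05)
})

test_that("pbvc guards against too few edge points", {
  ed <- structure(list(points = tibble::tibble(
    i = 1:5, j = 1, k = 1, nx = 1, ny = 0, nz = 0, area_mm2 = 9,
    displacement_mm = 0
  ), n_dropped = 0, voxel_size = c(3, 3, 3)), class = "edge_point_set")
  expect_error(pbvc(ed, 1000), "too few")
})

test_that("lesion counting follows 26-connectivity and the size floor", {
  expect_equal(count_lesions(array(FALSE, c(5, 5, 5)))$n_lesions, 0)
  m <- array(FALSE, c(10, 10, 10))
  m[2:3, 2:3, 2:3] <- TRUE            # 8 voxels
  m[6:7, 6:7, 6:7] <- TRUE            # disjoint 8 voxels
  expect_equal(count_lesions(m, c(1, 1, 1), min_size_mm3 = 5)$n_lesions, 2)
  # corner-to-corner contact merges under 26-connectivity
  m2 <- array(FALSE, c(10, 10, 10))
  m2[2:3, 2:3, 2:3] <- TRUE
  m2[4:5, 4:5, 4:5] <- TRUE           # touches only at voxel corner (3,3,3)-(4,4,4)
  expect_equal(count_lesions(m2, c(1, 1, 1), min_size_mm3 = 5)$n_lesions, 1)
  # components under the size floor are ignored, order/labels irrelevant
  m3 <- m
  m3[9, 9, 9] <- TRUE                 # 1 mm^3 speck
  lc <- count_lesions(m3, c(1, 1, 1), min_size_mm3 = 5)
  expect_equal(lc$n_lesions, 2)
  expect_equal(sort(unlist(lc$sizes_mm3)), c(8, 8))
})

test_that("percent volume change reproduces the published per-subject rows", {
  expect_equal(percent_volume_change(733, 718), -2.05, tolerance = 1e-2)
  expect_equal(percent_volume_change(659, 659), 0)
  expect_equal(percent_volume_change(100, 200), 100)
  expect_error(percent_volume_change(0, 10), "positive")
})

test_that("full structural pair analysis recovers a 2.6% gray-matter loss", {
  sp <- structural_phantom_spec(noise_sd = 10)
  pair <- generate_structural_pair(sp, atrophy_spec(tissue_scale = c(gm = 0.974)),
                                   seed = 2)
  res <- analyze_volume_pair(pair$vol1, pair$vol2, pair$brain_mask,
                             pair$voxel_size)
  gm <- res$volumes[res$volumes$tissue == "gm", ]
  wm <- res$volumes[res$volumes$tissue == "wm", ]
  expect_equal(gm$pct_change, -2.6, tolerance = 0.3)
  expect_equal(wm$pct_change, 0, tolerance = 0.3)
})
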