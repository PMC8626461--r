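test_that("a straight tube skeletonizes to its centreline length and radius", {
  m <- tube_mask(c(21, 61, 21), c(1, 1, 1), 10, 10, 4)
  sk <- skeletonize_mask(m, c(1, 1, 1))
  expect_false(sk$degenerate)
  # tube spans the grid: 61 voxel centres, 60 um end to end, +/- 2 steps
  expect_lt(abs(sk$main_length_um - 60), 2 * sqrt(3))
  expect_lt(abs(mean(sk$nodes$radius_um[sk$nodes$on_main]) - 4), 1.5)
  expect_equal(nrow(detect_sprouts(sk)), 0)
})

test_that("a sphere yields a degenerate-scale skeleton (length ~ diameter)", {
  co <- marrowmap:::coord_arrays(c(31, 31, 31), c(1, 1, 1))
  m <- (co$x - 15)^2 + (co$y - 15)^2 + (co$z - 15)^2 <= 100
  sk <- skeletonize_mask(m, c(1, 1, 1))
  expect_lte(sk$main_length_um, 2 * 10 + 3)
})

test_that("surface over length approximates 2*pi*r for a voxelized cylinder", {
  m <- tube_mask(c(45, 201, 45), c(1, 1, 1), 22, 22, 10)
  area <- component_surface_area(m, c(1, 1, 1))
  expect_lt(abs(area / 200 - 2 * pi * 10) / (2 * pi * 10), 0.10)
  sol <- surface_over_length(m, c(1, 1, 1))
  expect_lt(abs(sol$surface_over_length - 2 * pi * 10) / (2 * pi * 10), 0.10)
})

test_that("surface area halves/doubles with radius and flags sub-voxel objects", {
  m1 <- tube_mask(c(45, 101, 45), c(1, 1, 1), 22, 22, 5)
  m2 <- tube_mask(c(45, 101, 45), c(1, 1, 1), 22, 22, 10)
  a1 <- component_surface_area(m1, c(1, 1, 1))
  a2 <- component_surface_area(m2, c(1, 1, 1))
  expect_lt(abs(a2 / a1 - 2), 0.25)
  # a single voxel sits below mesh resolution: without smoothing the
  # dual-surface estimate is the inscribed octahedron, well under the cuboid
  # bound of 2*(2*1 + 2*1 + 1*1) = 10 um2
  mv <- array(FALSE, c(5, 5, 5))
  mv[3, 3, 3] <- TRUE
  av <- component_surface_area(mv, c(2, 1, 1), smooth_sigma_vox = 0)
  expect_gt(av, 0.5 * 10)
  expect_lt(av, 1.1 * 10)
})

test_that("surface estimates converge as the grid is refined", {
  # constant physical smoothing (1 um) at both resolutions
  m1 <- tube_mask(c(45, 201, 45), c(1, 1, 1), 22, 22, 10)
  e1 <- abs(component_surface_area(m1, c(1, 1, 1), 1) / 200 - 62.832) / 62.832
  m2 <- tube_mask(c(89, 401, 89), c(0.5, 0.5, 0.5), 22, 22, 10)
  e2 <- abs(component_surface_area(m2, c(0.5, 0.5, 0.5), 2) / 200 - 62.832) / 62.832
  expect_lt(e2, e1)
})

test_that("planted sprout density and length are recovered across densities", {
  cfg <- synthetic_config(
    dims = c(61, 221, 61), spacing = c(1, 1, 1), seed = 1,
    sprouts = list(length_mean = 8, length_sd = 2, radius = 1.5,
                   subtypes = "type_l")
  )
  tree <- straight_tree(c(30, 6, 30), c(30, 214, 30), radius = 10)
  for (dens in c(0, 2, 5, 10)) {
    cfg$sprouts$density_per_100um <- dens
    rec <- numeric(0)
    tru <- numeric(0)
    lens_rec <- numeric(0)
    lens_tru <- numeric(0)
    for (s in 1:10) {
      tr <- add_sprouts(tree, cfg, seed = s)
      vox <- voxelize_tree(tr, cfg)
      sk <- skeletonize_mask(vox$masks$type_l, c(1, 1, 1))
      spr <- detect_sprouts(sk)
      rec <- c(rec, attr(spr, "per_100um"))
      tru <- c(tru, 100 * nrow(tr$sprouts) / 208)
      lens_rec <- c(lens_rec, spr$length_um)
      lens_tru <- c(lens_tru, tr$sprouts$length_um)
    }
    if (dens == 0) {
      expect_equal(mean(rec), 0) # zero density recovered exactly
    } else {
      expect_lt(abs(mean(rec) - mean(tru)) / mean(tru), 0.15)
      expect_lt(abs(mean(lens_rec) - mean(lens_tru)) / mean(lens_tru), 0.20)
    }
  }
})

test_that("thick side branches are vessel branches, not sprouts", {
  cfg <- synthetic_config(dims = c(61, 221, 61), spacing = c(1, 1, 1), seed = 1)
  tree <- straight_tree(c(30, 6, 30), c(30, 214, 30), radius = 10)
  tree$segments <- dplyr::bind_rows(tree$segments, tibble::tibble(
    seg_id = 2L, parent_id = 1L, subtype = "type_l", radius_um = 6,
    length_um = 30,
    points = list(cbind(30, 100, seq(40, 10, length.out = 6)))
  ))
  vox <- voxelize_tree(tree, cfg)
  sk <- skeletonize_mask(vox$masks$type_l, c(1, 1, 1))
  expect_gte(nrow(sk$branches), 1)
  expect_equal(nrow(detect_sprouts(sk)), 0)
})

test_that("surface over length increases strictly with planted sprout count", {
  cfg <- synthetic_config(
    dims = c(61, 221, 61), spacing = c(1, 1, 1), seed = 1,
    sprouts = list(length_mean = 10, length_sd = 2, radius = 1.5,
                   subtypes = "type_l")
  )
  tree <- straight_tree(c(30, 6, 30), c(30, 214, 30), radius = 10)
  sal <- vapply(c(0, 5, 10), function(dens) {
    cfg$sprouts$density_per_100um <- dens
    mean(vapply(1:6, function(s) {
      tr <- add_sprouts(tree, cfg, seed = s)
      vox <- voxelize_tree(tr, cfg)
      surface_over_length(vox$masks$type_l, c(1, 1, 1))$surface_over_length
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sal) > 0))
})

test_that("lumen areas match the analytic annulus interior", {
  # hollow tube outer r=10, inner r=5
  hm <- tube_mask(c(45, 201, 45), c(1, 1, 1), 22, 22, 10, rinner = 5)
  full <- tube_mask(c(45, 201, 45), c(1, 1, 1), 22, 22, 10)
  sk <- skeletonize_mask(full, c(1, 1, 1))
  la <- lumen_area(hm, sk, c(1, 1, 1))
  expect_true(all(!la$collapsed))
  expect_lt(abs(mean(la$area_um2) - pi * 25) / (pi * 25), 0.15)

  # a fully solid tube has no cavity
  sol <- lumen_area(full, sk, c(1, 1, 1))
  expect_true(all(sol$area_um2 == 0))
  expect_true(all(sol$collapsed))
})

test_that("lumen area follows the generator scaling law", {
  cfg <- synthetic_config(dims = c(61, 141, 61), spacing = c(1, 1, 1), seed = 1,
                          vessels = list(lumen_fraction = 0.5))
  tree <- straight_tree(c(30, 6, 30), c(30, 134, 30), radius = 12)
  vox <- voxelize_tree(tree, cfg)
  sk <- skeletonize_mask(vox$masks$type_l, c(1, 1, 1))
  la <- lumen_area(vox$masks$type_l, sk, c(1, 1, 1),
                   lumen_mask = vox$masks$lumen)
  expect_lt(abs(mean(la$area_um2) - pi * 36) / (pi * 36), 0.15)
  # halving the lumen fraction quarters the area
  cfg2 <- synthetic_config(dims = c(61, 141, 61), spacing = c(1, 1, 1), seed = 1,
                           vessels = list(lumen_fraction = 0.25))
  vox2 <- voxelize_tree(tree, cfg2)
  la2 <- lumen_area(vox2$masks$type_l, sk, c(1, 1, 1),
                    lumen_mask = vox2$masks$lumen)
  expect_lt(abs(mean(la2$area_um2) / mean(la$area_um2) - 0.25), 0.1)
})

test_that("vessel volume fraction handles saturating, null and truth cases", {
  region <- array(FALSE, c(10, 10, 10))
  region[3:8, 3:8, 3:8] <- TRUE
  expect_equal(vessel_volume_fraction(region, region), 1)
  expect_equal(vessel_volume_fraction(array(FALSE, c(10, 10, 10)), region), 0)
  vessel <- array(FALSE, c(10, 10, 10))
  vessel[3:5, 3:8, 3:8] <- TRUE
  expect_equal(vessel_volume_fraction(vessel, region),
               sum(vessel & region) / sum(region))
  expect_error(vessel_volume_fraction(vessel, array(FALSE, c(10, 10, 10))),
               class = "mm_validation_error")
})

test_that("morphometry is invariant under translation and axis permutation", {
  base <- tube_mask(c(31, 81, 31), c(1, 1, 2), 14, 20, 6)
  a0 <- component_surface_area(base, c(1, 1, 2))
  l0 <- skeletonize_mask(base, c(1, 1, 2))$main_length_um
  # translate by 3 voxels in x
  tr <- array(FALSE, dim(base))
  tr[4:31, , ] <- base[1:28, , ]
  expect_equal(component_surface_area(tr, c(1, 1, 2)), a0, tolerance = 0.02)
  expect_equal(skeletonize_mask(tr, c(1, 1, 2))$main_length_um, l0,
               tolerance = 0.02)
  # permute axes (x <-> z), permuting spacing accordingly
  pm <- aperm(base, c(3, 2, 1))
  expect_equal(component_surface_area(pm, c(2, 1, 1)), a0, tolerance = 1e-6)
  expect_equal(skeletonize_mask(pm, c(2, 1, 1))$main_length_um, l0,
               tolerance = 1e-6)
})

test_that("the per-component morphometry table assembles all readouts", {
  cfg <- small_config(seed = 30)
  ds <- generate_dataset(cfg)
  map <- classify_voxels(ds$volume, derive_gates(ds$volume))
  comps <- extract_components(map, 500)
  mt <- morphometry_table(comps)
  expect_equal(nrow(mt), nrow(comps$components))
  expect_true(all(c("surface_area_um2", "length_um", "surface_over_length",
                    "n_sprouts", "sprouts_per_100um") %in% names(mt)))
  ok <- !mt$degenerate
  expect_true(all(mt$surface_area_um2[ok] > 0))
  expect_true(all(mt$length_um[ok] > 0))
})
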