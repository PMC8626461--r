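test_that("rendered spots are detected with sub-voxel-scale accuracy", {
  # 20 well-separated 10 um spots in an empty marrow (no vessels) volume
  cfg <- synthetic_config(dims = c(128, 128, 32), seed = 3,
                          vessels = list(n_arterioles = 0L),
                          dtc = list(n_spots = 20L, mix = c(perivascular_any = 0),
                                     min_separation = 25))
  vox <- voxelize_tree(
    structure(list(segments = build_vessel_tree(small_config())$segments[0, ],
                   sprouts = marrowmap:::empty_sprouts()),
              class = "vessel_tree"),
    cfg
  )
  sp <- place_dtcs(cfg, vox$masks, seed = 2)
  vol <- render_channels(vox$masks, cfg, seed = 5, spots = sp)
  det <- detect_spots(vol)
  expect_equal(nrow(det), 20)
  cross <- sqrt(outer(sp$x_um, det$x_um, "-")^2 +
                  outer(sp$y_um, det$y_um, "-")^2 +
                  outer(sp$z_um, det$z_um, "-")^2)
  # centroid error below one voxel diagonal
  diag_um <- sqrt(sum(cfg$spacing^2))
  expect_lt(max(apply(cross, 1, min)), diag_um)
})

test_that("a blank volume yields zero detections", {
  v0 <- image_volume(list(tumour = array(0, c(64, 64, 16))), c(1, 1, 2))
  expect_equal(nrow(detect_spots(v0)), 0)
  set.seed(41)
  v <- image_volume(
    list(tumour = array(abs(rnorm(64 * 64 * 16, 0, 1)), c(64, 64, 16))),
    c(1, 1, 2)
  )
  expect_equal(nrow(detect_spots(v)), 0)
})

test_that("two spots closer than the expected diameter merge into one detection", {
  dims <- c(64L, 64L, 32L)
  tum <- array(0L, dims)
  td <- array(Inf, dims)
  pts <- rbind(c(30, 30, 30), c(30, 34, 30)) # 4 um apart, diameter 10
  marrowmap:::cpp_paint_spheres(tum, td, dims, c(1, 1, 1), pts, c(5, 5), c(1L, 1L))
  v <- image_volume(list(tumour = array(150 * (tum > 0), dims)), c(1, 1, 1))
  det <- detect_spots(v, expected_diameter = 10, intensity_threshold = 10)
  expect_equal(nrow(det), 1)
  # the merged detection sits between the two true centres
  expect_gt(det$y_um, 30)
  expect_lt(det$y_um, 34)
})

test_that("detection is deterministic and validates the diameter", {
  cfg <- small_config(seed = 6)
  ds <- generate_dataset(cfg)
  d1 <- detect_spots(ds$volume)
  d2 <- detect_spots(ds$volume)
  expect_identical(d1, d2)
  expect_error(detect_spots(ds$volume, expected_diameter = 3),
               class = "mm_validation_error")
})

test_that("curation removes spots in bone and lumen with logged reasons", {
  cfg <- small_config(seed = 12)
  vox <- voxelize_tree(build_vessel_tree(cfg), cfg)
  masks <- vox$masks
  # craft spots: one in bone, one in lumen, one in admissible marrow
  bone_i <- which(masks$bone_surface)[1]
  lumen_i <- which(masks$lumen)[1]
  adm_i <- which(masks$marrow_admissible)[1]
  dims <- dim(masks$bone_surface)
  um <- marrowmap:::ijk_to_um(
    marrowmap:::index_to_ijk(c(bone_i, lumen_i, adm_i), dims), cfg$spacing
  )
  sp <- spot_set(tibble::tibble(
    id = 1:3, x_um = um[, 1], y_um = um[, 2], z_um = um[, 3],
    radius_um = 5, kind = "dtc"
  ))
  cur <- curate_spots(sp, masks)
  removed <- attr(cur, "removed")
  expect_equal(nrow(cur), 1)
  expect_equal(cur$id, 3)
  expect_setequal(removed$reason, c("in_bone", "in_lumen"))

  # all-pass rules leave the spot set unchanged
  cur2 <- curate_spots(sp, masks,
                       rules = list(remove_in_bone = FALSE,
                                    remove_in_lumen = FALSE))
  expect_equal(nrow(cur2), 3)
})

test_that("planted in-lumen artifacts are all removed by curation", {
  cfg <- small_config(seed = 15)
  vox <- voxelize_tree(build_vessel_tree(cfg), cfg)
  masks <- vox$masks
  dims <- dim(masks$lumen)
  lum_idx <- sample(which(masks$lumen), 5)
  um <- marrowmap:::ijk_to_um(marrowmap:::index_to_ijk(lum_idx, dims),
                              cfg$spacing)
  adm_idx <- sample(which(masks$marrow_admissible), 10)
  um2 <- marrowmap:::ijk_to_um(marrowmap:::index_to_ijk(adm_idx, dims),
                               cfg$spacing)
  sp <- spot_set(tibble::tibble(
    id = 1:15,
    x_um = c(um[, 1], um2[, 1]),
    y_um = c(um[, 2], um2[, 2]),
    z_um = c(um[, 3], um2[, 3]),
    radius_um = 5, kind = "dtc"
  ))
  cur <- curate_spots(sp, masks)
  expect_equal(nrow(attr(cur, "removed")), 5)
  expect_true(all(attr(cur, "removed")$reason == "in_lumen"))
})
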