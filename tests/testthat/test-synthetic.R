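test_that("vessel tree respects branching arithmetic and subtype hierarchy", {
  cfg <- small_config(seed = 4)
  tree <- build_vessel_tree(cfg)
  segs <- tree$segments
  expect_equal(sum(segs$subtype == "arterial"), 1)
  expect_equal(sum(segs$subtype == "type_h"), 2)
  expect_equal(sum(segs$subtype == "type_l"), 4)
  # parent of every type_h is arterial, of every type_l is type_h
  parent_subtype <- segs$subtype[match(segs$parent_id, segs$seg_id)]
  expect_true(all(parent_subtype[segs$subtype == "type_h"] == "arterial"))
  expect_true(all(parent_subtype[segs$subtype == "type_l"] == "type_h"))
  expect_true(all(segs$radius_um > 0))
})

test_that("tree generation is seed-deterministic and seed-sensitive", {
  cfg <- small_config(seed = 8)
  t1 <- build_vessel_tree(cfg, seed = 123)
  t2 <- build_vessel_tree(cfg, seed = 123)
  t3 <- build_vessel_tree(cfg, seed = 124)
  expect_identical(t1$segments$points, t2$segments$points)
  expect_false(identical(t1$segments$points, t3$segments$points))
})

test_that("a grid too small for the configured radii refuses to generate", {
  expect_error(
    build_vessel_tree(synthetic_config(dims = c(10, 10, 5), seed = 1)),
    class = "mm_generation_error"
  )
})

test_that("sprout counts follow the configured Poisson rate", {
  cfg <- small_config(seed = 2)
  tree <- straight_tree(c(20, 2, 30), c(20, 1002, 30), radius = 6)
  # density 3 per 100 um on 1000 um of vessel: mean 30 (pure Poisson; no
  # anchor-spacing thinning)
  cfg$sprouts$density_per_100um <- 3
  cfg$sprouts$min_anchor_gap <- 0
  cfg$sprouts$subtypes <- "type_l"
  counts <- vapply(1:400, function(s) {
    nrow(add_sprouts(tree, cfg, seed = s)$sprouts)
  }, numeric(1))
  se <- sqrt(30 / 400)
  expect_lt(abs(mean(counts) - 30), 3 * se)
  expect_true(all(vapply(1:5, function(s) {
    all(add_sprouts(tree, cfg, seed = s)$sprouts$length_um >= 1)
  }, logical(1))))

  cfg$sprouts$density_per_100um <- 0
  none <- add_sprouts(tree, cfg, seed = 1)
  expect_equal(nrow(none$sprouts), 0)
  expect_identical(none$segments, tree$segments)

  cfg$sprouts$density_per_100um <- -1
  expect_error(add_sprouts(tree, cfg, seed = 1), class = "mm_validation_error")
})

test_that("voxelized tube cross-sections match the analytic disc area", {
  cfg <- synthetic_config(dims = c(31, 41, 31), spacing = c(1, 1, 1), seed = 1)
  tree <- straight_tree(c(15, 0, 15), c(15, 40, 15), radius = 6)
  vox <- voxelize_tree(tree, cfg)
  # middle slice in y: count of in-mask voxels approximates pi * 6^2
  mid <- vox$masks$type_l[, 21, ]
  expect_lt(abs(sum(mid) - pi * 36) / (pi * 36), 0.08)
  # lumen fraction 0.5: lumen cross-section approximates pi * 3^2
  midl <- vox$masks$lumen[, 21, ]
  expect_lt(abs(sum(midl) - pi * 9) / (pi * 9), 0.25)
  expect_true(all(vox$masks$lumen[vox$masks$lumen] == vox$masks$vessel_any[vox$masks$lumen]))
})

test_that("an empty tree voxelizes to all-zero vessel masks", {
  cfg <- synthetic_config(dims = c(16, 16, 8), seed = 1)
  empty <- structure(
    list(segments = build_vessel_tree(small_config())$segments[0, ],
         sprouts = marrowmap:::empty_sprouts()),
    class = "vessel_tree"
  )
  vox <- voxelize_tree(empty, cfg)
  expect_equal(sum(vox$masks$vessel_any), 0)
  expect_equal(sum(vox$masks$lumen), 0)
})

test_that("subtype masks are pairwise disjoint and admissible excludes vessel and bone", {
  cfg <- small_config(seed = 6)
  vox <- voxelize_tree(add_sprouts(build_vessel_tree(cfg), cfg), cfg)
  m <- vox$masks
  expect_equal(sum(m$arterial & m$type_h), 0)
  expect_equal(sum(m$arterial & m$type_l), 0)
  expect_equal(sum(m$type_h & m$type_l), 0)
  expect_equal(sum(m$marrow_admissible & (m$vessel_any | m$bone_surface)), 0)
  expect_true(all(m$vessel_any[m$lumen]))
})

test_that("noiseless rendering reproduces the configured class means exactly", {
  cfg <- small_config(seed = 3, intensity = list(noise_sd = 0, blur_sigma = 0))
  vox <- voxelize_tree(build_vessel_tree(cfg), cfg)
  vol <- render_channels(vox$masks, cfg)
  for (s in c("arterial", "type_h", "type_l")) {
    expect_equal(unique(vol$channels$cd31[vox$masks[[s]]]),
                 cfg$intensity$mean_cd31[[s]])
    expect_equal(unique(vol$channels$emcn[vox$masks[[s]]]),
                 cfg$intensity$mean_emcn[[s]])
  }
})

test_that("noisy class-conditional means converge to the configured means", {
  cfg <- small_config(seed = 3, intensity = list(blur_sigma = 0))
  vox <- voxelize_tree(build_vessel_tree(cfg), cfg)
  vol <- render_channels(vox$masks, cfg, seed = 99)
  for (s in c("arterial", "type_h", "type_l")) {
    nvox <- sum(vox$masks[[s]])
    se <- cfg$intensity$noise_sd / sqrt(nvox)
    obs <- mean(vol$channels$cd31[vox$masks[[s]]])
    # clipping at 0 is negligible at these means; 4 s.e. guards flakiness
    expect_lt(abs(obs - cfg$intensity$mean_cd31[[s]]), 4 * se + 0.05)
  }
})

test_that("blur preserves class means but mixes the joint histogram", {
  cfg <- small_config(seed = 3)
  vox <- voxelize_tree(build_vessel_tree(cfg), cfg)
  v0 <- render_channels(vox$masks, cfg, seed = 5)
  cfgb <- small_config(seed = 3, intensity = list(blur_sigma = 2))
  vb <- render_channels(vox$masks, cfgb, seed = 5)
  # compare deep-interior voxels: symmetric blur leaves them unchanged while
  # boundary shells mix with the background
  depth <- array(marrowmap:::cpp_edt3d(!vox$masks$type_h,
                                       dim(vox$masks$type_h), cfg$spacing),
                 dim(vox$masks$type_h))
  core <- vox$masks$type_h & depth >= 3
  expect_lt(abs(mean(v0$channels$cd31[core]) - mean(vb$channels$cd31[core])), 12)
  # blur increases between-class overlap: fewer voxels stay near the pure
  # type_h intensity
  pure0 <- sum(v0$channels$cd31 > 170 & v0$channels$emcn > 170)
  pureb <- sum(vb$channels$cd31 > 170 & vb$channels$emcn > 170)
  expect_lt(pureb, pure0)
})

test_that("DTC placement honours class mixes, shells and separation", {
  cfg <- small_config(seed = 11)
  cfg$dtc$n_spots <- 60L
  cfg$dtc$mix <- c(perivascular_any = 1.0)
  vox <- voxelize_tree(add_sprouts(build_vessel_tree(cfg), cfg), cfg)
  sp <- place_dtcs(cfg, vox$masks)
  expect_equal(nrow(sp), 60)
  # constructive placement: every spot within the 10 um vessel shell
  expect_true(all(sp$true_dist_vessel_any <= cfg$dtc$shell + 1e-9))
  D <- as.matrix(dist(cbind(sp$x_um, sp$y_um, sp$z_um)))
  diag(D) <- Inf
  expect_gte(min(D), cfg$dtc$min_separation - 1e-9)
})

test_that("uniform placement matches the geometric shell fraction", {
  cfg <- small_config(seed = 13)
  cfg$dtc$n_spots <- 400L
  cfg$dtc$mix <- c(perivascular_any = 0) # pure uniform placement
  cfg$dtc$min_separation <- 1e-6
  vox <- voxelize_tree(build_vessel_tree(cfg), cfg)
  p_shell <- shell_volume_fraction(vox$masks, "vessel_any", 10)
  fr <- vapply(1:5, function(s) {
    sp <- place_dtcs(cfg, vox$masks, seed = s)
    mean(sp$true_dist_vessel_any <= 10)
  }, numeric(1))
  n_tot <- 5 * 400
  ci <- 2.58 * sqrt(p_shell * (1 - p_shell) / n_tot)
  expect_lt(abs(mean(fr) - p_shell), ci + 0.01)
})

test_that("zero requested spots yields an empty spot set", {
  cfg <- small_config(seed = 1)
  cfg$dtc$n_spots <- 0L
  vox <- voxelize_tree(build_vessel_tree(cfg), cfg)
  sp <- place_dtcs(cfg, vox$masks)
  expect_equal(nrow(sp), 0)
})

test_that("dataset generation is fully seed-deterministic", {
  cfg <- small_config(seed = 7)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$volume$channels$cd31, d2$volume$channels$cd31)
  expect_identical(d1$truth$spots$x_um, d2$truth$spots$x_um)
  d3 <- generate_dataset(small_config(seed = 8))
  expect_false(identical(d1$truth$spots$x_um, d3$truth$spots$x_um))
})

test_that("placement-mix calibration solves the shell-spillover equation", {
  cfg <- small_config(seed = 5)
  vox <- voxelize_tree(build_vessel_tree(cfg), cfg)
  p <- shell_volume_fraction(vox$masks, "vessel_any", 10)
  mix <- calibrate_placement_mix(vox$masks, "perivascular_any", 0.671)
  f <- unname(mix)
  expect_equal(f + (1 - f) * p, 0.671, tolerance = 1e-10)
  expect_error(calibrate_placement_mix(vox$masks, "perivascular_any", p / 2),
               class = "mm_validation_error")
})
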