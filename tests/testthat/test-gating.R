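test_that("joint histogram conserves counts and handles degenerate input", {
  v <- image_volume(list(cd31 = array(5, c(4, 4, 4)),
                         emcn = array(7, c(4, 4, 4))), c(1, 1, 1))
  h <- joint_intensity_histogram(v, bins = 8)
  expect_equal(sum(h$counts), 64)
  expect_equal(sum(h$counts > 0), 1) # constant volume: all mass in one bin
  expect_error(joint_intensity_histogram(v, bins = 1),
               class = "mm_validation_error")

  cfg <- small_config(seed = 2)
  ds <- generate_dataset(cfg)
  mask <- ds$truth$masks$vessel_any
  hm <- joint_intensity_histogram(ds$volume, bins = 32, mask = mask)
  expect_equal(hm$n_voxels, sum(mask))
  expect_equal(sum(hm$counts), sum(mask))
})

test_that("auto gates strictly separate the three configured class means", {
  cfg <- small_config(seed = 5, intensity = list(noise_sd = 0, blur_sigma = 0))
  ds <- generate_dataset(cfg)
  g <- derive_gates(ds$volume)
  it <- cfg$intensity
  expect_lt(g$vessel_presence, min(it$mean_cd31))
  expect_gt(g$vessel_presence, it$background[["cd31"]])
  expect_gt(g$cd31_lo_hi, it$mean_cd31[["type_l"]])
  expect_lt(g$cd31_lo_hi, it$mean_cd31[["arterial"]])
  expect_gt(g$emcn_neg_lo, it$mean_emcn[["arterial"]])
  expect_lt(g$emcn_neg_lo, it$mean_emcn[["type_l"]])
  expect_gt(g$emcn_lo_hi, it$mean_emcn[["type_l"]])
  expect_lt(g$emcn_lo_hi, it$mean_emcn[["type_h"]])
})

test_that("manual gates pass through unchanged; degenerate input errors", {
  manual <- gate_config(10, 100, 20, 120)
  v <- image_volume(list(cd31 = array(3, c(6, 6, 6)),
                         emcn = array(3, c(6, 6, 6))), c(1, 1, 1))
  out <- derive_gates(v, "manual", manual = manual)
  expect_identical(out, manual)
  # an all-background volume cannot support automatic gating
  expect_error(derive_gates(v, "auto"), class = "mm_validation_error")
  expect_error(gate_config(200, 100, 20, 120), class = "mm_validation_error")
})

test_that("classification follows the gate logic for canonical voxels", {
  g <- gate_config(vessel_presence = 20, cd31_lo_hi = 100,
                   emcn_neg_lo = 30, emcn_lo_hi = 100)
  mk <- function(cd, em) {
    image_volume(list(cd31 = array(cd, c(1, 1, 1)),
                      emcn = array(em, c(1, 1, 1))), c(1, 1, 1))
  }
  lab_of <- function(cd, em) classify_voxels(mk(cd, em), g)$labels[1]
  expect_equal(lab_of(0, 0), 0L)      # below presence: background
  expect_equal(lab_of(150, 5), 1L)    # CD31-hi EMCN-neg: arterial
  expect_equal(lab_of(150, 150), 2L)  # CD31-hi EMCN-hi: type H
  expect_equal(lab_of(50, 50), 3L)    # CD31-lo EMCN-lo: type L
})

test_that("classification is pure and monotone in the CD31 threshold", {
  cfg <- small_config(seed = 9)
  ds <- generate_dataset(cfg)
  g <- derive_gates(ds$volume)
  m1 <- classify_voxels(ds$volume, g)
  m2 <- classify_voxels(ds$volume, g)
  expect_identical(m1$labels, m2$labels)
  # raising cd31_lo_hi can only move voxels out of the CD31-high classes;
  # no type_l voxel may become arterial or type_h
  g2 <- gate_config(g$vessel_presence, g$cd31_lo_hi * 1.3,
                    g$emcn_neg_lo, g$emcn_lo_hi)
  m3 <- classify_voxels(ds$volume, g2)
  was_l <- m1$labels == 3L
  expect_equal(sum(m3$labels[was_l] %in% c(1L, 2L)), 0)
})

test_that("classification recovers ground truth (exact noiseless, >=95% noisy)", {
  cfg0 <- small_config(seed = 10, intensity = list(noise_sd = 0, blur_sigma = 0))
  ds0 <- generate_dataset(cfg0)
  m0 <- classify_voxels(ds0$volume, derive_gates(ds0$volume))
  expect_equal(mean(m0$labels == ds0$truth$subtype_label), 1)

  cfg1 <- small_config(seed = 10)
  ds1 <- generate_dataset(cfg1)
  m1 <- classify_voxels(ds1$volume, derive_gates(ds1$volume))
  expect_gte(mean(m1$labels == ds1$truth$subtype_label), 0.95)
  # per-subtype classified volume within 10% of the true mask volume
  for (s in 1:3) {
    truth_n <- sum(ds1$truth$subtype_label == s)
    expect_lt(abs(sum(m1$labels == s) - truth_n) / truth_n, 0.10)
  }
})

test_that("component extraction matches brute-force flood fill on small grids", {
  set.seed(42)
  for (r in 1:5) {
    dims <- c(12L, 12L, 8L)
    lab <- array(0L, dims)
    lab[array(runif(prod(dims)) < 0.15, dims)] <- 2L # sparse type_h voxels
    map <- structure(
      list(labels = lab, levels = marrowmap:::CLASS_LEVELS,
           gates = NULL, spacing = c(1, 1, 1)),
      class = "vessel_class_map"
    )
    comps <- extract_components(map, min_volume_um3 = 0)
    expect_equal(nrow(comps$components),
                 brute_component_count(lab == 2L, 26))
  }
})

test_that("two disjoint tubes yield two components with correct subtypes", {
  lab <- array(0L, c(30, 20, 12))
  lab[4:8, 3:18, 4:8] <- 1L
  lab[20:26, 3:18, 4:8] <- 2L
  map <- structure(
    list(labels = lab, levels = marrowmap:::CLASS_LEVELS, gates = NULL,
         spacing = c(1, 1, 1)),
    class = "vessel_class_map"
  )
  comps <- extract_components(map, min_volume_um3 = 10)
  expect_equal(nrow(comps$components), 2)
  expect_setequal(comps$components$subtype, c("arterial", "type_h"))
})

test_that("a small misclassified islet is merged into its surrounding vessel", {
  lab <- array(0L, c(24, 24, 10))
  lab[6:18, 6:18, 3:7] <- 2L            # large type_h block
  lab[11:12, 11:12, 5] <- 1L            # 4-voxel arterial islet inside it
  map <- structure(
    list(labels = lab, levels = marrowmap:::CLASS_LEVELS, gates = NULL,
         spacing = c(1, 1, 1)),
    class = "vessel_class_map"
  )
  comps <- extract_components(map, min_volume_um3 = 100)
  expect_equal(nrow(comps$components), 1)
  expect_equal(comps$components$subtype, "type_h")
  expect_equal(comps$components$n_voxels, sum(lab > 0L))
})

test_that("vessel mean intensities are exact for constant components and track truth", {
  lab <- array(0L, c(10, 10, 6))
  lab[3:7, 3:7, 2:4] <- 2L
  map <- structure(
    list(labels = lab, levels = marrowmap:::CLASS_LEVELS, gates = NULL,
         spacing = c(1, 1, 1)),
    class = "vessel_class_map"
  )
  comps <- extract_components(map, min_volume_um3 = 0)
  v <- image_volume(list(cd31 = array(42, c(10, 10, 6)),
                         emcn = array(7, c(10, 10, 6))), c(1, 1, 1))
  mi <- vessel_mean_intensity(comps, v)
  expect_equal(mi$mean_cd31, 42)
  expect_equal(mi$mean_emcn, 7)
})

test_that("met-like intensity boosting is visible in per-vessel means", {
  cfg_non <- small_config(seed = 14)
  cfg_met <- small_config(seed = 14)
  cfg_met$intensity$mean_cd31 <- cfg_met$intensity$mean_cd31 * 1.5
  vox <- voxelize_tree(build_vessel_tree(cfg_non), cfg_non)
  v_non <- render_channels(vox$masks, cfg_non, seed = 1)
  v_met <- render_channels(vox$masks, cfg_met, seed = 1)
  map_non <- classify_voxels(v_non, derive_gates(v_non))
  comps <- extract_components(map_non, 500)
  mean_non <- mean(vessel_mean_intensity(comps, v_non)$mean_cd31)
  mean_met <- mean(vessel_mean_intensity(comps, v_met)$mean_cd31)
  expect_gt(mean_met, mean_non)
})
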