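test_that("distance field matches hand-computed anisotropic distances", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  d <- distance_field(m, spacing = c(2, 1, 1))
  # voxel one x-step and three z-steps away: sqrt((1*2)^2 + (3*1)^2)
  expect_equal(d[2, 1, 4], sqrt(13))
  expect_equal(d[1, 1, 1], 0)
  full <- distance_field(array(TRUE, c(3, 3, 3)), spacing = c(1, 2, 3))
  expect_true(all(full == 0))
  expect_error(distance_field(array(FALSE, c(3, 3, 3)), c(1, 1, 1),
                              name = "bone_surface"),
               regexp = "bone_surface", class = "mm_validation_error")
})

test_that("distance field is 1-Lipschitz in the physical step", {
  set.seed(3)
  m <- array(runif(16 * 16 * 8) < 0.03, c(16, 16, 8))
  m[1] <- TRUE
  sp <- c(1.5, 1, 2)
  d <- distance_field(m, spacing = sp)
  expect_true(all(abs(apply(d, c(2, 3), diff)) <= sp[1] + 1e-9))
  expect_true(all(abs(apply(d, c(1, 3), diff)) <= sp[2] + 1e-9))
  expect_true(all(abs(apply(d, c(1, 2), diff)) <= sp[3] + 1e-9))
})

test_that("spot distances interpolate linearly and validate bounds", {
  m <- array(FALSE, c(11, 5, 5))
  m[1, , ] <- TRUE # plane at x = 0
  fld <- list(bone_surface = distance_field(m, spacing = c(1, 1, 1)))
  sp <- spot_set(tibble::tibble(
    id = 1:3, x_um = c(0, 4.5, 10), y_um = 2, z_um = 2,
    radius_um = 1, kind = "dtc"
  ))
  dt <- measure_spot_distances(sp, fld)
  expect_equal(dt$dist_bone_surface, c(0, 4.5, 10))
  # surface-referenced distances subtract the radius, clamped at zero
  dt2 <- measure_spot_distances(sp, fld, subtract_radius = TRUE)
  expect_equal(dt2$dist_bone_surface, c(0, 3.5, 9))
  out <- spot_set(tibble::tibble(id = 9L, x_um = 200, y_um = 2, z_um = 2,
                                 radius_um = 1, kind = "dtc"))
  expect_error(measure_spot_distances(out, fld), regexp = "9",
               class = "mm_validation_error")
})

test_that("interpolated distances stay within a voxel diagonal of brute force", {
  set.seed(8)
  dims <- c(14L, 12L, 10L)
  sp <- c(1, 1.5, 2)
  m <- array(runif(prod(dims)) < 0.05, dims)
  m[3, 3, 3] <- TRUE
  fld <- list(s = distance_field(m, spacing = sp))
  pts <- cbind(runif(300, 0, (dims[1] - 1) * sp[1]),
               runif(300, 0, (dims[2] - 1) * sp[2]),
               runif(300, 0, (dims[3] - 1) * sp[3]))
  spots <- spot_set(tibble::tibble(
    id = seq_len(300), x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
    radius_um = 1, kind = "dtc"
  ))
  dt <- measure_spot_distances(spots, fld)
  mask_um <- marrowmap:::ijk_to_um(
    marrowmap:::index_to_ijk(which(m), dims), sp
  )
  brute <- vapply(seq_len(300), function(i) {
    sqrt(min((mask_um[, 1] - pts[i, 1])^2 + (mask_um[, 2] - pts[i, 2])^2 +
               (mask_um[, 3] - pts[i, 3])^2))
  }, numeric(1))
  expect_lt(max(abs(dt$dist_s - brute)), sqrt(sum(sp^2)))
})

test_that("proximity fractions count thresholds correctly and summarise by volume", {
  tbl <- tibble::tibble(
    id = 1:4, kind = "dtc",
    dist_vessel_any = c(5, 9, 11, 30)
  )
  pr <- proximity_fraction(tbl, "vessel_any", 10)
  expect_equal(pr$fraction, 0.5)
  expect_equal(pr$n_spots, 4)

  tbl0 <- tibble::tibble(id = 1:3, kind = "dtc", dist_bone_surface = c(0, 0, 0))
  expect_equal(proximity_fraction(tbl0, "bone_surface", 10)$fraction, 1)

  # s.e.m. across volumes = sd / sqrt(n volumes)
  tblv <- tibble::tibble(
    id = 1:60, kind = "dtc",
    volume = rep(1:3, each = 20),
    dist_vessel_any = rep(c(5, 15), 30)
  )
  tblv$dist_vessel_any[tblv$volume == 2] <- 5
  prv <- proximity_fraction(tblv, "vessel_any", 10)
  per <- prv$per_volume[[1]]
  expect_equal(prv$n_volumes, 3)
  expect_equal(prv$fraction, mean(per$fraction))
  expect_equal(prv$sem, sd(per$fraction) / sqrt(3))
  expect_error(proximity_fraction(tbl[0, ], "vessel_any", 10),
               class = "mm_validation_error")
})

test_that("random spots require all vessel subtypes and bone to be present", {
  cfg <- small_config(seed = 21)
  vox <- voxelize_tree(build_vessel_tree(cfg), cfg)
  masks <- vox$masks
  no_art <- masks
  no_art$arterial <- structure_mask(array(FALSE, dim(masks$arterial)),
                                    "arterial", cfg$spacing)
  expect_error(generate_random_spots(no_art, 500, seed = 1),
               regexp = "arterial", class = "mm_precondition_error")
  expect_error(generate_random_spots(masks, 50, seed = 1),
               class = "mm_validation_error")
  r1 <- generate_random_spots(masks, 500, seed = 4)
  r2 <- generate_random_spots(masks, 500, seed = 4)
  expect_identical(r1, r2)
  expect_true(all(r1$kind == "random"))
  expect_equal(r1$radius_um[1], 5)
})

test_that("random spots are uniform across admissible sub-regions", {
  cfg <- small_config(seed = 22)
  vox <- voxelize_tree(build_vessel_tree(cfg), cfg)
  masks <- vox$masks
  dims <- dim(masks$marrow_admissible)
  rs <- generate_random_spots(masks, 20000, seed = 9)
  # split the admissible region at the x median of admissible voxels
  adm <- which(masks$marrow_admissible)
  xs <- marrowmap:::index_to_ijk(adm, dims)[, 1]
  cut <- median(xs)
  p_left <- mean(xs <= cut)
  obs_left <- mean(rs$x_um / cfg$spacing[1] <= cut + 0.45)
  ci <- 2.58 * sqrt(p_left * (1 - p_left) / 20000)
  expect_lt(abs(obs_left - p_left), ci + 0.01)
})

test_that("null-model convergence report follows the sqrt-n law", {
  cfg <- small_config(seed = 23)
  vox <- voxelize_tree(build_vessel_tree(cfg), cfg)
  res <- null_convergence_check(vox$masks, "vessel_any", n_random = 2000,
                                n_seeds = 6, seed = 2)
  expect_equal(nrow(res$report), 4)
  expect_true(all(c("n", "mean_fraction", "sd_fraction") %in% names(res$report)))
  # s.d. at the largest n should be below s.d. at the smallest (sqrt-n law,
  # allowing Monte-Carlo slack)
  expect_lt(res$report$sd_fraction[4],
            res$report$sd_fraction[1] * 2)
  # a vacuous tolerance accepts the smallest n
  res2 <- null_convergence_check(vox$masks, "vessel_any", n_random = 2000,
                                 n_seeds = 3, tolerance_pp = 100, seed = 2)
  expect_equal(res2$recommended_n, min(res2$report$n))
})

test_that("distance histograms respect right-open bins and the overflow bin", {
  tbl <- tibble::tibble(id = 1:3, kind = "dtc", dist_type_h = c(1, 9, 10))
  h <- distance_histogram(tbl, "type_h", bin_width = 10, max_um = 30)
  expect_equal(h$count, c(2, 1, 0, 0)) # 10 falls in the second bin
  expect_equal(sum(h$count), 3)
  expect_equal(h$bin_lo, c(0, 10, 20, 30))
  expect_true(is.infinite(h$bin_hi[4]))
  expect_error(distance_histogram(tbl, "type_h", bin_width = 0),
               class = "mm_validation_error")
})

test_that("type-H-homing DTCs concentrate in the first histogram bin", {
  cfg <- small_config(seed = 24)
  cfg$dtc$n_spots <- 150L
  cfg$dtc$mix <- c(near_type_h = 0.8)
  cfg$dtc$min_separation <- 1e-6 # density, not spacing, is under test here
  ds <- generate_dataset(cfg)
  fld <- list(type_h = distance_field(ds$truth$masks$type_h))
  ddt <- measure_spot_distances(ds$truth$spots, fld)
  rs <- generate_random_spots(ds$truth$masks, 2000, seed = 1)
  drs <- measure_spot_distances(rs, fld)
  h <- distance_histogram(dplyr::bind_rows(ddt, drs), "type_h")
  f_dtc <- h$fraction[h$kind == "dtc"]
  f_ran <- h$fraction[h$kind == "random"]
  expect_gt(f_dtc[1], 0.7)          # DTC mass concentrated within 10 um
  expect_gt(f_dtc[1], 2 * f_ran[1]) # random spots spread far wider
})

test_that("tumour volume follows the caliper formula", {
  expect_equal(tumour_volume(5, 8), 100)
  expect_equal(tumour_volume(0.001, 3), 1e-6 * 3 / 2)
  w <- 2.5
  expect_equal(tumour_volume(w, w), w^3 / 2)
  expect_error(tumour_volume(-1, 5), class = "mm_validation_error")
  expect_error(tumour_volume(5, 0), class = "mm_validation_error")
})
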