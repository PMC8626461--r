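#' Parameter-recovery study for DTC proximity fractions
#'
#' Validation protocol for the full localisation pipeline: for each seed,
#' generate a synthetic marrow volume whose DTC placement mix is calibrated
#' (via [calibrate_placement_mix()]) so that the expected fraction of DTCs
#' within `shell` µm of the target structure equals `target_fraction`; then
#' run blind spot detection on the rendered tumour channel, measure spot
#' distances to the structure, and recover the proximity fraction.
#'
#' For `near_type_h` with `use_classified = TRUE`, distances are measured to
#' the type H mask recovered by CD31/EMCN gating of the rendered channels
#' rather than to the generator truth, exercising the classification stage
#' as well.
#'
#' @param target_fraction the proximity fraction the generator is calibrated
#'   to (e.g. 0.671 for perivascular placement).
#' @param class placement class: `perivascular_any`, `near_bone` or
#'   `near_type_h`.
#' @param n_seeds number of independent volumes (default 20).
#' @param n_spots DTCs per volume (default 500).
#' @param base_seed integer; per-volume seeds are derived from it.
#' @param dims,spacing volume geometry (defaults 256 x 256 x 64 voxels at
#'   (1, 1, 2) µm).
#' @param shell placement shell and proximity threshold in µm (default 10).
#' @param use_classified measure distances to the gated class map instead of
#'   the generator truth masks (only meaningful for subtype targets).
#' @return list with `per_seed` tibble (seed, recovered, truth fraction,
#'   n detected) and the across-seed `recovered` mean.
#' @export
recovery_study_proximity <- function(target_fraction,
                                     class = c("perivascular_any", "near_bone",
                                               "near_type_h"),
                                     n_seeds = 20, n_spots = 500,
                                     base_seed = 1,
                                     dims = c(256L, 256L, 64L),
                                     spacing = c(1, 1, 2),
                                     shell = 10,
                                     use_classified = (class == "near_type_h")) {
  class <- match.arg(class)
  structure_name <- placement_target[[class]]
  rows <- purrr::map_dfr(seq_len(n_seeds), function(i) {
    seed <- derive_seed(base_seed, paste0("prox_", class, "_", i))
    cfg <- synthetic_config(dims = dims, spacing = spacing,
                            dtc = list(n_spots = n_spots), seed = seed)
    tree <- add_sprouts(build_vessel_tree(cfg), cfg)
    vox <- voxelize_tree(tree, cfg)
    mix <- calibrate_placement_mix(vox$masks, class, target_fraction, shell)
    cfg$dtc$mix <- mix
    ds <- generate_dataset(cfg, tree = tree, vox = vox)
    det <- detect_spots(ds$volume)
    mask <- if (use_classified) {
      map <- classify_voxels(ds$volume, derive_gates(ds$volume))
      class_map_masks(map)[[structure_name]]
    } else {
      ds$truth$masks[[structure_name]]
    }
    fld <- setNames(list(distance_field(mask, spacing, structure_name)),
                    structure_name)
    dt <- measure_spot_distances(det, fld)
    pr <- proximity_fraction(dt, structure_name, shell)
    tibble::tibble(
      seed = seed,
      recovered = pr$fraction,
      truth = mean(ds$truth$spots[[paste0("true_dist_", structure_name)]] <= shell),
      n_detected = nrow(det)
    )
  })
  list(per_seed = rows, recovered = mean(rows$recovered),
       truth = mean(rows$truth), n_spots_total = sum(rows$n_detected))
}

#' Null-model recovery of a calibrated type-H shell fraction
#'
#' Calibrates the generator's type H content so that the admissible-volume
#' fraction of the type-H 10-µm shell equals `target_fraction` (geometric
#' oracle), then draws uniform random spots with the null model and recovers
#' the fraction within the shell.
#'
#' @param target_fraction target shell volume fraction (e.g. 0.038).
#' @param n_random random spots per draw (default 50000).
#' @param n_seeds independent draws (default 10).
#' @param base_seed integer seed.
#' @param dims,spacing,shell volume geometry and shell distance.
#' @return list with `per_seed` tibble, the achieved `shell_fraction` and the
#'   mean `recovered` fraction.
#' @export
recovery_study_null_type_h <- function(target_fraction, n_random = 50000,
                                       n_seeds = 10, base_seed = 1,
                                       dims = c(256L, 256L, 64L),
                                       spacing = c(1, 1, 2), shell = 10) {
  cfg <- synthetic_config(dims = dims, spacing = spacing,
                          seed = derive_seed(base_seed, "null_th"))
  cal <- calibrate_type_h_shell(cfg, target_fraction, shell)
  masks <- cal$masks
  fld <- list(type_h = distance_field(masks$type_h, spacing, "type_h"))
  rows <- purrr::map_dfr(seq_len(n_seeds), function(i) {
    seed <- derive_seed(base_seed, paste0("null_draw_", i))
    rs <- generate_random_spots(masks, n_random, diameter = 2 * cfg$dtc$radius,
                                seed = seed)
    dt <- measure_spot_distances(rs, fld)
    tibble::tibble(seed = seed, recovered = mean(dt$dist_type_h <= shell))
  })
  list(per_seed = rows, shell_fraction = cal$shell_fraction,
       recovered = mean(rows$recovered))
}
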