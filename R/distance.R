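#' Exact anisotropic Euclidean distance transform of a structure mask
#'
#' Per-voxel Euclidean distance in µm from each voxel centre to the nearest
#' voxel of the mask (0 inside the mask), honouring anisotropic spacing
#' (separable exact squared-distance transform).
#'
#' @param mask logical 3D array (or `structure_mask`).
#' @param spacing voxel spacing in µm; taken from the mask attribute when
#'   present.
#' @param name structure name used in error messages.
#' @return numeric 3D array of class `distance_field` with `spacing` and
#'   `structure` attributes.
#' @export
distance_field <- function(mask, spacing = NULL,
                           name = attr(mask, "name") %||% "structure") {
  spacing <- check_spacing(spacing %||% mask_spacing(mask))
  dims <- grid_dims(mask)
  if (!any(mask)) {
    stop_validation(sprintf("structure '%s' mask is empty.", name))
  }
  d <- array(cpp_edt3d(as.logical(mask), dims, spacing), dims)
  attr(d, "spacing") <- spacing
  attr(d, "structure") <- name
  class(d) <- c("distance_field", class(d))
  d
}

#' Measure per-spot distances to each structure
#'
#' Trilinear interpolation of each distance field at the spot centroids;
#' distances are centre-of-spot to nearest structure voxel. With
#' `subtract_radius = TRUE` the spot radius is subtracted (surface-referenced
#' distance, clamped at 0).
#'
#' @param spots a `spot_set`.
#' @param fields named list of [distance_field()]s.
#' @param subtract_radius logical, default FALSE.
#' @return tibble with `id`, `kind` and one `dist_<structure>` column per
#'   field (µm).
#' @export
measure_spot_distances <- function(spots, fields, subtract_radius = FALSE) {
  if (nrow(spots) == 0) {
    out <- tibble::tibble(id = integer(), kind = character())
    for (nm in names(fields)) out[[paste0("dist_", nm)]] <- numeric()
    return(out)
  }
  f1 <- fields[[1]]
  spacing <- attr(f1, "spacing")
  dims <- grid_dims(f1)
  pts <- spot_coords(spots)
  # the grid's physical domain extends half a voxel beyond the first and last
  # voxel centres; fields are clamp-extrapolated over that half-voxel rim
  lo <- -0.5 * spacing
  hi <- (dims - 1) * spacing + 0.5 * spacing
  bad <- which(
    pts[, 1] < lo[1] | pts[, 2] < lo[2] | pts[, 3] < lo[3] |
      pts[, 1] > hi[1] | pts[, 2] > hi[2] | pts[, 3] > hi[3]
  )
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "spot centroid(s) outside the grid bounds: id %s.",
      paste(spots$id[bad], collapse = ", ")
    ))
  }
  out <- tibble::tibble(id = spots$id, kind = spots$kind)
  if ("volume" %in% names(spots)) out$volume <- spots$volume
  for (nm in names(fields)) {
    d <- as.numeric(cpp_trilinear(fields[[nm]], dims, spacing, pts))
    if (subtract_radius) d <- pmax(d - spots$radius_um, 0)
    out[[paste0("dist_", nm)]] <- d
  }
  out
}

#' Fraction of spots within a threshold distance of a structure
#'
#' The proximity statistic: per volume and spot kind, the fraction of spots
#' whose distance to the structure is at or below the threshold, summarised
#' across volumes as mean +/- s.e.m.
#'
#' @param table a distance table from [measure_spot_distances()] (optionally
#'   with a `volume` column identifying replicate volumes/mice).
#' @param structure structure name (matching a `dist_<structure>` column).
#' @param threshold proximity threshold in µm (default 10).
#' @return object of class `proximity_result`: tibble with one row per spot
#'   kind (`kind`, `structure`, `threshold_um`, `n_volumes`, `n_spots`,
#'   `fraction`, `sem`) and the per-volume fractions in the `per_volume`
#'   list-column.
#' @export
proximity_fraction <- function(table, structure, threshold = 10) {
  col <- paste0("dist_", structure)
  if (!col %in% names(table)) {
    stop_validation(sprintf("distance column '%s' not present.", col))
  }
  if (nrow(table) == 0) stop_validation("distance table is empty.")
  tbl <- tibble::as_tibble(table)
  if (!"volume" %in% names(tbl)) tbl$volume <- 1L
  if (!"kind" %in% names(tbl)) tbl$kind <- "dtc"
  per <- tbl |>
    dplyr::group_by(.data$kind, .data$volume) |>
    dplyr::summarise(
      n_spots = dplyr::n(),
      fraction = mean(.data[[col]] <= threshold),
      .groups = "drop"
    )
  out <- per |>
    dplyr::group_by(.data$kind) |>
    dplyr::summarise(
      structure = structure,
      threshold_um = threshold,
      n_volumes = dplyr::n(),
      n_spots = sum(.data$n_spots),
      sem = ifelse(dplyr::n() > 1, sd(.data$fraction) / sqrt(dplyr::n()), NA_real_),
      fraction = mean(.data$fraction),
      .groups = "drop"
    ) |>
    dplyr::relocate("fraction", .before = "sem")
  out$per_volume <- lapply(out$kind, function(k) per[per$kind == k, ])
  class(out) <- c("proximity_result", class(out))
  out
}

#' Generate null-model random spots over the admissible marrow
#'
#' Places `n_random` spots of DTC size uniformly over the admissible region
#' (marrow excluding vessels, vessel lumens and bone) with sub-voxel jitter.
#' Refuses to run unless every required structure is present in the volume,
#' so that chance proximity is neither over- nor underestimated.
#'
#' @param masks named mask list including `marrow_admissible`.
#' @param n_random number of random spots (>= 100).
#' @param diameter spot diameter in µm (default 10).
#' @param seed integer seed.
#' @param required structures whose presence is a precondition (default
#'   arterioles, type H, type L and bone).
#' @return a `spot_set` with `kind = "random"`.
#' @export
generate_random_spots <- function(masks, n_random, diameter = 10, seed = 1L,
                                  required = c("arterial", "type_h", "type_l",
                                               "bone_surface")) {
  if (n_random < 100) stop_validation("`n_random` must be at least 100.")
  if (diameter <= 0) stop_validation("`diameter` must be positive.")
  for (st in required) {
    if (!st %in% names(masks) || sum(masks[[st]]) == 0) {
      stop_precondition(sprintf(
        "volume lacks required structure '%s'; random spots are only generated on volumes containing all relevant vessel subtypes and bone.",
        st
      ))
    }
  }
  dims <- dim(masks[[1]])
  spacing <- mask_spacing(masks[[1]])
  adm <- which(masks$marrow_admissible)
  if (length(adm) == 0) stop_validation("admissible mask is empty.")
  with_seed(seed, {
    idx <- adm[sample.int(length(adm), n_random, replace = TRUE)]
    ijk <- index_to_ijk(idx, dims)
    centres <- ijk_to_um(ijk, spacing) +
      matrix(runif(3 * n_random, -0.45, 0.45), ncol = 3) *
        matrix(spacing, n_random, 3, byrow = TRUE)
    spot_set(tibble::tibble(
      id = seq_len(n_random),
      x_um = centres[, 1], y_um = centres[, 2], z_um = centres[, 3],
      radius_um = diameter / 2,
      kind = "random"
    ))
  })
}

#' Convergence check for the random-spot null model
#'
#' Recomputes the null-model proximity fraction at several spot counts across
#' repeated seeds and reports the across-seed standard deviation per count,
#' together with the smallest count whose s.d. falls below the tolerance —
#' the empirical "minimal number of random spots" validator.
#'
#' @param masks mask list.
#' @param structure structure name.
#' @param n_random reference spot count.
#' @param threshold proximity threshold in µm.
#' @param factors multipliers of `n_random` to test.
#' @param n_seeds seeds per count (>= 5 recommended).
#' @param tolerance_pp tolerance on the s.d. in percentage points.
#' @param seed base seed.
#' @return list with `report` tibble (`n`, `mean_fraction`, `sd_fraction`)
#'   and `recommended_n` (smallest n with s.d. below tolerance, NA if none).
#' @export
null_convergence_check <- function(masks, structure, n_random = 1000,
                                   threshold = 10,
                                   factors = c(0.25, 0.5, 1, 2),
                                   n_seeds = 5, tolerance_pp = 0.5,
                                   seed = 1L) {
  dims <- dim(masks[[1]])
  spacing <- mask_spacing(masks[[1]])
  fld <- distance_field(masks[[structure]], spacing, structure)
  fields <- setNames(list(fld), structure)
  ns <- pmax(100L, as.integer(round(factors * n_random)))
  rows <- purrr::map_dfr(seq_along(ns), function(i) {
    fr <- vapply(seq_len(n_seeds), function(s) {
      sp <- generate_random_spots(masks, ns[i], seed = derive_seed(seed, paste0("conv", i, "_", s)))
      dt <- measure_spot_distances(sp, fields)
      mean(dt[[paste0("dist_", structure)]] <= threshold)
    }, numeric(1))
    tibble::tibble(n = ns[i], mean_fraction = mean(fr), sd_fraction = sd(fr))
  })
  ok <- rows$n[rows$sd_fraction * 100 < tolerance_pp]
  list(report = rows, recommended_n = if (length(ok) > 0) min(ok) else NA_integer_)
}

#' Bin spot distances into a histogram with an overflow bin
#'
#' Right-open bins `[0, w), [w, 2w), ...` up to `max_um`, plus a final
#' overflow bin `[max_um, Inf)`; counts sum to the number of spots.
#'
#' @param table distance table.
#' @param structure structure name.
#' @param bin_width bin width in µm (default 10).
#' @param max_um start of the overflow bin (default 30).
#' @return tibble with `kind`, `bin_lo`, `bin_hi`, `count`, `fraction`.
#' @export
distance_histogram <- function(table, structure, bin_width = 10, max_um = 30) {
  if (bin_width <= 0) stop_validation("`bin_width` must be positive.")
  col <- paste0("dist_", structure)
  if (!col %in% names(table)) {
    stop_validation(sprintf("distance column '%s' not present.", col))
  }
  lo <- seq(0, max_um - bin_width, by = bin_width)
  edges <- c(lo, max_um)
  tbl <- tibble::as_tibble(table)
  if (!"kind" %in% names(tbl)) tbl$kind <- "dtc"
  purrr::map_dfr(split(tbl, tbl$kind), function(g) {
    d <- g[[col]]
    bin <- pmin(findInterval(d, edges), length(edges))
    counts <- tabulate(bin, nbins = length(edges))
    tibble::tibble(
      kind = g$kind[1],
      bin_lo = edges,
      bin_hi = c(edges[-1], Inf),
      count = counts,
      fraction = counts / length(d)
    )
  })
}

#' Tumour volume from caliper measurements
#'
#' The standard ellipsoidal approximation width^2 x length / 2.
#'
#' @param width_mm,length_mm caliper width and length in mm (> 0); vectorised.
#' @return tumour volume(s) in mm^3.
#' @examples
#' tumour_volume(5, 8) # 100
#' @export
tumour_volume <- function(width_mm, length_mm) {
  if (any(!is.finite(width_mm)) || any(!is.finite(length_mm)) ||
      any(width_mm <= 0) || any(length_mm <= 0)) {
    stop_validation("width and length must be positive.")
  }
  width_mm^2 * length_mm / 2
}
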