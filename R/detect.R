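#' Detect tumour-cell spots in the tumour-reporter channel
#'
#' Difference-of-Gaussian blob detection (a numerically robust approximation
#' of the scale-normalised Laplacian of Gaussian) at a single scale matched
#' to the expected spot diameter, with per-axis sigmas corrected for the
#' anisotropic voxel spacing. Local response maxima below the intensity
#' threshold are discarded; centroids are refined to sub-voxel precision by
#' a per-axis parabolic fit; detection uses no random numbers.
#'
#' @param vol an [image_volume()] with the spot channel.
#' @param expected_diameter expected spot diameter in µm (default 10, the
#'   size of a DTC). Must be at least twice the largest voxel spacing to be
#'   resolvable.
#' @param intensity_threshold minimum smoothed channel intensity at a
#'   candidate maximum; default `NULL` sets it to median + 8 MAD of the
#'   smoothed channel, which suppresses background texture while remaining
#'   robust to the spots themselves.
#' @param channel channel name (default `"tumour"`).
#' @return a `spot_set` tibble with `peak_intensity`, `quality` (normalised
#'   blob response) and `is_cluster` (fitted radius > 1.5 x expected).
#' @export
detect_spots <- function(vol, expected_diameter = 10,
                         intensity_threshold = NULL, channel = "tumour") {
  if (!channel %in% names(vol$channels)) {
    stop_validation(sprintf("channel '%s' not present in volume.", channel))
  }
  spacing <- vol$spacing
  if (expected_diameter < 2 * max(spacing)) {
    stop_validation(sprintf(
      "expected diameter %g um is below the resolvable size (2 x max spacing = %g um).",
      expected_diameter, 2 * max(spacing)
    ))
  }
  dims <- dim(vol)
  a <- as.numeric(vol$channels[[channel]])
  sigma_um <- expected_diameter / (2 * sqrt(3))
  s1 <- sigma_um / spacing
  g1 <- cpp_blur3d(a, dims, s1)
  g2 <- cpp_blur3d(a, dims, 1.6 * s1)
  dog <- g1 - g2
  if (is.null(intensity_threshold)) {
    # median + 8 MAD of the smoothed channel: robust to the spots themselves
    # (which can occupy percents of the volume and inflate a plain sd), while
    # sitting far above the maxima of smoothed background noise, whose
    # spatial correlation pushes extremes well past the few-sd range of
    # independent samples
    intensity_threshold <- stats::median(g1) + 8 * stats::mad(g1)
  }
  peaks <- cpp_local_maxima(dog, dims, 1e-9)
  if (nrow(peaks) == 0) return(empty_detection(expected_diameter))
  lin <- peaks[, 1] + dims[1] * (peaks[, 2] + dims[2] * peaks[, 3]) + 1
  keep <- g1[lin] >= intensity_threshold
  peaks <- peaks[keep, , drop = FALSE]
  lin <- lin[keep]
  if (nrow(peaks) == 0) return(empty_detection(expected_diameter))

  g1a <- array(g1, dims)
  doga <- array(dog, dims)
  refine <- function(p) {
    out <- numeric(3)
    for (ax in 1:3) {
      lo <- p
      hi <- p
      lo[ax] <- lo[ax] - 1
      hi[ax] <- hi[ax] + 1
      if (lo[ax] < 0 || hi[ax] >= dims[ax]) {
        out[ax] <- 0
        next
      }
      f0 <- doga[p[1] + 1, p[2] + 1, p[3] + 1]
      fm <- doga[lo[1] + 1, lo[2] + 1, lo[3] + 1]
      fp <- doga[hi[1] + 1, hi[2] + 1, hi[3] + 1]
      den <- fm - 2 * f0 + fp
      out[ax] <- if (abs(den) > 1e-12) min(max(0.5 * (fm - fp) / den, -0.5), 0.5) else 0
    }
    out
  }
  n <- nrow(peaks)
  centres <- matrix(0, n, 3)
  r_eff <- numeric(n)
  rbox <- ceiling(0.75 * expected_diameter / spacing)
  voxvol <- prod(spacing)
  for (s in seq_len(n)) {
    p <- peaks[s, ]
    centres[s, ] <- (p + refine(p)) * spacing
    i0 <- pmax(p - rbox, 0)
    i1 <- pmin(p + rbox, dims - 1)
    box <- g1a[(i0[1]:i1[1]) + 1, (i0[2]:i1[2]) + 1, (i0[3]:i1[3]) + 1]
    v <- sum(box >= 0.5 * g1a[p[1] + 1, p[2] + 1, p[3] + 1]) * voxvol
    r_eff[s] <- (3 * v / (4 * pi))^(1 / 3)
  }
  resp <- dog[lin]
  spot_set(tibble::tibble(
    id = seq_len(n),
    x_um = centres[, 1], y_um = centres[, 2], z_um = centres[, 3],
    radius_um = r_eff,
    kind = "dtc",
    peak_intensity = g1[lin],
    quality = resp / max(resp),
    is_cluster = r_eff > 1.5 * expected_diameter / 2
  ))
}

empty_detection <- function(expected_diameter) {
  spot_set(tibble::tibble(
    id = integer(), x_um = numeric(), y_um = numeric(), z_um = numeric(),
    radius_um = numeric(), kind = character(), peak_intensity = numeric(),
    quality = numeric(), is_cluster = logical()
  ))
}

#' Curate detected spots against structure masks
#'
#' Automated surrogate for manual curation: removes spots whose centroid lies
#' inside bone or a vessel lumen, outside the admissible marrow, or below a
#' quality cutoff. Removal reasons are recorded per spot.
#'
#' @param spots a `spot_set`.
#' @param masks named mask list (uses `bone_surface`, `lumen`,
#'   `marrow_admissible` when present).
#' @param rules list of switches: `remove_in_bone`, `remove_in_lumen`,
#'   `require_marrow`, `min_quality` (defaults TRUE, TRUE, FALSE, 0).
#' @return the curated `spot_set`; removed spots with reasons are attached as
#'   `attr(, "removed")`.
#' @export
curate_spots <- function(spots, masks,
                         rules = list(remove_in_bone = TRUE,
                                      remove_in_lumen = TRUE,
                                      require_marrow = FALSE,
                                      min_quality = 0)) {
  rules <- utils::modifyList(
    list(remove_in_bone = TRUE, remove_in_lumen = TRUE,
         require_marrow = FALSE, min_quality = 0),
    rules
  )
  if (nrow(spots) == 0) {
    attr(spots, "removed") <- tibble::tibble(id = integer(), reason = character())
    return(spots)
  }
  dims <- dim(masks[[1]])
  spacing <- mask_spacing(masks[[1]])
  ijk <- round(sweep(spot_coords(spots), 2, spacing, "/"))
  ijk <- pmin(pmax(ijk, 0), matrix(dims - 1, nrow(ijk), 3, byrow = TRUE))
  lin <- ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3]) + 1
  reason <- rep(NA_character_, nrow(spots))
  at <- function(mask) as.logical(mask)[lin]
  if (rules$remove_in_bone && "bone_surface" %in% names(masks)) {
    reason[is.na(reason) & at(masks$bone_surface)] <- "in_bone"
  }
  if (rules$remove_in_lumen && "lumen" %in% names(masks)) {
    reason[is.na(reason) & at(masks$lumen)] <- "in_lumen"
  }
  if (rules$require_marrow && "marrow_admissible" %in% names(masks)) {
    reason[is.na(reason) & !at(masks$marrow_admissible)] <- "outside_marrow"
  }
  if (rules$min_quality > 0 && "quality" %in% names(spots)) {
    reason[is.na(reason) & spots$quality < rules$min_quality] <- "low_quality"
  }
  removed <- tibble::tibble(id = spots$id[!is.na(reason)],
                            reason = reason[!is.na(reason)])
  out <- spots[is.na(reason), ]
  attr(out, "removed") <- removed
  out
}
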