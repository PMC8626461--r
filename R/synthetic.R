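#' Configuration for the synthetic bone-marrow generator
#'
#' Builds the full parameter set for [generate_dataset()]: grid geometry, bone
#' geometry, the hierarchical vessel network (arterioles branching into type H
#' capillaries, then type L sinusoids), per-subtype CD31/EMCN intensity model,
#' endothelial sprout model, and DTC placement model. Unspecified entries keep
#' their documented defaults; supplied lists are merged element-wise.
#'
#' Defaults: spacing (1, 1, 2) µm emulates confocal z-undersampling; subtype
#' radii (arterial 8, type H 5, type L 12 µm) follow the calibre hierarchy of
#' marrow arterioles, capillaries and sinusoids; the DTC spot radius of 5 µm
#' matches a 10 µm cell; intensity means put arterial voxels at
#' CD31-high/EMCN-background, type H at double-high and type L at double-low
#' so that per-channel three-class thresholds can separate them.
#'
#' @param dims integer length-3 voxel grid size (nx, ny, nz).
#' @param spacing numeric length-3 voxel size in µm (sx, sy, sz).
#' @param bone,vessels,intensity,sprouts,dtc named lists overriding the
#'   defaults printed by `str(synthetic_config())`.
#' @param seed integer master seed; every stochastic stage derives its own
#'   stream from it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(dims = c(256L, 256L, 64L),
                             spacing = c(1, 1, 2),
                             bone = list(),
                             vessels = list(),
                             intensity = list(),
                             sprouts = list(),
                             dtc = list(),
                             seed = 1L) {
  cfg <- list(
    dims = as.integer(dims),
    spacing = as.numeric(spacing),
    bone = utils::modifyList(list(
      cortical_thickness = 6,     # µm, solid plate at the x = 0 face
      n_trabeculae = 2,
      trabecular_thickness = 6,   # µm
      trabecular_radius = 30,     # µm, extent of each trabecular plate
      metaphysis_band = c(12, 70) # µm band (x) holding trabeculae
    ), bone),
    vessels = utils::modifyList(list(
      n_arterioles = 3L,
      branch_factor = 2L,
      radius_mean = c(arterial = 8, type_h = 5, type_l = 12),
      radius_sd = c(arterial = 1, type_h = 0.6, type_l = 1.5),
      seg_length = c(arterial = 90, type_h = 150, type_l = 80),
      lumen_fraction = 0.5,
      tortuosity = 2,  # µm-scale perpendicular jitter of centreline points
      step = 6         # µm centreline sampling step
    ), vessels),
    intensity = utils::modifyList(list(
      mean_cd31 = c(arterial = 200, type_h = 200, type_l = 80),
      mean_emcn = c(arterial = 8, type_h = 200, type_l = 80),
      background = c(cd31 = 10, emcn = 8),
      noise_sd = 12,
      blur_sigma = 0.5,   # µm
      nuclear_mean = 40,
      tumour_peak = 150
    ), intensity),
    sprouts = utils::modifyList(list(
      density_per_100um = 2,
      length_mean = 8,
      length_sd = 2,
      radius = 1.5,
      min_anchor_gap = 8,
      subtypes = c("type_h", "type_l")
    ), sprouts),
    dtc = utils::modifyList(list(
      n_spots = 500L,
      radius = 5,
      mix = c(perivascular_any = 0.5, near_bone = 0.03, near_type_h = 0.15),
      shell = 10,
      min_separation = 11
    ), dtc),
    seed = seed
  )
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  if (length(cfg$dims) != 3 || any(cfg$dims < 4)) {
    stop_validation("`dims` must be three voxel counts >= 4.")
  }
  cfg$spacing <- check_spacing(cfg$spacing)
  mix <- cfg$dtc$mix
  if (any(mix < 0) || any(mix > 1) || sum(mix) > 1 + 1e-12) {
    stop_validation("dtc placement mix fractions must lie in [0, 1] and sum to <= 1.")
  }
  pos <- c(cfg$vessels$radius_mean, cfg$vessels$seg_length, cfg$dtc$radius,
           cfg$dtc$shell, cfg$sprouts$length_mean, cfg$sprouts$radius,
           cfg$bone$cortical_thickness)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop_validation("all µm quantities (radii, lengths, shell) must be positive.")
  }
  if (cfg$sprouts$density_per_100um < 0) {
    stop_validation("sprout density must be non-negative.")
  }
  if (cfg$vessels$lumen_fraction < 0 || cfg$vessels$lumen_fraction >= 1) {
    stop_validation("`lumen_fraction` must lie in [0, 1).")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# --- vessel tree ---------------------------------------------------------

unit <- function(v) v / sqrt(sum(v^2))

# random unit vector perpendicular to d
perp_unit <- function(d) {
  repeat {
    r <- rnorm(3)
    p <- r - sum(r * d) * d
    n <- sqrt(sum(p^2))
    if (n > 1e-8) return(p / n)
  }
}

# Grow one polyline segment: a bounded-curvature random walk from `start`
# along `dir0`, with perpendicular jitter scaled by the tortuosity setting,
# clamped to stay `margin` µm inside the physical bounds.
grow_segment <- function(start, dir0, length_um, step, tortuosity, bounds, margin) {
  npts <- max(2L, as.integer(round(length_um / step)) + 1L)
  pts <- matrix(0, npts, 3)
  pts[1, ] <- start
  d <- unit(dir0)
  jitter_scale <- min(1, tortuosity / step)
  for (t in 2:npts) {
    d <- unit(d + jitter_scale * 0.6 * perp_unit(d) * abs(rnorm(1)))
    # keep heading within ~45 degrees of the segment's initial direction
    if (sum(d * unit(dir0)) < 0.7) d <- unit(0.5 * d + 0.5 * unit(dir0))
    p <- pts[t - 1, ] + d * step
    p <- pmin(pmax(p, margin), bounds - margin)
    pts[t, ] <- p
  }
  pts
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

trunc_rnorm <- function(n, mean, sd, lo) pmax(rnorm(n, mean, sd), lo)

#' Build a hierarchical marrow vessel tree
#'
#' Grows `n_arterioles` arterial paths entering from the face opposite the
#' cortical bone, each terminating in `branch_factor` type H capillary
#' branches that head toward the bone, each of which feeds `branch_factor`
#' type L sinusoid branches wandering back into the central marrow. The
#' subtype order along any root-to-leaf path is therefore always
#' arterial -> type_h -> type_l.
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed (defaults to a stream derived from `cfg$seed`).
#' @return an object of class `vessel_tree`: list with a `segments` tibble
#'   (seg_id, parent_id, subtype, radius_um, length_um, points) and an empty
#'   `sprouts` tibble (see [add_sprouts()]).
#' @export
build_vessel_tree <- function(cfg, seed = derive_seed(cfg$seed, "tree")) {
  bounds <- (cfg$dims - 1) * cfg$spacing
  if (any(bounds < 3 * max(cfg$vessels$radius_mean))) {
    stop_generation("grid too small to contain a minimal vessel tree at the configured radii.")
  }
  vs <- cfg$vessels
  with_seed(seed, {
    segs <- list()
    sid <- 0L
    add_seg <- function(parent, subtype, pts) {
      sid <<- sid + 1L
      segs[[sid]] <<- list(
        seg_id = sid, parent_id = parent, subtype = subtype,
        radius_um = trunc_rnorm(1, vs$radius_mean[[subtype]], vs$radius_sd[[subtype]], 1.5),
        length_um = polyline_length(pts), points = pts
      )
      sid
    }
    for (a in seq_len(vs$n_arterioles)) {
      start <- c(
        bounds[1] - 2,
        runif(1, 0.25, 0.75) * bounds[2],
        runif(1, 0.25, 0.75) * bounds[3]
      )
      dir0 <- unit(c(-1, rnorm(1, 0, 0.2), rnorm(1, 0, 0.2)))
      pts <- grow_segment(start, dir0, vs$seg_length[["arterial"]], vs$step,
                          vs$tortuosity, bounds, 2)
      aid <- add_seg(NA_integer_, "arterial", pts)
      aend <- pts[nrow(pts), ]
      atan <- unit(pts[nrow(pts), ] - pts[nrow(pts) - 1, ])
      for (h in seq_len(vs$branch_factor)) {
        dirh <- unit(0.8 * atan + 0.8 * perp_unit(atan))
        if (dirh[1] > -0.1) dirh <- unit(dirh + c(-0.5, 0, 0)) # keep heading boneward
        ptsh <- grow_segment(aend, dirh, vs$seg_length[["type_h"]], vs$step,
                             vs$tortuosity, bounds, 2)
        hid <- add_seg(aid, "type_h", ptsh)
        hend <- ptsh[nrow(ptsh), ]
        htan <- unit(ptsh[nrow(ptsh), ] - ptsh[nrow(ptsh) - 1, ])
        for (l in seq_len(vs$branch_factor)) {
          dirl <- unit(0.4 * htan + perp_unit(htan) + c(0.6, 0, 0))
          ptsl <- grow_segment(hend, dirl, vs$seg_length[["type_l"]], vs$step,
                               vs$tortuosity, bounds, 2)
          add_seg(hid, "type_l", ptsl)
        }
      }
    }
    segments <- tibble::tibble(
      seg_id = vapply(segs, `[[`, integer(1), "seg_id"),
      parent_id = vapply(segs, `[[`, integer(1), "parent_id"),
      subtype = vapply(segs, `[[`, character(1), "subtype"),
      radius_um = vapply(segs, `[[`, numeric(1), "radius_um"),
      length_um = vapply(segs, `[[`, numeric(1), "length_um"),
      points = lapply(segs, `[[`, "points")
    )
    structure(list(segments = segments, sprouts = empty_sprouts()),
              class = "vessel_tree")
  })
}

empty_sprouts <- function() {
  tibble::tibble(
    sprout_id = integer(), seg_id = integer(), subtype = character(),
    x_um = numeric(), y_um = numeric(), z_um = numeric(),
    dx = numeric(), dy = numeric(), dz = numeric(),
    length_um = numeric(), radius_um = numeric()
  )
}

# interpolate a point (and tangent) at arc position s along a polyline
polyline_point <- function(pts, s) {
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  s <- min(max(s, 0), cum[length(cum)])
  i <- max(1L, findInterval(s, cum, rightmost.closed = TRUE))
  i <- min(i, nrow(pts) - 1L)
  f <- if (seglen[i] > 0) (s - cum[i]) / seglen[i] else 0
  p <- pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
  list(point = p, tangent = unit(pts[i + 1, ] - pts[i, ]))
}

#' Add endothelial sprouts to a vessel tree
#'
#' Sprout anchors are drawn as a Poisson process along the centrelines of the
#' configured subtypes (type H and type L by default; arterioles are spared)
#' at `density_per_100um` expected sprouts per 100 µm of vessel length.
#' Lengths are Gaussian, truncated at 1 µm; directions are perpendicular to
#' the local centreline tangent.
#'
#' @param tree a [build_vessel_tree()] result.
#' @param cfg the [synthetic_config()].
#' @param seed integer seed.
#' @return the tree with its `sprouts` tibble filled in.
#' @export
add_sprouts <- function(tree, cfg, seed = derive_seed(cfg$seed, "sprouts")) {
  sp <- cfg$sprouts
  if (sp$density_per_100um < 0) stop_validation("sprout density must be non-negative.")
  if (nrow(tree$segments) == 0) stop_validation("vessel tree has no segments.")
  if (sp$density_per_100um == 0) {
    tree$sprouts <- empty_sprouts()
    return(tree)
  }
  with_seed(seed, {
    recs <- list()
    n_id <- 0L
    for (r in seq_len(nrow(tree$segments))) {
      seg <- tree$segments[r, ]
      if (!(seg$subtype %in% sp$subtypes)) next
      lambda <- sp$density_per_100um * seg$length_um / 100
      n <- rpois(1, lambda)
      if (n == 0) next
      pts <- seg$points[[1]]
      # lateral inhibition: anchors keep a minimum arc spacing, so sprouts
      # do not stack on top of each other (Matern-style thinning)
      anchors_s <- sort(runif(n) * seg$length_um)
      keep <- rep(TRUE, n)
      if (n > 1) {
        last <- anchors_s[1]
        for (t in 2:n) {
          if (anchors_s[t] - last < sp$min_anchor_gap) keep[t] <- FALSE
          else last <- anchors_s[t]
        }
      }
      anchors_s <- anchors_s[keep]
      for (t in seq_along(anchors_s)) {
        pp <- polyline_point(pts, anchors_s[t])
        d <- perp_unit(pp$tangent)
        # the sprout emanates from the endothelial surface, not the
        # centreline: anchor one vessel radius out along its direction
        anchor <- pp$point + d * seg$radius_um
        n_id <- n_id + 1L
        recs[[n_id]] <- tibble::tibble(
          sprout_id = n_id, seg_id = seg$seg_id, subtype = seg$subtype,
          x_um = anchor[1], y_um = anchor[2], z_um = anchor[3],
          dx = d[1], dy = d[2], dz = d[3],
          length_um = trunc_rnorm(1, sp$length_mean, sp$length_sd, 1),
          radius_um = sp$radius
        )
      }
    }
    tree$sprouts <- if (n_id > 0) dplyr::bind_rows(recs) else empty_sprouts()
    tree
  })
}

# --- voxelization --------------------------------------------------------

SUBTYPES <- c("arterial", "type_h", "type_l")

# vectorised arc-length resampling of a polyline at step ds
resample_polyline <- function(P, ds) {
  if (nrow(P) < 2) return(P)
  seglen <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  ss <- seq(0, total, by = ds)
  i <- pmin(pmax(findInterval(ss, cum, rightmost.closed = TRUE), 1L), nrow(P) - 1L)
  f <- ifelse(seglen[i] > 0, (ss - cum[i]) / seglen[i], 0)
  P[i, , drop = FALSE] + f * (P[i + 1L, , drop = FALSE] - P[i, , drop = FALSE])
}

# Resample all centrelines (and sprout axes) at ds spacing for capsule
# painting; returns pts matrix, radii, subtype labels.
tree_sample_points <- function(tree, ds, spacing, include_sprouts = TRUE) {
  pts <- list(); rad <- list(); lab <- list()
  for (r in seq_len(nrow(tree$segments))) {
    seg <- tree$segments[r, ]
    M <- resample_polyline(seg$points[[1]], ds)
    pts[[length(pts) + 1L]] <- M
    rad[[length(rad) + 1L]] <- rep(seg$radius_um, nrow(M))
    lab[[length(lab) + 1L]] <- rep(match(seg$subtype, SUBTYPES), nrow(M))
  }
  chains <- list()
  if (include_sprouts && nrow(tree$sprouts) > 0) {
    for (r in seq_len(nrow(tree$sprouts))) {
      s <- tree$sprouts[r, ]
      # paint the sprout body as a thin capsule for realistic surface area,
      # and additionally mark the nearest-voxel chain along its axis starting
      # inside the parent wall: the minimal 26-connected chain guarantees the
      # sprout stays voxel-connected to the vessel and survives thinning
      ss <- seq(-2, s$length_um, by = ds)
      M <- cbind(s$x_um + ss * s$dx, s$y_um + ss * s$dy, s$z_um + ss * s$dz)
      body <- ss >= 0 & ss <= max(0, s$length_um - 2 - s$radius_um)
      pts[[length(pts) + 1L]] <- M[body, , drop = FALSE]
      rad[[length(rad) + 1L]] <- rep(s$radius_um, sum(body))
      lab[[length(lab) + 1L]] <- rep(match(s$subtype, SUBTYPES), sum(body))
      chains[[length(chains) + 1L]] <- list(um = M,
                                            label = match(s$subtype, SUBTYPES))
    }
  }
  list(pts = do.call(rbind, pts), rad = unlist(rad), lab = as.integer(unlist(lab)),
       chains = if (length(chains) > 0) chains else NULL)
}

# Mark the voxels nearest to a polyline's sample points as a minimal
# 26-connected chain: consecutive duplicates and staircase-corner voxels
# (whose removal leaves the neighbours adjacent) are pruned, so the chain tip
# has exactly one neighbour and survives topological thinning intact.
mark_chain_voxels <- function(lab, chain_um, label, dims, spacing) {
  ijk <- cbind(round(chain_um[, 1] / spacing[1]),
               round(chain_um[, 2] / spacing[2]),
               round(chain_um[, 3] / spacing[3]))
  keep <- c(TRUE, rowSums(abs(diff(ijk))) > 0)
  ijk <- ijk[keep, , drop = FALSE]
  repeat {
    n <- nrow(ijk)
    if (n < 3) break
    drop <- rep(FALSE, n)
    i <- 2L
    while (i < n) {
      if (all(abs(ijk[i - 1, ] - ijk[i + 1, ]) <= 1)) {
        drop[i] <- TRUE
        i <- i + 2L # re-examined on the next sweep
      } else {
        i <- i + 1L
      }
    }
    if (!any(drop)) break
    ijk <- ijk[!drop, , drop = FALSE]
  }
  ok <- ijk[, 1] >= 0 & ijk[, 2] >= 0 & ijk[, 3] >= 0 &
    ijk[, 1] < dims[1] & ijk[, 2] < dims[2] & ijk[, 3] < dims[3]
  lin <- ijk[ok, 1] + dims[1] * (ijk[ok, 2] + dims[2] * ijk[ok, 3]) + 1
  free <- lab[lin] == 0L
  lab[lin[free]] <- label
  lab
}

build_bone_mask <- function(cfg, seed = derive_seed(cfg$seed, "bone")) {
  dims <- cfg$dims
  co <- coord_arrays(dims, cfg$spacing)
  bone <- co$x < cfg$bone$cortical_thickness
  if (cfg$bone$n_trabeculae > 0) {
    with_seed(seed, {
      for (t in seq_len(cfg$bone$n_trabeculae)) {
        centre <- c(
          runif(1, cfg$bone$metaphysis_band[1], cfg$bone$metaphysis_band[2]),
          runif(1, 0.25, 0.75) * (dims[2] - 1) * cfg$spacing[2],
          runif(1, 0.25, 0.75) * (dims[3] - 1) * cfg$spacing[3]
        )
        n <- unit(rnorm(3))
        dx <- co$x - centre[1]; dy <- co$y - centre[2]; dz <- co$z - centre[3]
        dot <- dx * n[1] + dy * n[2] + dz * n[3]
        r2 <- dx^2 + dy^2 + dz^2 - dot^2
        bone <- bone | (abs(dot) < cfg$bone$trabecular_thickness / 2 &
                          r2 < cfg$bone$trabecular_radius^2)
      }
    })
  }
  bone
}

#' Rasterise a vessel tree into per-structure masks
#'
#' Vessels are capsule unions: a voxel belongs to a subtype mask iff its
#' centre lies within the local radius of the nearest centreline sample;
#' subtype ties go to the nearest centreline. The lumen mask uses
#' `lumen_fraction * radius`. Bone is a cortical plate at the x = 0 face plus
#' the configured trabecular plates; vessels carve through bone. The
#' `marrow_admissible` mask is everything that is neither vessel nor bone.
#'
#' @param tree a [build_vessel_tree()] result (with or without sprouts).
#' @param cfg the [synthetic_config()].
#' @return list with `masks` (named list of `structure_mask`: `arterial`,
#'   `type_h`, `type_l`, `vessel_any`, `lumen`, `bone_surface`,
#'   `marrow_admissible`), `subtype_label` (integer array,
#'   0 = background, 1..3 = arterial/type_h/type_l) and a `vessels`
#'   ground-truth tibble.
#' @export
voxelize_tree <- function(tree, cfg) {
  dims <- cfg$dims
  spacing <- check_spacing(cfg$spacing)
  n <- prod(dims)
  ds <- min(spacing) / 2
  lab <- array(0L, dims)
  bestd <- array(Inf, dims)
  lum <- array(0L, dims)
  bestdl <- array(Inf, dims)
  if (nrow(tree$segments) > 0) {
    sm <- tree_sample_points(tree, ds, spacing, include_sprouts = TRUE)
    cpp_paint_spheres(lab, bestd, dims, spacing, sm$pts, sm$rad, sm$lab)
    for (ch in sm$chains) {
      lab <- mark_chain_voxels(lab, ch$um, as.integer(ch$label), dims, spacing)
    }
    core <- tree_sample_points(tree, ds, spacing, include_sprouts = FALSE)
    cpp_paint_spheres(lum, bestdl, dims, spacing, core$pts,
                      core$rad * cfg$vessels$lumen_fraction, core$lab)
  }
  bone <- build_bone_mask(cfg)
  bone <- bone & (lab == 0L)
  vessel_any <- lab > 0L
  masks <- list(
    arterial = lab == 1L,
    type_h = lab == 2L,
    type_l = lab == 3L,
    vessel_any = vessel_any,
    lumen = lum > 0L,
    bone_surface = bone,
    marrow_admissible = !vessel_any & !bone
  )
  masks <- lapply(setNames(names(masks), names(masks)), function(nm) {
    structure_mask(masks[[nm]], nm, spacing)
  })
  vessels <- dplyr::mutate(
    tree$segments[, c("seg_id", "parent_id", "subtype", "radius_um", "length_um")],
    lateral_area_um2 = 2 * pi * .data$radius_um * .data$length_um
  )
  list(masks = masks, subtype_label = lab, vessels = vessels)
}

# --- channel rendering ---------------------------------------------------

#' Render CD31/EMCN/nuclear/tumour channels from structure masks
#'
#' Each vessel subtype receives its configured mean CD31 and EMCN intensity
#' (arterial: CD31 high, EMCN at background; type H: both high; type L: both
#' low-positive), plus Gaussian noise and an optional isotropic Gaussian blur;
#' intensities are clipped at 0. The nuclear channel is a marrow background
#' texture; the tumour channel renders DTC spots as uniform spheres.
#'
#' @param masks mask list from [voxelize_tree()].
#' @param cfg the [synthetic_config()].
#' @param seed integer seed for the noise draws.
#' @param spots optional spot tibble rendered into the tumour channel.
#' @return an [image_volume()] with channels `nuclear`, `cd31`, `emcn`,
#'   `tumour`.
#' @export
render_channels <- function(masks, cfg, seed = derive_seed(cfg$seed, "render"),
                            spots = NULL) {
  need <- c(SUBTYPES, "bone_surface", "marrow_admissible")
  miss <- setdiff(need, names(masks))
  if (length(miss) > 0) {
    stop_generation(sprintf("mask set is missing structure(s): %s.",
                            paste(miss, collapse = ", ")))
  }
  dims <- dim(masks[[1]])
  spacing <- mask_spacing(masks[[1]], cfg$spacing)
  it <- cfg$intensity
  n <- prod(dims)
  sigma_vox <- if (it$blur_sigma > 0) it$blur_sigma / spacing else c(0, 0, 0)

  with_seed(seed, {
    finish <- function(a) {
      if (it$noise_sd > 0) a <- a + rnorm(n, 0, it$noise_sd)
      if (any(sigma_vox > 0)) a <- array(cpp_blur3d(a, dims, sigma_vox), dims)
      a[a < 0] <- 0
      array(a, dims)
    }
    cd31 <- array(it$background[["cd31"]], dims)
    emcn <- array(it$background[["emcn"]], dims)
    for (s in SUBTYPES) {
      cd31[masks[[s]]] <- it$mean_cd31[[s]]
      emcn[masks[[s]]] <- it$mean_emcn[[s]]
    }
    nuclear <- array(0.2 * it$nuclear_mean, dims)
    nuclear[masks$marrow_admissible] <- it$nuclear_mean
    tumour <- array(0, dims)
    if (!is.null(spots) && nrow(spots) > 0) {
      tl <- array(0L, dims)
      td <- array(Inf, dims)
      cpp_paint_spheres(tl, td, dims, spacing, spot_coords(spots),
                        spots$radius_um, rep(1L, nrow(spots)))
      tumour[tl > 0L] <- it$tumour_peak
    }
    image_volume(
      list(nuclear = finish(nuclear), cd31 = finish(cd31),
           emcn = finish(emcn), tumour = finish(tumour)),
      spacing
    )
  })
}

# --- DTC placement -------------------------------------------------------

placement_target <- c(
  perivascular_any = "vessel_any",
  near_bone = "bone_surface",
  near_type_h = "type_h",
  near_type_l = "type_l"
)

#' Place DTC spots with configurable spatial preference
#'
#' Each spot draws a placement class from the configured mix
#' (`perivascular_any`, `near_bone`, `near_type_h`, remainder uniform).
#' "Near-X" spots are placed uniformly among admissible voxels within the
#' shell distance of structure X; "uniform" spots uniformly over all
#' admissible voxels. Centres get sub-voxel jitter and respect a hard-core
#' minimum separation (DTCs model whole cells that cannot interpenetrate).
#' The true placement class and the true distance to each relevant structure
#' are recorded per spot.
#'
#' @param cfg the [synthetic_config()].
#' @param masks mask list from [voxelize_tree()].
#' @param seed integer seed.
#' @return a `spot_set` tibble with extra columns `true_class` and
#'   `true_dist_<structure>`.
#' @export
place_dtcs <- function(cfg, masks, seed = derive_seed(cfg$seed, "dtc")) {
  dims <- dim(masks[[1]])
  spacing <- mask_spacing(masks[[1]], cfg$spacing)
  n_spots <- cfg$dtc$n_spots
  if (n_spots == 0) {
    return(spot_set(tibble::tibble(
      id = integer(), x_um = numeric(), y_um = numeric(), z_um = numeric(),
      radius_um = numeric(), kind = character(), true_class = character()
    )))
  }
  adm <- which(masks$marrow_admissible)
  if (length(adm) == 0) stop_generation("marrow_admissible mask is empty.")

  mix <- cfg$dtc$mix
  mix <- mix[mix > 0]
  classes <- c(names(mix), "uniform")
  probs <- c(unname(mix), max(0, 1 - sum(mix)))

  # distance fields for every preference structure (reused for truth
  # records); vessel_any, when present, is always recorded as the principal
  # niche structure
  structures <- unique(unname(placement_target[names(mix)]))
  if (sum(masks$vessel_any) > 0) structures <- unique(c("vessel_any", structures))
  fields <- list()
  pools <- list(uniform = adm)
  for (st in unique(unname(placement_target[names(mix)]))) {
    if (sum(masks[[st]]) == 0) {
      stop_generation(sprintf("placement preference targets empty structure '%s'.", st))
    }
  }
  for (st in structures) {
    fields[[st]] <- array(cpp_edt3d(masks[[st]], dims, spacing), dims)
  }
  for (cl in names(mix)) {
    st <- placement_target[[cl]]
    pool <- adm[fields[[st]][adm] <= cfg$dtc$shell]
    if (length(pool) == 0) {
      stop_generation(sprintf(
        "placement class '%s': no admissible voxel within %g um of '%s'.",
        cl, cfg$dtc$shell, st
      ))
    }
    pools[[cl]] <- pool
  }

  with_seed(seed, {
    cls <- sample(classes, n_spots, replace = TRUE, prob = probs)
    centres <- matrix(NA_real_, n_spots, 3)
    accepted <- 0L
    minsep2 <- cfg$dtc$min_separation^2
    for (s in seq_len(n_spots)) {
      pool <- pools[[cls[s]]]
      placed <- FALSE
      for (try in seq_len(200L)) {
        idx <- pool[sample.int(length(pool), 1L)]
        ijk <- index_to_ijk(idx, dims)
        p <- as.numeric(ijk_to_um(ijk, spacing)) +
          runif(3, -0.45, 0.45) * spacing
        if (cls[s] != "uniform") {
          # constructive guarantee: sub-voxel jitter must not push a shell
          # placement beyond the shell distance
          st <- placement_target[[cls[s]]]
          dtrue <- cpp_trilinear(fields[[st]], dims, spacing, rbind(p))
          if (dtrue > cfg$dtc$shell) next
        }
        if (accepted > 0L) {
          d2 <- rowSums(sweep(centres[seq_len(accepted), , drop = FALSE], 2, p)^2)
          if (min(d2) < minsep2) next
        }
        accepted <- accepted + 1L
        centres[s, ] <- p
        placed <- TRUE
        break
      }
      if (!placed) { # crowded grid: accept the last candidate
        accepted <- accepted + 1L
        centres[s, ] <- p
        warning("DTC hard-core separation could not be satisfied for all spots; ",
                "the placement is denser than the requested minimum separation.",
                call. = FALSE)
      }
    }
    spots <- tibble::tibble(
      id = seq_len(n_spots),
      x_um = centres[, 1], y_um = centres[, 2], z_um = centres[, 3],
      radius_um = cfg$dtc$radius,
      kind = "dtc",
      true_class = cls
    )
    for (st in structures) {
      spots[[paste0("true_dist_", st)]] <-
        as.numeric(cpp_trilinear(fields[[st]], dims, spacing, centres))
    }
    spot_set(spots)
  })
}

# --- composition ---------------------------------------------------------

#' Generate a complete synthetic marrow dataset with ground truth
#'
#' Composes [build_vessel_tree()], [add_sprouts()], [voxelize_tree()],
#' [place_dtcs()] and [render_channels()] under seeds derived from
#' `cfg$seed`. Fully deterministic for a given configuration.
#'
#' @param cfg a [synthetic_config()].
#' @param tree,vox optional precomputed [build_vessel_tree()] /
#'   [voxelize_tree()] results (e.g. reused from a calibration pass); they
#'   must derive from the same configuration and seed.
#' @return an object of class `marrow_dataset`: list with `volume` (an
#'   [image_volume()]) and `truth` (masks, subtype label array, true spot
#'   table, sprout inventory, per-vessel table, the vessel tree, the resolved
#'   config and master seed).
#' @export
generate_dataset <- function(cfg, tree = NULL, vox = NULL) {
  cfg <- validate_synthetic_config(unclass(cfg))
  seed <- cfg$seed %||% sample.int(2^31 - 1, 1)
  cfg$seed <- seed
  if (is.null(tree)) {
    tree <- build_vessel_tree(cfg)
    tree <- add_sprouts(tree, cfg)
  }
  if (is.null(vox)) vox <- voxelize_tree(tree, cfg)
  spots <- place_dtcs(cfg, vox$masks)
  vol <- render_channels(vox$masks, cfg, spots = spots)
  structure(
    list(
      volume = vol,
      truth = list(
        masks = vox$masks,
        subtype_label = vox$subtype_label,
        spots = spots,
        sprouts = tree$sprouts,
        vessels = vox$vessels,
        tree = tree,
        config = cfg,
        seed = seed
      )
    ),
    class = "marrow_dataset"
  )
}

#' @export
print.marrow_dataset <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf(
    "<marrow_dataset> %d x %d x %d voxels, %d vessels, %d DTC spots, seed %d\n",
    d[1], d[2], d[3], nrow(x$truth$vessels), nrow(x$truth$spots), x$truth$seed
  ))
  invisible(x)
}

# --- calibration helpers -------------------------------------------------

#' Admissible-volume fraction of a structure's proximity shell
#'
#' Fraction of the admissible marrow volume lying within `shell` µm of the
#' named structure — the chance proximity fraction a uniform null model
#' converges to (the geometric oracle for random-spot statistics).
#'
#' @param masks mask list including `marrow_admissible`.
#' @param structure structure name.
#' @param shell shell distance in µm (default 10).
#' @return a single fraction in `[0, 1]`.
#' @export
shell_volume_fraction <- function(masks, structure, shell = 10) {
  dims <- dim(masks[[1]])
  spacing <- mask_spacing(masks[[1]])
  if (sum(masks[[structure]]) == 0) {
    stop_validation(sprintf("structure '%s' is empty.", structure))
  }
  d <- cpp_edt3d(masks[[structure]], dims, spacing)
  adm <- which(masks$marrow_admissible)
  mean(d[adm] <= shell)
}

#' Solve the placement-mix fraction that yields a target proximity fraction
#'
#' Uniformly placed spots still fall inside a structure's shell at the
#' geometric chance rate p; to make the expected total fraction of spots
#' within the shell equal `target`, the preferred fraction must be
#' f = (target - p) / (1 - p).
#'
#' @param masks mask list from [voxelize_tree()].
#' @param class placement class (`perivascular_any`, `near_bone`,
#'   `near_type_h`, `near_type_l`).
#' @param target target total proximity fraction in `[0, 1]`.
#' @param shell shell distance in µm.
#' @return named mix vector suitable for `synthetic_config(dtc = list(mix = ...))`.
#' @export
calibrate_placement_mix <- function(masks, class, target, shell = 10) {
  st <- placement_target[[class]]
  if (is.null(st)) stop_validation(sprintf("unknown placement class '%s'.", class))
  p <- shell_volume_fraction(masks, st, shell)
  if (target < p) {
    stop_validation(sprintf(
      "target fraction %.3f is below the chance shell fraction %.3f; not reachable by adding preference.",
      target, p
    ))
  }
  f <- (target - p) / (1 - p)
  setNames(f, class)
}

#' Calibrate type-H vessel content to a target shell volume fraction
#'
#' Iteratively rescales the type H segment length until the admissible-volume
#' fraction of the type-H `shell`-µm shell (measured on the voxelized masks
#' by the geometric oracle) matches `target` to relative tolerance `tol`.
#'
#' @param cfg a [synthetic_config()].
#' @param target target shell volume fraction.
#' @param shell shell distance in µm.
#' @param tol relative tolerance on the achieved fraction.
#' @param max_iter maximum refinement iterations.
#' @return list with the calibrated `config`, the achieved `shell_fraction`
#'   and the masks of the calibrated geometry.
#' @export
calibrate_type_h_shell <- function(cfg, target, shell = 10, tol = 0.01,
                                   max_iter = 10) {
  measure <- function(cfg) {
    tree <- build_vessel_tree(cfg)
    vox <- voxelize_tree(tree, cfg)
    list(p = shell_volume_fraction(vox$masks, "type_h", shell), vox = vox)
  }
  # Phase 1 — coarse: rescale the type H segment length. Each length change
  # regrows a different random tree, so the response is jagged; stop as soon
  # as the fraction is in the right ballpark.
  res <- measure(cfg)
  it <- 0
  while (abs(res$p / target - 1) > 0.15 && it < 3) {
    it <- it + 1
    scale <- (target / res$p)^0.9
    cfg$vessels$seg_length[["type_h"]] <-
      min(400, max(8, cfg$vessels$seg_length[["type_h"]] * scale))
    res <- measure(cfg)
  }
  # Phase 2 — fine: bisect on the type H mean radius. With the tree seed
  # fixed, radius changes leave the centrelines untouched, so the shell
  # fraction is a smooth, monotone, deterministic function of the radius.
  at_radius <- function(r) {
    cfg$vessels$radius_mean[["type_h"]] <- r
    list(cfg = cfg, res = measure(cfg))
  }
  r_mid <- cfg$vessels$radius_mean[["type_h"]]
  lo <- r_mid; hi <- r_mid
  cur <- list(cfg = cfg, res = res)
  guard <- 0
  while (cur$res$p < target && guard < 6) {
    guard <- guard + 1
    hi <- hi * 1.3
    cur <- at_radius(hi)
  }
  if (guard > 0) lo <- hi / 1.3 else {
    guard <- 0
    while (cur$res$p > target && guard < 6) {
      guard <- guard + 1
      lo <- lo / 1.3
      cur <- at_radius(lo)
    }
    if (guard > 0) hi <- lo * 1.3
  }
  it <- 0
  while (abs(cur$res$p / target - 1) > tol && it < max_iter) {
    it <- it + 1
    mid <- (lo + hi) / 2
    cur <- at_radius(mid)
    if (cur$res$p < target) lo <- mid else hi <- mid
  }
  list(config = cur$cfg, shell_fraction = cur$res$p, masks = cur$res$vox$masks)
}
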