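#' Skeletonize a vessel component
#'
#' 3D topological thinning of the component mask (simple-point removal
#' ordered by interior depth, preserving endpoints), followed by graph
#' analysis of the skeleton voxels: the main path is the longest geodesic
#' through the skeleton graph (physical edge lengths), side branches are the
#' paths from remaining leaf voxels to the main path, and per-node radii are
#' the interior-depth values of the distance transform.
#'
#' @param mask logical 3D array of the component (a full-grid mask or a
#'   cropped one).
#' @param spacing voxel spacing in µm.
#' @param main_min_radius µm; the main path is computed over skeleton nodes of
#'   at least this local radius, so that it runs through the vessel proper and
#'   is not deflected into thin surface sprouts (default 2, matching the
#'   sprout radius threshold). Falls back to all nodes when the component is
#'   thinner than this everywhere.
#' @return object of class `skeleton`: list with `nodes` tibble (`node`,
#'   `x_um`, `y_um`, `z_um`, `radius_um`, `on_main`), `main_length_um`,
#'   `branches` tibble (`branch_id`, `length_um`, `mean_radius_um`,
#'   `attach_node`, `nodes` list), and `degenerate` flag.
#' @export
skeletonize_mask <- function(mask, spacing = NULL, main_min_radius = 2) {
  spacing <- check_spacing(spacing %||% mask_spacing(mask))
  dims <- grid_dims(mask)
  m <- as.logical(mask)
  if (!any(m)) stop_validation("component mask is empty.")
  depth <- cpp_edt3d(!m, dims, spacing) # distance to outside = interior depth
  skel <- cpp_skeletonize(m, dims, depth)
  idx <- which(skel)
  if (length(idx) == 0) {
    return(structure(list(nodes = NULL, main_length_um = 0,
                          branches = empty_branches(), degenerate = TRUE),
                     class = "skeleton"))
  }
  ijk <- index_to_ijk(idx, dims)
  um <- ijk_to_um(ijk, spacing)
  nodes <- tibble::tibble(
    node = seq_along(idx), voxel = idx,
    x_um = um[, 1], y_um = um[, 2], z_um = um[, 3],
    radius_um = depth[idx]
  )
  # adjacency among skeleton voxels (26-neighbourhood)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  for (o in seq_len(nrow(offs))) {
    ni <- ijk[, 1] + offs[o, 1]
    nj <- ijk[, 2] + offs[o, 2]
    nk <- ijk[, 3] + offs[o, 3]
    ok <- ni >= 0 & nj >= 0 & nk >= 0 & ni < dims[1] & nj < dims[2] & nk < dims[3]
    lin <- ni[ok] + dims[1] * (nj[ok] + dims[2] * nk[ok]) + 1
    hit <- match(lin, idx)
    src <- which(ok)[!is.na(hit)]
    dst <- hit[!is.na(hit)]
    keep <- src < dst # undirected, one copy
    if (!any(keep)) next
    ef <- c(ef, src[keep]); et <- c(et, dst[keep])
    w <- sqrt(colSums((t(offs[o, , drop = FALSE]) * spacing)^2))
    ew <- c(ew, rep(w, sum(keep)))
  }
  if (length(ef) == 0) {
    return(structure(list(nodes = nodes, main_length_um = 0,
                          branches = empty_branches(), degenerate = TRUE),
                     class = "skeleton"))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = ef, to = et, weight = ew),
    directed = FALSE,
    vertices = data.frame(name = seq_along(idx))
  )
  # main path: longest geodesic through vessel-calibre nodes (double sweep).
  # Thin sprout nodes and end-cap remnants are excluded (they register as
  # side branches): first drop nodes thinner than `main_min_radius`, then
  # keep only nodes at least half the median calibre of what remains.
  core <- which(nodes$radius_um >= main_min_radius)
  if (length(core) >= 2) {
    rmed <- stats::median(nodes$radius_um[core])
    core2 <- which(nodes$radius_um >= max(main_min_radius, 0.5 * rmed))
    if (length(core2) >= 2) core <- core2
  }
  gmain <- if (length(core) >= 2) {
    igraph::induced_subgraph(g, core)
  } else {
    g
  }
  comp <- igraph::components(gmain)
  main_vertices <- which(comp$membership == which.max(comp$csize))
  d0 <- igraph::distances(gmain, v = main_vertices[1], to = main_vertices)
  a <- main_vertices[which.max(d0)]
  da <- igraph::distances(gmain, v = a, to = main_vertices)
  b <- main_vertices[which.max(da)]
  main_len <- max(da)
  sp <- igraph::shortest_paths(gmain, from = a, to = b, output = "vpath")
  main_path <- as.integer(igraph::as_ids(sp$vpath[[1]]))
  # trim end-cap artifacts: thinning leaves short low-radius runs at the
  # component ends that are not part of the centreline proper
  if (length(main_path) > 4) {
    rmed <- stats::median(nodes$radius_um[main_path])
    while (length(main_path) > 2 &&
           nodes$radius_um[main_path[1]] < 0.5 * rmed) {
      main_path <- main_path[-1]
    }
    while (length(main_path) > 2 &&
           nodes$radius_um[main_path[length(main_path)]] < 0.5 * rmed) {
      main_path <- main_path[-length(main_path)]
    }
  }
  # measure length on a lightly smoothed polyline: the voxel-level wiggle of
  # the thinned axis (staircase steps, deflections at branch junctions)
  # otherwise inflates the arc length by several percent
  pp <- cbind(nodes$x_um[main_path], nodes$y_um[main_path],
              nodes$z_um[main_path])
  if (nrow(pp) >= 5) {
    sm <- apply(pp, 2, function(v) stats::filter(v, rep(1 / 5, 5), sides = 2))
    ok <- !is.na(sm[, 1])
    pp <- rbind(pp[1, ], sm[ok, , drop = FALSE], pp[nrow(pp), ])
  }
  main_len <- sum(sqrt(rowSums(
    (pp[-1, , drop = FALSE] - pp[-nrow(pp), , drop = FALSE])^2
  )))
  nodes$on_main <- nodes$node %in% main_path

  # branches: connected components of the skeleton off the main path, each
  # traced from its attachment on the main path to its farthest node (tip).
  # Component-based extraction is robust to rasterisation artefacts that can
  # leave branch tips with degree 2.
  branches <- list()
  off <- setdiff(seq_along(idx), main_path)
  if (length(off) > 0 && length(main_path) > 0) {
    sub <- igraph::induced_subgraph(g, off)
    sc <- igraph::components(sub)
    sub_ids <- as.integer(igraph::as_ids(igraph::V(sub)))
    adj <- igraph::adjacent_vertices(g, off)
    for (ci in seq_len(sc$no)) {
      cn <- sub_ids[sc$membership == ci]
      # attachment: main-path node adjacent (in the full graph) to the branch
      nb_all <- unique(as.integer(unlist(lapply(
        which(sc$membership == ci), function(t) as.integer(adj[[t]])
      ))))
      attach <- intersect(nb_all, main_path)
      if (length(attach) == 0) next
      tgt <- attach[1]
      gb <- igraph::induced_subgraph(g, c(cn, tgt))
      gb_ids <- as.integer(igraph::as_ids(igraph::V(gb)))
      dfrom <- igraph::distances(gb, v = which(gb_ids == tgt))[1, ]
      dfrom[!is.finite(dfrom)] <- -Inf
      tipi <- which.max(dfrom)
      pth <- igraph::shortest_paths(gb, from = which(gb_ids == tgt),
                                    to = tipi, output = "vpath")$vpath[[1]]
      pids <- rev(as.integer(igraph::as_ids(pth))) # tip first
      branches[[length(branches) + 1]] <- tibble::tibble(
        branch_id = length(branches) + 1L,
        length_um = max(dfrom),
        mean_radius_um = mean(nodes$radius_um[pids]),
        attach_node = tgt,
        nodes = list(pids)
      )
    }
  }
  branches <- if (length(branches) > 0) dplyr::bind_rows(branches) else empty_branches()
  structure(
    list(nodes = nodes, main_path = main_path, main_length_um = main_len,
         branches = branches, degenerate = main_len <= 0, spacing = spacing),
    class = "skeleton"
  )
}

empty_branches <- function() {
  tibble::tibble(branch_id = integer(), length_um = numeric(),
                 mean_radius_um = numeric(), attach_node = integer(),
                 nodes = list())
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d nodes, main path %.1f um, %d side branches%s\n",
              if (is.null(x$nodes)) 0L else nrow(x$nodes), x$main_length_um,
              nrow(x$branches), if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# crop a full-grid component voxel list to a padded bounding-box mask
crop_component <- function(voxels, dims, pad = 2L) {
  ijk <- index_to_ijk(voxels, dims)
  lo <- pmax(apply(ijk, 2, min) - pad, 0)
  hi <- pmin(apply(ijk, 2, max) + pad, dims - 1)
  cd <- hi - lo + 1L
  m <- array(FALSE, cd)
  lin <- (ijk[, 1] - lo[1]) + cd[1] * ((ijk[, 2] - lo[2]) + cd[2] * (ijk[, 3] - lo[3])) + 1
  m[lin] <- TRUE
  list(mask = m, origin = lo, dims = cd)
}

#' Skeletonize one extracted vessel component
#'
#' @param components an [extract_components()] result.
#' @param comp_id component id.
#' @return a `skeleton` (node coordinates in the full-grid frame, µm).
#' @export
skeletonize_component <- function(components, comp_id) {
  row <- components$components[components$components$comp_id == comp_id, ]
  if (nrow(row) == 0) stop_validation(sprintf("no component with id %s.", comp_id))
  cr <- crop_component(row$voxels[[1]], dim(components$comp_map))
  sk <- skeletonize_mask(cr$mask, components$spacing)
  if (!is.null(sk$nodes)) {
    shift <- cr$origin * components$spacing
    sk$nodes$x_um <- sk$nodes$x_um + shift[1]
    sk$nodes$y_um <- sk$nodes$y_um + shift[2]
    sk$nodes$z_um <- sk$nodes$z_um + shift[3]
  }
  sk
}

#' Surface area of a component by smoothed isosurface triangulation
#'
#' Gaussian-smooths the binary mask (sigma in voxels, default 0.75) and sums the
#' triangle areas of the 0.5-level isosurface (marching tetrahedra). The mask
#' is zero-padded so surfaces touching the grid boundary are closed.
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing in µm.
#' @param smooth_sigma_vox Gaussian sigma in voxels (0 disables smoothing).
#' @return surface area in µm².
#' @export
component_surface_area <- function(mask, spacing = NULL, smooth_sigma_vox = 0.75) {
  spacing <- check_spacing(spacing %||% mask_spacing(mask))
  dims <- grid_dims(mask)
  if (!any(mask)) stop_validation("component mask is empty.")
  pad <- as.integer(max(2, ceiling(3 * smooth_sigma_vox)))
  pd <- dims + 2L * pad
  a <- array(0, pd)
  a[(pad + 1):(pad + dims[1]), (pad + 1):(pad + dims[2]),
    (pad + 1):(pad + dims[3])] <- as.numeric(mask)
  if (smooth_sigma_vox > 0) {
    a <- array(cpp_blur3d(a, pd, rep(smooth_sigma_vox, 3)), pd)
  }
  cpp_isosurface_area(a, pd, spacing, 0.5)
}

#' Surface area over vessel length
#'
#' Endothelial surface area divided by the skeleton main-path length — the
#' vessel-remodelling readout that rises with sprouting and surface
#' irregularity at constant calibre.
#'
#' @param mask component mask.
#' @param spacing voxel spacing in µm.
#' @param skeleton optional precomputed [skeletonize_mask()] result.
#' @param smooth_sigma_vox smoothing for the surface estimate.
#' @return list with `surface_area_um2`, `length_um`, `surface_over_length`
#'   (NA and `degenerate = TRUE` when the skeleton is degenerate).
#' @export
surface_over_length <- function(mask, spacing = NULL, skeleton = NULL,
                                smooth_sigma_vox = 0.75) {
  spacing <- check_spacing(spacing %||% mask_spacing(mask))
  if (is.null(skeleton)) skeleton <- skeletonize_mask(mask, spacing)
  area <- component_surface_area(mask, spacing, smooth_sigma_vox)
  if (skeleton$degenerate || skeleton$main_length_um <= 0) {
    return(list(surface_area_um2 = area, length_um = skeleton$main_length_um,
                surface_over_length = NA_real_, degenerate = TRUE))
  }
  list(surface_area_um2 = area, length_um = skeleton$main_length_um,
       surface_over_length = area / skeleton$main_length_um,
       degenerate = FALSE)
}

#' Detect endothelial sprouts on a vessel skeleton
#'
#' A sprout is a terminal skeleton branch that is thin (mean radius of its
#' extravascular portion below `radius_threshold`) and at least `min_length`
#' long outside the parent vessel. Branch length is measured beyond the
#' parent vessel radius (the skeleton path first traverses the vessel wall
#' from the centreline before exiting).
#'
#' @param skeleton a [skeletonize_mask()] result.
#' @param radius_threshold µm; branches with thicker extravascular portions
#'   are vessel branches, not sprouts (default 2).
#' @param min_length µm minimum extravascular length (default 2).
#' @return tibble of sprout records (`branch_id`, `length_um`,
#'   `mean_radius_um`, `anchor_x_um`, `anchor_y_um`, `anchor_z_um`) with the
#'   per-100 µm density in `attr(, "per_100um")`.
#' @export
detect_sprouts <- function(skeleton, radius_threshold = 2, min_length = 2) {
  if (skeleton$degenerate || nrow(skeleton$branches) == 0) {
    out <- tibble::tibble(branch_id = integer(), length_um = numeric(),
                          mean_radius_um = numeric(), anchor_x_um = numeric(),
                          anchor_y_um = numeric(), anchor_z_um = numeric())
    attr(out, "per_100um") <- if (skeleton$degenerate) NA_real_ else 0
    return(out)
  }
  nodes <- skeleton$nodes
  mp <- skeleton$main_path
  mx <- nodes$x_um[mp]; my <- nodes$y_um[mp]; mz <- nodes$z_um[mp]
  recs <- list()
  for (r in seq_len(nrow(skeleton$branches))) {
    br <- skeleton$branches[r, ]
    pids <- br$nodes[[1]]
    attach <- br$attach_node
    ax <- nodes$x_um[nodes$node == attach]
    ay <- nodes$y_um[nodes$node == attach]
    az <- nodes$z_um[nodes$node == attach]
    # extravascular portion: path nodes farther than the parent radius from
    # the centreline (nearest main-path node)
    dist_main <- vapply(pids, function(p) {
      sqrt(min((mx - nodes$x_um[p])^2 + (my - nodes$y_um[p])^2 +
                 (mz - nodes$z_um[p])^2))
    }, numeric(1))
    tip <- pids[1]
    tip_d2 <- (mx - nodes$x_um[tip])^2 + (my - nodes$y_um[tip])^2 +
      (mz - nodes$z_um[tip])^2
    nearest_main <- mp[which.min(tip_d2)]
    r_parent <- nodes$radius_um[nodes$node == nearest_main]
    outside <- dist_main > r_parent
    # sprout length: straight-line distance from the branch tip to the
    # centreline, less the parent vessel radius (the portion beyond the
    # endothelial surface); robust to the staircase wiggle of the thinned
    # connector path
    len_out <- max(0, sqrt(min(tip_d2)) - r_parent)
    if (len_out < min_length) next
    mr <- if (any(outside)) mean(nodes$radius_um[pids[outside]]) else min(nodes$radius_um[pids])
    if (mr >= radius_threshold) next
    recs[[length(recs) + 1]] <- tibble::tibble(
      branch_id = br$branch_id, length_um = len_out, mean_radius_um = mr,
      anchor_x_um = ax, anchor_y_um = ay, anchor_z_um = az
    )
  }
  out <- if (length(recs) > 0) dplyr::bind_rows(recs) else
    tibble::tibble(branch_id = integer(), length_um = numeric(),
                   mean_radius_um = numeric(), anchor_x_um = numeric(),
                   anchor_y_um = numeric(), anchor_z_um = numeric())
  attr(out, "per_100um") <- 100 * nrow(out) / skeleton$main_length_um
  out
}

#' Lumen cross-section areas along a vessel
#'
#' At `n_planes` equidistant main-path nodes (excluding nodes within
#' `exclude_um` of branch attachments and path ends), constructs the plane
#' perpendicular to the local centreline tangent, rasterises the lumen on a
#' fine in-plane grid, and measures the area of the in-plane region connected
#' to the centreline point. When no lumen mask is supplied, the lumen is
#' identified per plane as the cavity enclosed by the vessel wall (in-plane
#' hole fill).
#'
#' @param mask vessel component mask (wall + lumen, or wall only when a
#'   `lumen_mask` is given).
#' @param skeleton a [skeletonize_mask()] result for this mask.
#' @param spacing voxel spacing in µm.
#' @param lumen_mask optional lumen mask (e.g. generator truth).
#' @param n_planes number of sampled cross-sections (default 10).
#' @param plane_res in-plane sampling resolution in µm (default 0.5).
#' @param exclude_um exclusion zone around branch points and ends (default 5).
#' @return tibble with `plane`, `area_um2`, `collapsed` (TRUE when the plane
#'   missed the lumen).
#' @export
lumen_area <- function(mask, skeleton, spacing = NULL, lumen_mask = NULL,
                       n_planes = 10, plane_res = 0.5, exclude_um = 5) {
  spacing <- check_spacing(spacing %||% mask_spacing(mask))
  dims <- grid_dims(mask)
  if (skeleton$degenerate) {
    return(tibble::tibble(plane = integer(), area_um2 = numeric(),
                          collapsed = logical()))
  }
  nodes <- skeleton$nodes
  mp <- skeleton$main_path
  P <- cbind(nodes$x_um[mp], nodes$y_um[mp], nodes$z_um[mp])
  steps <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  arc <- c(0, cumsum(steps))
  total <- arc[length(arc)]
  ok <- arc >= exclude_um & arc <= total - exclude_um
  if (nrow(skeleton$branches) > 0) {
    for (attach in unique(skeleton$branches$attach_node)) {
      ai <- which(mp == attach)
      if (length(ai) == 1) ok <- ok & abs(arc - arc[ai]) > exclude_um
    }
  }
  cand <- which(ok)
  if (length(cand) == 0) cand <- seq_along(mp)
  sel <- cand[unique(pmax(1, round(seq(1, length(cand),
                                       length.out = min(n_planes, length(cand))))))]
  rmax <- max(nodes$radius_um[mp]) * 3
  half <- ceiling(rmax / plane_res)
  gg <- seq(-half, half) * plane_res
  lum <- if (!is.null(lumen_mask)) as.logical(lumen_mask) else NULL
  wall <- as.logical(mask)
  res <- purrr::map_dfr(seq_along(sel), function(si) {
    i <- sel[si]
    # local tangent from neighbouring main-path nodes
    i0 <- max(1, i - 2); i1 <- min(nrow(P), i + 2)
    tg <- unit(P[i1, ] - P[i0, ])
    u <- perp_unit_det(tg)
    v <- pracma_cross(tg, u)
    centre <- P[i, ]
    nG <- length(gg)
    gx <- centre[1] + outer(gg * u[1], gg * v[1], "+")
    gy <- centre[2] + outer(gg * u[2], gg * v[2], "+")
    gz <- centre[3] + outer(gg * u[3], gg * v[3], "+")
    ii <- round(gx / spacing[1]); jj <- round(gy / spacing[2]); kk <- round(gz / spacing[3])
    inb <- ii >= 0 & jj >= 0 & kk >= 0 &
      ii < dims[1] & jj < dims[2] & kk < dims[3]
    lin <- ii + dims[1] * (jj + dims[2] * kk) + 1
    lin[!inb] <- 1L
    if (!is.null(lum)) {
      plane <- matrix(lum[lin] & inb, nG, nG)
    } else {
      wallp <- matrix(wall[lin] & inb, nG, nG)
      # cavity = non-wall region not connected to the plane border
      bg <- !wallp
      labs <- array(cpp_label3d(bg, c(nG, nG, 1L), 6L), c(nG, nG))
      border <- unique(c(labs[1, ], labs[nG, ], labs[, 1], labs[, nG]))
      plane <- bg & !matrix(labs %in% border[border > 0], nG, nG)
    }
    cpos <- half + 1
    if (!plane[cpos, cpos]) {
      # centre may sit on a wall voxel edge; accept a small central window
      win <- plane[pmax(1, cpos - 2):pmin(nG, cpos + 2),
                   pmax(1, cpos - 2):pmin(nG, cpos + 2)]
      if (!any(win)) {
        return(tibble::tibble(plane = si, area_um2 = 0, collapsed = TRUE))
      }
    }
    labs2 <- array(cpp_label3d(plane, c(nG, nG, 1L), 6L), c(nG, nG))
    centre_lab <- labs2[cpos, cpos]
    if (centre_lab == 0) {
      win <- labs2[pmax(1, cpos - 2):pmin(nG, cpos + 2),
                   pmax(1, cpos - 2):pmin(nG, cpos + 2)]
      centre_lab <- if (any(win > 0)) min(win[win > 0]) else 0L
    }
    if (centre_lab == 0) {
      return(tibble::tibble(plane = si, area_um2 = 0, collapsed = TRUE))
    }
    tibble::tibble(plane = si,
                   area_um2 = sum(labs2 == centre_lab) * plane_res^2,
                   collapsed = FALSE)
  })
  res
}

# deterministic perpendicular unit vector (no RNG: lumen sampling is pure)
perp_unit_det <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(pracma_cross(d, ref))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Intralesional vessel volume fraction
#'
#' Fraction of a region's volume occupied by vessel voxels (voxel counts;
#' spacing cancels).
#'
#' @param vessel_mask logical vessel mask.
#' @param region_mask logical region (e.g. tumour) mask on the same grid.
#' @return fraction in `[0, 1]`.
#' @export
vessel_volume_fraction <- function(vessel_mask, region_mask) {
  if (!any(region_mask)) stop_validation("region mask is empty.")
  sum(vessel_mask & region_mask) / sum(region_mask)
}

#' Per-vessel morphometry table
#'
#' Convenience wrapper running skeletonization, surface estimation and sprout
#' detection for every component.
#'
#' @param components an [extract_components()] result.
#' @param radius_threshold,min_length sprout definition (see
#'   [detect_sprouts()]).
#' @param smooth_sigma_vox surface smoothing (see
#'   [component_surface_area()]).
#' @return tibble with one row per component: `comp_id`, `subtype`,
#'   `volume_um3`, `surface_area_um2`, `length_um`, `surface_over_length`,
#'   `n_sprouts`, `sprouts_per_100um`, `degenerate`.
#' @export
morphometry_table <- function(components, radius_threshold = 2, min_length = 2,
                              smooth_sigma_vox = 0.75) {
  comps <- components$components
  dims <- dim(components$comp_map)
  purrr::map_dfr(seq_len(nrow(comps)), function(r) {
    cr <- crop_component(comps$voxels[[r]], dims)
    sk <- skeletonize_mask(cr$mask, components$spacing)
    sol <- surface_over_length(cr$mask, components$spacing, skeleton = sk,
                               smooth_sigma_vox = smooth_sigma_vox)
    spr <- detect_sprouts(sk, radius_threshold, min_length)
    tibble::tibble(
      comp_id = comps$comp_id[r],
      subtype = comps$subtype[r],
      volume_um3 = comps$volume_um3[r],
      surface_area_um2 = sol$surface_area_um2,
      length_um = sol$length_um,
      surface_over_length = sol$surface_over_length,
      n_sprouts = nrow(spr),
      sprouts_per_100um = attr(spr, "per_100um"),
      degenerate = sol$degenerate
    )
  })
}
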