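#' Joint CD31/EMCN voxel-intensity histogram
#'
#' The 2D count grid over (CD31, EMCN) voxel intensities underlying the
#' density plot used to draw vessel-subtype gates.
#'
#' @param vol an [image_volume()] with `cd31` and `emcn` channels.
#' @param bins bins per axis (>= 2).
#' @param mask optional logical array restricting which voxels are counted.
#' @return object of class `joint_histogram`: list with `counts` (bins x bins
#'   matrix, CD31 on rows), `cd31_edges`, `emcn_edges`, `n_voxels`.
#' @export
joint_intensity_histogram <- function(vol, bins = 64, mask = NULL) {
  if (bins < 2) stop_validation("`bins` must be >= 2.")
  if (!all(c("cd31", "emcn") %in% names(vol$channels))) {
    stop_validation("volume must contain 'cd31' and 'emcn' channels.")
  }
  cd <- as.numeric(vol$channels$cd31)
  em <- as.numeric(vol$channels$emcn)
  if (!is.null(mask)) {
    keep <- as.logical(mask)
    cd <- cd[keep]
    em <- em[keep]
  }
  bin_edges <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) r[2] <- r[1] + 1e-9
    seq(r[1], r[2], length.out = bins + 1)
  }
  ce <- bin_edges(cd)
  ee <- bin_edges(em)
  bin_of <- function(x, e) pmin(pmax(findInterval(x, e, rightmost.closed = TRUE), 1L), bins)
  idx <- bin_of(cd, ce) + bins * (bin_of(em, ee) - 1L)
  counts <- matrix(tabulate(idx, nbins = bins * bins), bins, bins)
  structure(
    list(counts = counts, cd31_edges = ce, emcn_edges = ee, n_voxels = length(cd)),
    class = "joint_histogram"
  )
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat(sprintf("<joint_histogram> %d x %d bins over %d voxels\n",
              nrow(x$counts), ncol(x$counts), x$n_voxels))
  invisible(x)
}

#' Tidy a joint histogram into a tibble of bin centres and counts
#' @param x a `joint_histogram`.
#' @param ... unused.
#' @return tibble with `cd31`, `emcn` (bin centres) and `count`.
#' @export
tidy.joint_histogram <- function(x, ...) {
  cc <- (head(x$cd31_edges, -1) + tail(x$cd31_edges, -1)) / 2
  ec <- (head(x$emcn_edges, -1) + tail(x$emcn_edges, -1)) / 2
  tibble::tibble(
    cd31 = rep(cc, times = length(ec)),
    emcn = rep(ec, each = length(cc)),
    count = as.numeric(x$counts)
  )
}

# Three-class Otsu on a numeric sample: the pair of thresholds maximising
# between-class variance of the binned intensities.
otsu3 <- function(x, bins = 256) {
  if (length(unique(x)) < 3) {
    stop_validation("intensity distribution is degenerate (< 3 distinct values); use manual gates.")
  }
  r <- range(x)
  edges <- seq(r[1], r[2], length.out = bins + 1)
  h <- tabulate(pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), bins),
                nbins = bins)
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  w <- h / sum(h)
  cw <- cumsum(w)                 # class weight up to bin i
  cm <- cumsum(w * mids)          # class mass up to bin i
  total <- cm[bins]
  best <- -Inf
  bi <- bj <- NA_integer_
  for (i in 1:(bins - 2)) {
    w0 <- cw[i]
    if (w0 == 0) next
    m0 <- cm[i] / w0
    for (j in (i + 1):(bins - 1)) {
      w1 <- cw[j] - cw[i]
      w2 <- 1 - cw[j]
      if (w1 == 0 || w2 == 0) next
      m1 <- (cm[j] - cm[i]) / w1
      m2 <- (total - cm[j]) / w2
      v <- w0 * m0^2 + w1 * m1^2 + w2 * m2^2
      if (v > best) {
        best <- v
        bi <- i
        bj <- j
      }
    }
  }
  if (!is.finite(best)) {
    stop_validation("could not derive three-class thresholds; use manual gates.")
  }
  c(edges[bi + 1], edges[bj + 1])
}

#' Gate configuration for vessel-subtype classification
#'
#' @param vessel_presence CD31 level below which a voxel is background.
#' @param cd31_lo_hi CD31 threshold separating low from high.
#' @param emcn_neg_lo EMCN threshold separating negative from low.
#' @param emcn_lo_hi EMCN threshold separating low from high.
#' @param strategy `"auto"` or `"manual"`.
#' @return object of class `gate_config`.
#' @export
gate_config <- function(vessel_presence, cd31_lo_hi, emcn_neg_lo, emcn_lo_hi,
                        strategy = "manual") {
  vals <- c(vessel_presence, cd31_lo_hi, emcn_neg_lo, emcn_lo_hi)
  if (any(!is.finite(vals))) stop_validation("gate thresholds must be finite.")
  if (vessel_presence > cd31_lo_hi) {
    stop_validation("`vessel_presence` must be <= `cd31_lo_hi`.")
  }
  if (emcn_neg_lo > emcn_lo_hi) {
    stop_validation("`emcn_neg_lo` must be <= `emcn_lo_hi`.")
  }
  structure(
    list(vessel_presence = vessel_presence, cd31_lo_hi = cd31_lo_hi,
         emcn_neg_lo = emcn_neg_lo, emcn_lo_hi = emcn_lo_hi,
         strategy = strategy),
    class = "gate_config"
  )
}

#' @export
print.gate_config <- function(x, ...) {
  cat(sprintf(
    "<gate_config> (%s) CD31: presence %.4g, lo/hi %.4g; EMCN: neg/lo %.4g, lo/hi %.4g\n",
    x$strategy, x$vessel_presence, x$cd31_lo_hi, x$emcn_neg_lo, x$emcn_lo_hi
  ))
  invisible(x)
}

#' Derive CD31/EMCN gates automatically or pass through manual thresholds
#'
#' The published gates were drawn by eye; the default automatic strategy makes
#' them reproducible: `vessel_presence` and `cd31_lo_hi` come from three-class
#' Otsu thresholding of CD31 over all voxels, and the EMCN thresholds from
#' three-class Otsu over the vessel-presence voxels only.
#'
#' @param vol an [image_volume()] with `cd31` and `emcn` channels.
#' @param strategy `"auto"` (default) or `"manual"`.
#' @param manual a [gate_config()] (or list of the four thresholds) returned
#'   verbatim when `strategy = "manual"`.
#' @return a [gate_config()].
#' @export
derive_gates <- function(vol, strategy = c("auto", "manual"), manual = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "manual") {
    if (is.null(manual)) stop_config("manual strategy requires `manual` thresholds.")
    if (!inherits(manual, "gate_config")) {
      manual <- do.call(gate_config, c(manual, list(strategy = "manual")))
    }
    return(manual)
  }
  cd <- as.numeric(vol$channels$cd31)
  em <- as.numeric(vol$channels$emcn)
  th_cd <- otsu3(cd)
  present <- cd >= th_cd[1]
  if (sum(present) < 10) {
    stop_validation("almost no voxels above the CD31 presence threshold; use manual gates.")
  }
  th_em <- otsu3(em[present])
  gate_config(
    vessel_presence = th_cd[1], cd31_lo_hi = th_cd[2],
    emcn_neg_lo = th_em[1], emcn_lo_hi = th_em[2],
    strategy = "auto"
  )
}

CLASS_LEVELS <- c("background", "arterial", "type_h", "type_l")

#' Classify voxels into vessel subtypes from CD31/EMCN intensities
#'
#' Applies the gate logic: below `vessel_presence` on CD31 is background;
#' CD31-high with EMCN-negative is arterial; CD31-high with EMCN-high is
#' type H; CD31-low with EMCN-low(-positive) is type L. Voxels falling in the
#' gaps between gates (e.g. CD31-high with intermediate EMCN) are assigned to
#' the nearest class centroid in threshold-normalised gate space.
#'
#' @param vol an [image_volume()] with `cd31` and `emcn` channels.
#' @param gates a [gate_config()].
#' @return object of class `vessel_class_map`: list with `labels` (integer
#'   array: 0 background, 1 arterial, 2 type_h, 3 type_l), `levels`, `gates`.
#' @export
classify_voxels <- function(vol, gates) {
  dims <- dim(vol)
  cd <- as.numeric(vol$channels$cd31)
  em <- as.numeric(vol$channels$emcn)
  lab <- integer(length(cd))
  present <- cd >= gates$vessel_presence
  cd_hi <- cd >= gates$cd31_lo_hi
  em_neg <- em < gates$emcn_neg_lo
  em_hi <- em >= gates$emcn_lo_hi
  em_lo <- !em_neg & !em_hi
  lab[present & cd_hi & em_neg] <- 1L
  lab[present & cd_hi & em_hi] <- 2L
  lab[present & !cd_hi & em_lo] <- 3L
  amb <- which(present & lab == 0L)
  if (length(amb) > 0) {
    s_cd <- max(gates$cd31_lo_hi, 1e-9)
    s_em <- max(gates$emcn_lo_hi, 1e-9)
    centroid <- function(cls, fallback) {
      i <- which(lab == cls)
      if (length(i) > 0) c(mean(cd[i]), mean(em[i])) else fallback
    }
    cents <- rbind(
      centroid(1L, c(1.5 * gates$cd31_lo_hi, 0.5 * gates$emcn_neg_lo)),
      centroid(2L, c(1.5 * gates$cd31_lo_hi, 1.5 * gates$emcn_lo_hi)),
      centroid(3L, c(0.5 * (gates$vessel_presence + gates$cd31_lo_hi),
                     0.5 * (gates$emcn_neg_lo + gates$emcn_lo_hi)))
    )
    d <- sapply(1:3, function(cls) {
      ((cd[amb] - cents[cls, 1]) / s_cd)^2 + ((em[amb] - cents[cls, 2]) / s_em)^2
    })
    lab[amb] <- max.col(-matrix(d, ncol = 3))
  }
  structure(
    list(labels = array(lab, dims), levels = CLASS_LEVELS, gates = gates,
         spacing = vol$spacing),
    class = "vessel_class_map"
  )
}

#' @export
print.vessel_class_map <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, nbins = 4)
  cat("<vessel_class_map>\n")
  for (i in 1:4) cat(sprintf("  %s: %d voxels\n", x$levels[i], tab[i]))
  invisible(x)
}

#' Subtype masks from a class map
#' @param map a `vessel_class_map`.
#' @return named list of `structure_mask` (`arterial`, `type_h`, `type_l`,
#'   `vessel_any`).
#' @export
class_map_masks <- function(map) {
  sp <- map$spacing
  list(
    arterial = structure_mask(map$labels == 1L, "arterial", sp),
    type_h = structure_mask(map$labels == 2L, "type_h", sp),
    type_l = structure_mask(map$labels == 3L, "type_l", sp),
    vessel_any = structure_mask(map$labels > 0L, "vessel_any", sp)
  )
}

#' Extract per-vessel connected components from a class map
#'
#' 26-connected components per subtype. Components below `min_volume_um3` are
#' removed unless they touch a larger component of another subtype, in which
#' case they are merged into it and relabelled (continuity refinement for
#' noisy boundary islets).
#'
#' @param map a `vessel_class_map`.
#' @param min_volume_um3 minimum component volume in µm³ (default 500).
#' @return object of class `vessel_components`: list with `components`
#'   tibble (comp_id, subtype, n_voxels, volume_um3, voxel index list) and
#'   `comp_map` (integer array of component ids).
#' @export
extract_components <- function(map, min_volume_um3 = 500) {
  dims <- dim(map$labels)
  spacing <- map$spacing
  voxvol <- prod(spacing)
  comp_map <- array(0L, dims)
  subtype_of <- integer(0)
  next_id <- 0L
  for (s in 1:3) {
    m <- map$labels == s
    if (!any(m)) next
    lab <- cpp_label3d(m, dims, 26L)
    nl <- max(lab)
    sel <- lab > 0L
    comp_map[sel] <- lab[sel] + next_id
    subtype_of <- c(subtype_of, rep(s, nl))
    next_id <- next_id + nl
  }
  if (next_id == 0L) {
    return(structure(
      list(components = tibble::tibble(
        comp_id = integer(), subtype = character(), n_voxels = integer(),
        volume_um3 = numeric(), voxels = list()
      ), comp_map = comp_map, spacing = spacing),
      class = "vessel_components"
    ))
  }
  counts <- tabulate(comp_map[comp_map > 0L], nbins = next_id)
  vols <- counts * voxvol
  small <- which(vols < min_volume_um3)
  remap <- seq_len(next_id)
  if (length(small) > 0) {
    offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, ]
    for (cid in small) {
      vox <- which(comp_map == cid)
      if (length(vox) == 0) next
      ijk <- index_to_ijk(vox, dims)
      nb_ids <- integer(0)
      for (o in seq_len(nrow(offs))) {
        ni <- ijk[, 1] + offs[o, 1]
        nj <- ijk[, 2] + offs[o, 2]
        nk <- ijk[, 3] + offs[o, 3]
        ok <- ni >= 0 & nj >= 0 & nk >= 0 &
          ni < dims[1] & nj < dims[2] & nk < dims[3]
        if (!any(ok)) next
        lin <- ni[ok] + dims[1] * (nj[ok] + dims[2] * nk[ok]) + 1L
        v <- comp_map[lin]
        nb_ids <- c(nb_ids, v[v > 0L & v != cid])
      }
      nb_ids <- nb_ids[vols[nb_ids] >= min_volume_um3]
      if (length(nb_ids) > 0) {
        target <- as.integer(names(which.max(table(nb_ids))))
        comp_map[vox] <- target
        remap[cid] <- target
      } else {
        comp_map[vox] <- 0L
        remap[cid] <- 0L
      }
    }
  }
  keep <- sort(unique(comp_map[comp_map > 0L]))
  comps <- tibble::tibble(
    comp_id = keep,
    subtype = CLASS_LEVELS[subtype_of[keep] + 1L],
    voxels = lapply(keep, function(cid) which(comp_map == cid))
  )
  comps$n_voxels <- vapply(comps$voxels, length, integer(1))
  comps$volume_um3 <- comps$n_voxels * voxvol
  comps <- comps[, c("comp_id", "subtype", "n_voxels", "volume_um3", "voxels")]
  structure(
    list(components = comps, comp_map = comp_map, spacing = spacing),
    class = "vessel_components"
  )
}

#' @export
print.vessel_components <- function(x, ...) {
  cat(sprintf("<vessel_components> %d components\n", nrow(x$components)))
  print(dplyr::count(x$components, .data$subtype))
  invisible(x)
}

#' Mean per-vessel CD31 and EMCN voxel intensity
#'
#' @param components a [extract_components()] result.
#' @param vol the source [image_volume()].
#' @return tibble with `comp_id`, `subtype`, `volume_um3`, `mean_cd31`,
#'   `mean_emcn`.
#' @export
vessel_mean_intensity <- function(components, vol) {
  comps <- components$components
  if (nrow(comps) == 0) stop_validation("no components to measure.")
  cd <- vol$channels$cd31
  em <- vol$channels$emcn
  tibble::tibble(
    comp_id = comps$comp_id,
    subtype = comps$subtype,
    volume_um3 = comps$volume_um3,
    mean_cd31 = vapply(comps$voxels, function(v) {
      if (length(v) == 0) stop_validation("empty component.")
      mean(cd[v])
    }, numeric(1)),
    mean_emcn = vapply(comps$voxels, function(v) mean(em[v]), numeric(1))
  )
}
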