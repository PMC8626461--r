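#' Multi-channel 3D image volume
#'
#' Container for a multi-channel voxel grid with anisotropic physical spacing.
#' Channels are named 3D arrays of non-negative intensities (arbitrary units)
#' sharing a common shape; `spacing` gives the physical size of one voxel in
#' µm along (x, y, z). Voxel `(i, j, k)` (0-based) is centred at physical
#' position `(i*sx, j*sy, k*sz)` µm.
#'
#' @param channels named list of 3D numeric arrays with identical dimensions.
#'   Conventional channel names are `nuclear`, `cd31`, `emcn`, `tumour`,
#'   `bone`.
#' @param spacing numeric length-3, µm per voxel along (x, y, z); all > 0.
#' @return an object of class `image_volume`.
#' @examples
#' v <- image_volume(list(cd31 = array(1, c(4, 4, 2))), spacing = c(1, 1, 2))
#' dim(v$channels$cd31)
#' @export
image_volume <- function(channels, spacing) {
  if (!is.list(channels) || length(channels) == 0) {
    stop_format("`channels` must be a non-empty named list of 3D arrays.")
  }
  nm <- names(channels)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop_format("every channel must have a unique non-empty name.")
  }
  spacing <- check_spacing(spacing)
  d <- grid_dims(channels[[1]])
  for (ch in nm) {
    a <- channels[[ch]]
    if (!identical(grid_dims(a), d)) {
      stop_format(sprintf("channel '%s' does not match the shape of the first channel.", ch))
    }
    if (any(!is.finite(a)) || any(a < 0)) {
      stop_validation(sprintf("channel '%s' must contain finite non-negative intensities.", ch))
    }
  }
  structure(
    list(channels = channels, spacing = spacing),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<image_volume> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) um\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat("channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$channels[[1]])

#' Physical extent of a volume in µm along (x, y, z)
#' @param vol an [image_volume()].
#' @return numeric length-3 extent in µm (from the centre of the first voxel
#'   to the centre of the last).
#' @export
volume_extent <- function(vol) {
  (dim(vol) - 1) * vol$spacing
}

# --- TIFF storage --------------------------------------------------------
# Multi-page float32 TIFF, channel-major page order (all z of channel 1, then
# channel 2, ...). The installed TIFF codec stores samples in [0, 1], so each
# channel is normalised by a per-channel scale factor recorded, together with
# spacing and channel names, in a JSON sidecar `<path>.json`. Binary masks
# round-trip exactly; continuous intensities round-trip at float32 precision.

volume_sidecar_path <- function(path) paste0(path, ".json")

#' Write a multi-channel volume to disk
#'
#' Writes a channel-major multi-page 32-bit TIFF plus a JSON sidecar
#' (`<path>.json`) holding the voxel spacing, channel names and per-channel
#' intensity scale factors.
#'
#' @param vol an [image_volume()].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!inherits(vol, "image_volume")) {
    vol <- image_volume(vol$channels, vol$spacing)
  }
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0) {
    stop_io(sprintf("cannot write to '%s': directory missing or not writable.", dir))
  }
  d <- dim(vol)
  # the codec is only exact away from the top of its [0, 1] range (1.0 does
  # not round-trip); storing at half scale keeps 0/1 masks bit-exact
  scales <- vapply(vol$channels, function(a) 2 * max(max(a), 0.5), numeric(1))
  pages <- list()
  for (ci in seq_along(vol$channels)) {
    a <- vol$channels[[ci]] / scales[ci]
    for (k in seq_len(d[3])) {
      pages[[length(pages) + 1L]] <- t(a[, , k])
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(
    format = "marrowmap-volume",
    dims = as.integer(d),
    spacing_um = as.numeric(vol$spacing),
    channels = names(vol$channels),
    scales = as.numeric(scales),
    binary = vapply(vol$channels, function(a) all(a %in% c(0, 1)), logical(1))
  )
  jsonlite::write_json(meta, volume_sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-channel volume from disk
#'
#' Reads a TIFF stack written by [write_volume()] (using its JSON sidecar for
#' spacing and channel names) or a plain multi-page TIFF, in which case the
#' channel names and spacing must be declared by the caller.
#'
#' @param path TIFF file path.
#' @param spacing_override optional numeric length-3, µm per voxel (x, y, z);
#'   required when no sidecar metadata is present.
#' @param channel_names optional character vector declaring channel identity
#'   in page-major order; required when no sidecar is present. The page count
#'   must be a multiple of the declared channel count.
#' @return an [image_volume()].
#' @export
read_volume <- function(path, spacing_override = NULL, channel_names = NULL) {
  if (!file.exists(path)) stop_io(sprintf("file '%s' does not exist.", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  npages <- length(pages)
  sidecar <- volume_sidecar_path(path)
  meta <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  if (!is.null(meta)) {
    chn <- meta$channels
    spacing <- spacing_override %||% meta$spacing_um
    scales <- meta$scales %||% rep(1, length(chn))
    binary <- meta$binary %||% rep(FALSE, length(chn))
  } else {
    chn <- channel_names
    spacing <- spacing_override
    scales <- rep(1, length(chn))
    binary <- rep(FALSE, length(chn))
  }
  if (is.null(spacing)) {
    stop_config("no voxel spacing available: supply `spacing_override` or a metadata sidecar.")
  }
  spacing <- check_spacing(spacing)
  if (is.null(chn)) {
    stop_config("no channel names available: supply `channel_names` or a metadata sidecar.")
  }
  if (npages %% length(chn) != 0) {
    stop_format(sprintf(
      "page count (%d) is not a multiple of the declared channel count (%d).",
      npages, length(chn)
    ))
  }
  nz <- npages %/% length(chn)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  channels <- vector("list", length(chn))
  names(channels) <- chn
  for (ci in seq_along(chn)) {
    a <- array(0, c(nx, ny, nz))
    for (k in seq_len(nz)) {
      a[, , k] <- t(pages[[(ci - 1L) * nz + k]])
    }
    a <- a * scales[ci]
    # binary channels are stored losslessly up to codec quantisation; snap
    # them back to exact 0/1
    if (isTRUE(binary[ci])) a <- round(a)
    channels[[ci]] <- a
  }
  image_volume(channels, spacing)
}

# --- structure masks -----------------------------------------------------

#' Construct a named binary structure mask
#'
#' @param voxels logical (or 0/1) 3D array.
#' @param name structure class, e.g. `bone_surface`, `vessel_any`, `arterial`,
#'   `type_h`, `type_l`, `lumen`, `marrow_admissible`, `tumour_region`.
#' @param spacing voxel spacing in µm (x, y, z).
#' @return logical 3D array of class `structure_mask` with `name` and
#'   `spacing` attributes.
#' @export
structure_mask <- function(voxels, name, spacing) {
  d <- grid_dims(voxels)
  spacing <- check_spacing(spacing)
  m <- array(as.logical(voxels), d)
  attr(m, "name") <- name
  attr(m, "spacing") <- spacing
  class(m) <- c("structure_mask", class(m))
  m
}

mask_spacing <- function(mask, default = NULL) {
  attr(mask, "spacing") %||% default
}

#' Write a set of structure masks as TIFF volumes
#' @param masks named list of logical arrays (or `structure_mask` objects).
#' @param spacing voxel spacing in µm.
#' @param dir output directory; one `<name>.tif` per mask.
#' @return tibble of mask names and file paths, invisibly.
#' @export
write_masks <- function(masks, spacing, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(masks))
  for (i in seq_along(masks)) {
    nm <- names(masks)[i]
    paths[i] <- file.path(dir, paste0(nm, ".tif"))
    write_volume(
      image_volume(setNames(list(array(as.numeric(masks[[i]]), dim(masks[[i]]))), nm),
                   spacing),
      paths[i]
    )
  }
  invisible(tibble::tibble(name = names(masks), path = paths))
}
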