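#' Spot tables
#'
#' Spots are point objects — detected disseminated tumour cells (DTCs) or
#' null-model random spots — stored as a tibble with one row per spot and
#' µm coordinates: columns `id`, `x_um`, `y_um`, `z_um`, `radius_um`, `kind`
#' (`"dtc"` or `"random"`), plus any extra measurement columns.
#'
#' @param spots a data frame with at least the required columns.
#' @return a validated spot tibble (class `spot_set`).
#' @export
spot_set <- function(spots) {
  required <- c("id", "x_um", "y_um", "z_um", "radius_um", "kind")
  missing <- setdiff(required, names(spots))
  if (length(missing) > 0) {
    stop_format(sprintf("spot table is missing column(s): %s.",
                        paste(missing, collapse = ", ")))
  }
  spots <- tibble::as_tibble(spots)
  if (anyDuplicated(spots$id)) stop_validation("spot ids must be unique.")
  if (any(!is.finite(spots$radius_um)) || any(spots$radius_um <= 0)) {
    stop_validation("spot radii must be finite and > 0.")
  }
  class(spots) <- c("spot_set", class(spots))
  spots
}

#' Read a spot table from CSV
#'
#' @param path CSV path with columns `id`, `x_um`, `y_um`, `z_um`,
#'   `radius_um`, `kind`.
#' @return a `spot_set` tibble.
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file '%s' does not exist.", path))
  spots <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  spot_set(spots)
}

#' Write a spot table to CSV
#'
#' Coordinates are written at full double precision so that a read/write
#' round trip preserves positions to well below 1e-6 µm.
#'
#' @param spots a `spot_set` (or compatible data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  spots <- spot_set(spots)
  readr::write_csv(spots, path, progress = FALSE)
  invisible(path)
}

# physical centroid matrix (n x 3) from a spot table
spot_coords <- function(spots) {
  as.matrix(spots[, c("x_um", "y_um", "z_um")])
}
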