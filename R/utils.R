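# Internal helpers shared across modules.

# Structured condition helpers; classes let callers distinguish configuration
# problems from data problems programmatically.
mm_error <- function(class, message, ...) {
  rlang::abort(message, class = c(class, "mm_error"), ...)
}

stop_config <- function(message, ...) mm_error("mm_config_error", message, ...)
stop_format <- function(message, ...) mm_error("mm_format_error", message, ...)
stop_validation <- function(message, ...) mm_error("mm_validation_error", message, ...)
stop_generation <- function(message, ...) mm_error("mm_generation_error", message, ...)
stop_precondition <- function(message, ...) mm_error("mm_precondition_error", message, ...)
stop_dependency <- function(message, ...) mm_error("mm_dependency_error", message, ...)
stop_io <- function(message, ...) mm_error("mm_io_error", message, ...)

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic derivation of per-stage seeds from a master seed, kept within
# the 32-bit integer range R requires.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h * 7919) %% 2147483563) + 1L
}

# Physical voxel-centre coordinates along one axis (0-based index convention:
# voxel i sits at i * spacing).
axis_coords <- function(n, spacing) (seq_len(n) - 1) * spacing

# Full coordinate arrays for a grid; returned lazily as needed by callers.
coord_arrays <- function(dims, spacing) {
  xs <- axis_coords(dims[1], spacing[1])
  ys <- axis_coords(dims[2], spacing[2])
  zs <- axis_coords(dims[3], spacing[3])
  list(
    x = array(xs, dims),
    y = array(rep(ys, each = dims[1]), dims),
    z = array(rep(zs, each = dims[1] * dims[2]), dims)
  )
}

# linear index (1-based) -> 0-based voxel (i,j,k)
index_to_ijk <- function(idx, dims) {
  idx0 <- idx - 1L
  i <- idx0 %% dims[1]
  j <- (idx0 %/% dims[1]) %% dims[2]
  k <- idx0 %/% (dims[1] * dims[2])
  cbind(i = i, j = j, k = k)
}

# 0-based voxel triplets -> physical µm coordinates of voxel centres
ijk_to_um <- function(ijk, spacing) {
  cbind(
    x_um = ijk[, 1] * spacing[1],
    y_um = ijk[, 2] * spacing[2],
    z_um = ijk[, 3] * spacing[3]
  )
}

check_spacing <- function(spacing) {
  if (length(spacing) != 3 || !is.numeric(spacing) || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    stop_validation("`spacing` must be three strictly positive finite values (sx, sy, sz) in µm.")
  }
  as.numeric(spacing)
}

grid_dims <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3) {
    stop_validation("expected a 3D array.")
  }
  d
}
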