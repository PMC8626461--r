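# Independent oracles and shared fixtures. Each oracle is a direct,
# brute-force or closed-form computation kept deliberately separate from the
# implementation paths it checks.

# all-pairs Euclidean distance transform (exact, O(n * |mask|))
brute_edt <- function(mask, spacing) {
  dims <- dim(mask)
  idx <- which(mask)
  ijk <- marrowmap:::index_to_ijk(idx, dims)
  pts <- marrowmap:::ijk_to_um(ijk, spacing)
  allum <- marrowmap:::ijk_to_um(
    marrowmap:::index_to_ijk(seq_len(prod(dims)), dims), spacing
  )
  out <- array(0, dims)
  for (t in seq_len(prod(dims))) {
    out[t] <- sqrt(min((pts[, 1] - allum[t, 1])^2 +
                         (pts[, 2] - allum[t, 2])^2 +
                         (pts[, 3] - allum[t, 3])^2))
  }
  out
}

# brute-force connected-component count by queue flood fill
brute_component_count <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  lab <- array(0L, dims)
  nl <- 0L
  for (s in which(mask)) {
    if (lab[s] > 0) next
    nl <- nl + 1L
    queue <- s
    lab[s] <- nl
    while (length(queue) > 0) {
      cur <- queue[1]
      queue <- queue[-1]
      ijk <- marrowmap:::index_to_ijk(cur, dims)
      for (o in seq_len(nrow(offs))) {
        n <- ijk + offs[o, ]
        if (any(n < 0) || any(n >= dims)) next
        lin <- n[1] + dims[1] * (n[2] + dims[2] * n[3]) + 1
        if (mask[lin] && lab[lin] == 0L) {
          lab[lin] <- nl
          queue <- c(queue, lin)
        }
      }
    }
  }
  nl
}

# brute-force two-sample KS D: sup over all pooled thresholds of the
# absolute ECDF difference
brute_ks_D <- function(a, b) {
  pool <- sort(unique(c(a, b)))
  max(abs(vapply(pool, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# closed-form Student and Welch t statistics and two-sided p values
closed_form_t <- function(a, b, variant = "student") {
  n1 <- length(a); n2 <- length(b)
  if (variant == "student") {
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- var(a) / n1 + var(b) / n2
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((var(a) / n1)^2 / (n1 - 1) + (var(b) / n2)^2 / (n2 - 1))
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# hand-built vessel tree: one straight segment along the y axis
straight_tree <- function(from, to, radius, subtype = "type_l", n = 2) {
  pts <- cbind(seq(from[1], to[1], length.out = n),
               seq(from[2], to[2], length.out = n),
               seq(from[3], to[3], length.out = n))
  seg <- tibble::tibble(
    seg_id = 1L, parent_id = NA_integer_, subtype = subtype,
    radius_um = radius,
    length_um = sqrt(sum((to - from)^2)),
    points = list(pts)
  )
  structure(list(segments = seg, sprouts = marrowmap:::empty_sprouts()),
            class = "vessel_tree")
}

# binary tube mask along y: centreline at (cx, cz), given radius
tube_mask <- function(dims, spacing, cx, cz, radius, rinner = NULL) {
  co <- marrowmap:::coord_arrays(dims, spacing)
  m <- (co$x - cx)^2 + (co$z - cz)^2 <= radius^2
  if (!is.null(rinner)) {
    m <- m & ((co$x - cx)^2 + (co$z - cz)^2 > rinner^2)
  }
  m
}

# small, fast synthetic configuration for unit tests
small_config <- function(seed = 1L, ...) {
  synthetic_config(
    dims = c(96L, 96L, 32L), spacing = c(1, 1, 2),
    vessels = list(n_arterioles = 1L, seg_length = c(arterial = 50,
                                                     type_h = 60,
                                                     type_l = 40)),
    dtc = list(n_spots = 40L),
    seed = seed,
    ...
  )
}
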