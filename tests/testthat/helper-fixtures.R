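# Small shared fixtures: a 24^3 atlas is large enough for all 14 regions
# yet keeps per-test stratifications fast.
small_atlas <- function(shape = c(24L, 24L, 24L)) {
  build_synthetic_atlas(shape, voxel_size_mm = c(2, 2, 2))
}

noiseless_spec <- function(multipliers = list(), ...) {
  phantom_spec(multipliers, noise_sd = 0, smoothing_fwhm_mm = 0, ...)
}

# Brute-force 26-connected component labeling by BFS flood fill; the
# independent oracle for the fast label propagation.
flood_fill_label <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  k <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (s in seq_len(nrow(idx))) {
    p0 <- idx[s, ]
    if (lab[p0[1], p0[2], p0[3]] != 0L) next
    k <- k + 1L
    queue <- list(p0)
    lab[p0[1], p0[2], p0[3]] <- k
    while (length(queue) > 0L) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0L && dy == 0L && dz == 0L) next
        q <- p + c(dx, dy, dz)
        if (all(q >= 1L) && all(q <= d) && mask[q[1], q[2], q[3]] &&
            lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- k
          queue <- c(queue, list(q))
        }
      }
    }
  }
  lab
}

# Brute-force regional positivity from the flood-fill oracle.
oracle_region_positive <- function(mask, atlas, region, min_cluster) {
  lab <- flood_fill_label(mask)
  rmask <- region_mask(atlas, region)
  ids <- lab[rmask & mask]
  length(ids) > 0L && max(tabulate(ids)) >= min_cluster
}

expect_same_partition <- function(a, b, mask) {
  expect_equal(max(a), max(b))
  expect_true(all((a > 0) == mask))
  if (any(mask)) {
    tb <- table(a[mask], b[mask])
    expect_true(all(rowSums(tb > 0) == 1) && all(colSums(tb > 0) == 1))
  }
}
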