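# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is stored on disk.

# A section field directly from a label matrix (pixel size in mm).
make_field <- function(labels, pixel_size = 0.01) {
  section_field(matrix(as.integer(labels), nrow(labels)), pixel_size)
}

# A uniform field of one label.
uniform_field <- function(label, n = 20, pixel_size = 0.01) {
  make_field(matrix(label, n, n), pixel_size)
}

# Field with random lumen discs (plus epithelial rings) on stroma; used
# for profile-counting properties. Returns the field; the number of
# distinct lumen components is what profile counting should recover.
blob_field <- function(n = 200, n_blobs = 25, r_range = c(2, 6),
                       pixel_size = 0.01, seed = 1) {
  set.seed(seed)
  lab <- matrix(3L, n, n)
  for (b in seq_len(n_blobs)) {
    cx <- runif(1, 8, n - 8); cy <- runif(1, 8, n - 8)
    r <- runif(1, r_range[1], r_range[2])
    d <- sqrt(outer((1:n) - cx, rep(1, n))^2 +
                outer(rep(1, n), (1:n) - cy)^2)
    lab[d <= r * 1.6] <- 2L
    lab[d <= r] <- 1L
  }
  make_field(lab, pixel_size)
}

# Count distinct lumen components of a field with an independent
# labeling route (flood fill over a logical matrix in plain R).
count_lumen_components_oracle <- function(field) {
  lum <- field$labels == 1L
  seen <- matrix(FALSE, nrow(lum), ncol(lum))
  n <- 0L
  for (i in seq_len(nrow(lum))) for (j in seq_len(ncol(lum))) {
    if (!lum[i, j] || seen[i, j]) next
    n <- n + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii < 1 || jj < 1 || ii > nrow(lum) || jj > ncol(lum)) next
        if (lum[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  n
}

# Small tubule phantom used across tests (seeded, coarse, fast).
small_tubule_phantom <- function(seed = 7, voxel = 0.02, count = 4) {
  build_phantom(phantom_spec(block_edge_lengths = c(1, 1, 1),
                             voxel_size = voxel, tubule_count = count,
                             tubule_lumen_radius = 0.05,
                             epithelium_thickness = 0.02,
                             tubule_length = 0.8, rng_seed = seed))
}
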