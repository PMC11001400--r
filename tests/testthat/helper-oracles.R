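# Independent reference implementations used only by the tests; written
# loop-by-loop against the definitions, not against the package code paths.

# pixel-wise median via a full sort of each pixel's value vector
median_reference <- function(frames) {
  d <- dim(frames[[1]])
  out <- matrix(NA_real_, d[1], d[2])
  for (r in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      v <- sort(vapply(frames, function(f) f[r, c], 0))
      n <- length(v)
      out[r, c] <- if (n %% 2 == 1) v[(n + 1) / 2] else
        (v[n / 2] + v[n / 2 + 1]) / 2
    }
  }
  out
}

# per-region tally by scanning boundaries from the half-open split formula
tally_reference <- function(keypoints, shape, grid_rows = 2L, grid_cols = 4L) {
  counts <- integer(grid_rows * grid_cols)
  if (nrow(keypoints) == 0L) return(counts)
  h <- shape[1]; w <- shape[2]
  for (i in seq_len(nrow(keypoints))) {
    r0 <- keypoints$row[i] - 1L; c0 <- keypoints$col[i] - 1L
    tr <- NA_integer_; tc <- NA_integer_
    for (t in seq_len(grid_rows)) {
      if (r0 >= floor((t - 1) * h / grid_rows) &&
          r0 < floor(t * h / grid_rows)) tr <- t
    }
    for (t in seq_len(grid_cols)) {
      if (c0 >= floor((t - 1) * w / grid_cols) &&
          c0 < floor(t * w / grid_cols)) tc <- t
    }
    id <- (tr - 1L) * grid_cols + tc
    counts[id] <- counts[id] + 1L
  }
  counts
}

# place a discretized Gaussian peak with an explicit double loop
plant_peak <- function(frame, r, c, amplitude, sigma) {
  if (sigma <= 0) {
    frame[r, c] <- frame[r, c] + amplitude
    return(frame)
  }
  rad <- ceiling(3 * sigma)
  for (dr in -rad:rad) {
    for (dc in -rad:rad) {
      if (sqrt(dr^2 + dc^2) > 3 * sigma) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nrow(frame) || cc < 1 || cc > ncol(frame)) next
      frame[rr, cc] <- frame[rr, cc] +
        amplitude * exp(-(dr^2 + dc^2) / (2 * sigma^2))
    }
  }
  frame
}

# linearly separable toy descriptor set: misses are zero vectors, hits have
# clear counts in a couple of regions
toy_descriptor_set <- function(n_per_class = 40L, seed = 42L) {
  set.seed(seed)
  miss <- matrix(0L, n_per_class, 8L)
  hit <- t(vapply(seq_len(n_per_class), function(i) {
    v <- integer(8L)
    v[sample.int(8L, 3L)] <- sample(5:20, 3L, replace = TRUE)
    v
  }, integer(8L)))
  list(features = rbind(hit, miss),
       labels = rep(c("hit", "miss"), each = n_per_class))
}

# random frame for detector fuzzing: Poisson floor plus sparse bright spikes
random_test_frame <- function(h, w, lambda = 2, n_spikes = 15L) {
  f <- matrix(rpois(h * w, lambda), h, w)
  if (n_spikes > 0L) {
    idx <- sample.int(h * w, n_spikes)
    f[idx] <- f[idx] + runif(n_spikes, 10, 120)
  }
  f
}
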