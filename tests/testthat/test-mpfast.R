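test_that("cardinal test thresholds, compares strictly and checks bounds", {
  f <- matrix(0, 9, 9)
  f[5, 5] <- 10
  expect_false(cardinal_candidate_test(f, 5, 5))          # below tr = 20
  f[5, 5] <- 100
  expect_true(cardinal_candidate_test(f, 5, 5))           # beats all four 0s
  u <- matrix(50, 9, 9)                                   # flat: no strict win
  expect_false(cardinal_candidate_test(u, 5, 5))
  expect_error(cardinal_candidate_test(f, 2, 5), "border")

  # exactly three of four wins suffices; two does not
  g <- matrix(0, 9, 9); g[5, 5] <- 100; g[2, 5] <- 150
  expect_true(cardinal_candidate_test(g, 5, 5))
  g[5, 8] <- 150
  expect_false(cardinal_candidate_test(g, 5, 5))
})

test_that("apex refinement picks the 3x3 maximum with deterministic ties", {
  f <- matrix(0, 7, 7)
  f[4, 4] <- 50
  expect_equal(refine_apex(f, 4, 4),
               data.frame(row = 4, col = 4, intensity = 50))
  f[4, 5] <- 60                                          # east neighbour wins
  expect_equal(refine_apex(f, 4, 4),
               data.frame(row = 4, col = 5, intensity = 60))
  g <- matrix(0, 7, 7); g[4, 4] <- 50; g[3, 4] <- 50     # tie -> candidate
  expect_equal(refine_apex(g, 4, 4),
               data.frame(row = 4, col = 4, intensity = 50))
  expect_error(refine_apex(f, 1, 4), "border")
})

test_that("empty and degenerate frames behave as specified", {
  expect_identical(nrow(detect_keypoints(matrix(0, 32, 32))), 0L)
  expect_error(detect_keypoints(matrix(0, 6, 32)), "small")
  expect_error(brute_force_oracle(matrix(0, 32, 6)), "small")
})

test_that("a single planted Gaussian peak is localized at its apex", {
  # compact peak (every off-apex pixel beyond 1 px is below tr):
  # exactly one key point, at the apex
  f <- plant_peak(matrix(0, 64, 64), 30, 41, 45, 1.5)
  kp <- detect_keypoints(f)
  expect_identical(nrow(kp), 1L)
  expect_equal(kp$row, 30)
  expect_equal(kp$col, 41)
  expect_equal(kp$intensity, 45)

  # bright broad peak: shoulder pixels above tr are candidates too and
  # refine to within 1 px of the apex; the apex itself is always found
  g <- plant_peak(matrix(0, 64, 64), 30, 41, 200, 1.5)
  kpg <- detect_keypoints(g)
  expect_identical(kpg, brute_force_oracle(g))
  expect_true(any(kpg$row == 30 & kpg$col == 41 & kpg$intensity == 200))
  expect_true(all(abs(kpg$row - 30) <= 2 & abs(kpg$col - 41) <= 2))
})

test_that("vectorized detector equals the naive oracle on random frames", {
  set.seed(2024)
  for (case in 1:36) {
    tr <- c(0, 20, 50)[(case - 1) %% 3 + 1]
    f <- random_test_frame(48, 48, lambda = sample(c(1, 5, 20), 1))
    p <- detector_params(tr = tr)
    expect_identical(detect_keypoints(f, p), brute_force_oracle(f, p))
  }
})

test_that("detection is equivariant under content translation", {
  set.seed(5)
  base <- matrix(0, 64, 64)
  for (i in 1:5)
    base <- plant_peak(base, sample(15:40, 1), sample(15:40, 1),
                       runif(1, 80, 200), runif(1, 0, 1.2))
  kp <- detect_keypoints(base)
  shifted <- matrix(0, 64, 64)
  shifted[(1 + 9):64, (1 + 12):64] <- base[1:(64 - 9), 1:(64 - 12)]
  kp2 <- detect_keypoints(shifted)
  expect_equal(kp2$row, kp$row + 9)
  expect_equal(kp2$col, kp$col + 12)
})

test_that("scaling intensities above threshold does not change key points", {
  set.seed(6)
  f <- matrix(0, 48, 48)
  for (i in 1:4)
    f <- plant_peak(f, sample(10:38, 1), sample(10:38, 1),
                    runif(1, 50, 150), runif(1, 0, 1))
  kp1 <- detect_keypoints(f)
  kp3 <- detect_keypoints(f * 3)
  expect_identical(kp1[c("row", "col")], kp3[c("row", "col")])
})

test_that("no key point lies within the 3-pixel border ring", {
  set.seed(8)
  for (i in 1:10) {
    f <- random_test_frame(40, 40, lambda = 15)
    kp <- detect_keypoints(f, detector_params(tr = 0))
    if (nrow(kp) > 0) {
      expect_true(all(kp$row >= 4 & kp$row <= 37))
      expect_true(all(kp$col >= 4 & kp$col <= 37))
    }
  }
})

test_that("well-separated planted peaks are recovered exactly", {
  p <- sim_params(128, 128, background_rate = 0,
                  fixed_pattern_amplitude = 0, hot_pixel_fraction = 0,
                  n_peaks_range = c(12, 12), peak_amplitude_range = c(60, 250),
                  peak_sigma_range = c(0, 0.8), min_peak_separation = 9,
                  seed = 31)
  for (s in 1:6) {
    out <- generate_hit_frame(p, 500 + s)
    kp <- detect_keypoints(out$frame)
    truth <- out$truth$peaks[order(out$truth$peaks$row,
                                   out$truth$peaks$col), ]
    expect_identical(kp$row, truth$row)
    expect_identical(kp$col, truth$col)
  }
})

test_that("sequential-flag mode agrees with the canonical mode on separated peaks", {
  p <- sim_params(128, 128, background_rate = 0,
                  fixed_pattern_amplitude = 0, hot_pixel_fraction = 0,
                  n_peaks_range = c(10, 10), peak_sigma_range = c(0, 1),
                  min_peak_separation = 8, seed = 77)
  for (s in 1:5) {
    f <- generate_hit_frame(p, 900 + s)$frame
    oi <- detect_keypoints(f, detector_params(mode = "order_independent"))
    sq <- detect_keypoints(f, detector_params(mode = "sequential_flags"))
    expect_identical(oi, sq)
  }
})

test_that("chunked detection reproduces whole-frame results", {
  set.seed(9)
  # peaks deliberately straddling the 2/4/8-band boundaries of a 64-row frame
  f <- matrix(0, 64, 64)
  for (r in c(8, 16, 24, 32, 40, 48, 56)) {
    f <- plant_peak(f, r, sample(10:54, 1), runif(1, 80, 200), 1)
  }
  f <- f + matrix(rpois(64 * 64, 1), 64, 64)
  whole <- detect_keypoints(f)
  for (nc in c(1, 2, 4, 8)) {
    expect_identical(chunked_detect(f, n_chunks = nc), whole)
  }
})

test_that("excessive chunk counts are clamped with a warning", {
  f <- matrix(0, 32, 32)
  expect_warning(kp <- chunked_detect(f, n_chunks = 30), "clamped")
  expect_identical(nrow(kp), 0L)
})
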