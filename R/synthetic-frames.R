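#' Simulation parameters for synthetic diffraction frames
#'
#' Bundles the knobs of the synthetic-frame generator. A frame is a 2D grid of
#' nonnegative photon counts made of three ingredients: a Poisson diffuse
#' background, a static per-detector fixed-pattern field (smooth low-frequency
#' offsets plus hot pixels), and -- for hit frames -- a set of planted Bragg
#' peaks. A peak is either a single bright pixel (`sigma = 0`) or a
#' discretized isotropic Gaussian blob truncated at 3 sigma whose apex pixel
#' carries the drawn amplitude exactly, so ground-truth apices stay usable as
#' an exact oracle for the detector.
#'
#' Defaults describe a typical moderately clean run: 256x256 frames, one
#' background photon per pixel on average, compact peaks (sigma up to 1 px,
#' i.e. footprints of one to roughly nine pixels), amplitudes of 100-300
#' counts (well above the detection threshold of 20), 5-20 peaks per hit
#' frame at a minimum apex separation of 8 px.
#'
#' @param frame_height,frame_width Frame dimensions in pixels (both >= 16 so
#'   the radius-3 detector circle plus refinement margin fits).
#' @param background_rate Mean Poisson background counts per pixel (>= 0).
#' @param hot_pixel_fraction Fraction of pixels set to `hot_pixel_value` in
#'   the fixed pattern, in `[0, 1]`.
#' @param hot_pixel_value Intensity of hot pixels, counts.
#' @param fixed_pattern_amplitude Peak-to-trough scale of the smooth static
#'   offset field, counts.
#' @param n_peaks_range Inclusive integer interval for the number of peaks
#'   per hit frame.
#' @param peak_amplitude_range Inclusive interval for apex amplitudes, counts.
#' @param peak_sigma_range Inclusive interval for peak widths in pixels;
#'   0 means a single-pixel peak.
#' @param min_peak_separation Minimum pairwise Euclidean distance between
#'   apices, pixels (>= 1).
#' @param peak_poisson If `TRUE`, the rendered peak profile is resampled as
#'   Poisson counts (counting noise on the signal); default `FALSE` keeps the
#'   apex amplitude exact for oracle tests.
#' @param seed Integer run seed; all per-frame randomness is derived from it.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(frame_height = 256L, frame_width = 256L,
                       background_rate = 1, hot_pixel_fraction = 0.001,
                       hot_pixel_value = 500, fixed_pattern_amplitude = 10,
                       n_peaks_range = c(5L, 20L),
                       peak_amplitude_range = c(100, 300),
                       peak_sigma_range = c(0, 1),
                       min_peak_separation = 8,
                       peak_poisson = FALSE,
                       seed = 1L) {
  frame_height <- as.integer(frame_height)
  frame_width <- as.integer(frame_width)
  if (frame_height < 16L || frame_width < 16L)
    stop("frame dimensions must be >= 16 in both axes")
  if (background_rate < 0) stop("background_rate must be >= 0")
  if (hot_pixel_fraction < 0 || hot_pixel_fraction > 1)
    stop("hot_pixel_fraction must be in [0, 1]")
  n_peaks_range <- as.integer(n_peaks_range)
  if (length(n_peaks_range) != 2L || any(n_peaks_range < 0L) ||
      n_peaks_range[1] > n_peaks_range[2])
    stop("n_peaks_range must be an inclusive nonnegative integer interval")
  if (length(peak_amplitude_range) != 2L ||
      peak_amplitude_range[1] > peak_amplitude_range[2])
    stop("peak_amplitude_range must be an inclusive interval")
  if (length(peak_sigma_range) != 2L || any(peak_sigma_range < 0) ||
      peak_sigma_range[1] > peak_sigma_range[2])
    stop("peak_sigma_range must be an inclusive nonnegative interval")
  if (min_peak_separation < 1) stop("min_peak_separation must be >= 1")
  structure(list(
    frame_height = frame_height, frame_width = frame_width,
    background_rate = background_rate,
    hot_pixel_fraction = hot_pixel_fraction,
    hot_pixel_value = hot_pixel_value,
    fixed_pattern_amplitude = fixed_pattern_amplitude,
    n_peaks_range = n_peaks_range,
    peak_amplitude_range = as.numeric(peak_amplitude_range),
    peak_sigma_range = as.numeric(peak_sigma_range),
    min_peak_separation = min_peak_separation,
    peak_poisson = isTRUE(peak_poisson),
    seed = as.integer(seed)
  ), class = "sim_params")
}

# Deterministic per-frame sub-seed; kept < 2^31 so set.seed() accepts it.
frame_seed <- function(run_seed, frame_index) {
  s <- (as.double(run_seed) %% 2147483647) * 69621 + frame_index * 104729
  as.integer(s %% 2147483647)
}

empty_peak_table <- function() {
  data.frame(row = integer(0), col = integer(0), amplitude = numeric(0))
}

#' Static fixed-pattern field of a simulated detector
#'
#' Builds the per-pixel offset field reused by every frame of one simulated
#' run: a smooth low-frequency component (a small sum of random-phase cosine
#' waves, rescaled to `[0, fixed_pattern_amplitude]`) plus exactly
#' `round(hot_pixel_fraction * n_pixels)` hot pixels set to `hot_pixel_value`.
#' Deterministic for a given `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @return An `frame_height x frame_width` numeric matrix.
#' @export
make_fixed_pattern <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  h <- params$frame_height; w <- params$frame_width
  set.seed(frame_seed(params$seed, 0L))
  field <- matrix(0, h, w)
  if (params$fixed_pattern_amplitude > 0) {
    rr <- (seq_len(h) - 1) / h
    cc <- (seq_len(w) - 1) / w
    for (k in 1:3) {
      fr <- sample(1:3, 1); fc <- sample(1:3, 1)
      ph <- stats::runif(2, 0, 2 * pi)
      field <- field + outer(cos(2 * pi * fr * rr + ph[1]),
                             cos(2 * pi * fc * cc + ph[2]))
    }
    rng <- range(field)
    if (rng[2] > rng[1]) {
      field <- (field - rng[1]) / (rng[2] - rng[1]) *
        params$fixed_pattern_amplitude
    } else {
      field[] <- 0
    }
  }
  n_hot <- round(params$hot_pixel_fraction * h * w)
  if (n_hot > 0) {
    idx <- sample.int(h * w, n_hot)
    field[idx] <- params$hot_pixel_value
  }
  field
}

#' Generate one background-only (miss) frame
#'
#' @param params A [sim_params()] object.
#' @param frame_seed_value Integer seed for this frame's randomness; defaults
#'   to a sub-seed derived from `params$seed`.
#' @param fixed_pattern Optional precomputed [make_fixed_pattern()] field
#'   (recomputed from `params` when `NULL`).
#' @return A list with `frame` (numeric matrix) and `truth` (list with an
#'   empty `peaks` table and `label = "miss"`).
#' @export
generate_miss_frame <- function(params,
                                frame_seed_value = frame_seed(params$seed, 1L),
                                fixed_pattern = NULL) {
  stopifnot(inherits(params, "sim_params"))
  h <- params$frame_height; w <- params$frame_width
  if (is.null(fixed_pattern)) fixed_pattern <- make_fixed_pattern(params)
  set.seed(frame_seed_value)
  frame <- matrix(stats::rpois(h * w, params$background_rate), h, w) +
    fixed_pattern
  list(frame = frame,
       truth = list(peaks = empty_peak_table(), label = "miss"))
}

# Draw one element uniformly (safe for length-1 vectors).
draw_one <- function(x) x[sample.int(length(x), 1L)]

place_apices <- function(k, h, w, min_sep, max_tries = 1000L) {
  # apices must stay >= 4 px from every border (0-based), i.e. rows 5..h-4
  rows <- integer(0); cols <- integer(0)
  for (i in seq_len(k)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      r <- draw_one(5:(h - 4L)); c <- draw_one(5:(w - 4L))
      if (length(rows) == 0L ||
          all((rows - r)^2 + (cols - c)^2 >= min_sep^2)) {
        rows <- c(rows, r); cols <- c(cols, c); ok <- TRUE; break
      }
    }
    if (!ok)
      stop("peak placement failed: could not satisfy min_peak_separation ",
           "after ", max_tries, " attempts")
  }
  cbind(row = rows, col = cols)
}

render_peak <- function(frame, r, c, amplitude, sigma, poisson_resample) {
  h <- nrow(frame); w <- ncol(frame)
  if (sigma <= 0) {
    contrib_r <- r; contrib_c <- c; contrib_v <- amplitude
  } else {
    rad <- ceiling(3 * sigma)
    dr <- (-rad):rad
    rows <- r + dr; cols <- c + dr
    keep_r <- rows >= 1L & rows <= h
    keep_c <- cols >= 1L & cols <= w
    d2 <- outer(dr[keep_r]^2, dr[keep_c]^2, "+")
    v <- amplitude * exp(-d2 / (2 * sigma^2))
    v[sqrt(d2) > 3 * sigma] <- 0
    contrib_r <- rep(rows[keep_r], times = sum(keep_c))
    contrib_c <- rep(cols[keep_c], each = sum(keep_r))
    contrib_v <- as.vector(v)
  }
  if (poisson_resample) contrib_v <- stats::rpois(length(contrib_v), contrib_v)
  idx <- cbind(contrib_r, contrib_c)
  frame[idx] <- frame[idx] + contrib_v
  frame
}

#' Generate one hit frame with planted Bragg peaks
#'
#' Draws K uniformly from `n_peaks_range`, places K apices by rejection
#' sampling (pairwise separation >= `min_peak_separation`, all apices >= 4 px
#' from every border), renders each peak onto a miss-frame background and
#' records the apices as ground truth.
#'
#' @inheritParams generate_miss_frame
#' @return A list with `frame` and `truth` (`peaks` table with columns
#'   `row`, `col`, `amplitude`; `label = "hit"`). Coordinates are 1-based.
#' @export
generate_hit_frame <- function(params,
                               frame_seed_value = frame_seed(params$seed, 1L),
                               fixed_pattern = NULL) {
  stopifnot(inherits(params, "sim_params"))
  h <- params$frame_height; w <- params$frame_width
  if (is.null(fixed_pattern)) fixed_pattern <- make_fixed_pattern(params)
  set.seed(frame_seed_value)
  frame <- matrix(stats::rpois(h * w, params$background_rate), h, w) +
    fixed_pattern
  k <- draw_one(params$n_peaks_range[1]:params$n_peaks_range[2])
  apices <- place_apices(k, h, w, params$min_peak_separation)
  amps <- stats::runif(k, params$peak_amplitude_range[1],
                       params$peak_amplitude_range[2])
  sigmas <- stats::runif(k, params$peak_sigma_range[1],
                         params$peak_sigma_range[2])
  for (i in seq_len(k)) {
    frame <- render_peak(frame, apices[i, "row"], apices[i, "col"],
                         amps[i], sigmas[i], params$peak_poisson)
  }
  list(frame = frame,
       truth = list(peaks = data.frame(row = apices[, "row"],
                                       col = apices[, "col"],
                                       amplitude = amps),
                    label = "hit"))
}

#' Generate a labelled stack of synthetic frames
#'
#' Hit frames come first, then miss frames. Every frame draws its own
#' sub-seed from `params$seed` and its index, so any single frame can be
#' regenerated in isolation and the whole stack is bit-reproducible.
#'
#' @param params A [sim_params()] object.
#' @param n_hit,n_miss Nonnegative frame counts.
#' @return A list with `frames` (`N x H x W` array), `labels` (character),
#'   `truth` (list of per-frame ground truths) and `params`.
#' @export
generate_dataset <- function(params, n_hit, n_miss) {
  stopifnot(inherits(params, "sim_params"), n_hit >= 0, n_miss >= 0)
  n <- n_hit + n_miss
  h <- params$frame_height; w <- params$frame_width
  frames <- array(0, dim = c(n, h, w))
  labels <- character(n)
  truth <- vector("list", n)
  fp <- make_fixed_pattern(params)
  for (i in seq_len(n)) {
    sseed <- frame_seed(params$seed, i)
    out <- if (i <= n_hit) {
      generate_hit_frame(params, sseed, fp)
    } else {
      generate_miss_frame(params, sseed, fp)
    }
    frames[i, , ] <- out$frame
    labels[i] <- out$truth$label
    truth[[i]] <- out$truth
  }
  list(frames = frames, labels = labels, truth = truth, params = params)
}

#' Five-class synthetic data set
#'
#' Optional multi-class mode with the five label taxonomy common for
#' synthetic diffraction benchmarks (Blank, No Crystal, Weak, Good,
#' Strong). Classes are realized purely as planted-peak count bands
#' (0 / 1-2 / 3-8 / 9-20 / 21-40 peaks) on the same background model; this
#' is a structural stand-in for classifier plumbing, not a physically
#' faithful rendering of the class definitions.
#'
#' @param params A [sim_params()] object (its `n_peaks_range` is overridden
#'   per class).
#' @param n_per_class Frames per class.
#' @return Same structure as [generate_dataset()], with 5-level labels.
#' @export
generate_five_class_dataset <- function(params, n_per_class) {
  classes <- list(Blank = c(0L, 0L), No_Crystal = c(1L, 2L),
                  Weak = c(3L, 8L), Good = c(9L, 20L),
                  Strong = c(21L, 40L))
  n <- 5L * n_per_class
  h <- params$frame_height; w <- params$frame_width
  frames <- array(0, dim = c(n, h, w))
  labels <- character(n)
  truth <- vector("list", n)
  fp <- make_fixed_pattern(params)
  i <- 0L
  for (cl in names(classes)) {
    cl_params <- params
    cl_params$n_peaks_range <- classes[[cl]]
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      sseed <- frame_seed(params$seed, i)
      out <- if (classes[[cl]][2] == 0L) {
        generate_miss_frame(cl_params, sseed, fp)
      } else {
        generate_hit_frame(cl_params, sseed, fp)
      }
      frames[i, , ] <- out$frame
      labels[i] <- cl
      truth[[i]] <- out$truth
      truth[[i]]$label <- cl
    }
  }
  list(frames = frames, labels = labels, truth = truth, params = params)
}
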