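#' MP-FAST detector parameters
#'
#' MP-FAST adapts the FAST segment test from corner detection to Bragg-peak
#' apex detection. A pixel is a candidate when (i) its intensity strictly
#' exceeds the minimum threshold `tr` and (ii) it is strictly brighter than
#' at least `min_cardinal_wins` of the four cardinal pixels of the radius-3
#' FAST circle (pixels 1, 5, 9 and 13, i.e. offsets (-3,0), (0,+3), (+3,0),
#' (0,-3)). Candidates are then refined to the brightest pixel of their 3x3
#' neighbourhood, which recovers the apex of multiple-pixel peaks, and
#' identical apices are merged.
#'
#' @param tr Minimum intensity threshold in counts (default 20). Pixels at or
#'   below `tr` are ignored outright.
#' @param min_cardinal_wins How many of the four cardinal comparisons must be
#'   strict wins (default 3).
#' @param dedup Merge key points that share an apex position (default `TRUE`).
#' @param mode `"order_independent"` (canonical: the result does not depend
#'   on scan order, so sequential and parallel realizations agree) or
#'   `"sequential_flags"` (raster scan with a 3x3 checked-flag suppression
#'   around each processed candidate; a fast path whose output can differ
#'   when candidates are adjacent).
#' @return An object of class `detector_params`. `circle_radius` is fixed
#'   at 3.
#' @export
detector_params <- function(tr = 20, min_cardinal_wins = 3L, dedup = TRUE,
                            mode = c("order_independent", "sequential_flags")) {
  mode <- match.arg(mode)
  if (tr < 0) stop("tr must be >= 0")
  min_cardinal_wins <- as.integer(min_cardinal_wins)
  if (min_cardinal_wins < 1L || min_cardinal_wins > 4L)
    stop("min_cardinal_wins must be in 1..4")
  structure(list(tr = tr, circle_radius = 3L,
                 min_cardinal_wins = min_cardinal_wins,
                 dedup = isTRUE(dedup), mode = mode),
            class = "detector_params")
}

# cardinal offsets (circle pixels 1, 5, 9, 13), clockwise from north
cardinal_offsets <- cbind(dr = c(-3L, 0L, 3L, 0L), dc = c(0L, 3L, 0L, -3L))

# 3x3 refinement offsets in row-major order; index 5 is the centre
refine_dr <- rep(-1L:1L, each = 3L)
refine_dc <- rep(-1L:1L, times = 3L)

empty_keypoints <- function() {
  data.frame(row = integer(0), col = integer(0), intensity = numeric(0))
}

finish_keypoints <- function(kp, dedup) {
  if (nrow(kp) == 0L) return(empty_keypoints())
  if (dedup) kp <- kp[!duplicated(kp[c("row", "col")]), , drop = FALSE]
  kp <- kp[order(kp$row, kp$col), , drop = FALSE]
  rownames(kp) <- NULL
  kp
}

#' High-speed cardinal-pixel candidate test at one pixel
#'
#' `TRUE` iff the pixel's intensity strictly exceeds `tr` and strictly
#' exceeds the intensity at `min_cardinal_wins` or more of the four cardinal
#' pixels of the radius-3 circle. Pixels at or below `tr` short-circuit to
#' `FALSE` without looking at neighbours.
#'
#' @param frame Numeric matrix.
#' @param row,col 1-based pixel coordinates, at least `circle_radius` + 1
#'   from every border (i.e. in `4 .. H-3` / `4 .. W-3`).
#' @param params A [detector_params()] object.
#' @return Logical scalar.
#' @export
cardinal_candidate_test <- function(frame, row, col, params = detector_params()) {
  h <- nrow(frame); w <- ncol(frame)
  if (row < 4L || row > h - 3L || col < 4L || col > w - 3L)
    stop("(row, col) must be at least circle_radius from every border")
  v <- frame[row, col]
  if (v <= params$tr) return(FALSE)
  wins <- sum(v > frame[cbind(row + cardinal_offsets[, "dr"],
                              col + cardinal_offsets[, "dc"])])
  wins >= params$min_cardinal_wins
}

#' Refine a candidate to the apex of its 3x3 neighbourhood
#'
#' Returns the position of the maximum intensity over the candidate and its
#' eight neighbours, which moves the key point onto the apex of a
#' multiple-pixel peak. Ties are resolved in favour of the candidate, then
#' by smallest row, then smallest column.
#'
#' @param frame Numeric matrix.
#' @param row,col 1-based candidate coordinates, at least 1 px from borders.
#' @return A one-row data frame with `row`, `col`, `intensity`.
#' @export
refine_apex <- function(frame, row, col) {
  h <- nrow(frame); w <- ncol(frame)
  if (row < 2L || row > h - 1L || col < 2L || col > w - 1L)
    stop("(row, col) must be at least 1 pixel from every border")
  rows <- row + refine_dr; cols <- col + refine_dc
  vals <- frame[cbind(rows, cols)]
  maxv <- max(vals)
  if (frame[row, col] == maxv) {
    data.frame(row = row, col = col, intensity = maxv)
  } else {
    i <- which(vals == maxv)[1L]  # row-major first
    data.frame(row = rows[i], col = cols[i], intensity = maxv)
  }
}

# Vectorized candidate mask over the interior; returns cbind(row, col).
candidate_positions <- function(frame, params) {
  h <- nrow(frame); w <- ncol(frame)
  I <- frame[4:(h - 3L), 4:(w - 3L), drop = FALSE]
  wins <- (I > frame[1:(h - 6L), 4:(w - 3L), drop = FALSE]) +
          (I > frame[4:(h - 3L), 7:w, drop = FALSE]) +
          (I > frame[7:h, 4:(w - 3L), drop = FALSE]) +
          (I > frame[4:(h - 3L), 1:(w - 6L), drop = FALSE])
  idx <- which(I > params$tr & wins >= params$min_cardinal_wins,
               arr.ind = TRUE)
  idx + 3L
}

# Vectorized 3x3 apex refinement with candidate-wins / row-major tie rule.
refine_all <- function(frame, cand) {
  n <- nrow(cand)
  M <- matrix(0, n, 9L)
  for (k in 1:9) {
    M[, k] <- frame[cbind(cand[, 1L] + refine_dr[k],
                          cand[, 2L] + refine_dc[k])]
  }
  j <- max.col(M, ties.method = "first")
  maxv <- M[cbind(seq_len(n), j)]
  j[M[, 5L] == maxv] <- 5L  # tie goes to the candidate itself
  data.frame(row = cand[, 1L] + refine_dr[j],
             col = cand[, 2L] + refine_dc[j],
             intensity = maxv)
}

detect_order_independent <- function(frame, params, filter_border = TRUE) {
  cand <- candidate_positions(frame, params)
  if (nrow(cand) == 0L) return(empty_keypoints())
  kp <- refine_all(frame, cand)
  if (filter_border) kp <- filter_keypoint_border(kp, dim(frame))
  finish_keypoints(kp, params$dedup)
}

filter_keypoint_border <- function(kp, d) {
  keep <- kp$row >= 4L & kp$row <= d[1] - 3L &
          kp$col >= 4L & kp$col <= d[2] - 3L
  kp[keep, , drop = FALSE]
}

detect_sequential_flags <- function(frame, params) {
  cand <- candidate_positions(frame, params)
  if (nrow(cand) == 0L) return(empty_keypoints())
  # raster (row-major) processing order
  ord <- order(cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]
  flags <- matrix(FALSE, nrow(frame), ncol(frame))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1L]; c <- cand[i, 2L]
    if (flags[r, c]) next
    keep[i] <- TRUE
    flags[(r - 1L):(r + 1L), (c - 1L):(c + 1L)] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_keypoints())
  kp <- filter_keypoint_border(refine_all(frame, cand), dim(frame))
  finish_keypoints(kp, params$dedup)
}

#' Detect Bragg-peak key points in a frame
#'
#' Runs the MP-FAST procedure: threshold + cardinal-pixel candidate test on
#' every interior pixel, 3x3 apex refinement of each candidate, duplicate
#' suppression, and a final sort by (row, col). In the canonical
#' `order_independent` mode every interior pixel is tested, so the result is
#' independent of scan order; `sequential_flags` reproduces the CPU fast
#' path in which a processed candidate flags its 3x3 neighbourhood as
#' checked. Key points always lie at least `circle_radius` pixels from every
#' border and have intensity strictly above `tr`.
#'
#' @param frame Numeric matrix with both dimensions > 6.
#' @param params A [detector_params()] object.
#' @return A data frame with columns `row`, `col` (1-based), `intensity`,
#'   sorted by (row, col).
#' @export
detect_keypoints <- function(frame, params = detector_params()) {
  stopifnot(is.matrix(frame))
  if (nrow(frame) <= 2L * 3L || ncol(frame) <= 2L * 3L)
    stop("frame too small: both dimensions must exceed 2*circle_radius")
  if (params$mode == "sequential_flags") {
    detect_sequential_flags(frame, params)
  } else {
    detect_order_independent(frame, params)
  }
}

#' Naive reference detector (testing oracle)
#'
#' A deliberately loop-based restatement of the order-independent MP-FAST
#' semantics, written independently of [detect_keypoints()]'s vectorized
#' code path. Intended for tests; quadratic-ish and slow on purpose.
#'
#' @inheritParams detect_keypoints
#' @return Same shape of result as [detect_keypoints()].
#' @export
brute_force_oracle <- function(frame, params = detector_params()) {
  h <- nrow(frame); w <- ncol(frame)
  if (h <= 6L || w <= 6L)
    stop("frame too small: both dimensions must exceed 2*circle_radius")
  rows <- integer(0); cols <- integer(0); ints <- numeric(0)
  for (r in 4:(h - 3L)) {
    for (c in 4:(w - 3L)) {
      v <- frame[r, c]
      if (v <= params$tr) next
      wins <- 0L
      if (v > frame[r - 3L, c]) wins <- wins + 1L
      if (v > frame[r, c + 3L]) wins <- wins + 1L
      if (v > frame[r + 3L, c]) wins <- wins + 1L
      if (v > frame[r, c - 3L]) wins <- wins + 1L
      if (wins < params$min_cardinal_wins) next
      # refine: max over candidate + 8 neighbours, candidate wins ties,
      # then row-major order
      best_r <- r; best_c <- c; best_v <- v
      for (rr in (r - 1L):(r + 1L)) {
        for (cc in (c - 1L):(c + 1L)) {
          if (frame[rr, cc] > best_v) {
            best_r <- rr; best_c <- cc; best_v <- frame[rr, cc]
          }
        }
      }
      if (best_r < 4L || best_r > h - 3L || best_c < 4L || best_c > w - 3L)
        next
      dup <- FALSE
      if (params$dedup && length(rows) > 0L) {
        for (i in seq_along(rows)) {
          if (rows[i] == best_r && cols[i] == best_c) { dup <- TRUE; break }
        }
      }
      if (!dup) {
        rows <- c(rows, best_r); cols <- c(cols, best_c)
        ints <- c(ints, best_v)
      }
    }
  }
  kp <- data.frame(row = rows, col = cols, intensity = ints)
  ord <- order(kp$row, kp$col)
  kp <- kp[ord, , drop = FALSE]
  rownames(kp) <- NULL
  kp
}

#' Region-split detection (parallel-realization contract)
#'
#' Splits the frame into `n_chunks` horizontal bands with a 3-pixel halo on
#' each internal boundary, detects per band in order-independent mode,
#' merges, dedups and sorts. Output is identical to whole-frame
#' [detect_keypoints()]; this preserves, in single-process form, the
#' contract that region-parallel execution does not change the result.
#'
#' @inheritParams detect_keypoints
#' @param n_chunks Number of bands (>= 1); values too large for the frame
#'   height are clamped with a warning.
#' @return Same shape of result as [detect_keypoints()].
#' @export
chunked_detect <- function(frame, params = detector_params(), n_chunks = 1L) {
  stopifnot(is.matrix(frame))
  h <- nrow(frame); w <- ncol(frame)
  if (h <= 6L || w <= 6L)
    stop("frame too small: both dimensions must exceed 2*circle_radius")
  n_chunks <- as.integer(n_chunks)
  if (n_chunks < 1L) stop("n_chunks must be >= 1")
  max_chunks <- max(1L, h %/% 7L)
  if (n_chunks > max_chunks) {
    warning("n_chunks clamped from ", n_chunks, " to ", max_chunks)
    n_chunks <- max_chunks
  }
  pieces <- vector("list", n_chunks)
  for (b in seq_len(n_chunks)) {
    start <- (b - 1L) * h %/% n_chunks + 1L
    end <- b * h %/% n_chunks
    es <- max(1L, start - 3L)
    ee <- min(h, end + 3L)
    sub <- frame[es:ee, , drop = FALSE]
    kp <- detect_order_independent(sub, params, filter_border = FALSE)
    if (nrow(kp) > 0L) kp$row <- kp$row + es - 1L
    pieces[[b]] <- kp
  }
  kp <- do.call(rbind, pieces)
  kp <- filter_keypoint_border(kp, dim(frame))
  finish_keypoints(kp, dedup = TRUE)
}
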