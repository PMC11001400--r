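#' FIFO buffer of recent miss frames
#'
#' The background estimator keeps the most recent non-hit frames in a
#' fixed-capacity FIFO; a pixel-wise median through the buffer tracks both
#' the diffuse experimental background and static detector artefacts (fixed
#' pattern, hot pixels), which cancel exactly under the median because they
#' are present in every buffered frame.
#'
#' @param capacity Maximum number of buffered frames (default 100).
#' @return An object of class `miss_buffer`.
#' @export
miss_buffer <- function(capacity = 100L) {
  capacity <- as.integer(capacity)
  if (capacity < 1L) stop("capacity must be >= 1")
  structure(list(capacity = capacity, frames = list(),
                 insertions = 0L),
            class = "miss_buffer")
}

#' @export
length.miss_buffer <- function(x) length(x$frames)

#' Append a miss frame to the buffer
#'
#' Oldest frame is evicted once the capacity is exceeded. All buffered
#' frames must share one shape.
#'
#' @param buffer A [miss_buffer()].
#' @param frame Numeric matrix.
#' @return The updated buffer.
#' @export
push_miss <- function(buffer, frame) {
  stopifnot(inherits(buffer, "miss_buffer"), is.matrix(frame))
  if (length(buffer$frames) > 0L) {
    ref <- dim(buffer$frames[[1]])
    if (!identical(ref, dim(frame)))
      stop("frame shape ", paste(dim(frame), collapse = "x"),
           " does not match buffer shape ", paste(ref, collapse = "x"))
  }
  buffer$frames[[length(buffer$frames) + 1L]] <- frame
  if (length(buffer$frames) > buffer$capacity)
    buffer$frames <- buffer$frames[-1L]
  buffer$insertions <- buffer$insertions + 1L
  buffer
}

# Median of a numeric vector via partial sort of the central order
# statistics; even counts average the two central values.
pixel_median <- function(v) {
  n <- length(v)
  k <- (n + 1L) %/% 2L
  if (n %% 2L == 1L) {
    sort.int(v, partial = k)[k]
  } else {
    s <- sort.int(v, partial = c(k, k + 1L))
    (s[k] + s[k + 1L]) / 2
  }
}

#' Pixel-wise median background through a miss buffer
#'
#' For each pixel, the median of its values across all buffered frames; for
#' even buffer sizes, the mean of the two central order statistics.
#'
#' @param buffer A non-empty [miss_buffer()].
#' @return An object of class `background_estimate` with fields
#'   `median_frame`, `n_source_frames`, `stale_counter` and the insertion
#'   count at which it was computed (`refreshed_at`).
#' @export
compute_median_background <- function(buffer) {
  stopifnot(inherits(buffer, "miss_buffer"))
  n <- length(buffer$frames)
  if (n == 0L) stop("cannot compute a background from an empty buffer")
  d <- dim(buffer$frames[[1]])
  if (n == 1L) {
    med <- buffer$frames[[1]]
  } else {
    stack <- matrix(unlist(buffer$frames, use.names = FALSE),
                    nrow = d[1] * d[2], ncol = n)
    med <- matrix(apply(stack, 1L, pixel_median), d[1], d[2])
  }
  structure(list(median_frame = med, n_source_frames = n,
                 stale_counter = 0L, refreshed_at = buffer$insertions),
            class = "background_estimate")
}

#' Subtract a background estimate from a frame
#'
#' Residuals are clamped at zero: the downstream detector thresholds on
#' positive photon counts, so negative residuals carry no signal.
#'
#' @param frame Numeric matrix.
#' @param bg A [compute_median_background()] estimate.
#' @return `pmax(frame - median, 0)`, same shape as `frame`.
#' @export
subtract_background <- function(frame, bg) {
  stopifnot(is.matrix(frame), inherits(bg, "background_estimate"))
  if (!identical(dim(frame), dim(bg$median_frame)))
    stop("frame shape does not match background shape")
  res <- frame - bg$median_frame
  res[res < 0] <- 0
  res
}

#' Periodically refresh a background estimate
#'
#' Recomputes the pixel-wise median iff at least `update_every` insertions
#' happened since the estimate was last computed; otherwise returns the
#' estimate unchanged with its staleness counter incremented.
#'
#' @param buffer A [miss_buffer()].
#' @param bg The current `background_estimate`.
#' @param update_every Refresh period in insertions (>= 1, default 10).
#' @return A `background_estimate`.
#' @export
maybe_refresh <- function(buffer, bg, update_every = 10L) {
  stopifnot(inherits(buffer, "miss_buffer"),
            inherits(bg, "background_estimate"))
  if (update_every < 1L) stop("update_every must be >= 1")
  if (buffer$insertions - bg$refreshed_at >= update_every) {
    compute_median_background(buffer)
  } else {
    bg$stale_counter <- bg$stale_counter + 1L
    bg
  }
}

#' Save / load a background estimate
#'
#' Single-frame container so interrupted runs can be resumed with the same
#' background.
#'
#' @param bg A `background_estimate`.
#' @param path File path.
#' @return `load_background` returns a `background_estimate`.
#' @export
save_background <- function(bg, path) {
  stopifnot(inherits(bg, "background_estimate"))
  saveRDS(list(background = bg$median_frame,
               n_source_frames = bg$n_source_frames), path)
  invisible(path)
}

#' @rdname save_background
#' @export
load_background <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$background)) stop("file does not contain a 'background' frame")
  structure(list(median_frame = obj$background,
                 n_source_frames = obj$n_source_frames %||% 1L,
                 stale_counter = 0L, refreshed_at = 0L),
            class = "background_estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
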