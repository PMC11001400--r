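#' Save / load a frame stack
#'
#' Frame stacks travel as a single-file RDS container holding the `N x H x W`
#' intensity array (axis order frame, row, col), optional per-frame labels
#' and optional ground-truth peak tables. Round-trips are lossless for
#' numeric and integer stacks.
#'
#' @param path File path.
#' @param frames `N x H x W` numeric array.
#' @param labels Optional character vector of per-frame labels.
#' @param truth Optional list of per-frame ground truths (as produced by
#'   [generate_dataset()]).
#' @return `load_frames` returns a list with `frames`, `labels`, `truth`.
#' @export
save_frames <- function(path, frames, labels = NULL, truth = NULL) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (!is.null(labels) && length(labels) != dim(frames)[1])
    stop("labels length does not match frame count")
  saveRDS(list(format = "mpfast_frames", version = 1L,
               axis_order = c("frame", "row", "col"),
               coordinates = "1-based",
               data = frames, labels = labels, truth = truth),
          path)
  invisible(path)
}

#' @rdname save_frames
#' @export
load_frames <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "mpfast_frames"))
    stop("file is not an mpfast frame container")
  if (is.null(obj$data))
    stop("frame container is missing the 'data' array")
  list(frames = obj$data, labels = obj$labels, truth = obj$truth)
}

peaks_csv_header <- paste(
  "# peak list: frame_index and 0-based (row, col) with row 0 at the top;",
  "intensity in counts")

#' Write / read per-frame peak lists as CSV
#'
#' Columns `frame_index,row,col,intensity`. On disk, coordinates follow the
#' 0-based (row, col) convention with row 0 at the top (stated in a header
#' comment); the R side converts to/from 1-based indices.
#'
#' @param path File path.
#' @param keypoints_list List of per-frame key-point data frames (1-based
#'   `row`, `col`, `intensity`), one entry per frame, in frame order.
#' @return `read_peaks_csv` returns a list with `peaks` (a list of
#'   per-frame tables, 1-based) and `n_frames`.
#' @export
write_peaks_csv <- function(path, keypoints_list) {
  rows <- lapply(seq_along(keypoints_list), function(i) {
    kp <- keypoints_list[[i]]
    if (is.null(kp) || nrow(kp) == 0L) return(NULL)
    data.frame(frame_index = i - 1L, row = kp$row - 1L, col = kp$col - 1L,
               intensity = kp$intensity)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(frame_index = integer(0), row = integer(0),
                     col = integer(0), intensity = numeric(0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(peaks_csv_header, con)
  writeLines(sprintf("# n_frames=%d", length(keypoints_list)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peaks_csv
#' @export
read_peaks_csv <- function(path) {
  header <- readLines(path, n = 5L)
  n_frames <- NA_integer_
  m <- regmatches(header, regexpr("n_frames=[0-9]+", header))
  if (length(m) > 0)
    n_frames <- as.integer(sub("n_frames=", "", m[1]))
  df <- utils::read.csv(path, comment.char = "#")
  if (is.na(n_frames))
    n_frames <- if (nrow(df) > 0L) max(df$frame_index) + 1L else 0L
  peaks <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    sel <- df[df$frame_index == i - 1L, , drop = FALSE]
    peaks[[i]] <- data.frame(row = sel$row + 1L, col = sel$col + 1L,
                             intensity = sel$intensity)
  }
  list(peaks = peaks, n_frames = n_frames)
}

#' Write / read feature matrices as CSV
#'
#' Columns `f0..f{n-1}` (region counts) plus a `label` column.
#'
#' @param path File path.
#' @param features N x n matrix of descriptors.
#' @param labels Per-frame labels (optional; `NA` written when absent).
#' @return `read_features_csv` returns a list with `features` (matrix) and
#'   `labels` (character, possibly all `NA`).
#' @export
write_features_csv <- function(path, features, labels = NULL) {
  features <- as.matrix(features)
  if (is.null(labels)) labels <- rep(NA_character_, nrow(features))
  df <- as.data.frame(features)
  names(df) <- paste0("f", seq_len(ncol(features)) - 1L)
  df$label <- as.character(labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = NA, stringsAsFactors = FALSE)
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  list(features = as.matrix(df[fcols]),
       labels = if ("label" %in% names(df)) as.character(df$label) else NULL)
}

#' Write verdicts as CSV
#'
#' @param path File path.
#' @param verdicts The verdict table from [run_stream()].
#' @return The path, invisibly.
#' @export
write_verdicts_csv <- function(path, verdicts) {
  utils::write.csv(verdicts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write classification metrics as JSON
#'
#' @param path File path.
#' @param metrics A `classification_metrics` object.
#' @return The path, invisibly.
#' @export
write_metrics_json <- function(path, metrics) {
  jsonlite::write_json(list(f1 = metrics$f1, precision = metrics$precision,
                            recall = metrics$recall,
                            accuracy = metrics$accuracy),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
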