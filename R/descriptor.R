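#' Region-grid descriptor parameters
#'
#' The image descriptor partitions the frame into a `grid_rows x grid_cols`
#' rectangular tiling (default 2 x 4, i.e. n = 8 regions) and represents a
#' frame by the count of detected key points falling in each region. Counts,
#' not positions, make the feature robust to the experimental shifts that
#' move peaks around without changing their overall arrangement, and the
#' fixed length keeps the feature dimensionality constant across data sets
#' (a miss frame maps to the all-zero vector).
#'
#' @param grid_rows,grid_cols Tiling dimensions (product >= 1).
#' @return An object of class `descriptor_params`.
#' @export
descriptor_params <- function(grid_rows = 2L, grid_cols = 4L) {
  grid_rows <- as.integer(grid_rows); grid_cols <- as.integer(grid_cols)
  if (grid_rows < 1L || grid_cols < 1L)
    stop("grid dimensions must be >= 1")
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols,
                 n_regions = grid_rows * grid_cols),
            class = "descriptor_params")
}

# tile index (1-based) of 1-based pixel positions along one axis of size
# extent split into g tiles with half-open integer boundaries
# [floor(t*extent/g), floor((t+1)*extent/g))
tile_of <- function(pos1, extent, g) {
  bounds <- (0:g * extent) %/% g
  findInterval(pos1 - 1L, bounds, rightmost.closed = TRUE)
}

#' Region id of a pixel
#'
#' Regions tile the frame row-major: region `(tr - 1) * grid_cols + tc` for
#' tile row `tr` and tile column `tc` (1-based). Tile boundaries are the
#' half-open integer splits `[floor(t*H/grid_rows), floor((t+1)*H/grid_rows))`
#' of the 0-based pixel range, and likewise for columns.
#'
#' @param row,col 1-based pixel coordinates (vectorized).
#' @param frame_shape `c(H, W)`.
#' @param params A [descriptor_params()] object.
#' @return Integer region ids in `1..n_regions`.
#' @export
region_index <- function(row, col, frame_shape, params = descriptor_params()) {
  h <- frame_shape[1]; w <- frame_shape[2]
  if (params$grid_rows > h || params$grid_cols > w)
    stop("grid dimensions exceed frame dimensions")
  if (any(row < 1L | row > h | col < 1L | col > w))
    stop("pixel coordinates out of bounds")
  tr <- tile_of(row, h, params$grid_rows)
  tc <- tile_of(col, w, params$grid_cols)
  (tr - 1L) * params$grid_cols + tc
}

#' Per-region key-point count descriptor of a frame
#'
#' @param keypoints Data frame with `row`, `col` columns (1-based), e.g. the
#'   output of [detect_keypoints()]; extra columns are ignored.
#' @param frame_shape `c(H, W)`.
#' @param params A [descriptor_params()] object.
#' @return Integer vector of length `n_regions`; element i counts the key
#'   points in region i, so the vector sums to `nrow(keypoints)`. A frame
#'   without key points maps to the zero vector.
#' @export
compute_descriptor <- function(keypoints, frame_shape,
                               params = descriptor_params()) {
  n <- params$n_regions
  if (is.null(keypoints) || nrow(keypoints) == 0L)
    return(integer(n))
  idx <- region_index(keypoints$row, keypoints$col, frame_shape, params)
  tabulate(idx, nbins = n)
}
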