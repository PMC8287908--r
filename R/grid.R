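#' Encode spot coordinates as a grid-cell tensor
#'
#' Divides the image into square grid-cells of `cell_size` pixels and builds
#' the (H/cs) x (W/cs) x 3 target tensor the network regresses: channel 1 is
#' the per-cell spot probability (1 where the cell contains a spot, else 0),
#' channels 2-3 are the spot's within-cell (row, col) offsets normalized to
#' `[0, 1)`. A cell can host only one spot; when several fall into the same
#' cell the one closest to the cell centre is kept (remaining ties broken by
#' row-major coordinate order), which is the known capacity limitation of
#' grid-based coordinate regression.
#'
#' @param coords n x 2 matrix of (row, col) spot coordinates in pixels,
#'   0-based, `0 <= row < H`, `0 <= col < W`.
#' @param image_shape integer vector `c(H, W)`; both must be divisible by
#'   `cell_size`.
#' @param cell_size grid-cell side length in pixels, a power of two.
#' @return a `grid_tensor`: numeric array (H/cs) x (W/cs) x 3 with attribute
#'   `cell_size`.
#' @examples
#' g <- encode_grid(rbind(c(2, 3)), c(8, 8), cell_size = 4)
#' g[1, 1, ]  # probability 1, offsets (0.5, 0.75)
#' @seealso [decode_grid()]
#' @export
encode_grid <- function(coords, image_shape, cell_size = 4) {
  cs <- cell_size
  if (!is_pow2(cs)) stop("'cell_size' must be a power of two >= 1")
  H <- image_shape[1]; W <- image_shape[2]
  if (H %% cs != 0 || W %% cs != 0)
    stop("image shape must be divisible by 'cell_size'")
  coords <- as_coord_matrix(coords)
  if (nrow(coords) > 0 &&
      (any(coords[, 1] < 0) || any(coords[, 1] >= H) ||
       any(coords[, 2] < 0) || any(coords[, 2] >= W)))
    stop("coordinates out of image bounds")
  g <- array(0, dim = c(H / cs, W / cs, 3))
  if (nrow(coords) > 0) {
    cell_r <- floor(coords[, 1] / cs)
    cell_c <- floor(coords[, 2] / cs)
    off_r <- (coords[, 1] - cell_r * cs) / cs
    off_c <- (coords[, 2] - cell_c * cs) / cs
    # collision tie-break: nearest to the cell centre, then row-major coords
    d2 <- (off_r - 0.5)^2 + (off_c - 0.5)^2
    ord <- order(d2, coords[, 1], coords[, 2])
    seen <- character(0)
    for (i in ord) {
      key <- paste(cell_r[i], cell_c[i])
      if (key %in% seen) next
      seen <- c(seen, key)
      g[cell_r[i] + 1, cell_c[i] + 1, ] <- c(1, off_r[i], off_c[i])
    }
  }
  structure(g, cell_size = cs, class = "grid_tensor")
}

#' Decode a grid-cell tensor into spot coordinates
#'
#' Inverse of [encode_grid()]: every cell whose probability channel is at
#' least `prob_threshold` emits one coordinate
#' `(cell_row * cs + offset_row * cs, cell_col * cs + offset_col * cs)`.
#' Cells are visited in row-major order.
#'
#' @param grid a `grid_tensor` (or plain Hg x Wg x 3 array).
#' @param prob_threshold detection threshold on the probability channel,
#'   in `[0, 1]`.
#' @param cell_size grid-cell size; defaults to the tensor's `cell_size`
#'   attribute.
#' @return n x 2 matrix of (row, col) coordinates.
#' @export
decode_grid <- function(grid, prob_threshold = 0.5, cell_size = NULL) {
  cs <- cell_size %||% attr(grid, "cell_size")
  if (is.null(cs)) stop("'cell_size' not given and not stored on 'grid'")
  stopifnot_scalar(prob_threshold, "prob_threshold", min = 0, max = 1)
  p <- grid[, , 1, drop = FALSE][, , 1]
  if (!is.matrix(p)) p <- matrix(p, dim(grid)[1], dim(grid)[2])
  hit <- which(t(p) >= prob_threshold)  # transpose => row-major cell order
  if (length(hit) == 0) return(as_coord_matrix(NULL))
  Wg <- dim(grid)[2]
  ci <- (hit - 1) %% Wg          # 0-based cell col
  ri <- (hit - 1) %/% Wg         # 0-based cell row
  off_r <- grid[, , 2][cbind(ri + 1, ci + 1)]
  off_c <- grid[, , 3][cbind(ri + 1, ci + 1)]
  as_coord_matrix(cbind(ri * cs + off_r * cs, ci * cs + off_c * cs))
}
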