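# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. A NULL seed evaluates in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Coordinates are (row, col) with the centre of matrix element [i, j] at
# (i - 1, j - 1): 0-based, origin at the top-left pixel centre.
as_coord_matrix <- function(coords) {
  if (is.null(coords) || length(coords) == 0)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("r", "c"))))
  m <- if (is.matrix(coords)) coords else matrix(coords, ncol = 2, byrow = TRUE)
  if (ncol(m) != 2) stop("coordinates must have two columns (row, col)")
  storage.mode(m) <- "double"
  colnames(m) <- c("r", "c")
  m
}

stopifnot_scalar <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (x < min || x > max)
    stop(sprintf("'%s' must be in [%s, %s]", name, format(min), format(max)))
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name))
  invisible(x)
}

is_pow2 <- function(x) {
  x >= 1 && x == round(x) && bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L
}

# Mirror-pad a matrix on the bottom/right so both dimensions become multiples
# of `d`. Reflection excludes the edge pixel (row H+k maps to row H-k), which
# avoids a doubled edge and keeps coordinates of the original frame unchanged.
reflect_pad <- function(img, d) {
  H <- nrow(img); W <- ncol(img)
  ph <- (d - H %% d) %% d
  pw <- (d - W %% d) %% d
  if (ph >= H || pw >= W)
    stop("image too small to pad to a multiple of ", d)
  ri <- c(seq_len(H), H - seq_len(ph))
  ci <- c(seq_len(W), W - seq_len(pw))
  img[ri, ci, drop = FALSE]
}

# Rotate a matrix 90 degrees clockwise; 0-based coords map (r, c) -> (c, H-1-r).
rot90_cw <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])

rot90_coords_cw <- function(coords, H) {
  cbind(r = coords[, 2], c = H - 1 - coords[, 1])
}

flipud <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]

flipud_coords <- function(coords, H) {
  cbind(r = H - 1 - coords[, 1], c = coords[, 2])
}
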