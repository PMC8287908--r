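#' Predict spot coordinates on new images
#'
#' Applies the trained model to one image (numeric matrix) or a list of
#' images: each image is standardized exactly as during training,
#' reflect-padded so its shape divides the network's shape unit, passed
#' through the network, and the predicted grid is decoded at
#' `prob_threshold`. Detections falling in the padded margins are discarded,
#' so returned coordinates always lie in the original image frame. With
#' `refine = TRUE` each detection is post-processed by a local 2D Gaussian
#' fit on the raw input ([refine_gaussian()]).
#'
#' @param object a `spotnet` model.
#' @param image numeric matrix, or list of matrices.
#' @param prob_threshold detection threshold on the probability channel.
#' @param refine logical; run Gaussian refinement on the detections.
#' @param ... unused.
#' @return n x 2 matrix of (row, col) coordinates (or a list of such
#'   matrices).
#' @export
predict.spotnet <- function(object, image, prob_threshold = 0.5,
                            refine = FALSE, ...) {
  one <- function(img) {
    if (!is.matrix(img) || !is.numeric(img))
      stop("'image' must be a 2D numeric matrix")
    H <- nrow(img); W <- ncol(img)
    net <- object$network
    padded <- reflect_pad(standardize_image(img), shape_unit(net$config))
    grid <- network_forward(net, padded)
    coords <- decode_grid(grid, prob_threshold)
    coords <- coords[coords[, 1] < H & coords[, 2] < W, , drop = FALSE]
    if (refine) coords <- refine_gaussian(img, coords)
    coords
  }
  if (is.list(image)) lapply(image, one) else one(image)
}

#' Refine spot coordinates by local Gaussian fitting
#'
#' For each coordinate, least-squares fits an isotropic 2D Gaussian
#' (amplitude, centre, sigma, constant offset) to the raw pixel intensities
#' in a `window`-sized square around the rounded coordinate, initialized at
#' the input coordinate. The fitted centre replaces the input. If the fit
#' fails to converge, or moves the centre by more than `window / 2`, the
#' original coordinate is kept, so refinement can never displace a detection
#' beyond its own window.
#'
#' @param image raw (unnormalized) image matrix.
#' @param coords n x 2 matrix of (row, col) detections.
#' @param window odd window side length in pixels, at least 3.
#' @return n x 2 matrix of refined coordinates.
#' @export
refine_gaussian <- function(image, coords, window = 7) {
  stopifnot_scalar(window, "window", min = 3, integer = TRUE)
  if (window %% 2 == 0) stop("'window' must be odd")
  coords <- as_coord_matrix(coords)
  if (nrow(coords) == 0) return(coords)
  H <- nrow(image); W <- ncol(image)
  hw <- (window - 1) / 2
  out <- coords
  for (i in seq_len(nrow(coords))) {
    r0 <- unname(coords[i, 1]); c0 <- unname(coords[i, 2])
    # window around the rounded centre, clipped at the image border
    ri <- max(0, round(r0) - hw):min(H - 1, round(r0) + hw)
    ci <- max(0, round(c0) - hw):min(W - 1, round(c0) + hw)
    patch <- image[ri + 1, ci + 1, drop = FALSE]
    if (max(patch) - min(patch) <= 0) next  # flat window: keep original
    df <- data.frame(z = as.vector(patch),
                     r = rep(ri, times = length(ci)),
                     c = rep(ci, each = length(ri)))
    start <- list(A = max(patch) - min(patch), mr = r0, mc = c0,
                  s = 1.5, b = min(patch))
    fit <- tryCatch(
      minpack.lm::nlsLM(z ~ b + A * exp(-((r - mr)^2 + (c - mc)^2) / (2 * s^2)),
                        data = df, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    est <- stats::coef(fit)
    if (!all(is.finite(est[c("mr", "mc")]))) next
    if (sqrt((est["mr"] - r0)^2 + (est["mc"] - c0)^2) > window / 2) next
    out[i, ] <- c(est["mr"], est["mc"])
  }
  out
}
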