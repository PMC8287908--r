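#' Parameters for a synthetic spot field
#'
#' Describes one simulated fluorescence image: a flat background carrying
#' `n_spots` diffraction-limited emitters rendered as isotropic 2D Gaussians
#' (the small-spot PSF approximation), optional Poisson shot noise, and
#' additive Gaussian read noise. The signal-to-noise ratio of the field is
#' the spot amplitude divided by `noise_sd`; the defaults give SNR 16-24,
#' a bright, well-resolved regime typical of good smFISH acquisitions.
#'
#' @param height,width image size in pixels.
#' @param n_spots number of spots to place.
#' @param psf_sigma Gaussian PSF standard deviation in pixels.
#' @param amplitude_range length-2 numeric `(lo, hi)`; each spot's peak
#'   amplitude above background is drawn uniformly from this range.
#' @param background constant background intensity.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param use_poisson if `TRUE`, pixel intensities are Poisson-resampled
#'   (shot noise) before the Gaussian noise is added.
#' @param min_separation minimum pairwise Euclidean distance between spot
#'   centres, in pixels.
#' @param seed integer seed making generation reproducible; `NULL` uses the
#'   ambient RNG stream.
#' @return an object of class `spot_field_params`.
#' @seealso [simulate_spot_field()], [simulate_spot_dataset()]
#' @export
spot_field_params <- function(height = 128, width = 128, n_spots = 10,
                              psf_sigma = 1.5, amplitude_range = c(80, 120),
                              background = 100, noise_sd = 5,
                              use_poisson = FALSE, min_separation = 8,
                              seed = NULL) {
  stopifnot_scalar(height, "height", min = 1, integer = TRUE)
  stopifnot_scalar(width, "width", min = 1, integer = TRUE)
  stopifnot_scalar(n_spots, "n_spots", min = 0, integer = TRUE)
  stopifnot_scalar(psf_sigma, "psf_sigma", min = 1e-6)
  stopifnot_scalar(noise_sd, "noise_sd", min = 0)
  stopifnot_scalar(min_separation, "min_separation", min = 0)
  if (length(amplitude_range) != 2 || amplitude_range[1] > amplitude_range[2])
    stop("'amplitude_range' must be (lo, hi) with lo <= hi")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_spots = as.integer(n_spots), psf_sigma = psf_sigma,
                 amplitude_range = as.numeric(amplitude_range),
                 background = background, noise_sd = noise_sd,
                 use_poisson = isTRUE(use_poisson),
                 min_separation = min_separation, seed = seed),
            class = "spot_field_params")
}

#' Sample spot centre coordinates
#'
#' Draws `n_spots` continuous (row, col) positions uniformly over the image,
#' rejection-sampling so that all pairwise distances are at least
#' `min_separation`. Fails when the requested packing is infeasible within
#' the attempt budget.
#'
#' @param params a [spot_field_params()] object.
#' @param max_attempts rejection-sampling budget.
#' @return n x 2 matrix of (row, col) coordinates, `0 <= row < height`.
#' @export
sample_coordinates <- function(params, max_attempts = max(10000L, 500L * params$n_spots)) {
  stopifnot(inherits(params, "spot_field_params"))
  with_seed(params$seed, sample_coordinates_impl(params, max_attempts))
}

sample_coordinates_impl <- function(params, max_attempts) {
  n <- params$n_spots
  if (n == 0) return(as_coord_matrix(NULL))
  acc <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(paste0("could not place %d spots with min_separation ",
                          "%.3g in a %dx%d field (packing too dense)"),
                   n, params$min_separation, params$height, params$width))
    # centres live on the pixel-centre grid [0, H-1] x [0, W-1], so that
    # geometric label transforms (flips, rotations) stay within bounds
    cand <- c(stats::runif(1, 0, params$height - 1),
              stats::runif(1, 0, params$width - 1))
    if (placed > 0L && params$min_separation > 0) {
      d2 <- (acc[seq_len(placed), 1] - cand[1])^2 +
            (acc[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < params$min_separation^2) next
    }
    placed <- placed + 1L
    acc[placed, ] <- cand
  }
  as_coord_matrix(acc)
}

#' Render a spot-field image from coordinates
#'
#' Evaluates `background + sum_i A_i exp(-((r - r_i)^2 + (c - c_i)^2) /
#' (2 sigma^2))` at integer pixel centres (the centre of matrix element
#' `[i, j]` is at coordinates `(i-1, j-1)`), then applies optional Poisson
#' resampling and additive Gaussian noise. Deterministic for a fixed
#' `params$seed`.
#'
#' @param coords n x 2 matrix of (row, col) spot centres within bounds.
#' @inheritParams sample_coordinates
#' @return an object of class `spot_field`: list with `pixels` (height x
#'   width matrix), `coords` and `params`.
#' @export
render_spot_field <- function(coords, params) {
  stopifnot(inherits(params, "spot_field_params"))
  with_seed(params$seed, render_spot_field_impl(coords, params))
}

render_spot_field_impl <- function(coords, params) {
  coords <- as_coord_matrix(coords)
  H <- params$height; W <- params$width
  if (nrow(coords) > 0 &&
      (any(coords[, 1] < 0) || any(coords[, 1] >= H) ||
       any(coords[, 2] < 0) || any(coords[, 2] >= W)))
    stop("spot coordinates out of image bounds")
  img <- matrix(params$background, H, W)
  s2 <- 2 * params$psf_sigma^2
  rr <- seq_len(H) - 1
  cc <- seq_len(W) - 1
  for (i in seq_len(nrow(coords))) {
    a <- stats::runif(1, params$amplitude_range[1], params$amplitude_range[2])
    # isotropic Gaussian is separable: outer product of the two axis profiles
    img <- img + a * (exp(-(rr - coords[i, 1])^2 / s2) %o%
                        exp(-(cc - coords[i, 2])^2 / s2))
  }
  if (params$use_poisson)
    img <- matrix(stats::rpois(length(img), pmax(img, 0)), H, W)
  if (params$noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, params$noise_sd), H, W)
  structure(list(pixels = img, coords = coords, params = params),
            class = "spot_field")
}

#' Simulate a complete spot field
#'
#' Convenience wrapper drawing coordinates and rendering the image under a
#' single seeded RNG stream.
#'
#' @inheritParams sample_coordinates
#' @return a `spot_field` (see [render_spot_field()]).
#' @examples
#' f <- simulate_spot_field(spot_field_params(n_spots = 5, seed = 1))
#' dim(f$pixels); f$coords
#' @export
simulate_spot_field <- function(params) {
  stopifnot(inherits(params, "spot_field_params"))
  with_seed(params$seed, {
    coords <- sample_coordinates_impl(params, max(10000L, 500L * params$n_spots))
    render_spot_field_impl(coords, params)
  })
}

#' @export
print.spot_field <- function(x, ...) {
  cat(sprintf("spot field %dx%d px, %d spots, sigma %.2g px, noise sd %.3g\n",
              nrow(x$pixels), ncol(x$pixels), nrow(x$coords),
              x$params$psf_sigma, x$params$noise_sd))
  invisible(x)
}

#' Simulate a partitioned spot dataset
#'
#' Generates one image per element of `params_list` and assembles them into a
#' partitioned dataset archive with shuffled train/valid/test splits (floor
#' rounding for valid and test, remainder to train). All images must share
#' one shape. Reproducible: the same `seed` yields a byte-identical archive.
#'
#' @param params_list list of [spot_field_params()]; per-element seeds are
#'   ignored in favour of the dataset-level stream.
#' @param split_fractions length-3 positive fractions (train, valid, test)
#'   summing to 1.
#' @param seed integer seed for simulation and split shuffling.
#' @return a `spot_archive` (see [create_dataset()]).
#' @export
simulate_spot_dataset <- function(params_list, split_fractions = c(0.7, 0.15, 0.15),
                                  seed = 1) {
  stopifnot(length(params_list) > 0,
            all(vapply(params_list, inherits, TRUE, "spot_field_params")))
  with_seed(seed, {
    fields <- lapply(params_list, function(p) {
      p$seed <- NULL
      simulate_spot_field(p)
    })
    images <- lapply(fields, `[[`, "pixels")
    labels <- lapply(fields, `[[`, "coords")
    build_archive(images, labels, split_fractions, seed,
                  source = "simulate_spot_dataset")
  })
}

#' Write a spot field as a 16-bit TIFF plus coordinate CSV
#'
#' Persists `field$pixels` (clamped to `[0, 65535]` and rounded) as a
#' single-plane 16-bit grayscale TIFF and the ground-truth coordinates as a
#' plain `r,c` CSV next to it, for round-trip testing of the dataset reader.
#'
#' @param field a `spot_field`.
#' @param image_path output TIFF path; the CSV takes the same stem.
#' @param label_path optional explicit CSV path.
#' @return invisibly, paths of the two files written.
#' @export
write_spot_field <- function(field, image_path, label_path = NULL) {
  stopifnot(inherits(field, "spot_field"))
  label_path <- label_path %||%
    paste0(tools::file_path_sans_ext(image_path), ".csv")
  img <- round(pmin(pmax(field$pixels, 0), 65535))
  tiff::writeTIFF(img / 65535, image_path, bits.per.sample = 16L)
  lines <- c("r,c", sprintf("%.17g,%.17g", field$coords[, 1], field$coords[, 2]))
  writeLines(lines, label_path)
  invisible(c(image = image_path, label = label_path))
}
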