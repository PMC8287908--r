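#' Laplacian-of-Gaussian spot detection
#'
#' Classical blob detection used as a trainable-free baseline: the image is
#' convolved with a scale-normalized LoG kernel at `sigma = diameter /
#' (2 sqrt(2))` (the conventional blob-radius relation `r = sigma sqrt(2)`),
#' the sign is flipped so bright blobs give positive responses, and strict
#' 8-neighbour local maxima with positive response are returned. Sub-pixel
#' positions come from per-axis quadratic interpolation of the response
#' peak; the peak response serves as the detection's quality score.
#'
#' @param image numeric matrix.
#' @param diameter estimated blob diameter in pixels.
#' @return list with `coords` (n x 2 matrix of (row, col)) and `quality`
#'   (numeric vector of peak responses), ordered by decreasing quality.
#' @export
log_detect <- function(image, diameter) {
  stopifnot_scalar(diameter, "diameter", min = 1e-6)
  sigma <- diameter / (2 * sqrt(2))
  hw <- max(2L, as.integer(ceiling(4 * sigma)))
  ax <- -hw:hw
  r2 <- outer(ax^2, ax^2, `+`)
  g <- exp(-r2 / (2 * sigma^2))
  log_k <- (r2 - 2 * sigma^2) / sigma^4 * g / (2 * pi * sigma^2)
  k <- -sigma^2 * log_k          # scale-normalized, positive on bright blobs
  k <- k - mean(k)               # zero DC response: flat images give 0
  resp <- EBImage::filter2(image, k, boundary = "replicate")
  H <- nrow(resp); W <- ncol(resp)
  if (H < 3 || W < 3) return(list(coords = as_coord_matrix(NULL),
                                  quality = numeric(0)))
  ctr <- resp[2:(H - 1), 2:(W - 1)]
  is_max <- ctr > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (ctr > resp[2:(H - 1) + dr, 2:(W - 1) + dc])
  }
  # the FFT convolution leaves ~1e-14 ripples on flat regions; a floor tied
  # to the response and image magnitudes keeps only maxima that are positive
  # beyond numerical noise
  floor_q <- max(resp) * 1e-6 + 1e-9 * max(abs(image))
  is_max <- is_max & (ctr > floor_q)
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list(coords = as_coord_matrix(NULL),
                                  quality = numeric(0)))
  rr <- idx[, 1] + 1L            # 1-based indices in the full response
  cc <- idx[, 2] + 1L
  # quadratic sub-pixel interpolation per axis, clipped to half a pixel
  interp <- function(fm, f0, fp) {
    den <- fm - 2 * f0 + fp
    d <- ifelse(abs(den) > 1e-12, 0.5 * (fm - fp) / den, 0)
    pmin(pmax(d, -0.5), 0.5)
  }
  dr <- interp(resp[cbind(rr - 1L, cc)], resp[cbind(rr, cc)],
               resp[cbind(rr + 1L, cc)])
  dc <- interp(resp[cbind(rr, cc - 1L)], resp[cbind(rr, cc)],
               resp[cbind(rr, cc + 1L)])
  q <- resp[cbind(rr, cc)]
  ord <- order(q, decreasing = TRUE)
  list(coords = as_coord_matrix(cbind(rr - 1 + dr, cc - 1 + dc))[ord, ,
                                                                 drop = FALSE],
       quality = q[ord])
}

#' Select the LoG blob diameter and quality threshold
#'
#' Automates the baseline's manual thresholding: for every candidate
#' diameter, all images are detected, each image's quality scores are
#' normalized to that image's median quality, and 20 linearly spaced
#' quantile levels (0 to 0.95) of the pooled normalized qualities are tried
#' as cutoffs. At each (diameter, quantile value) the mean F1 integral score
#' against the ground truth is computed; the maximizing pair is returned
#' (ties resolved toward the lower quantile, which keeps more detections).
#' The top quantile level stops at 0.95 because a cutoff at the maximum
#' quality would discard every detection.
#'
#' @param images list of numeric matrices.
#' @param truths list of ground-truth coordinate tables (at least one spot in
#'   total).
#' @param diameters numeric vector of candidate blob diameters in pixels.
#' @return list with `diameter`, `threshold` (absolute normalized-quality
#'   cutoff), `mean_f1_integral`, and `grid` (data frame of all evaluated
#'   combinations).
#' @export
select_log_threshold <- function(images, truths, diameters) {
  stopifnot(length(images) == length(truths), length(images) > 0,
            length(diameters) > 0)
  truths <- lapply(truths, as_coord_matrix)
  if (sum(vapply(truths, nrow, 1L)) == 0)
    stop("at least one image must contain a ground-truth spot")
  grid <- data.frame()
  best <- list(f1 = -Inf)
  for (dia in diameters) {
    dets <- lapply(images, log_detect, diameter = dia)
    qnorm_list <- lapply(dets, function(d) {
      if (length(d$quality) == 0) numeric(0)
      else d$quality / stats::median(d$quality)
    })
    pooled <- unlist(qnorm_list)
    if (length(pooled) == 0) next
    levels <- seq(0, 0.95, length.out = 20)
    thresholds <- stats::quantile(pooled, levels, names = FALSE)
    for (th in thresholds) {
      f1s <- vapply(seq_along(images), function(i) {
        keep <- qnorm_list[[i]] >= th
        f1_integral(dets[[i]]$coords[keep, , drop = FALSE], truths[[i]])
      }, numeric(1))
      mf1 <- mean(f1s)
      grid <- rbind(grid, data.frame(diameter = dia, threshold = th,
                                     mean_f1_integral = mf1))
      if (mf1 > best$f1)
        best <- list(f1 = mf1, diameter = dia, threshold = th)
    }
  }
  if (!is.finite(best$f1))
    stop("no detections on any image for any candidate diameter")
  list(diameter = best$diameter, threshold = best$threshold,
       mean_f1_integral = best$f1, grid = grid)
}
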