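#' Network architecture configuration
#'
#' Describes the fully convolutional detector: a U-Net whose every encoding
#' step is `convs_per_block` 3x3 convolutions, a squeeze-and-excitation
#' (channel attention) block and spatial dropout before 2x downsampling;
#' decoding steps share the layout without dropout; a skip connection spans
#' the bottleneck; and a second encoder of `log2(cell_size)` downsampling
#' steps reduces the full-resolution representation to the grid resolution,
#' where a 1x1 convolution emits the (probability, row-offset, col-offset)
#' triple per grid-cell, all squashed to (0, 1) by a logistic activation.
#' The filter count is constant (default 64) across all layers. The
#' squeeze-and-excitation blocks, spatial dropout and the bottleneck skip can
#' be toggled individually for ablation studies.
#'
#' @param cell_size grid-cell side in pixels; a power of two.
#' @param filters constant number of convolution filters per layer.
#' @param unet_depth number of U-Net downsampling steps.
#' @param convs_per_block 3x3 convolutions per encode/decode block.
#' @param se_reduction channel reduction ratio of the squeeze-and-excitation
#'   bottleneck.
#' @param dropout_rate spatial dropout rate in `[0, 1)`.
#' @param use_se,use_dropout,use_bottom_skip ablation toggles.
#' @return object of class `network_config`.
#' @export
network_config <- function(cell_size = 4, filters = 64, unet_depth = 3,
                           convs_per_block = 3, se_reduction = 16,
                           dropout_rate = 0.3, use_se = TRUE,
                           use_dropout = TRUE, use_bottom_skip = TRUE) {
  if (!is_pow2(cell_size))
    stop("'cell_size' must be a power of two (1, 2, 4, 8, ...)")
  stopifnot_scalar(filters, "filters", min = 1, integer = TRUE)
  stopifnot_scalar(unet_depth, "unet_depth", min = 1, integer = TRUE)
  stopifnot_scalar(convs_per_block, "convs_per_block", min = 1, integer = TRUE)
  stopifnot_scalar(se_reduction, "se_reduction", min = 1)
  stopifnot_scalar(dropout_rate, "dropout_rate", min = 0, max = 1 - 1e-9)
  structure(list(cell_size = as.integer(cell_size),
                 filters = as.integer(filters),
                 unet_depth = as.integer(unet_depth),
                 convs_per_block = as.integer(convs_per_block),
                 se_reduction = se_reduction, dropout_rate = dropout_rate,
                 use_se = isTRUE(use_se), use_dropout = isTRUE(use_dropout),
                 use_bottom_skip = isTRUE(use_bottom_skip)),
            class = "network_config")
}

# Input shapes must be divisible by this unit.
shape_unit <- function(config) 2L^config$unet_depth * config$cell_size

he_mat <- function(nin, nout, fan) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / fan)), nin, nout)

se_hidden <- function(C, reduction) max(1L, as.integer(round(C / reduction)))

#' Build (initialize) a detector network
#'
#' Allocates He-initialized parameters for the architecture described by a
#' [network_config()]. The result is an untrained network; apply it to
#' images with [network_forward()] or train it via [fit_spotnet()].
#'
#' @param config a [network_config()].
#' @param in_channels number of input image channels (grayscale: 1).
#' @param seed integer seed for the parameter initialization.
#' @return object of class `spotnet_network`: list with `params` (flat named
#'   list of weight matrices), `config`, `in_channels`.
#' @export
build_network <- function(config = network_config(), in_channels = 1, seed = NULL) {
  stopifnot(inherits(config, "network_config"))
  with_seed(seed, {
    F <- config$filters
    K <- config$convs_per_block
    params <- list()
    add_block <- function(params, prefix, c_in) {
      cin <- c_in
      for (k in seq_len(K)) {
        params[[sprintf("%s.conv%d.W", prefix, k)]] <- he_mat(9 * cin, F, 9 * cin)
        params[[sprintf("%s.conv%d.b", prefix, k)]] <- numeric(F)
        cin <- F
      }
      if (config$use_se) {
        h <- se_hidden(F, config$se_reduction)
        params[[sprintf("%s.se.W1", prefix)]] <- he_mat(F, h, F)
        params[[sprintf("%s.se.b1", prefix)]] <- numeric(h)
        params[[sprintf("%s.se.W2", prefix)]] <- he_mat(h, F, h)
        params[[sprintf("%s.se.b2", prefix)]] <- numeric(F)
      }
      params
    }
    cin <- in_channels
    for (i in seq_len(config$unet_depth)) {
      params <- add_block(params, sprintf("enc%d", i), cin)
      cin <- F
    }
    params <- add_block(params, "bott", F)
    for (i in seq_len(config$unet_depth))
      params <- add_block(params, sprintf("dec%d", i), 2L * F)
    n2 <- as.integer(log2(config$cell_size))
    if (n2 > 0)
      for (s in seq_len(n2))
        params <- add_block(params, sprintf("enc2_%d", s), F)
    params[["head.W"]] <- matrix(stats::rnorm(F * 3L, 0, sqrt(1 / F)), F, 3L)
    # prior-probability initialization: spot-containing cells are rare, so
    # the probability channel starts near a low detection prior instead of
    # 0.5, which keeps the early dice gradients focused on true spots
    params[["head.b"]] <- c(log(0.02 / 0.98), 0, 0)
    structure(list(params = params, config = config,
                   in_channels = as.integer(in_channels)),
              class = "spotnet_network")
  })
}

#' @export
print.spotnet_network <- function(x, ...) {
  cfg <- x$config
  npar <- sum(vapply(x$params, length, 1L))
  cat(sprintf(paste0("grid-cell spot detection network: depth %d U-Net + ",
                     "%d-step second encoder, %d filters, cell size %d ",
                     "(%s parameters)\n"),
              cfg$unet_depth, as.integer(log2(cfg$cell_size)), cfg$filters,
              cfg$cell_size, format(npar, big.mark = ",")))
  invisible(x)
}

## ---- forward / backward -------------------------------------------------

se_fwd <- function(x, W1, b1, W2, b2) {
  s <- colMeans(x)
  zpre <- drop(s %*% W1) + b1
  z <- pmax(zpre, 0)
  gpre <- drop(z %*% W2) + b2
  g <- sigmoid(gpre)
  list(out = colscale(x, g), x = x, s = s, z = z, zmask = zpre > 0, g = g)
}

se_bwd <- function(dout, cache, W1, W2) {
  dx <- colscale(dout, cache$g)
  dg <- colSums(dout * cache$x)
  dgpre <- dg * cache$g * (1 - cache$g)
  gW2 <- cache$z %o% dgpre
  gb2 <- dgpre
  dz <- drop(W2 %*% dgpre) * cache$zmask
  gW1 <- cache$s %o% dz
  gb1 <- dz
  ds <- drop(W1 %*% dz)
  dx <- dx + matrix(ds / nrow(cache$x), nrow(cache$x), length(ds), byrow = TRUE)
  list(dx = dx, gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2)
}

block_fwd <- function(x, H, W, params, prefix, cfg) {
  cache <- list(convs = vector("list", cfg$convs_per_block))
  for (k in seq_len(cfg$convs_per_block)) {
    out <- conv3_fwd(x, params[[sprintf("%s.conv%d.W", prefix, k)]],
                     params[[sprintf("%s.conv%d.b", prefix, k)]], H, W, TRUE)
    cache$convs[[k]] <- list(x = x, out = out)
    x <- out
  }
  if (cfg$use_se) {
    sf <- se_fwd(x, params[[paste0(prefix, ".se.W1")]],
                 params[[paste0(prefix, ".se.b1")]],
                 params[[paste0(prefix, ".se.W2")]],
                 params[[paste0(prefix, ".se.b2")]])
    x <- sf$out
    cache$se <- sf[c("x", "s", "z", "zmask", "g")]
  }
  list(out = x, cache = cache)
}

block_bwd <- function(dout, cache, H, W, params, prefix, cfg, grads) {
  if (cfg$use_se) {
    sb <- se_bwd(dout, cache$se, params[[paste0(prefix, ".se.W1")]],
                 params[[paste0(prefix, ".se.W2")]])
    dout <- sb$dx
    grads[[paste0(prefix, ".se.W1")]] <- grads[[paste0(prefix, ".se.W1")]] + sb$gW1
    grads[[paste0(prefix, ".se.b1")]] <- grads[[paste0(prefix, ".se.b1")]] + sb$gb1
    grads[[paste0(prefix, ".se.W2")]] <- grads[[paste0(prefix, ".se.W2")]] + sb$gW2
    grads[[paste0(prefix, ".se.b2")]] <- grads[[paste0(prefix, ".se.b2")]] + sb$gb2
  }
  for (k in rev(seq_len(cfg$convs_per_block))) {
    nw <- sprintf("%s.conv%d.W", prefix, k)
    nb <- sprintf("%s.conv%d.b", prefix, k)
    cc <- cache$convs[[k]]
    cb <- conv3_bwd(cc$x, params[[nw]], cc$out, dout, H, W, TRUE)
    grads[[nw]] <- grads[[nw]] + cb$gW
    grads[[nb]] <- grads[[nb]] + cb$gb
    dout <- cb$dx
  }
  list(dx = dout, grads = grads)
}

# Forward pass on one image given as an (H*W) x C matrix (column-major pixel
# order). With train = TRUE, spatial dropout masks are drawn from the ambient
# RNG stream and recorded in the cache.
net_fwd <- function(net, x, H, W, train = FALSE) {
  cfg <- net$config
  params <- net$params
  unit <- shape_unit(cfg)
  if (H %% unit != 0 || W %% unit != 0)
    stop(sprintf("input shape %dx%d not divisible by %d (2^depth * cell_size)",
                 H, W, unit))
  Fn <- cfg$filters
  do_drop <- train && cfg$use_dropout && cfg$dropout_rate > 0
  drop_mask <- function() {
    if (!do_drop) return(NULL)
    stats::rbinom(Fn, 1, 1 - cfg$dropout_rate) / (1 - cfg$dropout_rate)
  }
  cache <- list(enc = list(), pool = list(), drop = list(),
                enc2 = list(), pool2 = list(), drop2 = list(), dims = list())
  skips <- list()
  h <- H; w <- W
  for (i in seq_len(cfg$unet_depth)) {
    bf <- block_fwd(x, h, w, params, sprintf("enc%d", i), cfg)
    x <- bf$out
    m <- drop_mask()
    if (!is.null(m)) x <- colscale(x, m)
    cache$enc[[i]] <- bf$cache
    cache$drop[i] <- list(m)
    cache$dims$enc[[i]] <- c(h, w)
    skips[[i]] <- x
    mp <- maxpool2(x, h, w)
    x <- mp$out
    cache$pool[[i]] <- mp$idx
    h <- h %/% 2L; w <- w %/% 2L
  }
  bin <- x
  bf <- block_fwd(x, h, w, params, "bott", cfg)
  x <- bf$out
  if (cfg$use_bottom_skip) x <- x + bin
  cache$bott <- bf$cache
  cache$dims$bott <- c(h, w)
  for (i in rev(seq_len(cfg$unet_depth))) {
    x <- upsample2(x, h, w)
    h <- 2L * h; w <- 2L * w
    x <- cbind(x, skips[[i]])
    bf <- block_fwd(x, h, w, params, sprintf("dec%d", i), cfg)
    x <- bf$out
    cache$dec[[i]] <- bf$cache
  }
  n2 <- as.integer(log2(cfg$cell_size))
  for (s in seq_len(n2)) {
    bf <- block_fwd(x, h, w, params, sprintf("enc2_%d", s), cfg)
    x <- bf$out
    m <- drop_mask()
    if (!is.null(m)) x <- colscale(x, m)
    cache$enc2[[s]] <- bf$cache
    cache$drop2[s] <- list(m)
    cache$dims$enc2[[s]] <- c(h, w)
    mp <- maxpool2(x, h, w)
    x <- mp$out
    cache$pool2[[s]] <- mp$idx
    h <- h %/% 2L; w <- w %/% 2L
  }
  pre <- x %*% params[["head.W"]]
  pre <- pre + rep(params[["head.b"]], each = nrow(pre))
  out <- sigmoid(pre)
  cache$head <- list(x = x, out = out)
  list(out = out, hg = h, wg = w, cache = cache)
}

# Backward pass: dout is dJ/d(sigmoid output), same shape as fwd$out.
# Returns gradients accumulated into `grads` (flat named list, zero-init).
net_bwd <- function(net, fwd, dout, grads) {
  cfg <- net$config
  params <- net$params
  cache <- fwd$cache
  out <- cache$head$out
  dpre <- dout * out * (1 - out)
  grads[["head.W"]] <- grads[["head.W"]] + crossprod(cache$head$x, dpre)
  grads[["head.b"]] <- grads[["head.b"]] + colSums(dpre)
  dx <- dpre %*% t(params[["head.W"]])
  n2 <- as.integer(log2(cfg$cell_size))
  for (s in rev(seq_len(n2))) {
    d <- cache$dims$enc2[[s]]
    dx <- maxpool2_bwd(dx, cache$pool2[[s]], d[1], d[2])
    m <- cache$drop2[[s]]
    if (!is.null(m)) dx <- colscale(dx, m)
    bb <- block_bwd(dx, cache$enc2[[s]], d[1], d[2], params,
                    sprintf("enc2_%d", s), cfg, grads)
    dx <- bb$dx
    grads <- bb$grads
  }
  Fn <- cfg$filters
  dskips <- vector("list", cfg$unet_depth)
  for (i in seq_len(cfg$unet_depth)) {
    d <- cache$dims$enc[[i]]
    bb <- block_bwd(dx, cache$dec[[i]], d[1], d[2], params,
                    sprintf("dec%d", i), cfg, grads)
    grads <- bb$grads
    dskips[[i]] <- bb$dx[, Fn + seq_len(Fn), drop = FALSE]
    dup <- bb$dx[, seq_len(Fn), drop = FALSE]
    dx <- upsample2_bwd(dup, d[1] %/% 2L, d[2] %/% 2L)
  }
  d <- cache$dims$bott
  dbin <- if (cfg$use_bottom_skip) dx else 0
  bb <- block_bwd(dx, cache$bott, d[1], d[2], params, "bott", cfg, grads)
  grads <- bb$grads
  dx <- bb$dx + dbin
  for (i in rev(seq_len(cfg$unet_depth))) {
    d <- cache$dims$enc[[i]]
    dx <- maxpool2_bwd(dx, cache$pool[[i]], d[1], d[2])
    dx <- dx + dskips[[i]]
    m <- cache$drop[[i]]
    if (!is.null(m)) dx <- colscale(dx, m)
    bb <- block_bwd(dx, cache$enc[[i]], d[1], d[2], params,
                    sprintf("enc%d", i), cfg, grads)
    dx <- bb$dx
    grads <- bb$grads
  }
  grads
}

#' Run the network on images
#'
#' Applies a (trained or freshly initialized) network to one image or a list
#' of images and returns the predicted grid tensor(s). Images must already
#' have shapes divisible by `2^unet_depth * cell_size`; [predict.spotnet()]
#' handles padding and normalization for end users.
#'
#' @param net a `spotnet_network`.
#' @param images numeric matrix or list of matrices.
#' @return a `grid_tensor` (Hg x Wg x 3), or a list of them.
#' @export
network_forward <- function(net, images) {
  stopifnot(inherits(net, "spotnet_network"))
  one <- function(img) {
    H <- nrow(img); W <- ncol(img)
    fw <- net_fwd(net, matrix(as.vector(img), ncol = 1), H, W, train = FALSE)
    g <- array(0, dim = c(fw$hg, fw$wg, 3))
    for (ch in 1:3) g[, , ch] <- matrix(fw$out[, ch], fw$hg, fw$wg)
    structure(g, cell_size = net$config$cell_size, class = "grid_tensor")
  }
  if (is.matrix(images)) one(images) else lapply(images, one)
}

## ---- losses -------------------------------------------------------------

#' Dice loss for spot-probability grids
#'
#' Soft Sørensen-Dice loss `1 - (2 sum(p*y) + eps) / (sum(p) + sum(y) + eps)`
#' over the whole grid (batch-pooled), robust to the extreme class imbalance
#' of spot detection where almost all grid-cells are background. The
#' smoothing term `eps` defines the empty-vs-empty case as loss 0.
#'
#' @param pred_p,true_p equal-shaped probability arrays in `[0, 1]`.
#' @param eps smoothing constant.
#' @return loss in `[0, 1]`.
#' @export
dice_loss <- function(pred_p, true_p, eps = 1e-7) {
  if (!identical(dim(pred_p) %||% length(pred_p),
                 dim(true_p) %||% length(true_p)))
    stop("'pred_p' and 'true_p' must have identical shape")
  1 - (2 * sum(pred_p * true_p) + eps) / (sum(pred_p) + sum(true_p) + eps)
}

#' Localization loss over spot-containing grid-cells
#'
#' RMSE of the within-cell offset channels restricted to cells that truly
#' contain a spot: `sqrt(sum_i |do_i|^2 / n)` where `do_i` is the 2-vector
#' offset error of spot `i` (both channels pooled into one squared Euclidean
#' deviation) and `n` the number of spot cells. Returns 0 when there are no
#' spot cells.
#'
#' @param pred_offsets,true_offsets offset arrays of shape `Hg x Wg x 2` (or
#'   `n x 2` matrices) in within-cell units.
#' @param spot_mask logical array (`Hg x Wg`, or length-n vector) marking
#'   ground-truth spot cells.
#' @return non-negative loss in offset units.
#' @export
localization_loss <- function(pred_offsets, true_offsets, spot_mask) {
  po <- matrix(pred_offsets, ncol = 2)
  to <- matrix(true_offsets, ncol = 2)
  if (!identical(dim(po), dim(to))) stop("offset shapes differ")
  m <- as.logical(spot_mask)
  if (length(m) != nrow(po)) stop("mask length does not match offsets")
  n <- sum(m)
  if (n == 0) return(0)
  sqerr <- sum((po[m, , drop = FALSE] - to[m, , drop = FALSE])^2)
  sqrt(sqerr / n)
}

#' Combined training objective
#'
#' `J = J_class + 2 * J_loc`: the dice classification loss on the
#' probability channel plus a doubly weighted localization RMSE over the
#' offset channels of ground-truth spot cells. The double weight reflects
#' that regressing sub-pixel coordinates is harder than classifying
#' spot-containing cells.
#'
#' @param pred_grid,true_grid `grid_tensor`s (Hg x Wg x 3) of equal shape;
#'   `true_grid` has a binary probability channel.
#' @return object of class `loss_breakdown`: list with `j`, `j_class`,
#'   `j_loc`, `n_spot_cells`.
#' @export
combined_loss <- function(pred_grid, true_grid) {
  if (!identical(dim(pred_grid), dim(true_grid)))
    stop("grid shapes differ")
  j_class <- dice_loss(pred_grid[, , 1], true_grid[, , 1])
  mask <- true_grid[, , 1] == 1
  j_loc <- localization_loss(pred_grid[, , 2:3], true_grid[, , 2:3], mask)
  structure(list(j = j_class + 2 * j_loc, j_class = j_class, j_loc = j_loc,
                 n_spot_cells = sum(mask)),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("J = %.6f (J_class %.6f + 2 x J_loc %.6f; %d spot cells)\n",
              x$j, x$j_class, x$j_loc, x$n_spot_cells))
  invisible(x)
}

# Batch-pooled loss and gradient on flat (n x 3) prediction/target matrices.
# Dice is computed over the concatenated batch; J_loc pools all spot cells of
# the batch. Returns per-image gradient matrices w.r.t. the sigmoid outputs.
batch_loss_grad <- function(preds, truths, eps = 1e-7) {
  sxy <- sx <- sy <- 0
  for (b in seq_along(preds)) {
    sxy <- sxy + sum(preds[[b]][, 1] * truths[[b]][, 1])
    sx <- sx + sum(preds[[b]][, 1])
    sy <- sy + sum(truths[[b]][, 1])
  }
  num <- 2 * sxy + eps
  den <- sx + sy + eps
  j_class <- 1 - num / den
  n <- 0
  sqerr <- 0
  for (b in seq_along(preds)) {
    m <- truths[[b]][, 1] == 1
    n <- n + sum(m)
    if (any(m))
      sqerr <- sqerr + sum((preds[[b]][m, 2:3, drop = FALSE] -
                            truths[[b]][m, 2:3, drop = FALSE])^2)
  }
  j_loc <- if (n > 0) sqrt(sqerr / n) else 0
  grads <- vector("list", length(preds))
  for (b in seq_along(preds)) {
    g <- matrix(0, nrow(preds[[b]]), 3)
    y1 <- truths[[b]][, 1]
    g[, 1] <- -(2 * y1 * den - num) / den^2
    m <- truths[[b]][, 1] == 1
    if (any(m) && j_loc > 0) {
      delta <- preds[[b]][m, 2:3, drop = FALSE] - truths[[b]][m, 2:3, drop = FALSE]
      g[m, 2:3] <- 2 * delta / (n * j_loc)
    }
    grads[[b]] <- g
  }
  list(j = j_class + 2 * j_loc, j_class = j_class, j_loc = j_loc, n = n,
       grads = grads)
}
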