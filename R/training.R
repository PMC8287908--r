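#' Training configuration
#'
#' Bundles the network architecture with the optimization settings. The
#' defaults are the tool's canonical configuration: cell size 4, dropout
#' 0.3, batch size 2, learning rate 1e-4, the AMSGrad adaptive optimizer and
#' 200 epochs.
#'
#' @param network a [network_config()].
#' @param learning_rate positive step size.
#' @param batch_size minibatch size.
#' @param epochs number of training epochs.
#' @param optimizer currently `"amsgrad"` (Adam variant keeping the running
#'   maximum of the second-moment estimate).
#' @param augment apply random flips and 90-degree rotations to image and
#'   coordinates during training.
#' @param seed integer seed for initialization, shuffling, dropout and
#'   augmentation.
#' @param checkpoint_policy `"best_valid_loss"`: the returned model carries
#'   the parameters of the epoch with the lowest validation loss.
#' @return object of class `train_config`.
#' @export
train_config <- function(network = network_config(), learning_rate = 1e-4,
                         batch_size = 2, epochs = 200, optimizer = "amsgrad",
                         augment = TRUE, seed = 42,
                         checkpoint_policy = "best_valid_loss") {
  stopifnot(inherits(network, "network_config"))
  stopifnot_scalar(learning_rate, "learning_rate", min = 1e-12)
  stopifnot_scalar(batch_size, "batch_size", min = 1, integer = TRUE)
  stopifnot_scalar(epochs, "epochs", min = 1, integer = TRUE)
  optimizer <- match.arg(optimizer, "amsgrad")
  checkpoint_policy <- match.arg(checkpoint_policy, "best_valid_loss")
  structure(list(network = network, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = optimizer,
                 augment = isTRUE(augment), seed = seed,
                 checkpoint_policy = checkpoint_policy),
            class = "train_config")
}

#' Default training configuration
#'
#' Returns the canonical defaults (see [train_config()]).
#' @return a `train_config`.
#' @examples
#' default_config()$learning_rate       # 1e-4
#' default_config()$network$cell_size   # 4
#' @export
default_config <- function() train_config()

#' Write / read a training configuration file
#'
#' The configuration is stored as a plain-text YAML document whose keys
#' mirror the [train_config()] and [network_config()] field names exactly.
#'
#' @param config a `train_config`.
#' @param path file path.
#' @return `read_train_config` returns a `train_config`; `write_train_config`
#'   returns `path` invisibly.
#' @export
write_train_config <- function(config, path) {
  stopifnot(inherits(config, "train_config"))
  lst <- unclass(config)
  lst$network <- unclass(lst$network)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_train_config
#' @export
read_train_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lst <- yaml::read_yaml(path)
  net <- do.call(network_config, lst$network %||% list())
  lst$network <- NULL
  do.call(train_config, c(list(network = net), lst))
}

# Random flip + 90-degree rotation of an image and its coordinates.
augment_sample <- function(img, coords, flip, k) {
  if (flip) {
    coords <- flipud_coords(coords, nrow(img))
    img <- flipud(img)
  }
  for (j in seq_len(k)) {
    coords <- rot90_coords_cw(coords, nrow(img))
    img <- rot90_cw(img)
  }
  # labels between the last pixel centre and the image edge would leave the
  # frame under the pixel-centre flip r -> H-1-r; clamp them back in
  if (nrow(coords) > 0) {
    coords[, 1] <- pmin(pmax(coords[, 1], 0), nrow(img) - 1)
    coords[, 2] <- pmin(pmax(coords[, 2], 0), ncol(img) - 1)
  }
  list(img = img, coords = coords)
}

standardize_image <- function(img) {
  (img - mean(img)) / (stats::sd(img) + 1e-8)
}

# Prepare one sample for the network: standardize, reflect-pad to the shape
# unit, encode the grid target on the padded shape.
prep_sample <- function(img, coords, cfg_net) {
  unit <- shape_unit(cfg_net)
  img <- reflect_pad(standardize_image(img), unit)
  grid <- encode_grid(coords, dim(img), cfg_net$cell_size)
  list(x = matrix(as.vector(img), ncol = 1), H = nrow(img), W = ncol(img),
       target = matrix(grid, ncol = 3))
}

zero_like <- function(params) lapply(params, function(p) p * 0)

amsgrad_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                         eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    state$vhat[[nm]] <- pmax(state$vhat[[nm]], state$v[[nm]])
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$vhat[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Train a spot detection model
#'
#' Fits the grid-cell regression network to a partitioned dataset archive by
#' minibatch optimization of the combined objective (dice classification
#' loss plus doubly weighted localization RMSE; see [combined_loss()]).
#' Images are standardized per image, reflect-padded to the network's shape
#' unit, optionally augmented with random flips and 90-degree rotations, and
#' encoded as grid targets. After every epoch the validation loss and the
#' validation F1 integral score (predictions decoded at threshold 0.5) are
#' recorded; the returned model carries the parameters of the epoch with the
#' lowest validation loss.
#'
#' @param archive a `spot_archive` with non-empty train and valid splits.
#' @param config a [train_config()].
#' @param verbose print a progress line per epoch.
#' @return object of class `spotnet`: list with `network` (the trained
#'   `spotnet_network`), `history` (data frame: epoch, train_loss,
#'   valid_loss, valid_f1_integral), `best_epoch`, `config`.
#' @seealso [predict.spotnet()], [plot.spotnet()]
#' @export
fit_spotnet <- function(archive, config = default_config(), verbose = FALSE) {
  stopifnot(inherits(archive, "spot_archive"),
            inherits(config, "train_config"))
  n_train <- dim(archive$x_train)[3]
  n_valid <- dim(archive$x_valid)[3]
  if (n_train == 0) stop("training split is empty")
  if (n_valid == 0) stop("validation split is empty")
  cfg_net <- config$network

  with_seed(config$seed, {
    net <- build_network(cfg_net, in_channels = 1)
    state <- list(m = zero_like(net$params), v = zero_like(net$params),
                  vhat = zero_like(net$params), t = 0)
    valid_prep <- lapply(seq_len(n_valid), function(i)
      prep_sample(archive$x_valid[, , i], archive$y_valid[[i]], cfg_net))
    valid_truth <- archive$y_valid
    valid_shape <- dim(archive$x_valid)[1:2]

    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          valid_loss = numeric(0),
                          valid_f1_integral = numeric(0))
    best <- list(loss = Inf, params = net$params, epoch = 0L)

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_train)
      batch_losses <- numeric(0)
      for (start in seq(1, n_train, by = config$batch_size)) {
        ids <- ord[start:min(start + config$batch_size - 1, n_train)]
        fwds <- vector("list", length(ids))
        targets <- vector("list", length(ids))
        for (b in seq_along(ids)) {
          img <- archive$x_train[, , ids[b]]
          coords <- archive$y_train[[ids[b]]]
          if (config$augment) {
            aug <- augment_sample(img, coords,
                                  flip = stats::runif(1) < 0.5,
                                  k = sample(0:3, 1))
            img <- aug$img; coords <- aug$coords
          }
          sm <- prep_sample(img, coords, cfg_net)
          fwds[[b]] <- net_fwd(net, sm$x, sm$H, sm$W, train = TRUE)
          targets[[b]] <- sm$target
        }
        bl <- batch_loss_grad(lapply(fwds, `[[`, "out"), targets)
        if (!is.finite(bl$j))
          stop(sprintf("non-finite loss at epoch %d (batch starting %d): %s",
                       epoch, start, format(bl$j)))
        grads <- zero_like(net$params)
        for (b in seq_along(ids))
          grads <- net_bwd(net, fwds[[b]], bl$grads[[b]], grads)
        st <- amsgrad_step(net$params, grads, state, config$learning_rate)
        net$params <- st$params
        state <- st$state
        batch_losses <- c(batch_losses, bl$j)
      }

      # validation: per-image loss and decoded F1 integral
      vloss <- numeric(n_valid)
      vf1 <- numeric(n_valid)
      for (i in seq_len(n_valid)) {
        sm <- valid_prep[[i]]
        fw <- net_fwd(net, sm$x, sm$H, sm$W, train = FALSE)
        vloss[i] <- batch_loss_grad(list(fw$out), list(sm$target))$j
        g <- array(0, dim = c(fw$hg, fw$wg, 3))
        for (ch in 1:3) g[, , ch] <- matrix(fw$out[, ch], fw$hg, fw$wg)
        pred <- decode_grid(g, 0.5, cfg_net$cell_size)
        pred <- pred[pred[, 1] < valid_shape[1] &
                     pred[, 2] < valid_shape[2], , drop = FALSE]
        vf1[i] <- f1_integral(pred, valid_truth[[i]])
      }
      history[epoch, ] <- list(epoch, mean(batch_losses), mean(vloss),
                               mean(vf1))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  valid %.4f  F1i %.4f",
                        epoch, mean(batch_losses), mean(vloss), mean(vf1)))
      if (mean(vloss) < best$loss)
        best <- list(loss = mean(vloss), params = net$params, epoch = epoch)
    }
    net$params <- best$params
    structure(list(network = net, history = history,
                   best_epoch = best$epoch, config = config),
              class = "spotnet")
  })
}

#' @export
print.spotnet <- function(x, ...) {
  h <- x$history
  cat(sprintf(paste0("spot detection model: %d epochs trained, best epoch %d ",
                     "(valid loss %.4f, valid F1 integral %.4f)\n"),
              nrow(h), x$best_epoch, h$valid_loss[x$best_epoch],
              h$valid_f1_integral[x$best_epoch]))
  print(x$network)
  invisible(x)
}

#' @export
summary.spotnet <- function(object, ...) {
  print(object)
  cat("\ntraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object$history)
}

#' Plot training history
#'
#' Training and validation loss curves with the validation F1 integral score
#' on a secondary axis; the checkpointed epoch is marked.
#'
#' @param x a `spotnet` model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.spotnet <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$valid_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss J", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::par(new = TRUE)
  graphics::plot(h$epoch, h$valid_f1_integral, type = "l", col = "steelblue",
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4)
  graphics::mtext("valid F1 integral", side = 4, line = 2.5)
  graphics::legend("right", c("train loss", "valid loss", "valid F1 integral"),
                   lty = 1, col = c("grey40", "firebrick", "steelblue"),
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Save / load a trained model
#'
#' Models are persisted as RDS checkpoints.
#'
#' @param model a `spotnet`.
#' @param path file path.
#' @return `load_spotnet` returns the `spotnet`; `save_spotnet` returns
#'   `path` invisibly.
#' @export
save_spotnet <- function(model, path) {
  stopifnot(inherits(model, "spotnet"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname save_spotnet
#' @export
load_spotnet <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- readRDS(path)
  if (!inherits(obj, "spotnet")) stop("file is not a spotnet model: ", path)
  obj
}
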