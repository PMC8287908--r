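# R reference for the fused conv kernel: explicit zero-padded 3x3 convolution.
ref_conv3 <- function(x, Wm, b, H, W, relu = TRUE) {
  C <- ncol(x)
  Cout <- ncol(Wm)
  xp <- array(0, dim = c(H + 2, W + 2, C))
  for (ch in seq_len(C)) xp[2:(H + 1), 2:(W + 1), ch] <- matrix(x[, ch], H, W)
  out <- matrix(0, H * W, Cout)
  for (co in seq_len(Cout)) {
    acc <- matrix(b[co], H, W)
    for (ch in seq_len(C)) for (dc in -1:1) for (dr in -1:1) {
      k <- (ch - 1) * 9 + (dc + 1) * 3 + (dr + 1) + 1
      acc <- acc + Wm[k, co] *
        xp[2:(H + 1) + dr, 2:(W + 1) + dc, ch]
    }
    out[, co] <- as.vector(acc)
  }
  if (relu) out <- pmax(out, 0)
  out
}

test_that("the fused convolution kernel matches an explicit R reference", {
  set.seed(31)
  for (rep in 1:5) {
    H <- sample(4:9, 1); W <- sample(4:9, 1)
    C <- sample(1:3, 1); Cout <- sample(1:4, 1)
    x <- matrix(rnorm(H * W * C), H * W, C)
    Wm <- matrix(rnorm(9 * C * Cout, 0, 0.3), 9 * C, Cout)
    b <- rnorm(Cout, 0, 0.1)
    got <- spotnet:::conv3_fwd(x, Wm, b, H, W, TRUE)
    want <- ref_conv3(x, Wm, b, H, W, TRUE)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("network output obeys the grid shape contract", {
  for (case in list(c(64, 64, 4, 2), c(32, 48, 2, 2), c(32, 32, 1, 2),
                    c(64, 32, 8, 1))) {
    H <- case[1]; W <- case[2]; cs <- case[3]; depth <- case[4]
    cfg <- network_config(cell_size = cs, filters = 4, unet_depth = depth,
                          convs_per_block = 1, se_reduction = 2)
    net <- build_network(cfg, seed = 1)
    g <- network_forward(net, matrix(rnorm(H * W), H, W))
    expect_equal(dim(g), c(H / cs, W / cs, 3))
    expect_true(all(g > 0 & g < 1))   # logistic squashing on all channels
  }
  expect_error(network_config(cell_size = 3), "power of two")
  cfg <- network_config(cell_size = 4, filters = 4, unet_depth = 2,
                        convs_per_block = 1)
  net <- build_network(cfg, seed = 1)
  expect_error(network_forward(net, matrix(0, 30, 32)), "divisible")
})

test_that("dice loss follows the smoothed overlap formula", {
  y <- c(1, 0, 0, 1)
  expect_equal(dice_loss(y, y), 0, tolerance = 1e-6)
  expect_equal(dice_loss(rep(0, 4), y), 1, tolerance = 1e-6)
  expect_equal(dice_loss(c(0.5, 0, 0, 0), c(1, 0, 0, 0)), 1 - 1 / 1.5,
               tolerance = 1e-6)
  expect_equal(dice_loss(numeric(4), numeric(4)), 0)  # empty vs empty
  expect_error(dice_loss(numeric(3), numeric(4)), "shape")
})

test_that("localization loss pools both offset channels per spot", {
  po <- rbind(c(0.5, 0.9), c(0.2, 0.2))
  to <- rbind(c(0.2, 0.5), c(0.9, 0.9))
  # only the first cell is a spot: error (0.3, 0.4) -> sqrt(0.25/1) = 0.5
  expect_equal(localization_loss(po, to, c(TRUE, FALSE)), 0.5,
               tolerance = 1e-12)
  expect_equal(localization_loss(po, po, c(TRUE, TRUE)), 0)
  expect_equal(localization_loss(po, to, c(FALSE, FALSE)), 0)
})

test_that("the combined objective decomposes as J = J_class + 2 J_loc", {
  set.seed(12)
  truth <- encode_grid(rbind(c(3, 3), c(10, 13)), c(16, 16), 4)
  pred <- truth
  expect_equal(combined_loss(pred, truth)$j, 0, tolerance = 1e-6)

  pred2 <- truth
  pred2[1, 1, 2:3] <- truth[1, 1, 2:3] + c(0.3, 0.4)
  lb <- combined_loss(pred2, truth)
  expect_equal(lb$j_loc, sqrt(0.25 / 2), tolerance = 1e-12)
  expect_equal(lb$j, lb$j_class + 2 * lb$j_loc)
  expect_equal(lb$n_spot_cells, 2)

  # perfect localization, all-zero probability: j collapses to j_class ~ 1
  pred3 <- truth
  pred3[, , 1] <- 0
  lb3 <- combined_loss(pred3, truth)
  expect_equal(lb3$j_loc, 0)
  expect_equal(lb3$j, lb3$j_class)
  expect_gt(lb3$j_class, 0.99)

  for (rep in 1:10) {
    rnd <- truth
    rnd[] <- runif(length(rnd))
    lbr <- combined_loss(rnd, truth)
    expect_equal(lbr$j, lbr$j_class + 2 * lbr$j_loc, tolerance = 1e-12)
    expect_gte(lbr$j_class, 0)
    expect_lte(lbr$j_class, 1)
  }
})

test_that("a few optimizer steps reduce the loss on a single sample", {
  cfg <- network_config(cell_size = 2, filters = 4, unet_depth = 1,
                        convs_per_block = 2, se_reduction = 2,
                        dropout_rate = 0)
  arch_img <- simulate_spot_field(spot_field_params(
    height = 16, width = 16, n_spots = 3, min_separation = 4, seed = 2))
  net <- build_network(cfg, seed = 4)
  sm <- spotnet:::prep_sample(arch_img$pixels, arch_img$coords, cfg)
  state <- list(m = spotnet:::zero_like(net$params),
                v = spotnet:::zero_like(net$params),
                vhat = spotnet:::zero_like(net$params), t = 0)
  losses <- numeric(30)
  for (i in 1:30) {
    fw <- spotnet:::net_fwd(net, sm$x, sm$H, sm$W, train = FALSE)
    bl <- spotnet:::batch_loss_grad(list(fw$out), list(sm$target))
    losses[i] <- bl$j
    grads <- spotnet:::net_bwd(net, fw, bl$grads[[1]],
                               spotnet:::zero_like(net$params))
    st <- spotnet:::amsgrad_step(net$params, grads, state, 1e-2)
    net$params <- st$params
    state <- st$state
  }
  expect_true(all(is.finite(losses)))
  expect_lt(losses[30], losses[1])
})

test_that("ablation toggles produce runnable architectures", {
  img <- matrix(rnorm(32 * 32), 32, 32)
  for (tog in list(list(use_se = FALSE), list(use_dropout = FALSE),
                   list(use_bottom_skip = FALSE),
                   list(use_se = FALSE, use_dropout = FALSE,
                        use_bottom_skip = FALSE))) {
    cfg <- do.call(network_config,
                   c(list(cell_size = 4, filters = 4, unet_depth = 2,
                          convs_per_block = 1, se_reduction = 2), tog))
    net <- build_network(cfg, seed = 2)
    g <- network_forward(net, img)
    expect_equal(dim(g), c(8, 8, 3))
    if (isFALSE(tog$use_se))
      expect_false(any(grepl("\\.se\\.", names(net$params))))
  }
})
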