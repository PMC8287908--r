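# Shared fixtures. The desk-scale fit (the suite's one expensive computation)
# is memoized so every test that needs a trained model reuses a single
# training run.

.fixture_env <- new.env(parent = emptyenv())

# Desk-scale study conditions: 80 bright spot fields of 128x128 px (10 spots,
# SNR 16-24, >= 8 px separation) split 64/8/8, and a reduced detector
# (16 filters, U-Net depth 2, cell size 4) trained for 20 epochs with
# AMSGrad at learning rate 3e-3 and batch size 2.
desk_params <- function() {
  list(
    fields = replicate(80, spot_field_params(height = 128, width = 128,
                                             n_spots = 10,
                                             min_separation = 8),
                       simplify = FALSE),
    split = c(0.8, 0.1, 0.1),
    data_seed = 101,
    config = train_config(
      network = network_config(cell_size = 4, filters = 16, unet_depth = 2,
                               dropout_rate = 0.3),
      learning_rate = 3e-3, batch_size = 2, epochs = 20, seed = 7))
}

desk_fixture <- function() {
  if (is.null(.fixture_env$desk)) {
    dp <- desk_params()
    archive <- simulate_spot_dataset(dp$fields, dp$split, seed = dp$data_seed)
    model <- fit_spotnet(archive, dp$config)
    .fixture_env$desk <- list(archive = archive, model = model)
  }
  .fixture_env$desk
}

# A fast throwaway model for smoke tests that only need a runnable network.
tiny_fit <- function(epochs = 2, seed = 3) {
  params <- replicate(8, spot_field_params(height = 32, width = 32,
                                           n_spots = 3, min_separation = 5),
                      simplify = FALSE)
  archive <- simulate_spot_dataset(params, c(0.6, 0.2, 0.2), seed = 12)
  cfg <- train_config(network = network_config(cell_size = 4, filters = 4,
                                               unet_depth = 1,
                                               convs_per_block = 1,
                                               se_reduction = 2),
                      learning_rate = 1e-3, batch_size = 2, epochs = epochs,
                      seed = seed)
  list(archive = archive, model = fit_spotnet(archive, cfg), config = cfg)
}
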