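test_that("coordinate sampling honours count, separation and determinism", {
  p0 <- spot_field_params(n_spots = 0, seed = 1)
  expect_equal(nrow(sample_coordinates(p0)), 0)

  p <- spot_field_params(height = 128, width = 128, n_spots = 10,
                         min_separation = 8, seed = 1)
  co <- sample_coordinates(p)
  expect_equal(nrow(co), 10)
  expect_gte(min(dist(co)), 8)
  expect_identical(co, sample_coordinates(p))

  # 2000 circles of radius 4 cannot pack into 64x64
  dense <- spot_field_params(height = 64, width = 64, n_spots = 2000,
                             min_separation = 8, seed = 1)
  expect_error(sample_coordinates(dense), "packing")
})

test_that("rendering evaluates the Gaussian PSF at pixel centres", {
  p <- spot_field_params(height = 32, width = 32, n_spots = 0,
                         background = 100, noise_sd = 0, seed = 1)
  flat <- render_spot_field(NULL, p)
  expect_true(all(flat$pixels == 100))

  p1 <- spot_field_params(height = 32, width = 32, psf_sigma = 1,
                          amplitude_range = c(50, 50), background = 100,
                          noise_sd = 0, seed = 1)
  one <- render_spot_field(rbind(c(10, 20)), p1)
  expect_equal(which(one$pixels == max(one$pixels), arr.ind = TRUE)[1, ],
               c(row = 11, col = 21))   # matrix index of coordinate (10, 20)
  expect_equal(max(one$pixels), 150)

  half <- render_spot_field(rbind(c(10.5, 20)), p1)
  expect_equal(half$pixels[11, 21], half$pixels[12, 21])
})

test_that("noise realizations match the requested statistics", {
  # empirical SNR: peak amplitude / noise sd over 100 integer-placed spots
  set.seed(2)
  amp <- 100; noise <- 5
  p <- spot_field_params(height = 300, width = 300, psf_sigma = 1.5,
                         amplitude_range = c(amp, amp), background = 50,
                         noise_sd = noise, seed = 9)
  centres <- as.matrix(expand.grid(seq(10, 290, by = 28),
                                   seq(10, 290, by = 31)))[1:100, ]
  f <- render_spot_field(centres, p)
  peaks <- f$pixels[centres + 1] - 50
  expect_lt(abs(mean(peaks) / noise - amp / noise) / (amp / noise), 0.1)

  # noise-only background mean within 3 sd of the standard error
  p0 <- spot_field_params(height = 64, width = 64, n_spots = 0,
                          background = 200, noise_sd = 8, seed = 3)
  bg <- render_spot_field(NULL, p0)
  expect_lt(abs(mean(bg$pixels) - 200), 3 * 8 / sqrt(64 * 64))
})

test_that("seeded dataset generation is byte-reproducible and splits correctly", {
  mk <- function() {
    params <- replicate(20, spot_field_params(height = 32, width = 32,
                                              n_spots = 3, min_separation = 4),
                        simplify = FALSE)
    simulate_spot_dataset(params, c(0.7, 0.15, 0.15), seed = 5)
  }
  a1 <- mk(); a2 <- mk()
  f1 <- tempfile(); f2 <- tempfile()
  save_archive(a1, f1); save_archive(a2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(dim(a1$x_train)[3], 14)
  expect_equal(dim(a1$x_valid)[3], 3)
  expect_equal(dim(a1$x_test)[3], 3)

  two <- replicate(2, spot_field_params(height = 16, width = 16, n_spots = 1),
                   simplify = FALSE)
  expect_error(simulate_spot_dataset(two, c(0.7, 0.15, 0.15), seed = 1),
               "too few images")
})

test_that("rendered spot fields round-trip through TIFF and CSV", {
  p <- spot_field_params(height = 48, width = 40, n_spots = 4,
                         min_separation = 6, seed = 21)
  f <- simulate_spot_field(p)
  tf <- file.path(tempdir(), "field_rt.tif")
  write_spot_field(f, tf)
  img <- read_image(tf)
  expect_equal(dim(img), c(48, 40))
  expect_equal(img, round(pmin(pmax(f$pixels, 0), 65535)))
  labels <- read_label_table(file.path(tempdir(), "field_rt.csv"))
  expect_equal(unname(labels), unname(f$coords))
})
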