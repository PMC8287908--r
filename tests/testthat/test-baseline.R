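noiseless_field <- function(coords, H = 64, W = 64, amp = 100) {
  p <- spot_field_params(height = H, width = W, psf_sigma = 1.5,
                         amplitude_range = c(amp, amp), background = 50,
                         noise_sd = 0, seed = 1)
  render_spot_field(coords, p)$pixels
}

test_that("LoG detection finds isolated blobs with sub-pixel precision", {
  expect_equal(nrow(log_detect(matrix(5, 64, 64), 4)$coords), 0)

  truth <- rbind(c(30.4, 25.8))
  det <- log_detect(noiseless_field(truth), diameter = 2 * sqrt(2) * 1.5)
  expect_gte(nrow(det$coords), 1)
  expect_lt(sqrt(sum((det$coords[1, ] - truth)^2)), 0.5)

  two <- rbind(c(20, 20), c(20, 40))
  det2 <- log_detect(noiseless_field(two), diameter = 2 * sqrt(2) * 1.5)
  m <- match_spots(det2$coords, two, 1)
  expect_equal(nrow(m$pairs), 2)
})

test_that("threshold selection keeps everything when all detections are true", {
  set.seed(10)
  truths <- lapply(1:4, function(i)
    sample_coordinates(spot_field_params(height = 64, width = 64,
                                         n_spots = 5, min_separation = 14,
                                         seed = 40 + i)))
  # keep spots away from the border so every one is cleanly detectable
  truths <- lapply(truths, function(co) 10 + co * 44 / 63)
  images <- lapply(truths, noiseless_field)
  sel <- select_log_threshold(images, truths, diameters = 2 * sqrt(2) * 1.5)
  expect_gt(sel$mean_f1_integral, 0.9)
  # the lowest quantile keeps the most detections and cannot be beaten
  lowest <- min(sel$grid$threshold)
  expect_equal(sel$threshold, lowest)
})

test_that("threshold selection removes separable low-quality spurious blobs", {
  set.seed(20)
  mk <- function(seed) {
    bright <- sample_coordinates(spot_field_params(height = 96, width = 96,
                                                   n_spots = 5,
                                                   min_separation = 18,
                                                   seed = seed))
    bright <- 12 + bright * 70 / 95
    faint <- 12 + sample_coordinates(spot_field_params(height = 96, width = 96,
                                                       n_spots = 5,
                                                       min_separation = 18,
                                                       seed = seed + 50)) * 70 / 95
    img <- noiseless_field(bright, 96, 96, amp = 100) +
      noiseless_field(faint, 96, 96, amp = 12) - 50
    list(img = img, truth = bright)
  }
  sets <- lapply(1:3, mk)
  images <- lapply(sets, `[[`, "img")
  truths <- lapply(sets, `[[`, "truth")
  dia <- 2 * sqrt(2) * 1.5
  sel <- select_log_threshold(images, truths, diameters = dia)
  at_zero <- sel$grid$mean_f1_integral[which.min(sel$grid$threshold)]
  expect_gt(sel$mean_f1_integral, at_zero)
  expect_gt(sel$threshold, min(sel$grid$threshold))
})

test_that("selection fails loudly without any ground-truth spots", {
  images <- list(noiseless_field(rbind(c(30, 30))))
  expect_error(select_log_threshold(images, list(NULL), 4), "ground-truth")
})

test_that("per-image median normalization cancels intensity rescaling", {
  set.seed(30)
  truths <- lapply(1:3, function(i)
    10 + sample_coordinates(spot_field_params(height = 64, width = 64,
                                              n_spots = 4,
                                              min_separation = 14,
                                              seed = 60 + i)) * 44 / 63)
  images <- lapply(truths, noiseless_field)
  scaled <- images
  scaled[[1]] <- scaled[[1]] * 5   # LoG is linear: qualities scale by 5
  dia <- 2 * sqrt(2) * 1.5
  a <- select_log_threshold(images, truths, dia)
  b <- select_log_threshold(scaled, truths, dia)
  expect_equal(a$threshold, b$threshold, tolerance = 1e-6)
  expect_equal(a$mean_f1_integral, b$mean_f1_integral, tolerance = 1e-6)
})
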