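test_that("matching retains only pairs within the cutoff and counts FP/FN", {
  truth <- rbind(c(0, 0), c(0, 4))
  pred <- rbind(c(0, 3), c(0, 5))
  # optimal maximal matching pairs (0,3)<->(0,0) at 3 px and (0,5)<->(0,4) at
  # 1 px; the greedy alternative (0,3)<->(0,4) would leave (0,5) unmatched
  m <- match_spots(pred, truth, cutoff = 3.5)
  expect_equal(nrow(m$pairs), 2)
  expect_equal(sort(m$pairs$distance), c(1, 3))
  expect_equal(m$fp, 0)
  expect_equal(m$fn, 0)

  ident <- random_coords(7)
  mi <- match_spots(ident, ident, 3)
  expect_equal(nrow(mi$pairs), 7)
  expect_equal(mi$pairs$distance, rep(0, 7))

  me <- match_spots(NULL, random_coords(5), 3)
  expect_equal(nrow(me$pairs), 0)
  expect_equal(me$fp, 0)
  expect_equal(me$fn, 5)
})

test_that("assignment agrees with exhaustive enumeration on random instances", {
  set.seed(421)
  for (rep in 1:200) {
    np <- sample(0:6, 1)
    nt <- sample(0:6, 1)
    pred <- random_coords(np, 10, 10)
    truth <- random_coords(nt, 10, 10)
    cutoff <- runif(1, 0.5, 6)
    m <- match_spots(pred, truth, cutoff)
    oracle <- brute_force_match(pred, truth, cutoff)
    expect_identical(nrow(m$pairs), oracle$tp)
    expect_equal(sum(m$pairs$distance), oracle$total, tolerance = 1e-10)
  }
})

test_that("F1 score follows 2TP/(2TP+FP+FN) with a zero convention", {
  m <- match_spots(rbind(c(0, 0), c(0, 1), c(50, 50)),
                   rbind(c(0, 0), c(0, 1), c(20, 20)), 3)
  expect_equal(f1_score(m), 2 * 2 / (2 * 2 + 1 + 1))
  expect_equal(f1_score(match_spots(NULL, NULL, 3)), 0)
  p <- random_coords(4)
  expect_equal(f1_score(match_spots(p, p, 3)), 1)
})

test_that("F1 is non-decreasing in the cutoff and symmetric in FP/FN", {
  set.seed(99)
  for (rep in 1:20) {
    pred <- random_coords(sample(0:8, 1), 16, 16)
    truth <- random_coords(sample(0:8, 1), 16, 16)
    cuts <- seq(0, 5, length.out = 15)
    f1 <- vapply(cuts, function(ct) f1_score(match_spots(pred, truth, ct)),
                 numeric(1))
    expect_true(all(diff(f1) >= -1e-12))
    ct <- runif(1, 0, 4)
    a <- match_spots(pred, truth, ct)
    b <- match_spots(truth, pred, ct)
    expect_equal(a$fp, b$fn)
    expect_equal(a$fn, b$fp)
    expect_equal(f1_score(a), f1_score(b))
  }
})

test_that("F1 integral hits its boundary values and the closed-form case", {
  set.seed(3)
  tt <- random_coords(25, 512, 512)
  expect_equal(f1_integral(tt, tt), 1.0, tolerance = 1e-9)
  expect_identical(f1_integral(tt + 10, tt), 0)
  # one pair at 1.5 px: the F1-vs-cutoff curve is a unit step at 1.5
  expect_equal(f1_integral(rbind(c(0, 1.5)), rbind(c(0, 0))),
               step_f1_integral(1.5))
  expect_equal(step_f1_integral(1.5), 0.5)
  # other step positions agree with the independent step oracle too
  for (d0 in c(0.4, 1.0, 2.2, 2.9))
    expect_equal(f1_integral(rbind(c(0, d0)), rbind(c(0, 0))),
                 step_f1_integral(d0))
})

test_that("F1 integral is bounded and maximal only for permutations", {
  set.seed(17)
  for (rep in 1:25) {
    pred <- random_coords(sample(0:6, 1), 32, 32)
    truth <- random_coords(sample(0:6, 1), 32, 32)
    v <- f1_integral(pred, truth)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
  truth <- random_coords(6, 32, 32)
  perm <- truth[sample(6), ]
  expect_equal(f1_integral(perm, truth), 1, tolerance = 1e-9)
  expect_lt(f1_integral(truth + 0.2, truth), 1)
})

test_that("RMSE over true positives follows the root-mean-square form", {
  truth <- rbind(c(0, 0), c(10, 10))
  pred <- rbind(c(0, 1), c(10, 12))     # distances 1 and 2
  expect_equal(rmse_spots(pred, truth), sqrt((1 + 4) / 2), tolerance = 1e-12)
  p <- random_coords(3)
  expect_equal(rmse_spots(p, p), 0)
  expect_true(is.na(rmse_spots(p + 50, p)))
})

test_that("evaluation aggregates per-image metrics with sample sd", {
  a <- random_coords(5)
  b <- random_coords(4, 20, 20)
  rep <- evaluate_detections(list(a, b + 50), list(a, b))
  expect_equal(rep$per_image$f1_integral, c(1, 0), tolerance = 1e-9)
  expect_equal(rep$summary$f1_integral, c(0.5, sd(c(1, 0))))
  # rmse aggregated only over images with true positives
  expect_equal(rep$summary$rmse, c(0, 0))

  single <- evaluate_detections(list(a), list(a))
  expect_equal(single$summary$f1_integral, c(1, 0), tolerance = 1e-9)

  expect_error(evaluate_detections(list(a), list(a, b)), "equal length")
})
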