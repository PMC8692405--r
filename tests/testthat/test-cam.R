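# Class activation maps: weighted merge, scaling, upsampling, binarization,
# localization scoring.

test_that("compute_cam merges feature maps with the class weights", {
  f1 <- array(matrix(runif(25), 5, 5), c(5, 5, 1))
  expect_equal(compute_cam(f1, matrix(1, 1, 1), 1), f1[, , 1])
  f3 <- array(runif(5 * 5 * 3), c(5, 5, 3))
  W <- matrix(rnorm(6), 3, 2)
  expect_equal(compute_cam(f3, matrix(0, 3, 2), 2), matrix(0, 5, 5))
  # brute-force per-pixel oracle
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    oracle[i, j] <- sum(W[, 2] * f3[i, j, ])
  }
  expect_lt(max(abs(compute_cam(f3, W, 2) - oracle)), 1e-6)
  expect_error(compute_cam(f3, W, 3), "invalid class")
})

test_that("compute_cam is linear in the weights", {
  f <- array(runif(4 * 4 * 3), c(4, 4, 3))
  W1 <- matrix(rnorm(3)); W2 <- matrix(rnorm(3))
  expect_equal(compute_cam(f, W1 + W2, 1),
               compute_cam(f, W1, 1) + compute_cam(f, W2, 1),
               tolerance = 1e-12)
})

test_that("scale_cam min-max normalizes and flags constant maps", {
  expect_equal(as.numeric(scale_cam(matrix(c(0, 5, 10), 1))), c(0, 0.5, 1))
  expect_equal(as.numeric(scale_cam(matrix(c(-2, 0, 2), 1))), c(0, 0.5, 1))
  const <- scale_cam(matrix(3.3, 4, 4))
  expect_true(attr(const, "degenerate"))
  expect_equal(as.numeric(const), rep(0, 16))
  r <- scale_cam(matrix(rnorm(36), 6))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("binarization is inclusive at the threshold and monotone", {
  m <- matrix(c(0.299, 0.3, 0.301, 0.9), 2)
  expect_equal(as.numeric(binarize_cam(m, 0.3)), c(0, 1, 1, 1))
  expect_error(binarize_cam(m, 1.5), "threshold")
  u <- matrix(runif(100), 10)
  expect_true(all(binarize_cam(u, 0.6) <= binarize_cam(u, 0.3)))
})

test_that("upsampling preserves constants, bounds and peak location", {
  expect_equal(upsample_cam(matrix(0.7, 3, 3), 9), matrix(0.7, 9, 9),
               tolerance = 1e-12)
  m <- matrix(runif(49), 7, 7)
  up <- upsample_cam(m, 14)
  expect_lte(max(up), max(m) + 1e-6)
  peak <- matrix(0, 7, 7); peak[3, 5] <- 1
  big <- upsample_cam(peak, 224)
  am <- which(big == max(big), arr.ind = TRUE)[1, ]
  # pixel centers map to (i - 0.5) * scale + 0.5
  expect_lt(abs(am[1] - ((3 - 0.5) * 32 + 0.5)), 32 / 2 + 1)
  expect_lt(abs(am[2] - ((5 - 0.5) * 32 + 0.5)), 32 / 2 + 1)
  expect_error(upsample_cam(m, 5), "below source")
})

test_that("CAM exactly decomposes the class-score difference", {
  cfg <- gap_classifier_config(channels = c(4L, 8L), strides = c(2L, 2L),
                               side = 32L)
  model <- init_gap_classifier(cfg, seed = 21)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  fw <- forward_gap(model, x)
  f <- fw$f[, , , 1]
  gap_sum <- sum(compute_cam(f, fw$W, 2) - compute_cam(f, fw$W, 1))
  expect_lt(abs(gap_sum - (fw$S[1, 2] - fw$S[1, 1])), 1e-4)
})

test_that("localization scores any-overlap correctness", {
  # one hot feature map -> CAM concentrated there
  f <- array(0, c(8, 8, 1)); f[2, 2, 1] <- 1
  W <- matrix(c(0, 1), 1, 2)   # malignant CAM = the map
  fake <- list(p = matrix(c(0.1, 0.9), 1), f = array(f, c(8, 8, 1, 1)),
               W = W)
  gt_near <- matrix(FALSE, 64, 64); gt_near[8:20, 8:20] <- TRUE
  gt_far <- matrix(FALSE, 64, 64); gt_far[50:60, 50:60] <- TRUE
  hit <- localize(fake, gt_near, "malignant")
  miss <- localize(fake, gt_far, "malignant")
  expect_true(hit$correct)
  expect_gte(hit$overlap_px, 1)
  expect_false(miss$correct)
  expect_equal(miss$overlap_px, 0L)
  expect_error(localize(fake, matrix(FALSE, 64, 64), "malignant"), "empty")
})

test_that("degenerate constant CAMs are counted incorrect", {
  f <- array(1, c(8, 8, 1))
  fake <- list(p = matrix(c(0.1, 0.9), 1), f = array(f, c(8, 8, 1, 1)),
               W = matrix(c(0, 1), 1, 2))
  gt <- matrix(TRUE, 64, 64)
  out <- localize(fake, gt, "malignant")
  expect_true(out$degenerate)
  expect_false(out$correct)
})

test_that("the class policy selects the evaluated class", {
  f <- array(runif(8 * 8 * 2), c(8, 8, 2, 1))
  W <- matrix(rnorm(4), 2, 2)
  fake <- list(p = matrix(c(0.8, 0.2), 1), f = f, W = W)
  gt <- matrix(FALSE, 64, 64); gt[1:64, 1:64] <- TRUE
  expect_equal(localize(fake, gt, "benign", policy = "predicted")$evaluated_class, 1L)
  expect_equal(localize(fake, gt, "benign", policy = "malignant")$evaluated_class, 2L)
  expect_equal(localize(fake, gt, "malignant", policy = "true_class")$evaluated_class, 2L)
})

test_that("localization tables count correct/incorrect by true class", {
  mk <- function(lb, ok) {
    structure(list(true_label = lb, evaluated_class = 2L, correct = ok,
                   overlap_px = as.integer(ok), degenerate = FALSE),
              class = "localization_outcome")
  }
  outcomes <- c(lapply(1:99, function(i) mk("benign", TRUE)),
                list(mk("benign", FALSE)),
                lapply(1:100, function(i) mk("malignant", TRUE)))
  tab <- localization_table(outcomes)
  expect_equal(unname(tab), matrix(c(99L, 100L, 1L, 0L), 2))
  expect_equal(sum(tab), length(outcomes))
  all_ok <- localization_table(c(lapply(1:5, function(i) mk("benign", TRUE)),
                                 lapply(1:7, function(i) mk("malignant", TRUE))))
  expect_equal(unname(all_ok[, "incorrect"]), c(0L, 0L))
})
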