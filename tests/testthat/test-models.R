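# GAP classifier equation chain, initialization, training; U-Net contracts.

test_that("global average pooling computes the spatial sum", {
  expect_equal(global_average_pool(array(1, c(7, 7, 1))), 49)
  expect_equal(global_average_pool(array(0, c(5, 5, 1))), 0)
  expect_equal(global_average_pool(array(c(1, 3, 2, 4), c(2, 2, 1))), 10)
  expect_equal(global_average_pool(array(1, c(4, 4, 1)), pool = "mean"), 1)
  batch <- array(seq_len(2 * 2 * 3 * 2), c(2, 2, 3, 2))
  F <- global_average_pool(batch)
  expect_equal(dim(F), c(2, 3))
  expect_equal(F[1, 1], sum(batch[, , 1, 1]))
})

test_that("class scores are the bias-free inner product", {
  expect_equal(class_scores(c(1, 2), diag(2)), c(1, 2))
  expect_equal(class_scores(c(1, 2), matrix(0, 2, 2)), c(0, 0))
  W <- cbind(c(0.5, 0.5), c(-0.5, -0.5))
  expect_equal(class_scores(c(1, 1), W), c(1, -1))
  expect_error(class_scores(c(1, 2, 3), diag(2)), "mismatch")
})

test_that("softmax and POM behave as the printed definition", {
  sp <- softmax_pom(c(0, 0), malignant_index = 2)
  expect_equal(sp$p, c(0.5, 0.5))
  expect_equal(sp$pom, 0.5)
  expect_equal(softmax_pom(c(log(2), 0), malignant_index = 1)$pom, 2 / 3)
  a <- softmax_pom(c(1.3, -0.2))
  b <- softmax_pom(c(1.3, -0.2) + 57)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_error(softmax_pom(c(Inf, 0)), "finite")
})

test_that("forward pass is self-consistent and batch-independent", {
  cfg <- gap_classifier_config(channels = c(4L, 8L), strides = c(2L, 2L),
                               side = 32L)
  model <- init_gap_classifier(cfg, seed = 5)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  fw <- forward_gap(model, x)
  S2 <- class_scores(global_average_pool(fw$f), fw$W)
  expect_lt(max(abs(S2 - fw$S)), 1e-5)
  expect_equal(rowSums(fw$p), c(1, 1), tolerance = 1e-6)
  # zero head -> uninformative probabilities
  m0 <- model; m0$params$head[] <- 0
  expect_equal(forward_gap(m0, x)$p, matrix(0.5, 2, 2))
  # duplicated input in a batch gives identical per-item outputs
  xdup <- x; xdup[, , , 2] <- x[, , , 1]
  fwd <- forward_gap(model, xdup)
  expect_equal(fwd$pom[1], fwd$pom[2], tolerance = 1e-12)
})

test_that("He initialization is seeded and has the rectifier-scaled variance", {
  cfg <- gap_classifier_config(channels = c(8L, 16L, 32L, 64L),
                               strides = c(2L, 2L, 2L, 2L), side = 32L)
  m1 <- init_gap_classifier(cfg, seed = 11)
  m2 <- init_gap_classifier(cfg, seed = 11)
  m3 <- init_gap_classifier(cfg, seed = 12)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params$conv2, m3$params$conv2))
  w4 <- m1$params$conv4                       # 3x3x32x64 = 18432 draws
  fan_in <- prod(dim(w4)[1:3])
  expect_lt(abs(var(as.numeric(w4)) - 2 / fan_in) / (2 / fan_in), 0.1)
  expect_true(all(m1$params$bias1 == 0))
})

test_that("training separates strongly contrasting phantoms", {
  recs <- easy_records(30, side = 64L)
  xy <- records_xy(recs, side = 64L)
  tune_idx <- c(1:10, 31:40)
  fit_idx <- setdiff(seq_along(recs), tune_idx)
  cfg <- gap_classifier_config(side = 64L)
  m <- train_classifier(xy$x[, , , fit_idx, drop = FALSE], xy$y[fit_idx],
                        xy$x[, , , tune_idx, drop = FALSE], xy$y[tune_idx],
                        cfg, training_config(batch_size = 16L, epochs = 15L,
                                             lr = 3e-3, weight_decay = 1e-3,
                                             seed = 3))
  expect_gte(max(m$log$tune_auc), 0.95)
})

test_that("stronger L2 shrinks the learned weights", {
  recs <- easy_records(8, side = 64L)
  xy <- records_xy(recs, side = 64L)
  fit <- function(lambda) {
    train_classifier(xy$x, xy$y, NULL, NULL,
                     gap_classifier_config(side = 64L),
                     training_config(batch_size = 8L, epochs = 3L, lr = 3e-3,
                                     weight_decay = lambda, seed = 3),
                     warn_empty_tune = FALSE)
  }
  norm_of <- function(m) {
    uscam:::l2_norm2(m$params[!startsWith(names(m$params), "bias")])
  }
  expect_lt(norm_of(fit(100)), norm_of(fit(0)))
})

test_that("empty tuning set falls back to the final epoch with a warning", {
  recs <- easy_records(4, side = 64L)
  xy <- records_xy(recs, side = 64L)
  expect_warning(
    m <- train_classifier(xy$x, xy$y, NULL, NULL,
                          gap_classifier_config(side = 64L),
                          training_config(batch_size = 8L, epochs = 2L,
                                          seed = 1)),
    "final-epoch")
  expect_equal(m$best_epoch, 2L)
})

test_that("seeded training is reproducible", {
  recs <- easy_records(6, side = 64L)
  xy <- records_xy(recs, side = 64L)
  tc <- training_config(batch_size = 8L, epochs = 2L, lr = 3e-3, seed = 17)
  run <- function() {
    train_classifier(xy$x[, , , 1:8, drop = FALSE], xy$y[1:8],
                     xy$x[, , , 9:12, drop = FALSE], xy$y[9:12],
                     gap_classifier_config(side = 64L), tc)
  }
  expect_identical(run()$log$tune_auc, run()$log$tune_auc)
})

test_that("grid search picks by tune AUC and retrains on everything", {
  recs <- easy_records(12, side = 64L)
  xy <- records_xy(recs, side = 64L)
  tune_idx <- c(1:4, 13:16)
  single <- grid_search(xy$x, xy$y, tune_idx,
                        grid = list(lr = 3e-3, weight_decay = 1e-3,
                                    epochs = 2L),
                        gap_classifier_config(side = 64L),
                        training_config(batch_size = 8L, seed = 2))
  expect_equal(single$best_config$lr, 3e-3)
  expect_equal(nrow(single$results), 1L)
  duo <- grid_search(xy$x, xy$y, tune_idx,
                     grid = list(lr = 3e-3, epochs = c(0L, 6L)),
                     gap_classifier_config(side = 64L),
                     training_config(batch_size = 8L, weight_decay = 1e-3,
                                     seed = 2))
  expect_equal(duo$best_config$epochs, 6L)
  expect_error(grid_search(xy$x, xy$y, tune_idx, grid = list(),
                           gap_classifier_config(side = 64L)),
               "empty grid")
})

test_that("segmenter validates inputs and outputs probabilities", {
  recs <- easy_records(4, side = 32L)
  x <- uscam:::stack_images(lapply(recs, `[[`, "pixels"))
  g <- uscam:::stack_images(lapply(recs, function(r) r$mask * 1))
  g0 <- g; g0[, , , 3] <- 0
  expect_error(train_segmenter(x, g0), "all-background")
  m <- train_segmenter(x, g, training_config(batch_size = 4L, epochs = 2L,
                                             lr = 3e-3, seed = 4),
                       base_channels = 4L)
  sm <- segment_masks(m, x)
  expect_true(all(sm$prob >= 0 & sm$prob <= 1))
  expect_equal(dim(sm$prob), c(32, 32, 8))
  expect_type(sm$mask, "logical")
})
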