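# Phantom generator: determinism, texture statistics, lesion morphology,
# rendering physics, dataset structure.

test_that("backgrounds are deterministic in (profile, seed) and vary with seed", {
  p <- internal_profile()
  a <- make_background(48, 48, p, seed = 9)
  b <- make_background(48, 48, p, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, make_background(48, 48, p, seed = 10)))
  expect_error(make_background(16, 48, p, 1), "at least 32")
})

test_that("pure normalized speckle has mid-range mean; gamma darkens", {
  p0 <- machine_profile(blur_sigma = 0, gain = 1, gamma = 1,
                        layer_contrast = 0)
  means <- vapply(1:10, function(s) mean(make_background(64, 64, p0, s)), 0)
  expect_true(all(means > 0.2 & means < 0.8))
  p2 <- machine_profile(blur_sigma = 0, gain = 1, gamma = 2,
                        layer_contrast = 0)
  g1 <- make_background(64, 64, p0, seed = 3)
  g2 <- make_background(64, 64, p2, seed = 3)
  expect_true(all(g2 <= g1 + 1e-12))
})

test_that("speckle scale controls relative fluctuation after normalization", {
  lo <- machine_profile(speckle_scale = 1, blur_sigma = 0, layer_contrast = 0)
  hi <- machine_profile(speckle_scale = 1.5, blur_sigma = 0, layer_contrast = 0)
  cv <- function(x) sd(x) / mean(x)
  cvs <- vapply(1:5, function(s) {
    cv(make_background(64, 64, hi, s)) - cv(make_background(64, 64, lo, s))
  }, 0)
  expect_true(all(cvs > 0))
})

test_that("benign masks are ellipses with the analytic area", {
  spec <- lesion_spec("benign", center = c(64, 64), semi_axes = c(10, 20))
  mask <- make_lesion_mask(spec, 128, 128)
  expect_lt(abs(sum(mask) - pi * 10 * 20) / (pi * 10 * 20), 0.03)
})

test_that("zero spicule amplitude reduces a malignant mask to the ellipse", {
  mal <- lesion_spec("malignant", center = c(64, 64), semi_axes = c(12, 18),
                     spicule_count = 8, spicule_amplitude = 0,
                     posterior_effect = 0)
  ben <- lesion_spec("benign", center = c(64, 64), semi_axes = c(12, 18))
  expect_identical(make_lesion_mask(mal, 128, 128),
                   make_lesion_mask(ben, 128, 128))
})

test_that("spiculation raises shape compactness (perimeter^2/area)", {
  mal <- lesion_spec("malignant", center = c(64, 64), semi_axes = c(12, 18),
                     spicule_count = 8, spicule_amplitude = 0.4,
                     posterior_effect = 0)
  ben <- lesion_spec("benign", center = c(64, 64), semi_axes = c(12, 18))
  expect_gt(compactness(make_lesion_mask(mal, 128, 128)),
            compactness(make_lesion_mask(ben, 128, 128)))
})

test_that("out-of-bounds lesions are rejected", {
  spec <- lesion_spec("benign", center = c(5, 64), semi_axes = c(10, 20))
  expect_error(make_lesion_mask(spec, 128, 128), "exceeds image bounds")
})

test_that("rendering with zero effects is the identity", {
  bg <- make_background(64, 64, seed = 2)
  spec <- lesion_spec("benign", center = c(32, 32), semi_axes = c(6, 9),
                      echogenicity_offset = 0, posterior_effect = 0)
  mask <- make_lesion_mask(spec, 64, 64)
  expect_identical(render_lesion(bg, spec, mask), bg)
  expect_error(render_lesion(bg[1:32, ], spec, mask), "dimensions differ")
})

test_that("hypoechoic offset darkens the lesion interior", {
  bg <- make_background(64, 64, seed = 2)
  spec <- lesion_spec("benign", center = c(32, 32), semi_axes = c(6, 9),
                      echogenicity_offset = -0.5, posterior_effect = 0)
  mask <- make_lesion_mask(spec, 64, 64)
  out <- render_lesion(bg, spec, mask)
  expect_lt(mean(out[mask]), mean(bg[mask]))
})

test_that("posterior shadowing darkens the column below the lesion", {
  bg <- make_background(64, 64, seed = 2)
  spec <- lesion_spec("malignant", center = c(20, 32), semi_axes = c(6, 9),
                      spicule_count = 6, spicule_amplitude = 0.2,
                      echogenicity_offset = -0.5, posterior_effect = -0.5)
  mask <- make_lesion_mask(spec, 64, 64)
  out <- render_lesion(bg, spec, mask)
  bb <- mask_bbox(mask)
  post_rows <- (bb[2] + 3):64
  post_cols <- (bb[3] + 1):bb[4]
  expect_lt(mean(out[post_rows, post_cols]), mean(bg[post_rows, post_cols]))
})

test_that("sampled lesion specs honor the class morphology archetypes", {
  withr::with_seed(99, {
    for (i in 1:25) {
      b <- sample_lesion_spec("benign", 128, 128)
      m <- sample_lesion_spec("malignant", 128, 128)
      expect_identical(b$spicule_count, 0L)
      expect_gte(b$posterior_effect, 0)
      expect_gte(b$semi_axes[2], b$semi_axes[1])   # wider than tall
      expect_gte(m$spicule_count, 4L)
      expect_lte(m$posterior_effect, 0)
    }
  })
})

test_that("generated masks are valid and morphology separates the classes", {
  sim <- small_sim()
  masks <- lapply(sim$records, `[[`, "mask")
  expect_true(all(vapply(masks, sum, 0) > 0))
  expect_true(all(vapply(masks, uscam:::single_component_4, NA)))
  comp <- vapply(masks, compactness, 0)
  lab <- vapply(sim$records, `[[`, "", "label")
  expect_gte(mean(comp[lab == "malignant"]), 1.2 * mean(comp[lab == "benign"]))
})

test_that("simulation is a pure function of config and seed", {
  cfg <- dataset_config(n_train = 6, n_tune = 2, n_internal = 4,
                        n_external = 4)
  s1 <- simulate_dataset(cfg, seed = 31)
  s2 <- simulate_dataset(cfg, seed = 31)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$manifest, s2$manifest)
  s3 <- simulate_dataset(cfg, seed = 32)
  expect_false(identical(s1$records, s3$records))
})

test_that("manifest structure matches the configured composition", {
  sim <- small_sim()
  mf <- sim$manifest
  counts <- table(mf$split, mf$label)
  expect_equal(unname(counts["train", ]), c(30, 30))
  expect_equal(unname(counts["internal_val", ]), c(12, 12))
  expect_equal(unname(counts["external_val", ]), c(12, 12))
  expect_equal(sum(mf$tune & mf$split == "train" & mf$label == "benign"), 6)
  expect_equal(sum(mf$tune & mf$split == "train" & mf$label == "malignant"), 6)
  expect_false(any(duplicated(mf$id)))
})

test_that("disk round trip preserves labels, splits and masks", {
  dir <- withr::local_tempdir()
  cfg <- dataset_config(n_train = 3, n_tune = 1, n_internal = 2,
                        n_external = 2)
  mf <- generate_dataset(cfg, dir, seed = 8)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_false(any(duplicated(mf$image)))
  back <- load_dataset(dir)
  expect_identical(back$manifest$label, mf$label)
  sim <- simulate_dataset(cfg, seed = 8)
  for (i in seq_along(sim$records)) {
    expect_identical(back$records[[i]]$mask, sim$records[[i]]$mask)
    expect_lt(max(abs(back$records[[i]]$pixels - sim$records[[i]]$pixels)),
              1 / 255)
  }
  mf2 <- generate_dataset(cfg, withr::local_tempdir(), seed = 8)
  expect_identical(mf$label, mf2$label)
  expect_identical(mf$seed, mf2$seed)
})
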