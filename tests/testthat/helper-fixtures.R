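# Shared small fixtures, built in code and memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# A small simulated dataset shared by structural tests.
small_sim <- function() {
  memo("small_sim", simulate_dataset(
    dataset_config(n_train = 30, n_tune = 6, n_internal = 12,
                   n_external = 12),
    seed = 421))
}

records_xy <- function(records, side = 128L) {
  list(x = uscam:::stack_images(lapply(records, function(r) {
         resize_normalize(r$pixels, side)
       })),
       y = uscam:::label01(vapply(records, `[[`, "", "label")))
}

# Boundary length of a binary mask: count of 4-neighbour foreground/background
# transitions (image border counts as background).
mask_perimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1L
  sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
}

compactness <- function(mask) {
  mask_perimeter(mask)^2 / (4 * pi * sum(mask))
}

# Strongly separable phantom set: large dark spiculated malignant lesions vs
# small faint benign ovals, used for training smoke tests.
easy_records <- function(n_per_class, side = 64L, seed = 7) {
  withr::with_seed(seed, {
    recs <- list()
    for (i in seq_len(n_per_class)) {
      for (lb in c("benign", "malignant")) {
        bg <- make_background(side, side, internal_profile(),
                              seed = sample.int(1e6, 1))
        jitter <- round(runif(2, -0.06, 0.06) * side)
        spec <- if (lb == "benign") {
          lesion_spec("benign", center = c(side / 2, side / 2) + jitter,
                      semi_axes = (c(0.12, 0.16) + runif(2, 0, 0.03)) * side,
                      orientation = runif(1, -0.2, 0.2),
                      margin_sharpness = 3, echogenicity_offset = -0.5,
                      posterior_effect = 0)
        } else {
          lesion_spec("malignant", center = c(side / 2, side / 2) + jitter,
                      semi_axes = (c(0.20, 0.23) + runif(2, 0, 0.03)) * side,
                      orientation = runif(1, 0, pi), spicule_count = 8,
                      spicule_amplitude = 0.35, margin_sharpness = 1,
                      echogenicity_offset = -0.85, posterior_effect = -0.4)
        }
        mask <- make_lesion_mask(spec, side, side)
        recs[[length(recs) + 1]] <- list(
          id = sprintf("easy_%s_%d", lb, i), label = lb, split = "train",
          tune = FALSE, seed = i, pixels = render_lesion(bg, spec, mask),
          mask = mask, lesion_size_px = 1L)
      }
    }
    recs
  })
}

# Leave-one-out jackknife estimate of AUC variances and covariance for two
# paired score vectors: the independent oracle for the DeLong components.
jackknife_auc_cov <- function(s1, s2, labels) {
  n <- length(labels)
  t1 <- vapply(seq_len(n), function(i) roc_auc(s1[-i], labels[-i])$auc, 0)
  t2 <- vapply(seq_len(n), function(i) roc_auc(s2[-i], labels[-i])$auc, 0)
  jk <- function(a, b) (n - 1) / n * sum((a - mean(a)) * (b - mean(b)))
  list(var1 = jk(t1, t1), var2 = jk(t2, t2), cov = jk(t1, t2))
}
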