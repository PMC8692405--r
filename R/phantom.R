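# Synthetic B-mode speckle phantom generator.
#
# Emulates the statistical structure of a two-institution breast-ultrasound
# dataset: grayscale speckled images, one hypoechoic lesion per image with a
# ground-truth binary mask, benign vs malignant morphology archetypes, and a
# machine-profile domain shift for the external validation split.

#' Ultrasound machine rendering profile
#'
#' Bundles the texture parameters that characterise one scanner: speckle
#' strength, point-spread blur, gain, contrast gamma and the amplitude of
#' horizontal tissue banding. Two splits rendered with different profiles
#' exhibit a domain shift analogous to images from different vendors.
#'
#' @param speckle_scale positive multiplier of the speckle's relative
#'   fluctuation (coefficient of variation): 1 gives fully developed
#'   Rayleigh speckle (CV 0.52), larger values noisier texture. Defined
#'   relative to the local mean so that it survives per-image min-max
#'   normalization.
#' @param blur_sigma non-negative Gaussian point-spread sigma, in pixels.
#' @param gain positive multiplicative brightness applied after gamma.
#' @param gamma contrast exponent, must lie in `[0.5, 2]`.
#' @param layer_contrast amplitude in `[0, 1]` of the horizontal banding that
#'   mimics layered tissue.
#' @return an object of class `machine_profile`.
#' @export
machine_profile <- function(speckle_scale = 1, blur_sigma = 1, gain = 1,
                            gamma = 1, layer_contrast = 0.15) {
  assert_that(speckle_scale > 0, "speckle_scale must be positive")
  assert_that(blur_sigma >= 0, "blur_sigma must be non-negative")
  assert_that(gain > 0, "gain must be positive")
  assert_that(gamma >= 0.5 && gamma <= 2, "gamma must lie in [0.5, 2]")
  assert_that(layer_contrast >= 0 && layer_contrast <= 1,
              "layer_contrast must lie in [0, 1]")
  structure(list(speckle_scale = speckle_scale, blur_sigma = blur_sigma,
                 gain = gain, gamma = gamma, layer_contrast = layer_contrast),
            class = "machine_profile")
}

#' Default internal-institution machine profile
#' @return a `machine_profile`.
#' @export
internal_profile <- function() machine_profile()

#' Default external-institution machine profile
#'
#' Relative to [internal_profile()]: speckle scale x1.3, gamma 1.2 and an
#' extra 0.5 px of blur — enough to degrade, but not destroy, transfer of a
#' classifier trained on the internal profile.
#' @return a `machine_profile`.
#' @export
external_profile <- function() {
  machine_profile(speckle_scale = 1.3, blur_sigma = 1.5, gain = 1,
                  gamma = 1.2, layer_contrast = 0.15)
}

#' Render a speckled B-mode-like background
#'
#' Multiplicative Rayleigh speckle over a horizontally banded echogenicity
#' field, Gaussian-blurred, min–max normalized, then gamma- and
#' gain-adjusted. Deterministic given `(profile, seed)`.
#'
#' @param height,width image dimensions, each at least 32.
#' @param profile a [machine_profile()].
#' @param seed integer seed.
#' @return numeric matrix in `[0, 1]`.
#' @export
make_background <- function(height, width, profile = internal_profile(),
                            seed = 1) {
  assert_that(is.numeric(height) && is.numeric(width) &&
                height >= 32 && width >= 32,
              "image dimensions must be at least 32 x 32")
  stopifnot(inherits(profile, "machine_profile"))
  tex <- withr::with_seed(as.integer(seed), {
    u <- matrix(pmax(runif(height * width), 1e-12), height, width)
    ray <- sqrt(-2 * log(u))                  # Rayleigh(1) draws
    mu <- sqrt(pi / 2)
    spk <- pmax(1 + profile$speckle_scale * (ray - mu) / mu, 0)
    period <- runif(1, 0.15, 0.35) * height
    phase <- runif(1, 0, 2 * pi)
    band <- 1 + profile$layer_contrast * sin(2 * pi * seq_len(height) / period + phase)
    band * spk
  })
  if (profile$blur_sigma > 0) {
    tex <- matrix(as.numeric(EBImage::gblur(tex, sigma = profile$blur_sigma)),
                  height, width)
  }
  rng <- range(tex)
  tex <- (tex - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  clip01(profile$gain * tex^profile$gamma)
}

#' Specification of a single lesion
#'
#' Benign lesions are smooth ellipses (circumscribed, wider-than-tall, with
#' optional posterior enhancement); malignant lesions are star-shaped
#' spiculated regions (irregular margins, optional posterior shadowing).
#'
#' @param label `"benign"` or `"malignant"`.
#' @param center numeric `(row, col)` center, 1-based pixel coordinates.
#' @param semi_axes numeric pair `(along-rows, along-cols)` in pixels.
#' @param orientation rotation in radians.
#' @param spicule_count number of radial spicules; 0 for benign, >= 4 for
#'   malignant.
#' @param spicule_amplitude relative radial modulation amplitude in `[0, 1)`.
#' @param margin_sharpness edge ramp width in pixels (> 0); small values give
#'   sharp, angular margins.
#' @param echogenicity_offset relative hypoechoic contrast in `[-1, 0)`.
#' @param posterior_effect posterior acoustic feature in `[-1, 1]`: negative
#'   is shadowing (malignant), positive is enhancement (benign).
#' @return an object of class `lesion_spec`.
#' @export
lesion_spec <- function(label, center, semi_axes, orientation = 0,
                        spicule_count = 0, spicule_amplitude = 0,
                        margin_sharpness = 2, echogenicity_offset = -0.5,
                        posterior_effect = 0) {
  label <- match.arg(label, c("benign", "malignant"))
  assert_that(all(semi_axes > 0), "semi_axes must be positive")
  assert_that(spicule_count >= 0 && spicule_count == round(spicule_count),
              "spicule_count must be a non-negative integer")
  assert_that(spicule_amplitude >= 0 && spicule_amplitude < 1,
              "spicule_amplitude must lie in [0, 1)")
  assert_that(margin_sharpness > 0, "margin_sharpness must be positive")
  assert_that(echogenicity_offset >= -1 && echogenicity_offset < 0 ||
                echogenicity_offset == 0,
              "echogenicity_offset must lie in [-1, 0]")
  assert_that(posterior_effect >= -1 && posterior_effect <= 1,
              "posterior_effect must lie in [-1, 1]")
  if (label == "benign") {
    assert_that(spicule_count == 0, "benign lesions have no spicules")
    assert_that(posterior_effect >= 0,
                "benign lesions cannot have posterior shadowing")
  } else {
    assert_that(spicule_count >= 4, "malignant lesions need >= 4 spicules")
    assert_that(posterior_effect <= 0,
                "malignant lesions cannot have posterior enhancement")
  }
  structure(list(label = label, center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes), orientation = orientation,
                 spicule_count = as.integer(spicule_count),
                 spicule_amplitude = spicule_amplitude,
                 margin_sharpness = margin_sharpness,
                 echogenicity_offset = echogenicity_offset,
                 posterior_effect = posterior_effect),
            class = "lesion_spec")
}

#' Rasterize the binary mask of a lesion
#'
#' Benign: the rotated ellipse defined by `center`, `semi_axes` and
#' `orientation`. Malignant: a star-shaped region whose elliptical radius is
#' modulated by `spicule_count` sinusoidal radial perturbations of relative
#' amplitude `spicule_amplitude`. Star-shape about the center guarantees a
#' single connected component.
#'
#' @param spec a [lesion_spec()].
#' @param height,width image dimensions.
#' @return logical matrix.
#' @export
make_lesion_mask <- function(spec, height, width) {
  stopifnot(inherits(spec, "lesion_spec"))
  maxr <- max(spec$semi_axes) * (1 + spec$spicule_amplitude)
  ctr <- spec$center
  assert_that(ctr[1] - maxr >= 1 && ctr[1] + maxr <= height &&
                ctr[2] - maxr >= 1 && ctr[2] + maxr <= width,
              "lesion support exceeds image bounds")
  dx <- matrix(seq_len(height) - ctr[1], height, width)
  dy <- matrix(seq_len(width) - ctr[2], height, width, byrow = TRUE)
  co <- cos(spec$orientation); si <- sin(spec$orientation)
  u <- dx * co + dy * si
  v <- -dx * si + dy * co
  rho <- sqrt((u / spec$semi_axes[1])^2 + (v / spec$semi_axes[2])^2)
  bound <- 1
  if (spec$label == "malignant" && spec$spicule_amplitude > 0) {
    theta <- atan2(v, u)
    bound <- 1 + spec$spicule_amplitude * cos(spec$spicule_count * theta)
  }
  rho <= bound
}

#' Composite a lesion into a background
#'
#' Inside the mask the background intensity is reduced by
#' `echogenicity_offset` with a linear edge ramp of width `margin_sharpness`
#' (multiplicative, so speckle texture is preserved inside the lesion). A
#' soft-edged column from the lesion's bottom tangent to the image bottom is
#' darkened (shadowing) or brightened (enhancement) in proportion to
#' `posterior_effect`. With both effects zero the background is returned
#' unchanged.
#'
#' @param background numeric matrix in `[0, 1]`.
#' @param spec a [lesion_spec()].
#' @param mask logical matrix from [make_lesion_mask()].
#' @param seed reserved for stochastic texture variants; rendering is
#'   currently deterministic.
#' @return numeric matrix in `[0, 1]`.
#' @export
render_lesion <- function(background, spec, mask, seed = NULL) {
  assert_that(all(dim(background) == dim(mask)),
              "background and mask dimensions differ")
  out <- background
  if (spec$echogenicity_offset != 0 && any(mask)) {
    d <- matrix(as.numeric(EBImage::distmap(matrix(as.numeric(mask),
                                                   nrow(mask), ncol(mask)))),
                nrow(mask), ncol(mask))
    ramp <- pmin(d / spec$margin_sharpness, 1)
    out <- out * (1 + spec$echogenicity_offset * ramp)
  }
  if (spec$posterior_effect != 0 && any(mask)) {
    bb <- mask_bbox(mask)
    if (bb[2] < nrow(mask)) {
      w0 <- matrix(0, nrow(mask), ncol(mask))
      w0[(bb[2] + 1):nrow(mask), (bb[3] + 1):bb[4]] <- 1
      wsm <- matrix(as.numeric(EBImage::gblur(w0, sigma = 2)),
                    nrow(mask), ncol(mask))
      out <- out * (1 + 0.5 * spec$posterior_effect * wsm)
    }
  }
  clip01(out)
}

#' Sample a class-conditional lesion specification
#'
#' Draws one lesion from the default morphology archetypes using the current
#' RNG state. Mask diameters span roughly 10–50% of the image width.
#'
#' @param label `"benign"` or `"malignant"`.
#' @param height,width image dimensions.
#' @return a [lesion_spec()].
#' @export
sample_lesion_spec <- function(label, height, width) {
  label <- match.arg(label, c("benign", "malignant"))
  major <- runif(1, 0.10, 0.50) * width / 2
  if (label == "benign") {
    aspect <- runif(1, 0.50, 0.85)
    axes <- c(major * aspect, major)          # wider than tall
    orient <- runif(1, -pi / 12, pi / 12)
    k <- 0L; amp <- 0
    sharp <- min(runif(1, 3, 6), max(0.8, 0.5 * min(axes)))
    echo <- runif(1, -0.65, -0.35)
    post <- if (runif(1) < 0.5) 0 else runif(1, 0.2, 0.5)
  } else {
    aspect <- runif(1, 0.60, 1.00)
    axes <- c(major * aspect, major)
    orient <- runif(1, 0, pi)
    k <- sample(4:12, 1)
    amp <- runif(1, 0.15, 0.40)
    sharp <- runif(1, 0.8, 2)
    echo <- runif(1, -0.8, -0.5)
    post <- if (runif(1) < 0.5) 0 else runif(1, -0.6, -0.2)
  }
  maxr <- max(axes) * (1 + amp) + 2
  ctr <- c(runif(1, 1 + maxr, height - maxr), runif(1, 1 + maxr, width - maxr))
  lesion_spec(label, center = round(ctr), semi_axes = axes,
              orientation = orient, spicule_count = k, spicule_amplitude = amp,
              margin_sharpness = sharp, echogenicity_offset = echo,
              posterior_effect = post)
}

#' Dataset generation configuration
#'
#' Per-class counts default to the study composition: 500 training images per
#' class (of which 100 per class are flagged as the hyperparameter tuning
#' subset) and 100 per class in each validation split. The external
#' validation split is rendered with a different machine profile.
#'
#' @param n_train,n_tune,n_internal,n_external per-class counts; `n_tune`
#'   images per class are flagged inside the training split.
#' @param side square image side in pixels.
#' @param internal_profile,external_profile [machine_profile()]s for the
#'   training/internal splits and the external split.
#' @return an object of class `dataset_config`.
#' @export
dataset_config <- function(n_train = 500, n_tune = 100, n_internal = 100,
                           n_external = 100, side = 128,
                           internal_profile = uscam::internal_profile(),
                           external_profile = uscam::external_profile()) {
  assert_that(n_train > 0 && n_internal > 0 && n_external > 0,
              "per-class counts must be positive")
  assert_that(n_tune >= 0 && n_tune < n_train,
              "n_tune must be smaller than n_train")
  assert_that(side >= 32, "side must be at least 32")
  structure(list(n_train = n_train, n_tune = n_tune, n_internal = n_internal,
                 n_external = n_external, side = side,
                 internal_profile = internal_profile,
                 external_profile = external_profile),
            class = "dataset_config")
}

simulate_record <- function(label, split, profile, side, seed) {
  spec <- withr::with_seed(seed, sample_lesion_spec(label, side, side))
  bg <- make_background(side, side, profile,
                        seed = (seed + 77003L) %% .Machine$integer.max)
  mask <- make_lesion_mask(spec, side, side)
  img <- render_lesion(bg, spec, mask)
  bb <- mask_bbox(mask)
  list(label = label, split = split, tune = FALSE, seed = seed,
       pixels = img, mask = mask,
       lesion_size_px = max(bb[2] - bb[1], bb[4] - bb[3]))
}

#' Simulate a full phantom dataset in memory
#'
#' Pure function of `(config, seed)`: per-image seeds, lesion draws and the
#' tuning-subset assignment are all derived from the master seed.
#'
#' @param config a [dataset_config()].
#' @param seed master integer seed.
#' @return list with `records` (list of phantom records, each holding
#'   `pixels`, `mask`, `label`, `split`, `tune`, `lesion_size_px`, `seed`)
#'   and `manifest` (data frame, one row per record).
#' @export
simulate_dataset <- function(config = dataset_config(), seed = 1) {
  plan <- data.frame(
    split = rep(c("train", "internal_val", "external_val"),
                times = 2 * c(config$n_train, config$n_internal,
                              config$n_external)),
    label = c(rep(c("benign", "malignant"), each = config$n_train),
              rep(c("benign", "malignant"), each = config$n_internal),
              rep(c("benign", "malignant"), each = config$n_external)),
    stringsAsFactors = FALSE)
  seeds_tune <- withr::with_seed(as.integer(seed), {
    s <- sample.int(.Machine$integer.max - 77004L, nrow(plan))
    tn <- unlist(lapply(c("benign", "malignant"), function(lb) {
      idx <- which(plan$split == "train" & plan$label == lb)
      sample(idx, config$n_tune)
    }))
    list(s, tn)
  })
  records <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    prof <- if (plan$split[i] == "external_val") config$external_profile
            else config$internal_profile
    records[[i]] <- simulate_record(plan$label[i], plan$split[i], prof,
                                    config$side, seeds_tune[[1]][i])
    records[[i]]$id <- sprintf("%s_%s_%04d", plan$split[i],
                               substr(plan$label[i], 1, 3), i)
  }
  for (i in seeds_tune[[2]]) records[[i]]$tune <- TRUE
  list(records = records, manifest = manifest_from_records(records))
}

manifest_from_records <- function(records, paths = NULL) {
  df <- data.frame(
    id = vapply(records, `[[`, "", "id"),
    image = if (is.null(paths)) NA_character_ else paths$image,
    mask = if (is.null(paths)) NA_character_ else paths$mask,
    label = vapply(records, `[[`, "", "label"),
    split = vapply(records, `[[`, "", "split"),
    tune = vapply(records, `[[`, NA, "tune"),
    lesion_size_px = vapply(records, function(r) as.integer(r$lesion_size_px), 1L),
    seed = vapply(records, function(r) as.integer(r$seed), 1L),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Generate a phantom dataset on disk
#'
#' Writes one 8-bit grayscale PNG per image with a sibling `_mask.png`, plus
#' a `manifest.csv` with columns (id, image, mask, label, split, tune,
#' lesion_size_px, seed). Fully reproducible from the master seed.
#'
#' @param config a [dataset_config()].
#' @param out_dir output directory (created if missing).
#' @param seed master integer seed.
#' @return the manifest data frame, invisibly.
#' @export
generate_dataset <- function(config = dataset_config(), out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(out_dir), "cannot create output directory")
  sim <- simulate_dataset(config, seed)
  img_paths <- file.path(out_dir, paste0(vapply(sim$records, `[[`, "", "id"), ".png"))
  mask_paths <- sub("\\.png$", "_mask.png", img_paths)
  for (i in seq_along(sim$records)) {
    png::writePNG(round(sim$records[[i]]$pixels * 255) / 255, img_paths[i])
    png::writePNG(sim$records[[i]]$mask * 1, mask_paths[i])
  }
  manifest <- manifest_from_records(sim$records,
                                    paths = list(image = img_paths,
                                                 mask = mask_paths))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load a generated dataset back into memory
#'
#' @param dir directory containing `manifest.csv` as written by
#'   [generate_dataset()].
#' @return list with `records` and `manifest`, as in [simulate_dataset()].
#' @export
load_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(manifest)), function(i) {
    list(id = manifest$id[i], label = manifest$label[i],
         split = manifest$split[i], tune = manifest$tune[i],
         seed = manifest$seed[i],
         lesion_size_px = manifest$lesion_size_px[i],
         pixels = png::readPNG(manifest$image[i]),
         mask = png::readPNG(manifest$mask[i]) >= 0.5)
  })
  list(records = records, manifest = manifest)
}

#' Subset dataset records by split
#'
#' @param records list of phantom records.
#' @param split one of `"train"`, `"internal_val"`, `"external_val"`.
#' @param tune `NA` (default) keeps all records of the split; `TRUE`/`FALSE`
#'   keeps only the tuning subset / its complement (train split only).
#' @return list of records.
#' @export
split_records <- function(records, split, tune = NA) {
  keep <- vapply(records, function(r) {
    r$split == split && (is.na(tune) || identical(r$tune, tune))
  }, NA)
  records[keep]
}

# Flood-fill check that a mask is one 4-connected component (vectorized
# frontier dilation; used by tests and validation, not on the hot path).
single_component_4 <- function(mask) {
  if (!any(mask)) return(FALSE)
  seed_idx <- which(mask, arr.ind = TRUE)[1, ]
  reached <- matrix(FALSE, nrow(mask), ncol(mask))
  reached[seed_idx[1], seed_idx[2]] <- TRUE
  repeat {
    grown <- reached
    grown[-1, ] <- grown[-1, ] | reached[-nrow(mask), ]
    grown[-nrow(mask), ] <- grown[-nrow(mask), ] | reached[-1, ]
    grown[, -1] <- grown[, -1] | reached[, -ncol(mask)]
    grown[, -ncol(mask)] <- grown[, -ncol(mask)] | reached[, -1]
    grown <- grown & mask
    if (identical(grown, reached)) break
    reached <- grown
  }
  all(reached == mask)
}
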