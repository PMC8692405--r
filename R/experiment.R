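# Study orchestration: three supervision arms (weakly-supervised whole
# image; fully-supervised manual-ROI; fully-supervised automated-ROI), two
# validation splits (internal, external/domain-shifted), CAM localization
# scoring, and the pairwise statistical comparisons.

#' Study configuration
#'
#' @param dataset a [dataset_config()]; its defaults are the study
#'   composition (500+500 train with a 100+100 tuning subset, 100+100 per
#'   validation split).
#' @param model_config classifier architecture, shared by all arms.
#' @param classifier_train [training_config()] for both classifiers.
#' @param segmenter_train [training_config()] for the U-Net.
#' @param segmenter_channels U-Net base channels.
#' @param segmenter_n number of training images (drawn from the training
#'   split) used to fit the U-Net.
#' @param roi_margin ROI crop margin in pixels.
#' @param cam_threshold CAM binarization cut.
#' @param cam_policy localization class policy.
#' @param operating_threshold POM cut for sensitivity/specificity.
#' @return an object of class `study_config`.
#' @export
study_config <- function(dataset = dataset_config(),
                         model_config = gap_classifier_config(side = dataset$side),
                         classifier_train = training_config(epochs = 40L, lr = 3e-3,
                                                           weight_decay = 1e-3),
                         segmenter_train = training_config(batch_size = 8L,
                                                           epochs = 10L,
                                                           lr = 3e-3),
                         segmenter_channels = 8L, segmenter_n = 200L,
                         roi_margin = 30L, cam_threshold = 0.3,
                         cam_policy = "predicted",
                         operating_threshold = 0.5) {
  assert_that(model_config$side == dataset$side,
              "classifier input side must match the dataset side")
  structure(list(dataset = dataset, model_config = model_config,
                 classifier_train = classifier_train,
                 segmenter_train = segmenter_train,
                 segmenter_channels = as.integer(segmenter_channels),
                 segmenter_n = as.integer(segmenter_n),
                 roi_margin = as.integer(roi_margin),
                 cam_threshold = cam_threshold, cam_policy = cam_policy,
                 operating_threshold = operating_threshold),
            class = "study_config")
}

# Prepared-input array for a roster of records under one arm.
# pred_masks: list of predicted masks (full_auto arm), aligned with records.
arm_inputs <- function(records, arm, side, margin, pred_masks = NULL) {
  n_fallback <- 0L
  mats <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    if (arm == "weak") {
      resize_normalize(r$pixels, side = side, provenance = "whole_image")
    } else {
      msk <- if (arm == "full_manual") r$mask else pred_masks[[i]]
      if (arm == "full_auto" && sum(msk) == 0) {
        n_fallback <<- n_fallback + 1L
        resize_normalize(r$pixels, side = side, provenance = "roi_automated")
      } else {
        crop_roi(r$pixels, msk, margin = margin, side = side,
                 provenance = if (arm == "full_manual") "roi_manual"
                              else "roi_automated")
      }
    }
  })
  list(x = stack_images(mats), n_fallback = n_fallback)
}

# Chunked forward pass retaining feature maps for CAM reuse.
forward_collect <- function(model, x, chunk = 64L) {
  n <- dim(x)[4]
  pom <- numeric(n); p <- NULL; f <- NULL
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    fw <- forward_gap(model, x[, , , s:e, drop = FALSE])
    if (is.null(f)) {
      f <- array(0, c(dim(fw$f)[1:3], n))
      p <- matrix(0, n, ncol(fw$p))
    }
    f[, , , s:e] <- fw$f
    p[s:e, ] <- fw$p
    pom[s:e] <- fw$pom
  }
  list(pom = pom, p = p, f = f, W = model$params$head)
}

#' Evaluate one supervision arm on a roster
#'
#' The weak arm scores whole images and additionally runs CAM localization
#' against the ground-truth masks; `full_manual` crops with the ground-truth
#' mask (the phantom stand-in for manual annotation); `full_auto` crops with
#' the segmenter-predicted mask and reports the segmenter's Dice agreement.
#'
#' @param records validation records (identical roster across arms).
#' @param arm `"weak"`, `"full_manual"` or `"full_auto"`.
#' @param models list with `weak` and `roi` classifiers and, for
#'   `full_auto`, `segmenter` (or precomputed `pred_masks`).
#' @param config a [study_config()].
#' @return object of class `arm_evaluation`: `arm`, `pom`, `labels01`,
#'   `auc` ([roc_auc()] estimate), `sens_spec`, and arm-specific extras
#'   (`localization` outcomes + table for weak; `dsc` mean/sd and
#'   `n_fallback` for full_auto).
#' @export
run_arm <- function(records, arm, models, config = study_config()) {
  arm <- match.arg(arm, c("weak", "full_manual", "full_auto"))
  side <- config$model_config$side
  y <- label01(vapply(records, `[[`, "", "label"))
  pred_masks <- NULL
  dsc <- NULL
  if (arm == "full_auto") {
    if (!is.null(models$pred_masks)) {
      pred_masks <- models$pred_masks
    } else {
      assert_that(!is.null(models$segmenter), "full_auto needs a segmenter")
      xs <- stack_images(lapply(records, `[[`, "pixels"))
      pred_masks <- lapply(seq_along(records), function(i) {
        segment_masks(models$segmenter,
                      xs[, , , i, drop = FALSE])$mask[, , 1]
      })
    }
    dsc <- vapply(seq_along(records), function(i) {
      if (sum(pred_masks[[i]]) == 0) return(0)
      dice_coefficient(pred_masks[[i]], records[[i]]$mask)
    }, 0)
  }
  inp <- arm_inputs(records, arm, side, config$roi_margin, pred_masks)
  classifier <- if (arm == "weak") models$weak else models$roi
  fc <- forward_collect(classifier, inp$x)
  out <- list(arm = arm, n = length(records),
              ids = vapply(records, `[[`, "", "id"),
              pom = fc$pom, labels01 = y,
              auc = roc_auc(fc$pom, y),
              sens_spec = sens_spec(fc$pom, y, config$operating_threshold))
  if (arm == "weak") {
    d <- dim(fc$f)
    outcomes <- lapply(seq_along(records), function(i) {
      localize(list(p = fc$p[i, , drop = FALSE],
                    f = array(fc$f[, , , i], c(d[1:3], 1)), W = fc$W),
               records[[i]]$mask, records[[i]]$label,
               policy = config$cam_policy, threshold = config$cam_threshold,
               malignant_index = config$model_config$malignant_index)
    })
    out$localization <- outcomes
    out$localization_table <- localization_table(outcomes)
  }
  if (arm == "full_auto") {
    out$dsc <- c(mean = mean(dsc), sd = sd(dsc))
    out$dsc_per_case <- dsc
    out$n_fallback <- inp$n_fallback
  }
  structure(out, class = "arm_evaluation")
}

# Paired correctness at the operating point, restricted to one class.
paired_discordance <- function(eval1, eval2, class01, threshold) {
  idx <- eval1$labels01 == class01
  correct <- function(ev) {
    pos <- ev$pom[idx] >= threshold
    if (class01 == 1) pos else !pos
  }
  c1 <- correct(eval1); c2 <- correct(eval2)
  c(b = sum(c1 & !c2), c = sum(!c1 & c2))
}

#' Pairwise statistical comparison of the three arms
#'
#' DeLong tests on the AUC pairs (weak vs manual, weak vs automated), exact
#' McNemar tests on sensitivity (malignant cases) and specificity (benign
#' cases) at the operating threshold, and Fisher's exact test on the weak
#' arm's localization table.
#'
#' @param evals named list of [run_arm()] results: `weak`, `full_manual`,
#'   `full_auto`, all on the identical roster.
#' @param operating_threshold POM cut for correctness.
#' @return object of class `comparison_report` with `auc_table`,
#'   `metric_table`, `delong`, `mcnemar`, `fisher_localization`.
#' @export
compare_arms <- function(evals, operating_threshold = 0.5) {
  w <- evals$weak
  for (ev in evals) {
    assert_that(identical(ev$ids, w$ids), "arm rosters are not paired")
  }
  delong <- lapply(evals[c("full_manual", "full_auto")], function(ev) {
    delong_test(w$pom, ev$pom, w$labels01)
  })
  mcn <- lapply(evals[c("full_manual", "full_auto")], function(ev) {
    d_sens <- paired_discordance(w, ev, 1L, operating_threshold)
    d_spec <- paired_discordance(w, ev, 0L, operating_threshold)
    list(sensitivity = mcnemar_exact(d_sens["b"], d_sens["c"]),
         specificity = mcnemar_exact(d_spec["b"], d_spec["c"]),
         discordant = list(sensitivity = d_sens, specificity = d_spec))
  })
  fisher_p <- if (!is.null(w$localization_table)) {
    fisher_exact_2x2(w$localization_table)
  } else NA_real_
  auc_table <- data.frame(
    arm = names(evals),
    auc = vapply(evals, function(e) e$auc$auc, 0),
    ci_low = vapply(evals, function(e) e$auc$ci[1], 0),
    ci_high = vapply(evals, function(e) e$auc$ci[2], 0),
    row.names = NULL)
  metric_table <- data.frame(
    arm = names(evals),
    sensitivity = vapply(evals, function(e) e$sens_spec$sensitivity, 0),
    specificity = vapply(evals, function(e) e$sens_spec$specificity, 0),
    sens_str = vapply(evals, function(e) e$sens_spec$sens_str, ""),
    spec_str = vapply(evals, function(e) e$sens_spec$spec_str, ""),
    row.names = NULL)
  structure(list(auc_table = auc_table, metric_table = metric_table,
                 delong = list(weak_vs_manual = delong$full_manual,
                               weak_vs_auto = delong$full_auto),
                 mcnemar = list(weak_vs_manual = mcn$full_manual,
                                weak_vs_auto = mcn$full_auto),
                 fisher_localization = fisher_p,
                 localization_table = w$localization_table),
            class = "comparison_report")
}

#' Run the complete phantom study
#'
#' Simulates the dataset, trains the weakly-supervised classifier, the
#' ROI-cropped classifier and the U-Net segmenter on the training split only,
#' evaluates all three arms on both validation splits, scores CAM
#' localization, and runs every pairwise comparison. All randomness derives
#' from `seed`.
#'
#' @param config a [study_config()].
#' @param seed master integer seed.
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @param sim optional pre-simulated dataset (as from [simulate_dataset()])
#'   to reuse; must match `config$dataset`.
#' @return object of class `study_result`: `evals` (per split, per arm),
#'   `reports` (per split [compare_arms()]), `models`, `summary` (flat
#'   named list of headline numbers), `seed`.
#' @export
run_study <- function(config = study_config(), seed = 1L, out_dir = NULL,
                      sim = NULL) {
  side <- config$dataset$side
  if (is.null(sim)) sim <- simulate_dataset(config$dataset, seed = seed)
  rec <- sim$records
  train_fit <- split_records(rec, "train", tune = FALSE)
  train_tune <- split_records(rec, "train", tune = TRUE)
  vals <- list(internal_val = split_records(rec, "internal_val"),
               external_val = split_records(rec, "external_val"))
  train_all <- c(train_fit, train_tune)

  ids <- function(rs) vapply(rs, `[[`, "", "id")
  assert_that(length(intersect(ids(train_all),
                               unlist(lapply(vals, ids)))) == 0,
              "information leak: training and validation rosters intersect")

  # --- weakly-supervised classifier on whole images
  tcw <- config$classifier_train; tcw$seed <- as.integer(seed + 101L)
  xw <- arm_inputs(train_fit, "weak", side, config$roi_margin)$x
  yw <- label01(vapply(train_fit, `[[`, "", "label"))
  xt <- arm_inputs(train_tune, "weak", side, config$roi_margin)$x
  yt <- label01(vapply(train_tune, `[[`, "", "label"))
  weak <- train_classifier(xw, yw, xt, yt, config$model_config, tcw)

  # --- U-Net segmenter on a training subset
  seg_idx <- withr::with_seed(as.integer(seed + 202L),
                              sample(seq_along(train_all),
                                     min(config$segmenter_n,
                                         length(train_all))))
  tcs <- config$segmenter_train; tcs$seed <- as.integer(seed + 203L)
  seg_rec <- train_all[seg_idx]
  segmenter <- train_segmenter(
    stack_images(lapply(seg_rec, `[[`, "pixels")),
    stack_images(lapply(seg_rec, function(r) r$mask * 1)),
    tcs, base_channels = config$segmenter_channels)

  # --- ROI-cropped classifier (ground-truth masks stand in for manual
  #     annotation during training)
  tcr <- config$classifier_train; tcr$seed <- as.integer(seed + 303L)
  xr <- arm_inputs(train_fit, "full_manual", side, config$roi_margin)$x
  xrt <- arm_inputs(train_tune, "full_manual", side, config$roi_margin)$x
  roi <- train_classifier(xr, yw, xrt, yt, config$model_config, tcr)

  models <- list(weak = weak, roi = roi, segmenter = segmenter)

  evals <- lapply(vals, function(vr) {
    list(weak = run_arm(vr, "weak", models, config),
         full_manual = run_arm(vr, "full_manual", models, config),
         full_auto = run_arm(vr, "full_auto", models, config))
  })
  reports <- lapply(evals, compare_arms,
                    operating_threshold = config$operating_threshold)

  loc_rate <- function(ev, lb) {
    tab <- ev$localization_table
    tab[lb, "correct"] / sum(tab[lb, ])
  }
  summary <- list(
    auc_weak_internal = evals$internal_val$weak$auc$auc,
    auc_weak_external = evals$external_val$weak$auc$auc,
    auc_manual_internal = evals$internal_val$full_manual$auc$auc,
    auc_auto_internal = evals$internal_val$full_auto$auc$auc,
    delong_p_weak_vs_manual_internal = reports$internal_val$delong$weak_vs_manual$p,
    delong_p_weak_vs_manual_external = reports$external_val$delong$weak_vs_manual$p,
    localization_malignant_internal = loc_rate(evals$internal_val$weak, "malignant"),
    localization_benign_internal = loc_rate(evals$internal_val$weak, "benign"),
    localization_malignant_external = loc_rate(evals$external_val$weak, "malignant"),
    localization_benign_external = loc_rate(evals$external_val$weak, "benign"),
    fisher_p_internal = reports$internal_val$fisher_localization,
    fisher_p_external = reports$external_val$fisher_localization,
    dsc_mean_internal = unname(evals$internal_val$full_auto$dsc["mean"]),
    dsc_mean_external = unname(evals$external_val$full_auto$dsc["mean"]))

  result <- structure(list(evals = evals, reports = reports, models = models,
                           summary = summary, seed = seed, config = config),
                      class = "study_result")
  if (!is.null(out_dir)) write_study_artifacts(result, out_dir)
  result
}

#' Write study artifacts to a directory
#'
#' CSV report tables per split plus a machine-readable `results.json`
#' (floats rounded to 6 places for byte-stable reproducibility checks).
#'
#' @param result a `study_result`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_study_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (split in names(result$reports)) {
    rep <- result$reports[[split]]
    write.csv(rep$auc_table,
              file.path(out_dir, paste0("auc_", split, ".csv")),
              row.names = FALSE)
    write.csv(rep$metric_table,
              file.path(out_dir, paste0("metrics_", split, ".csv")),
              row.names = FALSE)
    write.csv(as.data.frame(rep$localization_table),
              file.path(out_dir, paste0("localization_", split, ".csv")))
    poms <- data.frame(id = result$evals[[split]]$weak$ids,
                       label = result$evals[[split]]$weak$labels01,
                       pom_weak = result$evals[[split]]$weak$pom,
                       pom_manual = result$evals[[split]]$full_manual$pom,
                       pom_auto = result$evals[[split]]$full_auto$pom)
    write.csv(poms, file.path(out_dir, paste0("pom_", split, ".csv")),
              row.names = FALSE)
  }
  json <- list(schema_version = "1.0", seed = result$seed,
               summary = lapply(result$summary, function(v) round(v, 6)))
  jsonlite::write_json(json, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
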