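# Class activation mapping and discriminative localization.
#
# M_c = sum_k w_{k,c} f_k at feature-map resolution, min-max scaled to
# M'_c, bilinearly upsampled to input resolution, binarized at
# M'_c >= 0.3 (inclusive), and scored as correct when the binary region
# overlaps the ground-truth lesion mask in at least one pixel.

#' Raw class activation map
#'
#' Merges the final-layer feature maps with the head weights of class `c`:
#' `M_c(i,j) = sum_k w_{k,c} f_k(i,j)`.
#'
#' @param f `(h, w, K)` feature maps of one image.
#' @param W `K x N_c` head weight matrix.
#' @param class_index 1-based class index.
#' @return `h x w` numeric matrix.
#' @export
compute_cam <- function(f, W, class_index) {
  d <- dim(f)
  assert_that(length(d) == 3 && d[3] == nrow(W), "feature/weight mismatch")
  assert_that(class_index >= 1 && class_index <= ncol(W),
              "invalid class index")
  matrix(matrix(f, d[1] * d[2], d[3]) %*% W[, class_index], d[1], d[2])
}

#' Min-max scale a CAM
#'
#' `M' = (M - min) / (max - min)`. A constant map cannot be scaled; it is
#' returned as all zeros with the `degenerate` attribute set.
#'
#' @param M numeric matrix.
#' @return matrix in `[0, 1]` with logical attribute `degenerate`.
#' @export
scale_cam <- function(M) {
  rng <- range(M)
  if (rng[2] - rng[1] < .Machine$double.eps * max(abs(rng), 1)) {
    out <- matrix(0, nrow(M), ncol(M))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (M - rng[1]) / (rng[2] - rng[1])
  attr(out, "degenerate") <- FALSE
  out
}

#' Upsample a scaled CAM to input resolution
#'
#' Bilinear interpolation with pixel-center alignment, clipped to `[0, 1]`.
#'
#' @param M numeric matrix (feature-map resolution).
#' @param side target side length, at least the source resolution.
#' @return `side x side` matrix in `[0, 1]`.
#' @export
upsample_cam <- function(M, side) {
  assert_that(side >= max(dim(M)), "target resolution below source")
  clip01(resize_bilinear(M, side, side))
}

#' Binarize a scaled CAM
#'
#' Inclusive comparison: a pixel is kept iff its value is `>= threshold`.
#'
#' @param M matrix with values in `[0, 1]`.
#' @param threshold cut in `[0, 1]` (default 0.3, the study's empirically
#'   chosen value).
#' @return logical matrix.
#' @export
binarize_cam <- function(M, threshold = 0.3) {
  assert_that(threshold >= 0 && threshold <= 1, "threshold must be in [0, 1]")
  M >= threshold
}

#' CAM pipeline for one image
#'
#' @param f `(h, w, K)` feature maps.
#' @param W head weight matrix.
#' @param class_index class whose CAM is computed.
#' @param side output resolution.
#' @param threshold binarization cut.
#' @return list of class `cam_result`: `raw`, `scaled`, `upsampled`,
#'   `binary`, `class_index`, `degenerate`.
#' @export
cam_result <- function(f, W, class_index, side, threshold = 0.3) {
  raw <- compute_cam(f, W, class_index)
  scaled <- scale_cam(raw)
  degen <- isTRUE(attr(scaled, "degenerate"))
  up <- upsample_cam(scaled, side)
  structure(list(raw = raw, scaled = scaled, upsampled = up,
                 binary = binarize_cam(up, threshold),
                 class_index = class_index, degenerate = degen),
            class = "cam_result")
}

#' Score discriminative localization for one image
#'
#' Chooses the class per `policy` (default: the predicted class), computes
#' the binarized CAM and counts overlap pixels with the ground-truth mask.
#' Localization is correct iff the overlap is at least one pixel; a
#' degenerate (constant) CAM is counted incorrect.
#'
#' @param forward output of [forward_gap()] for a single image (batch of 1).
#' @param gt_mask ground-truth binary mask at input resolution (nonempty).
#' @param true_label `"benign"` or `"malignant"`.
#' @param policy `"predicted"`, `"true_class"` or `"malignant"`.
#' @param threshold CAM binarization cut.
#' @param malignant_index 1-based malignant class index.
#' @return list of class `localization_outcome`: `true_label`,
#'   `evaluated_class`, `correct`, `overlap_px`, `degenerate`.
#' @export
localize <- function(forward, gt_mask, true_label,
                     policy = c("predicted", "true_class", "malignant"),
                     threshold = 0.3, malignant_index = 2L) {
  policy <- match.arg(policy)
  assert_that(any(gt_mask != 0), "empty ground-truth mask")
  cls <- switch(policy,
    predicted = which.max(forward$p[1, ]),
    true_class = if (true_label == "malignant") malignant_index
                 else setdiff(seq_len(ncol(forward$p)), malignant_index)[1],
    malignant = malignant_index)
  f1 <- array(forward$f, dim(forward$f)[1:3])   # batch of one
  cr <- cam_result(f1, forward$W, cls, side = nrow(gt_mask),
                   threshold = threshold)
  overlap <- sum(cr$binary & (gt_mask != 0))
  structure(list(true_label = true_label, evaluated_class = cls,
                 correct = overlap >= 1, overlap_px = overlap,
                 degenerate = cr$degenerate),
            class = "localization_outcome")
}

#' Localization contingency table
#'
#' Counts correct/incorrect localization by true class, in the layout fed to
#' Fisher's exact test (rows: benign, malignant; columns: correct,
#' incorrect).
#'
#' @param outcomes list of `localization_outcome`s covering both classes.
#' @return 2x2 integer matrix with dimnames.
#' @export
localization_table <- function(outcomes) {
  labs <- vapply(outcomes, `[[`, "", "true_label")
  corr <- vapply(outcomes, `[[`, NA, "correct")
  tab <- matrix(0L, 2, 2,
                dimnames = list(c("benign", "malignant"),
                                c("correct", "incorrect")))
  for (lb in c("benign", "malignant")) {
    tab[lb, "correct"] <- sum(labs == lb & corr)
    tab[lb, "incorrect"] <- sum(labs == lb & !corr)
  }
  tab
}

#' Export a CAM heatmap overlay as PNG
#'
#' Grayscale image in the red channel plus the upsampled CAM in green —
#' a lightweight qualitative-review composite.
#'
#' @param pixels grayscale image matrix in `[0, 1]`.
#' @param cam upsampled CAM matrix in `[0, 1]`, same shape.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_cam_overlay <- function(pixels, cam, path) {
  rgb <- array(0, c(nrow(pixels), ncol(pixels), 3))
  rgb[, , 1] <- pixels
  rgb[, , 2] <- clip01(0.6 * pixels + 0.4 * cam)
  rgb[, , 3] <- pixels * (1 - 0.5 * cam)
  png::writePNG(rgb, path)
  invisible(path)
}
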