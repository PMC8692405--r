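# Input preparation for the two supervision pathways: whole-image
# resize+normalize (weakly-supervised arm) and mask-driven square ROI
# cropping with a fixed 30-pixel margin (fully-supervised arms).

#' Resize and max-normalize an image
#'
#' Bilinear resize to `side x side`, then division by the post-resize maximum
#' so the output maximum is exactly 1.
#'
#' @param pixels numeric matrix with at least one nonzero pixel.
#' @param side target side length in pixels (the clinical recipe used 224;
#'   desk-scale phantom runs default to 128 elsewhere).
#' @param provenance one of `"whole_image"`, `"roi_manual"`,
#'   `"roi_automated"`; recorded as an attribute.
#' @return numeric `side x side` matrix in `[0, 1]` with max exactly 1 and a
#'   `provenance` attribute.
#' @export
resize_normalize <- function(pixels, side = 224, provenance = "whole_image") {
  assert_that(is.matrix(pixels) && length(pixels) > 0, "pixels must be a matrix")
  assert_that(any(pixels > 0), "cannot normalize an all-zero image")
  out <- if (nrow(pixels) == side && ncol(pixels) == side) pixels
         else resize_bilinear(pixels, side, side)
  out <- out / max(out)
  attr(out, "provenance") <- provenance
  out
}

#' Tight bounding box of a binary mask
#'
#' @param mask logical or 0/1 matrix with at least one true pixel.
#' @return integer vector `(row_min, row_max, col_min, col_max)`, 0-based
#'   half-open: rows `row_min <= r < row_max` are covered.
#' @export
mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  assert_that(nrow(idx) > 0, "mask is empty")
  c(min(idx[, 1]) - 1L, max(idx[, 1]), min(idx[, 2]) - 1L, max(idx[, 2]))
}

#' Square ROI crop around a lesion mask
#'
#' Expands the mask bounding box by `margin` pixels on all sides, pads the
#' shorter dimension symmetrically to a square, clips to the image bounds
#' (accepting a non-square crop at borders), crops, and applies
#' [resize_normalize()].
#'
#' @param pixels numeric matrix.
#' @param mask binary matrix, same shape.
#' @param margin margin in pixels added around the bounding box (default 30).
#' @param side output side length.
#' @param provenance recorded on the output (default `"roi_manual"`).
#' @return normalized `side x side` matrix.
#' @export
crop_roi <- function(pixels, mask, margin = 30, side = 224,
                     provenance = "roi_manual") {
  assert_that(all(dim(pixels) == dim(mask)), "pixels/mask dimensions differ")
  bb <- mask_bbox(mask)
  r1 <- bb[1] - margin; r2 <- bb[2] + margin
  c1 <- bb[3] - margin; c2 <- bb[4] + margin
  hh <- r2 - r1; ww <- c2 - c1
  if (hh < ww) {
    extra <- ww - hh
    r1 <- r1 - floor(extra / 2); r2 <- r2 + ceiling(extra / 2)
  } else if (ww < hh) {
    extra <- hh - ww
    c1 <- c1 - floor(extra / 2); c2 <- c2 + ceiling(extra / 2)
  }
  r1 <- max(r1, 0L); c1 <- max(c1, 0L)
  r2 <- min(r2, nrow(pixels)); c2 <- min(c2, ncol(pixels))
  assert_that(r2 - r1 >= 8 && c2 - c1 >= 8, "ROI crop degenerated below 8 x 8")
  crop <- pixels[(r1 + 1):r2, (c1 + 1):c2, drop = FALSE]
  resize_normalize(crop, side = side, provenance = provenance)
}
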