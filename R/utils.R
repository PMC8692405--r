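# Shared small helpers: resizing, clipping, array plumbing.

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Bilinear resize of a numeric matrix
#'
#' Thin wrapper around [EBImage::resize()] with bilinear filtering and
#' pixel-center alignment.
#'
#' @param x numeric matrix.
#' @param height,width target dimensions (rows, columns).
#' @return numeric matrix of size `height x width`.
#' @keywords internal
resize_bilinear <- function(x, height, width) {
  y <- EBImage::resize(x, w = height, h = width, filter = "bilinear")
  matrix(as.numeric(y), nrow = height, ncol = width)
}

# Nearest-neighbour resize; preserves binary masks exactly.
resize_nearest <- function(x, height, width) {
  y <- EBImage::resize(x, w = height, h = width, filter = "none")
  matrix(as.numeric(y), nrow = height, ncol = width)
}

# Stack a list of equally-sized matrices into an (H, W, 1, N) array.
stack_images <- function(mats) {
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])
  array(unlist(mats, use.names = FALSE), dim = c(h, w, 1, length(mats)))
}

# 0/1 integer labels (1 = malignant) from a character/factor vector.
label01 <- function(labels) as.integer(as.character(labels) == "malignant")

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
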