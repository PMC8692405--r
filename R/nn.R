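# Low-level neural-network plumbing shared by the GAP classifier and the
# U-Net: He initialization, the Adam optimizer, and array helpers. Conv
# forward/backward kernels live in src/conv.cpp (im2col + BLAS gemm).

#' He (fan-in, rectifier-scaled) weight initialization
#'
#' Draws `N(0, 2/fan_in)` weights, the standard initialization for
#' ReLU networks, using the current RNG state.
#'
#' @param dims integer dimensions of the parameter array; for a conv filter
#'   `(kh, kw, c_in, c_out)` the fan-in is `kh*kw*c_in`, for a dense matrix
#'   `(k_in, k_out)` it is `k_in`.
#' @return numeric array of the given dimensions.
#' @export
he_init <- function(dims) {
  fan_in <- prod(dims[-length(dims)])
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

conv_fwd <- function(x, w, stride = 1L, pad = 1L, bias = NULL) {
  y <- conv2d_fwd(x, w, as.integer(stride), as.integer(pad))
  if (!is.null(bias)) {
    d <- dim(y)
    y <- y + rep(rep(bias, each = d[1] * d[2]), d[4])
    dim(y) <- d
  }
  y
}

# Gradient of the per-channel conv bias: sum of dz over space and batch.
bias_grad <- function(dz) {
  d <- dim(dz)
  rowSums(matrix(colSums(matrix(dz, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
}

conv_bwd <- function(x, w, dy, stride = 1L, pad = 1L) {
  conv2d_bwd(x, w, dy, as.integer(stride), as.integer(pad))
}

# 2x nearest-neighbour upsampling of an (H, W, C, N) array, and its adjoint.
upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  o1 <- seq(1, d[1], 2); e1 <- seq(2, d[1], 2)
  o2 <- seq(1, d[2], 2); e2 <- seq(2, d[2], 2)
  dy[o1, o2, , , drop = FALSE] + dy[e1, o2, , , drop = FALSE] +
    dy[o1, e2, , , drop = FALSE] + dy[e1, e2, , , drop = FALSE]
}

# Adam state and update. `params` and `grads` are named lists of arrays.
adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Sum of squares over a list of parameter arrays (L2 penalty term).
l2_norm2 <- function(params) sum(vapply(params, function(p) sum(p * p), 0))
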