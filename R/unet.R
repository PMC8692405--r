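# Small U-Net-style encoder-decoder for automated lesion segmentation
# (the "automated annotation" arm). Depth 3 (two stride-2 downsamplings plus
# a bottleneck), nearest-neighbour upsampling, skip connections by channel
# concatenation, sigmoid output head, BCE + soft-Dice loss.

#' U-Net configuration and initialization
#'
#' @param base_channels channels of the first encoder level; doubled at each
#'   downsampling.
#' @param side input side length; must be divisible by 4.
#' @param seed He-initialization seed.
#' @return an object of class `unet`.
#' @export
init_unet <- function(base_channels = 8L, side = 128L, seed = 1L) {
  assert_that(side %% 4 == 0, "side must be divisible by 4")
  C <- as.integer(base_channels)
  shapes <- list(
    enc1a = c(3L, 3L, 1L, C),      enc1b = c(3L, 3L, C, C),
    down1 = c(3L, 3L, C, 2L * C),  enc2 = c(3L, 3L, 2L * C, 2L * C),
    down2 = c(3L, 3L, 2L * C, 4L * C), bott = c(3L, 3L, 4L * C, 4L * C),
    up2 = c(3L, 3L, 4L * C, 2L * C), dec2 = c(3L, 3L, 4L * C, 2L * C),
    up1 = c(3L, 3L, 2L * C, C),    dec1 = c(3L, 3L, 2L * C, C),
    out = c(1L, 1L, C, 1L))
  model <- structure(list(base_channels = C, side = as.integer(side),
                          shapes = shapes, params = NULL),
                     class = "unet")
  init_weights(model, seed)
}

concat_ch <- function(a, b) {
  da <- dim(a)
  out <- array(0, c(da[1], da[2], da[3] + dim(b)[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(dim(b)[3]), ] <- b
  out
}

unet_forward_full <- function(model, x) {
  p <- model$params
  cv <- function(a, nm, s = 1L, pd = 1L) {
    conv_fwd(a, p[[nm]], stride = s, pad = pd, bias = p[[paste0("b_", nm)]])
  }
  x <- x - 0.5   # center the [0,1] input
  z1 <- cv(x, "enc1a");  a1 <- relu(z1)
  z2 <- cv(a1, "enc1b"); a2 <- relu(z2)
  z3 <- cv(a2, "down1", 2L); a3 <- relu(z3)
  z4 <- cv(a3, "enc2");  a4 <- relu(z4)
  z5 <- cv(a4, "down2", 2L); a5 <- relu(z5)
  z6 <- cv(a5, "bott");  a6 <- relu(z6)
  u2 <- upsample2(a6)
  z7 <- cv(u2, "up2");   a7 <- relu(z7)
  c2 <- concat_ch(a7, a4)
  z8 <- cv(c2, "dec2");  a8 <- relu(z8)
  u1 <- upsample2(a8)
  z9 <- cv(u1, "up1");   a9 <- relu(z9)
  c1 <- concat_ch(a9, a2)
  z10 <- cv(c1, "dec1"); a10 <- relu(z10)
  zo <- cv(a10, "out", 1L, 0L)
  prob <- 1 / (1 + exp(-zo))
  list(prob = prob, z1 = z1, a1 = a1, z2 = z2, a2 = a2, z3 = z3, a3 = a3,
       z4 = z4, a4 = a4, z5 = z5, a5 = a5, z6 = z6, a6 = a6, u2 = u2,
       z7 = z7, c2 = c2, z8 = z8, u1 = u1, z9 = z9, c1 = c1, z10 = z10,
       a8 = a8, a10 = a10, x = x)
}

unet_backward <- function(model, fw, dzo) {
  p <- model$params
  C <- model$base_channels
  g <- list()
  bo <- conv_bwd(fw$a10, p$out, dzo, 1L, 0L)
  g$out <- bo$dw
  g$b_out <- bias_grad(dzo)
  dz10 <- bo$dx * (fw$z10 > 0)
  b10 <- conv_bwd(fw$c1, p$dec1, dz10)
  g$dec1 <- b10$dw
  g$b_dec1 <- bias_grad(dz10)
  da9 <- b10$dx[, , seq_len(C), , drop = FALSE]
  da2s <- b10$dx[, , C + seq_len(C), , drop = FALSE]
  dz9 <- da9 * (fw$z9 > 0)
  b9 <- conv_bwd(fw$u1, p$up1, dz9)
  g$up1 <- b9$dw
  g$b_up1 <- bias_grad(dz9)
  da8 <- upsample2_bwd(b9$dx)
  dz8 <- da8 * (fw$z8 > 0)
  b8 <- conv_bwd(fw$c2, p$dec2, dz8)
  g$dec2 <- b8$dw
  g$b_dec2 <- bias_grad(dz8)
  da7 <- b8$dx[, , seq_len(2L * C), , drop = FALSE]
  da4s <- b8$dx[, , 2L * C + seq_len(2L * C), , drop = FALSE]
  dz7 <- da7 * (fw$z7 > 0)
  b7 <- conv_bwd(fw$u2, p$up2, dz7)
  g$up2 <- b7$dw
  g$b_up2 <- bias_grad(dz7)
  da6 <- upsample2_bwd(b7$dx)
  dz6 <- da6 * (fw$z6 > 0)
  b6 <- conv_bwd(fw$a5, p$bott, dz6)
  g$bott <- b6$dw
  g$b_bott <- bias_grad(dz6)
  dz5 <- b6$dx * (fw$z5 > 0)
  b5 <- conv_bwd(fw$a4, p$down2, dz5, stride = 2L)
  g$down2 <- b5$dw
  g$b_down2 <- bias_grad(dz5)
  da4 <- b5$dx + da4s
  dz4 <- da4 * (fw$z4 > 0)
  b4 <- conv_bwd(fw$a3, p$enc2, dz4)
  g$enc2 <- b4$dw
  g$b_enc2 <- bias_grad(dz4)
  dz3 <- b4$dx * (fw$z3 > 0)
  b3 <- conv_bwd(fw$a2, p$down1, dz3, stride = 2L)
  g$down1 <- b3$dw
  g$b_down1 <- bias_grad(dz3)
  da2 <- b3$dx + da2s
  dz2 <- da2 * (fw$z2 > 0)
  b2 <- conv_bwd(fw$a1, p$enc1b, dz2)
  g$enc1b <- b2$dw
  g$b_enc1b <- bias_grad(dz2)
  dz1 <- b2$dx * (fw$z1 > 0)
  b1 <- conv_bwd(fw$x, p$enc1a, dz1)
  g$enc1a <- b1$dw
  g$b_enc1a <- bias_grad(dz1)
  g
}

# BCE + soft-Dice loss and its gradient w.r.t. the pre-sigmoid output.
unet_loss_grad <- function(prob, target) {
  d <- dim(prob)
  N <- d[4]; npix <- prod(d[1:3])
  eps <- 1e-7
  pcl <- pmin(pmax(prob, eps), 1 - eps)
  bce <- -mean(target * log(pcl) + (1 - target) * log(1 - pcl))
  dz <- (prob - target) / (npix * N)
  dice_terms <- numeric(N)
  for (n in seq_len(N)) {
    pn <- prob[, , , n]; gn <- target[, , , n]
    sp <- sum(pn); sg <- sum(gn); spg <- sum(pn * gn)
    den <- sp + sg + eps
    dice_terms[n] <- (2 * spg + eps) / den
    ddp <- -(2 * gn * den - (2 * spg + eps)) / den^2 / N
    dz[, , , n] <- dz[, , , n] + ddp * pn * (1 - pn)
  }
  list(loss = bce + mean(1 - dice_terms), dz = dz,
       mean_dice = mean(dice_terms))
}

#' Train the U-Net segmenter
#'
#' BCE + soft-Dice loss, Adam with the same optimizer constants as the
#' classifier. Every training mask must be nonempty.
#'
#' @param x `(side, side, 1, N)` input images.
#' @param masks `(side, side, 1, N)` binary target masks.
#' @param train_config a [training_config()]; `batch_size` is typically
#'   reduced (default here 8) because full-resolution feature maps dominate
#'   memory.
#' @param base_channels first-level channel count.
#' @return a trained `unet` with attached `log`.
#' @export
train_segmenter <- function(x, masks,
                            train_config = training_config(batch_size = 8L,
                                                           epochs = 8L),
                            base_channels = 8L) {
  assert_that(identical(dim(x), dim(masks)), "image/mask dimensions differ")
  per_img <- colSums(matrix(masks, prod(dim(masks)[1:3]), dim(masks)[4]))
  assert_that(all(per_img > 0), "all-background target masks are degenerate")
  tc <- train_config
  model <- init_unet(base_channels, side = dim(x)[1], seed = tc$seed)
  state <- adam_init(model$params)
  n <- dim(x)[4]
  log <- data.frame(epoch = integer(), loss = numeric(), dice = numeric())
  withr::with_seed(tc$seed + 1L, {
    for (ep in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      losses <- c(); dices <- c()
      for (s in seq(1, n, by = tc$batch_size)) {
        idx <- ord[s:min(s + tc$batch_size - 1, n)]
        fw <- unet_forward_full(model, x[, , , idx, drop = FALSE])
        lg <- unet_loss_grad(fw$prob, masks[, , , idx, drop = FALSE])
        grads <- unet_backward(model, fw, lg$dz)
        if (tc$weight_decay > 0) {
          for (nm in names(grads)) {
            if (!startsWith(nm, "b_")) {
              grads[[nm]] <- grads[[nm]] + 2 * tc$weight_decay * model$params[[nm]]
            }
          }
        }
        up <- adam_step(model$params, grads, state, lr = tc$lr,
                        beta1 = tc$beta1, beta2 = tc$beta2)
        model$params <- up$params
        state <- up$state
        losses <- c(losses, lg$loss); dices <- c(dices, lg$mean_dice)
      }
      log <- rbind(log, data.frame(epoch = ep, loss = mean(losses),
                                   dice = mean(dices)))
    }
  })
  model$log <- log
  model
}

#' Segment images with a trained U-Net
#'
#' @param model a trained `unet`.
#' @param x `(side, side, 1, N)` array or a single matrix.
#' @param threshold probability cut for the binary mask (default 0.5).
#' @param chunk images per forward chunk.
#' @return list with `prob` (`(side, side, N)` probability maps in `[0, 1]`)
#'   and `mask` (logical array, `prob >= threshold`).
#' @export
segment_masks <- function(model, x, threshold = 0.5, chunk = 32L) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  n <- dim(x)[4]
  prob <- array(0, c(dim(x)[1], dim(x)[2], n))
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    fw <- unet_forward_full(model, x[, , , s:e, drop = FALSE])
    prob[, , s:e] <- fw$prob[, , 1, ]
  }
  list(prob = prob, mask = prob >= threshold)
}
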