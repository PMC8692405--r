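# GAP-headed convolutional classifier.
#
# The head follows the study's four equations exactly: the final conv layer's
# feature maps f_k are pooled into feature scores F_k (spatial sum by
# default), a bias-free fully-connected layer gives class scores
# S_c = sum_k w_{k,c} F_k, softmax yields p_c, and the probability of
# malignancy (POM) is the malignant-class probability. The bias-free head
# makes the class activation map an exact decomposition of S_c.

#' GAP classifier configuration
#'
#' @param backbone `"tiny"` (the desk-scale default: stride-2 conv blocks
#'   with ReLU) — the only backbone trainable in this stack; named
#'   large-scale backbones are out of scope and rejected.
#' @param channels integer vector of conv block output channels; the last
#'   entry is K, the number of feature maps feeding the GAP head.
#' @param strides per-block conv strides (default: stride 2 everywhere,
#'   halving resolution per block).
#' @param num_classes number of classes (2).
#' @param malignant_index 1-based index of the malignant class.
#' @param side input side length in pixels.
#' @param pool `"sum"` (the printed GAP equation) or `"mean"`; the two differ
#'   only by a constant factor absorbable into the head weights.
#' @return an object of class `gap_classifier_config`.
#' @export
gap_classifier_config <- function(backbone = "tiny",
                                  channels = c(8L, 16L, 32L, 32L),
                                  strides = c(2L, 2L, 2L, 2L),
                                  num_classes = 2L, malignant_index = 2L,
                                  side = 128L, pool = c("sum", "mean")) {
  if (!identical(backbone, "tiny")) {
    stop("only the 'tiny' backbone is available; large pretrained backbones ",
         "are out of scope at desk scale", call. = FALSE)
  }
  pool <- match.arg(pool)
  assert_that(malignant_index >= 1 && malignant_index <= num_classes,
              "malignant_index out of range")
  assert_that(length(strides) == length(channels),
              "strides and channels must have equal length")
  assert_that(side %% prod(strides) == 0,
              "side must be divisible by the product of strides")
  structure(list(backbone = backbone, channels = as.integer(channels),
                 strides = as.integer(strides),
                 K = as.integer(channels[length(channels)]),
                 num_classes = as.integer(num_classes),
                 malignant_index = as.integer(malignant_index),
                 side = as.integer(side), pool = pool),
            class = "gap_classifier_config")
}

#' Training recipe
#'
#' Defaults follow the study's printed recipe: L2 regularization, batch size
#' 64, Adam with learning rate 0.001, beta 0.9 and beta2 0.999, He
#' initialization.
#'
#' @param batch_size minibatch size.
#' @param lr Adam learning rate (eta).
#' @param beta1,beta2 Adam moment decay rates.
#' @param epochs number of passes over the training set; the returned model
#'   is the best-tune-AUC snapshot.
#' @param weight_decay L2 penalty coefficient lambda (loss adds
#'   `lambda * sum(w^2)`).
#' @param seed integer seed for initialization and shuffling.
#' @return an object of class `training_config`.
#' @export
training_config <- function(batch_size = 64L, lr = 1e-3, beta1 = 0.9,
                            beta2 = 0.999, epochs = 15L, weight_decay = 1e-4,
                            seed = 1L) {
  structure(list(batch_size = as.integer(batch_size), lr = lr, beta1 = beta1,
                 beta2 = beta2, epochs = as.integer(epochs),
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "training_config")
}

#' Global average pooling as a spatial sum
#'
#' Collapses each feature map to one feature score, `F_k = sum_{i,j}
#' f_k(i,j)` (the printed equation; `pool = "mean"` divides by the number of
#' spatial positions).
#'
#' @param f feature maps: `(h, w, K)` array for one input or `(h, w, K, N)`
#'   for a batch.
#' @param pool `"sum"` or `"mean"`.
#' @return numeric vector of length K, or an `N x K` matrix for a batch.
#' @export
global_average_pool <- function(f, pool = "sum") {
  d <- dim(f)
  assert_that(length(d) %in% c(3, 4) && all(d > 0), "f must be (h, w, K[, N])")
  K <- d[3]; N <- if (length(d) == 4) d[4] else 1L
  s <- colSums(matrix(f, d[1] * d[2], K * N))
  if (pool == "mean") s <- s / (d[1] * d[2])
  if (length(d) == 3) s else t(matrix(s, K, N))
}

#' Bias-free class scores
#'
#' `S_c = sum_k w_{k,c} F_k`; no bias term, so the class activation map
#' explains the class score exactly.
#'
#' @param F feature scores: length-K vector or `N x K` matrix.
#' @param W `K x N_c` head weight matrix.
#' @return length-`N_c` vector or `N x N_c` matrix.
#' @export
class_scores <- function(F, W) {
  if (is.matrix(F)) {
    assert_that(ncol(F) == nrow(W), "feature/weight dimension mismatch")
    F %*% W
  } else {
    assert_that(length(F) == nrow(W), "feature/weight dimension mismatch")
    as.numeric(F %*% W)
  }
}

#' Softmax probabilities and probability of malignancy
#'
#' Numerically stable softmax (max subtraction); POM is the probability at
#' `malignant_index`.
#'
#' @param S class scores: vector or `N x N_c` matrix.
#' @param malignant_index 1-based malignant class index.
#' @return list with `p` (same shape as `S`) and `pom`.
#' @export
softmax_pom <- function(S, malignant_index = 2L) {
  Sm <- if (is.matrix(S)) S else matrix(S, 1)
  assert_that(all(is.finite(Sm)), "class scores must be finite")
  z <- exp(Sm - apply(Sm, 1, max))
  p <- z / rowSums(z)
  pom <- p[, malignant_index]
  if (!is.matrix(S)) p <- as.numeric(p)
  list(p = p, pom = as.numeric(pom))
}

#' Initialize a GAP classifier
#'
#' @param config a [gap_classifier_config()].
#' @param seed integer seed for He initialization.
#' @return an object of class `gap_classifier` holding `config` and `params`.
#' @export
init_gap_classifier <- function(config = gap_classifier_config(), seed = 1L) {
  model <- structure(list(config = config, params = NULL),
                     class = "gap_classifier")
  init_weights(model, seed)
}

#' (Re-)initialize model weights with the He scheme
#'
#' Deterministic per seed: conv filters and the head matrix are drawn from
#' `N(0, 2/fan_in)`.
#'
#' @param model a `gap_classifier` or `unet` model.
#' @param seed integer seed.
#' @return the model with freshly drawn parameters.
#' @export
init_weights <- function(model, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    if (inherits(model, "gap_classifier")) {
      cfg <- model$config
      cin <- c(1L, cfg$channels[-length(cfg$channels)])
      params <- list()
      for (b in seq_along(cfg$channels)) {
        params[[paste0("conv", b)]] <- he_init(c(3L, 3L, cin[b], cfg$channels[b]))
        params[[paste0("bias", b)]] <- numeric(cfg$channels[b])
      }
      # He w.r.t. the pooled features: under sum pooling the feature scores
      # carry an extra factor of the pooled area, so the head init absorbs
      # it to keep initial logits O(1) (the constant is absorbable into W).
      hw <- (cfg$side / prod(cfg$strides))^2
      params$head <- he_init(c(cfg$K, cfg$num_classes)) /
        (if (cfg$pool == "sum") hw else 1)
      model$params <- params
    } else if (inherits(model, "unet")) {
      prm <- lapply(model$shapes, he_init)
      for (nm in names(model$shapes)) {
        prm[[paste0("b_", nm)]] <- numeric(model$shapes[[nm]][4])
      }
      model$params <- prm
    } else {
      stop("unknown model class", call. = FALSE)
    }
  })
  model
}

# Backbone forward pass; returns final feature maps plus per-block caches.
backbone_forward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$config
  cache <- if (keep_cache) vector("list", length(cfg$channels)) else NULL
  a <- x - 0.5   # center the [0,1] input
  for (b in seq_along(cfg$channels)) {
    z <- conv_fwd(a, model$params[[paste0("conv", b)]],
                  stride = cfg$strides[b], pad = 1L,
                  bias = model$params[[paste0("bias", b)]])
    if (keep_cache) cache[[b]] <- list(input = a, pre = z)
    a <- relu(z)
  }
  list(f = a, cache = cache)
}

#' Forward pass of the GAP classifier
#'
#' Returns every intermediate of the equation chain so the CAM module can
#' reuse the feature maps and head weights without recomputation.
#'
#' @param model a trained or initialized `gap_classifier`.
#' @param x input: a single `side x side` matrix or an `(side, side, 1, N)`
#'   array of prepared inputs.
#' @param keep_cache keep per-block activations (training internals).
#' @return list with `f` (feature maps, `(h, w, K, N)`), `F` (`N x K`
#'   feature scores), `S` (`N x N_c` class scores), `p` (probabilities),
#'   `pom` (length-N vector) and `W` (the head matrix).
#' @export
forward_gap <- function(model, x, keep_cache = FALSE) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  assert_that(dim(x)[1] == model$config$side && dim(x)[2] == model$config$side,
              "input side does not match model config")
  bk <- backbone_forward(model, x, keep_cache)
  F <- global_average_pool(bk$f, pool = model$config$pool)
  if (!is.matrix(F)) F <- matrix(F, 1)
  S <- class_scores(F, model$params$head)
  sp <- softmax_pom(S, model$config$malignant_index)
  list(f = bk$f, F = F, S = S, p = sp$p, pom = sp$pom,
       W = model$params$head, cache = bk$cache)
}

#' Predict probability of malignancy for a batch
#'
#' @param model a `gap_classifier`.
#' @param x `(side, side, 1, N)` array.
#' @param chunk number of images per forward chunk (memory control).
#' @return numeric vector of POMs.
#' @export
predict_pom <- function(model, x, chunk = 128L) {
  n <- dim(x)[4]
  out <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    out[s:e] <- forward_gap(model, x[, , , s:e, drop = FALSE])$pom
  }
  out
}

# One minibatch gradient step; returns grads and the batch loss.
gap_batch_grads <- function(model, xb, yb, lambda) {
  cfg <- model$config
  fw <- forward_gap(model, xb, keep_cache = TRUE)
  B <- dim(xb)[4]
  Y <- matrix(0, B, cfg$num_classes)
  Y[cbind(seq_len(B), ifelse(yb == 1L, cfg$malignant_index,
                             setdiff(seq_len(cfg$num_classes),
                                     cfg$malignant_index)[1]))] <- 1
  eps <- 1e-12
  wts <- model$params[!startsWith(names(model$params), "bias")]
  loss <- -mean(log(rowSums(fw$p * Y) + eps)) + lambda * l2_norm2(wts)
  dS <- (fw$p - Y) / B
  grads <- list(head = crossprod(fw$F, dS) + 2 * lambda * model$params$head)
  dF <- dS %*% t(model$params$head)                       # B x K
  d <- dim(fw$f)
  hw <- d[1] * d[2]
  scale <- if (cfg$pool == "mean") 1 / hw else 1
  df <- array(rep(as.vector(t(dF)) * scale, each = hw), dim = d)
  da <- df
  for (b in rev(seq_along(cfg$channels))) {
    cc <- fw$cache[[b]]
    dz <- da * (cc$pre > 0)
    bw <- conv_bwd(cc$input, model$params[[paste0("conv", b)]], dz,
                   stride = cfg$strides[b], pad = 1L)
    grads[[paste0("conv", b)]] <- bw$dw +
      2 * lambda * model$params[[paste0("conv", b)]]
    grads[[paste0("bias", b)]] <- bias_grad(dz)
    da <- bw$dx
  }
  list(grads = grads, loss = loss)
}

#' Train the GAP classifier
#'
#' Minimizes cross-entropy plus `lambda * sum(w^2)` with Adam, logging
#' per-epoch loss and tuning-set AUC, and returns the best-tune-AUC
#' snapshot. With no tuning set the final-epoch model is returned with a
#' warning.
#'
#' @param x `(side, side, 1, N)` training inputs.
#' @param y 0/1 labels (1 = malignant); both classes must be present.
#' @param tune_x,tune_y optional tuning set for snapshot selection.
#' @param model_config a [gap_classifier_config()].
#' @param train_config a [training_config()].
#' @param warn_empty_tune warn when no tuning set is supplied.
#' @return a `gap_classifier` with attached `log` (data frame of epoch,
#'   loss, tune_auc) and `best_epoch`.
#' @export
train_classifier <- function(x, y, tune_x = NULL, tune_y = NULL,
                             model_config = gap_classifier_config(),
                             train_config = training_config(),
                             warn_empty_tune = TRUE) {
  assert_that(length(unique(y)) == 2, "training set must contain both classes")
  tc <- train_config
  model <- init_gap_classifier(model_config, seed = tc$seed)
  state <- adam_init(model$params)
  n <- dim(x)[4]
  has_tune <- !is.null(tune_x) && length(tune_y) > 0
  if (!has_tune && warn_empty_tune) {
    warning("no tuning set: returning the final-epoch snapshot")
  }
  log <- data.frame(epoch = integer(), loss = numeric(), tune_auc = numeric())
  best <- list(auc = -Inf, params = model$params, epoch = 0L)
  withr::with_seed(tc$seed + 1L, {
    for (ep in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (s in seq(1, n, by = tc$batch_size)) {
        idx <- ord[s:min(s + tc$batch_size - 1, n)]
        gb <- gap_batch_grads(model, x[, , , idx, drop = FALSE], y[idx],
                              tc$weight_decay)
        up <- adam_step(model$params, gb$grads, state, lr = tc$lr,
                        beta1 = tc$beta1, beta2 = tc$beta2)
        model$params <- up$params
        state <- up$state
        losses <- c(losses, gb$loss)
      }
      tune_auc <- NA_real_
      if (has_tune) {
        tune_auc <- roc_auc(predict_pom(model, tune_x), tune_y)$auc
        if (tune_auc > best$auc) {
          best <- list(auc = tune_auc, params = model$params, epoch = ep)
        }
      }
      log <- rbind(log, data.frame(epoch = ep, loss = mean(losses),
                                   tune_auc = tune_auc))
    }
  })
  if (has_tune) {
    model$params <- best$params
    model$best_epoch <- best$epoch
  } else {
    model$best_epoch <- tc$epochs
  }
  model$log <- log
  model
}

#' Grid search over training hyperparameters
#'
#' Exhaustively evaluates the grid by tuning-set AUC (ties broken by lower
#' weight decay, then lower learning rate), then retrains the winning
#' configuration on the whole training set (tuning images included).
#'
#' @param x,y full training inputs and 0/1 labels.
#' @param tune_idx indices of `x` forming the tuning split (disjoint from
#'   the gradient steps during the search phase).
#' @param grid named list with candidate vectors `lr` and `weight_decay`.
#' @param model_config a [gap_classifier_config()].
#' @param train_config base [training_config()]; `lr`/`weight_decay` are
#'   overridden by grid points.
#' @return list with `best_config`, `model` (retrained on all of `x`),
#'   and `results` (one row per grid point).
#' @export
grid_search <- function(x, y, tune_idx, grid,
                        model_config = gap_classifier_config(),
                        train_config = training_config()) {
  assert_that(length(grid) > 0 && all(lengths(grid) > 0), "empty grid")
  pts <- expand.grid(lr = grid$lr %||% train_config$lr,
                     weight_decay = grid$weight_decay %||% train_config$weight_decay,
                     epochs = grid$epochs %||% train_config$epochs)
  fit_idx <- setdiff(seq_len(dim(x)[4]), tune_idx)
  results <- pts
  results$tune_auc <- NA_real_
  for (i in seq_len(nrow(pts))) {
    tc <- train_config
    tc$lr <- pts$lr[i]; tc$weight_decay <- pts$weight_decay[i]
    tc$epochs <- as.integer(pts$epochs[i])
    if (tc$epochs == 0) {
      m <- init_gap_classifier(model_config, seed = tc$seed)
    } else {
      m <- train_classifier(x[, , , fit_idx, drop = FALSE], y[fit_idx],
                            x[, , , tune_idx, drop = FALSE], y[tune_idx],
                            model_config, tc)
    }
    results$tune_auc[i] <- roc_auc(predict_pom(m, x[, , , tune_idx, drop = FALSE]),
                                   y[tune_idx])$auc
  }
  ord <- order(-results$tune_auc, results$weight_decay, results$lr)
  wi <- ord[1]
  best_tc <- train_config
  best_tc$lr <- results$lr[wi]
  best_tc$weight_decay <- results$weight_decay[wi]
  best_tc$epochs <- as.integer(results$epochs[wi])
  final <- train_classifier(x, y, NULL, NULL, model_config, best_tc,
                            warn_empty_tune = FALSE)
  list(best_config = best_tc, model = final, results = results)
}
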