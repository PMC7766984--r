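# Autoencoder training.
#
# The fusion layer is bypassed: each corpus image is encoded and its feature
# stack decoded straight back, and encoder + decoder are trained jointly to
# reconstruct the input under the mixed cross-entropy + SSIM loss.
# Optimisation is Adam (beta1 0.9, beta2 0.999, eps 1e-8) on mini-batch mean
# gradients with the exponential per-epoch learning-rate decay of
# lr_schedule().  Everything is seeded, so a given corpus + config yields
# bit-identical loss logs.

#' Training configuration
#'
#' @param lr0 base learning rate (default 5e-4).
#' @param batch_size mini-batch size (default 32).
#' @param epochs number of passes over the corpus (default 10).
#' @param alpha,beta mixed-loss weights (defaults 500 and 1).
#' @param seed RNG seed driving initialisation and shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(lr0 = 5e-4, batch_size = 32L, epochs = 10L,
                         alpha = 500, beta = 1, seed = 1L) {
  if (lr0 <= 0 || batch_size < 1L || epochs < 1L ||
      alpha < 0 || beta < 0 || alpha + beta <= 0)
    stop_stage("train", "invalid training configuration")
  structure(list(lr0 = lr0, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), alpha = alpha, beta = beta,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Forward + backward pass for one image; returns loss pieces and per-layer
# parameter gradients (same list layout as params$layers).
autoencoder_grads <- function(img, params, alpha, beta) {
  a <- params$arch
  L <- params$layers
  enc <- encoder_forward(img, params)
  dec <- decoder_forward(enc$stack, enc$H, enc$W, params)
  lg <- mixed_loss_grad_logit(img, matrix(dec$O, enc$H, enc$W), alpha, beta)
  sgrad <- function(z) selu_grad(z, a$selu_lambda, a$selu_alpha)
  w <- a$width

  # decoder backward
  dz3 <- matrix(lg$dlogit, enc$H * enc$W, 1L)
  b3 <- conv3_backward(dz3, dec$g[[3L]], L$D3$W)
  dz2 <- b3$dx * sgrad(dec$z[[2L]])
  b2 <- conv3_backward(dz2, dec$g[[2L]], L$D2$W)
  dz1 <- b2$dx * sgrad(dec$z[[1L]])
  b1 <- conv3_backward(dz1, dec$g[[1L]], L$D1$W)
  dstack <- b1$dx

  # encoder backward: stack = concat(h2, h3), h3 = CIDN3(h2)
  dh3 <- dstack[, w + seq_len(w), drop = FALSE]
  dz4 <- dh3 * sgrad(enc$z[[4L]])
  b4 <- conv3_backward(dz4, enc$f[[4L]], L$CIDN3$W)
  dh2 <- dstack[, seq_len(w), drop = FALSE] + b4$dx
  dz3e <- dh2 * sgrad(enc$z[[3L]])
  b3e <- conv3_backward(dz3e, enc$f[[3L]], L$CIDN2$W)
  dcat <- b3e$dx
  dh1 <- dcat[, w + seq_len(w), drop = FALSE]
  dz2e <- dh1 * sgrad(enc$z[[2L]])
  b2e <- conv3_backward(dz2e, enc$f[[2L]], L$CIDN1$W)
  dh0 <- dcat[, seq_len(w), drop = FALSE] + b2e$dx
  dz1e <- dh0 * sgrad(enc$z[[1L]])
  b1e <- conv3_backward(dz1e, enc$f[[1L]], L$C1$W)

  list(
    loss = lg$loss, ce = lg$ce, ssim = lg$ssim,
    grads = list(
      C1 = list(W = b1e$dW, b = b1e$db),
      CIDN1 = list(W = b2e$dW, b = b2e$db),
      CIDN2 = list(W = b3e$dW, b = b3e$db),
      CIDN3 = list(W = b4$dW, b = b4$db),
      D1 = list(W = b1$dW, b = b1$db),
      D2 = list(W = b2$dW, b = b2$db),
      D3 = list(W = b3$dW, b = b3$db)
    )
  )
}

zero_like_layers <- function(layers) {
  lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
}

#' Train the encoder/decoder autoencoder
#'
#' Minimises the mixed loss over the corpus with seeded Adam; the fusion
#' layer is bypassed (each image is reconstructed from its own feature
#' stack).  Returns trained parameters with the per-epoch loss log attached
#' as attribute `loss_log` (a data frame with columns `epoch`, `lr`,
#' `loss`, `ce`, `ssim`).
#'
#' @param corpus list of grayscale matrices in \[0,1\] (a common size is
#'   expected; see [make_training_corpus()]).
#' @param cfg a [train_config()].
#' @param arch a [net_arch()].
#' @param verbose print per-epoch progress.
#' @return Trained [net_params][init_net_params()] with a `loss_log`
#'   attribute.
#' @export
train_autoencoder <- function(corpus, cfg = train_config(),
                              arch = net_arch(), verbose = FALSE) {
  if (!is.list(corpus) || length(corpus) == 0L)
    stop_stage("train", "corpus must be a non-empty list of images")
  for (im in corpus) assert_gray(im, "train", min_dim = 8L)
  params <- init_net_params(arch, seed = cfg$seed)
  m <- zero_like_layers(params$layers)
  v <- zero_like_layers(params$layers)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  log <- data.frame(epoch = integer(), lr = numeric(), loss = numeric(),
                    ce = numeric(), ssim = numeric())

  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_schedule(epoch - 1L, cfg$lr0)
      ord <- sample.int(length(corpus))
      ep_loss <- ep_ce <- ep_ssim <- 0
      nb <- 0L
      for (start in seq(1L, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        acc <- NULL
        bl <- bc <- bs <- 0
        for (i in idx) {
          g <- autoencoder_grads(corpus[[i]], params, cfg$alpha, cfg$beta)
          if (!is.finite(g$loss))
            stop_stage("train", "non-finite loss at epoch ", epoch)
          bl <- bl + g$loss; bc <- bc + g$ce; bs <- bs + g$ssim
          if (is.null(acc)) acc <- g$grads
          else for (nm in names(acc)) {
            acc[[nm]]$W <- acc[[nm]]$W + g$grads[[nm]]$W
            acc[[nm]]$b <- acc[[nm]]$b + g$grads[[nm]]$b
          }
        }
        nbatch <- length(idx)
        step <- step + 1L
        for (nm in names(acc)) {
          for (pn in c("W", "b")) {
            gmean <- acc[[nm]][[pn]] / nbatch
            m[[nm]][[pn]] <- b1 * m[[nm]][[pn]] + (1 - b1) * gmean
            v[[nm]][[pn]] <- b2 * v[[nm]][[pn]] + (1 - b2) * gmean^2
            mhat <- m[[nm]][[pn]] / (1 - b1^step)
            vhat <- v[[nm]][[pn]] / (1 - b2^step)
            params$layers[[nm]][[pn]] <- params$layers[[nm]][[pn]] -
              lr * mhat / (sqrt(vhat) + adam_eps)
          }
        }
        ep_loss <- ep_loss + bl; ep_ce <- ep_ce + bc; ep_ssim <- ep_ssim + bs
        nb <- nb + nbatch
      }
      log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                   loss = ep_loss / nb, ce = ep_ce / nb,
                                   ssim = ep_ssim / nb))
      if (verbose)
        message(sprintf("epoch %d: lr=%.3g loss=%.4f ce=%.4f ssim=%.4f",
                        epoch, lr, ep_loss / nb, ep_ce / nb, ep_ssim / nb))
    }
  })
  attr(params, "loss_log") <- log
  params
}

#' Reconstruct an image through the autoencoder
#'
#' `decode(encode(img))` without fusion; used for held-out reconstruction
#' checks.
#'
#' @param img grayscale matrix.
#' @param params trained [net_params][init_net_params()].
#' @return Reconstructed matrix in (0,1).
#' @export
reconstruct <- function(img, params) {
  decode(encode(img, params), params)
}
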