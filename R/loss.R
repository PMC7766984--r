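# Reconstruction losses.
#
# The autoencoder is trained with  L = alpha * CE + beta * (1 - SSIM),
# where CE is the per-pixel-mean Bernoulli cross entropy between the input
# image I and the logistic decoder output O, and SSIM uses the metric
# module's 11x11 Gaussian-window definition.  The mean reduction keeps
# alpha and beta independent of image size; set `reduction = "sum"` for the
# literal summed form.

#' Bernoulli cross-entropy reconstruction loss
#'
#' Mean over pixels of \eqn{-[I \log O + (1-I) \log(1-O)]} with O clamped
#' to \[eps, 1-eps\] for log safety.
#'
#' @param I input (target) image in \[0,1\].
#' @param O reconstruction in (0,1), same shape.
#' @param eps clamping constant.
#' @param reduction `"mean"` (default) or `"sum"` over pixels.
#' @return Non-negative loss.
#' @export
cross_entropy_loss <- function(I, O, eps = 1e-7, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  assert_same_shape("loss", I, O)
  Oc <- pmin(pmax(O, eps), 1 - eps)
  v <- -(I * log(Oc) + (1 - I) * log(1 - Oc))
  if (reduction == "mean") mean(v) else sum(v)
}

#' Structural-similarity reconstruction loss
#'
#' `1 - ssim(I, O)`, in \[0, 2\].
#'
#' @inheritParams cross_entropy_loss
#' @param ... passed to [ssim()] (window, sigma, stabilisers).
#' @return Loss in \[0, 2\]; 0 iff the images are identical.
#' @export
ssim_loss <- function(I, O, ...) 1 - ssim(I, O, ...)

#' Mixed reconstruction loss
#'
#' `alpha * cross_entropy_loss + beta * ssim_loss`; the training objective.
#'
#' @inheritParams cross_entropy_loss
#' @param alpha,beta non-negative loss weights (defaults 500 and 1).
#' @return Non-negative loss.
#' @export
mixed_loss <- function(I, O, alpha = 500, beta = 1) {
  if (alpha < 0 || beta < 0 || alpha + beta <= 0)
    stop_stage("loss", "alpha, beta must be non-negative with alpha+beta > 0")
  alpha * cross_entropy_loss(I, O) + beta * ssim_loss(I, O)
}

#' Exponentially decayed learning rate
#'
#' `0.95^epoch_num * lr0`; epoch 0 returns `lr0` unchanged and the schedule
#' is strictly decreasing.
#'
#' @param epoch_num epoch index, >= 0.
#' @param lr0 base learning rate, > 0.
#' @return Learning rate for the epoch.
#' @examples
#' lr_schedule(0, 5e-4); lr_schedule(1, 5e-4)
#' @export
lr_schedule <- function(epoch_num, lr0 = 5e-4) {
  if (any(epoch_num < 0) || any(epoch_num != floor(epoch_num)))
    stop_stage("train", "epoch_num must be a non-negative integer")
  if (lr0 <= 0) stop_stage("train", "lr0 must be positive")
  0.95^epoch_num * lr0
}

# Gradient of mean-SSIM with respect to the second image y, using the
# standard two-factor SSIM map S = (A1*A2)/(B1*B2) with
# A1 = 2 mux muy + c1, A2 = 2 sxy + c2, B1 = mux^2 + muy^2 + c1,
# B2 = sxx + syy + c2 (identical in value to the product form with
# c3 = c2/2).  Each valid window w contributes through its mean, variance
# and covariance; the chain rule folds back into three filterings:
#   d mean(S)/dy = [ spread(W1) + 2 y spread(W2) + x spread(W3) ] / n_win
# with W1 = dS/dmuy - 2 muy dS/dsyy - mux dS/dsxy, W2 = dS/dsyy,
# W3 = dS/dsxy.
ssim_value_grad <- function(x, y, window = 11L, sigma = 1.5,
                            c1 = 0.01^2, c2 = 0.03^2) {
  kern <- gaussian_kernel(window, sigma)
  st <- ssim_stats(x, y, kern)
  A1 <- 2 * st$mux * st$muy + c1
  A2 <- 2 * st$sxy + c2
  B1 <- st$mux^2 + st$muy^2 + c1
  B2 <- st$sxx + st$syy + c2
  S <- A1 * A2 / (B1 * B2)
  dS_dmuy <- 2 * st$mux * A2 / (B1 * B2) - S * 2 * st$muy / B1
  dS_dsyy <- -S / B2
  dS_dsxy <- 2 * A1 / (B1 * B2)
  W1 <- dS_dmuy - 2 * st$muy * dS_dsyy - st$mux * dS_dsxy
  M <- nrow(x); N <- ncol(x)
  g <- spread_valid(W1, kern, M, N) +
    2 * y * spread_valid(dS_dsyy, kern, M, N) +
    x * spread_valid(dS_dsxy, kern, M, N)
  list(value = mean(S), grad = g / length(S))
}

# Mixed loss value and gradient with respect to the decoder logit z
# (O = logistic(z)).  The cross-entropy/logistic pair collapses to
# (O - I)/n; the SSIM part is chained through dO/dz = O (1 - O).
mixed_loss_grad_logit <- function(I, O, alpha, beta,
                                  window = 11L, sigma = 1.5) {
  n <- length(I)
  ce <- cross_entropy_loss(I, O)
  sg <- ssim_value_grad(I, O, window, sigma)
  dz <- alpha * (O - I) / n + beta * (-sg$grad) * O * (1 - O)
  list(loss = alpha * ce + beta * (1 - sg$value),
       ce = ce, ssim = sg$value, dlogit = dz)
}
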