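#' Fit a medical image fusion model
#'
#' Trains the encoder/decoder autoencoder on a grayscale corpus (the fusion
#' layer is bypassed during training) and returns a fitted model object.
#' With no corpus supplied, a seeded synthetic corpus of `n_corpus` images
#' is generated with [make_training_corpus()].  The fitted object fuses
#' image pairs through [predict()].
#'
#' @param corpus list of grayscale matrices in \[0,1\]; `NULL` to generate
#'   a synthetic corpus.
#' @param n_corpus,size synthetic corpus size and image side, used only
#'   when `corpus` is `NULL`.
#' @param epochs,batch_size,lr0,alpha,beta training settings, see
#'   [train_config()].  Defaults: 10 epochs, batch 32, learning rate 5e-4
#'   with 0.95-per-epoch decay, loss weights alpha = 500 (cross entropy)
#'   and beta = 1 (SSIM).
#' @param seed integer seed controlling initialisation, shuffling and the
#'   synthetic corpus.
#' @param arch a [net_arch()].
#' @param ctrl a [fusion_control()] stored for prediction-time fusion.
#' @param verbose print per-epoch progress.
#' @return An object of class `medfuse`: list with `params` (trained
#'   weights), `loss_log`, `config`, `ctrl`, `call`.
#' @examples
#' \donttest{
#' fit <- medfuse(n_corpus = 20, epochs = 2, seed = 1)
#' pair <- make_phantom_pair(64, seed = 3)
#' fused <- predict(fit, pair)
#' }
#' @seealso [fuse_pair()], [run_evaluation()], [evaluate_all()]
#' @export
medfuse <- function(corpus = NULL, n_corpus = 200L, size = 64L,
                    epochs = 10L, batch_size = 32L, lr0 = 5e-4,
                    alpha = 500, beta = 1, seed = 1L,
                    arch = net_arch(), ctrl = fusion_control(),
                    verbose = FALSE) {
  cl <- match.call()
  if (is.null(corpus))
    corpus <- make_training_corpus(n_corpus, size, seed)
  cfg <- train_config(lr0 = lr0, batch_size = batch_size, epochs = epochs,
                      alpha = alpha, beta = beta, seed = seed)
  params <- train_autoencoder(corpus, cfg, arch, verbose = verbose)
  structure(list(
    params = params,
    loss_log = attr(params, "loss_log"),
    config = cfg,
    ctrl = ctrl,
    call = cl
  ), class = "medfuse")
}

#' @export
print.medfuse <- function(x, ...) {
  ll <- x$loss_log
  cat("Multi-modal image fusion model\n")
  cat(sprintf("  encoder width %d, trained %d epochs on batches of %d\n",
              x$params$arch$width, x$config$epochs, x$config$batch_size))
  cat(sprintf("  mixed loss (alpha=%g, beta=%g): %.4f -> %.4f\n",
              x$config$alpha, x$config$beta,
              ll$loss[1L], ll$loss[nrow(ll)]))
  invisible(x)
}

#' @export
summary.medfuse <- function(object, ...) {
  structure(list(loss_log = object$loss_log, config = object$config,
                 arch = object$params$arch),
            class = "summary.medfuse")
}

#' @export
print.summary.medfuse <- function(x, ...) {
  cat("Training log (per-epoch means)\n")
  print(x$loss_log, row.names = FALSE)
  cat(sprintf("lr0=%g, batch=%d, alpha=%g, beta=%g, seed=%d\n",
              x$config$lr0, x$config$batch_size, x$config$alpha,
              x$config$beta, x$config$seed))
  invisible(x)
}

#' @export
coef.medfuse <- function(object, ...) object$params$layers

#' Plot the training loss curve
#'
#' @param x a fitted [medfuse()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.medfuse <- function(x, ...) {
  ll <- x$loss_log
  graphics::plot(ll$epoch, ll$loss, type = "b", xlab = "epoch",
                 ylab = "mixed loss", ...)
  invisible(x)
}

#' Fuse or reconstruct images with a fitted model
#'
#' `newdata` may be a [make_phantom_pair()] object or a list with elements
#' `structural` (matrix) and `functional` (RGB [color_image()] or `NULL`).
#' With a functional image the colour pipeline runs ([fuse_pair()]); with
#' two grayscale images ([fuse_gray_pair()]); with only `structural`,
#' the autoencoder reconstruction is returned.
#'
#' @param object a fitted [medfuse()] model.
#' @param newdata input images (see Details).
#' @param type `"fusion"` (default) or `"reconstruction"`.
#' @param ... unused.
#' @return A [color_image()], or a grayscale matrix.
#' @export
predict.medfuse <- function(object, newdata,
                            type = c("fusion", "reconstruction"), ...) {
  type <- match.arg(type)
  if (type == "reconstruction") {
    img <- if (is.list(newdata)) newdata$structural else newdata
    return(reconstruct(img, object$params))
  }
  if (inherits(newdata, "phantom_pair") ||
      (is.list(newdata) && !is.null(newdata$functional))) {
    s <- newdata$structural
    f <- newdata$functional
    if (inherits(f, "color_image"))
      return(fuse_pair(unclass_attr(s), f, object$params, object$ctrl))
    return(fuse_gray_pair(unclass_attr(s), f, object$params, object$ctrl))
  }
  if (is.list(newdata) && length(newdata) == 2L &&
      is.matrix(newdata[[1L]]) && is.matrix(newdata[[2L]]))
    return(fuse_gray_pair(newdata[[1L]], newdata[[2L]],
                          object$params, object$ctrl))
  stop_stage("pipeline", "newdata must be a phantom pair or image list")
}

#' Reconstruction residuals of a fitted model
#'
#' Difference between an image and its autoencoder reconstruction.
#'
#' @param object a fitted [medfuse()] model.
#' @param image grayscale matrix to reconstruct.
#' @param ... unused.
#' @return Matrix of residuals `image - reconstruction`.
#' @export
residuals.medfuse <- function(object, image, ...) {
  image - reconstruct(image, object$params)
}
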