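# Encoder / decoder network.
#
# Encoder: one stem convolution C1 followed by a three-layer detail-capture
# block (CIDN) with a single dense feature-reuse layer: CIDN2 sees the
# concatenation of C1's and CIDN1's outputs, and its output feeds both
# CIDN3 and the fusion layer.  The encoder output routed to fusion is the
# concatenation of CIDN2 and CIDN3 feature maps.  Decoder: three 3x3
# convolutions; the last one is squashed by a logistic so outputs are valid
# Bernoulli means for the cross-entropy loss.  All convolutions are 3x3,
# zero-padded, stride 1, SeLU-activated unless noted.

#' Scaled exponential linear unit
#'
#' \eqn{selu(x) = \lambda x} for \eqn{x > 0} and
#' \eqn{\lambda \alpha (e^x - 1)} for \eqn{x \le 0}, with the
#' self-normalizing constants \eqn{\lambda = 1.0507009873554805},
#' \eqn{\alpha = 1.6732632423543772} by default.
#'
#' @param x numeric vector/matrix/array.
#' @param lambda,alpha SeLU constants.
#' @return Object of the same shape as `x`.
#' @examples
#' selu(0); selu(1)
#' @export
selu <- function(x, lambda = 1.0507009873554805, alpha = 1.6732632423543772) {
  neg <- x <= 0
  out <- lambda * x
  out[neg] <- lambda * alpha * expm1(x[neg])
  out
}

selu_grad <- function(x, lambda = 1.0507009873554805,
                      alpha = 1.6732632423543772) {
  neg <- x <= 0
  out <- array(lambda, dim(x) %||% length(x))
  out[neg] <- lambda * alpha * exp(x[neg])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

logistic <- function(x) 1 / (1 + exp(-x))

#' Network architecture descriptor
#'
#' Channel widths of the encoder/decoder.  The stem and each CIDN layer emit
#' `width` maps; CIDN2 consumes `2*width` (dense reuse of C1 + CIDN1); the
#' encoder output is `2*width` maps (CIDN2 and CIDN3 concatenated); the
#' decoder narrows through `dec_widths` down to one channel.
#'
#' @param width channel width of the stem and CIDN layers (default 16).
#' @param dec_widths hidden widths of the first two decoder layers.
#' @param selu_lambda,selu_alpha activation constants, see [selu()].
#' @return A list describing the architecture.
#' @export
net_arch <- function(width = 16L, dec_widths = c(16L, 8L),
                     selu_lambda = 1.0507009873554805,
                     selu_alpha = 1.6732632423543772) {
  stopifnot(width >= 1L, length(dec_widths) == 2L, all(dec_widths >= 1L))
  list(
    width = as.integer(width),
    dec_widths = as.integer(dec_widths),
    kernel = 3L,
    selu_lambda = selu_lambda,
    selu_alpha = selu_alpha,
    version = 1L
  )
}

net_layer_dims <- function(arch) {
  w <- arch$width
  d <- arch$dec_widths
  list(
    C1    = c(1L, w),
    CIDN1 = c(w, w),
    CIDN2 = c(2L * w, w),  # dense reuse: concat(C1, CIDN1)
    CIDN3 = c(w, w),
    D1    = c(2L * w, d[1]),  # fusion stack: concat(CIDN2, CIDN3)
    D2    = c(d[1], d[2]),
    D3    = c(d[2], 1L)
  )
}

#' Initialise network parameters
#'
#' Variance-scaling (LeCun normal) initialisation, appropriate for
#' self-normalizing activations: kernel entries are drawn from
#' N(0, 1/fan_in) with fan_in = 9 * input channels; biases start at zero.
#'
#' @param arch architecture from [net_arch()].
#' @param seed integer RNG seed; the draw is reproducible and does not
#'   disturb the caller's RNG state.
#' @return Object of class `net_params`.
#' @export
init_net_params <- function(arch = net_arch(), seed = 1L) {
  dims <- net_layer_dims(arch)
  layers <- with_seed(seed, lapply(dims, function(d) {
    fan_in <- 9L * d[1]
    list(
      W = matrix(stats::rnorm(fan_in * d[2], sd = sqrt(1 / fan_in)),
                 fan_in, d[2]),
      b = numeric(d[2])
    )
  }))
  structure(list(layers = layers, arch = arch, seed = seed),
            class = "net_params")
}

#' @export
print.net_params <- function(x, ...) {
  dims <- net_layer_dims(x$arch)
  np <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b), numeric(1)))
  cat(sprintf("<net_params width=%d, %d layers, %d parameters>\n",
              x$arch$width, length(dims), as.integer(np)))
  invisible(x)
}

as_chw <- function(z, H, W) array(z, c(H, W, ncol(z)))

# Full encoder forward pass with caches for backprop.
encoder_forward <- function(img, params) {
  a <- params$arch
  H <- nrow(img); W <- ncol(img)
  L <- params$layers
  act <- function(z) selu(z, a$selu_lambda, a$selu_alpha)

  x <- array(img, c(H, W, 1L))
  f1 <- conv3_forward(x, L$C1$W, L$C1$b);  h0 <- act(f1$z)
  f2 <- conv3_forward(as_chw(h0, H, W), L$CIDN1$W, L$CIDN1$b); h1 <- act(f2$z)
  f3 <- conv3_forward(as_chw(cbind(h0, h1), H, W), L$CIDN2$W, L$CIDN2$b)
  h2 <- act(f3$z)
  f4 <- conv3_forward(as_chw(h2, H, W), L$CIDN3$W, L$CIDN3$b); h3 <- act(f4$z)
  list(f = list(f1, f2, f3, f4), z = list(f1$z, f2$z, f3$z, f4$z),
       h = list(h0, h1, h2, h3), stack = cbind(h2, h3), H = H, W = W)
}

decoder_forward <- function(stack_mat, H, W, params) {
  a <- params$arch
  L <- params$layers
  act <- function(z) selu(z, a$selu_lambda, a$selu_alpha)
  g1 <- conv3_forward(as_chw(stack_mat, H, W), L$D1$W, L$D1$b); u1 <- act(g1$z)
  g2 <- conv3_forward(as_chw(u1, H, W), L$D2$W, L$D2$b);       u2 <- act(g2$z)
  g3 <- conv3_forward(as_chw(u2, H, W), L$D3$W, L$D3$b)
  O <- logistic(g3$z)
  list(g = list(g1, g2, g3), z = list(g1$z, g2$z, g3$z),
       u = list(u1, u2), logit = g3$z, O = O)
}

#' Encode an image into a feature stack
#'
#' Runs the encoder (stem + CIDN with dense feature reuse) on a single
#' grayscale image of any size >= 8x8 and returns the feature stack routed
#' to the fusion layer: the concatenated CIDN2 and CIDN3 maps, spatially
#' aligned with the input (same padding throughout).
#'
#' @param img numeric matrix in \[0,1\], at least 8x8.
#' @param params [net_params][init_net_params()].
#' @param source optional source label carried on the stack.
#' @return A `feature_stack`: H x W x n array with attribute `source`.
#' @export
encode <- function(img, params, source = NULL) {
  assert_gray(img, "encode", min_dim = 8L)
  check_params(params)
  fw <- encoder_forward(img, params)
  feature_stack(as_chw(fw$stack, fw$H, fw$W), source = source)
}

#' Construct a feature stack
#'
#' @param maps H x W x n numeric array of feature maps.
#' @param source optional source label.
#' @return A `feature_stack` object.
#' @export
feature_stack <- function(maps, source = NULL) {
  if (length(dim(maps)) != 3L)
    stop_stage("encode", "feature stack must be an H x W x n array")
  structure(maps, class = "feature_stack", source = source)
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<feature_stack %dx%d, %d maps>\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Decode a feature stack into an image
#'
#' Three-layer decoder; the first two layers are SeLU-activated and the last
#' is squashed through a logistic, so all outputs lie strictly in (0,1).
#'
#' @param stack a `feature_stack` whose channel count matches the decoder
#'   input width.
#' @param params [net_params][init_net_params()].
#' @return Grayscale matrix with the stack's spatial shape.
#' @export
decode <- function(stack, params) {
  check_params(params)
  d <- dim(stack)
  if (length(d) != 3L) stop_stage("decode", "expected a feature stack")
  dims <- net_layer_dims(params$arch)
  if (d[3] != dims$D1[1])
    stop_stage("decode", "stack has ", d[3], " maps but decoder expects ",
               dims$D1[1])
  fw <- decoder_forward(matrix(stack, d[1] * d[2], d[3]), d[1], d[2], params)
  matrix(fw$O, d[1], d[2])
}

check_params <- function(params) {
  if (!inherits(params, "net_params"))
    stop_stage("network", "expected net_params (see init_net_params/medfuse)")
  dims <- net_layer_dims(params$arch)
  for (nm in names(dims)) {
    l <- params$layers[[nm]]
    if (is.null(l) || nrow(l$W) != 9L * dims[[nm]][1] ||
        ncol(l$W) != dims[[nm]][2] || length(l$b) != dims[[nm]][2])
      stop_stage("network", "layer ", nm, " is inconsistent with architecture")
  }
  invisible(params)
}

#' Save or load network parameters
#'
#' Checkpoints are single RDS files embedding the architecture descriptor,
#' so a reloaded checkpoint reproduces `encode()` outputs bit-identically.
#'
#' @param params [net_params][init_net_params()].
#' @param path checkpoint file path.
#' @return `read_net_params()` returns the `net_params`;
#'   `write_net_params()` the path, invisibly.
#' @export
write_net_params <- function(params, path) {
  check_params(params)
  saveRDS(params, path)
  invisible(path)
}

#' @rdname write_net_params
#' @export
read_net_params <- function(path) {
  if (!file.exists(path)) stop_stage("io", "no such checkpoint: ", path)
  p <- readRDS(path)
  check_params(p)
  p
}
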