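#' Colour images with an explicit channel-space tag
#'
#' A `color_image` is an H x W x 3 numeric array carrying a `space`
#' attribute, either `"RGB"` or `"YIQ"`.  RGB intensities live in \[0,1\];
#' YIQ values are unconstrained intermediates and are only clamped when
#' converted back to RGB.
#'
#' @param data numeric H x W x 3 array.
#' @param space `"RGB"` or `"YIQ"`.
#' @return A `color_image` object.
#' @examples
#' img <- color_image(array(runif(12), c(2, 2, 3)), "RGB")
#' color_space(img)
#' @export
color_image <- function(data, space = c("RGB", "YIQ")) {
  space <- match.arg(space)
  if (!is.array(data) || length(dim(data)) != 3L || dim(data)[3] != 3L)
    stop_stage("color", "expected an H x W x 3 array")
  if (!all(is.finite(data)))
    stop_stage("color", "non-finite channel values")
  if (space == "RGB") data <- clamp01(data)
  structure(data, space = space, class = "color_image")
}

#' @rdname color_image
#' @param x a `color_image`.
#' @export
color_space <- function(x) attr(x, "space")

#' @export
print.color_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<color_image %dx%d, space=%s, range [%.3f, %.3f]>\n",
              d[1], d[2], color_space(x), min(x), max(x)))
  invisible(x)
}

# Luma/chroma transform matrices.  The standard signed NTSC matrix has
# zero-sum I and Q rows, so achromatic pixels map to (Y, 0, 0); the
# "paper-literal" variant is an all-positive matrix (blue luma weight 0.144)
# kept for comparison, but it does not separate chroma and is not the default.
yiq_matrix <- function(matrix = c("standard", "paper-literal")) {
  matrix <- match.arg(matrix)
  if (matrix == "standard") {
    rbind(
      c(0.299,  0.587,  0.114),
      c(0.596, -0.274, -0.322),
      c(0.211, -0.523,  0.312)
    )
  } else {
    rbind(
      c(0.299, 0.587, 0.144),
      c(0.596, 0.274, 0.322),
      c(0.211, 0.523, 0.312)
    )
  }
}

apply_pixel_matrix <- function(data, M) {
  d <- dim(data)
  flat <- matrix(data, d[1] * d[2], 3L)
  out <- flat %*% t(M)
  array(out, d)
}

#' Convert between RGB and YIQ colour spaces
#'
#' Per-pixel linear maps by the 3x3 NTSC luma/chroma matrix.  The default
#' signed matrix sends gray pixels to zero chroma; its exact numerical
#' inverse is used for the return trip, and RGB output is clamped to
#' \[0,1\] only on the way back (out-of-gamut YIQ triples are legal
#' intermediates).
#'
#' @param img a [color_image()] in the expected source space.
#' @param matrix `"standard"` (signed NTSC, default) or `"paper-literal"`
#'   (an all-positive variant retained for comparison).
#' @return A [color_image()] in the target space.
#' @examples
#' x <- color_image(array(runif(27), c(3, 3, 3)), "RGB")
#' y <- rgb_to_yiq(x)
#' max(abs(yiq_to_rgb(y) - x)) < 1e-6
#' @export
rgb_to_yiq <- function(img, matrix = "standard") {
  if (!inherits(img, "color_image") || color_space(img) != "RGB")
    stop_stage("color", "rgb_to_yiq() needs a color_image in RGB space")
  M <- yiq_matrix(matrix)
  color_image(apply_pixel_matrix(unclass(img), M), "YIQ")
}

#' @rdname rgb_to_yiq
#' @export
yiq_to_rgb <- function(img, matrix = "standard") {
  if (!inherits(img, "color_image") || color_space(img) != "YIQ")
    stop_stage("color", "yiq_to_rgb() needs a color_image in YIQ space")
  M <- yiq_matrix(matrix)
  Minv <- tryCatch(solve(M), error = function(e)
    stop_stage("color", "configured colour matrix is singular"))
  color_image(clamp01(apply_pixel_matrix(unclass(img), Minv)), "RGB")
}

#' Extract or replace the luma channel of a YIQ image
#'
#' `get_luma()` returns channel Y as a grayscale matrix; `replace_luma()`
#' substitutes a fused luma while leaving the two chroma channels untouched
#' (the step that preserves functional-image colour through fusion).
#'
#' @param img a [color_image()] in YIQ space.
#' @param y numeric matrix with the image's spatial shape.
#' @return `get_luma()`: a matrix; `replace_luma()`: a YIQ [color_image()].
#' @export
replace_luma <- function(img, y) {
  if (!inherits(img, "color_image") || color_space(img) != "YIQ")
    stop_stage("color", "replace_luma() needs a YIQ color_image")
  d <- dim(img)
  if (!is.matrix(y) || nrow(y) != d[1] || ncol(y) != d[2])
    stop_stage("color", "luma shape does not match image")
  out <- unclass(img)
  out[, , 1L] <- y
  color_image(out, "YIQ")
}

#' @rdname replace_luma
#' @export
get_luma <- function(img) {
  if (!inherits(img, "color_image") || color_space(img) != "YIQ")
    stop_stage("color", "get_luma() needs a YIQ color_image")
  unclass(img)[, , 1L]
}
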