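# Raster I/O.  PNG and TIFF, 8- or 16-bit; intensities are normalised to
# [0,1] doubles at read time (integer codes divided by their max code value,
# which png/tiff already do) and clamped on write.

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop_stage("io", "unsupported image format: .", ext)
}

#' Read and write images
#'
#' `read_gray_image()` reads a single-channel image (colour files are
#' converted via the luma row of the standard YIQ matrix);
#' `read_color_image()` reads a 3-channel RGB image (grayscale files are
#' replicated).  `write_gray_image()`/`write_color_image()` write PNG or
#' TIFF according to the file extension, clamping to \[0,1\].
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param img matrix (gray) or [color_image()] in RGB space.
#' @return Read: a matrix or [color_image()]; write: the path, invisibly.
#' @export
read_gray_image <- function(path) {
  a <- read_raster(path)
  if (length(dim(a)) == 2L) return(a)
  a <- a[, , 1:3, drop = FALSE]  # drop alpha if present
  w <- yiq_matrix("standard")[1L, ]
  a[, , 1L] * w[1] + a[, , 2L] * w[2] + a[, , 3L] * w[3]
}

#' @rdname read_gray_image
#' @export
read_color_image <- function(path) {
  a <- read_raster(path)
  if (length(dim(a)) == 2L) {
    a <- array(rep(a, 3L), c(dim(a), 3L))
  } else {
    a <- a[, , 1:3, drop = FALSE]
  }
  color_image(a, "RGB")
}

read_raster <- function(path) {
  if (!file.exists(path)) stop_stage("io", "no such file: ", path)
  a <- switch(img_format(path),
    png = png::readPNG(path),
    tiff = tiff::readTIFF(path)
  )
  if (length(dim(a)) == 3L && dim(a)[3] == 1L) a <- a[, , 1L]
  a
}

#' @rdname read_gray_image
#' @export
write_gray_image <- function(img, path) {
  assert_gray(img, "io")
  write_raster(clamp01(img), path)
}

#' @rdname read_gray_image
#' @export
write_color_image <- function(img, path) {
  if (!inherits(img, "color_image") || color_space(img) != "RGB")
    stop_stage("io", "write_color_image() needs an RGB color_image")
  write_raster(clamp01(unclass(img)), path)
}

write_raster <- function(a, path) {
  switch(img_format(path),
    png = png::writePNG(a, path),
    tiff = tiff::writeTIFF(a, path, bits.per.sample = 16L)
  )
  invisible(path)
}
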