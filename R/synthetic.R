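# Synthetic phantoms and training corpus.
#
# Registered structural/functional pairs stand in for clinical MRI +
# PET/SPECT slices: the structural phantom is a piecewise-constant
# nested-ellipse head (skull ring, tissue regions, lesions) with
# band-limited texture and sharp edges; the functional phantom places
# smooth Gaussian activity blobs inside the same anatomy mask and maps them
# through a black-blue-green-yellow-red perfusion colormap.  The training
# corpus mixes random ellipses, ramps and filtered noise so histograms are
# broad.  All generators are seeded and deterministic.

ellipse_mask <- function(size, cx, cy, ax, ay, angle = 0) {
  xs <- matrix(rep(seq_len(size), size), size)      # row coordinate
  ys <- matrix(rep(seq_len(size), each = size), size)
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  (u / ax)^2 + (v / ay)^2 <= 1
}

#' Structural (MRI-like) phantom
#'
#' Piecewise-constant nested-ellipse head phantom: a bright skull ring, a
#' mid-gray brain, a handful of random tissue ellipses and low-amplitude
#' band-limited texture.  Values lie in \[0,1\] and edges are sharp, so
#' gradient-based metrics are discriminative.
#'
#' @param size image side, >= 32.
#' @param seed integer seed; the same seed reproduces the image bit for bit.
#' @return Grayscale matrix with attribute `geometry` (head-ellipse
#'   parameters and anatomy mask) used to register a functional phantom.
#' @export
make_structural <- function(size = 64L, seed = 1L) {
  if (size < 32L) stop_stage("synthetic", "phantom size must be >= 32")
  with_seed(mix_seed(seed, 1), {
    cx <- size / 2 + stats::runif(1, -2, 2)
    cy <- size / 2 + stats::runif(1, -2, 2)
    ax <- size * stats::runif(1, 0.36, 0.42)
    ay <- size * stats::runif(1, 0.30, 0.36)
    ang <- stats::runif(1, -0.3, 0.3)
    outer_m <- ellipse_mask(size, cx, cy, ax, ay, ang)
    inner_m <- ellipse_mask(size, cx, cy, 0.88 * ax, 0.88 * ay, ang)
    img <- matrix(0.02, size, size)
    img[outer_m] <- 0.95                       # skull ring
    img[inner_m] <- 0.35                       # brain tissue
    n_reg <- sample(3:5, 1)
    for (i in seq_len(n_reg)) {
      m <- ellipse_mask(size,
                        cx + stats::runif(1, -0.4, 0.4) * ax,
                        cy + stats::runif(1, -0.4, 0.4) * ay,
                        stats::runif(1, 0.08, 0.25) * size,
                        stats::runif(1, 0.08, 0.25) * size,
                        stats::runif(1, 0, pi)) & inner_m
      img[m] <- stats::runif(1, 0.15, 0.85)
    }
    tex <- gaussian_blur(matrix(stats::rnorm(size^2), size), 1.0)
    img[inner_m] <- img[inner_m] + 0.06 * tex[inner_m] / max(abs(tex))
    img <- clamp01(img)
    structure(img, geometry = list(
      cx = cx, cy = cy, ax = ax, ay = ay, angle = ang,
      mask = inner_m, size = size
    ))
  })
}

#' Functional (PET/SPECT-like) phantom
#'
#' Smooth Gaussian activity blobs confined to the anatomy mask of a
#' structural phantom, rendered through a black-blue-green-yellow-red
#' perfusion colormap (increasing activity runs black to red).
#'
#' @param size image side; must match the geometry's size.
#' @param seed integer seed.
#' @param geometry the `geometry` attribute of [make_structural()].
#' @return An RGB [color_image()]; all activity lies inside the anatomy
#'   mask, with attribute `activity` (the underlying \[0,1\] activity map).
#' @export
make_functional <- function(size = 64L, seed = 1L, geometry) {
  if (missing(geometry) || is.null(geometry$mask))
    stop_stage("synthetic", "geometry from make_structural() is required")
  if (geometry$size != size)
    stop_stage("synthetic", "geometry size does not match requested size")
  with_seed(mix_seed(seed, 2), {
    act <- matrix(0, size, size)
    xs <- matrix(rep(seq_len(size), size), size)
    ys <- matrix(rep(seq_len(size), each = size), size)
    n_blob <- sample(2:4, 1)
    for (i in seq_len(n_blob)) {
      bx <- geometry$cx + stats::runif(1, -0.5, 0.5) * geometry$ax
      by <- geometry$cy + stats::runif(1, -0.5, 0.5) * geometry$ay
      s <- stats::runif(1, 0.06, 0.16) * size
      amp <- stats::runif(1, 0.5, 1)
      act <- act + amp * exp(-((xs - bx)^2 + (ys - by)^2) / (2 * s^2))
    }
    act <- act / max(act, 1e-12)
    act[!geometry$mask] <- 0
    rgb <- perfusion_colormap(act)
    structure(color_image(rgb, "RGB"), activity = act)
  })
}

# Piecewise-linear black -> blue -> green -> yellow -> red colormap.
perfusion_colormap <- function(act) {
  anchors <- rbind(
    c(0, 0, 0),    # black
    c(0, 0, 1),    # blue
    c(0, 1, 0),    # green
    c(1, 1, 0),    # yellow
    c(1, 0, 0)     # red
  )
  pos <- c(0, 0.25, 0.5, 0.75, 1)
  out <- array(0, c(dim(act), 3L))
  for (ch in 1:3) {
    out[, , ch] <- matrix(
      stats::approx(pos, anchors[, ch], xout = as.vector(act),
                    rule = 2)$y,
      nrow(act), ncol(act)
    )
  }
  out
}

#' Registered structural/functional phantom pair
#'
#' @param size image side, >= 32.
#' @param seed integer seed shared by both modalities.
#' @return A `phantom_pair`: list with `structural` (matrix), `functional`
#'   (RGB [color_image()]), `geometry` and `seed`.
#' @examples
#' p <- make_phantom_pair(64, seed = 7)
#' dim(p$structural); dim(p$functional)
#' @export
make_phantom_pair <- function(size = 64L, seed = 1L) {
  s <- make_structural(size, seed)
  g <- attr(s, "geometry")
  f <- make_functional(size, seed, g)
  structure(list(structural = s, functional = f, geometry = g, seed = seed),
            class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("<phantom_pair %dx%d, seed %d>\n",
              nrow(x$structural), ncol(x$structural), x$seed))
  invisible(x)
}

#' Synthetic grayscale training corpus
#'
#' `n` seeded grayscale images mixing nested-ellipse phantoms, oriented
#' ramps and band-limited filtered noise, giving broad histogram coverage
#' (mean 256-level entropy above 4 bits) for autoencoder training.
#'
#' @param n number of images.
#' @param size image side (default 64).
#' @param seed integer seed.
#' @return List of `n` matrices in \[0,1\].
#' @export
make_training_corpus <- function(n = 200L, size = 64L, seed = 1L) {
  if (n < 1L) stop_stage("synthetic", "n must be >= 1")
  lapply(seq_len(n), function(i) {
    with_seed((seed * 97 + i * 131) %% 2147483647, {
      kind <- sample(c("phantom", "ramp", "noise", "mix"), 1)
      img <- switch(kind,
        phantom = unclass_attr(make_structural(max(size, 32L),
                                               seed * 1000 + i)),
        ramp = {
          th <- stats::runif(1, 0, pi)
          xs <- matrix(rep(seq_len(size), size), size) / size
          ys <- matrix(rep(seq_len(size), each = size), size) / size
          r <- xs * cos(th) + ys * sin(th)
          (r - min(r)) / max(max(r) - min(r), 1e-12)
        },
        noise = {
          z <- gaussian_blur(matrix(stats::rnorm(size^2), size),
                             stats::runif(1, 0.8, 2.5))
          (z - min(z)) / max(max(z) - min(z), 1e-12)
        },
        mix = {
          base <- unclass_attr(make_structural(max(size, 32L),
                                               seed * 2000 + i))
          z <- gaussian_blur(matrix(stats::rnorm(size^2), size), 1.5)
          clamp01(0.7 * base + 0.3 * (z - min(z)) /
                    max(max(z) - min(z), 1e-12))
        }
      )
      if (nrow(img) != size) img <- img[seq_len(size), seq_len(size)]
      img
    })
  })
}

unclass_attr <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Write phantom fixtures to disk
#'
#' Writes `n` seeded phantom pairs as PNG files plus a JSON manifest of
#' seeds and geometry, for use outside R.
#'
#' @param out output directory (created if needed).
#' @param n number of pairs.
#' @param size image side.
#' @param seed base seed; pair i uses `seed + i - 1`.
#' @return The manifest path, invisibly.
#' @export
make_fixtures <- function(out, n = 4L, size = 64L, seed = 7L) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- vector("list", n)
  for (i in seq_len(n)) {
    p <- make_phantom_pair(size, seed + i - 1L)
    sp <- file.path(out, sprintf("structural_%03d.png", i))
    fp <- file.path(out, sprintf("functional_%03d.png", i))
    write_gray_image(unclass_attr(p$structural), sp)
    write_color_image(p$functional, fp)
    g <- p$geometry
    manifest[[i]] <- list(structural = basename(sp), functional = basename(fp),
                          seed = p$seed,
                          geometry = g[c("cx", "cy", "ax", "ay", "angle")])
  }
  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
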