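# Low-level 2-D convolution machinery.
#
# The network works on H x W x C arrays.  Convolutions are computed by the
# im2col trick: every 3x3 neighbourhood (zero padded, stride 1) is unrolled
# into a row of a (H*W) x (9*C) matrix so a whole layer is a single BLAS
# matrix product.  The column order is (channel fastest, then ky, then kx),
# which `kernel_as_matrix()` mirrors when flattening a 4-D kernel.

pad_zero <- function(x, p) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

# x: H x W x C  ->  list of 9 (H*W) x C shifted-neighbourhood slabs for a
# 3x3 same-padded window, ordered (dy fastest, then dx) to match
# kernel_as_matrix() row blocks.  Equivalent to the columns of an im2col
# patch matrix, kept separate to avoid a wide copy.
conv3_slabs <- function(x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  P <- pad_zero(x, 1L)
  slabs <- vector("list", 9L)
  k <- 1L
  ri <- seq_len(H)
  ci <- seq_len(W)
  for (dx in 0:2) {
    for (dy in 0:2) {
      s <- P[dy + ri, dx + ci, , drop = FALSE]
      dim(s) <- c(H * W, C)
      slabs[[k]] <- s
      k <- k + 1L
    }
  }
  slabs
}

# Spatially flipped, channel-transposed kernel matrix: convolving the output
# gradient with it is the adjoint of the forward correlation (zero padding),
# replacing an explicit scatter-add with a second gather + matmul.
flip_kernel_matrix <- function(Wm, Cin, Cout) {
  V <- matrix(0, 9L * Cout, Cin)
  for (dx in 0:2) {
    for (dy in 0:2) {
      src <- ((2L - dx) * 3L + (2L - dy)) * Cin + seq_len(Cin)
      dst <- (dx * 3L + dy) * Cout + seq_len(Cout)
      V[dst, ] <- t(Wm[src, , drop = FALSE])
    }
  }
  V
}

# 3x3xCinxCout kernel -> (9*Cin) x Cout matrix matching im2col3 column order.
kernel_as_matrix <- function(kern) {
  d <- dim(kern)
  m <- aperm(kern, c(3L, 1L, 2L, 4L))
  dim(m) <- c(d[1] * d[2] * d[3], d[4])
  m
}

# Forward 3x3 same convolution.  Returns the pre-activation (H*W) x Cout
# matrix together with the neighbourhood slabs (kept for the backward pass).
conv3_forward <- function(x, Wm, b) {
  d <- dim(x)
  C <- d[3]
  slabs <- conv3_slabs(x)
  z <- slabs[[1L]] %*% Wm[seq_len(C), , drop = FALSE]
  for (k in 2:9) {
    z <- z + slabs[[k]] %*% Wm[(k - 1L) * C + seq_len(C), , drop = FALSE]
  }
  z <- z + rep(b, each = d[1] * d[2])
  list(z = z, slabs = slabs, H = d[1], W = d[2], Cin = C)
}

# Backward pass of conv3_forward.  dz: (H*W) x Cout gradient at the
# pre-activation.  Returns gradients for kernel matrix, bias and input
# (as a (H*W) x Cin matrix).
conv3_backward <- function(dz, fwd, Wm) {
  Cin <- fwd$Cin
  Cout <- ncol(dz)
  dW <- matrix(0, 9L * Cin, Cout)
  for (k in 1:9) {
    dW[(k - 1L) * Cin + seq_len(Cin), ] <- crossprod(fwd$slabs[[k]], dz)
  }
  db <- colSums(dz)
  V <- flip_kernel_matrix(Wm, Cin, Cout)
  dzm <- dz
  dim(dzm) <- c(fwd$H, fwd$W, Cout)
  dslab <- conv3_slabs(dzm)
  dx <- dslab[[1L]] %*% V[seq_len(Cout), , drop = FALSE]
  for (k in 2:9) {
    dx <- dx + dslab[[k]] %*% V[(k - 1L) * Cout + seq_len(Cout), , drop = FALSE]
  }
  list(dW = dW, db = db, dx = dx)
}

# Single-channel valid-mode linear filter with an arbitrary k x k kernel
# (used by SSIM, VIF and the Gaussian pyramids).  x: M x N matrix.
filter_valid <- function(x, kern) {
  k <- nrow(kern)
  M <- nrow(x); N <- ncol(x)
  Ho <- M - k + 1L; Wo <- N - k + 1L
  if (Ho < 1L || Wo < 1L)
    stop_stage("filter", "image smaller than filter window")
  out <- matrix(0, Ho, Wo)
  ri <- seq_len(Ho)
  ci <- seq_len(Wo)
  for (dx in 0:(k - 1L)) {
    sub <- x[, dx + ci, drop = FALSE]
    for (dy in 0:(k - 1L)) {
      out <- out + kern[dy + 1L, dx + 1L] * sub[dy + ri, , drop = FALSE]
    }
  }
  out
}

# Adjoint of filter_valid: spread a (M-k+1) x (N-k+1) gradient back to M x N.
spread_valid <- function(g, kern, M, N) {
  k <- nrow(kern)
  Ho <- nrow(g); Wo <- ncol(g)
  out <- matrix(0, M, N)
  ri <- seq_len(Ho)
  ci <- seq_len(Wo)
  for (dx in 0:(k - 1L)) {
    for (dy in 0:(k - 1L)) {
      out[dy + ri, dx + ci] <- out[dy + ri, dx + ci] + kern[dy + 1L, dx + 1L] * g
    }
  }
  out
}

gaussian_kernel <- function(size, sigma) {
  half <- (size - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Same-padded Gaussian smoothing of a matrix (phantom texture, blur tests).
gaussian_blur <- function(x, sigma, size = 2L * ceiling(3 * sigma) + 1L) {
  k <- gaussian_kernel(size, sigma)
  p <- (size - 1L) / 2L
  xp <- array(0, c(nrow(x) + 2 * p, ncol(x) + 2 * p, 1L))
  # replicate borders so blur does not darken edges
  xi <- pmin(pmax(seq_len(nrow(x) + 2 * p) - p, 1L), nrow(x))
  yi <- pmin(pmax(seq_len(ncol(x) + 2 * p) - p, 1L), ncol(x))
  filter_valid(x[xi, yi, drop = FALSE], k)
}
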