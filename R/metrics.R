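# Fusion-quality metrics.
#
# Ten objective metrics for a (source a, source b, fused f) triple:
# histogram entropy (EN), symmetric histogram divergence (CE), weighted RMSE,
# average gradient (AG), SSIM, feature mutual information (FMI), the
# universal image quality index family (Q0 -> Qabf, Qw, Qe) and pixel-domain
# visual information fidelity (VIF).  Intensities are assumed in [0,1];
# histogram metrics use 256 gray levels, FMI 64, and VIF works on a
# 255-scaled copy with noise variance 2 (the conventional 8-bit setting).

hist256 <- function(x) {
  idx <- pmin(pmax(floor(x * 256), 0), 255)
  tabulate(idx + 1L, 256L)
}

#' Image histogram entropy (EN)
#'
#' Shannon entropy in bits of the 256-bin gray-level histogram; empty bins
#' contribute nothing.  A constant image has entropy 0; an image covering
#' all 256 levels uniformly has entropy 8.
#'
#' @param f grayscale matrix in \[0,1\].
#' @return Entropy in bits, >= 0.
#' @export
entropy_en <- function(f) {
  assert_gray(f, "metrics")
  p <- hist256(f) / length(f)
  p <- p[p > 0]
  -sum(p * log2(p))
}

sym_divergence <- function(p, q) {
  # symmetric Kullback-Leibler divergence of two smoothed histograms
  sum(p * log(p / q)) + sum(q * log(q / p))
}

smoothed_hist <- function(x) {
  h <- hist256(x) + 1e-12
  h / sum(h)
}

#' Fused-image cross entropy (CE)
#'
#' Symmetric histogram divergence D(P:Q) between each source and the fused
#' image, combined as `eta_a * D(a:f) + eta_b * D(b:f)`.  The default
#' weights 0.7/0.3 reflect the surveyed preference of neurologists for
#' structural over colour information (35 of 50 physicians).
#'
#' @param a,b,f grayscale matrices of the same shape (structural source,
#'   functional source, fused image).
#' @param eta_a,eta_b source weights, non-negative.
#' @return Non-negative divergence (natural log).
#' @export
cross_entropy_ce <- function(a, b, f, eta_a = 0.7, eta_b = 0.3) {
  assert_same_shape("metrics", a, b, f)
  pa <- smoothed_hist(a); pb <- smoothed_hist(b); pf <- smoothed_hist(f)
  eta_a * sym_divergence(pa, pf) + eta_b * sym_divergence(pb, pf)
}

#' Fused-image root mean square error (RMSE)
#'
#' `wa * rmse(a, f) + wb * rmse(b, f)` with the per-pair RMSE the usual
#' root of the mean squared pixel difference.
#'
#' @inheritParams cross_entropy_ce
#' @param wa,wb source weights (default 0.5 each).
#' @return Non-negative error.
#' @export
rmse_fused <- function(a, b, f, wa = 0.5, wb = 0.5) {
  assert_same_shape("metrics", a, b, f)
  r <- function(x, y) sqrt(mean((x - y)^2))
  wa * r(a, f) + wb * r(b, f)
}

#' Average gradient (AG)
#'
#' Mean over interior pixels of
#' \eqn{\sqrt{((\Delta_x F)^2 + (\Delta_y F)^2)/2}} with forward
#' differences; the last row and column (no forward neighbour) are
#' excluded.  A sharpness proxy: larger is sharper.
#'
#' @inheritParams entropy_en
#' @return Non-negative scalar.
#' @export
avg_gradient <- function(f) {
  assert_gray(f, "metrics")
  M <- nrow(f); N <- ncol(f)
  dx <- f[seq_len(M - 1L), seq_len(N - 1L)] - f[2:M, seq_len(N - 1L)]
  dy <- f[seq_len(M - 1L), seq_len(N - 1L)] - f[seq_len(M - 1L), 2:N]
  mean(sqrt((dx^2 + dy^2) / 2))
}

# Forward-difference gradient magnitude; last row/column padded with zero
# differences.  Shared by Qe edge images and the FMI feature images.
grad_mag <- function(x) {
  M <- nrow(x); N <- ncol(x)
  gx <- matrix(0, M, N); gy <- matrix(0, M, N)
  gx[seq_len(M - 1L), ] <- x[2:M, ] - x[seq_len(M - 1L), ]
  gy[, seq_len(N - 1L)] <- x[, 2:N] - x[, seq_len(N - 1L)]
  sqrt(gx^2 + gy^2)
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM over 11x11 Gaussian windows (sigma 1.5), dynamic range 1,
#' stabilisers c1 = 0.01^2, c2 = 0.03^2, c3 = c2/2, in the
#' luminance-contrast-structure product form.
#'
#' @param x,y grayscale matrices of the same shape, min dimension >= 11.
#' @param window,sigma Gaussian window size and width.
#' @param c1,c2 stabilising constants (c3 is c2/2).
#' @return SSIM in \[-1, 1\]; 1 iff the images are identical.
#' @export
ssim <- function(x, y, window = 11L, sigma = 1.5, c1 = 0.01^2, c2 = 0.03^2) {
  assert_same_shape("metrics", x, y)
  if (min(dim(x)) < window)
    stop_stage("metrics", "image smaller than the SSIM window")
  st <- ssim_stats(x, y, gaussian_kernel(window, sigma))
  mean(ssim_map(st, c1, c2))
}

ssim_stats <- function(x, y, kern) {
  mux <- filter_valid(x, kern)
  muy <- filter_valid(y, kern)
  sxx <- filter_valid(x * x, kern) - mux^2
  syy <- filter_valid(y * y, kern) - muy^2
  sxy <- filter_valid(x * y, kern) - mux * muy
  list(mux = mux, muy = muy, sxx = sxx, syy = syy, sxy = sxy)
}

ssim_map <- function(st, c1 = 0.01^2, c2 = 0.03^2) {
  c3 <- c2 / 2
  sx <- sqrt(pmax(st$sxx, 0))
  sy <- sqrt(pmax(st$syy, 0))
  l <- (2 * st$mux * st$muy + c1) / (st$mux^2 + st$muy^2 + c1)
  co <- (2 * sx * sy + c2) / (sx^2 + sy^2 + c2)
  s <- (st$sxy + c3) / (sx * sy + c3)
  l * co * s
}

# ---- universal image quality index family ---------------------------------

# Per-window means, unbiased variances and covariance over all n x n sliding
# windows (step 1).  Returned as (M-n+1) x (N-n+1) matrices.
uiqi_stats <- function(a, b, n = 8L) {
  ones <- matrix(1, n, n)
  nn <- n * n
  s1a <- filter_valid(a, ones); s1b <- filter_valid(b, ones)
  mua <- s1a / nn; mub <- s1b / nn
  va <- (filter_valid(a * a, ones) - s1a^2 / nn) / (nn - 1)
  vb <- (filter_valid(b * b, ones) - s1b^2 / nn) / (nn - 1)
  cab <- (filter_valid(a * b, ones) - s1a * s1b / nn) / (nn - 1)
  list(mua = mua, mub = mub, va = va, vb = vb, cab = cab)
}

# Combined-form Q0 per window: 4*cov*mua*mub / ((va+vb)(mua^2+mub^2)).
# Windows with zero variance or zero mean energy are undefined (NA).
q0_map <- function(st, eps = 1e-12) {
  den1 <- st$va + st$vb
  den2 <- st$mua^2 + st$mub^2
  out <- 4 * st$cab * st$mua * st$mub / (den1 * den2)
  out[den1 <= eps | den2 <= eps] <- NA_real_
  out
}

#' Universal image quality index (Q0) and its fusion extensions
#'
#' `q0()` averages the windowed universal quality index (correlation x
#' luminance x contrast agreement) over all 8x8 sliding windows, skipping
#' degenerate zero-variance windows.  `qabf()` blends `Q0(a,f|w)` and
#' `Q0(b,f|w)` per window with saliency weights
#' `lambda(w) = s(a|w) / (s(a|w)+s(b|w))` (saliency = local variance);
#' `qw()` additionally weights windows by their overall saliency
#' `C(w) = max(s(a|w), s(b|w))`, normalised over windows; `qe()` combines
#' `qw` on the images and on their gradient-magnitude edge images as
#' `qw^(1-alpha) * qw_edges^alpha` (negative values floored at 0 before a
#' fractional exponent, where the power would be undefined).
#'
#' @param a,b,f grayscale matrices of a common shape, min dimension >= 8.
#' @param window sliding window size (default 8).
#' @param alpha_edge contribution of the edge images in `qe()`.
#' @return Scalar in \[-1, 1\] (`qe`: \[0, 1\]).
#' @export
q0 <- function(a, b, window = 8L) {
  assert_same_shape("metrics", a, b)
  if (min(dim(a)) < window) stop_stage("metrics", "image smaller than window")
  v <- q0_map(uiqi_stats(a, b, window))
  v <- v[!is.na(v)]
  if (!length(v)) {
    warning("all windows degenerate; Q0 undefined")
    return(NA_real_)
  }
  mean(v)
}

# Per-window pieces shared by qabf and qw: blended Q0 and window saliency.
piella_windows <- function(a, b, f, window = 8L, eps = 1e-12) {
  sa <- uiqi_stats(a, f, window)
  sb <- uiqi_stats(b, f, window)
  q_af <- q0_map(sa, eps)
  q_bf <- q0_map(sb, eps)
  va <- sa$va   # saliency of a per window (local variance)
  vb <- sb$va
  lam <- ifelse(va + vb <= eps, 0.5, va / (va + vb))
  blended <- lam * q_af + (1 - lam) * q_bf
  keep <- !is.na(blended)
  list(blended = blended[keep], cw = pmax(va, vb)[keep], any = any(keep))
}

#' @rdname q0
#' @export
qabf <- function(a, b, f, window = 8L) {
  assert_same_shape("metrics", a, b, f)
  if (min(dim(a)) < window) stop_stage("metrics", "image smaller than window")
  pw <- piella_windows(a, b, f, window)
  if (!pw$any) return(NA_real_)
  mean(pw$blended)
}

#' @rdname q0
#' @export
qw <- function(a, b, f, window = 8L) {
  assert_same_shape("metrics", a, b, f)
  if (min(dim(a)) < window) stop_stage("metrics", "image smaller than window")
  pw <- piella_windows(a, b, f, window)
  if (!pw$any) return(NA_real_)
  tot <- sum(pw$cw)
  if (tot <= 0) return(mean(pw$blended))  # uniform weights when saliency flat
  sum(pw$cw / tot * pw$blended)
}

#' @rdname q0
#' @export
qe <- function(a, b, f, alpha_edge = 0.5, window = 8L) {
  # negative qw is floored at 0 only where a fractional power would be
  # undefined, so the exponent-collapse identities at alpha 0 and 1 are exact
  pw <- function(v, e) {
    if (e == 0) 1 else if (e == 1) v else max(v, 0)^e
  }
  q1 <- qw(a, b, f, window)
  q2 <- qw(grad_mag(a), grad_mag(b), grad_mag(f), window)
  pw(q1, 1 - alpha_edge) * pw(q2, alpha_edge)
}

# ---- feature mutual information -------------------------------------------

# Mutual information (bits) between two images after independent min-max
# scaling to 64 gray levels.  Constant images carry no information: MI 0.
mi_binned <- function(x, y, bins = 64L) {
  scale_idx <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi <= lo) return(rep(0L, length(v)))
    pmin(as.integer(floor((v - lo) / (hi - lo) * bins)), bins - 1L)
  }
  ix <- scale_idx(x); iy <- scale_idx(y)
  joint <- tabulate(ix * bins + iy + 1L, bins * bins) / length(x)
  jm <- matrix(joint, bins, bins, byrow = TRUE)  # rows: x bins
  px <- rowSums(jm); py <- colSums(jm)
  pp <- outer(px, py)
  pos <- jm > 0
  sum(jm[pos] * log2(jm[pos] / pp[pos]))
}

#' Feature mutual information (FMI)
#'
#' Mutual information between gradient-magnitude feature images of the
#' fused image and each source, summed:
#' `MI(feat(f), feat(a)) + MI(feat(f), feat(b))`, with 64-bin joint
#' histograms and base-2 logs.
#'
#' @inheritParams cross_entropy_ce
#' @param bins joint-histogram bins per axis.
#' @return Non-negative information in bits.
#' @export
fmi <- function(a, b, f, bins = 64L) {
  assert_same_shape("metrics", a, b, f)
  ff <- grad_mag(f)
  mi_binned(ff, grad_mag(a), bins) + mi_binned(ff, grad_mag(b), bins)
}

# ---- visual information fidelity ------------------------------------------

#' Pixel-domain visual information fidelity (VIF)
#'
#' Four-scale pixel-domain VIF: per scale the images are Gaussian filtered
#' and 2x downsampled, local statistics are taken over Gaussian windows, and
#' each block's distorted-channel information is compared to the reference
#' information under an additive-noise channel with variance `sigma_nsq`
#' (default 2 on the 0-255 scale, to which \[0,1\] inputs are rescaled).
#' `vif(x, x)` is 1 up to degenerate-block guards; information-losing
#' distortions give values below 1.  Scales whose filtered image has no
#' valid window (very small inputs) are skipped.
#'
#' @param ref,dist reference and distorted grayscale matrices, min dimension
#'   >= 32.
#' @param sigma_nsq channel noise variance on the 0-255 intensity scale.
#' @return Non-negative fidelity; 1 for identical images.
#' @export
vif <- function(ref, dist, sigma_nsq = 2) {
  assert_same_shape("metrics", ref, dist)
  if (min(dim(ref)) < 32L)
    stop_stage("metrics", "VIF needs images of at least 32x32")
  eps <- 1e-10
  r <- ref * 255; d <- dist * 255
  num <- 0; den <- 0
  for (scale in 1:4) {
    k <- 2L^(4L - scale + 1L) + 1L
    win <- gaussian_kernel(k, k / 5)
    if (scale > 1) {
      if (min(dim(r)) < k) break
      r <- filter_valid(r, win)
      d <- filter_valid(d, win)
      r <- r[seq(1L, nrow(r), by = 2L), seq(1L, ncol(r), by = 2L), drop = FALSE]
      d <- d[seq(1L, nrow(d), by = 2L), seq(1L, ncol(d), by = 2L), drop = FALSE]
    }
    if (min(dim(r)) < k) break
    mu1 <- filter_valid(r, win); mu2 <- filter_valid(d, win)
    s1 <- pmax(filter_valid(r * r, win) - mu1^2, 0)
    s2 <- pmax(filter_valid(d * d, win) - mu2^2, 0)
    s12 <- filter_valid(r * d, win) - mu1 * mu2
    g <- s12 / (s1 + eps)
    sv <- s2 - g * s12
    g[s1 < eps] <- 0; sv[s1 < eps] <- s2[s1 < eps]; s1[s1 < eps] <- 0
    sv[s2 < eps] <- 0; g[s2 < eps] <- 0
    sv[g < 0] <- s2[g < 0]; g[g < 0] <- 0
    sv[sv <= eps] <- eps
    num <- num + sum(log10(1 + g^2 * s1 / (sv + sigma_nsq)))
    den <- den + sum(log10(1 + s1 / sigma_nsq))
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' @rdname vif
#' @param a,b,f source and fused images; the fused VIF averages
#'   `vif(a, f)` and `vif(b, f)` with equal weight.
#' @export
vif_fused <- function(a, b, f, sigma_nsq = 2) {
  0.5 * vif(a, f, sigma_nsq) + 0.5 * vif(b, f, sigma_nsq)
}

# ---- report ----------------------------------------------------------------

#' Evaluate all ten fusion metrics for a triple
#'
#' Populates a `metric_report` with EN, CE, RMSE, AG, SSIM, FMI, Qabf, Qw,
#' Qe and VIF for a (source a, source b, fused f) triple, echoing the
#' parameters used.  For colour fusion results, pass the fused image's luma
#' against the structural image and the functional luma.
#'
#' @inheritParams cross_entropy_ce
#' @param params optional overrides: `eta_a`, `eta_b`, `wa`, `wb`,
#'   `ssim_window`, `q_window`, `alpha_edge`, `fmi_bins`, `sigma_nsq`.
#' @return A `metric_report`: named metric values plus the parameter echo.
#' @examples
#' a <- matrix(runif(64 * 64), 64, 64)
#' rep <- evaluate_all(a, a, a)
#' rep$values[c("SSIM", "RMSE")]
#' @export
evaluate_all <- function(a, b, f, params = list()) {
  assert_same_shape("metrics", a, b, f)
  p <- utils::modifyList(list(
    eta_a = 0.7, eta_b = 0.3, wa = 0.5, wb = 0.5,
    ssim_window = 11L, ssim_sigma = 1.5,
    q_window = 8L, alpha_edge = 0.5, fmi_bins = 64L, sigma_nsq = 2
  ), params)
  vals <- c(
    EN = entropy_en(f),
    CE = cross_entropy_ce(a, b, f, p$eta_a, p$eta_b),
    RMSE = rmse_fused(a, b, f, p$wa, p$wb),
    AG = avg_gradient(f),
    SSIM = 0.5 * ssim(a, f, p$ssim_window, p$ssim_sigma) +
           0.5 * ssim(b, f, p$ssim_window, p$ssim_sigma),
    FMI = fmi(a, b, f, p$fmi_bins),
    Qabf = qabf(a, b, f, p$q_window),
    Qw = qw(a, b, f, p$q_window),
    Qe = qe(a, b, f, p$alpha_edge, p$q_window),
    VIF = vif_fused(a, b, f, p$sigma_nsq)
  )
  structure(list(values = vals, params = p), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Fusion quality report\n")
  print(round(x$values, 4))
  invisible(x)
}
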