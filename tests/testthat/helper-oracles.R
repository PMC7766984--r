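# Independent naive nested-loop oracles for the windowed metrics and small
# operations.  Everything here is written scalar-by-scalar, without reusing
# the package's filter machinery, so implementation and oracle only share
# the mathematical definitions.

rand_img <- function(m, n = m) matrix(runif(m * n), m, n)

o_hist256 <- function(x) {
  h <- numeric(256)
  for (v in as.vector(x)) {
    k <- min(max(floor(v * 256), 0), 255) + 1
    h[k] <- h[k] + 1
  }
  h
}

o_en <- function(f) {
  p <- o_hist256(f) / length(f)
  s <- 0
  for (pi in p) if (pi > 0) s <- s - pi * log2(pi)
  s
}

o_ce <- function(a, b, f, eta_a = 0.7, eta_b = 0.3) {
  sh <- function(x) { h <- o_hist256(x) + 1e-12; h / sum(h) }
  dv <- function(p, q) {
    s <- 0
    for (i in seq_along(p)) s <- s + p[i] * log(p[i] / q[i]) +
        q[i] * log(q[i] / p[i])
    s
  }
  eta_a * dv(sh(a), sh(f)) + eta_b * dv(sh(b), sh(f))
}

o_rmse <- function(a, b, f, wa = 0.5, wb = 0.5) {
  r <- function(x, y) {
    s <- 0
    for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
    sqrt(s / length(x))
  }
  wa * r(a, f) + wb * r(b, f)
}

o_ag <- function(f) {
  M <- nrow(f); N <- ncol(f)
  s <- 0
  for (i in seq_len(M - 1)) for (j in seq_len(N - 1)) {
    dx <- f[i, j] - f[i + 1, j]
    dy <- f[i, j] - f[i, j + 1]
    s <- s + sqrt((dx^2 + dy^2) / 2)
  }
  s / ((M - 1) * (N - 1))
}

o_gauss_kernel <- function(size, sigma) {
  half <- (size - 1) / 2
  k <- matrix(0, size, size)
  for (i in 1:size) for (j in 1:size)
    k[i, j] <- exp(-((i - 1 - half)^2 + (j - 1 - half)^2) / (2 * sigma^2))
  k / sum(k)
}

o_ssim <- function(x, y, window = 11, sigma = 1.5,
                   c1 = 0.01^2, c2 = 0.03^2) {
  k <- o_gauss_kernel(window, sigma)
  c3 <- c2 / 2
  M <- nrow(x); N <- ncol(x)
  vals <- c()
  for (i in seq_len(M - window + 1)) for (j in seq_len(N - window + 1)) {
    wx <- x[i:(i + window - 1), j:(j + window - 1)]
    wy <- y[i:(i + window - 1), j:(j + window - 1)]
    mux <- sum(k * wx); muy <- sum(k * wy)
    sxx <- sum(k * wx * wx) - mux^2
    syy <- sum(k * wy * wy) - muy^2
    sxy <- sum(k * wx * wy) - mux * muy
    sx <- sqrt(max(sxx, 0)); sy <- sqrt(max(syy, 0))
    l <- (2 * mux * muy + c1) / (mux^2 + muy^2 + c1)
    co <- (2 * sx * sy + c2) / (sx^2 + sy^2 + c2)
    st <- (sxy + c3) / (sx * sy + c3)
    vals <- c(vals, l * co * st)
  }
  mean(vals)
}

# Per-window UIQI pieces used by the Q0 family oracles.
o_uiqi_window <- function(wa, wb, eps = 1e-12) {
  n <- length(wa)
  mua <- mean(wa); mub <- mean(wb)
  va <- sum((wa - mua)^2) / (n - 1)
  vb <- sum((wb - mub)^2) / (n - 1)
  cab <- sum((wa - mua) * (wb - mub)) / (n - 1)
  den1 <- va + vb; den2 <- mua^2 + mub^2
  q <- if (den1 <= eps || den2 <= eps) NA_real_
       else 4 * cab * mua * mub / (den1 * den2)
  list(q = q, va = va, vb = vb)
}

o_q0 <- function(a, b, window = 8) {
  M <- nrow(a); N <- ncol(a)
  vals <- c()
  for (i in seq_len(M - window + 1)) for (j in seq_len(N - window + 1)) {
    w <- o_uiqi_window(a[i:(i + window - 1), j:(j + window - 1)],
                       b[i:(i + window - 1), j:(j + window - 1)])
    if (!is.na(w$q)) vals <- c(vals, w$q)
  }
  mean(vals)
}

# Shared loop for qabf (saliency-blended mean) and qw (saliency-weighted).
o_piella <- function(a, b, f, window = 8, eps = 1e-12) {
  M <- nrow(a); N <- ncol(a)
  blended <- cw <- c()
  for (i in seq_len(M - window + 1)) for (j in seq_len(N - window + 1)) {
    ii <- i:(i + window - 1); jj <- j:(j + window - 1)
    waf <- o_uiqi_window(a[ii, jj], f[ii, jj])
    wbf <- o_uiqi_window(b[ii, jj], f[ii, jj])
    sa <- waf$va; sb <- wbf$va
    lam <- if (sa + sb <= eps) 0.5 else sa / (sa + sb)
    v <- lam * waf$q + (1 - lam) * wbf$q
    if (!is.na(v)) {
      blended <- c(blended, v)
      cw <- c(cw, max(sa, sb))
    }
  }
  list(blended = blended, cw = cw)
}

o_qabf <- function(a, b, f, window = 8) mean(o_piella(a, b, f, window)$blended)

o_qw <- function(a, b, f, window = 8) {
  p <- o_piella(a, b, f, window)
  if (sum(p$cw) <= 0) return(mean(p$blended))
  sum(p$cw / sum(p$cw) * p$blended)
}

o_grad_mag <- function(x) {
  M <- nrow(x); N <- ncol(x)
  g <- matrix(0, M, N)
  for (i in 1:M) for (j in 1:N) {
    gx <- if (i < M) x[i + 1, j] - x[i, j] else 0
    gy <- if (j < N) x[i, j + 1] - x[i, j] else 0
    g[i, j] <- sqrt(gx^2 + gy^2)
  }
  g
}

o_qe <- function(a, b, f, alpha = 0.5, window = 8) {
  q1 <- max(o_qw(a, b, f, window), 0)
  q2 <- max(o_qw(o_grad_mag(a), o_grad_mag(b), o_grad_mag(f), window), 0)
  q1^(1 - alpha) * q2^alpha
}

o_mi <- function(x, y, bins = 64) {
  idx <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi <= lo) return(rep(0, length(v)))
    pmin(floor((v - lo) / (hi - lo) * bins), bins - 1)
  }
  ix <- idx(as.vector(x)); iy <- idx(as.vector(y))
  joint <- matrix(0, bins, bins)
  for (k in seq_along(ix)) joint[ix[k] + 1, iy[k] + 1] <-
      joint[ix[k] + 1, iy[k] + 1] + 1
  joint <- joint / length(ix)
  px <- rowSums(joint); py <- colSums(joint)
  s <- 0
  for (i in 1:bins) for (j in 1:bins) {
    if (joint[i, j] > 0)
      s <- s + joint[i, j] * log2(joint[i, j] / (px[i] * py[j]))
  }
  s
}

o_fmi <- function(a, b, f, bins = 64) {
  ff <- o_grad_mag(f)
  o_mi(ff, o_grad_mag(a), bins) + o_mi(ff, o_grad_mag(b), bins)
}
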