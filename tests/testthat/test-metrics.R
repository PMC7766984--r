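test_that("histogram entropy hits its closed-form anchor cases", {
  expect_equal(entropy_en(matrix(0.4, 8, 8)), 0)
  half <- matrix(rep(c(0, 1), each = 32), 8, 8)
  expect_equal(entropy_en(half), 1)
  ramp <- matrix((0:255) / 256, 16, 16)  # each of the 256 bins exactly once
  expect_equal(entropy_en(ramp), 8)
})

test_that("cross entropy is a symmetric divergence, zero at identity", {
  set.seed(61)
  a <- rand_img(16); b <- rand_img(16)
  expect_equal(cross_entropy_ce(a, a, a), 0, tolerance = 1e-9)
  d1 <- cross_entropy_ce(a, a, b, eta_a = 1, eta_b = 0)
  d2 <- cross_entropy_ce(b, b, a, eta_a = 1, eta_b = 0)
  expect_equal(d1, d2, tolerance = 1e-9)   # D(P:Q) = D(Q:P) by construction
  expect_gt(d1, 0)
})

test_that("rmse and average gradient match constant-offset closed forms", {
  set.seed(62)
  a <- rand_img(12) * 0.8
  f <- a + 0.1
  expect_equal(rmse_fused(a, f, f), 0.5 * 0.1, tolerance = 1e-12)
  expect_equal(rmse_fused(a, a, a), 0)
  expect_equal(avg_gradient(matrix(0.7, 9, 9)), 0)
  # horizontal ramp with step s per column: AG = s/sqrt(2)
  s <- 0.02
  ramp <- matrix(rep(s * (0:9), each = 10), 10, 10)
  expect_equal(avg_gradient(ramp), s / sqrt(2), tolerance = 1e-12)
  # adding high-frequency detail increases AG
  base <- matrix(0.5, 16, 16)
  checker <- 0.1 * outer(1:16, 1:16, function(i, j) (-1)^(i + j))
  expect_gt(avg_gradient(base + checker), avg_gradient(base))
})

test_that("ssim is 1 at identity, symmetric, and penalises luminance shift", {
  set.seed(63)
  x <- rand_img(20)
  expect_equal(ssim(x, x), 1, tolerance = 1e-9)
  expect_lt(ssim(x, pmin(x + 0.5, 1)), 1)
  y <- rand_img(20)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  expect_error(ssim(rand_img(8), rand_img(8)), class = "medfuse_error")
})

test_that("q0 family satisfies its identity and reduction properties", {
  set.seed(64)
  a <- rand_img(16); b <- rand_img(16); f <- rand_img(16)
  expect_equal(q0(a, a), 1, tolerance = 1e-9)
  expect_lt(q0(a, 1 - a), 0)  # anti-correlated
  expect_equal(qabf(a, a, a), 1, tolerance = 1e-9)
  expect_equal(qw(a, a, a), 1, tolerance = 1e-9)
  expect_equal(qe(a, a, a, 0.3), 1, tolerance = 1e-9)
  # b = a collapses the blend to q0(a, f)
  expect_equal(qabf(a, a, f), q0(a, f), tolerance = 1e-9)
  # exponent collapse
  expect_equal(qe(a, b, f, alpha_edge = 0), qw(a, b, f), tolerance = 1e-12)
  ga <- medfuse:::grad_mag(a); gb <- medfuse:::grad_mag(b)
  gf <- medfuse:::grad_mag(f)
  expect_equal(qe(a, b, f, alpha_edge = 1), qw(ga, gb, gf),
               tolerance = 1e-12)
  for (rep in 1:5) {
    v <- qw(rand_img(12), rand_img(12), rand_img(12))
    expect_gte(v, -1); expect_lte(v, 1)
  }
})

test_that("feature mutual information behaves like an information measure", {
  set.seed(65)
  a <- rand_img(64)
  # identical triple: each MI term is the feature entropy
  ha <- o_mi(medfuse:::grad_mag(a), medfuse:::grad_mag(a))
  expect_equal(fmi(a, a, a), 2 * ha, tolerance = 1e-9)
  # independent noise shares almost no information
  x <- rand_img(256); y <- rand_img(256)
  expect_lt(o_mi(x, y) , 0.05)
  expect_gt(fmi(a, a, a), 0)
})

test_that("vif is 1 at identity and decreases under blur and noise", {
  set.seed(66)
  x <- unclass(make_structural(64, seed = 9))
  attributes(x) <- list(dim = dim(x))
  expect_equal(vif(x, x), 1, tolerance = 1e-6)
  blur <- medfuse:::gaussian_blur(x, 1.2)
  expect_lt(vif(x, blur), 1)
  noisy <- medfuse:::clamp01(x + matrix(rnorm(64 * 64, sd = 0.05), 64, 64))
  expect_lt(vif(x, noisy), vif(x, x))
  expect_error(vif(rand_img(16), rand_img(16)), class = "medfuse_error")
})

test_that("evaluate_all is deterministic and correct on the identity triple", {
  set.seed(67)
  a <- rand_img(64)
  r <- evaluate_all(a, a, a)
  v <- r$values
  expect_equal(unname(v["SSIM"]), 1, tolerance = 1e-9)
  expect_equal(unname(v["RMSE"]), 0)
  expect_equal(unname(v["CE"]), 0, tolerance = 1e-9)
  expect_equal(unname(v[c("Qabf", "Qw", "Qe")]), c(1, 1, 1),
               tolerance = 1e-9)
  expect_equal(unname(v["VIF"]), 1, tolerance = 1e-6)
  expect_named(v, c("EN", "CE", "RMSE", "AG", "SSIM", "FMI",
                    "Qabf", "Qw", "Qe", "VIF"))
  expect_equal(r$params$eta_a, 0.7)
  r2 <- evaluate_all(a, a, a)
  expect_identical(r$values, r2$values)
})

test_that("windowed metrics agree with naive nested-loop oracles", {
  set.seed(68)
  for (rep in 1:6) {
    a <- rand_img(16); b <- rand_img(16); f <- rand_img(16)
    expect_equal(entropy_en(f), o_en(f), tolerance = 1e-9)
    expect_equal(cross_entropy_ce(a, b, f), o_ce(a, b, f), tolerance = 1e-9)
    expect_equal(rmse_fused(a, b, f), o_rmse(a, b, f), tolerance = 1e-9)
    expect_equal(avg_gradient(f), o_ag(f), tolerance = 1e-9)
    expect_equal(ssim(a, f), o_ssim(a, f), tolerance = 1e-9)
    expect_equal(q0(a, f), o_q0(a, f), tolerance = 1e-9)
    expect_equal(qabf(a, b, f), o_qabf(a, b, f), tolerance = 1e-9)
    expect_equal(qw(a, b, f), o_qw(a, b, f), tolerance = 1e-9)
    expect_equal(qe(a, b, f), o_qe(a, b, f), tolerance = 1e-9)
    expect_equal(fmi(a, b, f), o_fmi(a, b, f), tolerance = 1e-9)
  }
})
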