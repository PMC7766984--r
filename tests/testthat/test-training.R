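test_that("cross-entropy loss matches closed forms and a scalar loop", {
  half <- matrix(0.5, 4, 4)
  expect_equal(cross_entropy_loss(half, half), log(2), tolerance = 1e-12)
  bin <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_lt(cross_entropy_loss(bin, bin), 2e-7)
  set.seed(51)
  I <- matrix(runif(4), 2, 2); O <- matrix(runif(4) * 0.8 + 0.1, 2, 2)
  s <- 0
  for (k in 1:4) s <- s - (I[k] * log(O[k]) + (1 - I[k]) * log(1 - O[k]))
  expect_equal(cross_entropy_loss(I, O), s / 4, tolerance = 1e-12)
  expect_equal(cross_entropy_loss(I, O, reduction = "sum"), s,
               tolerance = 1e-12)
  expect_error(cross_entropy_loss(I, matrix(0.5, 3, 3)),
               class = "medfuse_error")
})

test_that("ssim loss is zero at identity and bounded in [0,2]", {
  set.seed(52)
  x <- matrix(runif(16 * 16), 16, 16)
  expect_equal(ssim_loss(x, x), 0, tolerance = 1e-12)
  anti <- ssim_loss(x, 1 - x)
  expect_gt(anti, 1)   # anti-correlated high-contrast pair
  expect_lte(anti, 2)
  for (rep in 1:5) {
    a <- matrix(runif(144), 12, 12); b <- matrix(runif(144), 12, 12)
    v <- ssim_loss(a, b)
    expect_gte(v, 0); expect_lte(v, 2)
  }
})

test_that("mixed loss is the stated linear combination", {
  set.seed(53)
  I <- matrix(runif(12 * 12), 12, 12)
  O <- matrix(runif(12 * 12) * 0.98 + 0.01, 12, 12)
  expect_equal(mixed_loss(I, O, alpha = 0, beta = 4), 4 * ssim_loss(I, O))
  expect_equal(mixed_loss(I, O, alpha = 2, beta = 3),
               2 * cross_entropy_loss(I, O) + 3 * ssim_loss(I, O),
               tolerance = 1e-12)
  bin <- round(I)
  expect_lt(mixed_loss(bin, pmin(pmax(bin, 1e-9), 1 - 1e-9), beta = 0), 1e-4)
  expect_error(mixed_loss(I, O, alpha = 0, beta = 0), class = "medfuse_error")
})

test_that("learning-rate schedule decays exponentially from lr0", {
  expect_identical(lr_schedule(0, 5e-4), 5e-4)
  expect_equal(lr_schedule(1, 5e-4), 0.000475)
  expect_equal(lr_schedule(10, 5e-4), 0.95^10 * 5e-4)
  expect_true(all(diff(lr_schedule(0:20, 5e-4)) < 0))
  expect_error(lr_schedule(-1, 5e-4), class = "medfuse_error")
})

test_that("analytic gradients agree with finite differences", {
  arch <- net_arch(width = 2L, dec_widths = c(2L, 2L))
  p <- init_net_params(arch, seed = 55)
  set.seed(55)
  img <- matrix(runif(14 * 14), 14, 14)
  g <- medfuse:::autoencoder_grads(img, p, alpha = 500, beta = 1)
  lossfn <- function(pp) {
    enc <- medfuse:::encoder_forward(img, pp)
    dec <- medfuse:::decoder_forward(enc$stack, 14, 14, pp)
    medfuse:::mixed_loss_grad_logit(img, matrix(dec$O, 14, 14), 500, 1)$loss
  }
  h <- 1e-6
  for (nm in c("C1", "CIDN1", "CIDN2", "CIDN3", "D1", "D2", "D3")) {
    i <- sample(length(p$layers[[nm]]$W), 1)
    pp <- p; pp$layers[[nm]]$W[i] <- pp$layers[[nm]]$W[i] + h
    pm <- p; pm$layers[[nm]]$W[i] <- pm$layers[[nm]]$W[i] - h
    fd <- (lossfn(pp) - lossfn(pm)) / (2 * h)
    expect_equal(g$grads[[nm]]$W[i], fd, tolerance = 1e-4)
  }
})

test_that("short training runs are logged, deterministic and improving", {
  corpus <- make_training_corpus(24, 32, seed = 3)
  cfg <- train_config(epochs = 3, batch_size = 8, seed = 7)
  p1 <- train_autoencoder(corpus, cfg,
                          net_arch(width = 6L, dec_widths = c(6L, 4L)))
  log1 <- attr(p1, "loss_log")
  expect_equal(nrow(log1), 3)
  expect_equal(log1$lr, lr_schedule(0:2, cfg$lr0))
  expect_lt(log1$loss[3], log1$loss[1])
  p2 <- train_autoencoder(corpus, cfg,
                          net_arch(width = 6L, dec_widths = c(6L, 4L)))
  expect_identical(log1, attr(p2, "loss_log"))       # determinism contract
  expect_identical(p1$layers, p2$layers)
  expect_error(train_autoencoder(list(), cfg), class = "medfuse_error")
})

test_that("the medfuse fit object exposes the usual model methods", {
  fit <- medfuse(n_corpus = 12, size = 32, epochs = 2, batch_size = 6,
                 seed = 2, arch = net_arch(width = 4L, dec_widths = c(4L, 2L)))
  expect_s3_class(fit, "medfuse")
  expect_equal(nrow(fit$loss_log), 2)
  expect_output(print(fit), "fusion model")
  expect_output(print(summary(fit)), "Training log")
  expect_named(coef(fit), c("C1", "CIDN1", "CIDN2", "CIDN3", "D1", "D2", "D3"))
  img <- matrix(runif(32 * 32), 32, 32)
  rec <- predict(fit, img, type = "reconstruction")
  expect_equal(dim(rec), c(32L, 32L))
  expect_equal(residuals(fit, img), img - rec)
  pair <- make_phantom_pair(32, seed = 5)
  fused <- predict(fit, pair)
  expect_s3_class(fused, "color_image")
  expect_equal(dim(fused)[1:2], c(32L, 32L))
})
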