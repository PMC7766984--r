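test_that("non-membership is the linear ramp between the image extrema", {
  img <- matrix(c(0.2, 0.5, 0.8, 0.5), 2, 2)
  nu <- non_membership(img)
  expect_equal(nu[cbind(1, 1)], 1)      # g = gmin
  expect_equal(nu[cbind(1, 2)], 0)      # g = gmax
  expect_equal(nu[2, 1], 0.5)           # midpoint
  expect_true(all(nu >= 0 & nu <= 1))
})

test_that("fuzzy images obey their closed forms and nu + xi = 1", {
  set.seed(21)
  img <- matrix(runif(64), 8, 8)
  im1 <- ifs_images(img, 1)
  expect_equal(im1$nu, non_membership(img))
  for (lam in c(0.5, 2, 200, 800)) {
    im <- ifs_images(img, lam)
    expect_identical(im$nu + im$xi, matrix(1, 8, 8))
    expect_true(all(im$mu >= 0 & im$mu <= 1))
  }
  # nu = 0.5 squared is 0.25, xi = 0.75
  two <- matrix(c(0, 1, 0.5, 0.5), 2, 2)
  im2 <- ifs_images(two, 2)
  expect_equal(im2$nu[1, 2], 0.25)
  expect_equal(im2$xi[1, 2], 0.75)
  expect_error(ifs_images(img, 0), class = "medfuse_error")
  expect_error(ifs_images(img, -3), class = "medfuse_error")
})

test_that("entropy is a normalized symmetry measure in [0,1]", {
  # at lam = 1, mu = (g-gmin)/(gmax-gmin) and xi = 1 - nu = mu, so every
  # pixel term is 1 except the gmin pixel where mu = xi = 0 contributes 0
  img <- matrix(c(0, 1, 0.25, 0.75), 2, 2)
  expect_equal(ifs_entropy(img, 1), 3 / 4)
  set.seed(5)
  for (lam in c(1, 10, 200, 800)) {
    e <- ifs_entropy(matrix(runif(64), 8, 8), lam)
    expect_gte(e, 0); expect_lte(e, 1)
  }
  # brute-force per-pixel evaluation on a 4x4 image
  img4 <- matrix(runif(16), 4, 4)
  lam <- 3
  gmin <- min(img4); gmax <- max(img4)
  s <- 0
  for (i in 1:4) for (j in 1:4) {
    mu <- ((img4[i, j] - gmin) / (gmax - gmin))^lam
    xi <- 1 - ((gmax - img4[i, j]) / (gmax - gmin))^lam
    s <- s + if (mu == 0 && xi == 0) 0 else 2 * mu * xi / (mu^2 + xi^2)
  }
  expect_equal(ifs_entropy(img4, lam), s / 16, tolerance = 1e-12)
})

test_that("lambda selection matches an exhaustive scan with smallest-tie rule", {
  set.seed(9)
  grid <- ifp_default_grid()
  for (rep in 1:5) {
    img <- unclass(make_structural(32, seed = rep))
    attributes(img) <- list(dim = dim(img))
    res <- select_lambda(img, grid)
    ent <- sapply(grid, function(l) ifs_entropy(img, l))
    expect_equal(res$lambda_star, grid[which.max(ent)])
    expect_equal(unname(res$entropy_by_lambda), ent)
    expect_length(res$entropy_by_lambda, length(grid))
    expect_true(all(res$enhanced >= 0 & res$enhanced <= 1))
  }
  one <- select_lambda(matrix(runif(64), 8, 8), grid = 400)
  expect_equal(one$lambda_star, 400)
})

test_that("constant images pass through with a degenerate warning", {
  flat <- matrix(0.5, 8, 8)
  expect_warning(res <- select_lambda(flat), "constant")
  expect_true(res$degenerate)
  expect_equal(res$enhanced, flat)
  expect_equal(res$lambda_star, ifp_default_grid()[1])
  expect_warning(out <- ifp_preprocess(flat), "constant")
  expect_equal(out, flat)
})

test_that("enhancement is monotone in intensity and bypassable", {
  set.seed(13)
  img <- matrix(runif(256), 16, 16)
  enh <- ifp_preprocess(img)
  ord <- order(img)
  expect_true(all(diff(enh[ord]) >= 0))
  expect_true(all(enh >= 0 & enh <= 1))
  expect_identical(ifp_preprocess(img, enabled = FALSE), img)
})
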