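test_that("map_trace sums the main diagonal, also for rectangular maps", {
  expect_equal(map_trace(diag(3)), 3)
  expect_equal(map_trace(matrix(0, 4, 7)), 0)
  m <- matrix(seq_len(12), 3, 4)
  expect_equal(map_trace(m), m[1, 1] + m[2, 2] + m[3, 3])
})

test_that("trace of a symmetric map equals the sum of its eigenvalues", {
  set.seed(41)
  for (rep in 1:10) {
    a <- matrix(rnorm(36), 6, 6)
    s <- (a + t(a)) / 2
    expect_equal(map_trace(s), sum(eigen(s, only.values = TRUE)$values),
                 tolerance = 1e-8)
  }
})

rand_stack <- function(h, w, n) feature_stack(array(rnorm(h * w * n), c(h, w, n)))

test_that("fusion weights are a probability vector with known special cases", {
  set.seed(42)
  st <- rand_stack(6, 6, 4)
  w <- fusion_weights(list(st, st))
  expect_equal(as.numeric(w), c(0.5, 0.5), tolerance = 1e-12)
  zero <- feature_stack(array(0, c(6, 6, 4)))
  expect_equal(as.numeric(fusion_weights(list(zero, st))), c(0, 1))
  expect_equal(as.numeric(fusion_weights(list(zero, zero))), c(0.5, 0.5))
  # stacks built to have salience 1, 2, 3 -> weights 1/6, 2/6, 3/6
  mk <- function(s) feature_stack(array(diag(s / 6, 6), c(6, 6, 1)))
  w3 <- fusion_weights(list(mk(1), mk(2), mk(3)))
  expect_equal(as.numeric(w3), c(1, 2, 3) / 6, tolerance = 1e-12)
})

test_that("fusion is a convex combination with the expected identities", {
  set.seed(43)
  x <- rand_stack(5, 5, 3)
  y <- rand_stack(5, 5, 3)
  expect_equal(unclass(fuse_features(list(x, y), c(1, 0))), unclass(x),
               ignore_attr = TRUE)
  neg <- feature_stack(-unclass(x))
  expect_equal(max(abs(fuse_features(list(x, neg), c(0.5, 0.5)))), 0)
  # element-wise scalar loop on 2x2 toy maps
  a <- feature_stack(array(1:8 / 8, c(2, 2, 2)))
  b <- feature_stack(array(8:1 / 8, c(2, 2, 2)))
  w <- c(0.3, 0.7)
  fused <- fuse_features(list(a, b), w)
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    expect_equal(fused[i, j, k], 0.3 * a[i, j, k] + 0.7 * b[i, j, k])
})

test_that("weights and fused stacks respect permutation and bounds", {
  set.seed(44)
  for (rep in 1:20) {
    stacks <- lapply(1:3, function(i) rand_stack(7, 5, 3))
    w <- fusion_weights(stacks)
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_true(all(w >= 0))
    perm <- sample(3)
    wp <- fusion_weights(stacks[perm])
    expect_equal(as.numeric(wp), as.numeric(w)[perm], tolerance = 1e-12)
    expect_equal(unclass(fuse_features(stacks[perm], wp)),
                 unclass(fuse_features(stacks, w)),
                 tolerance = 1e-12, ignore_attr = TRUE)
    fused <- fuse_features(stacks, w)
    lo <- pmin(unclass(stacks[[1]]), unclass(stacks[[2]]), unclass(stacks[[3]]))
    hi <- pmax(unclass(stacks[[1]]), unclass(stacks[[2]]), unclass(stacks[[3]]))
    expect_true(all(fused >= lo - 1e-12 & fused <= hi + 1e-12))
  }
})

test_that("scaling a stack up strictly increases its weight", {
  set.seed(45)
  stacks <- list(rand_stack(6, 6, 3), rand_stack(6, 6, 3))
  w0 <- fusion_weights(stacks)
  stacks[[1]] <- feature_stack(3 * unclass(stacks[[1]]))
  w1 <- fusion_weights(stacks)
  expect_gt(w1[1], w0[1])
})

test_that("mismatched stacks are rejected", {
  expect_error(fusion_weights(list(rand_stack(4, 4, 2))),
               class = "medfuse_error")
  expect_error(fusion_weights(list(rand_stack(4, 4, 2), rand_stack(4, 4, 3))),
               class = "medfuse_error")
  expect_error(fuse_features(list(rand_stack(4, 4, 2), rand_stack(4, 4, 2)),
                             c(1, 0, 0)), class = "medfuse_error")
})
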