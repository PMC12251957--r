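test_that("mse and pixel distances match closed forms", {
  expect_equal(mse(matrix(1:4, 2), matrix(1:4, 2)), 0)
  expect_equal(mse(matrix(0, 2, 2), matrix(0.1, 2, 2)), 0.01)
  expect_equal(mse(c(0, 1), c(1, 1)), 0.5)
  pd <- pixel_distances(c(0, 0), c(0, 2))
  expect_equal(pd$mae, 1)
  expect_equal(pd$rmse, sqrt(2))
  # constant error: rmse = mae, ratio 1
  pd2 <- pixel_distances(matrix(0, 3, 3), matrix(0.2, 3, 3))
  expect_equal(pd2$mae, pd2$rmse)
  expect_equal(pd2$ratio, 1)
  # rmse >= mae always; rmse^2 = mse
  set.seed(1)
  a <- runif(100); b <- runif(100)
  pd3 <- pixel_distances(a, b)
  expect_gte(pd3$rmse, pd3$mae)
  expect_equal(pd3$rmse^2, mse(a, b), tolerance = 1e-12)
})

test_that("psnr follows 10 log10(max^2/mse), capped at zero error", {
  a <- matrix(0, 10, 10); b <- matrix(0.1, 10, 10)  # mse 0.01
  expect_equal(as.numeric(psnr(a, b)), 20)
  expect_equal(as.numeric(psnr(a, a + 1)), 0)       # mse 1 -> 0 dB
  capped <- psnr(a, a)
  expect_equal(as.numeric(capped), 120)
  expect_true(attr(capped, "capped"))
  # 8-bit scale: same image pair, max 255
  expect_equal(as.numeric(psnr(a * 255, b * 255, max_value = 255)), 20)
  # monotone: larger mse, smaller psnr
  set.seed(2)
  base <- matrix(runif(64), 8)
  noises <- c(0.01, 0.05, 0.1, 0.3)
  ps <- vapply(noises, function(s) as.numeric(psnr(base, base + s)), 0)
  expect_true(all(diff(ps) < 0))
})

test_that("spectral correlation behaves like Pearson on flattened values", {
  set.seed(3)
  x <- array(runif(48), c(4, 4, 3))
  expect_equal(as.numeric(scc(x, 2 * x + 1)), 1, tolerance = 1e-12)
  expect_equal(as.numeric(scc(x, -x)), -1, tolerance = 1e-12)
  # hand computation on 3-vectors per the definition
  y <- c(1, 2, 3); yh <- c(1, 2, 4)
  r_hand <- sum((y - mean(y)) * (yh - mean(yh))) /
    sqrt(sum((y - mean(y))^2) * sum((yh - mean(yh))^2))
  expect_equal(as.numeric(scc(y, yh)), r_hand, tolerance = 1e-12)
  # constant input is flagged undefined
  r <- scc(rep(1, 10), runif(10))
  expect_true(is.na(r))
  expect_false(attr(r, "defined"))
  # positive affine invariance in either argument
  expect_equal(as.numeric(scc(3 * x + 0.2, x)), as.numeric(scc(x, x)),
               tolerance = 1e-12)
})

test_that("global SSIM matches its closed form", {
  set.seed(4)
  x <- matrix(runif(100), 10)
  expect_equal(ssim(x, x), 1)
  # constant 0 vs constant 1: sigma terms vanish, value = C1/(1+C1) * 1
  c1 <- 1e-4
  v <- ssim(matrix(0, 4, 4), matrix(1, 4, 4), c1 = c1, c2 = 9e-4)
  expect_equal(v, c1 / (1 + c1), tolerance = 1e-12)
  # mean shift by delta: sx = sy = sxy, closed form reduction
  delta <- 0.2
  y <- x + delta
  mx <- mean(x); my <- mean(y)
  sx <- mean((x - mx)^2)
  c1d <- 0.01^2; c2d <- 0.03^2
  expected <- ((2 * mx * my + c1d) * (2 * sx + c2d)) /
    ((mx^2 + my^2 + c1d) * (2 * sx + c2d))
  expect_equal(ssim(x, y), expected, tolerance = 1e-12)
  # symmetry, and 1 only for identical inputs
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-15)
  expect_lt(ssim(x, y), 1)
  # windowed variant also rates identical images 1
  expect_equal(ssim(x, x, window = 5), 1, tolerance = 1e-9)
})

test_that("histogram similarity compares distributions, not positions", {
  set.seed(5)
  a <- matrix(runif(256), 16)
  expect_equal(as.numeric(histogram_similarity(a, a)), 1)
  # spatial permutation leaves the histogram unchanged
  perm <- matrix(sample(a), 16)
  expect_equal(as.numeric(histogram_similarity(a, perm, bins = 32,
                                               range = c(0, 1))), 1,
               tolerance = 1e-12)
  # disjoint single-bin masses with 2 bins: correlation of (1,0) vs (0,1)
  lo <- rep(0.1, 50); hi <- rep(0.9, 50)
  expect_equal(as.numeric(histogram_similarity(lo, hi, bins = 2,
                                               range = c(0, 1))), -1)
  # degenerate: both in one common bin
  d <- histogram_similarity(rep(0.5, 10), rep(0.5, 10), bins = 4,
                            range = c(0, 1))
  expect_equal(as.numeric(d), 1)
  expect_true(attr(d, "degenerate"))
})

test_that("metrics_report aggregates per-band scores", {
  set.seed(6)
  truth <- array(runif(96), c(4, 4, 6))
  pred <- truth + 0.05
  rep3 <- metrics_report(truth, pred)
  expect_equal(rep3$mse, 0.0025, tolerance = 1e-12)
  expect_equal(rep3$mae, 0.05, tolerance = 1e-12)
  expect_equal(rep3$rmse, 0.05, tolerance = 1e-12)
  expect_equal(rep3$scc, 1, tolerance = 1e-12)
  expect_lt(rep3$ssim, 1)
})
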