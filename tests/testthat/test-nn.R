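# Building-block checks for the hand-written network primitives, including
# numeric differentiation oracles for every composite block.

num_grad <- function(loss_fn, ly, nm, i, eps = 1e-6) {
  p0 <- ly[[nm]]
  p <- p0; p[i] <- p0[i] + eps; assign(nm, p, envir = ly); lp <- loss_fn()
  p[i] <- p0[i] - eps; assign(nm, p, envir = ly); lm <- loss_fn()
  assign(nm, p0, envir = ly)
  (lp - lm) / (2 * eps)
}

test_that("convolution reproduces a hand-computed 3x3 case", {
  ly <- pseudonir:::new_layer("conv", k = 3L, cin = 1L, cout = 1L,
                              W = matrix(0, 9, 1), b = 0.25)
  # weight picking only the center tap: identity + bias
  ly$W[5, 1] <- 1
  x <- array(runif(16), c(4, 4, 1, 1))
  y <- pseudonir:::conv_fw(ly, x)
  expect_equal(y[, , 1, 1], x[, , 1, 1] + 0.25, tolerance = 1e-12)
  # an off-center tap shifts the image (zero padding at the border):
  # patch column 4 reads the pixel one row above, so content moves down
  ly$W[] <- 0; ly$b <- 0
  ly$W[4, 1] <- 1
  y2 <- pseudonir:::conv_fw(ly, x)
  expect_equal(y2[2:4, , 1, 1], x[1:3, , 1, 1], tolerance = 1e-12)
  expect_equal(y2[1, , 1, 1], rep(0, 4))
})

test_that("max-pool and nearest upsample are exact inverses on constants", {
  x <- array(runif(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  mp <- pseudonir:::maxpool_fw(x)
  expect_identical(dim(mp$y), c(4L, 4L, 2L, 2L))
  # each pooled value is the max of its 2x2 block
  expect_equal(mp$y[1, 1, 1, 1], max(x[1:2, 1:2, 1, 1]))
  expect_equal(mp$y[4, 3, 2, 1], max(x[7:8, 5:6, 2, 1]))
  up <- pseudonir:::upsample_fw(mp$y)
  expect_identical(dim(up), dim(x))
  expect_equal(up[1:2, 1:2, 1, 1], array(mp$y[1, 1, 1, 1], c(2, 2)))
  # pool-gradient scatters to the argmax position only
  dy <- array(1, dim(mp$y))
  dx <- pseudonir:::maxpool_bw(dy, mp)
  expect_equal(sum(dx != 0), length(mp$y))
  expect_equal(sum(dx), sum(dy))
})

test_that("batch norm standardizes per channel in training mode", {
  set.seed(1)
  ly <- pseudonir:::bn_layer(3L)
  x <- array(rnorm(6 * 6 * 3 * 4, mean = 5, sd = 2), c(6, 6, 3, 4))
  y <- pseudonir:::bn_fw(ly, x, train = TRUE)
  M <- pseudonir:::chan_mat(y)
  expect_equal(colMeans(M), rep(0, 3), tolerance = 1e-9)
  expect_equal(apply(M, 2, stats::sd), rep(1, 3), tolerance = 1e-2)
  # running stats move toward the batch stats
  expect_true(all(ly$run_mean > 0))
})

test_that("mixer with zero dense weights is a residual passthrough", {
  set.seed(2)
  ly <- pseudonir:::mixer_layer(4L, expansion = 2L)
  ly$fc1$W[] <- 0; ly$fc1$b[] <- 0; ly$fc2$W[] <- 0; ly$fc2$b[] <- 0
  x <- array(rnorm(3 * 3 * 4 * 2), c(3, 3, 4, 2))
  y <- pseudonir:::mixer_fw(ly, x, train = TRUE)
  xbn <- pseudonir:::bn_fw(pseudonir:::bn_layer(4L), x, train = TRUE)
  expect_equal(y, xbn, tolerance = 1e-12)
})

test_that("mixer is equivariant to spatial permutations", {
  set.seed(3)
  ly <- pseudonir:::mixer_layer(4L)
  x <- array(rnorm(2 * 2 * 4), c(2, 2, 4, 1))
  y <- pseudonir:::mixer_fw(ly, x, train = TRUE)
  # swap the two rows: all mixer ops act per pixel along channels
  xp <- x[c(2, 1), , , , drop = FALSE]
  yp <- pseudonir:::mixer_fw(ly, xp, train = TRUE)
  expect_equal(yp, y[c(2, 1), , , , drop = FALSE], tolerance = 1e-12)
})

test_that("CBAM preserves shape, damps magnitudes and passes zeros", {
  set.seed(4)
  ly <- pseudonir:::cbam_layer(8L, reduction = 4L, spatial_kernel = 7L)
  x <- array(rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2))
  y <- pseudonir:::cbam_fw(ly, x)
  expect_identical(dim(y), dim(x))
  # both attention gates are sigmoids: |y| <= |x| elementwise
  expect_true(all(abs(y) <= abs(x) + 1e-12))
  expect_true(all(pseudonir:::cbam_fw(ly, array(0, dim(x))) == 0))
  expect_error(pseudonir:::cbam_layer(8L, reduction = 16L),
               class = "pseudonir_config_error")
})

test_that("multi-scale block has the contracted structure", {
  set.seed(5)
  ly <- pseudonir:::msc_layer(6L, kernels = c(3L, 5L, 7L))
  # three branch convs C -> C and a 1x1 reduce from 3C
  expect_length(ly$branches, 3L)
  expect_identical(dim(ly$reduce$W), c(18L, 6L))
  x <- array(rnorm(4 * 4 * 6 * 2), c(4, 4, 6, 2))
  y <- pseudonir:::msc_fw(ly, x, train = TRUE)
  expect_identical(dim(y), dim(x))
  # zero weights everywhere: output collapses to 0 (residual adds 0 too)
  for (br in ly$branches) { br$W[] <- 0; br$b[] <- 0 }
  ly$reduce$W[] <- 0; ly$reduce$b[] <- 0
  ly$mixer$fc1$W[] <- 0; ly$mixer$fc1$b[] <- 0
  ly$mixer$fc2$W[] <- 0; ly$mixer$fc2$b[] <- 0
  ly$mixer$bn$gamma[] <- 0
  y0 <- pseudonir:::msc_fw(ly, x, train = TRUE)
  expect_true(all(y0 == 0))
})

test_that("composite blocks backpropagate exact gradients", {
  set.seed(6)
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  t <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  blocks <- list(
    mixer = list(ly = pseudonir:::mixer_layer(4L),
                 fw = function(ly, z) pseudonir:::mixer_fw(ly, z, TRUE),
                 bw = pseudonir:::mixer_bw),
    msc = list(ly = pseudonir:::msc_layer(4L),
               fw = function(ly, z) pseudonir:::msc_fw(ly, z, TRUE),
               bw = pseudonir:::msc_bw),
    cbam = list(ly = pseudonir:::cbam_layer(4L, reduction = 2L,
                                            spatial_kernel = 3L),
                fw = pseudonir:::cbam_fw,
                bw = pseudonir:::cbam_bw))
  for (bname in names(blocks)) {
    b <- blocks[[bname]]
    loss_fn <- function() mean((b$fw(b$ly, x) - t)^2)
    y <- b$fw(b$ly, x)
    dy <- 2 * (y - t) / length(y)
    b$bw(b$ly, dy)
    lys <- pseudonir:::collect_layers(b$ly)
    for (ly in lys) {
      for (nm in pseudonir:::layer_param_names(ly)) {
        g <- ly$grads[[nm]]
        if (is.null(g)) next
        nz <- which(abs(g) > 1e-7)
        if (!length(nz)) next
        i <- nz[1]
        expect_equal(g[i], num_grad(loss_fn, ly, nm, i), tolerance = 1e-4,
                     label = paste(bname, ly$type, nm, "gradient"))
      }
    }
  }
})

test_that("Adam reduces the loss of a small regression layer", {
  set.seed(7)
  ly <- pseudonir:::dense_layer(3L, 1L)
  X <- matrix(rnorm(300), 100, 3)
  yt <- X %*% c(1, -2, 0.5) + 0.1
  opt <- pseudonir:::make_adam(ly, lr = 0.05)
  loss0 <- mean((pseudonir:::dense_fw(ly, X) - yt)^2)
  for (i in 1:200) {
    pred <- pseudonir:::dense_fw(ly, X)
    pseudonir:::dense_bw(ly, 2 * (pred - yt) / length(yt))
    opt$step()
  }
  loss1 <- mean((pseudonir:::dense_fw(ly, X) - yt)^2)
  expect_lt(loss1, loss0 / 100)
  expect_equal(as.numeric(ly$W), c(1, -2, 0.5), tolerance = 0.05)
})
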