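small_cfg <- function(...) {
  fusenet_config("tiny", input_hw = c(16, 16),
                 encoder_widths = c(4L, 8L, 12L, 16L),
                 bottleneck_width = 24L, cbam_reduction = 2L, seed = 7L, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(fusenet_config("tiny", input_hw = c(30, 32)),
               class = "pseudonir_config_error")
  expect_error(fusenet_config("tiny", encoder_widths = c(8L, 8L, 32L, 64L)),
               class = "pseudonir_config_error")
  expect_error(fusenet_config("tiny", msc_kernels = c(3L, 4L, 7L)),
               class = "pseudonir_config_error")
  expect_error(fusenet_train_config("tiny", val_split = 0),
               class = "pseudonir_config_error")
  # paper preset carries the published hyperparameters
  tc <- fusenet_train_config("paper")
  expect_equal(tc$learning_rate, 2e-4)
  expect_equal(tc$batch_size, 16L)
  expect_equal(tc$max_epochs, 450L)
  expect_equal(tc$early_stop_patience, 30L)
  expect_equal(tc$plateau_patience, 10L)
  expect_equal(tc$plateau_factor, 0.5)
  expect_equal(tc$val_split, 0.2)
  expect_setequal(tc$augmentation, c("flip", "rotation", "zoom"))
  mc <- fusenet_config("paper")
  expect_equal(mc$encoder_widths, c(64L, 128L, 256L, 512L))
  expect_equal(mc$bottleneck_width, 1024L)
})

test_that("forward pass maps inputs to same-size 3-band stacks", {
  m <- build_fusenet(small_cfg())
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  out <- pseudonir:::fusenet_forward(m, x)
  expect_identical(dim(out$y), c(16L, 16L, 3L, 2L))
  # deterministic given fixed weights
  out2 <- pseudonir:::fusenet_forward(m, x)
  expect_identical(out$y, out2$y)
  # same seed rebuilds identical weights
  m2 <- build_fusenet(small_cfg())
  expect_identical(pseudonir:::snapshot_params(m$layers),
                   pseudonir:::snapshot_params(m2$layers))
})

test_that("ablation variants nest strictly by parameter count", {
  n_par <- function(um, us) pseudonir:::n_parameters(
    build_fusenet(small_cfg(use_mixer = um, use_msc = us))$layers)
  a <- n_par(FALSE, FALSE); b <- n_par(FALSE, TRUE)
  c_ <- n_par(TRUE, FALSE); full <- n_par(TRUE, TRUE)
  expect_lt(a, b); expect_lt(a, c_)
  expect_lt(b, full); expect_lt(c_, full)
  # the msc block contains a mixer, so variant B outweighs C here
  expect_equal(full - b, c_ - a)  # mixer cost is additive
})

test_that("predict clips to [0,1], keeps dims and validates input size", {
  m <- build_fusenet(small_cfg())
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  p1 <- predict(m, x)
  expect_identical(dim(p1), c(16L, 16L, 3L))
  expect_true(min(p1) >= 0 && max(p1) <= 1)
  expect_identical(predict(m, x), p1)
  expect_error(predict(m, array(runif(15 * 16 * 3), c(15, 16, 3))),
               class = "pseudonir_config_error")
  # list input returns a list
  p2 <- predict(m, list(x, x))
  expect_length(p2, 2)
  expect_identical(p2[[1]], p2[[2]])
})

test_that("plateau scheduler halves the rate per stagnant window", {
  sch <- plateau_scheduler(2e-4, factor = 0.5, patience = 10)
  lr <- numeric(25)
  for (e in 1:25) lr[e] <- sch$update(1.0)
  # the first update sets the baseline; 10 stagnant epochs follow
  expect_equal(lr[10], 2e-4)
  expect_equal(lr[11], 1e-4)   # first plateau
  expect_equal(lr[20], 1e-4)
  expect_equal(lr[21], 5e-5)   # second consecutive plateau: 0.25 x initial
  expect_equal(sch$n_reductions, 2L)
  # an improvement resets the wait counter
  sch2 <- plateau_scheduler(1e-3, patience = 3)
  for (l in c(1, 0.9, 0.95, 0.96, 0.8)) sch2$update(l)
  expect_equal(sch2$lr, 1e-3)
  expect_equal(sch2$n_reductions, 0L)
})

test_that("early stopper restores-best bookkeeping is correct", {
  st <- early_stopper(patience = 3)
  losses <- c(1, 0.5, 0.6, 0.4, 0.45, 0.46, 0.47)
  stops <- vapply(seq_along(losses),
                  function(e) st$update(losses[e], e), TRUE)
  expect_equal(st$best, 0.4)
  expect_equal(st$best_epoch, 4L)
  expect_false(any(stops[1:6]))
  expect_true(stops[7])  # 3 stagnant epochs after the best
})

test_that("training runs deterministically and learns on a small task", {
  set <- generate_training_set(8, scene_params(height = 16, width = 16,
                                               seed = 13),
                               target_rule = "linear_2g_minus_r")
  xs <- lapply(set, `[[`, "x"); ys <- lapply(set, `[[`, "y")
  tc <- fusenet_train_config("tiny", max_epochs = 6, seed = 21)
  f1 <- fusenet(xs, ys, config = small_cfg(), train_config = tc)
  expect_s3_class(f1, "fusenet")
  expect_named(f1$history, c("epoch", "train_loss", "val_loss", "lr"))
  expect_equal(nrow(f1$history), 6)
  # loss drops relative to the starting epoch
  expect_lt(f1$history$train_loss[6], f1$history$train_loss[1])
  # restored best weights: re-evaluating equals the recorded minimum
  expect_equal(evaluate_fusenet(f1, f1$val_data$x, f1$val_data$y),
               min(f1$history$val_loss), tolerance = 1e-12)
  # identical seeds reproduce the exact loss history
  f2 <- fusenet(xs, ys, config = small_cfg(), train_config = tc)
  expect_identical(f1$history, f2$history)
  # trained model beats an untrained one
  m0 <- build_fusenet(small_cfg())
  expect_lt(f1$best_val_loss,
            evaluate_fusenet(m0, f1$val_data$x, f1$val_data$y))
})

test_that("augmentation keeps input and target aligned", {
  set.seed(9)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  y <- x + 0.001  # target tracks input exactly
  ap <- pseudonir:::augment_pair(x, y, c("flip", "rotation"))
  expect_identical(dim(ap$x), dim(x))
  expect_equal(ap$y, ap$x + 0.001, tolerance = 1e-12)
  # flips/rotations permute pixels: the value multiset is unchanged
  expect_equal(sort(as.numeric(ap$x)), sort(as.numeric(x)))
  ap2 <- pseudonir:::augment_pair(x, y, "zoom")
  expect_identical(dim(ap2$x), dim(x))
  expect_true(min(ap2$x) >= 0 && max(ap2$x) <= 1)
})
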