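test_that("scene pairs are seed-reproducible with vegetation structure", {
  p <- scene_params(height = 24, width = 24, seed = 5)
  a <- generate_scene_pair(p)
  b <- generate_scene_pair(p)
  expect_identical(unclass(a$cube), unclass(b$cube))
  expect_identical(unclass(a$rgb), unclass(b$rgb))
  expect_false(identical(
    unclass(generate_scene_pair(scene_params(height = 24, width = 24,
                                             seed = 6))$cube),
    unclass(a$cube)))
  # bounds
  expect_true(min(a$cube) >= 0 && max(a$cube) <= 1)
  expect_true(min(a$rgb) >= 0 && max(a$rgb) <= 1)
})

test_that("vegetation spectra rise across the red edge", {
  p <- scene_params(height = 24, width = 24, seed = 7, noise_sd = 0)
  pair <- generate_scene_pair(p)
  mask <- attr(pair, "leaf_mask")
  expect_gt(sum(mask), 5)    # fixture sanity: scene has both classes
  expect_gt(sum(!mask), 5)
  cube <- unclass(pair$cube)
  wl <- seq(400, 1000, length.out = p$n_bands)
  red <- which(wl >= 600 & wl <= 690)
  nir <- which(wl >= 760)
  veg_red <- mean(cube[, , red][rep(mask, length(red))])
  veg_nir <- mean(cube[, , nir][rep(mask, length(nir))])
  expect_gt(veg_nir, veg_red * 2)  # steep red-edge rise
  # background is spectrally flat: red and NIR means agree closely
  bg_red <- mean(cube[, , red][rep(!mask, length(red))])
  bg_nir <- mean(cube[, , nir][rep(!mask, length(nir))])
  expect_lt(abs(bg_nir - bg_red), 0.02)
})

test_that("true-cube GNDVI separates vegetation from background", {
  for (seed in 1:5) {
    p <- scene_params(height = 24, width = 24, seed = seed)
    pair <- generate_scene_pair(p)
    mask <- attr(pair, "leaf_mask")
    if (sum(mask) < 5 || sum(!mask) < 5) next
    nir <- band_slice(pair$cube, 91L)[, , 1]
    grn <- unclass(pair$rgb)[, , 2]
    g <- compute_index(nir, grn, "gndvi")
    expect_gt(mean(g[mask]), mean(g[!mask]))
  }
})

test_that("RGB rendering is linear in the cube", {
  cube <- random_cube(6, 6, 120, seed = 8, max_val = 0.4)
  sens <- sensor_model(120)
  r1 <- render_rgb(cube, sens, clip = FALSE)
  r2 <- render_rgb(spectral_cube(unclass(cube) * 2,
                                 normalized = TRUE), sens, clip = FALSE)
  expect_equal(r2, 2 * r1, tolerance = 1e-12)
  # channel weights are nonnegative and normalized
  expect_true(all(sens >= 0))
  expect_equal(colSums(sens), c(R = 1, G = 1, B = 1), tolerance = 1e-12)
})

test_that("planted-variance cube behaves as the band-selection oracle input", {
  c1 <- make_planted_variance_cube(10, 10, 120, hot_bands = 91L, seed = 2)
  c2 <- make_planted_variance_cube(10, 10, 120, hot_bands = 91L, seed = 2)
  expect_identical(unclass(c1), unclass(c2))
  tab <- cumulative_loading_scores(flatten_to_pixel_matrix(c1, 70:119), 3)
  expect_equal(top_k_bands(tab, 1), 91L)
  expect_error(make_planted_variance_cube(4, 4, 10, hot_bands = 3L,
                                          hot_sd = 0.01, base_sd = 0.01),
               class = "pseudonir_config_error")
  expect_error(make_planted_variance_cube(4, 4, 10, hot_bands = 12L),
               class = "pseudonir_config_error")
})

test_that("training sets follow their target rule", {
  set <- generate_training_set(
    3, scene_params(height = 16, width = 16, seed = 4),
    target_rule = "linear_2g_minus_r", target_noise_sd = 0.01)
  for (s in set) {
    plane <- pmin(pmax(2 * s$x[, , 2] - s$x[, , 1], 0), 1)
    resid <- s$y - array(plane, dim(s$y))
    # residual is exactly the injected iid noise: small and centered
    expect_lt(max(abs(resid)), 0.06)
    expect_equal(stats::sd(as.numeric(resid)), 0.01, tolerance = 0.15)
  }
  set2 <- generate_training_set(
    2, scene_params(height = 16, width = 16, seed = 4),
    target_rule = "from_cube", combination = c(70L, 91L, 108L))
  for (s in set2)
    expect_identical(s$y, band_slice(s$pair$cube, c(70L, 91L, 108L)))
  # scenes differ across the set (distinct derived seeds)
  expect_false(identical(set2[[1]]$x, set2[[2]]$x))
})
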