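# Independent oracle: brute-force eigendecomposition of the covariance
# matrix, summing absolute eigenvector entries over the leading components.
oracle_scores <- function(mat, n_components = 3) {
  ev <- eigen(stats::cov(mat), symmetric = TRUE)
  rowSums(abs(ev$vectors[, seq_len(n_components), drop = FALSE]))
}

test_that("flatten_to_pixel_matrix has the contracted shape", {
  cube <- random_cube(2, 2, 10, seed = 1)
  m <- flatten_to_pixel_matrix(cube, 0:4)
  expect_identical(dim(m), c(4L, 5L))
  expect_identical(colnames(m), paste0("band", 0:4))
  m2 <- flatten_to_pixel_matrix(list(cube, random_cube(2, 2, 10, 2)), 0:4)
  expect_identical(dim(m2), c(8L, 5L))
  expect_identical(m2[1:4, ], m)  # row concatenation preserves order
  expect_error(flatten_to_pixel_matrix(cube, integer(0)),
               class = "pseudonir_config_error")
})

test_that("cumulative loading scores match the eigendecomposition oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    nb <- sample(4:8, 1)
    mat <- matrix(rnorm(60 * nb), 60, nb)
    tab <- cumulative_loading_scores(mat, n_components = 3)
    expect_equal(tab$score, oracle_scores(mat, 3), tolerance = 1e-8)
  }
})

test_that("loading vectors are unit-norm and sign-canonical", {
  set.seed(9)
  mat <- matrix(rnorm(200 * 6), 200, 6)
  tab <- cumulative_loading_scores(mat, 3)
  L <- attr(tab, "loadings")
  expect_equal(colSums(L^2), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  for (j in 1:3) expect_gt(L[which.max(abs(L[, j])), j], 0)
})

test_that("a planted dominant-variance column earns the top score", {
  set.seed(10)
  mat <- matrix(rnorm(300 * 6, sd = 0.01), 300, 6)
  mat[, 4] <- rnorm(300, sd = 1)           # all variance in column 4
  # PC1 lies on column 4; with few columns the trailing noise components
  # spread sizeable absolute loadings, so score on the leading component
  tab <- cumulative_loading_scores(mat, 1)
  expect_equal(which.max(tab$score), 4L)
  # two independent equal-variance columns dominate jointly
  mat2 <- matrix(rnorm(300 * 6, sd = 0.01), 300, 6)
  mat2[, 2] <- rnorm(300); mat2[, 5] <- rnorm(300)
  tab2 <- cumulative_loading_scores(mat2, 2)
  expect_setequal(order(-tab2$score)[1:2], c(2L, 5L))
  expect_error(
    cumulative_loading_scores(matrix(1, 5, 3)),
    class = "pseudonir_degenerate_error")
})

test_that("top_k_bands sorts by score with index tie-breaks", {
  tab <- structure(
    data.frame(band_index = c(70L, 71L, 72L, 73L),
               score = c(0.5, 0.9, 0.9, 0.1)),
    class = c("loading_score_table", "data.frame"))
  expect_identical(top_k_bands(tab, 4), c(71L, 72L, 70L, 73L))
  expect_identical(top_k_bands(tab, 1), 71L)
  expect_error(top_k_bands(tab, 5), class = "pseudonir_config_error")
})

test_that("band grouping follows the early/mid/late NIR scheme", {
  sch <- band_group_scheme()
  expect_equal(band_group_of(70, sch), "early")
  expect_equal(band_group_of(80, sch), "early")
  expect_equal(band_group_of(81, sch), "mid")
  expect_equal(band_group_of(91, sch), "mid")
  expect_equal(band_group_of(95, sch), "mid")
  expect_equal(band_group_of(96, sch), "late")
  expect_equal(band_group_of(108, sch), "late")
  expect_error(band_group_of(42, sch), class = "pseudonir_config_error")
  expect_error(band_group_scheme(early = 70:85, mid = 81:95),
               class = "pseudonir_config_error")
})

test_that("combination sampling is distinct, grouped and reproducible", {
  sch <- band_group_scheme()
  combos <- sample_combinations(sch, n = 20, seed = 7)
  expect_length(combos, 20)
  keys <- vapply(combos, paste, "", collapse = ",")
  expect_false(anyDuplicated(keys) > 0)
  for (tri in combos) validate_combination(tri, sch)
  expect_identical(sample_combinations(sch, n = 20, seed = 7), combos)
  expect_false(identical(sample_combinations(sch, n = 20, seed = 8), combos))
  # single candidate per group forces the unique triple
  one <- sample_combinations(sch, candidates = c(70L, 91L, 108L), n = 1)
  expect_identical(one[[1]], c(70L, 91L, 108L))
  expect_error(sample_combinations(sch, candidates = c(70L, 91L, 108L),
                                   n = 2), class = "pseudonir_config_error")
  expect_error(validate_combination(c(70L, 72L, 108L), sch),
               class = "pseudonir_config_error")
})

test_that("planted-variance cube ranks its hot bands on top", {
  cube <- make_planted_variance_cube(12, 12, 120, hot_bands = c(75L, 91L,
                                                                105L),
                                     hot_sd = 0.15, base_sd = 0.002,
                                     seed = 3)
  mat <- flatten_to_pixel_matrix(cube, 70:119)
  tab <- cumulative_loading_scores(mat, 3)
  top5 <- top_k_bands(tab, 5)
  expect_true(all(c(75L, 91L, 105L) %in% top5))
})
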