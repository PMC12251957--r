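# PCA-based NIR band selection: rank bands by cumulative absolute loadings
# on the first principal components of the pixel x band reflectance matrix,
# then sample three-band combinations with one band per physiological NIR
# subgroup (early / mid / late).

#' Flatten cubes into a pixel-by-band matrix
#'
#' Every pixel of every cube contributes one row; columns are the requested
#' bands (0-based indices), in order.
#'
#' @param cubes a `spectral_cube` or list of cubes sharing a band count.
#' @param band_range integer vector of 0-based band indices (e.g. `70:119`).
#' @return numeric matrix, total_pixels x length(band_range), with column
#'   names `band<index>`.
#' @export
flatten_to_pixel_matrix <- function(cubes, band_range) {
  if (inherits(cubes, "spectral_cube")) cubes <- list(cubes)
  assert_that(length(band_range) >= 1L, "empty band range",
              class = "pseudonir_config_error")
  nb <- dim(cubes[[1]])[3]
  assert_that(all(vapply(cubes, function(cc) dim(cc)[3], 0) == nb),
              "cubes differ in band count")
  rows <- lapply(cubes, function(cc) {
    sl <- band_slice(cc, band_range)
    matrix(sl, ncol = length(band_range))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("band", band_range)
  m
}

#' Cumulative PCA loading scores per band
#'
#' Runs PCA on the column-centered covariance of the pixel matrix (no unit
#' variance scaling) and scores each band as the sum of absolute loadings
#' over the first `n_components` principal components. Loadings are entries
#' of the unit-norm eigenvectors of the covariance matrix; taking absolute
#' values makes the score invariant to eigenvector sign.
#'
#' @param mat pixel x band matrix from [flatten_to_pixel_matrix()].
#' @param n_components number of leading components to accumulate
#'   (default 3).
#' @return data.frame of class `loading_score_table` with columns
#'   `band_index` (0-based, parsed from column names when present) and
#'   `score`; attribute `n_components_used`; attribute `loadings` holds the
#'   sign-canonicalized loading matrix.
#' @export
cumulative_loading_scores <- function(mat, n_components = 3L) {
  assert_that(nrow(mat) >= 2L, "need at least 2 pixel rows")
  assert_that(n_components >= 1L && n_components <= ncol(mat),
              "n_components must lie in [1, ncol(mat)]",
              class = "pseudonir_config_error")
  total_var <- sum(apply(mat, 2, stats::var))
  assert_that(total_var > 0, "zero-variance matrix: PCA is degenerate",
              class = "pseudonir_degenerate_error")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  load <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # canonical sign: largest-magnitude entry of each component positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  band_index <- if (!is.null(colnames(mat)) &&
                    all(grepl("^band\\d+$", colnames(mat))))
    as.integer(sub("^band", "", colnames(mat)))
  else seq_len(ncol(mat)) - 1L
  out <- data.frame(band_index = band_index,
                    score = rowSums(abs(load)))
  rownames(out) <- NULL
  structure(out, class = c("loading_score_table", "data.frame"),
            n_components_used = as.integer(n_components), loadings = load)
}

#' Top-k bands by cumulative loading score
#'
#' @param table a `loading_score_table`.
#' @param k number of bands to keep (default 20).
#' @return integer vector of 0-based band indices sorted by descending
#'   score; ties broken by ascending band index.
#' @export
top_k_bands <- function(table, k = 20L) {
  assert_that(k >= 1L && k <= nrow(table), "k must lie in [1, ", nrow(table),
              "]", class = "pseudonir_config_error")
  ord <- order(-table$score, table$band_index)
  table$band_index[ord][seq_len(k)]
}

#' NIR band grouping scheme
#'
#' Defaults follow the physiological split of the 750-1000 nm region on a
#' 120-band axis: early NIR (bands 70-80, rising red edge), mid NIR (81-95,
#' cell-structure reflectance), late NIR (96 and above, water absorption).
#'
#' @param early,mid,late integer ranges of 0-based band indices; must be
#'   disjoint and in increasing order.
#' @return object of class `band_group_scheme`.
#' @export
band_group_scheme <- function(early = 70:80, mid = 81:95, late = 96:119) {
  assert_that(max(early) < min(mid) && max(mid) < min(late),
              "groups must be disjoint and ordered early < mid < late",
              class = "pseudonir_config_error")
  structure(list(early = early, mid = mid, late = late),
            class = "band_group_scheme")
}

#' Group label of a band
#'
#' @param band 0-based band index.
#' @param scheme a [band_group_scheme()].
#' @return "early", "mid" or "late".
#' @export
band_group_of <- function(band, scheme = band_group_scheme()) {
  if (band %in% scheme$early) return("early")
  if (band %in% scheme$mid) return("mid")
  if (band %in% scheme$late) return("late")
  stop_pseudonir("band ", band, " lies outside the grouped NIR span",
                 class = "pseudonir_config_error")
}

#' Sample three-band combinations, one band per NIR group
#'
#' Draws `n` distinct (early, mid, late) triples uniformly from the
#' candidate pool, seed-reproducibly. Candidates may be the top-k PCA bands
#' or whole groups; each triple takes one member per group.
#'
#' @param scheme a [band_group_scheme()].
#' @param candidates integer vector of candidate band indices (default: all
#'   grouped bands).
#' @param n number of distinct combinations (default 20).
#' @param seed RNG seed.
#' @return list of integer triples `c(early, mid, late)`.
#' @export
sample_combinations <- function(scheme = band_group_scheme(),
                                candidates = NULL, n = 20L, seed = 1L) {
  if (is.null(candidates))
    candidates <- c(scheme$early, scheme$mid, scheme$late)
  pools <- lapply(scheme[c("early", "mid", "late")], intersect, x = candidates)
  sizes <- vapply(pools, length, 0L)
  assert_that(all(sizes >= 1L),
              "each NIR group needs at least one candidate band",
              class = "pseudonir_config_error")
  assert_that(prod(sizes) >= n, "only ", prod(sizes),
              " distinct combinations exist, cannot draw ", n,
              class = "pseudonir_config_error")
  pick <- function(v) if (length(v) == 1L) v else sample(v, 1L)
  with_seed(seed, {
    seen <- character(0)
    out <- vector("list", n)
    i <- 0L
    while (i < n) {
      tri <- c(pick(pools$early), pick(pools$mid), pick(pools$late))
      key <- paste(tri, collapse = ",")
      if (!key %in% seen) {
        i <- i + 1L
        seen <- c(seen, key)
        out[[i]] <- tri
      }
    }
    out
  })
}

#' Validate a band combination against the grouping scheme
#'
#' @param combination integer triple (early, mid, late band indices).
#' @param scheme a [band_group_scheme()].
#' @return the combination, invisibly; errors if any member is outside its
#'   group.
#' @export
validate_combination <- function(combination, scheme = band_group_scheme()) {
  assert_that(length(combination) == 3L, "a combination is a band triple",
              class = "pseudonir_config_error")
  want <- c("early", "mid", "late")
  got <- vapply(combination, band_group_of, character(1), scheme = scheme)
  assert_that(identical(got, want),
              "combination (", paste(combination, collapse = ", "),
              ") maps to groups (", paste(got, collapse = ", "),
              "), expected (early, mid, late)",
              class = "pseudonir_config_error")
  invisible(combination)
}
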