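# Normalized-difference vegetation/water index maps and the GNDVI
# functional-fidelity comparison between predicted and true index maps.

#' Compute a normalized-difference index map
#'
#' With `nir` the near-infrared plane and `vis` the visible plane (green for
#' GNDVI/NDWI, red for NDVI):
#' \itemize{
#'   \item GNDVI = (NIR - G) / (NIR + G)
#'   \item NDVI  = (NIR - R) / (NIR + R)
#'   \item NDWI  = (G - NIR) / (G + NIR) = -GNDVI
#' }
#' Pixels where the denominator is zero are set to 0 and flagged in the
#' `valid` attribute mask (no epsilon inflation, which would manufacture
#' extreme values on dark background pixels).
#'
#' @param nir H x W nonnegative matrix, the NIR band.
#' @param vis H x W nonnegative matrix, the visible band (green or red).
#' @param kind one of "gndvi", "ndvi", "ndwi".
#' @return H x W matrix of class `index_map` with attributes `index_kind`
#'   and `valid` (logical mask, FALSE where the denominator vanished).
#' @export
compute_index <- function(nir, vis, kind = c("gndvi", "ndvi", "ndwi")) {
  kind <- match.arg(kind)
  assert_that(identical(dim(nir), dim(vis)), "band shapes differ",
              class = "pseudonir_format_error")
  assert_that(min(nir) >= 0 && min(vis) >= 0,
              "index inputs must be nonnegative reflectances")
  num <- switch(kind, gndvi = nir - vis, ndvi = nir - vis, ndwi = vis - nir)
  den <- nir + vis
  valid <- den != 0
  vals <- ifelse(valid, num / ifelse(valid, den, 1), 0)
  structure(vals, class = c("index_map", class(vals)),
            index_kind = toupper(kind), valid = valid)
}

#' @export
print.index_map <- function(x, ...) {
  cat(sprintf("<%s index map %d x %d, range [%.3f, %.3f], %d invalid px>\n",
              attr(x, "index_kind"), nrow(x), ncol(x), min(x), max(x),
              sum(!attr(x, "valid"))))
  invisible(x)
}

#' Compare a predicted index map against the ground truth
#'
#' Reports per-pixel RMSE, the Pearson correlation over flattened pixels, and
#' the histogram similarity between the two value distributions (64 bins over
#' [-1, 1] by default, the native range of normalized-difference indices).
#' If either map is constant the Pearson correlation is undefined and
#' reported as `NA` with `pearson_defined = FALSE`.
#'
#' @param predicted_map,truth_map index maps (same shape and kind).
#' @param bins,range histogram-similarity binning (see
#'   [histogram_similarity()]).
#' @return list of class `gndvi_fidelity` with elements `rmse`, `pearson`,
#'   `histogram_similarity`, `pearson_defined`.
#' @export
evaluate_gndvi_fidelity <- function(predicted_map, truth_map, bins = 64L,
                                    range = c(-1, 1)) {
  assert_that(identical(dim(predicted_map), dim(truth_map)),
              "index maps differ in shape", class = "pseudonir_format_error")
  ka <- attr(predicted_map, "index_kind"); kb <- attr(truth_map, "index_kind")
  if (!is.null(ka) && !is.null(kb))
    assert_that(identical(ka, kb), "index kinds differ: ", ka, " vs ", kb)
  p <- as.vector(predicted_map); t <- as.vector(truth_map)
  rmse <- sqrt(mean((p - t)^2))
  defined <- stats::sd(p) > 0 && stats::sd(t) > 0
  pearson <- if (defined) stats::cor(p, t) else NA_real_
  hs <- histogram_similarity(p, t, bins = bins, range = range)
  structure(list(rmse = rmse, pearson = pearson,
                 histogram_similarity = as.numeric(hs),
                 pearson_defined = defined),
            class = "gndvi_fidelity")
}

#' @export
print.gndvi_fidelity <- function(x, ...) {
  cat(sprintf("GNDVI fidelity: RMSE %.4f | Pearson %s | hist. similarity %.4f\n",
              x$rmse,
              if (x$pearson_defined) sprintf("%.4f", x$pearson) else "NA (constant map)",
              x$histogram_similarity))
  invisible(x)
}
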