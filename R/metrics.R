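# Reconstruction quality metrics: MSE, PSNR (dB), spectral correlation
# (Pearson over flattened values), SSIM (global-statistics form, windowed
# variant optional), L1/L2 pixel distances and histogram similarity.

check_same_shape <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (is.null(da)) da <- length(a)
  if (is.null(db)) db <- length(b)
  assert_that(identical(da, db), "inputs differ in shape",
              class = "pseudonir_format_error")
}

#' Mean squared error
#'
#' @param truth,pred arrays of identical shape.
#' @return mean over all elements of the squared difference.
#' @export
mse <- function(truth, pred) {
  check_same_shape(truth, pred)
  mean((as.numeric(truth) - as.numeric(pred))^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 * log10(max_value^2 / MSE)`. When the MSE underflows (below 1e-12,
#' e.g. identical inputs) the value is capped at 120 dB and flagged via the
#' `capped` attribute.
#'
#' @param truth,pred arrays of identical shape.
#' @param max_value maximum possible value of the signal (1.0 for float
#'   images, 255 for 8-bit).
#' @return PSNR in dB (attribute `capped` TRUE when the cap was applied).
#' @export
psnr <- function(truth, pred, max_value = 1.0) {
  assert_that(max_value > 0, "max_value must be positive")
  m <- mse(truth, pred)
  if (m < 1e-12)
    return(structure(120, capped = TRUE))
  structure(10 * log10(max_value^2 / m), capped = FALSE)
}

#' Spectral correlation coefficient
#'
#' Pearson correlation between all flattened elements of the two arrays. If
#' either input is constant the correlation is undefined and `NA` is
#' returned with attribute `defined = FALSE`. With `per_band = TRUE` and 3-d
#' inputs, per-band correlations are attached as an attribute.
#'
#' @param truth,pred arrays of identical shape.
#' @param per_band also compute per-band correlations for 3-d stacks.
#' @return correlation in [-1, 1] (or flagged NA).
#' @export
scc <- function(truth, pred, per_band = FALSE) {
  check_same_shape(truth, pred)
  x <- as.numeric(truth); y <- as.numeric(pred)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, defined = FALSE))
  r <- structure(stats::cor(x, y), defined = TRUE)
  if (per_band && length(dim(truth)) == 3L) {
    nb <- dim(truth)[3]
    attr(r, "per_band") <- vapply(seq_len(nb), function(b)
      stats::cor(as.numeric(truth[, , b]), as.numeric(pred[, , b])), 0)
  }
  r
}

#' Structural similarity index
#'
#' Global-statistics SSIM,
#' `(2*mu_x*mu_y + C1) * (2*sigma_xy + C2) /
#'  ((mu_x^2 + mu_y^2 + C1) * (sigma_x^2 + sigma_y^2 + C2))`,
#' with the conventional stabilizers `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`
#' on dynamic range `L`. A sliding-window variant (uniform window, mean of
#' local SSIM values) is available via `window`.
#'
#' @param truth,pred arrays of identical shape.
#' @param c1,c2 stabilizing constants.
#' @param L dynamic range used for the default constants (1.0 for floats).
#' @param window if a positive odd integer, compute mean local SSIM over
#'   square windows of that size instead of the global form (2-d inputs).
#' @return SSIM value (<= 1; equals 1 iff the inputs are identical).
#' @export
ssim <- function(truth, pred, c1 = (0.01 * L)^2, c2 = (0.03 * L)^2, L = 1.0,
                 window = NULL) {
  check_same_shape(truth, pred)
  if (!is.null(window)) {
    assert_that(length(dim(truth)) == 2L && window %% 2 == 1,
                "windowed SSIM needs a 2-d input and an odd window")
    kern <- matrix(1 / window^2, window, window)
    f <- function(z) EBImage::filter2(z, kern, boundary = "replicate")
    mx <- f(truth); my <- f(pred)
    sx <- f(truth^2) - mx^2; sy <- f(pred^2) - my^2
    sxy <- f(truth * pred) - mx * my
    smap <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
      ((mx^2 + my^2 + c1) * (sx + sy + c2))
    return(mean(smap))
  }
  x <- as.numeric(truth); y <- as.numeric(pred)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx <- mean((x - mx)^2); sy <- mean((y - my)^2)  # population variance
  sxy <- mean((x - mx) * (y - my))
  ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sx + sy + c2))
}

#' L1 and L2 pixel distances
#'
#' MAE = mean absolute difference; RMSE = root mean squared difference,
#' reported on the caller's value scale. The L2/L1 ratio (reported, not
#' judged) highlights whether errors are concentrated in small regions.
#'
#' @param a,b arrays of identical shape.
#' @return list with `mae`, `rmse` and `ratio` (= rmse/mae, NA when mae = 0).
#' @export
pixel_distances <- function(a, b) {
  check_same_shape(a, b)
  d <- as.numeric(a) - as.numeric(b)
  mae <- mean(abs(d))
  rmse <- sqrt(mean(d^2))
  list(mae = mae, rmse = rmse,
       ratio = if (mae > 0) rmse / mae else NA_real_)
}

#' Histogram similarity
#'
#' Pearson correlation between the normalized bin-count vectors of the two
#' arrays over a common binning. Defaults suit 8-bit-scale image comparisons
#' (256 bins over the data range); index maps use 64 bins over [-1, 1]. If
#' both arrays occupy a single common bin the histograms are constant and
#' the similarity is 1 by convention (flagged via `degenerate`).
#'
#' @param a,b arrays sharing a value-range convention.
#' @param bins number of histogram bins.
#' @param range numeric length-2 bin range; defaults to the joint data range.
#' @return similarity in [-1, 1] with attribute `degenerate`.
#' @export
histogram_similarity <- function(a, b, bins = 256L, range = NULL) {
  x <- as.numeric(a); y <- as.numeric(b)
  if (is.null(range)) range <- range(c(x, y))
  if (range[1] == range[2]) range <- range + c(-0.5, 0.5)
  brk <- seq(range[1], range[2], length.out = bins + 1L)
  bin_counts <- function(v) {
    v <- clamp(v, range[1], range[2])
    h <- tabulate(findInterval(v, brk, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = bins)
    h / sum(h)
  }
  ha <- bin_counts(x); hb <- bin_counts(y)
  # both distributions collapsed onto one common bin: similarity 1 by
  # convention, flagged (the correlation itself is uninformative there)
  if (sum(ha > 0) == 1L && sum(hb > 0) == 1L &&
      which.max(ha) == which.max(hb))
    return(structure(1, degenerate = TRUE))
  if (stats::sd(ha) == 0 || stats::sd(hb) == 0)
    return(structure(0, degenerate = TRUE))
  structure(stats::cor(ha, hb), degenerate = FALSE)
}

#' Full reconstruction metrics report for one truth/prediction pair
#'
#' Multi-band stacks are scored per band and averaged (set
#' `flatten = TRUE` to score the flattened stack instead).
#'
#' @param truth,pred arrays of identical shape (2-d planes or 3-d stacks).
#' @param max_value PSNR peak value.
#' @param hist_bins,hist_range histogram-similarity binning.
#' @param flatten score the flattened stack rather than band means.
#' @return list of class `metrics_report` with elements `mse`, `psnr_db`,
#'   `scc`, `ssim`, `mae`, `rmse`, `histogram_similarity`.
#' @export
metrics_report <- function(truth, pred, max_value = 1.0, hist_bins = 256L,
                           hist_range = c(0, 1), flatten = FALSE) {
  check_same_shape(truth, pred)
  nb <- if (length(dim(truth)) == 3L && !flatten) dim(truth)[3] else 1L
  slice <- function(z, b) if (nb == 1L) z else z[, , b]
  one <- function(b) {
    tt <- slice(truth, b); pp <- slice(pred, b)
    pd <- pixel_distances(tt, pp)
    list(mse = mse(tt, pp),
         psnr_db = as.numeric(psnr(tt, pp, max_value)),
         scc = as.numeric(scc(tt, pp)),
         ssim = ssim(tt, pp, L = max_value),
         mae = pd$mae, rmse = pd$rmse,
         histogram_similarity = as.numeric(
           histogram_similarity(tt, pp, bins = hist_bins, range = hist_range)))
  }
  per <- lapply(seq_len(nb), one)
  agg <- lapply(stats::setNames(nm = names(per[[1]])), function(k)
    mean(vapply(per, `[[`, 0, k), na.rm = TRUE))
  structure(agg, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "MSE %.5g | PSNR %.2f dB | SCC %.4f | SSIM %.4f | MAE %.5g | RMSE %.5g | HS %.4f\n",
    x$mse, x$psnr_db, x$scc, x$ssim, x$mae, x$rmse, x$histogram_similarity))
  invisible(x)
}
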