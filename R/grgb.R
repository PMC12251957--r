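# GNDVI-guided green channel adjustment (the G-RGB transform).
#
# Healthy vegetation reflects strongly in the NIR while absorbing red light,
# so the green-red difference of an RGB image carries a crude NIR-like
# signal. The transform estimates a pseudo-NIR plane as
#   NIR_hat = G + (G - R) = 2G - R,
# then shifts the green channel toward it,
#   G' = clamp(G + lambda * (NIR_hat - G), 0, 1),
# and reassembles the image as (R, G', B). lambda in [0, 1] controls the
# correction strength; 0 leaves the image untouched.

#' G-RGB transform parameters
#'
#' @param lambda_coeff adjustment coefficient in [0, 1]; 0.5 is the default
#'   correction strength, the empirical optimum of the lambda sensitivity
#'   sweep (see [lambda_sweep()]).
#' @param clamp_low,clamp_high clamping bounds for the adjusted green channel.
#' @return object of class `grgb_params`.
#' @export
grgb_params <- function(lambda_coeff = 0.5, clamp_low = 0, clamp_high = 1) {
  assert_that(is.numeric(lambda_coeff) && length(lambda_coeff) == 1L &&
              lambda_coeff >= 0 && lambda_coeff <= 1,
              "lambda_coeff must be a single value in [0, 1]",
              class = "pseudonir_config_error")
  assert_that(clamp_low < clamp_high, "clamp_low must be < clamp_high",
              class = "pseudonir_config_error")
  structure(list(lambda_coeff = lambda_coeff, clamp_low = clamp_low,
                 clamp_high = clamp_high), class = "grgb_params")
}

#' Estimate the pseudo-NIR plane from an RGB image
#'
#' Computes `NIR_hat = G + (G - R) = 2G - R` per pixel. The result is *not*
#' clamped: negative values (red-dominant pixels) and values above 1 are
#' retained; clamping is applied only to the adjusted green channel in
#' [adjust_green()].
#'
#' @param image an [rgb_image()].
#' @return H x W numeric matrix of pseudo-NIR values.
#' @export
estimate_pseudo_nir <- function(image) {
  x <- unclass(image)
  out <- 2 * x[, , 2, drop = FALSE] - x[, , 1, drop = FALSE]
  array(out, dim(x)[1:2])  # keep matrix shape even for 1-pixel images
}

#' Adjust the green channel toward the pseudo-NIR estimate
#'
#' `G' = G + lambda * (NIR_hat - G)`, then the three-branch clamp: values
#' below `clamp_low` map to `clamp_low`, values above `clamp_high` to
#' `clamp_high`, and in-range values pass through unchanged.
#'
#' @param image an [rgb_image()].
#' @param params a [grgb_params()].
#' @return H x W numeric matrix, the adjusted green channel.
#' @export
adjust_green <- function(image, params = grgb_params()) {
  assert_that(inherits(params, "grgb_params"),
              "params must be created by grgb_params()",
              class = "pseudonir_config_error")
  g <- array(unclass(image)[, , 2, drop = FALSE], dim(image)[1:2])
  nir_hat <- estimate_pseudo_nir(image)
  raw <- g + params$lambda_coeff * (nir_hat - g)
  clamp(raw, params$clamp_low, params$clamp_high)
}

#' Build the G-RGB image
#'
#' Replaces the green channel by its adjusted version; red and blue planes
#' are passed through bit-identically. At `lambda_coeff = 0` the output
#' equals the input exactly.
#'
#' @param image an [rgb_image()].
#' @param params a [grgb_params()].
#' @return an [rgb_image()] with channels (R, G', B).
#' @export
build_grgb <- function(image, params = grgb_params()) {
  out <- unclass(image)
  out[, , 2] <- adjust_green(image, params)
  rgb_image(out, source_bit_depth = attr(image, "source_bit_depth"))
}
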