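# Synthetic paired RGB + hyperspectral scenes with vegetation-like spectral
# structure: elliptical "leaves" whose spectra show low red reflectance and
# a steep red-edge rise onto a NIR plateau, over a spectrally flat
# background, with per-pixel brightness jitter and per-band Gaussian noise.
# The RGB rendering integrates the cube under Gaussian sensor response
# curves. These scenes make the whole pipeline testable without real data;
# they claim no radiative-transfer realism.

#' Synthetic scene parameters
#'
#' The spectral axis maps `n_bands` bands linearly onto 400-1000 nm, so the
#' default 120-band axis puts the red edge near band 62 and the NIR plateau
#' over bands 70-119, matching the conventional NIR indexing used by the
#' band-selection defaults.
#'
#' @param height,width scene dimensions in pixels.
#' @param n_bands number of spectral bands (default 120).
#' @param n_leaves number of elliptical leaves.
#' @param leaf_scale leaf radius as a fraction of the smaller scene side.
#' @param veg_visible visible-range reflectance level of vegetation (low:
#'   chlorophyll absorbs red and blue).
#' @param veg_green_bump extra green-peak reflectance at ~550 nm.
#' @param red_edge_nm wavelength of the red-edge inflection (700-750 nm).
#' @param red_edge_width_nm width of the sigmoid rise.
#' @param nir_plateau NIR plateau reflectance of vegetation.
#' @param background_level flat background reflectance.
#' @param brightness_jitter_sd sd of per-pixel multiplicative brightness.
#' @param noise_sd per-band additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(height = 64L, width = 64L, n_bands = 120L,
                         n_leaves = 6L, leaf_scale = 0.18,
                         veg_visible = 0.06, veg_green_bump = 0.08,
                         red_edge_nm = 715, red_edge_width_nm = 12,
                         nir_plateau = 0.55, background_level = 0.25,
                         brightness_jitter_sd = 0.08, noise_sd = 0.01,
                         seed = 1L) {
  assert_that(noise_sd >= 0 && all(c(veg_visible, nir_plateau,
                                     background_level) >= 0) &&
              all(c(veg_visible, nir_plateau, background_level) <= 1),
              "reflectance levels must lie in [0, 1]",
              class = "pseudonir_config_error")
  wl <- seq(400, 1000, length.out = n_bands)
  assert_that(red_edge_nm > min(wl) && red_edge_nm < max(wl),
              "red edge must lie inside the spectral axis",
              class = "pseudonir_config_error")
  structure(as.list(environment()), class = "scene_params")
}

#' Gaussian RGB sensor model
#'
#' Per-channel spectral response weights over the band axis: Gaussian
#' curves centered at the given wavelengths (default ~610/550/470 nm for
#' R/G/B), each normalized to sum to 1.
#'
#' @param n_bands number of bands.
#' @param centers_nm response-curve centers (R, G, B order).
#' @param sd_nm response-curve standard deviation.
#' @param range_nm spectral axis limits.
#' @return B x 3 weight matrix of class `sensor_model` (columns R, G, B).
#' @export
sensor_model <- function(n_bands = 120L, centers_nm = c(610, 550, 470),
                         sd_nm = 40, range_nm = c(400, 1000)) {
  wl <- seq(range_nm[1], range_nm[2], length.out = n_bands)
  W <- vapply(centers_nm, function(mu) {
    w <- exp(-0.5 * ((wl - mu) / sd_nm)^2)
    w / sum(w)
  }, numeric(n_bands))
  colnames(W) <- c("R", "G", "B")
  structure(W, class = c("sensor_model", "matrix"))
}

# Spectral templates over the band axis.
vegetation_spectrum <- function(p) {
  wl <- seq(400, 1000, length.out = p$n_bands)
  edge <- 1 / (1 + exp(-(wl - p$red_edge_nm) / p$red_edge_width_nm))
  green <- p$veg_green_bump * exp(-0.5 * ((wl - 550) / 35)^2)
  p$veg_visible + green + (p$nir_plateau - p$veg_visible) * edge
}

background_spectrum <- function(p) {
  rep(p$background_level, p$n_bands)
}

# Random elliptical leaf mask.
leaf_mask <- function(p) {
  mask <- matrix(FALSE, p$height, p$width)
  rr <- p$leaf_scale * min(p$height, p$width)
  xg <- matrix(seq_len(p$height), p$height, p$width)
  yg <- matrix(seq_len(p$width), p$height, p$width, byrow = TRUE)
  for (l in seq_len(p$n_leaves)) {
    cx <- stats::runif(1, 1, p$height); cy <- stats::runif(1, 1, p$width)
    a <- stats::runif(1, 0.6, 1.6) * rr; b <- stats::runif(1, 0.4, 1.1) * rr
    th <- stats::runif(1, 0, pi)
    u <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
    v <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
    mask <- mask | ((u / a)^2 + (v / b)^2 <= 1)
  }
  mask
}

#' Render an RGB image from a reflectance cube
#'
#' Per-pixel weighted band sums under the sensor model; linear in the cube
#' (pre-clipping). Output clipped to [0, 1].
#'
#' @param cube a `spectral_cube` (or H x W x B array).
#' @param sensor a [sensor_model()] with matching band count.
#' @param clip clip the rendering to [0, 1] (default TRUE).
#' @return an [rgb_image()] (or plain array when `clip = FALSE`).
#' @export
render_rgb <- function(cube, sensor, clip = TRUE) {
  d <- dim(cube)
  assert_that(d[3] == nrow(sensor), "sensor band count mismatch",
              class = "pseudonir_config_error")
  M <- matrix(unclass(cube), ncol = d[3]) %*% unclass(sensor)
  px <- array(M, c(d[1], d[2], 3L))
  if (clip) rgb_image(clamp(px)) else px
}

#' Generate one paired RGB + hyperspectral scene
#'
#' Blends vegetation and background spectral templates under a random leaf
#' mask, applies per-pixel multiplicative brightness jitter and per-band
#' additive Gaussian noise, clips to [0, 1], and renders the RGB image from
#' the cube under the sensor model. Bit-reproducible for a fixed seed.
#'
#' @param params a [scene_params()].
#' @param sensor a [sensor_model()]; defaults to one matching
#'   `params$n_bands`.
#' @param identifier pair identifier.
#' @return a [dataset_pair()] whose `scene_label` is "vegetated" or "sparse"
#'   (by leaf cover), with the leaf mask attached as attribute `leaf_mask`.
#' @export
generate_scene_pair <- function(params = scene_params(),
                                sensor = sensor_model(params$n_bands),
                                identifier = paste0("scene", params$seed)) {
  with_seed(params$seed, {
    mask <- leaf_mask(params)
    veg <- vegetation_spectrum(params)
    bg <- background_spectrum(params)
    H <- params$height; W <- params$width; B <- params$n_bands
    base <- array(0, c(H, W, B))
    mvec <- as.vector(mask)
    Mspec <- matrix(0, H * W, B)
    Mspec[mvec, ] <- matrix(veg, sum(mvec), B, byrow = TRUE)
    Mspec[!mvec, ] <- matrix(bg, sum(!mvec), B, byrow = TRUE)
    jitter <- 1 + stats::rnorm(H * W, sd = params$brightness_jitter_sd)
    Mspec <- Mspec * pmax(jitter, 0.2)
    if (params$noise_sd > 0)
      Mspec <- Mspec + stats::rnorm(length(Mspec), sd = params$noise_sd)
    cube <- spectral_cube(clamp(array(Mspec, c(H, W, B))), normalized = TRUE)
    rgb <- render_rgb(cube, sensor)
    label <- if (mean(mask) > 0.25) "vegetated" else "sparse"
    pair <- dataset_pair(rgb, cube, identifier, scene_label = label)
    attr(pair, "leaf_mask") <- mask
    pair
  })
}

#' Cube with planted high-variance bands
#'
#' All bands fluctuate around a common mean; the `hot_bands` carry sd
#' `hot_sd`, the rest `base_sd`. Oracle input for the PCA band-selection
#' procedure: the hot bands must dominate the cumulative loading scores.
#'
#' @param height,width,n_bands cube dimensions.
#' @param hot_bands 0-based indices of the high-variance bands.
#' @param hot_sd,base_sd band standard deviations (`hot_sd > base_sd`).
#' @param mean_level common mean reflectance.
#' @param seed RNG seed.
#' @return a `spectral_cube`.
#' @export
make_planted_variance_cube <- function(height = 16L, width = 16L,
                                       n_bands = 120L, hot_bands = 91L,
                                       hot_sd = 0.2, base_sd = 0.001,
                                       mean_level = 0.5, seed = 1L) {
  assert_that(hot_sd > base_sd && base_sd >= 0,
              "need hot_sd > base_sd >= 0", class = "pseudonir_config_error")
  assert_that(all(hot_bands >= 0L & hot_bands <= n_bands - 1L),
              "hot band outside range", class = "pseudonir_config_error")
  with_seed(seed, {
    sds <- rep(base_sd, n_bands)
    sds[hot_bands + 1L] <- hot_sd
    vals <- array(stats::rnorm(height * width * n_bands,
                               mean = mean_level,
                               sd = rep(sds, each = height * width)),
                  c(height, width, n_bands))
    spectral_cube(clamp(vals), normalized = TRUE)
  })
}

#' Generate a synthetic training set
#'
#' Produces `n_pairs` scene pairs with varying leaf placement (one derived
#' seed per scene) and attaches a 3-band training target per the rule:
#' `"from_cube"` extracts the true cube bands at `combination`;
#' `"linear_2g_minus_r"` builds the analytic pixelwise target
#' `clip(2G - R) + N(0, target_noise_sd^2)` in every band, a known-learnable
#' mapping used for trainer sanity checks.
#'
#' @param n_pairs number of pairs.
#' @param params a [scene_params()]; its seed is the master seed.
#' @param sensor a [sensor_model()].
#' @param target_rule "from_cube" or "linear_2g_minus_r".
#' @param combination 0-based band triple for "from_cube".
#' @param target_noise_sd additive noise sd on the analytic target.
#' @return list of elements `list(x = input array, y = target array,
#'   pair = dataset_pair)`.
#' @export
generate_training_set <- function(n_pairs, params = scene_params(),
                                  sensor = sensor_model(params$n_bands),
                                  target_rule = c("from_cube",
                                                  "linear_2g_minus_r"),
                                  combination = c(70L, 91L, 108L),
                                  target_noise_sd = 0.01) {
  target_rule <- match.arg(target_rule)
  assert_that(n_pairs >= 1L, "n_pairs must be >= 1")
  seeds <- derive_seeds(params$seed, n_pairs + 1L)
  out <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    p_i <- params
    p_i$seed <- seeds[i]
    pair <- generate_scene_pair(p_i, sensor,
                                identifier = sprintf("synth%03d", i))
    x <- unclass(pair$rgb)
    attributes(x) <- list(dim = dim(pair$rgb))
    y <- if (target_rule == "from_cube") {
      band_slice(pair$cube, combination)
    } else {
      plane <- clamp(2 * x[, , 2] - x[, , 1])
      tgt <- array(plane, c(dim(x)[1:2], 3L))
      if (target_noise_sd > 0)
        tgt <- tgt + with_seed(seeds[n_pairs + 1L] %% 1e6 + i,
                               stats::rnorm(length(tgt),
                                            sd = target_noise_sd))
      tgt
    }
    out[[i]] <- list(x = x, y = y, pair = pair)
  }
  out
}
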