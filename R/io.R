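# Image and cube containers -------------------------------------------------

#' Construct an RGB image
#'
#' Internal image representation: an H x W x 3 float array with all values in
#' [0, 1] and channel order R, G, B along the third axis.
#'
#' @param pixels numeric H x W x 3 array in [0, 1].
#' @param source_bit_depth 8 for images read from 8-bit files, "float"
#'   otherwise. Informational only.
#' @return object of class `rgb_image` (an array).
#' @export
rgb_image <- function(pixels, source_bit_depth = "float") {
  assert_that(is.array(pixels) && length(dim(pixels)) == 3L,
              "rgb_image requires an H x W x C array",
              class = "pseudonir_format_error")
  assert_that(dim(pixels)[3] == 3L,
              "rgb_image requires exactly 3 channels, got ", dim(pixels)[3],
              class = "pseudonir_format_error")
  assert_that(dim(pixels)[1] >= 1L && dim(pixels)[2] >= 1L,
              "empty image")
  assert_that(all(is.finite(pixels)) && min(pixels) >= 0 && max(pixels) <= 1,
              "rgb_image values must be finite and within [0, 1]")
  structure(pixels, class = c("rgb_image", "array"),
            source_bit_depth = source_bit_depth)
}

#' Construct a spectral reflectance cube
#'
#' An H x W x B float array, band axis last. Band indices are 0-based
#' throughout the package so that the conventional NIR band numbering of a
#' 120-band visible-to-NIR axis (bands 70-119 covering roughly 750-1000 nm)
#' maps directly onto indices: band `b` is array slice `b + 1`.
#'
#' @param values numeric H x W x B array.
#' @param normalized logical; TRUE once values have been scaled by the global
#'   maximum reflectance (see [preprocess_cube()]).
#' @return object of class `spectral_cube`.
#' @export
spectral_cube <- function(values, normalized = FALSE) {
  assert_that(is.array(values) && length(dim(values)) == 3L,
              "spectral_cube requires an H x W x B array",
              class = "pseudonir_format_error")
  assert_that(all(is.finite(values)), "cube values must be finite")
  if (normalized)
    assert_that(min(values) >= 0 && max(values) <= 1,
                "normalized cube must lie in [0, 1]")
  structure(values, class = c("spectral_cube", "array"),
            normalized = normalized)
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<spectral_cube %d x %d x %d bands, %s, range [%.4g, %.4g]>\n",
              d[1], d[2], d[3],
              if (isTRUE(attr(x, "normalized"))) "normalized" else "raw",
              min(x), max(x)))
  invisible(x)
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, range [%.4g, %.4g]>\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

#' Extract cube bands (0-based indexing)
#'
#' @param cube a `spectral_cube`.
#' @param bands integer vector of 0-based band indices.
#' @return H x W x length(bands) array.
#' @export
band_slice <- function(cube, bands) {
  nb <- dim(cube)[3]
  assert_that(all(bands >= 0L & bands <= nb - 1L),
              "band index out of range [0, ", nb - 1L, "]")
  unclass(cube)[, , bands + 1L, drop = FALSE]
}

#' Pair an RGB image with its aligned reflectance cube
#'
#' @param rgb an `rgb_image`.
#' @param cube a `spectral_cube` with matching spatial dimensions.
#' @param identifier character id for the pair.
#' @param scene_label optional stratification label (e.g. plant condition).
#' @return object of class `dataset_pair`.
#' @export
dataset_pair <- function(rgb, cube, identifier, scene_label = NULL) {
  assert_that(identical(dim(rgb)[1:2], dim(cube)[1:2]),
              "rgb and cube spatial dimensions differ")
  structure(list(rgb = rgb, cube = cube, identifier = as.character(identifier),
                 scene_label = scene_label),
            class = "dataset_pair")
}

# Raster I/O -----------------------------------------------------------------

#' Read an RGB raster image
#'
#' Supports PNG, TIFF and JPEG. 8-bit (and 16-bit) integer samples are scaled
#' to [0, 1] by the underlying readers; float samples are clipped to [0, 1].
#' Inputs must carry exactly 3 channels; RGBA or grayscale rasters are
#' rejected with a format error naming the channel count.
#'
#' @param path image file path.
#' @return an [rgb_image()].
#' @export
read_rgb <- function(path) {
  assert_that(file.exists(path), "file not found: ", path,
              class = "pseudonir_io_error")
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      assert_that(requireNamespace("jpeg", quietly = TRUE),
                  "the 'jpeg' package is required to read JPEG files",
                  class = "pseudonir_io_error")
      jpeg::readJPEG(path)
    },
    stop_pseudonir("unsupported image format: .", ext,
                   class = "pseudonir_format_error")
  )
  nch <- if (length(dim(px)) == 3L) dim(px)[3] else 1L
  assert_that(nch == 3L,
              "expected a 3-channel RGB raster, got ", nch, " channel(s)",
              class = "pseudonir_format_error")
  rgb_image(clamp(px), source_bit_depth = if (ext %in% c("tif", "tiff") &&
                                              max(px) > 1) "float" else 8)
}

#' Write an RGB image as PNG
#'
#' @param image an `rgb_image`.
#' @param path output path (.png).
#' @return `path`, invisibly.
#' @export
write_rgb <- function(image, path) {
  png::writePNG(unclass(image), path)
  invisible(path)
}

# Cube I/O -------------------------------------------------------------------

#' Read a spectral cube
#'
#' Formats by extension: `.npy` (array container, exact float64 round trip)
#' and multi-page float TIFF (`.tif`/`.tiff`, one page per band).
#'
#' @param path file path.
#' @return a [spectral_cube()].
#' @export
read_cube <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    npy = read_npy(path),
    tif = ,
    tiff = {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      array(unlist(pages), dim = c(dim(pages[[1]])[1:2], length(pages)))
    },
    stop_pseudonir("unsupported cube format: .", ext,
                   class = "pseudonir_format_error")
  )
  assert_that(length(dim(vals)) == 3L, "cube file does not hold a 3-d array",
              class = "pseudonir_format_error")
  spectral_cube(vals, normalized = max(vals) <= 1 && min(vals) >= 0)
}

#' Write a spectral cube
#'
#' `.npy` writes the float64 array container (bit-exact round trip);
#' `.tif`/`.tiff` writes one 32-bit float page per band.
#'
#' @param cube a `spectral_cube`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  ext <- tolower(tools::file_ext(path))
  vals <- unclass(cube)
  attributes(vals) <- list(dim = dim(cube))
  switch(ext,
    npy = write_npy(vals, path),
    tif = ,
    tiff = {
      pages <- lapply(seq_len(dim(vals)[3]), function(b) vals[, , b])
      tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    },
    stop_pseudonir("unsupported cube format: .", ext,
                   class = "pseudonir_format_error")
  )
  invisible(path)
}

# Preprocessing --------------------------------------------------------------

#' Normalize and resize a reflectance cube
#'
#' Divides by the global cube maximum (a single scalar, so relative band
#' structure is preserved), then resizes each band to the target spatial
#' dimensions with bilinear interpolation. Band count is unchanged.
#'
#' @param cube a `spectral_cube`.
#' @param target_h,target_w output spatial dimensions (default keeps input).
#' @param per_band if TRUE, normalize each band by its own maximum instead of
#'   the global maximum.
#' @return a normalized `spectral_cube` of shape target_h x target_w x B.
#' @export
preprocess_cube <- function(cube, target_h = dim(cube)[1],
                            target_w = dim(cube)[2], per_band = FALSE) {
  assert_that(target_h >= 1 && target_w >= 1, "target dims must be >= 1")
  vals <- unclass(cube)
  attributes(vals) <- list(dim = dim(cube))
  if (per_band) {
    mx <- apply(vals, 3, max)
    assert_that(all(mx > 0), "cannot normalize: some band is all zero",
                class = "pseudonir_degenerate_error")
    vals <- sweep(vals, 3, mx, "/")
  } else {
    mx <- max(vals)
    assert_that(mx > 0, "cannot normalize an all-zero cube",
                class = "pseudonir_degenerate_error")
    vals <- vals / mx
  }
  d <- dim(vals)
  if (target_h != d[1] || target_w != d[2]) {
    out <- array(0, dim = c(target_h, target_w, d[3]))
    for (b in seq_len(d[3])) {
      # EBImage::resize maps w to the first array dimension
      out[, , b] <- EBImage::resize(vals[, , b], w = target_h, h = target_w,
                                    filter = "bilinear")
    }
    vals <- clamp(out)
  }
  spectral_cube(vals, normalized = TRUE)
}

# Dataset splitting ----------------------------------------------------------

#' Split a paired dataset into folds or a holdout partition
#'
#' Holdout mode assigns `round((1 - fraction) * n)` pairs to "train" and the
#' rest to "validation". K-fold mode produces folds whose sizes differ by at
#' most one; when all pairs carry a `scene_label`, assignment is stratified
#' within labels. Deterministic under a fixed seed.
#'
#' @param pairs list of `dataset_pair` objects (or a character vector of ids).
#' @param mode "kfold" or "holdout".
#' @param k number of folds (kfold mode).
#' @param fraction validation fraction in (0, 1) (holdout mode).
#' @param seed integer RNG seed.
#' @return named integer vector (fold id per identifier) for kfold, or named
#'   character vector ("train"/"validation") for holdout.
#' @export
split_dataset <- function(pairs, mode = c("kfold", "holdout"), k = 5,
                          fraction = 0.2, seed = 1L) {
  mode <- match.arg(mode)
  ids <- if (is.character(pairs)) pairs
         else vapply(pairs, function(p) p$identifier, character(1))
  labels <- if (is.character(pairs)) rep(NA_character_, length(ids))
            else vapply(pairs, function(p)
              if (is.null(p$scene_label)) NA_character_
              else as.character(p$scene_label), character(1))
  n <- length(ids)
  assert_that(n >= 1L, "empty dataset")
  assert_that(!anyDuplicated(ids), "duplicate pair identifiers")
  if (mode == "holdout") {
    assert_that(fraction > 0 && fraction < 1,
                "holdout fraction must lie in (0, 1)",
                class = "pseudonir_config_error")
    n_val <- max(1L, round(fraction * n))
    out <- with_seed(seed, {
      val <- sample(ids, n_val)
      stats::setNames(ifelse(ids %in% val, "validation", "train"), ids)
    })
    return(out)
  }
  assert_that(k >= 2L && k <= n, "k must satisfy 2 <= k <= n (n = ", n, ")",
              class = "pseudonir_config_error")
  with_seed(seed, {
    assign_group <- function(members, offset) {
      # shuffle, then deal round-robin starting at a rotating offset so
      # fold sizes stay balanced across strata
      members <- sample(members)
      folds <- ((seq_along(members) - 1L + offset) %% k) + 1L
      stats::setNames(folds, members)
    }
    if (!anyNA(labels)) {
      res <- integer(0)
      offset <- 0L
      for (lab in unique(labels)) {
        members <- ids[labels == lab]
        res <- c(res, assign_group(members, offset))
        offset <- (offset + length(members)) %% k
      }
      res[ids]
    } else {
      assign_group(ids, 0L)[ids]
    }
  })
}
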