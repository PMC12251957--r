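# Pipeline configuration files (YAML or JSON) mapping onto the package's
# parameter constructors, with light schema validation.

#' Load a pipeline configuration file
#'
#' Reads a YAML or JSON file with optional top-level sections `grgb`,
#' `model`, `train`, `bands`, and `scene`, validates the fields against the
#' corresponding constructors, and returns ready-to-use parameter objects.
#' Unknown fields raise an error naming the offender.
#'
#' @param path configuration file (.yaml/.yml/.json).
#' @return list with elements `grgb` ([grgb_params()]), `model`
#'   ([fusenet_config()]), `train` ([fusenet_train_config()]), `bands`
#'   (list: `scheme` a [band_group_scheme()], `combination`), `scene`
#'   ([scene_params()]); sections absent from the file get defaults.
#' @export
read_pipeline_config <- function(path) {
  assert_that(file.exists(path), "config file not found: ", path,
              class = "pseudonir_io_error")
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop_pseudonir("unsupported config format: .", ext,
                   class = "pseudonir_format_error"))
  if (is.null(raw)) raw <- list()
  known <- c("grgb", "model", "train", "bands", "scene")
  bad <- setdiff(names(raw), known)
  assert_that(length(bad) == 0, "unknown config section(s): ",
              paste(bad, collapse = ", "), class = "pseudonir_config_error")
  call_checked <- function(fn, args, where) {
    ok <- names(formals(fn))
    bad <- setdiff(names(args), ok)
    assert_that(length(bad) == 0, "unknown field(s) in '", where, "': ",
                paste(bad, collapse = ", "),
                class = "pseudonir_config_error")
    do.call(fn, args)
  }
  bands_raw <- raw$bands
  scheme <- if (!is.null(bands_raw$groups))
    call_checked(band_group_scheme,
                 lapply(bands_raw$groups, function(r) r[1]:r[2]),
                 "bands$groups")
  else band_group_scheme()
  list(
    grgb = call_checked(grgb_params, raw$grgb %||% list(), "grgb"),
    model = call_checked(fusenet_config, raw$model %||% list(), "model"),
    train = call_checked(fusenet_train_config, raw$train %||% list(),
                         "train"),
    bands = list(scheme = scheme,
                 combination = as.integer(bands_raw$combination %||%
                                            c(70L, 91L, 108L))),
    scene = call_checked(scene_params, raw$scene %||% list(), "scene")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
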