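# Minimal NPY v1.0 array container (float64), used as the cube serialization
# format. R arrays are column-major, so cubes are written with
# fortran_order: True and the raw vector dumped as little-endian doubles --
# the round trip is bit-exact. The reader additionally accepts C-order and
# the common integer/float dtypes so cubes produced elsewhere load too.

npy_descr <- list(
  "<f8" = list(what = "double",  size = 8L),
  "<f4" = list(what = "double",  size = 4L),
  "<i8" = list(what = "integer", size = 8L),
  "<i4" = list(what = "integer", size = 4L)
)

#' Write an array to an NPY file
#'
#' Serializes a numeric array (any number of dimensions) as an NPY v1.0
#' float64 array. Written column-major (`fortran_order: True`), so the
#' read/write round trip through [read_npy()] is bit-exact.
#'
#' @param x numeric vector, matrix or array.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path) {
  dims <- dim(x)
  if (is.null(dims)) dims <- length(x)
  # python tuple syntax: (n,) for 1-d, (a, b, c) otherwise
  shape <- if (length(dims) == 1L) paste0("(", dims, ",)") else
    paste0("(", paste(dims, collapse = ", "), ")")
  header <- sprintf(
    "{'descr': '<f8', 'fortran_order': True, 'shape': %s, }", shape)
  # total header block (magic 6 + version 2 + len 2 + dict) padded to 64 bytes
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(0x01, 0x00))), con)
  writeBin(nchar(header), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.vector(as.double(x)), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read an NPY file
#'
#' Reads NPY v1.0/2.0 arrays of dtype `<f8`, `<f4`, `<i8` or `<i4`, in either
#' C or Fortran order, returning a base R array.
#'
#' @param path file path.
#' @return numeric array with the stored shape.
#' @export
read_npy <- function(path) {
  assert_that(file.exists(path), "file not found: ", path,
              class = "pseudonir_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  assert_that(identical(magic, c(as.raw(0x93), charToRaw("NUMPY"))),
              "not an NPY file: ", path, class = "pseudonir_format_error")
  ver <- readBin(con, "raw", 2L)
  hlen <- if (as.integer(ver[1]) >= 2L)
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  else readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  spec <- npy_descr[[descr]]
  assert_that(!is.null(spec), "unsupported NPY dtype: ", descr,
              class = "pseudonir_format_error")
  n <- prod(dims)
  vals <- readBin(con, spec$what, n, size = spec$size, endian = "little")
  if (length(dims) > 1L) {
    if (fortran) dim(vals) <- dims
    else {
      dim(vals) <- rev(dims)
      vals <- aperm(vals, rev(seq_along(dims)))
    }
  }
  vals
}
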