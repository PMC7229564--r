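#' Thermal image container
#'
#' A `thermal_image` wraps a 2-D grid of non-negative intensity values
#' (arbitrary thermal units or temperatures). Rows increase downward and
#' columns increase rightward; all pixel coordinates in this package are
#' 1-based `(column, row)` pairs.
#'
#' @param pixels numeric matrix of intensities, at least 32x32, finite and
#'   non-negative.
#' @param source free-text provenance string.
#' @return An object of class `thermal_image` with fields `pixels` and
#'   `source`.
#' @examples
#' img <- thermal_image(matrix(runif(32 * 32, 0, 100), 32, 32), "example")
#' img_height(img); img_width(img)
#' @export
thermal_image <- function(pixels, source = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    guan_abort("guan_validation_error", "`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) < 32 || ncol(pixels) < 32) {
    guan_abort(
      "guan_validation_error",
      sprintf("image must be at least 32x32 (got %dx%d)", nrow(pixels), ncol(pixels))
    )
  }
  if (!all(is.finite(pixels))) {
    guan_abort("guan_validation_error", "image contains non-finite pixel values")
  }
  if (min(pixels) < 0) {
    guan_abort("guan_validation_error", "image contains negative intensities")
  }
  structure(
    list(pixels = unname(pixels), source = as.character(source)[1]),
    class = "thermal_image"
  )
}

#' @rdname thermal_image
#' @param image a `thermal_image`.
#' @export
img_height <- function(image) nrow(image$pixels)

#' @rdname thermal_image
#' @export
img_width <- function(image) ncol(image$pixels)

#' @export
print.thermal_image <- function(x, ...) {
  cat(sprintf(
    "<thermal_image> %d x %d px, intensity range [%.6g, %.6g]%s\n",
    img_height(x), img_width(x), min(x$pixels), max(x$pixels),
    if (nzchar(x$source)) paste0(", source: ", x$source) else ""
  ))
  invisible(x)
}

# Bit depth of a PNG file, from byte 25 of the stream (IHDR bit-depth field).
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  sig <- as.integer(hdr[1:8])
  if (length(hdr) < 25L ||
      !identical(sig, c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L))) {
    guan_abort("guan_io_error", sprintf("'%s' is not a PNG file", path))
  }
  as.integer(hdr[25L])
}

guess_kind <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = "tiff",
    png = "png",
    csv = , txt = , dat = , tsv = "csv",
    guan_abort("guan_format_error",
               sprintf("cannot guess image format from extension '.%s'", ext))
  )
}

collapse_channels <- function(arr, convert, path) {
  if (length(dim(arr)) == 2L) return(arr)
  nch <- dim(arr)[3]
  if (nch == 1L) return(arr[, , 1L])
  if (!convert) {
    guan_abort(
      "guan_format_error",
      sprintf("'%s' has %d channels; pass convert = TRUE for luminance conversion", path, nch)
    )
  }
  warning(sprintf("'%s': converting %d channels to luminance", path, nch))
  w <- if (nch >= 3) c(0.2126, 0.7152, 0.0722) else rep(1 / nch, nch)
  out <- matrix(0, dim(arr)[1], dim(arr)[2])
  for (k in seq_along(w)) out <- out + w[k] * arr[, , k]
  out
}

#' Read a thermal image
#'
#' Supported formats: grayscale TIFF (8/16-bit), grayscale PNG (8/16-bit) and
#' plain-text matrices (comma- or whitespace-delimited, one image row per
#' line, no header). Integer image formats are returned in their native
#' integer units (a 16-bit PNG pixel of 1234 reads as 1234); intensities are
#' never rescaled silently. CSV values are read as-is at full precision.
#'
#' @param path path to the image file.
#' @param kind one of `"auto"` (by extension), `"tiff"`, `"png"`, `"csv"`.
#' @param convert if `TRUE`, multichannel images are collapsed to luminance
#'   with a warning instead of raising a format error.
#' @return A [thermal_image].
#' @export
read_image <- function(path, kind = c("auto", "tiff", "png", "csv"), convert = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    guan_abort("guan_io_error", sprintf("file '%s' does not exist", path))
  }
  if (kind == "auto") kind <- guess_kind(path)
  px <- switch(kind,
    tiff = {
      arr <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                      error = function(e) guan_abort("guan_io_error", conditionMessage(e)))
      collapse_channels(arr, convert, path)
    },
    png = {
      depth <- png_bit_depth(path)
      arr <- tryCatch(png::readPNG(path),
                      error = function(e) guan_abort("guan_io_error", conditionMessage(e)))
      round(collapse_channels(arr, convert, path) * (2^depth - 1))
    },
    csv = read_csv_matrix(path)
  )
  thermal_image(px, source = path)
}

read_csv_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- tryCatch(
    utils::read.table(path, header = FALSE, sep = sep, colClasses = "numeric"),
    error = function(e) guan_abort("guan_io_error", conditionMessage(e))
  )
  px <- as.matrix(df)
  if (!all(is.finite(px))) {
    guan_abort("guan_validation_error",
               sprintf("'%s' contains NaN or infinite values", path))
  }
  dimnames(px) <- NULL
  px
}

#' Write a thermal image
#'
#' TIFF is written as 8- or 16-bit grayscale (exact round trip for
#' integer-valued images up to the chosen bit depth); PNG is written 8-bit
#' (the limit of the PNG writer used); CSV is written at full double
#' precision.
#'
#' @param image a [thermal_image].
#' @param path output path; format chosen by extension unless `kind` given.
#' @param kind `"auto"`, `"tiff"`, `"png"` or `"csv"`.
#' @param bits bit depth for TIFF output (8 or 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, kind = c("auto", "tiff", "png", "csv"), bits = 16L) {
  stopifnot(inherits(image, "thermal_image"))
  kind <- match.arg(kind)
  if (kind == "auto") kind <- guess_kind(path)
  px <- image$pixels
  wrap_io <- function(expr) {
    tryCatch(expr, error = function(e) guan_abort("guan_io_error", conditionMessage(e)))
  }
  switch(kind,
    tiff = {
      if (!bits %in% c(8L, 16L)) guan_abort("guan_param_error", "`bits` must be 8 or 16")
      mx <- 2^bits - 1
      if (max(px) > mx) {
        guan_abort("guan_validation_error",
                   sprintf("intensities exceed %d; rescale before writing %d-bit TIFF", mx, bits))
      }
      wrap_io(tiff::writeTIFF(px / mx, path, bits.per.sample = as.integer(bits)))
    },
    png = {
      if (max(px) > 255) {
        guan_abort("guan_validation_error",
                   "intensities exceed 255; PNG output is 8-bit (use TIFF for 16-bit)")
      }
      wrap_io(png::writePNG(px / 255, path))
    },
    csv = wrap_io(utils::write.table(
      px, path, sep = ",", row.names = FALSE, col.names = FALSE
    ))
  )
  invisible(path)
}
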