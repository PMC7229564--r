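#' GUAN localization result
#'
#' Bundles the pixel coordinates of the detected GUAN site, optional
#' real-world millimetre coordinates (present when a camera geometry was
#' configured), the optional wrist-crease reference column and the mapped
#' crease-to-GUAN distance, plus a diagnostics list of intermediate
#' quantities. All pixel coordinates are 1-based `(column, row)`.
#'
#' @param x0_px column index of GUAN.
#' @param y0_px row index of GUAN.
#' @param x_world_mm,y_world_mm optional mapped millimetre coordinates.
#' @param crease_x_px optional wrist-crease reference column.
#' @param x_distance_mm optional |crease - GUAN| mapped distance in mm.
#' @param diagnostics named list of intermediate quantities.
#' @param img_width,img_height optional image dimensions; when supplied the
#'   pixel coordinates are validated against them.
#' @return An object of class `guan_result`.
#' @export
guan_result <- function(x0_px, y0_px, x_world_mm = NULL, y_world_mm = NULL,
                        crease_x_px = NULL, x_distance_mm = NULL,
                        diagnostics = list(), img_width = NULL, img_height = NULL) {
  if (!is.null(img_width) && (x0_px < 1 || x0_px > img_width)) {
    guan_abort("guan_validation_error",
               sprintf("x0_px = %s outside image columns 1..%d", x0_px, img_width))
  }
  if (!is.null(img_height) && (y0_px < 1 || y0_px > img_height)) {
    guan_abort("guan_validation_error",
               sprintf("y0_px = %s outside image rows 1..%d", y0_px, img_height))
  }
  structure(
    list(
      x0_px = x0_px, y0_px = y0_px,
      x_world_mm = x_world_mm, y_world_mm = y_world_mm,
      crease_x_px = crease_x_px, x_distance_mm = x_distance_mm,
      diagnostics = diagnostics
    ),
    class = "guan_result"
  )
}

#' @export
print.guan_result <- function(x, ...) {
  cat(sprintf("<guan_result> GUAN at pixel (col %s, row %s)\n", x$x0_px, x$y0_px))
  if (!is.null(x$x_world_mm)) {
    cat(sprintf("  world: x = %.3f mm, y = %.3f mm\n", x$x_world_mm, x$y_world_mm))
  }
  if (!is.null(x$crease_x_px)) {
    cat(sprintf("  crease reference at col %s", x$crease_x_px))
    if (!is.null(x$x_distance_mm)) cat(sprintf(", crease-GUAN distance %.3f mm", x$x_distance_mm))
    cat("\n")
  }
  invisible(x)
}

#' Write / read a localization result as JSON
#'
#' Fields absent from the result (e.g. world coordinates without a configured
#' geometry) are omitted from the document, not null-filled. Numbers are
#' serialized at full precision.
#'
#' @param result a [guan_result].
#' @param path output (input) file path.
#' @return `write_result()` returns `path` invisibly; `read_result()` returns
#'   a [guan_result].
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "guan_result"))
  doc <- result[!vapply(result, is.null, logical(1))]
  doc <- unclass(doc)
  if (length(doc$diagnostics) == 0) doc$diagnostics <- NULL
  tryCatch(
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA),
    error = function(e) guan_abort("guan_io_error", conditionMessage(e))
  )
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  if (!file.exists(path)) guan_abort("guan_io_error", sprintf("file '%s' does not exist", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  guan_result(
    x0_px = doc$x0_px, y0_px = doc$y0_px,
    x_world_mm = doc$x_world_mm, y_world_mm = doc$y_world_mm,
    crease_x_px = doc$crease_x_px, x_distance_mm = doc$x_distance_mm,
    diagnostics = doc$diagnostics %||% list()
  )
}

#' Write an annotated rendering of a localization
#'
#' Renders the image to 8-bit grayscale, draws a vertical line through the
#' GUAN column over the full image height and a cross at the GUAN pixel, and
#' writes a PNG. The input image object is not modified.
#'
#' @param image a [thermal_image].
#' @param result a [guan_result] with coordinates inside `image`.
#' @param path output PNG path.
#' @param cross_px half-length of the cross arms, in pixels.
#' @return `path`, invisibly.
#' @export
write_annotated <- function(image, result, path, cross_px = 6L) {
  stopifnot(inherits(image, "thermal_image"), inherits(result, "guan_result"))
  H <- img_height(image); W <- img_width(image)
  x0 <- result$x0_px; y0 <- result$y0_px
  if (x0 < 1 || x0 > W || y0 < 1 || y0 > H) {
    guan_abort("guan_validation_error", "result coordinates lie outside the image")
  }
  px <- image$pixels
  rng <- range(px)
  gray <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  rgb <- array(gray, dim = c(H, W, 3))
  # vertical line at the GUAN column, red
  rgb[, x0, 1] <- 1; rgb[, x0, 2] <- 0; rgb[, x0, 3] <- 0
  rows <- pmin(pmax(seq(y0 - cross_px, y0 + cross_px), 1L), H)
  cols <- pmin(pmax(seq(x0 - cross_px, x0 + cross_px), 1L), W)
  rgb[y0, cols, 1] <- 1; rgb[y0, cols, 2] <- 0; rgb[y0, cols, 3] <- 0
  rgb[rows, x0, 1] <- 1; rgb[rows, x0, 2] <- 0; rgb[rows, x0, 3] <- 0
  tryCatch(png::writePNG(rgb, path),
           error = function(e) guan_abort("guan_io_error", conditionMessage(e)))
  invisible(path)
}
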