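#' Create an image grid
#'
#' The package's basic image container: a 2-D double-precision pixel matrix
#' together with its nominal dynamic range `D` (maximum minus minimum
#' representable value), which the quality metrics need. Pixels are stored
#' row-major-agnostically as an R matrix, origin at the top-left, pixel
#' centers at integer coordinates.
#'
#' @param pixels Numeric matrix (U rows x V columns), all values finite.
#' @param dynamic_range Positive scalar `D`; defaults to 1 (images mapped
#'   to `[0, 1]`).
#' @return An object of class `image_grid`.
#' @export
#' @examples
#' img <- image_grid(matrix(0.5, 8, 8))
#' dim(img$pixels)
image_grid <- function(pixels, dynamic_range = 1) {
  if (is.null(dim(pixels))) pixels <- as.matrix(pixels)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_invalid("'pixels' must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop_invalid("image must have at least one row and one column")
  if (!all(is.finite(pixels)))
    stop_invalid("all pixel values must be finite")
  if (!is.numeric(dynamic_range) || length(dynamic_range) != 1L ||
      !is.finite(dynamic_range) || dynamic_range < 0)
    stop_invalid("'dynamic_range' must be a non-negative scalar")
  structure(list(pixels = unname(pixels * 1.0),
                 dynamic_range = as.double(dynamic_range)),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d, D = %g, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$dynamic_range,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$pixels)

# Accept an image_grid or bare matrix; return the pixel matrix.
as_pixels <- function(x) {
  if (inherits(x, "image_grid")) return(x$pixels)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop_invalid("expected an 'image_grid' or a numeric matrix")
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop_invalid("images must have identical dimensions (",
                 paste(dim(a), collapse = "x"), " vs ",
                 paste(dim(b), collapse = "x"), ")")
  invisible(TRUE)
}

#' Display an image grid
#'
#' @param x An `image_grid`.
#' @param y Ignored.
#' @param ... Passed to [graphics::image()].
#' @export
plot.image_grid <- function(x, y, ...) {
  px <- x$pixels
  # flip rows so the top-left origin displays upright
  graphics::image(t(px[nrow(px):1, , drop = FALSE]),
                  col = grDevices::grey.colors(256, 0, 1),
                  asp = nrow(px) / ncol(px),
                  axes = FALSE, ...)
  invisible(x)
}

#' Read and write images
#'
#' Images travel as 16-bit integer TIFF (`.tif`/`.tiff`, values quantized
#' over `[0, D]` — the only point in the pipeline where clamping to the
#' dynamic range happens) or plain-text TSV (`.tsv`, full double
#' precision, one row per image row; the lossless raw format). TSV
#' round-trips are exact; TIFF round-trips are accurate to one part in
#' 65535 of the dynamic range.
#'
#' @param img An `image_grid`.
#' @param path Output/input file path; format chosen by extension.
#' @param bits TIFF bit depth, 16 (default) or 8.
#' @param dynamic_range Dynamic range `D` used to de-quantize TIFF pixels
#'   and attached to the result (default 1).
#' @return `write_image` returns `path` invisibly; `read_image` returns an
#'   `image_grid`.
#' @export
write_image <- function(img, path, bits = 16) {
  px <- as_pixels(img)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!bits %in% c(8, 16)) stop_invalid("'bits' must be 8 or 16")
    D <- if (inherits(img, "image_grid")) img$dynamic_range else 1
    q <- pmin(pmax(px / D, 0), 1)
    tiff::writeTIFF(q, path, bits.per.sample = as.integer(bits))
  } else if (ext == "tsv") {
    txt <- formatC(px, format = "g", digits = 17)
    utils::write.table(txt, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else {
    stop_invalid("unsupported image extension '.", ext,
                 "' (use .tif, .tiff or .tsv)")
  }
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path, dynamic_range = 1) {
  if (!file.exists(path)) stop_invalid("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path)
    if (length(dim(px)) == 3L) px <- px[, , 1]
    px <- px * dynamic_range
  } else if (ext == "tsv") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "numeric")
    px <- unname(as.matrix(tab))
  } else {
    stop_invalid("unsupported image extension '.", ext, "'")
  }
  image_grid(px, dynamic_range)
}
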