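#' Raster image container
#'
#' The unit the whole pipeline operates on: a 2D grid of non-negative
#' integer pixel intensities (raw stored CT values, dimensionless).  Values
#' must fit an unsigned 16-bit range, and no downstream operation ever
#' modifies them in place -- masking, windowing and rendering all derive new
#' objects.
#'
#' Coordinates are row-major with origin at the top-left; in R code pixels
#' are addressed `pixels(img)[row, col]` with 1-based indices.
#'
#' @param pixels integer matrix, all values in `[0, 65535]`.
#' @param source_format provenance of the pixel grid: `"dicom"`, `"png16"`,
#'   `"text"`, or `"memory"` for grids built in R (the default).
#' @return An object of class `svmi_image`.
#' @examples
#' img <- raster_image(matrix(0:5, 2, 3))
#' dim(img)
#' pixels(img)
#' @export
raster_image <- function(pixels, source_format = "memory") {
  if (is.data.frame(pixels)) pixels <- as.matrix(pixels)
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  source_format <- match.arg(source_format, c("memory", "dicom", "png16", "text"))
  if (anyNA(pixels)) stop("pixel values must not be NA")
  if (is.double(pixels)) {
    if (any(pixels != round(pixels))) stop("pixel values must be integers")
    storage.mode(pixels) <- "integer"
  }
  if (!is.integer(pixels)) stop("pixel values must be integers")
  if (any(pixels < 0L)) stop("pixel values must be >= 0 (signed data is rejected, not clamped)")
  if (any(pixels > 65535L)) stop("pixel values must be <= 65535 (16-bit contract)")
  dimnames(pixels) <- NULL
  structure(list(pixels = pixels, source_format = source_format),
            class = "svmi_image")
}

#' @rdname raster_image
#' @param x,img an `svmi_image`.
#' @export
pixels <- function(img) {
  stopifnot(is_raster_image(img))
  img$pixels
}

#' @rdname raster_image
#' @export
is_raster_image <- function(x) inherits(x, "svmi_image")

#' @rdname raster_image
#' @export
dim.svmi_image <- function(x) dim(x$pixels)

#' @rdname raster_image
#' @param ... ignored.
#' @export
as.matrix.svmi_image <- function(x, ...) x$pixels

#' @export
print.svmi_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<svmi_image> %d x %d pixels (%s), values %d..%d\n",
              d[1], d[2], x$source_format, min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Accept either an svmi_image or a bare integer matrix; always return the
# integer pixel matrix.  Internal convenience used across modules.
as_pixel_matrix <- function(img) {
  if (is_raster_image(img)) return(img$pixels)
  if (is.matrix(img)) return(pixels(raster_image(img)))
  stop("expected an svmi_image or an integer matrix")
}
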