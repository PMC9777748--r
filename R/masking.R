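#' Pixel masks: hide non-informative pixels
#'
#' A pixel mask is a logical matrix with the same shape as its image;
#' `TRUE` means the pixel is retained (displayed, counted in statistics),
#' `FALSE` means it is suppressed.  Figures may paint suppressed pixels
#' black or white; the polarity here is fixed and rendering decides the
#' color.
#'
#' * `zero_mask()` suppresses exactly the zero-valued (background) pixels.
#' * `high_value_mask()` suppresses pixels whose value is strictly greater
#'   than `threshold` (default 100) -- bone and other structures whose
#'   immense values would crush the soft-tissue contrast on a linear scale.
#' * `central_region_mask()` keeps the central soft-tissue region: the
#'   largest axis-aligned ellipse inscribed in the tight bounding box of
#'   the nonzero pixels, optionally shrunk by `margin` pixels.  A pixel
#'   exactly on the ellipse boundary is retained.
#' * `fraction_mask()` suppresses a band of 1/3 or 2/3 of the rows or
#'   columns from one side (e.g. the upper third, near the eyes).  The
#'   band size is `fraction * extent` rounded half away from zero.
#'
#' @param img an [raster_image()] or integer matrix.
#' @param threshold integer >= 1; values strictly above it are suppressed.
#' @param margin non-negative number of pixels to shrink the inscribed
#'   ellipse semi-axes by.
#' @param shape integer vector `c(rows, cols)`.
#' @param side one of `"top"`, `"bottom"`, `"left"`, `"right"`.
#' @param fraction `1/3` or `2/3`.
#' @return A logical matrix (`TRUE` = retained).
#' @examples
#' m <- matrix(c(0L, 50L, 200L), 1, 3)
#' combine_masks(list(zero_mask(m), high_value_mask(m, 100)))
#' @name masks
NULL

#' @rdname masks
#' @export
zero_mask <- function(img) {
  as_pixel_matrix(img) != 0L
}

#' @rdname masks
#' @export
high_value_mask <- function(img, threshold = 100L) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 1)
    stop("`threshold` must be a single integer >= 1")
  as_pixel_matrix(img) <= threshold
}

#' @rdname masks
#' @export
central_region_mask <- function(img, margin = 0) {
  m <- as_pixel_matrix(img)
  nz <- which(m != 0L, arr.ind = TRUE)
  if (nrow(nz) == 0L) stop("cannot build central region mask: image is all zero (no soft tissue to bound)")
  r0 <- min(nz[, 1L]); r1 <- max(nz[, 1L])
  c0 <- min(nz[, 2L]); c1 <- max(nz[, 2L])
  cy <- (r0 + r1) / 2; cx <- (c0 + c1) / 2
  ry <- (r1 - r0) / 2 - margin
  rx <- (c1 - c0) / 2 - margin
  rows <- seq_len(nrow(m)); cols <- seq_len(ncol(m))
  dy2 <- if (ry > 0) ((rows - cy) / ry)^2 else ifelse(rows == cy, 0, Inf)
  dx2 <- if (rx > 0) ((cols - cx) / rx)^2 else ifelse(cols == cx, 0, Inf)
  outer(dy2, dx2, `+`) <= 1  # boundary pixels retained
}

#' @rdname masks
#' @export
fraction_mask <- function(shape, side, fraction) {
  side <- match.arg(side, c("top", "bottom", "left", "right"))
  if (!isTRUE(all.equal(fraction, 1 / 3)) && !isTRUE(all.equal(fraction, 2 / 3)))
    stop("`fraction` must be 1/3 or 2/3")
  nr <- as.integer(shape[1L]); nc <- as.integer(shape[2L])
  extent <- if (side %in% c("top", "bottom")) nr else nc
  band <- round_half_away(fraction * extent)
  mask <- matrix(TRUE, nr, nc)
  if (band > 0L) switch(side,
    top    = mask[seq_len(band), ] <- FALSE,
    bottom = mask[seq(nr - band + 1L, nr), ] <- FALSE,
    left   = mask[, seq_len(band)] <- FALSE,
    right  = mask[, seq(nc - band + 1L, nc)] <- FALSE)
  mask
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Combine pixel masks
#'
#' Element-wise combination of retained flags: `"intersect"` keeps a pixel
#' only if every mask keeps it (the union of the suppressed sets),
#' `"union"` keeps a pixel if any mask keeps it.
#'
#' @param masks list of logical matrices of equal shape.
#' @param mode `"intersect"` (default) or `"union"`.
#' @return A logical matrix.
#' @export
combine_masks <- function(masks, mode = c("intersect", "union")) {
  mode <- match.arg(mode)
  stopifnot(is.list(masks), length(masks) >= 1L)
  shapes <- vapply(masks, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) stop("cannot combine masks of different shapes: ", paste(unique(shapes), collapse = " vs "))
  Reduce(if (mode == "intersect") `&` else `|`, masks)
}

#' Apply a mask to an image
#'
#' Suppressed pixels are set to zero; retained pixels keep their value.
#' The input image is never modified.
#'
#' @param img an [raster_image()] or integer matrix.
#' @param mask logical matrix of the same shape.
#' @return An [raster_image()] with suppressed pixels zeroed.
#' @export
apply_mask <- function(img, mask) {
  m <- as_pixel_matrix(img)
  check_same_shape(m, mask)
  out <- m
  out[!mask] <- 0L
  raster_image(out, source_format = if (is_raster_image(img)) img$source_format else "memory")
}

#' Fraction of pixels a mask retains
#'
#' `100 * retained / total`, reported to one decimal place -- the coverage
#' figure quoted alongside each mask (e.g. a central region holding 37.4%
#' of all pixels).
#'
#' @param mask logical matrix.
#' @param digits decimal places to report (default 1).
#' @return Percentage of retained pixels.
#' @export
coverage_fraction <- function(mask, digits = 1L) {
  round(100 * sum(mask) / length(mask), digits)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

#' Serialize a pixel mask
#'
#' `write_mask()` stores a mask either as an 8-bit grayscale PNG
#' (retained = 255, suppressed = 0) or as run-length text: a header line
#' `rows cols`, then one `value count` pair per line in row-major order.
#' `read_mask()` reads either format back to a logical matrix.
#'
#' @param mask logical matrix.
#' @param path output file.
#' @param format `"png"` or `"rle"`.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` a
#'   logical matrix.
#' @export
write_mask <- function(mask, path, format = c("rle", "png")) {
  format <- match.arg(format)
  if (format == "png") {
    png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  } else {
    v <- as.integer(t(mask))  # row-major
    r <- rle(v)
    writeLines(c(paste(nrow(mask), ncol(mask)),
                 paste(r$values, r$lengths)), path)
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, format = c("rle", "png")) {
  format <- match.arg(format)
  if (format == "png") {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L) x <- x[, , 1L]
    return(x >= 0.5)
  }
  lines <- readLines(path)
  hd <- as.integer(strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]])
  pairs <- do.call(rbind, lapply(strsplit(trimws(lines[-1L]), "[[:space:]]+"), as.numeric))
  v <- inverse.rle(list(values = pairs[, 1L], lengths = pairs[, 2L]))
  matrix(as.logical(v), nrow = hd[1L], ncol = hd[2L], byrow = TRUE)
}
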