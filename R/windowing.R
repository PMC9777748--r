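#' Contiguous integer gray-level range
#'
#' The display window: an inclusive run `[lo, hi]` of successive integer
#' pixel values chosen by the reader.  A range written `{18, 42}` contains
#' `hi - lo + 1 = 25` integer levels (inclusive at both ends).
#'
#' @param lo,hi integers, `0 <= lo <= hi`.
#' @return An object of class `svmi_range` with fields `lo`, `hi` and
#'   `n_levels`.
#' @examples
#' level_range(18, 42)$n_levels  # 25
#' @export
level_range <- function(lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo != round(lo) || hi != round(hi))
    stop("`lo` and `hi` must be integers")
  if (lo < 0) stop("`lo` must be >= 0")
  if (hi < lo) stop("`hi` must be >= `lo`")
  structure(list(lo = as.integer(lo), hi = as.integer(hi),
                 n_levels = as.integer(hi - lo + 1L)),
            class = "svmi_range")
}

#' @export
print.svmi_range <- function(x, ...) {
  cat(sprintf("<svmi_range> [%d, %d] (%d integer levels)\n", x$lo, x$hi, x$n_levels))
  invisible(x)
}

as_level_range <- function(range) {
  if (inherits(range, "svmi_range")) return(range)
  if (is.numeric(range) && length(range) == 2L) return(level_range(range[1L], range[2L]))
  stop("`range` must be a level_range() or a length-2 numeric vector c(lo, hi)")
}

#' Integer-level histogram over retained pixels
#'
#' Tallies how many retained pixels hold each integer value.  Suppressed
#' pixels are excluded entirely -- they are not counted as zeros.  With a
#' `range`, only values in `[lo, hi]` are tallied and every level of the
#' range appears in the output (possibly with count 0); without one, all
#' values observed among retained pixels appear.
#'
#' @param img an [raster_image()] or integer matrix.
#' @param mask logical matrix (`TRUE` = retained); `NULL` keeps all pixels.
#' @param range optional [level_range()].
#' @return A `data.frame` with integer columns `value` and `count`.
#' @export
level_histogram <- function(img, mask = NULL, range = NULL) {
  m <- as_pixel_matrix(img)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(m), ncol(m))
  check_same_shape(m, mask)
  v <- m[mask]
  if (is.null(range)) {
    if (length(v) == 0L)
      return(data.frame(value = integer(0), count = integer(0)))
    tab <- table(v)
    return(data.frame(value = as.integer(names(tab)),
                      count = as.integer(tab)))
  }
  range <- as_level_range(range)
  lev <- range$lo:range$hi
  counts <- tabulate(match(v, lev), nbins = length(lev))
  data.frame(value = lev, count = as.integer(counts))
}

#' Number of distinct values among retained pixels
#'
#' @inheritParams level_histogram
#' @return Integer count of distinct retained values.
#' @export
distinct_values <- function(img, mask = NULL) {
  m <- as_pixel_matrix(img)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(m), ncol(m))
  check_same_shape(m, mask)
  length(unique(m[mask]))
}

#' Mask of pixels inside a level range
#'
#' Retains exactly the pixels whose value `v` satisfies `lo <= v <= hi`
#' (inclusive at both ends).
#'
#' @inheritParams level_histogram
#' @param range a [level_range()] or `c(lo, hi)`.
#' @return A logical matrix.
#' @export
range_mask <- function(img, range) {
  m <- as_pixel_matrix(img)
  range <- as_level_range(range)
  m >= range$lo & m <= range$hi
}

#' Rescale a level range onto [0, 1]
#'
#' The windowing step: value `v` in `[lo, hi]` maps affinely to
#' `(v - lo) / (hi - lo)`, so the chosen run of integer levels spans the
#' full display range and adjacent integers differ by exactly
#' `1 / (hi - lo)`.  Pixels outside the range, or suppressed by `mask`,
#' become `NA` (suppressed) -- never clamped into `[0, 1]`, because `0` is
#' the image of `lo`.
#'
#' @inheritParams range_mask
#' @param mask optional logical matrix of additionally retained pixels.
#' @return A numeric matrix in `[0, 1]` with `NA` at suppressed pixels.
#' @export
rescale_unit <- function(img, range, mask = NULL) {
  m <- as_pixel_matrix(img)
  range <- as_level_range(range)
  if (range$hi == range$lo)
    stop("degenerate level range: hi == lo (nothing to rescale)")
  keep <- range_mask(m, range)
  if (!is.null(mask)) {
    check_same_shape(m, mask)
    keep <- keep & mask
  }
  out <- (m - range$lo) / (range$hi - range$lo)
  out[!keep] <- NA_real_
  out
}

#' Gray contrast between adjacent levels in the unrescaled display
#'
#' When the full image is normalized by its maximum value, two adjacent
#' integer levels differ by only `1 / max_value` on the 0..1 gray scale --
#' about 0.0006 for a maximum of 1682, far below what an observer can
#' separate, which is why the range-rescaling step exists.
#'
#' @param max_value positive integer, the normalization maximum.
#' @return `1 / max_value`.
#' @export
relative_gray_step <- function(max_value) {
  if (!is.numeric(max_value) || length(max_value) != 1L || max_value < 1)
    stop("`max_value` must be a single integer >= 1")
  1 / max_value
}

#' Statistics over retained pixels only
#'
#' Mean, standard deviation and variance of the retained pixel values.
#' Suppressed pixels contribute nothing -- they are excluded, not treated
#' as zeros, so masking cannot drag the mean down.  The variance is the
#' population variance (divide by `n`): these are descriptive statistics
#' of a fixed pixel set, not an estimate from a sample.
#'
#' @inheritParams level_histogram
#' @return An object of class `svmi_stats`: list with `mean`, `deviation`,
#'   `variance`, `n`.
#' @examples
#' masked_stats(matrix(c(2L, 4L, 6L, 99L), 2, 2),
#'              matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
#' @export
masked_stats <- function(img, mask = NULL) {
  m <- as_pixel_matrix(img)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(m), ncol(m))
  check_same_shape(m, mask)
  v <- as.numeric(m[mask])
  if (length(v) == 0L)
    stop("no retained pixels: statistics over an empty set are undefined")
  mu <- mean(v)
  va <- mean((v - mu)^2)  # population variance
  structure(list(mean = mu, deviation = sqrt(va), variance = va,
                 n = length(v)),
            class = "svmi_stats")
}

#' @export
print.svmi_stats <- function(x, digits = 2L, ...) {
  cat(sprintf("<svmi_stats> n = %d, mean = %.*f, deviation = %.*f, variance = %.*f\n",
              x$n, digits, x$mean, digits, x$deviation, digits, x$variance))
  invisible(x)
}

# The k-pixel averaging stencil: the center pixel plus its k - 1 nearest
# neighbors by Euclidean distance, ties broken by (row, col) order.  For
# the default k = 7 this is the center, the 4-connected cross, and the two
# upper diagonal neighbors.  Returns a k x 2 matrix of (d_row, d_col).
stencil_offsets <- function(k) {
  r <- ceiling(sqrt(k)) + 1L
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[order(g$dr^2 + g$dc^2, g$dr, g$dc), ]
  as.matrix(g[seq_len(k), c("dr", "dc")])
}

#' Neighborhood mean filter over retained pixels
#'
#' Each retained pixel is replaced by the mean of a `k`-pixel stencil (the
#' pixel itself plus its `k - 1` nearest neighbors; see Details).  Stencil
#' members that fall outside the image or on suppressed pixels are simply
#' absent and the mean is renormalized over the members actually present,
#' so suppressed values never leak into the average.  Suppressed pixels
#' stay suppressed (`NA`).  `k = 1` is the identity on the retained set.
#'
#' @details The stencil is deterministic for any `k`: offsets are ordered
#' by squared Euclidean distance from the center, ties broken by row then
#' column.  `k = 7` -- the default used for display smoothing -- averages
#' the center, its four edge neighbors, and the two diagonal neighbors in
#' the row above.
#'
#' @inheritParams level_histogram
#' @param k integer >= 1, number of pixels in the stencil.
#' @return A numeric matrix; `NA` at suppressed pixels.
#' @export
neighborhood_average <- function(img, k = 7L, mask = NULL) {
  m <- as_pixel_matrix(img)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("`k` must be a single integer >= 1")
  if (k > length(m)) stop("`k` exceeds the number of pixels in the image")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(m), ncol(m))
  check_same_shape(m, mask)
  if (k == 1L) {
    out <- m + 0.0
    out[!mask] <- NA_real_
    return(out)
  }
  offs <- stencil_offsets(k)
  acc <- matrix(0, nrow(m), ncol(m))
  cnt <- matrix(0L, nrow(m), ncol(m))
  vm <- m * 1.0
  vm[!mask] <- 0
  pm <- mask * 1L
  for (i in seq_len(nrow(offs))) {
    acc <- acc + shift_matrix(vm, offs[i, 1L], offs[i, 2L], fill = 0)
    cnt <- cnt + shift_matrix(pm, offs[i, 1L], offs[i, 2L], fill = 0L)
  }
  out <- acc / pmax(cnt, 1L)
  out[!mask] <- NA_real_
  out
}

# Value of the pixel at (row + dr, col + dc), or `fill` outside the image.
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r0 <- max(1L, 1L - dr); r1 <- min(nr, nr - dr)  # destination rows
  c0 <- max(1L, 1L - dc); c1 <- min(nc, nc - dc)
  if (r0 <= r1 && c0 <= c1) {
    sr <- r0:r1; sc <- c0:c1
    out[sr, sc] <- m[sr + dr, sc + dc]
  }
  out
}
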