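#' Map a light wavelength to RGB
#'
#' Piecewise-linear approximation of the visible spectrum (380--780 nm):
#' hue varies over 380--645 nm through violet, blue, cyan, green, yellow,
#' orange to red, with a linear intensity falloff toward both spectrum
#' edges (below 420 nm and above 645 nm, where hue no longer changes) so
#' that every wavelength gets a distinct color.  Components lie in
#' `[0, 1]`; the table is a fixed pure function, so outputs are bit-stable.
#'
#' @param wavelength numeric vector of wavelengths in nanometers.
#' @return A matrix with one row per wavelength and columns `r`, `g`, `b`.
#' @export
wavelength_to_rgb <- function(wavelength) {
  w <- as.numeric(wavelength)
  r <- g <- b <- numeric(length(w))
  seg <- function(lo, hi) w >= lo & w < hi
  i <- seg(380, 440); r[i] <- (440 - w[i]) / 60; b[i] <- 1
  i <- seg(440, 490); g[i] <- (w[i] - 440) / 50; b[i] <- 1
  i <- seg(490, 510); g[i] <- 1; b[i] <- (510 - w[i]) / 20
  i <- seg(510, 580); r[i] <- (w[i] - 510) / 70; g[i] <- 1
  i <- seg(580, 645); r[i] <- 1; g[i] <- (645 - w[i]) / 65
  i <- w >= 645 & w <= 780; r[i] <- 1
  # intensity falloff at the spectrum edges; strictly monotone where the
  # hue is constant, so no two wavelengths share a color
  f <- rep(1, length(w))
  i <- w < 420; f[i] <- 0.3 + 0.7 * (w[i] - 380) / 40
  i <- w > 645; f[i] <- 0.3 + 0.7 * (780 - w[i]) / 135
  out <- cbind(r = r * f, g = g * f, b = b * f)
  out[w < 380 | w > 780, ] <- 0
  pmin(pmax(out, 0), 1)
}

#' Wavelength-based color assignment for a level range
#'
#' Maps the integer levels of a display range linearly onto light
#' wavelengths (`lo` -> 380 nm violet end, `hi` -> 780 nm red end) and
#' converts each wavelength to RGB with [wavelength_to_rgb()].  Adjacent
#' levels therefore get visibly different hues, and the assignment is
#' injective: no two levels share a color.  Alternative maps can be
#' substituted wherever a `cmap` is accepted; this wavelength map is
#' merely the default.
#'
#' @param range a [level_range()] with at least 2 levels.
#' @param lambda length-2 numeric, wavelength endpoints in nm.
#' @return An object of class `svmi_cmap`: a `data.frame` with columns
#'   `level`, `wavelength`, `r`, `g`, `b`.
#' @examples
#' cm <- wavelength_colormap(level_range(18, 42))
#' nrow(cm)  # 25 distinct colors
#' @export
wavelength_colormap <- function(range, lambda = c(380, 780)) {
  range <- as_level_range(range)
  if (range$n_levels < 2L)
    stop("cannot build a colormap for a single-level range")
  lev <- range$lo:range$hi
  wl <- lambda[1L] + (lev - range$lo) / (range$hi - range$lo) * (lambda[2L] - lambda[1L])
  rgb <- wavelength_to_rgb(wl)
  cm <- data.frame(level = lev, wavelength = wl,
                   r = rgb[, 1L], g = rgb[, 2L], b = rgb[, 3L])
  if (anyDuplicated(cm[, c("r", "g", "b")]))
    stop("internal error: colormap assignment is not injective")
  class(cm) <- c("svmi_cmap", "data.frame")
  cm
}

render_legend <- function(range, norm_max) {
  lev <- range$lo:range$hi
  rel <- lev / norm_max
  data.frame(level = lev, relative_gray = rel,
             label = sprintf("%d: %.5f", lev, rel))
}

suppressed_rgb <- function(suppressed) {
  switch(match.arg(suppressed, c("white", "black")),
         white = c(1, 1, 1), black = c(0, 0, 0))
}

new_render <- function(arr, legend, range, suppressed) {
  structure(arr, legend = legend, range = c(lo = range$lo, hi = range$hi),
            suppressed_color = suppressed, class = "svmi_render")
}

#' Exact-value gray render of a level range
#'
#' Displays level `v` as the gray intensity `(v - lo) / (hi - lo)`, black
#' at `lo` and white at `hi`, so the chosen run of integer levels spans
#' the whole gray scale.  Pixels outside the range or suppressed by the
#' mask render in the suppression color (white by default; black matches
#' the mask-visualization convention).  The source image is never
#' modified, and the legend maps every level to its exact gray, so the
#' render is invertible on the retained in-range pixels.
#'
#' @param img an [raster_image()] or integer matrix.
#' @param range a [level_range()] with `hi > lo`.
#' @param mask optional logical matrix (`TRUE` = retained).
#' @param suppressed `"white"` (default) or `"black"`.
#' @param norm_max normalization maximum for the legend's relative-gray
#'   labels; defaults to the image maximum.
#' @return An object of class `svmi_render`: an `rows x cols x 3` RGB
#'   array in `[0, 1]` with a `legend` attribute.
#' @export
render_gray <- function(img, range, mask = NULL, suppressed = "white",
                        norm_max = NULL) {
  m <- as_pixel_matrix(img)
  range <- as_level_range(range)
  if (range$hi == range$lo) stop("degenerate level range: hi == lo")
  sup <- suppressed_rgb(suppressed)
  if (is.null(norm_max)) norm_max <- max(m)
  g <- rescale_unit(m, range, mask)
  arr <- array(0, dim = c(nrow(m), ncol(m), 3L))
  for (ch in 1:3) {
    plane <- g
    plane[is.na(plane)] <- sup[ch]
    arr[, , ch] <- plane
  }
  new_render(arr, render_legend(range, norm_max), range, suppressed)
}

#' False-color render of a level range
#'
#' In-range retained pixels take the color their integer level is assigned
#' by `cmap` (the wavelength map by default); all other pixels take the
#' suppression color.  The legend lists every level with its color and its
#' relative gray value.
#'
#' @inheritParams render_gray
#' @param cmap a [wavelength_colormap()] (or compatible `svmi_cmap`)
#'   covering exactly the levels of `range`; `NULL` builds the wavelength
#'   map for `range`.
#' @return An `svmi_render` RGB array with a `legend` attribute.
#' @export
render_color <- function(img, range, mask = NULL, cmap = NULL,
                         suppressed = "white", norm_max = NULL) {
  m <- as_pixel_matrix(img)
  range <- as_level_range(range)
  if (is.null(cmap)) cmap <- wavelength_colormap(range)
  if (!identical(as.integer(cmap$level), range$lo:range$hi))
    stop("colormap does not cover the requested level range [",
         range$lo, ", ", range$hi, "]")
  sup <- suppressed_rgb(suppressed)
  if (is.null(norm_max)) norm_max <- max(m)
  keep <- range_mask(m, range)
  if (!is.null(mask)) {
    check_same_shape(m, mask)
    keep <- keep & mask
  }
  idx <- m - range$lo + 1L  # valid only where keep
  arr <- array(0, dim = c(nrow(m), ncol(m), 3L))
  for (ch in 1:3) {
    lut <- cmap[[c("r", "g", "b")[ch]]]
    plane <- matrix(sup[ch], nrow(m), ncol(m))
    plane[keep] <- lut[idx[keep]]
    arr[, , ch] <- plane
  }
  legend <- cbind(render_legend(range, norm_max),
                  cmap[, c("r", "g", "b")])
  new_render(arr, legend, range, suppressed)
}

#' Overlay a segment in a solid color
#'
#' Paints the pixels of `segment` (e.g. a thresholded averaged lesion
#' region) in the overlay color -- red by default -- on top of an existing
#' render; all other pixels keep their colors.
#'
#' @param render an `svmi_render`.
#' @param segment logical matrix; `TRUE` pixels are painted.
#' @param color RGB triple in `[0, 1]`.
#' @return A new `svmi_render`; the input is not modified.
#' @export
overlay_segment <- function(render, segment, color = c(1, 0, 0)) {
  stopifnot(inherits(render, "svmi_render"))
  if (!identical(dim(render)[1:2], dim(segment)))
    stop("shape mismatch between render and segment")
  out <- render
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[segment] <- color[ch]
    out[, , ch] <- plane
  }
  attributes(out) <- attributes(render)
  out
}

#' @export
print.svmi_render <- function(x, ...) {
  d <- dim(x)
  rg <- attr(x, "range")
  cat(sprintf("<svmi_render> %d x %d RGB, levels [%d, %d], suppressed = %s\n",
              d[1], d[2], rg["lo"], rg["hi"], attr(x, "suppressed_color")))
  invisible(x)
}

#' Write a render to an 8-bit RGB PNG with a legend sidecar
#'
#' @param render an `svmi_render`.
#' @param path output PNG path.
#' @param legend_path optional path for the legend text sidecar; defaults
#'   to `path` with extension `.legend.txt`.
#' @return `path`, invisibly.
#' @export
write_render <- function(render, path, legend_path = NULL) {
  stopifnot(inherits(render, "svmi_render"))
  arr <- array(as.numeric(render), dim = dim(render))
  png::writePNG(arr, path)
  if (is.null(legend_path)) legend_path <- paste0(sub("\\.png$", "", path), ".legend.txt")
  leg <- attr(render, "legend")
  utils::write.table(leg, legend_path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
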