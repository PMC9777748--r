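#' Synthetic head-CT phantom specification
#'
#' Describes a synthetic non-contrast head slice emulating the value
#' regime of a typical 512x512 MDCT slice: most pixels are zero
#' background, a high-value skull annulus (values well above 100, up to
#' 1682), and a central soft-tissue disc whose values span a short
#' contiguous run of integer levels (25 by default), optionally containing
#' a lesion whose levels are shifted by a signed offset.  The phantom is
#' fully seeded and emits ground-truth coordinate sets, so every pipeline
#' stage is testable without clinical data.
#'
#' Geometry: the head is a disc concentric with the image; the skull is an
#' annulus of width `skull_width` at its rim; the head radius is chosen so
#' that roughly 60% of pixels are zero background, matching the regime of
#' a real slice.  Optional eye-socket-like high-value blobs can be placed
#' in the upper third to motivate the upper-third fraction mask.
#'
#' @param size image side length in pixels (default 512).
#' @param skull_range integer interval of skull values; all values must
#'   exceed 100 so the default high-value mask removes the skull entirely.
#' @param tissue_range a [level_range()] of soft-tissue levels (default
#'   `[18, 42]`, 25 levels).
#' @param skull_width annulus width in pixels (default 12).
#' @param lesion `NULL`, or a list with `center = c(row, col)`, `radius`
#'   (pixels), and `level_shift` (signed integer added to the tissue
#'   levels inside the lesion).
#' @param eye_blobs place two high-value blobs in the upper third
#'   (default `FALSE`).
#' @param noise integer jitter amplitude added to tissue values and then
#'   clamped back into the tissue range, so level sets remain contiguous
#'   integer runs (default 0; the method is defined on integer levels).
#' @param seed integer seed; the same seed always gives the same phantom.
#' @return An object of class `svmi_phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(size = 512L, skull_range = c(300L, 1682L),
                         tissue_range = level_range(18, 42),
                         skull_width = 12L, lesion = NULL,
                         eye_blobs = FALSE, noise = 0L, seed = 1L) {
  tissue_range <- as_level_range(tissue_range)
  stopifnot(size >= 16L, skull_width >= 1L, noise >= 0L)
  if (min(skull_range) <= 100L)
    stop("skull values must all exceed 100 (the default high-value threshold)")
  if (tissue_range$hi >= min(skull_range))
    stop("tissue and skull value ranges must be disjoint")
  if (!is.null(lesion)) {
    stopifnot(is.list(lesion), length(lesion$center) == 2L,
              lesion$radius > 0)
    shifted <- c(tissue_range$lo, tissue_range$hi) + lesion$level_shift
    if (any(shifted < 0L) || any(shifted > 65535L))
      stop("lesion levels fall outside the 16-bit range")
  }
  structure(list(size = as.integer(size),
                 background_value = 0L,
                 skull_range = as.integer(skull_range),
                 tissue_range = tissue_range,
                 skull_width = as.integer(skull_width),
                 lesion = lesion, eye_blobs = isTRUE(eye_blobs),
                 noise = as.integer(noise), seed = as.integer(seed)),
            class = "svmi_phantom_spec")
}

# Sample n values uniformly from lo:hi, guaranteeing that every level of
# the run appears at least once when n >= number of levels.
sample_levels <- function(lo, hi, n) {
  lev <- lo:hi
  if (n >= length(lev))
    sample(c(lev, sample(lev, n - length(lev), replace = TRUE)))
  else
    sample(lev, n, replace = TRUE)
}

#' Generate a synthetic head-CT phantom
#'
#' Builds the pixel grid described by a [phantom_spec()] together with its
#' ground truth: four disjoint coordinate classes (background, skull,
#' tissue, lesion) that partition the grid.  All randomness comes from one
#' generator seeded with `spec$seed`; the caller's RNG state is left
#' untouched, and the same spec always yields an identical phantom.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `svmi_phantom`: list with `image` (an
#'   [raster_image()]) and `truth`, a list of four logical matrices
#'   `background`, `skull`, `tissue`, `lesion` (`TRUE` = pixel belongs to
#'   the class).
#' @examples
#' ph <- generate_phantom(phantom_spec(size = 64, seed = 7))
#' regime_report(ph$image)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "svmi_phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(list = ".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  n <- spec$size
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`))
  r_head <- 0.354 * n                 # ~60% of pixels end up as zero background
  r_tissue <- r_head - spec$skull_width

  skull <- d <= r_head & d > r_tissue
  tissue <- d <= r_tissue
  background <- !skull & !tissue
  lesion <- matrix(FALSE, n, n)
  if (!is.null(spec$lesion)) {
    lc <- spec$lesion$center
    dl <- sqrt(outer((seq_len(n) - lc[1L])^2, (seq_len(n) - lc[2L])^2, `+`))
    lesion <- dl <= spec$lesion$radius
    if (any(lesion & !tissue))
      stop("lesion extends outside the soft-tissue disc")
    tissue <- tissue & !lesion
  }
  if (spec$eye_blobs) {
    r_blob <- max(3, round(n / 32))
    for (bc in list(c(ctr - 0.62 * r_head, ctr - 0.35 * r_head),
                    c(ctr - 0.62 * r_head, ctr + 0.35 * r_head))) {
      db <- sqrt(outer((seq_len(n) - bc[1L])^2, (seq_len(n) - bc[2L])^2, `+`))
      blob <- db <= r_blob
      skull <- skull | blob
      tissue <- tissue & !blob
      background <- background & !blob
      lesion <- lesion & !blob
    }
  }

  m <- matrix(0L, n, n)
  tr <- spec$tissue_range
  if (any(tissue)) {
    v <- sample_levels(tr$lo, tr$hi, sum(tissue))
    if (spec$noise > 0L) {
      v <- v + sample(-spec$noise:spec$noise, length(v), replace = TRUE)
      v <- pmin(pmax(v, tr$lo), tr$hi)
    }
    m[tissue] <- v
  }
  if (any(lesion))
    m[lesion] <- sample_levels(tr$lo + spec$lesion$level_shift,
                               tr$hi + spec$lesion$level_shift, sum(lesion))
  if (any(skull))
    m[skull] <- sample(spec$skull_range[1L]:spec$skull_range[2L], sum(skull), replace = TRUE)

  structure(list(image = raster_image(m),
                 truth = list(background = background, skull = skull,
                              tissue = tissue, lesion = lesion),
                 spec = spec),
            class = "svmi_phantom")
}

#' @export
print.svmi_phantom <- function(x, ...) {
  cat(sprintf("<svmi_phantom> %d x %d; background %d, skull %d, tissue %d, lesion %d pixels\n",
              x$spec$size, x$spec$size, sum(x$truth$background),
              sum(x$truth$skull), sum(x$truth$tissue), sum(x$truth$lesion)))
  invisible(x)
}

#' Value-regime summary of an image
#'
#' The four quantities used to characterize a slice's value regime: how
#' many pixels are zero, how many exceed 100, the maximum value, and the
#' number of distinct integer values.
#'
#' @param img an [raster_image()] or integer matrix.
#' @return A list with `zero_count`, `high_count` (values > 100),
#'   `max_value`, `distinct_values`.
#' @export
regime_report <- function(img) {
  m <- as_pixel_matrix(img)
  list(zero_count = sum(m == 0L),
       high_count = sum(m > 100L),
       max_value = max(m),
       distinct_values = length(unique(as.vector(m))))
}
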