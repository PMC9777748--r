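#' Pipeline configuration
#'
#' All parameters of one visualization run.  The method is deliberately
#' interactive -- the reader chooses the level range, the mask, the color
#' map and the averaging width per invocation -- so the configuration
#' holds explicit values only; nothing is inferred from the image.
#'
#' @param range a [level_range()] or `c(lo, hi)`: the display window.
#' @param threshold high-value suppression threshold (default 100);
#'   `NULL` disables the high-value mask.
#' @param central keep only the central soft-tissue region
#'   (default `TRUE`).
#' @param cuts list of spatial cuts, each `list(side =, fraction =)` as in
#'   [fraction_mask()]; e.g. `list(list(side = "top", fraction = 1/3))`.
#' @param k averaging stencil size (default 1 = no smoothing).
#' @param cmap `"wavelength"` or `"gray"`.
#' @param suppressed `"white"` or `"black"` for suppressed pixels.
#' @param norm_max legend normalization maximum; `NULL` = image maximum.
#' @param decimals decimal places for reported statistics (default 2).
#' @return An object of class `svmi_config`.
#' @export
svmi_config <- function(range, threshold = 100L, central = TRUE,
                        cuts = list(), k = 1L,
                        cmap = c("wavelength", "gray"),
                        suppressed = c("white", "black"),
                        norm_max = NULL, decimals = 2L) {
  range <- as_level_range(range)
  cmap <- match.arg(cmap)
  suppressed <- match.arg(suppressed)
  stopifnot(k >= 1L, is.list(cuts))
  for (cut in cuts) stopifnot(is.list(cut), !is.null(cut$side), !is.null(cut$fraction))
  structure(list(range = range, threshold = threshold,
                 central = isTRUE(central), cuts = cuts, k = as.integer(k),
                 cmap = cmap, suppressed = suppressed, norm_max = norm_max,
                 decimals = as.integer(decimals)),
            class = "svmi_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full visualization pipeline
#'
#' Executes the stages in order: content masking (zero mask, high-value
#' mask, optional central region, optional spatial cuts), level-range
#' selection, rescaling, colorization, optional neighborhood averaging,
#' and statistics.  The source image is never modified, and each output
#' equals what the individual operations produce when composed by hand.
#'
#' Averaging (`k > 1`) smooths the raw integer values over the retained
#' in-range set, rounds the result to the nearest integer level, and
#' re-renders; the reported statistics and histogram always describe the
#' original pixel values, since processing must not change image content.
#'
#' @param img an [raster_image()] or integer matrix.
#' @param cfg an [svmi_config()].
#' @return An object of class `svmi_result`: list with `render` (an
#'   `svmi_render`), `stats` (an `svmi_stats` over the retained in-range
#'   pixels of the original image), `histogram` (a [level_histogram()]
#'   `data.frame` over the same pixels), `content_mask`, `display_mask`,
#'   `rescaled` (numeric `[0, 1]` grid with `NA` at suppressed pixels),
#'   and `config`.
#' @examples
#' ph <- generate_phantom(phantom_spec(size = 64, seed = 1))
#' res <- run_svmi(ph$image, svmi_config(range = c(18, 42)))
#' res$stats
#' @export
run_svmi <- function(img, cfg) {
  stopifnot(inherits(cfg, "svmi_config"))
  m <- as_pixel_matrix(img)

  content <- with_stage("masking", {
    masks <- list(zero_mask(m))
    if (!is.null(cfg$threshold)) masks <- c(masks, list(high_value_mask(m, cfg$threshold)))
    if (cfg$central) masks <- c(masks, list(central_region_mask(m)))
    for (cut in cfg$cuts)
      masks <- c(masks, list(fraction_mask(dim(m), cut$side, cut$fraction)))
    combine_masks(masks, "intersect")
  })

  display <- with_stage("range selection",
    combine_masks(list(content, range_mask(m, cfg$range)), "intersect"))

  rescaled <- with_stage("rescale", rescale_unit(m, cfg$range, content))

  render <- with_stage("colorize",
    if (cfg$cmap == "gray")
      render_gray(m, cfg$range, content, cfg$suppressed, cfg$norm_max)
    else
      render_color(m, cfg$range, content, wavelength_colormap(cfg$range),
                   cfg$suppressed, cfg$norm_max))

  if (cfg$k > 1L) {
    render <- with_stage("averaging", {
      avg <- neighborhood_average(m, cfg$k, display)
      lev <- matrix(0L, nrow(m), ncol(m))
      lev[display] <- as.integer(round_half_away(avg[display]))
      if (cfg$cmap == "gray")
        render_gray(lev, cfg$range, display, cfg$suppressed,
                    if (is.null(cfg$norm_max)) max(m) else cfg$norm_max)
      else
        render_color(lev, cfg$range, display, wavelength_colormap(cfg$range),
                     cfg$suppressed,
                     if (is.null(cfg$norm_max)) max(m) else cfg$norm_max)
    })
  }

  stats <- with_stage("statistics", masked_stats(m, display))
  hist <- with_stage("statistics", level_histogram(m, content, cfg$range))

  structure(list(render = render, stats = stats, histogram = hist,
                 content_mask = content, display_mask = display,
                 rescaled = rescaled, config = cfg),
            class = "svmi_result")
}

#' @export
print.svmi_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<svmi_result> levels [%d, %d], cmap %s, k = %d\n",
              cfg$range$lo, cfg$range$hi, cfg$cmap, cfg$k))
  cat(sprintf("  retained: %d pixels (%.1f%%)\n", x$stats$n,
              100 * x$stats$n / length(x$display_mask)))
  d <- cfg$decimals
  cat(sprintf("  mean = %.*f, deviation = %.*f, variance = %.*f\n",
              d, x$stats$mean, d, x$stats$deviation, d, x$stats$variance))
  invisible(x)
}

#' Percentage of a count, with an explicit rounding rule
#'
#' `100 * count / total` rounded to `decimals` places, either half-up
#' (0.05 -> 0.1) or truncated toward zero -- the arithmetic behind survey
#' response tables such as "19 of 20, 95.0%".
#'
#' @param count non-negative integer, `count <= total`.
#' @param total positive integer.
#' @param decimals decimal places (default 1).
#' @param rounding `"half_up"` (default) or `"truncate"`.
#' @return The rounded percentage.
#' @examples
#' survey_proportion(19, 20)                  # 95.0
#' survey_proportion(9, 11, 2, "truncate")    # 81.81
#' @export
survey_proportion <- function(count, total, decimals = 1L,
                              rounding = c("half_up", "truncate")) {
  rounding <- match.arg(rounding)
  if (total < 1) stop("`total` must be >= 1")
  if (count < 0 || count > total) stop("`count` must lie in [0, total]")
  x <- 100 * count / total
  s <- 10^decimals
  if (rounding == "half_up") floor(x * s + 0.5) / s else trunc(x * s) / s
}

#' Save and restore a pipeline configuration
#'
#' Flat plain-text `key = value` serialization, one parameter per line, so
#' two runs can be diffed at a glance.  `write_run_log()` writes the same
#' representation as a sidecar next to an output artifact, which is enough
#' to re-run the identical pipeline; no patient metadata is ever logged.
#'
#' @param cfg an [svmi_config()].
#' @param path output text file.
#' @return `write_config()` and `write_run_log()` return `path`
#'   invisibly; `read_config()` returns an `svmi_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "svmi_config"))
  cuts <- vapply(cfg$cuts, function(cut)
    paste0(cut$side, ":", format(cut$fraction, digits = 17)), "")
  lines <- c(
    paste("lo =", cfg$range$lo),
    paste("hi =", cfg$range$hi),
    paste("threshold =", if (is.null(cfg$threshold)) "none" else cfg$threshold),
    paste("central =", tolower(cfg$central)),
    paste("cuts =", if (length(cuts)) paste(cuts, collapse = ",") else "none"),
    paste("k =", cfg$k),
    paste("cmap =", cfg$cmap),
    paste("suppressed =", cfg$suppressed),
    paste("norm_max =", if (is.null(cfg$norm_max)) "image_max" else cfg$norm_max),
    paste("decimals =", cfg$decimals))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "[[:space:]]*=[[:space:]]*")
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  cuts <- list()
  if (vals[["cuts"]] != "none") {
    for (s in strsplit(vals[["cuts"]], ",")[[1L]]) {
      p <- strsplit(s, ":")[[1L]]
      cuts <- c(cuts, list(list(side = p[1L], fraction = as.numeric(p[2L]))))
    }
  }
  svmi_config(
    range = level_range(as.integer(vals[["lo"]]), as.integer(vals[["hi"]])),
    threshold = if (vals[["threshold"]] == "none") NULL else as.integer(vals[["threshold"]]),
    central = vals[["central"]] == "true",
    cuts = cuts,
    k = as.integer(vals[["k"]]),
    cmap = vals[["cmap"]],
    suppressed = vals[["suppressed"]],
    norm_max = if (vals[["norm_max"]] == "image_max") NULL else as.numeric(vals[["norm_max"]]),
    decimals = as.integer(vals[["decimals"]]))
}

#' @rdname write_config
#' @param artifact_path path of the output artifact the log describes;
#'   the log is written next to it as `<artifact>.log.txt`.
#' @export
write_run_log <- function(cfg, artifact_path) {
  write_config(cfg, paste0(artifact_path, ".log.txt"))
}
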