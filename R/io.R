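#' Read a raster image losslessly
#'
#' Reads a single-channel integer image and returns the stored pixel values
#' exactly as they appear in the file: no rescale, normalization or window
#' is applied.  Supported formats are single-frame uncompressed DICOM,
#' 16-bit (or 8-bit) grayscale PNG, and a plain-text integer matrix
#' (whitespace-separated values, one row per line, no header).
#'
#' For DICOM the raw stored values are returned by default; the 0..1682
#' value regime of a typical non-contrast head slice is raw stored
#' integers, not Hounsfield units.  Set `hu = TRUE` to apply the file's
#' RescaleSlope/RescaleIntercept, which returns a plain numeric matrix
#' (Hounsfield values can be negative, so the result leaves the integer
#' pipeline).
#'
#' @param path file to read.
#' @param format one of `"dicom"`, `"png16"`, `"text"`.  Defaults to a
#'   guess from the file extension.
#' @param hu DICOM only: apply RescaleSlope/RescaleIntercept and return a
#'   numeric matrix of Hounsfield units instead of an `svmi_image`.
#' @return An [raster_image()] (`svmi_image`), or a numeric matrix when
#'   `hu = TRUE`.
#' @seealso [write_image()], [strip_metadata()]
#' @examples
#' f <- tempfile(fileext = ".txt")
#' write_image(raster_image(matrix(c(0, 1, 2, 1682), 2, 2)), f, "text")
#' pixels(read_image(f, "text"))
#' @export
read_image <- function(path, format = guess_format(path), hu = FALSE) {
  format <- match.arg(format, c("dicom", "png16", "text"))
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  switch(format,
    text = raster_image(read_text_matrix(path), source_format = "text"),
    png16 = raster_image(read_png16(path), source_format = "png16"),
    dicom = {
      els <- dcm_parse(path)
      m <- dcm_pixels(els)
      if (hu) {
        slope <- as.numeric(if (is.null(els[["0028,1053"]])) "1" else dcm_string(els[["0028,1053"]]))
        intercept <- as.numeric(if (is.null(els[["0028,1052"]])) "0" else dcm_string(els[["0028,1052"]]))
        return(m * slope + intercept)
      }
      raster_image(m, source_format = "dicom")
    })
}

#' Write a raster image losslessly
#'
#' Writes the pixel grid so that [read_image()] reproduces it exactly.
#' PNG output is 16-bit grayscale; DICOM output is Explicit VR Little
#' Endian, single-frame monochrome, and never contains patient metadata.
#' Output bytes are a pure function of the pixel grid (no timestamps), so
#' writing the same image twice gives byte-identical files.
#'
#' @param img an [raster_image()] or integer matrix.
#' @param path output file.
#' @param format one of `"dicom"`, `"png16"`, `"text"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, format = guess_format(path)) {
  format <- match.arg(format, c("dicom", "png16", "text"))
  m <- as_pixel_matrix(img)
  switch(format,
    text = write_text_matrix(m, path),
    png16 = write_png16(m, path),
    dicom = dcm_write(m, path))
  invisible(path)
}

#' Strip patient metadata from a DICOM file
#'
#' Parses a DICOM dataset and keeps only the pixel grid and its
#' dimensions; the returned object carries no name, ID, date, institution
#' or any other header field, so nothing the package subsequently writes
#' can leak patient identity.
#'
#' @param path DICOM file with pixel data.
#' @return An [raster_image()] containing only pixels and dimensions.
#' @export
strip_metadata <- function(path) {
  els <- dcm_parse(path)
  raster_image(dcm_pixels(els), source_format = "dicom")
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    dcm = "dicom", dicom = "dicom",
    png = "png16",
    txt = "text", text = "text", tsv = "text",
    stop("cannot guess image format from extension '", ext, "'; pass `format`"))
}

read_text_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty text matrix file: ", path)
  rows <- lapply(strsplit(trimws(lines), "[[:space:]]+"), function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) stop("non-numeric entry in text matrix file: ", path)
    v
  })
  n <- lengths(rows)
  if (length(unique(n)) != 1L) stop("ragged rows in text matrix file: ", path)
  do.call(rbind, rows)
}

write_text_matrix <- function(m, path) {
  writeLines(apply(m, 1L, paste, collapse = " "), path)
}
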