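# Minimal single-frame DICOM codec.
#
# Scope: uncompressed single-frame monochrome images, Explicit or Implicit
# VR Little Endian transfer syntax, 8- or 16-bit samples.  Multi-frame
# series, sequences with undefined length, and compressed transfer
# syntaxes are out of scope and rejected with an informative error.  The
# reader returns raw stored values -- no rescale is applied -- because the
# windowing pipeline is defined on stored integers.

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

uint16_le <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256))
uint32_le <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256, x %/% 65536 %% 256, x %/% 16777216 %% 256))

dcm_pad_even <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

# One explicit-VR-LE data element.
dcm_element <- function(group, elem, vr, value) {
  tag <- c(uint16_le(group), uint16_le(elem))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(tag, charToRaw(vr), as.raw(c(0, 0)), uint32_le(length(value)), value)
  else
    c(tag, charToRaw(vr), uint16_le(length(value)), value)
}

dcm_str <- function(s, uid = FALSE) {
  dcm_pad_even(charToRaw(s), pad = if (uid) as.raw(0) else as.raw(0x20))
}

# Write a single-frame monochrome DICOM file (Explicit VR Little Endian).
# Patient identity fields are only written when explicitly supplied; the
# package's own outputs never carry them.
dcm_write <- function(m, path, patient_name = NULL, patient_id = NULL,
                      rescale_intercept = NULL, rescale_slope = NULL,
                      bits = 16L) {
  stopifnot(is.matrix(m), bits %in% c(8L, 16L))
  if (any(m < 0) || any(m >= 2^bits)) stop("pixel values out of range for ", bits, "-bit DICOM")
  nr <- nrow(m); nc <- ncol(m)
  vals <- as.vector(t(m))  # row-major
  px <- if (bits == 16L) {
    b <- matrix(0L, 2L, length(vals))
    b[1L, ] <- vals %% 256L
    b[2L, ] <- vals %/% 256L
    as.raw(as.vector(b))
  } else as.raw(vals)

  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", dcm_str("1.2.840.10008.5.1.4.1.1.2", uid = TRUE)),
    dcm_element(0x0002, 0x0003, "UI", dcm_str("1.2.826.0.1.3680043.8.498.1", uid = TRUE)),
    dcm_element(0x0002, 0x0010, "UI", dcm_str(TS_EXPLICIT_LE, uid = TRUE))
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", uint32_le(length(meta_body))), meta_body)

  body <- c(
    dcm_element(0x0008, 0x0016, "UI", dcm_str("1.2.840.10008.5.1.4.1.1.2", uid = TRUE)),
    dcm_element(0x0008, 0x0018, "UI", dcm_str("1.2.826.0.1.3680043.8.498.1", uid = TRUE)),
    dcm_element(0x0008, 0x0060, "CS", dcm_str("CT"))
  )
  if (!is.null(patient_name)) body <- c(body, dcm_element(0x0010, 0x0010, "PN", dcm_str(patient_name)))
  if (!is.null(patient_id))   body <- c(body, dcm_element(0x0010, 0x0020, "LO", dcm_str(patient_id)))
  body <- c(body,
    dcm_element(0x0028, 0x0002, "US", uint16_le(1L)),
    dcm_element(0x0028, 0x0004, "CS", dcm_str("MONOCHROME2")),
    dcm_element(0x0028, 0x0010, "US", uint16_le(nr)),
    dcm_element(0x0028, 0x0011, "US", uint16_le(nc)),
    dcm_element(0x0028, 0x0100, "US", uint16_le(bits)),
    dcm_element(0x0028, 0x0101, "US", uint16_le(bits)),
    dcm_element(0x0028, 0x0102, "US", uint16_le(bits - 1L)),
    dcm_element(0x0028, 0x0103, "US", uint16_le(0L)))
  if (!is.null(rescale_intercept))
    body <- c(body, dcm_element(0x0028, 0x1052, "DS", dcm_str(format(rescale_intercept))))
  if (!is.null(rescale_slope))
    body <- c(body, dcm_element(0x0028, 0x1053, "DS", dcm_str(format(rescale_slope))))
  body <- c(body, dcm_element(0x7fe0, 0x0010, "OW", px))

  writeBin(c(raw(128), charToRaw("DICM"), meta, body), path)
  invisible(path)
}

DCM_KNOWN_VRS <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD", "IS",
                   "LO", "LT", "OB", "OD", "OF", "OW", "PN", "SH", "SL", "SQ",
                   "SS", "ST", "TM", "UI", "UL", "UN", "US", "UT")

dcm_rd16 <- function(b, i) as.integer(b[i]) + 256L * as.integer(b[i + 1L])
dcm_rd32 <- function(b, i) {
  as.numeric(b[i]) + 256 * as.numeric(b[i + 1L]) +
    65536 * as.numeric(b[i + 2L]) + 16777216 * as.numeric(b[i + 3L])
}

# Parse a DICOM file into a flat list of elements: names "gggg,eeee" in
# lower-case hex, values raw vectors.  Stops on constructs outside the
# supported profile.
dcm_parse <- function(path) {
  b <- readBin(path, "raw", n = file.size(path))
  if (length(b) < 132L || rawToChar(b[129:132]) != "DICM")
    stop("unreadable DICOM file (missing DICM marker): ", path)
  pos <- 133L
  els <- list()
  explicit <- TRUE  # file meta group is always explicit VR LE
  ts <- TS_EXPLICIT_LE
  in_meta <- TRUE
  while (pos + 7L <= length(b) + 1L && pos <= length(b)) {
    group <- dcm_rd16(b, pos); elem <- dcm_rd16(b, pos + 2L)
    if (in_meta && group != 0x0002) {
      in_meta <- FALSE
      explicit <- identical(ts, TS_EXPLICIT_LE)
    }
    pos <- pos + 4L
    if (explicit || group == 0x0002) {
      vr <- rawToChar(b[pos:(pos + 1L)])
      if (!vr %in% DCM_KNOWN_VRS) stop("unsupported DICOM element (unknown VR '", vr, "')")
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        len <- dcm_rd32(b, pos + 4L); pos <- pos + 8L
      } else {
        len <- dcm_rd16(b, pos + 2L); pos <- pos + 4L
      }
    } else {
      len <- dcm_rd32(b, pos); pos <- pos + 4L
    }
    if (len == 4294967295) stop("unsupported DICOM: undefined-length element (sequence or encapsulated pixel data)")
    if (pos + len - 1L > length(b)) stop("corrupt DICOM: element extends past end of file")
    key <- sprintf("%04x,%04x", group, elem)
    els[[key]] <- if (len > 0) b[pos:(pos + len - 1L)] else raw(0)
    if (key == "0002,0010") ts <- dcm_string(els[[key]])
    pos <- pos + as.integer(len)
  }
  if (!ts %in% c(TS_EXPLICIT_LE, TS_IMPLICIT_LE))
    stop("unsupported DICOM transfer syntax: ", ts)
  attr(els, "transfer_syntax") <- ts
  els
}

# Decode a DICOM string value: drop padding nul bytes, trim spaces.
dcm_string <- function(r) {
  trimws(rawToChar(r[r != as.raw(0)]))
}

dcm_us <- function(els, key, default = NULL) {
  if (is.null(els[[key]])) return(default)
  dcm_rd16(els[[key]], 1L)
}

# Decode the pixel grid of a parsed DICOM element list into an integer
# matrix of raw stored values.  Signed data with negative stored values is
# rejected: the windowing pipeline is defined on values >= 0.
dcm_pixels <- function(els) {
  if (is.null(els[["7fe0,0010"]])) stop("DICOM file has no pixel data element")
  spp <- dcm_us(els, "0028,0002", 1L)
  if (spp != 1L) stop("unsupported DICOM pixel data: SamplesPerPixel = ", spp,
                      " (only single-channel monochrome is supported)")
  bits <- dcm_us(els, "0028,0100", 16L)
  if (!bits %in% c(8L, 16L)) stop("unsupported DICOM pixel data: BitsAllocated = ", bits)
  nr <- dcm_us(els, "0028,0010"); nc <- dcm_us(els, "0028,0011")
  if (is.null(nr) || is.null(nc)) stop("corrupt DICOM: missing Rows/Columns")
  px <- els[["7fe0,0010"]]
  n <- nr * nc
  signed <- identical(dcm_us(els, "0028,0103", 0L), 1L)
  if (bits == 16L) {
    if (length(px) < 2L * n) stop("corrupt DICOM: pixel data shorter than Rows x Columns")
    v <- readBin(px, "integer", n = n, size = 2L, signed = FALSE, endian = "little")
    if (signed) v <- ifelse(v >= 32768L, v - 65536L, v)
  } else {
    v <- as.integer(px[seq_len(n)])
    if (signed) v <- ifelse(v >= 128L, v - 256L, v)
  }
  if (any(v < 0L))
    stop("unsupported DICOM pixel data: negative stored values (signed data is rejected, not clamped)")
  matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
}
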