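# Minimal 16-bit grayscale PNG encoder.
#
# The established R readers (`png::readPNG`) decode 16-bit grayscale PNG
# losslessly, but no writer at hand emits bit depth 16, so encoding is done
# here directly: one IHDR / IDAT / IEND chunk each, filter type 0 on every
# scanline, pixels stored big-endian.  `memCompress(type = "gzip")` in R
# produces an RFC-1950 zlib stream, which is exactly the IDAT payload
# format.  Output is a pure function of the pixel grid (no timestamps, no
# ancillary chunks), so identical images give byte-identical files.

png_crc_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    cc <- i
    for (k in 1:8) {
      cc <- if (bitwAnd(cc, 1L) != 0L)
        bitwXor(bitwShiftR(cc, 1L), -306674912L)  # 0xEDB88320
      else
        bitwShiftR(cc, 1L)
    }
    tab[i + 1L] <- cc
  }
  tab
})

# CRC-32 of a raw vector, returned as 4 big-endian raw bytes.
png_crc32 <- function(r) {
  v <- as.integer(r)
  cc <- -1L
  tab <- png_crc_table
  for (b in v) cc <- bitwXor(bitwShiftR(cc, 8L), tab[bitwAnd(bitwXor(cc, b), 255L) + 1L])
  cc <- bitwXor(cc, -1L)
  as.raw(c(bitwAnd(bitwShiftR(cc, 24L), 255L), bitwAnd(bitwShiftR(cc, 16L), 255L),
           bitwAnd(bitwShiftR(cc, 8L), 255L), bitwAnd(cc, 255L)))
}

uint32_be <- function(x) {
  as.raw(c(x %/% 16777216 %% 256, x %/% 65536 %% 256, x %/% 256 %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(uint32_be(length(data)), body, png_crc32(body))
}

write_png16 <- function(m, path) {
  stopifnot(is.matrix(m))
  if (any(m < 0) || any(m > 65535)) stop("png16 pixel values must lie in [0, 65535]")
  nr <- nrow(m); nc <- ncol(m)
  # scanlines: filter byte 0, then 16-bit big-endian samples, row-major
  sl <- matrix(0L, nrow = 1L + 2L * nc, ncol = nr)
  sl[seq(2L, by = 2L, length.out = nc), ] <- t(m %/% 256L)
  sl[seq(3L, by = 2L, length.out = nc), ] <- t(m %% 256L)
  idat <- memCompress(as.raw(as.vector(sl)), type = "gzip")  # zlib stream
  ihdr <- c(uint32_be(nc), uint32_be(nr),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, grayscale, deflate, filter 0, no interlace
  bytes <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
             png_chunk("IHDR", ihdr),
             png_chunk("IDAT", idat),
             png_chunk("IEND", raw(0)))
  writeBin(bytes, path)
  invisible(path)
}

# Lossless read of a single-channel PNG (8- or 16-bit) back to stored
# integers.  `png::readPNG` normalizes to [0, 1] by (2^depth - 1); the bit
# depth is recovered from the IHDR so the original integers are exact.
read_png16 <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L && dim(x)[3] > 1L)
    stop("unsupported PNG: multi-channel image (expected single-channel grayscale)")
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  depth <- png_bit_depth(path)
  m <- round(x * (2^depth - 1))
  storage.mode(m) <- "integer"
  m
}

png_bit_depth <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 25L)
  if (length(hdr) < 25L || !identical(hdr[1:8], as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))))
    stop("not a PNG file: ", path)
  as.integer(hdr[25L])
}
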