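test_that("text matrix round-trip preserves exact values", {
  m <- matrix(c(0L, 1L, 2L, 1682L), 2, 2)
  f <- withr::local_tempfile(fileext = ".txt")
  write_image(raster_image(m), f, "text")
  img <- read_image(f, "text")
  expect_identical(pixels(img), m)
  expect_identical(img$source_format, "text")
})

test_that("16-bit PNG round-trip is lossless, including extreme values", {
  set.seed(11)
  cases <- list(
    matrix(0L, 4, 4),
    matrix(c(0L, 1L, 2L, 1682L), 2, 2),
    matrix(65535L, 3, 2),
    matrix(sample(0:65535, 40 * 30, replace = TRUE), 40, 30)
  )
  for (m in cases) {
    f <- withr::local_tempfile(fileext = ".png")
    write_image(raster_image(m), f, "png16")
    r <- read_image(f, "png16")
    expect_identical(pixels(r), m)
    expect_identical(max(pixels(r)), max(m))
    expect_identical(min(pixels(r)), min(m))
  }
})

test_that("PNG output is byte-stable for fixed input", {
  set.seed(3)
  img <- raster_image(matrix(sample(0:1682, 30 * 30, TRUE), 30, 30))
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  write_image(img, f1, "png16")
  write_image(img, f2, "png16")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("a 512x512 phantom survives a 16-bit PNG round trip", {
  ph <- generate_phantom(phantom_spec(size = 512, seed = 21))
  f <- withr::local_tempfile(fileext = ".png")
  write_image(ph$image, f, "png16")
  back <- read_image(f, "png16")
  expect_identical(length(pixels(back)), 262144L)
  expect_identical(pixels(back), pixels(ph$image))
  expect_identical(max(pixels(back)), max(pixels(ph$image)))
})

test_that("Pillow reads our 16-bit PNG to the same integers", {
  set.seed(5)
  m <- matrix(sample(0:1682, 24 * 18, TRUE), 24, 18)
  f <- withr::local_tempfile(fileext = ".png")
  out <- withr::local_tempfile(fileext = ".txt")
  write_image(raster_image(m), f, "png16")
  status <- system2("python", c("-c", shQuote(sprintf(
    "import numpy as np; from PIL import Image; np.savetxt(%s, np.array(Image.open(%s)), fmt='%%d')",
    deparse(out), deparse(f)))))
  expect_identical(status, 0L)
  oracle <- unname(as.matrix(utils::read.table(out)))
  storage.mode(oracle) <- "integer"
  expect_identical(oracle, m)
})

test_that("DICOM round-trip is lossless and our reader matches pydicom", {
  set.seed(8)
  m <- matrix(sample(0:1682, 16 * 12, TRUE), 16, 12)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_image(raster_image(m), f, "dicom")
  expect_identical(pixels(read_image(f, "dicom")), m)

  out <- withr::local_tempfile(fileext = ".txt")
  status <- system2("python", c("-c", shQuote(sprintf(
    "import numpy as np, pydicom; np.savetxt(%s, pydicom.dcmread(%s).pixel_array, fmt='%%d')",
    deparse(out), deparse(f)))))
  expect_identical(status, 0L)
  oracle <- unname(as.matrix(utils::read.table(out)))
  storage.mode(oracle) <- "integer"
  expect_identical(oracle, m)
})

test_that("our reader decodes a pydicom-written file exactly", {
  f <- withr::local_tempfile(fileext = ".dcm")
  ref <- withr::local_tempfile(fileext = ".txt")
  script <- sprintf(paste(
    "import numpy as np, pydicom, pydicom.uid",
    "from pydicom.dataset import Dataset, FileDataset, FileMetaDataset",
    "arr = (np.arange(42).reshape(6, 7) * 97 %% 1683).astype(np.uint16)",
    "meta = FileMetaDataset()",
    "meta.MediaStorageSOPClassUID = pydicom.uid.CTImageStorage",
    "meta.MediaStorageSOPInstanceUID = pydicom.uid.generate_uid()",
    "meta.TransferSyntaxUID = pydicom.uid.ExplicitVRLittleEndian",
    "ds = FileDataset(%s, {}, file_meta=meta, preamble=b'\\x00'*128)",
    "ds.PatientName = 'SENTINEL^PATIENT'",
    "ds.PatientID = 'ID0001'",
    "ds.Rows, ds.Columns = 6, 7",
    "ds.SamplesPerPixel = 1",
    "ds.PhotometricInterpretation = 'MONOCHROME2'",
    "ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15",
    "ds.PixelRepresentation = 0",
    "ds.PixelData = arr.tobytes()",
    "ds.save_as(%s)",
    "np.savetxt(%s, arr, fmt='%%d')",
    sep = "\n"), deparse(f), deparse(f), deparse(ref))
  status <- system2("python", c("-c", shQuote(script)))
  expect_identical(status, 0L)

  oracle <- unname(as.matrix(utils::read.table(ref)))
  storage.mode(oracle) <- "integer"
  img <- read_image(f, "dicom")
  expect_identical(pixels(img), oracle)

  # metadata stripping: no header field survives in any written artifact
  stripped <- strip_metadata(f)
  expect_identical(pixels(stripped), oracle)
  expect_false(any(grepl("SENTINEL", unlist(lapply(stripped, as.character)))))
  has_sentinel <- function(path) {
    bytes <- readBin(path, "raw", file.size(path))
    grepl("SENTINEL", rawToChar(bytes[bytes != as.raw(0)]),
          fixed = TRUE, useBytes = TRUE)
  }
  png_out <- withr::local_tempfile(fileext = ".png")
  write_image(stripped, png_out, "png16")
  expect_false(has_sentinel(png_out))
  dcm_out <- withr::local_tempfile(fileext = ".dcm")
  write_image(stripped, dcm_out, "dicom")
  expect_false(has_sentinel(dcm_out))
})

test_that("HU conversion applies slope and intercept on request only", {
  m <- matrix(c(0L, 1000L, 2000L, 30L), 2, 2)
  f <- withr::local_tempfile(fileext = ".dcm")
  svmi:::dcm_write(m, f, rescale_intercept = -1024, rescale_slope = 1)
  expect_identical(pixels(read_image(f, "dicom")), m)    # raw by default
  hu <- read_image(f, "dicom", hu = TRUE)
  expect_equal(unname(hu), m - 1024)
})

test_that("malformed inputs fail with informative errors", {
  expect_error(read_image(tempfile(), "text"), "no such file")
  expect_error(write_image(raster_image(matrix(65535L, 1, 1)), tempfile(), "png16"), NA)
  expect_error(raster_image(matrix(65536L, 1, 1)), "65535")
  expect_error(raster_image(matrix(-1L, 1, 1)), "signed")
  expect_error(raster_image(matrix(0.5, 1, 1)), "integer")
  # multi-channel PNG is rejected, naming the offending property
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(12), dim = c(2, 2, 3)), f)
  expect_error(read_image(f, "png16"), "multi-channel")
  # DICOM without pixel data
  g <- withr::local_tempfile(fileext = ".dcm")
  writeBin(c(raw(128), charToRaw("DICM"),
             svmi:::dcm_element(0x0002, 0x0010, "UI",
                                svmi:::dcm_str(svmi:::TS_EXPLICIT_LE, uid = TRUE))), g)
  expect_error(read_image(g, "dicom"), "no pixel data")
  # not a DICOM file at all
  h <- withr::local_tempfile(fileext = ".dcm")
  writeLines("plain text", h)
  expect_error(read_image(h, "dicom"), "DICM")
})
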