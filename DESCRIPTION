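Package: svmi
Title: Smart Visualization of Non-Contrast Brain CT Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Windowing, masking and false-color display of 16-bit
    non-contrast brain multi-detector CT (MDCT) slices.  Non-informative
    pixels (background zeros, bone and other high-value structures,
    everything outside the soft-tissue region) are suppressed with pixel
    masks; a contiguous run of integer gray levels chosen by the reader is
    rescaled to the full display range, colorized with a
    wavelength-of-light color map so that adjacent levels are visually
    distinct, optionally smoothed by neighborhood averaging, and
    summarized by statistics computed only over the retained pixels.
    Includes lossless raster I/O (plain-text matrix, 16-bit grayscale PNG,
    single-frame DICOM with patient-metadata stripping), a seedable
    synthetic head-phantom generator with ground truth so the whole
    pipeline is testable without clinical data, and a small command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
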