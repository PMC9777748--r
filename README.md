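# svmi — smart visualization of non-contrast brain CT slices

Reading a non-contrast (native) brain MDCT slice is hard because almost none
of the stored dynamic range carries diagnostic information: on a typical
512×512 slice most pixels are zero background, bone reaches values above
1000, and the soft tissue where hypo- or hyperdense lesions hide spans only
about 25 successive integer values. Displayed linearly against the slice
maximum `M`, two adjacent tissue levels differ by a gray contrast of only
`1/M` (≈ 0.0006 for `M = 1682`) — far below what any reader can separate.

`svmi` implements the windowing-with-masking pipeline that makes those
levels visible, for radiologists-in-training, medical-imaging teachers and
image-analysis researchers:

1. **Content masking** — suppress non-informative pixels: the zero
   background, everything strictly above a bone threshold (default 100),
   everything outside the central soft-tissue region (the largest ellipse
   inscribed in the bounding box of the nonzero pixels), and optional
   spatial cuts of 1/3 or 2/3 of the rows/columns from any side.
2. **Level-range selection** — an inclusive run `[lo, hi]` of integer gray
   levels chosen by the reader (e.g. `{18, 42}`, 25 levels).
3. **Rescaling** — the affine map `v ↦ (v − lo)/(hi − lo)` stretches the
   chosen run over the full 0–1 display range; adjacent integers then
   differ by exactly `1/(hi − lo)` instead of `1/M`.
4. **Colorization** — each integer level gets a distinct color from a
   wavelength-of-light map (380–780 nm, violet → red), so neighbouring
   levels are told apart by hue, not just by gray.
5. **Averaging** — optional smoothing where each retained pixel takes the
   mean of its k-pixel neighborhood (default k = 7), renormalized over the
   members actually retained.
6. **Statistics** — mean, standard deviation and (population) variance
   computed **only** over retained in-range pixels; suppressed pixels are
   excluded, not counted as zeros.

Everything is supported by lossless raster I/O (plain-text matrix, 16-bit
grayscale PNG, single-frame DICOM with patient-metadata stripping) and a
seedable synthetic head-phantom generator with ground truth, so the whole
pipeline can be exercised and validated without any clinical data.

## Worked example

```r
library(svmi)

# A 512x512 synthetic head slice: zero background, high-value skull
# annulus, a 25-level soft-tissue disc, and a lesion shifted +25 levels.
ph <- generate_phantom(phantom_spec(size = 512, seed = 7,
        lesion = list(center = c(310, 310), radius = 25, level_shift = 25L)))
regime_report(ph$image)
#> $zero_count        158968     (60.6% of 262,144 pixels)
#> $high_count        13208      (pixels above 100: the skull annulus)
#> $max_value         1682
#> $distinct_values   1434

res <- run_svmi(ph$image, svmi_config(range = c(18, 42), k = 7))
res
#> <svmi_result> levels [18, 42], cmap wavelength, k = 7
#>   retained: 88007 pixels (33.6%)
#>   mean = 30.02, deviation = 7.22, variance = 52.11

coverage_fraction(res$content_mask)
#> [1] 34.3
write_render(res$render, "slice.png")   # 8-bit RGB + legend sidecar
```

The retained 88,007 pixels are exactly the soft-tissue disc that survives
the zero/high-value/central masks and falls in the 25-level window; their
mean (30.02) is a statistic of the tissue alone — bone and background can
no longer drag it. The lesion, sitting at levels 43–67, is then isolated by
re-running with `range = c(43, 67)`.

A thin command-line driver wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "svmi.R", package = "svmi"))') \
    phantom --size 512 --seed 7 --lesion 310,310,25,25 --out phantom.png
```

with subcommands `phantom`, `mask`, `window`, `stats`, `render`, `run`.

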