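---
title: "Masked integer-level windowing of brain CT: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked integer-level windowing of brain CT: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svmi)
```

## The problem and the model

A non-contrast brain MDCT slice stores integers on a 16-bit scale, but the
information a reader needs sits in a tiny sub-range. On a representative
512×512 slice roughly 60% of pixels are zero background, bone and other
dense structures run into the hundreds and above (up to 1682 in the regime
this package emulates), and the soft tissue of interest occupies about 25
successive integer values. Two facts follow:

* Displayed linearly against the slice maximum `M`, adjacent tissue levels
  differ by `relative_gray_step(M) = 1/M` — about 0.0006 for `M = 1682` —
  so tissue structure is invisible.
* Any statistic computed over the whole grid is dominated by background
  zeros and bone, not by tissue.

The pipeline therefore couples *windowing* with *masking*. A window is an
inclusive run of integer levels `[lo, hi]` (a range written `{18, 42}`
contains `hi − lo + 1 = 25` levels; we adopt the inclusive count
throughout). Masks are boolean grids with `TRUE` = retained; suppression
means exclusion, so a suppressed pixel contributes to no display, no
histogram and no statistic — it is not treated as a zero. The displayed
value of a retained in-range pixel is the affine rescale
`(v − lo)/(hi − lo)`, which maps `lo → 0`, `hi → 1` with step
`1/(hi − lo)`, and is strictly monotone, so the display never reorders
levels. Out-of-range pixels are carried as a suppression flag (`NA`),
never clamped, because 0 is already the image of `lo`.

The method is deliberately interactive: the reader chooses the window, the
mask, the color map and the averaging width. Nothing in this package
suggests a range or a diagnosis, and none of its outputs constitute an
automatic analysis.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `threshold` | values strictly above are suppressed | 100 | separates soft tissue (tens) from bone (hundreds+) in the emulated regime; strict `> t` keeps the boundary value |
| `range = [lo, hi]` | displayed integer levels | none (reader's choice) | the window *is* the reader's question |
| `k` | averaging stencil size | 1 (off); 7 for smoothing | 7 = center + 4-cross + two upper diagonals; see below |
| `cmap` | level colors | wavelength map | adjacent levels get distinct hues |
| `suppressed` | display of suppressed pixels | white | white for displays; black is the mask-visualization convention |
| `norm_max` | legend normalization | image maximum | relative-gray labels `level/norm_max` at 5 decimals |

## Geometry and numerical choices

**Central region.** The soft-tissue region is taken as the largest
axis-aligned ellipse inscribed in the tight bounding box of the nonzero
pixels, optionally shrunk by a margin (default 0). This is deterministic
and parameter-light, and it matches a head's convex outline; a pixel whose
ellipse equation equals 1 exactly is retained, so rasterization is
reproducible. On a fully nonzero square image this reduces to the
inscribed disc (≈ π/4 coverage). Real coverage figures from hand-drawn or
scanner-specific masks will differ; the ellipse rule is a computed
stand-in, not a reproduction of any particular clinical mask.

**Fraction cuts.** A cut removes `round(fraction × extent)` rows or
columns from one side, with half-away-from-zero rounding (1/3 of 512 rows
= 171), restricted to the two fractions used in practice, 1/3 and 2/3.

**Averaging stencil.** "k adjacent pixels" is made precise as the center
plus its `k − 1` nearest neighbors by Euclidean distance, ties broken by
(row, col) order — deterministic for every `k`. Members outside the image
or suppressed are dropped and the mean renormalized over those present, so
suppressed values never leak into the average, and averaging never widens
the local value range. `k = 1` is the identity.

**Statistics.** Population variance (divide by `n`): the retained pixel
set is a fixed population being described, not a sample from which we
estimate. Reported statistics print at two decimals by default; stored
values keep full precision.

**Wavelength color map.** Levels map linearly onto 380–780 nm
(`lo` → violet end, `hi` → red end) and each wavelength converts to RGB by
a fixed piecewise-linear approximation of the visible spectrum with a
linear intensity falloff below 420 nm and above 645 nm. The falloff starts
at 645 nm — where the hue stops changing — so that intensity varies
strictly wherever hue does not, making the level → color assignment
injective (verified in tests up to 65,536 levels). The endpoints are
configurable; the table is a pure function, so renders are bit-stable.

**Pipeline order.** `run_svmi()` executes masking → range selection →
rescale → colorize → optional averaging → statistics. Averaging smooths
the raw integer values over the retained in-range set, rounds to the
nearest integer level and re-renders; the reported statistics and
histogram always describe the *original* values, because processing must
never change image content. Each stage's errors carry the stage name.

## Lossless I/O

All three formats round-trip exactly: `read(write(x)) == x` element-wise.
16-bit PNG encoding is implemented in the package (single IDAT, filter 0)
because the available writers quantize PNG to 8 bits; decoding goes
through `png::readPNG` with the bit depth read from the IHDR. DICOM
support is a minimal single-frame uncompressed codec (Explicit/Implicit VR
Little Endian, monochrome, 8/16-bit); sequences, multi-frame series and
compressed transfer syntaxes are rejected with informative errors.
`strip_metadata()` keeps only pixels and dimensions, and the test suite
verifies byte-level absence of a planted patient-name sentinel in every
artifact the package writes. Signed stored values are rejected rather than
clamped — the pipeline is defined on values ≥ 0, and "16-bit" is taken as
unsigned since every value in the emulated regime is non-negative. DICOM
reading returns raw stored values by default; Hounsfield conversion via
RescaleSlope/Intercept is opt-in and returns a plain numeric matrix.

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds a 512×512 (configurable) slice: zero
background, a skull annulus (width 12 px by default) of values in
[300, 1682], a concentric soft-tissue disc sampling 25 integer levels
([18, 42] by default, every level guaranteed present), an optional lesion
disc whose levels are shifted by a signed offset, and optional high-value
"eye-socket" blobs in the upper third to motivate the upper-third cut. The
head radius is 0.354 × size, chosen so about 60% of pixels are zero, the
background share of the emulated regime. All randomness flows from one
seed and the generator emits ground-truth class masks that partition the
grid.

What it does **not** emulate: spatial texture and correlation of real
parenchyma (tissue levels are i.i.d. uniform), partial-volume boundaries,
beam hardening, reconstruction-kernel noise, Hounsfield calibration, or
anatomy beyond a disc-and-annulus head. Passing tests therefore show the
*operations* are correct (masks select exactly the intended sets, windows
rescale exactly, statistics match brute force), not that any clinical
image will yield particular coverages or means. Regime figures printed for
real slices (e.g. specific zero counts or coverage percentages) depend on
the un-distributed source image and are matched qualitatively, not
reproduced.

Noise, when enabled, is integer-valued and clamped into the tissue range
so level sets remain contiguous integer runs — the method is defined on
integer levels.

## Problem sizes and determinism

Tests run brute-force oracle comparisons on ≤ 64×64 phantoms (loops in
seconds) and the full pipeline-versus-manual-composition and
lesion-recovery checks on seeded 512×512 phantoms (well under a minute).
`scripts/acceptance.R` uses one 512×512 phantom and derives all randomness
from its `--seed`. The same seed gives bit-identical phantoms, renders and
statistics everywhere.

## Known limitations

* DICOM support is deliberately minimal (no sequences, no multi-frame, no
  compressed transfer syntaxes, no PACS).
* The central-region rule is geometric, not anatomical; it assumes the
  head is roughly convex and centered in its nonzero bounding box.
* Lesion isolation by level range requires the shift to move the lesion
  outside the displayed tissue run; overlapping distributions will leak.
* No automatic analysis: the package renders and summarizes, the reader
  decides.
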