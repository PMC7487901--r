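---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhoquant)
```

rhoquant implements the measurement procedures behind the standard
cell-biology assays used to study Rho-family GTPase signalling — biosensor
FRET imaging, focal adhesion and invadopodia scoring, fluorescent-gelatin
degradation, wound healing, single-cell motility, DNA-content and Annexin/PI
cytometry, gel densitometry and simple morphometry — together with a
synthetic-scene simulator that provides exact ground truth for every stage.
This vignette records the models, the parameters that matter, and the design
choices made where the published descriptions of these assays leave the
details open.

## Ratiometric FRET quantification

A unimolecular biosensor reports GTPase GTP-loading as an increased ratio of
the sensitized-emission channel (CFP excitation / YFP emission) to the donor
channel (CFP excitation / CFP emission). The pipeline is:

1. **Background correction** (`correct_background`): subtract the *median*
   intensity of a background region and clip at zero. If no region is given,
   one is derived as the complement of the Otsu-thresholded foreground
   dilated by 5 px. The median is used rather than the mean because stray
   debris in the background field otherwise drags the correction.
2. **Masking** (`make_cell_mask`): Otsu threshold on the directly excited
   acceptor (YFP) image, hole filling, largest 8-connected component. The
   acceptor channel is used because its intensity is independent of sensor
   activation.
3. **Ratio** (`ratio_image`): pixelwise FRET/donor over the mask. Pixels
   whose donor intensity is at or below a floor are dropped from the mask
   first; the default floor is 3x a robust (MAD) estimate of the residual
   background noise, because the quotient explodes at dim pixels. On
   noiseless scenes, shrinking the floor to zero does not change the result.
4. **Summary**: the per-cell activation is the *arithmetic mean of pixel
   ratios* (`mean_ratio`), and conditions are compared as
   `mean(sample cell means) / mean(control cell means)`
   (`fret_fold_change`).

**Mean of ratios vs ratio of means.** The assay convention "average the mean
FRET ratio over the cell area" is ambiguous. We take the mean of pixelwise
ratios as the primary statistic, since it weights every pixel of the cell
equally rather than weighting by donor brightness; the alternative
(`ratio_of_means` = mean FRET / mean donor) is computed on every
`ratio_image` for users who prefer the photometrically weighted version. For
a spatially uniform true ratio the two coincide in the noiseless limit; mean
of pixelwise ratios carries a small upward bias of order
`(sigma_donor / mu_donor)^2`, which is below 1% at SNR 10.

No channel registration or bleed-through correction is performed: the
channels of a filter-cube acquisition are assumed aligned, and crosstalk
coefficients are out of scope.

## Puncta detection (focal adhesions, invadopodia)

Detection follows the classic ImageJ recipe of local contrast enhancement
plus Laplacian-of-Gaussian (LoG) blob filtering, made reproducible:

- `log_response(img, sigma)` is the scale-normalized negative LoG,
  `-sigma^2 * Laplacian(G_sigma * img)`; bright blobs give positive peaks
  and a Gaussian spot of nominal radius r responds best at
  `sigma = r / sqrt(2)`. Kernels are zero-sum adjusted so constants and
  linear ramps map to numerical zero.
- The detection threshold is `median + k * MAD` of the response inside the
  cell mask (`k_mad = 5` by default). Because both the response and its
  robust statistics scale linearly with intensity, detection is exactly
  invariant under global multiplicative exposure changes — without any
  histogram equalization.
- Supra-threshold pixels form 8-connected components; components above
  `max_area_px` are split by assigning pixels to their nearest
  local-maximum seed (a light-weight watershed), and surviving components
  within the size filter become puncta. With several scales (adhesions:
  `sigma_px = c(2, 4, 8)` by default in spirit; the per-pixel maximum
  response over scales is used) overlapping cross-scale duplicates are
  pruned, keeping the stronger response.

**CLAHE.** `clahe()` implements contrast-limited adaptive histogram
equalization (tile 64 px, clip limit 0.01, 256 bins) and is available both
standalone and as `detect_puncta(enhance = TRUE)`. It is *not* applied by
default before detection: on scenes with flat background it amplifies
background noise into the LoG band and costs recall at low SNR, while the
MAD threshold already provides the scale invariance that CLAHE contributes
in the manual recipe. Enable it for fields with strong uneven illumination.

**Punctum area.** The reported `area_px` is measured on the *intensity*
image, not the filter response: the pixels connected to the punctum peak
that lie above half of the peak height over the local background (FWHM
area), after a light Gaussian smoothing (sd 0.8 px) whose analytic widening
(`2*pi*ln2*0.64` px) is subtracted. Measuring on the response would inflate
areas by the filter scale (`+sigma^2` of variance), biasing size
comparisons between small and large structures; the FWHM-on-intensity
definition makes the area of a Gaussian spot proportional to its true
footprint regardless of the detection scale. The raw supra-threshold pixel
count is kept as `supra_px`, and the size filter applies to it.

Adhesion size is summarized as the mean punctum area pooled over all cells
of a condition divided by the pooled control mean
(`adhesion_area_fold`); whether "size" should instead be the per-cell total
adhesion area is genuinely open, so `mode = "per_cell_total"` is provided.
Invadopodia are reported as absolute counts per cell and their mean
(`invadopodia_count`), not as fold change.

## Matrix degradation index

Cells that form functional invadopodia digest fluorescent gelatin under
their footprint. The per-cell index is

D = mean(matrix fluorescence in a background ROI) / mean(under the cell trace),

with D = 1 for an untouched matrix and D > 1 reflecting degradation. The
published form of this assay says only that "a similar ROI" is traced in the
background; we fix the convention as an **equal-area annulus** grown outward
from the cell trace ring by ring (8-connected), skipping every cell
footprint in the field, until it holds exactly as many pixels as the trace.
This samples background immediately adjacent to the cell, which protects the
index against large-scale illumination gradients; it errors when less than
25% of the needed area is available. A fully degraded footprint (cell mean
~ 0) yields the sentinel `D = Inf` with a flag rather than an error, and
such cells are excluded (with a warning) from fold changes.

D is a ratio of means over the same image, so it is exactly invariant under
exposure rescaling.

## Wound healing and motility

- `wound_widths`: the wound is the cell-free band crossing the mask; widths
  are read at **11 evenly spaced rows** (the assay's "11 different points";
  even spacing is our determinism choice) as the longest 0-run per row times
  the pixel size.
- `closure_rate`: `(mean width at t0 - mean width at t1) / hours`, using the
  two endpoint frames only — the assay images a wound at two time points.
  The elapsed time is always an explicit argument, never assumed.
- `track_stats` / `cohort_speed`: total path length is the sum of
  consecutive Euclidean steps of the raw, unsmoothed track; speed = total
  path / duration (e.g. over the standard 120 min of 1-min frames); net
  displacement is first-to-last. Localization noise inflates the raw path
  length, so the estimated speed is an upper bound in noisy data; the
  `subsample` argument measures every k-th frame, which reduces this bias
  monotonically, and is off by default to match the raw-path convention.
- `link_detections` adds greedy nearest-neighbour linking with a hard
  distance gate for users starting from per-frame centroids; the assays
  themselves assume curated tracks.

## Cytometry

**DNA content.** Phases are defined purely by ploidy: G0/G1 at 2n, G2/M at
4n, S strictly between. The 2n peak is the strongest density mode (with a
guard: if a comparable mode sits at half the strongest mode's position, the
strongest mode is 4n of a G2/M-dominated sample); 4n is fixed at exactly
twice the 2n mode, assuming PI linearity. Gates are `2n*(1 +/- k*CV)` and
`4n*(1 +/- k*CV)`, half-open, with `k = 2` and the CV estimated by MAD
around the 2n mode; sub-G1 and >4n events leave the denominator.

Raw gate counts are kept (`fractions_raw`), but they systematically
misassign the S-phase bridge: the 4n gate is twice as wide as the 2n gate
in absolute terms and swallows the upper ~`2*k*CV` of the bridge, an error
of ~0.04 at a CV of 5%. The reported `fractions` therefore solve the 3x3
linear system mapping true class counts to expected gate counts (Gaussian
peak tails, uniform bridge overlap) — a closed-form spillover correction,
not a curve fit, and classes whose gate is empty are never invented. With
the correction, simulated mixtures are recovered to well within 0.02 at
n = 10,000; without it they are not, which is why the correction is the
default.

**Annexin V / PI.** Quadrant rules: double-negative = live, Annexin-only =
early apoptotic, double-positive = necrotic, PI-only = "other". Default
thresholds are per-channel cuts at the density valley between the negative
and positive populations on the log scale; a unimodal channel is treated as
all-negative, with the cut placed 5 robust SDs above its single mode.

## Densitometry and morphometry

Densitometry normalizes each lane's band to its loading control and reports
fold change to a named control lane; the double ratio is exactly invariant
to per-replicate exposure. Sphere morphometry uses the circular closed
forms, area = pi d^2/4 and volume = pi d^3/6 (sphericity assumed — the
source assays compute volume from 2-D measurements without stating a
formula); a mask yields d as the equivalent-circle diameter. Tissue
quantification is the mean fluorescence intensity per pixel over fixed-area
frames, compared between groups as a ratio of group means.

## The synthetic world

Every generator returns `(data, truth)` and is deterministic per seed, with
independent named RNG substreams for placement, noise and sampling, so
changing the noise level never reshuffles geometry. Defaults encode the
stated conditions of the assays they emulate:

- FRET: elliptical cell, donor 1000 counts over background 100, Poisson
  shot noise plus Gaussian read noise (sd 20 by default; a pure-Gaussian
  mode exists for analytic tests). Activation scenarios use ratio 1.6 and
  1.5 versus control 1.0, and a "tail hotspot" models persistent activation
  at the rear of a cell. The source imagery's noise characteristics are
  unpublished, so these noise defaults are declared arbitrary.
- Matrix: gelatin at 1000 counts with circular degradation spots (max-depth
  combination on overlap, since re-degradation cannot un-degrade); a
  requested degraded fraction is hit to one pixel by trimming the last
  spot. Spots may spill slightly past the footprint (motile cells);
  `clip_to_footprint = TRUE` gives the analytic construction.
- Puncta: Gaussian spots of nominal radius r (profile sd `r/sqrt(2)`,
  so the best LoG scale is `r/sqrt(2)`), peak 500 over background 100,
  placed with a minimum separation; explicit `centers`/`radii` allow paired
  conditions differing only in spot size.
- Motility: persistent random walk with fixed per-track step (0.3 um at
  1-min frames for 120 frames — the control condition's speed), heading
  evolving by a wrapped-Gaussian turn with
  `sd = sqrt(-2 log(persistence))`, chosen so the expected turn cosine
  equals the persistence.
- Wound: width `w(t) = max(0, w0 - rate*t)` (defaults 500 um, 5 um/hr)
  with a fixed, zero-mean sinusoidal edge-roughness profile drawn once per
  scene, so a zero rate yields bit-identical frames.
- Cytometry: lognormal 2n/4n peaks (2n at 200 AU, CV 5%) with a uniform
  S bridge; Annexin/PI as three lognormal clusters separated by 1.2 decades
  with 0.15-decade spread.

What the simulator does *not* emulate: optics (PSF, spectral bleed-through),
3-D structure, autofluorescence, cell-to-cell biological variability, or
motion blur. A green test therefore establishes that an estimator recovers
its own stated model's truth at realistic noise — not that it is robust to
everything real microscopy produces.

## Numerical conventions

- Rasters are (row, col), 0-based physical convention
  (x = (col-1)*pixel size); intensities are doubles internally, with the
  source bit depth kept only for lossless integer writing. Reading never
  rescales.
- No TIFF-capable R package is available in the supported environment, so
  the package carries a minimal baseline TIFF 6.0 codec: uncompressed
  grayscale, 8/16-bit unsigned and 32-bit float, multi-page; the reader
  accepts both byte orders and multi-strip files. The physical pixel size
  travels in a YAML sidecar (`<file>.tif.meta.yaml`) because classic TIFF
  has no reliable calibrated-unit tag.
- `pixel_size_um` defaults to 1 with a warning when unstated, since none of
  the emulated assays publish their calibration.
- Connected components and hole filling use iterative label/flood
  propagation; dilation uses Euclidean disks. Otsu thresholds use 256 bins.
- Ties and degenerate inputs: uniform images refuse to threshold; an empty
  mask, an all-dim donor, a zero loading lane and a single-point track are
  errors; a fully degraded cell is a flagged sentinel, not an error.
- Pipeline runs write `summary.csv` and a YAML log carrying the package
  version, seed and full parameter set; no timestamps, so identical
  config + seed reproduce outputs byte for byte.

## Known limitations

- The FWHM area needs the spot interior to clear its local background by
  more than the noise; at SNR well below 5 area estimates (not detections)
  degrade first, with small structures biased high relative to large ones.
- The degradation ROI convention differs from labs that trace the
  background ROI by hand at an arbitrary location; with strong illumination
  gradients the two disagree.
- The spillover correction assumes the gated sample is a two-peaks-plus-
  bridge mixture; aneuploid or heavily apoptotic samples violate it (the
  raw fractions remain available).
- Greedy track linking has no motion model and will fragment tracks in
  dense fields; it is a convenience, not a tracker.
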