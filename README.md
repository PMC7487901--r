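# rhoquant

Quantitative imaging and cytometry for Rho GTPase cell-biology assays.

Studies of Rho-family GTPases (RhoA, Rac1, Cdc42) in migrating and invading
cells lean on a recurring set of quantitative readouts: ratiometric FRET
biosensor imaging, vinculin/TKS4 puncta scoring (focal adhesions and
invadopodia), fluorescent-gelatin matrix degradation, wound-healing closure
rates, single-cell motility statistics, DNA-content and Annexin/PI flow
cytometry, and gel densitometry. These are usually assembled ad hoc from
ImageJ plugins and spreadsheets. rhoquant implements the full set as tested,
scriptable R functions, and pairs every analyzer with a synthetic-scene
generator that produces the same kind of data *with known ground truth*, so
each measurement can be validated end to end.

## The statistics at the core

| Readout | Definition |
|---|---|
| Biosensor activation | per-pixel ratio R = I_FRET / I_donor over a cell mask (background-corrected); per-cell mean ratio; condition fold = mean(sample) / mean(control) |
| Adhesion size | mean punctum area (LoG-detected, FWHM-measured), fold vs control |
| Invadopodia | absolute puncta count per cell and its mean |
| Degradation index | D = mean matrix fluorescence in an equal-area background ROI / mean under the cell trace; D > 1 means degradation |
| Wound closure | (mean of 11 line widths at t0 − at t1) / elapsed hours, in um/hr |
| Cell speed | total path length / duration (um/min), net displacement first→last |
| Cell cycle | G0/G1 = 2n, S strictly between, G2/M = 4n, mode-anchored gates with spillover correction |
| Apoptosis | Annexin/PI quadrants: −/− live, +/− early apoptotic, +/+ necrotic |
| Densitometry | (band / loading) relative to control lane |

## Worked example

Simulate a biosensor experiment — ten control cells and ten cells with a
1.6-fold elevated true activation ratio — and recover the fold change:

```r
library(rhoquant)

measure_cell <- function(ratio, seed) {
  sc  <- make_fret_scene(ratio_baseline = ratio, seed = seed)
  set <- fret_image_set(correct_background(sc$images$donor),
                        correct_background(sc$images$fret),
                        sc$images$acceptor)
  ratio_image(set, make_cell_mask(sc$images$acceptor))$mean_ratio
}
sample_means  <- sapply(1:10, function(s) measure_cell(1.6, 100 + s))
control_means <- sapply(1:10, function(s) measure_cell(1.0, 200 + s))
round(fret_fold_change(sample_means, control_means), 3)
#> [1] 1.6
```

The same pattern — generate a scene, run the analyzer, compare with the
scene's `$truth` — works for every module. The whole battery runs from one
config:

```r
run_pipeline(demo_config(seed = 1, outdir = "demo_run"))
```

which prints (and writes to `demo_run/summary.csv`):

```
          stage                   metric      value seed
1          fret                fret_fold  1.5997434    1
2        matrix         degradation_fold  1.4106675    1
3        puncta     mean_puncta_per_cell 12.0000000    1
4         wound       closure_rate_um_hr  5.0000000    1
5        tracks        mean_speed_um_min  0.3000000    1
6     cytometry            fraction_g0g1  0.5973903    1
7     cytometry               fraction_s  0.2082377    1
8     cytometry             fraction_g2m  0.1943720    1
9       annexin            fraction_live  0.6994000    1
10      annexin fraction_early_apoptotic  0.2014000    1
11      annexin        fraction_necrotic  0.0992000    1
12      annexin           fraction_other  0.0000000    1
13 densitometry             fold_control  1.0000000    1
14 densitometry              fold_sample  2.5000000    1
```

Reading the rows: the FRET stage recovers the simulated 1.6-fold activation
(1.5997); the degradation stage reports the fold increase in index D of
degrading cells over pristine controls; puncta counts hit the planted 12
spots per cell exactly; the wound stage recovers the simulated 5 um/hr
closure; tracks recover the 0.3 um/min control speed exactly; the cytometry
stages recover the simulated (0.6, 0.2, 0.2) cell-cycle and (0.7, 0.2, 0.1)
Annexin/PI mixtures to within sampling error; densitometry reports the
simulated 2.5-fold band increase. Identical seed and config reproduce this
table byte for byte.

Real data enter through the same I/O layer: `read_raster()` (TIFF),
`read_tracks()` (CSV), plain data.frames for cytometry events and gel bands.
A command-line wrapper lives at
`system.file("cli", "rhoquant", package = "rhoquant")`
(`rhoquant run config.yaml`, `rhoquant demo`, `rhoquant fixtures`).

## Layout

- `R/` — implementation: I/O (`tiff.R`, `tracks.R`), simulators
  (`scene_sim.R`), analyzers (`fret.R`, `puncta.R`, `degradation.R`,
  `motility.R`, `aux_quant.R`), orchestration (`pipeline.R`).
- `tests/testthat/` — unit, property and acceptance suites.
- `vignettes/rhoquant-methods.Rmd` — models, parameter conventions and the
  reasoning behind every open design choice.
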