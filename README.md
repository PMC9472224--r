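# spheroidArray

Quantitative image analysis for 3D tumor spheroids cultured in
microfluidic **droplet trapping arrays**.

In these devices, a flow-focusing junction encapsulates cells in hydrogel
droplets that settle into a regular array of circular traps (990 traps of
150 µm, or 450 traps of 300 µm per device), where each droplet grows into
one spheroid that can be imaged over days and treated with drugs.
`spheroidArray` implements the full analysis chain for such experiments:

- **Trap detection** — circular-Hough-style annulus matched filtering at
  the nominal trap radius, regularized to a fitted lattice, with
  interpolation of occluded sites and rigid registration of imaging days.
- **Spheroid segmentation** — grayscale conversion, median-filter
  denoising, per-trap Otsu thresholding, morphological cleanup, and
  largest-component selection inside each trap; a droplet mode for day-0
  images and blob-based counting of encapsulated cells.
- **Morphometrics** — pixel area, equivalent-circle diameter
  `d = 2√(A/π)`, chain-code perimeter, circularity `4πA/P²`, and maximum
  Feret diameter.
- **Growth analysis** — per-trap day-series linking, growth
  classification by a one-sided OLS slope test, estimation of the
  minimum encapsulated-cell count required for growth, and size
  distribution summaries (`mean ± SD (n)`).
- **Fluorescence quantification** — background-subtracted per-spheroid
  intensities, Ki-67 proliferation normalized as FITC/DAPI scaled to a
  reference condition, and live/dead viability fractions.
- **Statistics** — one-way ANOVA with Fisher LSD pairwise comparisons and
  the `***` (p < 0.001) / `ns` (p > 0.05) labeling convention.
- **Synthetic scenes** — a first-class generator that renders brightfield
  and fluorescence images of trap arrays with full ground truth (trap
  centers, spheroid masks, Poisson cell loading, gated growth,
  condition-dependent fluorescence), so every stage is testable without
  external data.

## Worked example

Simulate a small 300 µm array, write it to disk as TIFFs + ground truth,
and run the pipeline end to end:

```r
library(spheroidArray)

spec  <- sceneSpec("array300", rows = 5, cols = 5, seed = 11)
scene <- simulateScene(spec, loadingModel(6),
                       growthModel(min_growth_count = 10), seed = 11)
writeSceneDataset(scene, "demo", conditions = c("E2 only", "100 nM ICI + E2"))

cfg <- readRunConfig("demo/config.yaml")
cfg$fluorescence$reference_condition <- "E2 only"
res <- runPipeline(cfg, out_dir = "demo/results")

table(res$track_summary$label)
#>  growing stagnant
#>        2       23
summarizeDistribution(res$tracks, 7)$text
#> [1] "32.1 ± 12.4 µm (n = 25)"
tapply(res$fluorescence$normalized_ki67, res$fluorescence$condition, mean)
#> 100 nM ICI + E2         E2 only
#>      0.09016238      1.00000000
```

At a mean loading of 6 cells/droplet most droplets start below the
10-cell growth gate, so most tracks are stagnant; the two tracks that
started with ≥ 10 cells are classified growing. The normalized Ki-67
means show the fulvestrant dose almost eliminating estrogen-driven
proliferation relative to the E2-only control (mean = 1 by construction).

Outputs land in `demo/results/`: tidy `measurements.csv` (one row per
trap per day), `tracks.csv` / `track_summary.csv`, per-day
`distributions.csv`, ANOVA and Fisher-LSD reports, `fluorescence.csv`, a
QC overlay with the detected trap circles, and a `manifest.yaml` carrying
the seed and config hash. A thin CLI over the same functions lives at
`inst/scripts/spheroid-array.R` (subcommands `simulate` and `run`).

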