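---
title: "Methods: quantifying spheroids in droplet trapping arrays"
author: "spheroidArray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying spheroids in droplet trapping arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and numerical
choices: what each stage assumes, which parameters matter, what the
synthetic generator does and does not emulate, and where the design was
genuinely open.

## The measurement problem

A droplet trapping array holds one hydrogel droplet — and after a day of
culture, one spheroid — in each circular trap of a regular lattice (990
traps of 150 µm or 450 traps of 300 µm per device). Brightfield images
taken on successive days, plus fluorescence channels for viability
(calcein / ethidium homodimer / Hoechst) and proliferation (Ki-67),
yield per-spheroid morphometrics, growth tracks, and drug-response
readouts. The pipeline stages mirror that chain: detect traps → segment
the object in each trap → measure → link days into tracks → classify
growth → quantify fluorescence → test group differences.

## Trap detection

Traps are dark-walled circles of known nominal radius $r$ on a regular
lattice. Detection is annulus matched filtering — circular Hough voting
restricted to radii within ±15 % of nominal — on a copy of the image
downsampled so $r \approx 12$–19 px, which makes the transform cheap on
full-device images. Three design points matter:

* **Non-maximum suppression at 1.9 r.** Two true traps can never be
  closer than one trap diameter (the disks are disjoint), while the
  strongest clutter — the ring-like response midway between four droplet
  rims — always is. Suppressing peaks within $1.9r$ of a stronger peak
  removes that clutter class entirely. A true trap occasionally loses to
  adjacent clutter; the lattice fill recovers it (below).
* **Lattice regularization.** Pitch and rotation are bootstrapped from
  the strongest 60 % of detections (nearest-neighbour distances below
  $1.9r$ are ignored as clutter when estimating pitch); every candidate
  is then tested against the fitted lattice and kept only if it lands
  within 0.3 pitch of a site. Final trap centers are the fitted lattice
  positions — averaging over hundreds of detections gives sub-pixel
  accuracy even though raw peaks are quantized by the downsampling.
  Sites without a raw detection are interpolated and flagged
  `provisional`; border rows/columns supported by almost no detections
  (< 30 % occupancy) are trimmed so isolated clutter cannot inflate the
  array's bounding box.
* **Failure is loud.** Fewer than four peaks above an absolute response
  floor raises a "no array found" error; a lattice residual above a
  quarter pitch is recorded as a degraded-fit warning in the result.

The trap radius is reported as the scanned radius that responds best at
the detected peaks. Day-to-day correspondence is iterative closest point
with a Kabsch update, flagging traps whose nearest counterpart is
farther than half a pitch.

## Segmentation

Brightfield preprocessing is luminance conversion plus a radius-2 median
filter (edge-preserving, and exactly the right tool for salt-and-pepper
noise). Background flattening by large-scale Gaussian subtraction is
available but off by default: thresholds are computed per trap, which
already defeats the device-scale illumination gradient.

Spheroid segmentation thresholds the **trap interior** (the disk minus
the rendered wall thickness) with Otsu's method computed over interior
pixels only, takes dark pixels as foreground, applies morphological
closing and hole filling, and keeps the largest connected component.
Two guards prevent phantom objects: a minimum area (50 px² default) and
a minimum foreground/background contrast (0.15) below which the trap is
declared empty — Otsu always "finds" a threshold, even in pure noise.

Day-0 droplets need a different region: droplets can slightly exceed the
trap diameter (a 153 µm droplet sits in a 150 µm trap), so droplet mode
searches the whole pitch cell and instead suppresses the thin dark trap
wall by morphological opening at the wall thickness before filling. The
droplet's own rim then fills to the droplet disk.

Cell counting on day 0 is scale-selective blob detection: invert, smooth
with a Gaussian at half the cell radius, and count local maxima at least
one cell radius apart whose prominence above the droplet's median
exceeds 0.08. The droplet mask is eroded by the cell radius plus rim
width so the rim is never counted. Overlapping cells merge into one
blob; undercounting tight clusters is the expected failure mode and the
generator therefore renders cells with a minimum separation of one cell
diameter.

## Morphometrics

Area is the pixel count; the primary diameter is the equivalent-circle
diameter $d = 2\sqrt{A/\pi}$, chosen over Feret because it is stable
under boundary noise and consistent with area-based growth readouts (the
maximum Feret diameter is emitted as an auxiliary column). Perimeter
uses Kulpa-weighted chain codes ($0.948\,N_{even} + 1.340\,N_{odd}$),
which keeps disk circularity $4\pi A/P^2$ within $[1.00, 1.02]$ for
radii 10–200 px where naive pixel-edge perimeters bias it near 0.9.
Circularity is clipped at 1.05; values up to ~1.1 arise routinely from
digitization of small masks and are clipped silently, anything larger
triggers a warning. Masks must be single connected components; empty or
fragmented masks are errors, not silent zeros.

## Growth analysis

Tracks link each reference trap's measurements across days (missing days
stay missing — no imputation). "Growing" is formalized as a positive OLS
slope of diameter against day with a one-sided p below α = 0.05; the
population-level day-1 vs day-7 contrast in the source experiments is
consistent with this per-track rule, but growth in such studies is
typically read off plots, so the rule is this package's testable
definition. Tracks
with fewer than two observed days are `unclassified`; with exactly two
days the slope has no residual degrees of freedom, the p-value is `NA`,
and the track is conservatively `stagnant`.

The minimum-cell threshold estimator is the maximum-accuracy split: the
smallest integer $c$ such that calling `count ≥ c` growing and
`count < c` stagnant misclassifies the fewest tracks (ties go to the
smallest $c$; all-one-label inputs return a flagged boundary estimate).
It is deterministic and assumption-light, and recovers the generating
gate in ≥ 9/10 seeded replicates at gates 5, 10 and 15.

## Fluorescence

Per-object intensity is the mask mean minus the **median** over a
background annulus 3 px outside the mask and 5 px wide — median, because
the annulus may clip neighbouring objects and the gradient. Normalized
Ki-67 is the per-spheroid FITC/DAPI ratio scaled so the reference
condition's mean is 1: DAPI division controls for spheroid size and
cellularity, and control scaling matches a normalized reporting axis.
How the source study normalized its proliferation axis is not stated;
this scheme is the package's documented assumption, and the reference
condition is a configuration field. The operation is idempotent and
invariant to a common gain on both channels.

Viability positivity uses per-channel Otsu with two guards: a channel
whose intensity spread is below 0.1 is treated as signal-free, and the
threshold is floored at median + 5 MAD — with very sparse positives Otsu
otherwise lands inside the background noise and calls half the
background positive.

## Statistics

One-way fixed-effects ANOVA (via `stats::lm`/`anova`) with Fisher LSD
pairwise comparisons computed from the pooled within-group mean square,
deliberately unadjusted for multiplicity — that is the LSD's definition.
LSD runs unprotected by default, with an option to gate on omnibus
p < 0.05; both usages exist in practice. Labels follow the convention
`***` for p < 0.001 and `ns` for p > 0.05; the convention defines only
the two extremes, so intermediate p-values are printed numerically
(`p=0.0100`) rather than inventing star tiers. Degenerate inputs are
flagged, not fatal: zero within-group variance with unequal means yields
an infinite F with p = 0.

## The synthetic generator

The generator is the package's test bed and defines its study
conditions:

* **Loading** is i.i.d. Poisson per droplet — the standard model for
  passive encapsulation; occupancy is $1 - e^{-\lambda}$, so
  $\lambda = 2.3026$ reproduces 90 % occupancy, and $\lambda \approx 25$
  puts laden droplets of the larger array in the 10–45 cells range.
  Whether real cells-per-droplet counts are exactly Poisson is not
  established by the source data; λ is a free calibration parameter.
* **Growth** is linear and gated: initial diameter follows a cube-root
  packing rule $d_0 = 16\,\mu m \cdot count^{1/3}$, tracks with at least
  `min_growth_count` (default 10) cells grow at 6 µm/day, occupied
  tracks below the gate stay flat, and Gaussian jitter (1 µm) is applied
  per day. The rates are chosen so day-7 sizes land in the tens of
  micrometers, matching the reported day-7 distributions.
* **Appearance**: traps are dark annuli (wall ≈ 4 % of the diameter),
  spheroids dark-rimmed disks with granular interiors, droplets contrast
  disks containing individual dark cells; grid tilings are 33 × 30 and
  30 × 15 (near-square; any factorization is configurable), pitch 1.3 ×
  trap diameter (1.5 × for droplet scenes so +3 SD droplets fit a pitch
  cell), pixel scale 1 µm/px so pixel and micrometer examples coincide.
  Degradation is additive Gaussian noise (σ = 0.05), optional
  salt-and-pepper, and a 10 % linear illumination gradient across the
  width — applied to brightfield only; fluorescence renders assume a
  flat field, as epifluorescence flat-fielding would provide.
* **Determinism**: every stochastic operation takes an explicit seed and
  restores the caller's RNG state; identical scene + seed gives
  bit-identical images.

What it does **not** emulate: optics (no point-spread function, no
defocus), droplet physics (no pinch-off or gelation), partial trap
occupancy by multiple droplets, spheroid irregularity (objects are
disks), or tile stitching — whole-device images are assumed
pre-stitched. Passing tests therefore demonstrate correctness of the
measurement chain under controlled contrast and noise, not robustness to
every real-microscopy artifact.

## Problem sizes and tolerances

The shipped checks use 350- and 400-trap day-7 scenes and 300-droplet
day-0 scenes (means recovered within 3 % of the generating
distributions), full 990- and 450-trap noise-free renders for detection
completeness, $10^5$ droplets for occupancy (compared within 3
Monte-Carlo standard errors), 200 tracks for threshold recovery, and
10,000 null replicates for the ANOVA type-I check (5 % ± 0.7 %). These
sizes keep a full run to a few minutes on one CPU while leaving the
Monte-Carlo error well inside each tolerance.

## Known limitations

Trap detection assumes a single rectangular lattice of circular traps of
one nominal size; rotations are handled only up to a few degrees (the
angle-folding step breaks near 45°). Droplet measurements carry a small
positive bias (~1–2 %) where the droplet rim merges with the trap wall.
Cell counts saturate once droplets become confluent. The growth model is
linear — no exponential or Gompertz fitting — and spheroid merging or
splitting is out of scope.
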