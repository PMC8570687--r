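---
title: "Quantifying labeled pericytes and microglia in whole brain sections"
author: "periglia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying labeled pericytes and microglia in whole brain sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(periglia)
```

## The analysis model

The package quantifies three-channel (DAPI / DsRed / GFP) fluorescence
images of brain sections in five stages, each exposed as ordinary functions
so any stage can be rerun or replaced.

**Masking.** Tissue is found by a per-pixel rule on the smoothed average of
the three channels: Gaussian prefilter (sigma 2 px), inclusive threshold
(50 counts), then a fixed cleanup order — fill holes smaller than
1000 µm², drop components smaller than 1,000,000 µm², erode by 40 µm
(disc), drop fragments smaller than 10,000 µm². The erosion exists because
section edges are systematically brighter (mounting and drying artifacts);
removing a 40 µm rim costs little area and avoids a rim of false-positive
cells. Large DsRed-bright vessels — vascular smooth muscle rather than
capillary pericytes — are found the same way on the DsRed channel alone
(threshold 400, min 150 µm², holes 1000 µm², no erosion or fragment step:
the text of the procedure applies those two stages to tissue only) and
subtracted. The remaining tissue is intersected with named region polygons.

**Nucleus detection.** The DAPI channel passes through a fixed operator
chain: optional resampling, optional median filter, optional background
subtraction, Gaussian smoothing (sigma 1.5 px), inclusive threshold,
single-pixel hole filling, then a watershed on the Euclidean distance
transform to split touching nuclei. Components outside 10–400 µm² are
dropped, as are components whose centroid leaves the mask. Watershed seeds
are distance-transform maxima found within a radius of
`sqrt(min_area / pi)` µm; two merged nuclei that present a single maximum
deliberately remain one detection — that failure mode exists in any
automated counter and the synthetic data reproduces it on purpose.
Background subtraction is implemented as a grayscale white top-hat (disc
opening subtracted from the image) and is off by default: genetically
encoded reporters give a clean background, and the option exists for
immunofluorescence-style data.

**Cell expansion and measurement.** Each nucleus is grown by 2 µm;
competing expansions meet at the nearest-nucleus midline (geodesic
propagation from the nucleus labels inside the dilated footprint), so cell
regions are always disjoint and each contains its nucleus. Mean
intensities per channel are measured on the *raw* pixels over both the
nucleus and the full cell region; smoothing only ever affects segmentation.

**Classification.** A cell is DsRed-positive iff its DsRed cell mean is
`>=` the region's DsRed threshold, GFP analogously; both gives DUAL,
neither NEGATIVE. The partition is exhaustive and exclusive and asserted
on every run. DUAL cells — usually two adjacent cells the nucleus splitter
could not separate — are counted separately and excluded from the
pericyte/microglia tallies, but kept in the denominator of "% of total".
Comparisons are inclusive throughout; at the grid resolution used for
optimization (steps of 25 counts) the choice is immaterial, but it is
fixed and documented.

**Quantification.** Region area is the mask pixel count times the squared
pixel size; counts take the cells whose nucleus centroid lies in the
region mask (cells straddling a border belong to the region holding their
centroid). Overall percentages across regions are computed per section by
pooling counts over the analyzed regions, then averaged across sections —
so an eight-section cohort reports a mean ± SD of eight per-section
values, not a cell-weighted grand total.

## Threshold optimization

The optimization metric is the percent difference between the automated
count $A_c$ and a manual count $M_c$ inside a small test annotation:

$$\%\,\text{difference} = \frac{A_c - M_c}{M_c} \times 100$$

Zero means agreement, positive overcounting, negative undercounting; when
the threshold exceeds every cell's intensity the curve converges to
−100 %. One 300 × 200 µm rectangle per region per section keeps manual
counting feasible (50–150 nuclei, a handful of marker-positive cells).
`run_sweep()` applies the full detection (and classification) pipeline
inside each annotation for every grid value, changing only the swept
parameter, and records the mean and sample SD (n − 1) of the percent
difference across annotations. Detections are cached when only a
classification threshold changes — the cached quantity is exactly
invariant, so this is a pure speed-up. Annotations whose manual count is
zero cannot be scored by a relative metric and are excluded with a
warning.

`select_optimum()` codifies the selection narrative — greatest accuracy,
least variability, a preference for undercounting — as an explicit
lexicographic rule: (1) minimize |mean %difference|; (2) break ties by
smaller SD; (3) then prefer a non-positive mean; (4) then the larger
threshold. The original choice among near-equal grid values was made by
visual inspection; this rule is a documented, deterministic stand-in, and
ties are resolved at grid resolution only (no interpolation — reported
optima are grid values). `pooled_region_optimum()` covers the case where
one threshold must serve several sub-regions (e.g. dentate gyrus and
CA1/CA3 pooled into one hippocampal threshold): it minimizes the
worst-case |mean| across the sub-region curves with the same tie-breaks.

## The synthetic-section generator

`section_config()` / `generate_section()` render sections with exhaustive
ground truth. What the defaults emulate, and why:

* **Geometry** — 1300 × 1300 µm at 0.65 µm/px (2000 × 2000 px), a 50 µm
  empty slide margin, four square regions (cortex, hippocampus, thalamus,
  hypothalamus). The extent is chosen so the tissue rectangle
  (1.44 mm²) comfortably clears the 1,000,000 µm² tissue-mask floor while
  staying desk-scale; a full coronal section (~40 mm²) would behave
  identically but slow every test.
* **Densities** — 1500–2100 nuclei/mm², giving roughly 70–120 nuclei per
  300 × 200 µm annotation, the workload a manual counter actually faces.
* **Class fractions** — pericytes a few percent with the thalamus richest
  (6.2 %) and microglia 3–6 % with the cortex richest (5.5 %), matching
  the reported regional pattern for this reporter line, so the
  quantification stage can be checked for both recovery and ordering.
* **Intensity model** — arbitrary 16-bit-like counts. Backgrounds
  (DAPI 20, DsRed 100, GFP 60) and truncated-normal foreground amplitudes
  (DAPI 500 ± 40, DsRed 250 ± 20, GFP 250 ± 25, clamped at ±2 SD) are
  chosen so the separating gaps straddle the conventional sweep grids:
  positive DsRed cell means land near 300–390 against negatives below
  ~200 (capillary crossings included), GFP positives near 260–360 against
  negatives below ~100. Amplitude clamping is what makes the classes
  *learnable by thresholding* — an explicit generator invariant tested at
  every labelled cell. The DsRed soma amplitude is additionally capped so
  smoothed somata stay below the vessel-classifier threshold of 400:
  only the rendered vessels (amplitude 1500) may enter the vessel mask.
* **Structures** — pericyte somata are elongated plateaus on a capillary
  segment; microglia get 2–5 thin random-walk processes; capillaries run
  at 1 mm/mm². Morphology is cosmetic (classification is intensity-only);
  what matters is that processes and capillaries crossing *negative*
  cells stay below the positive gaps.
* **Artifacts** — 2 % of nuclei are rendered at half amplitude
  (out-of-focus stand-ins; they are the main source of the few-percent
  undercount at high DAPI thresholds), 2 % are placed as deliberately
  touching pairs (exercising watershed splitting and the dual-
  classification artifact), an 80-count additive ramp brightens a 25 µm
  band inside the tissue edge (motivating the 40 µm erosion), and two
  large bright vessels cross the tissue (motivating the vessel mask).
  Nuclei are never placed under vessels — a capillary lumen holds no
  parenchymal nuclei, and it keeps the ground truth countable.

What the generator does **not** emulate: point-spread optics, 3-D
structure and z-stacks, realistic vascular topology, NG2-positive
oligodendrocyte precursors as a separate class, autofluorescence, or
intensity gradients within regions. Green tests therefore demonstrate
that the *pipeline logic* is correct under controlled conditions, not
that any particular threshold transfers to real tissue — thresholds are
tissue- and scanner-specific by construction, which is the entire reason
the sweep machinery exists.

## Numerical conventions and degenerate inputs

* Rasters are matrices `[row = y, col = x]`; pixel `(r, c)` covers the
  half-open square `[c-1, c) × [r-1, r)` in 0-based pixel coordinates;
  physical units enter only through `pixel_size_um`.
* Point-in-polygon is even-odd ray casting everywhere (counting,
  rasterization, placement); points exactly on an edge follow that rule's
  half-open asymmetry, so no cell is ever counted twice or dropped at a
  shared border.
* All intensity comparisons are inclusive (`>=`).
* Morphological discs use the pixel set `dx² + dy² ≤ r²` with `r` in
  pixels (erosion/dilation radii round to the nearest pixel).
* Empty outcomes are defined, not fatal: an empty mask after filtering is
  a warning (a section may legitimately fail); a region with zero
  detections reports zero percentages with a flag; a manual count of zero
  excludes that annotation from a sweep with a warning; an empty
  measurement table writes a header-only CSV.
* Detections are sorted by (y, x) centroid and every random stage consumes
  an explicit seed, so identical inputs give identical outputs — the
  pipeline manifest hashes (MD5) are reproducible end to end.

## Problem sizes

The shipped tests validate the full study conditions on an eight-section
cohort at 2000 × 2000 px (sweeps over the full grids in all four regions,
then quantification at the recovered optima); unit tests use a smaller
two-region section (1231 × 1000 px) and constructed 64 × 64 fixtures for
the exact per-pixel oracle checks. `scripts/acceptance.R` reruns the
eight-section analysis from scratch in a few minutes on one CPU.

## Known limitations

* Parity with the original interactive tool is not claimable: its
  built-in detector's internals are not published, so this package fixes
  its own documented operator chain and validates against ground truth
  and the qualitative sweep behavior instead.
* Merged nuclei with a single distance maximum stay merged; the resulting
  DUAL classifications are reported, not repaired.
* The nearest-nucleus partition of cell expansions uses chamfer geodesic
  distances, which can deviate from exact Euclidean midlines by a few
  percent of a pixel dimension.
* Whole-slide pyramidal inputs are out of scope; images are single-
  resolution rasters sized for desk-scale analysis.
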