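# periglia

Automated detection, classification and quantification of fluorescently
labeled pericytes and microglia in multi-channel images of whole mouse
brain sections.

## The problem

Transgenic reporter lines such as NG2-DsRed × CX3CR1-GFP label capillary
pericytes (DsRed) and microglia (GFP) throughout the brain. Counting these
cells across a complete coronal section means segmenting tens of thousands
of DAPI-stained nuclei, deciding for each cell whether its DsRed and/or GFP
signal clears a positivity threshold, and doing so with thresholds that are
*justified* rather than eyeballed — regional differences in background and
expression mean a single global threshold over- or under-counts somewhere.

`periglia` implements that workflow as composable R functions:

1. **Tissue and vessel masking** — pixel classification on the smoothed
   average channel (sigma 2 px, threshold 50, min area 10⁶ µm², holes
   < 1000 µm² filled, 40 µm erosion, fragments < 10⁴ µm² dropped) defines
   the tissue; a DsRed classifier (threshold 400, min 150 µm²) finds large
   DsRed-bright vessels (vascular smooth muscle, not pericytes), which are
   subtracted before intersecting with named brain-region annotations.
2. **Nucleus detection** — Gaussian smoothing (sigma 1.5 px) of the DAPI
   channel, inclusive thresholding, distance-transform watershed to split
   touching nuclei, area filtering (10–400 µm²), and a 2 µm cell expansion
   whose competing rings meet at the nearest-nucleus midline.
3. **Classification** — each cell is DsRed-positive iff its mean DsRed cell
   intensity ≥ the region's DsRed threshold (GFP analogously); both ⇒ DUAL,
   neither ⇒ NEGATIVE. Dual cells are tallied but excluded from the
   pericyte/microglia counts.
4. **Threshold optimization** — any detection or classification parameter
   can be swept over a grid (DAPI 50–1000, DsRed 200–550, GFP 100–450, step
   25) inside small test annotations (300 × 200 µm) and scored against
   manual counts with the percent-difference metric

   ```
   %difference = (Ac − Mc) / Mc × 100
   ```

   (Ac automated, Mc manual). The optimum minimizes |mean %difference|,
   then the SD across annotations, preferring undercounting, then the
   larger threshold.
5. **Quantification** — per-region areas (mm²), counts, class percentages
   and densities (cells/mm²), with cross-section mean ± SD summaries.

Because the original slide-scanner images are not public, the package ships
a first-class **synthetic-section generator** (`generate_section()`) that
renders DAPI/DsRed/GFP rasters with exhaustive ground truth — nuclei at
region-dependent densities, pericyte somata on a capillary network, large
bright vessels, ramified microglia, edge brightening and noise — so every
stage is testable end to end.

## Worked example

```r
library(periglia)

gen   <- generate_section(section_config(seed = 7))
clean <- mask_subtract(detect_tissue(gen$image), detect_vessels(gen$image))
dets  <- detect_cells(gen$image, detection_params(threshold = 150), clean)
dets  <- classify_cells(dets, classifier_params(300, 225))
rmask <- intersect_regions(clean, gen$annotations)$thalamus
quantify_region(dets, rmask, section = "demo", region = "thalamus")
```

prints (one row; columns abridged):

```
  section   region  area_mm2 n_total n_dsred n_gfp n_dual pct_dsred  pct_gfp per_mm2_total
1    demo thalamus 0.2301121     313      19    18      0  6.070288 5.750799      1360.207
```

— 313 nuclei detected in 0.23 mm² of masked thalamus (≈ 1360 cells/mm²),
of which 6.1 % classified DsRed-positive (pericytes; this region is
configured pericyte-rich) and 5.8 % GFP-positive (microglia), with no
dual-classified cells in this section.

A sweep against ground-truth counts, and its selected optimum:

```r
rects <- test_rect_table(generate_test_annotations(gen$annotations, c(300, 200)))
mc <- sapply(seq_len(nrow(rects)), function(k)
  ground_truth_counts(gen$cells, rect_polygon(rects$x_um[k], rects$y_um[k],
                                              rects$w_um[k], rects$h_um[k]))[["total"]])
sw <- run_sweep(sweep_spec("detection.threshold", c(50, 1000), step = 25,
                           channel = "DAPI", annotations = rects,
                           manual_counts = mc),
                images = list(section1 = gen$image))
select_optimum(sw)
plot(sw)   # the % difference curve: plateau near 0, dropping to -100 %
```

## Command line

```sh
exec/periglia generate --config cfg.yaml --out dir/ --seed 1
exec/periglia mask     --image section.tif --out masks/
exec/periglia detect   --image section.tif --threshold 150 --out cells.csv
exec/periglia run-all  --config cfg.yaml --out run/ --seed 1
```

## Scope and formats

Multi-page 16-bit TIFF images (pixel size in a JSON sidecar), GeoJSON
annotations (`properties.classification.name` + `properties.role`, the
common whole-slide dialect; count points carry `properties.channel`), CSV
measurement tables. Proprietary `.vsi` slide files, pyramidal images,
z-stacks, morphology-based or trainable classifiers are out of scope; see
the methods vignette (`vignettes/whole-section-quantification.Rmd`) for the
model, parameter choices and known limitations.
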