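# Shared fixtures, generated in code. The small section (1000 x 1000 px, two
# regions) backs the unit tests; the full-scale eight-section set backing the
# acceptance tests is built lazily and cached for the whole run.

small_config <- function(seed = 11, ...) {
  args <- list(
    width_um = 800, height_um = 650, pixel_size_um = 0.65,
    tissue_margin_um = 40,
    regions = list(cortex = rect_polygon(80, 100, 320, 450),
                   thalamus = rect_polygon(430, 100, 320, 450)),
    nucleus_density = c(cortex = 1800, thalamus = 1500),
    pericyte_fraction = c(cortex = 0.0268, thalamus = 0.062),
    microglia_fraction = c(cortex = 0.0554, thalamus = 0.0399),
    seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(section_config, args)
}

# mask parameters rescaled to the small fixture (its tissue rectangle is far
# smaller than a whole coronal section)
small_tissue_params <- function() {
  mask_params(min_area_um2 = 1e5, min_hole_um2 = 1000, erode_um = 40,
              min_fragment_um2 = 1e4)
}

.fixture_cache <- new.env(parent = emptyenv())

small_section <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- generate_section(small_config())
  }
  .fixture_cache$small
}

# hand-built classified detections spread over a given physical extent
fake_classified_dets <- function(n, n_dsred = 0, n_gfp = 0, n_dual = 0,
                                 extent_um = 1000, pixel_size_um = 10) {
  set.seed(n + n_dsred)
  cls <- c(rep("DSRED_POS", n_dsred), rep("GFP_POS", n_gfp),
           rep("DUAL", n_dual), rep("NEGATIVE", n - n_dsred - n_gfp - n_dual))
  tab <- data.frame(
    id = seq_len(n),
    x_um = runif(n, 1, extent_um - 1), y_um = runif(n, 1, extent_um - 1),
    nucleus_area_um2 = 30, cell_area_um2 = 70,
    DAPI_nucleus = 500, DsRed_nucleus = 100, GFP_nucleus = 60,
    DAPI_cell = 400,
    DsRed_cell = ifelse(cls %in% c("DSRED_POS", "DUAL"), 450, 120),
    GFP_cell = ifelse(cls %in% c("GFP_POS", "DUAL"), 300, 80),
    class = cls, stringsAsFactors = FALSE)
  structure(list(table = tab, nucleus_labels = NULL, cell_labels = NULL,
                 pixel_size_um = pixel_size_um), class = "cell_detections")
}

# a plain synthetic image with well-separated identical nuclei on a grid
grid_nuclei_image <- function(n = 50, s = 0.5, amp = 600, bg = 20,
                              radius_px = 6) {
  side <- ceiling(sqrt(n))
  pitch <- 30  # px
  dim_px <- side * pitch + 2 * pitch
  dapi <- matrix(bg, dim_px, dim_px)
  centers <- data.frame(x = numeric(0), y = numeric(0))
  k <- 0
  for (i in seq_len(side)) {
    for (j in seq_len(side)) {
      if (k >= n) break
      k <- k + 1
      cc <- pitch + j * pitch; rr <- pitch + i * pitch
      cs <- (cc - 10):(cc + 10); rs <- (rr - 10):(rr + 10)
      d <- sqrt(outer((rs - rr)^2, (cs - cc)^2, "+"))
      prof <- exp(-pmax(d - 0.7 * radius_px, 0)^2 / (2 * (0.3 * radius_px)^2))
      dapi[rs, cs] <- pmax(dapi[rs, cs], bg + amp * prof)
      centers <- rbind(centers, data.frame(x = (cc - 0.5) * s,
                                           y = (rr - 0.5) * s))
    }
  }
  list(image = section_image(list(DAPI = dapi,
                                  DsRed = matrix(100, dim_px, dim_px),
                                  GFP = matrix(60, dim_px, dim_px)), s),
       centers = centers)
}
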