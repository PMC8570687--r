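test_that("zero densities give pure background noise and empty ground truth", {
  cfg <- small_config(
    nucleus_density = c(cortex = 0, thalamus = 0),
    capillary_density_mm_per_mm2 = 0, large_vessel_count = 0,
    intensity = list(edge_amp = 0))
  gen <- generate_section(cfg)
  expect_equal(nrow(gen$cells), 0)
  dapi <- get_channel(gen$image, "DAPI")
  # inside-tissue background 20 plus N(0, 8) noise only: nothing near signal
  expect_lt(max(dapi), 20 + 6 * 8)
  interior <- dapi[100:900, 100:1100]  # inside the tissue rectangle
  expect_gt(mean(interior > 10 & interior < 30), 0.7)
})

test_that("cell counts follow the configured density (Poisson sampling)", {
  gen <- small_section()
  cfg <- small_config()
  for (reg in names(cfg$regions)) {
    lambda <- cfg$nucleus_density[[reg]] *
      polygon_area(cfg$regions[[reg]]) / 1e6
    n <- sum(gen$cells$region == reg)
    expect_lt(abs(n - lambda), 4 * sqrt(lambda))
  }
})

test_that("class fractions are recovered within binomial sampling error", {
  gen <- small_section()
  th <- gen$cells[gen$cells$region == "thalamus", ]
  p <- 0.062
  phat <- mean(th$class == "pericyte")
  expect_lt(abs(phat - p), 4 * sqrt(p * (1 - p) / nrow(th)))
  # classes partition the nuclei: per-region class counts sum to the total
  tab <- table(gen$cells$region, gen$cells$class)
  expect_equal(unname(rowSums(tab)),
               unname(as.vector(table(gen$cells$region))))
})

test_that("generation is deterministic under a fixed seed", {
  g1 <- generate_section(small_config(seed = 99))
  g2 <- generate_section(small_config(seed = 99))
  expect_identical(g1$image, g2$image)
  expect_identical(g1$cells, g2$cells)
})

test_that("marker foreground is learnable at every labelled cell", {
  gen <- small_section()
  cfg <- small_config()
  s <- cfg$pixel_size_um
  for (cl in c("pericyte", "microglia")) {
    ch <- if (cl == "pericyte") "DsRed" else "GFP"
    fg <- if (cl == "pericyte") cfg$intensity$dsred_fg else cfg$intensity$gfp_fg
    img <- get_channel(gen$image, ch)
    cells <- gen$cells[gen$cells$class == cl, ]
    for (k in seq_len(nrow(cells))) {
      r_px <- (cells$radius_um[k] + 2) / s
      cc <- cells$x_um[k] / s + 0.5; rr <- cells$y_um[k] / s + 0.5
      cs <- max(1, round(cc - r_px)):min(ncol(img), round(cc + r_px))
      rs <- max(1, round(rr - r_px)):min(nrow(img), round(rr + r_px))
      sel <- outer((rs - rr)^2, (cs - cc)^2, "+") <= r_px^2
      expect_gte(mean(img[rs, cs][sel]), fg[["mean"]] - 2 * fg[["sd"]])
    }
  }
})

test_that("the vessel mask never swallows pericyte somata", {
  gen <- small_section()
  vm <- detect_vessels(gen$image)
  peri <- gen$cells[gen$cells$class == "pericyte", ]
  s <- vm$pixel_size_um
  rr <- floor(peri$y_um / s) + 1
  cc <- floor(peri$x_um / s) + 1
  expect_false(any(vm$mask[cbind(rr, cc)]))
})

test_that("overlapping region polygons are rejected", {
  expect_error(small_config(
    regions = list(cortex = rect_polygon(100, 100, 300, 300),
                   thalamus = rect_polygon(200, 200, 300, 300))),
    "overlap")
})

test_that("test annotations are contained rectangles of the requested size", {
  gen <- small_section()
  ta <- generate_test_annotations(gen$annotations, c(300, 200), seed = 5)
  feats <- annotation_features(ta, "test-rect")
  expect_length(feats, 2)
  s <- 0.65
  for (f in feats) {
    rect <- f$parts[[1]]$outer
    expect_equal(polygon_area(rect) * s^2, 300 * 200, tolerance = 1e-9)
    region <- annotation_features(gen$annotations, "region", f$name)[[1]]
    expect_true(all(point_in_polygon(rect[, 1], rect[, 2],
                                     region$parts[[1]]$outer)))
  }
  # a different seed places the rectangles elsewhere, still contained
  tb <- generate_test_annotations(gen$annotations, c(300, 200), seed = 6)
  ra <- annotation_features(ta, "test-rect")[[1]]$parts[[1]]$outer
  rb <- annotation_features(tb, "test-rect")[[1]]$parts[[1]]$outer
  expect_false(isTRUE(all.equal(ra, rb)))
})

test_that("a rectangle equal to a rectangular region is accepted; an
           oversized request errors", {
  regions <- annotation_set(list(list(
    name = "square", role = "region",
    parts = rect_polygon(0, 0, 300, 200))), pixel_size_um = 1)
  ta <- generate_test_annotations(regions, c(300, 200), seed = 1)
  rect <- annotation_features(ta, "test-rect")[[1]]$parts[[1]]$outer
  expect_equal(sort(unique(rect[, 1])), c(0, 300))
  expect_error(generate_test_annotations(regions, c(400, 200), seed = 1),
               "cannot contain")
})

test_that("ground-truth counting uses the point-in-polygon convention", {
  empty <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      radius_um = numeric(0), class = character(0),
                      region = character(0))
  expect_equal(ground_truth_counts(empty, rect_polygon(0, 0, 10, 10)),
               c(total = 0L, dsred = 0L, gfp = 0L))
  set.seed(21)
  cells <- data.frame(
    id = 1:15,
    x_um = c(runif(10, 5, 95), runif(5, 120, 200)),
    y_um = runif(15, 5, 95),
    radius_um = 3,
    class = sample(c("pericyte", "microglia", "negative"), 15, TRUE),
    region = "r")
  poly <- rect_polygon(0, 0, 100, 100)
  counts <- ground_truth_counts(cells, poly)
  oracle_in <- pip_oracle(cells$x_um, cells$y_um, poly)
  expect_equal(counts[["total"]], sum(oracle_in))
  expect_equal(counts[["total"]], 10L)
  expect_equal(counts[["dsred"]],
               sum(oracle_in & cells$class == "pericyte"))
  negatives <- cells
  negatives$class <- "negative"
  expect_equal(ground_truth_counts(negatives, poly)[c("dsred", "gfp")],
               c(dsred = 0L, gfp = 0L))
})
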