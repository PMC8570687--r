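test_that("a blank image yields no detections", {
  img <- section_image(list(DAPI = matrix(20, 100, 100),
                            DsRed = matrix(100, 100, 100),
                            GFP = matrix(60, 100, 100)), 0.5)
  dets <- detect_nuclei(img, detection_params(150))
  expect_equal(nrow(dets$table), 0)
  img$channels$DAPI <- NULL
  img$channels$DAPI2 <- matrix(20, 100, 100)
  expect_error(detect_nuclei(img, detection_params(150)), "DAPI")
})

test_that("well-separated nuclei are each detected exactly once", {
  fix <- grid_nuclei_image(n = 50)
  dets <- detect_nuclei(fix$image, detection_params(150))
  expect_equal(nrow(dets$table), 50)
  m <- match_detections(dets$table, data.frame(x_um = fix$centers$x,
                                               y_um = fix$centers$y))
  expect_equal(m$recall, 1)
  expect_equal(m$spurious, 0)
})

test_that("watershed splits two overlapping discs with distinct maxima", {
  n <- 80; s <- 0.5; r <- 8
  dapi <- matrix(20, n, n)
  for (cc in list(c(40, 32), c(40, 48))) {  # centers 16 px apart, r = 8
    d <- sqrt(outer((seq_len(n) - cc[1])^2, (seq_len(n) - cc[2])^2, "+"))
    dapi <- pmax(dapi, 20 + 600 * exp(-pmax(d - 0.7 * r, 0)^2 / (2 * (0.3 * r)^2)))
  }
  img <- section_image(list(DAPI = dapi, DsRed = matrix(100, n, n),
                            GFP = matrix(60, n, n)), s)
  dets <- detect_nuclei(img, detection_params(150))
  expect_equal(nrow(dets$table), 2)
  # one fused blob with a single maximum stays one detection
  d1 <- sqrt(outer((seq_len(n) - 40)^2, (seq_len(n) - 40)^2, "+"))
  img$channels$DAPI <- 20 + 600 * exp(-pmax(d1 - 0.7 * r, 0)^2 / (2 * (0.3 * r)^2))
  expect_equal(nrow(detect_nuclei(img, detection_params(150))$table), 1)
})

test_that("cell expansion forms the expected annulus and stays disjoint", {
  n <- 120; s <- 0.5
  mk <- function(centers, r = 6) {
    dapi <- matrix(20, n, n)
    for (cc in centers) {
      d <- sqrt(outer((seq_len(n) - cc[1])^2, (seq_len(n) - cc[2])^2, "+"))
      dapi <- pmax(dapi, 20 + 600 * (d <= r))
    }
    section_image(list(DAPI = dapi, DsRed = matrix(100, n, n),
                       GFP = matrix(60, n, n)), s)
  }
  img <- mk(list(c(60, 60)))
  d0 <- detect_nuclei(img, detection_params(150, sigma_px = 0))
  # zero expansion: cell region is the nucleus region
  e0 <- expand_cells(d0, 0)
  expect_identical(e0$cell_labels, e0$nucleus_labels)
  # 2 um expansion of an isolated disc: area close to pi (r + 2)^2
  e2 <- expand_cells(d0, 2)
  r_um <- sqrt(d0$table$nucleus_area_um2 / pi)
  expect_equal(e2$table$cell_area_um2, pi * (r_um + 2)^2, tolerance = 0.08)
  expect_true(all(e2$cell_labels[e2$nucleus_labels > 0] ==
                  e2$nucleus_labels[e2$nucleus_labels > 0]))

  # two nuclei 3 um apart (6 px): rings truncate at the midline, disjoint
  img2 <- mk(list(c(60, 54), c(60, 72)), r = 5)
  d2 <- detect_nuclei(img2, detection_params(150, sigma_px = 0))
  expect_equal(nrow(d2$table), 2)
  e <- expand_cells(d2, 2)
  a1 <- sum(e$cell_labels == 1); a2 <- sum(e$cell_labels == 2)
  iso <- sum(expand_cells(d2, 2)$table$cell_area_um2) / 0.25
  # each truncated cell is smaller than the free annulus of its own nucleus
  free1 <- pi * ((sqrt(sum(d2$nucleus_labels == 1) / pi)) + 2 / 0.5)^2
  expect_lt(a1, free1)
  expect_false(any(e$cell_labels == 1 & e$cell_labels == 2))
})

test_that("intensity means are computed on raw values and match the oracle", {
  n <- 60; s <- 0.5
  dapi <- matrix(20, n, n)
  d <- sqrt(outer((seq_len(n) - 30)^2, (seq_len(n) - 30)^2, "+"))
  dapi <- dapi + 600 * (d <= 6)
  half <- matrix(rep(c(100, 300), each = n * n / 2), n, n)  # left/right halves
  img <- section_image(list(DAPI = dapi, DsRed = half,
                            GFP = matrix(42, n, n)), s)
  dets <- detect_cells(img, detection_params(150, sigma_px = 0))
  expect_equal(nrow(dets$table), 1)
  expect_equal(dets$table$GFP_cell, 42)
  expect_equal(dets$table$GFP_nucleus, 42)
  # straddling the half-bright boundary: mean is the midpoint, and exactly
  # the per-pixel oracle value
  expect_equal(dets$table$DsRed_nucleus,
               label_mean_oracle(dets$nucleus_labels, half, 1))
  expect_equal(dets$table$DsRed_cell,
               label_mean_oracle(dets$cell_labels, half, 1))
  expect_equal(dets$table$DsRed_nucleus, 200, tolerance = 0.1)

  # marker in the ring only: cell mean exceeds nucleus mean
  ring <- matrix(100, n, n)
  ring[d > 6 & d <= 10] <- 500
  img$channels$DsRed <- ring
  dets2 <- measure_intensities(dets, img)
  expect_gt(dets2$table$DsRed_cell, dets2$table$DsRed_nucleus)
})

test_that("detections stay inside the mask and are deterministic", {
  gen <- small_section()
  tissue <- detect_tissue(gen$image, small_tissue_params())
  clean <- mask_subtract(tissue, detect_vessels(gen$image))
  d1 <- detect_cells(gen$image, detection_params(150), clean)
  d2 <- detect_cells(gen$image, detection_params(150), clean)
  expect_identical(d1$table, d2$table)
  expect_identical(d1$cell_labels, d2$cell_labels)
  s <- d1$pixel_size_um
  rr <- floor(d1$table$y_um / s) + 1
  cc <- floor(d1$table$x_um / s) + 1
  expect_true(all(clean$mask[cbind(rr, cc)]))
  # nucleus area bounds hold
  expect_true(all(d1$table$nucleus_area_um2 >= 10 &
                  d1$table$nucleus_area_um2 <= 400))
  # marker-positive counts are non-increasing in the threshold
  counts <- vapply(seq(100, 600, by = 50),
                   function(t) positive_count(d1, "DsRed", t), 0)
  expect_true(all(diff(counts) <= 0))
})
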