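flat_image <- function(v, n = 100, s = 1) {
  section_image(list(DAPI = matrix(v[1], n, n), DsRed = matrix(v[2], n, n),
                     GFP = matrix(v[3], n, n)), s)
}

test_that("a uniformly dim image yields an empty tissue mask", {
  img <- flat_image(c(10, 10, 10))
  expect_warning(m <- detect_tissue(img, mask_params(min_area_um2 = 100,
                                                     erode_um = 0,
                                                     min_fragment_um2 = 0)),
                 "empty")
  expect_false(any(m$mask))
})

test_that("erosion shortens a solid bright square by twice the radius", {
  n <- 400; s <- 1
  ch <- matrix(0, n, n)
  ch[51:350, 51:350] <- 100  # 300 x 300 um square
  img <- section_image(list(DAPI = ch, DsRed = ch, GFP = ch), s)
  m <- detect_tissue(img, mask_params(threshold = 50, min_area_um2 = 1e4,
                                      min_hole_um2 = 0, erode_um = 40,
                                      min_fragment_um2 = 0))
  idx <- which(m$mask, arr.ind = TRUE)
  side_r <- diff(range(idx[, 1])) + 1
  side_c <- diff(range(idx[, 2])) + 1
  expect_lte(abs(side_r - (300 - 80)), 2)
  expect_lte(abs(side_c - (300 - 80)), 2)
})

test_that("components below the minimum area are removed", {
  n <- 1000; s <- 1
  ch <- matrix(0, n, n)
  # ~500,000 um^2 bright square (707 x 707) with the 1,000,000 um^2 floor
  ch[100:806, 100:806] <- 200
  img <- section_image(list(DAPI = ch, DsRed = ch, GFP = ch), s)
  expect_warning(m <- detect_tissue(img, mask_params(erode_um = 0,
                                                     min_fragment_um2 = 0)),
                 "empty")
  expect_false(any(m$mask))
})

test_that("vessel detection keeps a wide bright stripe and drops specks", {
  n <- 200; s <- 1
  ds <- matrix(0, n, n)
  ds[, 91:110] <- 1500                    # 20 um wide stripe
  img <- section_image(list(DAPI = ds * 0, DsRed = ds, GFP = ds * 0), s)
  m <- detect_vessels(img)
  expect_true(all(m$mask[, 100]))
  expect_false(any(m$mask[, 1:70]))

  blob <- matrix(0, n, n)
  blob[100:109, 100:109] <- 1500          # 100 um^2 < 150 um^2 floor
  img2 <- section_image(list(DAPI = blob * 0, DsRed = blob, GFP = blob * 0), s)
  expect_warning(m2 <- detect_vessels(img2), "empty")
  expect_false(any(m2$mask))

  expect_warning(m3 <- detect_vessels(flat_image(c(0, 300, 0))), "empty")
  expect_false(any(m3$mask))
})

test_that("mask subtraction and intersection match per-pixel oracles", {
  set.seed(5)
  a <- matrix(runif(64 * 64) > 0.4, 64, 64)
  b <- matrix(runif(64 * 64) > 0.6, 64, 64)
  ma <- binary_mask(a, 1); mb <- binary_mask(b, 1)
  sub <- mask_subtract(ma, mb)
  expect_identical(sub$mask, subtract_oracle(a, b))
  # b empty leaves a unchanged; subtracting a from itself empties it
  expect_identical(mask_subtract(ma, binary_mask(a & FALSE, 1))$mask, a)
  expect_false(any(mask_subtract(ma, ma)$mask))
  # area identity
  expect_equal(sum(sub$mask), sum(a) - sum(a & b))
  expect_error(mask_subtract(ma, binary_mask(matrix(TRUE, 3, 3), 1)),
               "shapes differ")
})

test_that("erosion matches the brute-force structuring-element oracle", {
  set.seed(9)
  base <- matrix(FALSE, 64, 64)
  base[10:50, 8:40] <- TRUE
  base[20:30, 45:60] <- TRUE
  img <- section_image(list(DAPI = base * 100, DsRed = base * 100,
                            GFP = base * 100), 1)
  for (r in c(2, 3.5)) {
    m <- detect_tissue(img, mask_params(sigma_px = 0, threshold = 50,
                                        min_area_um2 = 0, min_hole_um2 = 0,
                                        erode_um = r, min_fragment_um2 = 0))
    expect_identical(m$mask, erode_oracle(base, r))
  }
})

test_that("region intersection respects polygon area and disjointness", {
  tissue <- binary_mask(matrix(TRUE, 100, 100), 1)
  regions <- annotation_set(list(
    list(name = "left", role = "region", parts = rect_polygon(10, 10, 30, 60)),
    list(name = "right", role = "region",
         parts = rect_polygon(55, 10, 30, 60))), pixel_size_um = 1)
  rm <- intersect_regions(tissue, regions)
  expect_equal(sum(rm$left$mask), 30 * 60)
  expect_false(any(rm$left$mask & rm$right$mask))
  expect_identical(rm$left$mask,
                   intersect_oracle(tissue$mask,
                                    rasterize_polygon(rect_polygon(10, 10, 30, 60),
                                                      c(100, 100))))
  # region fully outside the tissue mask is empty
  empty_tissue <- binary_mask(matrix(FALSE, 100, 100), 1)
  expect_false(any(intersect_regions(empty_tissue, regions)$left$mask))
  expect_error(intersect_regions(tissue, regions, names = "midbrain"),
               "unknown region")
})

test_that("hole filling only adds pixels strictly inside components", {
  n <- 120
  ch <- matrix(0, n, n)
  ch[11:110, 11:110] <- 100
  ch[41:45, 41:45] <- 0      # 25 um^2 hole: filled (< 1000)
  ch[60:99, 60:99] <- 0      # 1600 um^2 hole: kept (>= 1000)
  img <- section_image(list(DAPI = ch, DsRed = ch, GFP = ch), 1)
  m <- detect_tissue(img, mask_params(sigma_px = 0, threshold = 50,
                                      min_area_um2 = 100, min_hole_um2 = 1000,
                                      erode_um = 0, min_fragment_um2 = 0))
  expect_true(all(m$mask[41:45, 41:45]))
  expect_false(any(m$mask[65:95, 65:95]))
  # cleanup stages never add pixels outside the thresholded component
  expect_false(any(m$mask & ch < 50 &
                   !(row(ch) %in% 41:45 & col(ch) %in% 41:45)))
})
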