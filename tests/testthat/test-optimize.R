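test_that("percent difference follows the (Ac - Mc) / Mc convention", {
  expect_identical(percent_difference(100, 100), 0)
  expect_equal(percent_difference(0, 10), -100)
  expect_equal(percent_difference(120, 100), 20)
  expect_error(percent_difference(5, 0), "> 0")
  # linear in ac, antisymmetric about mc
  set.seed(3)
  mc <- sample(10:200, 20)
  a <- sample(0:300, 20)
  b <- sample(0:300, 20)
  w <- runif(20)
  expect_equal(percent_difference(w * a + (1 - w) * b, mc),
               w * percent_difference(a, mc) +
                 (1 - w) * percent_difference(b, mc))
  delta <- sample(1:9, 20, TRUE)
  expect_equal(percent_difference(mc + delta, mc),
               -percent_difference(mc - delta, mc))
})

fake_sweep <- function(value, mean_pct, sd_pct, n = 8) {
  structure(list(parameter = "classifier.dsred_threshold", channel = "DsRed",
                 grid = value,
                 table = data.frame(value = value, mean_pct = mean_pct,
                                    sd_pct = sd_pct, n = n)),
            class = "sweep_result")
}

test_that("optimum selection ranks by accuracy, SD, then undercounting", {
  # |mean| tie broken by smaller SD
  r <- fake_sweep(c(100, 125), c(-2, 2), c(5, 15))
  expect_equal(select_optimum(r)$value, 100)
  # |mean| and SD tie: prefer the undercounting (non-positive) mean
  r <- fake_sweep(c(150, 175), c(-1, 1), c(4, 4))
  expect_equal(select_optimum(r)$value, 150)
  # full tie: larger threshold wins
  r <- fake_sweep(c(200, 225), c(0, 0), c(0, 0))
  expect_equal(select_optimum(r)$value, 225)
  # single candidate returns itself; empty result errors
  expect_equal(select_optimum(fake_sweep(300, -4, 2))$value, 300)
  expect_error(select_optimum(fake_sweep(300, NA_real_, NA_real_, n = 0)),
               "no scored")
  # the audit ranking covers the whole grid
  r <- fake_sweep(c(1, 2, 3), c(5, -1, 0), c(1, 1, 1))
  opt <- select_optimum(r)
  expect_equal(opt$ranking$value, c(3, 2, 1))
})

test_that("pooled optimum minimizes the worst case across sub-regions", {
  grid <- c(50, 75, 100)
  sub1 <- fake_sweep(grid, c(0, -1, -8), c(1, 1, 1))
  sub2 <- fake_sweep(grid, c(-8, -1, 0), c(1, 1, 1))
  expect_equal(pooled_region_optimum(list(sub1, sub2))$value, 75)
  # identical curves reduce to the single-sweep answer
  expect_equal(pooled_region_optimum(list(sub1, sub1))$value,
               select_optimum(sub1)$value)
  # disjoint near-zero windows: the minimax value is still returned
  sub3 <- fake_sweep(grid, c(0, -60, -100), c(1, 1, 1))
  sub4 <- fake_sweep(grid, c(-100, -60, 0), c(1, 1, 1))
  expect_equal(pooled_region_optimum(list(sub3, sub4))$value, 75)
  expect_error(pooled_region_optimum(list(sub1, fake_sweep(c(1, 2), 0, 0))),
               "common grid")
})

test_that("a sweep over synthetic annotations scores the grid correctly", {
  gen <- small_section()
  clean <- mask_subtract(detect_tissue(gen$image, small_tissue_params()),
                         detect_vessels(gen$image))
  rects <- test_rect_table(
    generate_test_annotations(gen$annotations, c(250, 200), seed = 3),
    section = "s1")
  images <- list(s1 = gen$image); masks <- list(s1 = clean)
  base <- list(detection = detection_params(150))
  # first pass to obtain the automated counts at a mid-gap threshold
  gt_mc <- sapply(seq_len(nrow(rects)), function(k) {
    ground_truth_counts(gen$cells,
                        rect_polygon(rects$x_um[k], rects$y_um[k],
                                     rects$w_um[k], rects$h_um[k]))[["dsred"]]
  })
  spec_full <- sweep_spec("classifier.dsred_threshold", c(250, 550),
                          step = 100, channel = "DsRed",
                          annotations = rects, manual_counts = pmax(gt_mc, 1))
  res <- run_sweep(spec_full, images, masks, base)
  expect_equal(dim(res$ac), c(4, nrow(rects)))
  # positive counts (hence mean % difference) are non-increasing in the
  # threshold, and every positive is gone above the foreground ceiling
  expect_true(all(diff(res$table$mean_pct) <= 1e-9))
  expect_equal(unname(res$ac[4, ]), rep(0, nrow(rects)))

  # a one-value sweep with manual counts equal to the automated counts
  # scores mean 0 with SD 0
  ac0 <- res$ac[1, ]
  keep <- which(ac0 > 0)
  expect_gte(length(keep), 1)  # the thalamus rectangle always holds pericytes
  res0 <- run_sweep(sweep_spec("classifier.dsred_threshold", 250,
                               channel = "DsRed",
                               annotations = rects[keep, , drop = FALSE],
                               manual_counts = ac0[keep]),
                    images, masks, base)
  expect_equal(res0$table$mean_pct, 0)
  expect_equal(res0$table$sd_pct, 0)

  # an annotation with a zero manual count is excluded with a warning
  bad_mc <- pmax(gt_mc, 1)
  bad_mc[1] <- 0
  expect_warning(
    res2 <- run_sweep(sweep_spec("classifier.dsred_threshold", c(250, 275),
                                 step = 25, channel = "DsRed",
                                 annotations = rects,
                                 manual_counts = bad_mc),
                      images, masks, base),
    "excluded")
  expect_true(all(is.na(res2$pct[, 1])))
  expect_equal(res2$table$n[1], nrow(rects) - 1)
})
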