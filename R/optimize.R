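# Grid sweeps of detection / classification parameters scored against manual
# counts with the percent-difference metric, and optimum selection by the
# accuracy / variability / undercounting-preference rule.

#' Percent difference between automated and manual counts
#'
#' `((ac - mc) / mc) * 100`: 0 when the counts agree, positive for
#' overcounting, negative for undercounting; -100 when nothing is detected.
#' Exactly linear in `ac` and antisymmetric about `mc`.
#'
#' @param ac automated count(s); @param mc manual count(s), must be > 0.
#' @return numeric percent difference (vectorized).
#' @export
percent_difference <- function(ac, mc) {
  if (any(mc <= 0)) stop("manual count must be > 0 to compute a % difference")
  (ac - mc) / mc * 100
}

#' Specification of a one-parameter grid sweep
#'
#' @param parameter parameter path: `"detection.threshold"` (or any other
#'   `detection.<field>` of [detection_params()]),
#'   `"classifier.dsred_threshold"` or `"classifier.gfp_threshold"`.
#' @param grid numeric vector of values, or `c(start, stop)` with `step`.
#' @param step optional step turning `grid = c(start, stop)` into a sequence.
#' @param channel counted channel: `"DAPI"` (total detections), `"DsRed"` or
#'   `"GFP"` (marker-positive detections).
#' @param annotations data.frame with columns
#'   `section, region, x_um, y_um, w_um, h_um` — one test rectangle per row
#'   (see [test_rect_table()]).
#' @param manual_counts numeric vector, one manual count per annotation row.
#' @return object of class `sweep_spec`.
#' @export
sweep_spec <- function(parameter, grid, step = NULL, channel = "DAPI",
                       annotations, manual_counts) {
  if (!is.null(step)) {
    stopifnot(step > 0, length(grid) == 2)
    grid <- seq(grid[1], grid[2], by = step)
  }
  stopifnot(length(grid) >= 1, !anyDuplicated(grid))
  if (nrow(annotations) != length(manual_counts)) {
    stop("every annotation needs a manual count")
  }
  need <- c("section", "region", "x_um", "y_um", "w_um", "h_um")
  stopifnot(all(need %in% names(annotations)))
  kind <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  if (length(kind) != 2 || !kind[1] %in% c("detection", "classifier")) {
    stop("parameter must be 'detection.<field>' or 'classifier.<field>'")
  }
  structure(list(parameter = parameter, grid = sort(grid), channel = channel,
                 annotations = annotations,
                 manual_counts = as.numeric(manual_counts)),
            class = "sweep_spec")
}

#' Run a parameter sweep against manual counts
#'
#' For every grid value the detection (and, for classifier sweeps,
#' classification) pipeline is run inside each test annotation with only the
#' swept parameter changed, the automated count is compared with the manual
#' count via [percent_difference()], and the per-value mean and sample SD
#' across annotations are recorded. Detections are computed once and cached
#' when only classification thresholds change. Annotations with a manual
#' count of 0 are excluded with a warning.
#'
#' @param spec a [sweep_spec()].
#' @param images named list of `section_image` objects (by section id), or a
#'   function `function(section_id)` returning one.
#' @param masks optional named list of `binary_mask` objects restricting
#'   detection (tissue minus vessels), by section id.
#' @param base_params list with element `detection` (a [detection_params()])
#'   giving the non-swept parameter values.
#' @param margin_um context margin cropped around each annotation so border
#'   cells are detected with their surroundings (default 10).
#' @return object of class `sweep_result`: `table` (value, mean_pct, sd_pct,
#'   n), matrices `ac` and `pct` (grid values x annotations), `mc`, and the
#'   spec fields.
#' @export
run_sweep <- function(spec, images, masks = NULL,
                      base_params = list(detection = detection_params(100)),
                      margin_um = 10) {
  ann <- spec$annotations
  mc <- spec$manual_counts
  usable <- mc > 0
  if (any(!usable)) {
    warning(sum(!usable), " annotation(s) with manual count 0 excluded ",
            "from the sweep")
  }
  get_image <- if (is.function(images)) images else function(id) {
    if (is.null(images[[id]])) stop("no image for section '", id, "'")
    images[[id]]
  }
  kind <- strsplit(spec$parameter, ".", fixed = TRUE)[[1]]
  values <- spec$grid
  n_ann <- nrow(ann)
  ac <- matrix(NA_real_, length(values), n_ann,
               dimnames = list(values, paste(ann$section, ann$region,
                                             sep = "/")))
  for (j in seq_len(n_ann)) {
    if (!usable[j]) next
    img <- get_image(ann$section[j])
    cr <- crop_section(img, ann$x_um[j] - margin_um, ann$y_um[j] - margin_um,
                       ann$w_um[j] + 2 * margin_um, ann$h_um[j] + 2 * margin_um)
    sub <- cr$image; orig <- cr$origin_um
    within <- NULL
    if (!is.null(masks) && !is.null(masks[[ann$section[j]]])) {
      full <- masks[[ann$section[j]]]
      d <- dim(sub); s <- sub$pixel_size_um
      r0 <- round(orig["y"] / s); c0 <- round(orig["x"] / s)
      within <- binary_mask(full$mask[r0 + seq_len(d[1]), c0 + seq_len(d[2]),
                                      drop = FALSE], s)
    }
    in_rect <- function(tab) {
      point_in_rect(tab$x_um + orig["x"], tab$y_um + orig["y"],
                    ann$x_um[j], ann$y_um[j], ann$w_um[j], ann$h_um[j])
    }
    if (kind[1] == "classifier") {
      dets <- tryCatch(detect_cells(sub, base_params$detection, within),
                       error = function(e) {
                         warning("detection failed for annotation ", j, ": ",
                                 conditionMessage(e))
                         NULL
                       })
      if (is.null(dets)) next
      tab <- dets$table[in_rect(dets$table), , drop = FALSE]
      chan <- switch(kind[2], dsred_threshold = "DsRed",
                     gfp_threshold = "GFP",
                     stop("unknown classifier field: ", kind[2]))
      if (spec$channel != chan) {
        stop("channel '", spec$channel, "' does not match swept parameter '",
             spec$parameter, "'")
      }
      for (i in seq_along(values)) {
        ac[i, j] <- positive_count(tab, chan, values[i])
      }
    } else {
      for (i in seq_along(values)) {
        p <- base_params$detection
        if (!kind[2] %in% names(p)) {
          stop("unknown detection field: ", kind[2])
        }
        p[[kind[2]]] <- values[i]
        dets <- tryCatch(detect_nuclei(sub, p, within),
                         error = function(e) {
                           warning("detection failed for annotation ", j,
                                   " at value ", values[i], ": ",
                                   conditionMessage(e))
                           NULL
                         })
        if (is.null(dets)) next
        ac[i, j] <- sum(in_rect(dets$table))
      }
    }
  }
  pct <- sweep_pct_matrix(ac, mc, usable)
  tabl <- data.frame(
    value = values,
    mean_pct = apply(pct, 1, function(r) if (all(is.na(r))) NA_real_
                     else mean(r, na.rm = TRUE)),
    sd_pct = apply(pct, 1, function(r) if (sum(!is.na(r)) < 2) NA_real_
                   else sd(r, na.rm = TRUE)),
    n = apply(pct, 1, function(r) sum(!is.na(r))))
  structure(list(parameter = spec$parameter, channel = spec$channel,
                 grid = values, ac = ac, pct = pct, mc = mc,
                 annotations = ann, table = tabl),
            class = "sweep_result")
}

sweep_pct_matrix <- function(ac, mc, usable) {
  pct <- ac
  for (j in seq_along(mc)) {
    pct[, j] <- if (usable[j]) (ac[, j] - mc[j]) / mc[j] * 100 else NA_real_
  }
  pct
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s (%s), %d grid values x %d annotation(s)\n",
              x$parameter, x$channel, length(x$grid), nrow(x$annotations)))
  print(head(x$table, 4))
  cat("...\n")
  invisible(x)
}

#' Plot a sweep curve (mean percent difference +/- SD)
#' @param x a `sweep_result`; @param ... passed to [graphics::plot()].
#' @export
plot.sweep_result <- function(x, ...) {
  t <- x$table
  plot(t$value, t$mean_pct, type = "b", pch = 16,
       xlab = paste0(x$parameter, " (", x$channel, ")"),
       ylab = "% difference vs manual counts", ...)
  ok <- !is.na(t$sd_pct)
  if (any(ok)) {
    arrows(t$value[ok], t$mean_pct[ok] - t$sd_pct[ok], t$value[ok],
           t$mean_pct[ok] + t$sd_pct[ok], angle = 90, code = 3, length = 0.02)
  }
  abline(h = 0, lty = 3)
  invisible(x)
}

optimum_order <- function(mean_pct, sd_pct, value, eps = 1e-9) {
  # lexicographic: |mean|, then SD, then prefer mean <= 0, then larger value
  sd0 <- ifelse(is.na(sd_pct), Inf, sd_pct)
  order(round(abs(mean_pct) / eps) * eps,
        round(sd0 / eps) * eps,
        mean_pct > eps,
        -value)
}

#' Select the optimal grid value from a sweep
#'
#' Codified selection rule: (1) smallest absolute mean percent difference
#' (greatest accuracy); (2) ties by smallest SD (least variability);
#' (3) ties prefer a non-positive mean (undercounting over overcounting);
#' (4) remaining ties take the larger threshold. Returned with the full
#' ranking for audit.
#'
#' @param result a `sweep_result`.
#' @return list with `value` (the optimum) and `ranking` (the scored table,
#'   best first), of class `sweep_optimum`.
#' @export
select_optimum <- function(result) {
  t <- result$table[result$table$n > 0 & !is.na(result$table$mean_pct), ,
                    drop = FALSE]
  if (nrow(t) == 0) stop("sweep contains no scored grid values")
  ord <- optimum_order(t$mean_pct, t$sd_pct, t$value)
  ranking <- t[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(value = ranking$value[1], ranking = ranking,
                 parameter = result$parameter, channel = result$channel),
            class = "sweep_optimum")
}

#' @export
print.sweep_optimum <- function(x, ...) {
  cat(sprintf("<sweep_optimum> %s (%s): %g\n", x$parameter, x$channel,
              x$value))
  print(head(x$ranking, 3))
  invisible(x)
}

#' Pooled optimum across sub-region sweeps
#'
#' When one threshold must serve several sub-regions (e.g. dentate gyrus and
#' CA1/CA3 pooled into a whole-hippocampus threshold), selects the grid value
#' minimizing the worst-case absolute mean percent difference across the
#' sub-regions; ties are broken as in [select_optimum()] using the worst-case
#' SD and worst-case mean.
#'
#' @param results list of >= 2 `sweep_result` objects over a common grid.
#' @return a `sweep_optimum`; its ranking carries the worst-case columns.
#' @export
pooled_region_optimum <- function(results) {
  stopifnot(length(results) >= 2)
  grids <- lapply(results, `[[`, "grid")
  if (!all(vapply(grids, identical, TRUE, grids[[1]]))) {
    stop("sub-region sweeps must share a common grid")
  }
  means <- sapply(results, function(r) r$table$mean_pct)
  sds <- sapply(results, function(r) r$table$sd_pct)
  worst_abs <- apply(abs(means), 1, max)
  worst_sd <- apply(sds, 1, function(r) if (all(is.na(r))) NA_real_
                    else max(r, na.rm = TRUE))
  worst_mean <- apply(means, 1, max)
  ok <- !is.na(worst_abs)
  if (!any(ok)) stop("sweep contains no scored grid values")
  t <- data.frame(value = grids[[1]], mean_pct = worst_mean,
                  sd_pct = worst_sd,
                  n = apply(sapply(results, function(r) r$table$n), 1, min))[ok, ]
  ord <- optimum_order(worst_abs[ok], t$sd_pct, t$value)
  ranking <- t[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(value = ranking$value[1], ranking = ranking,
                 parameter = results[[1]]$parameter,
                 channel = results[[1]]$channel),
            class = "sweep_optimum")
}

#' Export a sweep report as CSV
#'
#' One row per (grid value, annotation): automated count, manual count,
#' percent difference, plus the per-value mean and SD.
#'
#' @param result a `sweep_result`; @param path output CSV.
#' @export
write_sweep_report <- function(result, path) {
  ann <- result$annotations
  rows <- do.call(rbind, lapply(seq_along(result$grid), function(i) {
    data.frame(value = result$grid[i], section = ann$section,
               region = ann$region, ac = result$ac[i, ], mc = result$mc,
               pct_diff = result$pct[i, ],
               mean_pct = result$table$mean_pct[i],
               sd_pct = result$table$sd_pct[i])
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
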