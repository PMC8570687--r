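# Per-region quantification (counts, percentages, densities) and
# cross-section summaries.

quant_columns <- function() {
  c("section", "region", "area_mm2", "n_total", "n_dsred", "n_gfp", "n_dual",
    "n_negative", "pct_dsred", "pct_gfp", "pct_dual", "pct_negative",
    "per_mm2_total", "per_mm2_dsred", "per_mm2_gfp", "per_mm2_dual",
    "per_mm2_negative", "flagged")
}

#' Quantify classified detections inside a region mask
#'
#' Region area comes from the mask pixel count times the squared pixel size;
#' detections are counted when their nucleus centroid lies inside the mask.
#' Percentages are per class out of all detections (dual-positives included
#' in the denominator); densities are per mm^2 of masked tissue.
#'
#' @param dets a classified `cell_detections`.
#' @param region_mask a non-empty `binary_mask` (tissue AND region).
#' @param section,region identifiers recorded in the output row.
#' @return one-row data.frame with count, percentage and density columns;
#'   `flagged` is `TRUE` when the region contained no detections (all
#'   percentages reported as 0).
#' @export
quantify_region <- function(dets, region_mask, section = "section1",
                            region = "region") {
  if (!any(region_mask$mask)) stop("region mask is empty")
  tab <- dets$table
  if (nrow(tab) && anyNA(tab$class)) {
    stop("unclassified detections present: run classify_cells() first")
  }
  inside <- if (nrow(tab)) centroid_in_mask(tab$x_um, tab$y_um, region_mask)
            else logical(0)
  counts <- class_counts(tab[inside, , drop = FALSE])
  area <- mask_area_mm2(region_mask)
  total <- counts[["n_total"]]
  flagged <- total == 0
  pct <- if (flagged) rep(0, 4) else
    100 * counts[c("n_dsred", "n_gfp", "n_dual", "n_negative")] / total
  out <- data.frame(
    section = section, region = region, area_mm2 = area,
    n_total = total, n_dsred = counts[["n_dsred"]], n_gfp = counts[["n_gfp"]],
    n_dual = counts[["n_dual"]], n_negative = counts[["n_negative"]],
    pct_dsred = pct[1], pct_gfp = pct[2], pct_dual = pct[3],
    pct_negative = pct[4],
    per_mm2_total = total / area, per_mm2_dsred = counts[["n_dsred"]] / area,
    per_mm2_gfp = counts[["n_gfp"]] / area,
    per_mm2_dual = counts[["n_dual"]] / area,
    per_mm2_negative = counts[["n_negative"]] / area,
    flagged = flagged, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize quantifications across sections
#'
#' Per-region mean and sample SD of every metric across sections, plus an
#' `"all"` row computed by first pooling counts over the analyzed regions of
#' each section (so overall class percentages are the mean across sections
#' of per-section pooled percentages) and then averaging across sections.
#'
#' @param quants data.frame of [quantify_region()] rows (several sections).
#' @return long-format data.frame: `region, metric, mean, sd, n` (`sd` is
#'   `NA` for a single section).
#' @export
summarize_quantifications <- function(quants) {
  stopifnot(nrow(quants) >= 1)
  metrics <- c("area_mm2", "n_total", "pct_dsred", "pct_gfp", "pct_dual",
               "pct_negative", "per_mm2_total", "per_mm2_dsred",
               "per_mm2_gfp")
  pooled <- do.call(rbind, lapply(split(quants, quants$section), function(q) {
    area <- sum(q$area_mm2)
    tot <- sum(q$n_total)
    data.frame(
      section = q$section[1], region = "all", area_mm2 = area, n_total = tot,
      pct_dsred = if (tot) 100 * sum(q$n_dsred) / tot else 0,
      pct_gfp = if (tot) 100 * sum(q$n_gfp) / tot else 0,
      pct_dual = if (tot) 100 * sum(q$n_dual) / tot else 0,
      pct_negative = if (tot) 100 * sum(q$n_negative) / tot else 0,
      per_mm2_total = tot / area,
      per_mm2_dsred = sum(q$n_dsred) / area,
      per_mm2_gfp = sum(q$n_gfp) / area, stringsAsFactors = FALSE)
  }))
  blocks <- c(split(quants, quants$region), list(all = pooled))
  rows <- lapply(names(blocks), function(reg) {
    b <- blocks[[reg]]
    do.call(rbind, lapply(metrics, function(m) {
      v <- b[[m]]
      data.frame(region = reg, metric = m, mean = mean(v),
                 sd = if (length(v) >= 2) sd(v) else NA_real_,
                 n = length(v), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write per-region measurements as CSV
#'
#' One row per (section, region) with areas, counts, percentages and
#' densities; an empty input yields a header-only file.
#'
#' @param quants data.frame of [quantify_region()] rows (possibly empty or a
#'   zero-row data.frame).
#' @param path output CSV path.
#' @export
write_measurements <- function(quants, path) {
  if (is.null(quants) || nrow(as.data.frame(quants)) == 0) {
    empty <- as.data.frame(setNames(rep(list(numeric(0)),
                                        length(quant_columns())),
                                    quant_columns()))
    write.csv(empty, path, row.names = FALSE)
    return(invisible(path))
  }
  quants <- as.data.frame(quants)[, quant_columns()]
  write.csv(quants, path, row.names = FALSE)
  invisible(path)
}
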