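# Four-way classification of detections from per-channel cell-mean
# intensities. Positivity is inclusive (>=); the partition
# {DSRED_POS, GFP_POS, DUAL, NEGATIVE} is exhaustive and exclusive. Dual
# detections are tallied separately and excluded from the pericyte and
# microglia counts.

CELL_CLASSES <- c("DSRED_POS", "GFP_POS", "DUAL", "NEGATIVE")

#' Per-region classifier thresholds
#'
#' @param dsred_threshold,gfp_threshold cell-mean intensity thresholds
#'   (inclusive).
#' @param region optional region name the thresholds were optimized for.
#' @return object of class `classifier_params`.
#' @export
classifier_params <- function(dsred_threshold, gfp_threshold, region = NULL) {
  stopifnot(dsred_threshold >= 0, gfp_threshold >= 0)
  structure(list(region = region, dsred_threshold = dsred_threshold,
                 gfp_threshold = gfp_threshold), class = "classifier_params")
}

#' Read / write classifier parameter files (JSON keyed by region)
#'
#' The on-disk format is a JSON object mapping region names to
#' `{"dsred_threshold": ..., "gfp_threshold": ...}`.
#'
#' @param path JSON file.
#' @return named list of `classifier_params`.
#' @export
read_classifiers <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(raw), function(nm) {
    classifier_params(raw[[nm]]$dsred_threshold, raw[[nm]]$gfp_threshold,
                      region = nm)
  })
  setNames(out, names(raw))
}

#' @rdname read_classifiers
#' @param classifiers named list of `classifier_params`.
#' @export
write_classifiers <- function(classifiers, path) {
  out <- lapply(classifiers, function(p) {
    list(dsred_threshold = p$dsred_threshold, gfp_threshold = p$gfp_threshold)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Classify detections by cell-mean intensity thresholds
#'
#' A detection is DsRed-positive iff its DsRed cell mean is `>=`
#' `dsred_threshold` (GFP analogously); positivity in both channels gives
#' `DUAL`, in neither `NEGATIVE`.
#'
#' @param dets a measured `cell_detections`.
#' @param params a [classifier_params()].
#' @return the `cell_detections` with the `class` column set.
#' @export
classify_cells <- function(dets, params) {
  tab <- dets$table
  if (nrow(tab) == 0) return(dets)
  if (is.null(tab$DsRed_cell) || is.null(tab$GFP_cell) ||
      anyNA(tab$DsRed_cell) || anyNA(tab$GFP_cell)) {
    stop("cell-mean intensities missing: run measure_intensities() first")
  }
  dp <- tab$DsRed_cell >= params$dsred_threshold
  gp <- tab$GFP_cell >= params$gfp_threshold
  cls <- ifelse(dp & gp, "DUAL",
         ifelse(dp, "DSRED_POS",
         ifelse(gp, "GFP_POS", "NEGATIVE")))
  stopifnot(all(cls %in% CELL_CLASSES))
  dets$table$class <- cls
  dets
}

#' Count detections per class
#'
#' @param dets a classified `cell_detections` (or its table).
#' @return named integer vector
#'   `c(n_total, n_dsred, n_gfp, n_dual, n_negative)`; always satisfies
#'   `n_total == n_dsred + n_gfp + n_dual + n_negative`.
#' @export
class_counts <- function(dets) {
  tab <- if (inherits(dets, "cell_detections")) dets$table else dets
  if (nrow(tab) && anyNA(tab$class)) {
    stop("unclassified detections present: run classify_cells() first")
  }
  n <- c(n_total = nrow(tab),
         n_dsred = sum(tab$class == "DSRED_POS"),
         n_gfp = sum(tab$class == "GFP_POS"),
         n_dual = sum(tab$class == "DUAL"),
         n_negative = sum(tab$class == "NEGATIVE"))
  stopifnot(n[["n_total"]] ==
              sum(n[c("n_dsred", "n_gfp", "n_dual", "n_negative")]))
  n
}

#' Count marker-positive detections at a threshold
#'
#' Single-channel positivity (`cell mean >= threshold`) irrespective of the
#' other channel — the quantity compared against manual marker counts during
#' threshold sweeps. Non-increasing in the threshold.
#'
#' @param dets measured `cell_detections` (or table).
#' @param channel `"DsRed"` or `"GFP"`.
#' @param threshold intensity threshold (inclusive).
#' @return integer count.
#' @export
positive_count <- function(dets, channel, threshold) {
  tab <- if (inherits(dets, "cell_detections")) dets$table else dets
  col <- paste0(channel, "_cell")
  if (is.null(tab[[col]])) stop("no cell means for channel ", channel)
  sum(tab[[col]] >= threshold)
}
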