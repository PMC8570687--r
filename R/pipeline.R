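# End-to-end orchestration: generate (or load) sections, mask, detect,
# classify or optimize, quantify — from one configuration, with per-stage
# seed substreams and a reproducible artifact manifest.

#' Assemble a pipeline run configuration
#'
#' Either supply `synthetic` (a [section_config()] used as the template for
#' `n_sections` sections, seeded `seed + 1 .. seed + n`) or `sections`
#' (named character vector of TIFF paths). Per region supply either fixed
#' classifier thresholds (`classifiers`) or a sweep request (`optimize`),
#' never both.
#'
#' @param out_dir output directory (created if needed).
#' @param synthetic optional [section_config()] template.
#' @param n_sections number of synthetic sections to generate.
#' @param sections optional named vector of TIFF paths (alternative input).
#' @param annotations optional path to a region GeoJSON (required with
#'   `sections`; synthetic runs carry their own regions).
#' @param tissue,vessels [mask_params()] for the two pixel classifiers.
#' @param detection a [detection_params()]; its `threshold` is replaced by
#'   per-region optima when `optimize` is active.
#' @param classifiers named list (by region) of [classifier_params()].
#' @param optimize `NULL`, or a list with `dapi_grid`, `dsred_grid`,
#'   `gfp_grid` (each `c(start, stop, step)`) and `test_rect_um`
#'   (`c(w, h)`); thresholds are then recovered per region from sweeps
#'   against the synthetic ground truth.
#' @param seed integer master seed; stage substreams are derived from it.
#' @return validated `run_config` list.
#' @export
run_config <- function(out_dir, synthetic = NULL, n_sections = 2,
                       sections = NULL, annotations = NULL,
                       tissue = mask_params(), vessels = vessel_params(),
                       detection = detection_params(150),
                       classifiers = NULL, optimize = NULL, seed = 1L) {
  if (is.null(synthetic) == is.null(sections)) {
    stop("supply exactly one of 'synthetic' or 'sections'")
  }
  if (!is.null(classifiers) && !is.null(optimize)) {
    stop("supply per-region 'classifiers' or an 'optimize' request, not both")
  }
  if (is.null(classifiers) && is.null(optimize)) {
    stop("supply per-region 'classifiers' or an 'optimize' request")
  }
  if (!is.null(sections) && is.null(annotations)) {
    stop("image input needs a region annotation GeoJSON")
  }
  structure(list(out_dir = out_dir, synthetic = synthetic,
                 n_sections = n_sections, sections = sections,
                 annotations = annotations, tissue = tissue,
                 vessels = vessels, detection = detection,
                 classifiers = classifiers, optimize = optimize,
                 seed = as.integer(seed)), class = "run_config")
}

stage_seed <- function(seed, stage) {
  # fixed per-stage offsets; kept below .Machine$integer.max
  offsets <- c(generate = 1000L, annotate = 2000L, optimize = 3000L)
  (seed %% 1000000L) * 1000L + offsets[[stage]]
}

#' Run the full pipeline
#'
#' Stages: generate/load sections -> tissue and vessel masks (vessels
#' subtracted, intersected with regions) -> per-region threshold sweeps (if
#' requested) -> detection + classification -> per-region quantification and
#' summary. All artifacts are written under `config$out_dir` and listed in
#' `manifest.json` with their MD5 hashes; rerunning with the same config
#' reproduces identical hashes.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  for (d in file.path(out, c("sections", "masks", "detections", "results"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  files <- character(0)
  note <- function(p) files <<- c(files, p)

  # ---- stage 1: sections ---------------------------------------------------
  sections <- list(); truths <- list(); regions <- NULL
  if (!is.null(config$synthetic)) {
    base <- stage_seed(config$seed, "generate")
    for (i in seq_len(config$n_sections)) {
      cfg <- config$synthetic
      cfg$seed <- base + i
      gen <- generate_section(cfg)
      id <- sprintf("section%02d", i)
      tp <- file.path(out, "sections", paste0(id, ".tif"))
      write_section(gen$image, tp)
      note(tp); note(paste0(tp, ".json"))
      gp <- file.path(out, "sections", paste0(id, "_cells.csv"))
      write.csv(gen$cells, gp, row.names = FALSE); note(gp)
      sections[[id]] <- gen$image
      truths[[id]] <- gen$cells
      if (is.null(regions)) {
        regions <- gen$annotations
        ap <- file.path(out, "sections", "regions.geojson")
        write_annotations(regions, ap); note(ap)
      }
    }
  } else {
    for (id in names(config$sections)) {
      sections[[id]] <- read_section(config$sections[[id]])
    }
    regions <- read_annotations(config$annotations)
  }

  # ---- stage 2: masks ------------------------------------------------------
  region_names <- vapply(annotation_features(regions, "region"), `[[`, "",
                         "name")
  masks <- list(); region_masks <- list()
  for (id in names(sections)) {
    tm <- detect_tissue(sections[[id]], config$tissue)
    vm <- detect_vessels(sections[[id]], config$vessels)
    clean <- mask_subtract(tm, vm)
    masks[[id]] <- clean
    region_masks[[id]] <- intersect_regions(clean, regions)
    mp <- file.path(out, "masks", paste0(id, "_tissue.tif"))
    write_mask(clean, mp); note(mp)
  }

  # ---- stage 3: thresholds (fixed or optimized) ----------------------------
  sweep_reports <- list()
  if (!is.null(config$optimize)) {
    if (is.null(config$synthetic)) {
      stop("sweep optimization needs synthetic ground truth or manual counts")
    }
    opt <- config$optimize
    rects <- do.call(rbind, lapply(names(sections), function(id) {
      ta <- generate_test_annotations(
        regions, size_um = opt$test_rect_um,
        seed = stage_seed(config$seed, "annotate") + match(id, names(sections)),
        pixel_size_um = sections[[id]]$pixel_size_um)
      test_rect_table(ta, section = id)
    }))
    classifiers <- list(); detection_opts <- list()
    for (reg in region_names) {
      rr <- rects[rects$region == reg, , drop = FALSE]
      mcs <- t(sapply(seq_len(nrow(rr)), function(k) {
        ground_truth_counts(truths[[rr$section[k]]],
                            rect_polygon(rr$x_um[k], rr$y_um[k], rr$w_um[k],
                                         rr$h_um[k]))
      }))
      dapi <- run_sweep(sweep_spec("detection.threshold", opt$dapi_grid[1:2],
                                   step = opt$dapi_grid[3], channel = "DAPI",
                                   annotations = rr,
                                   manual_counts = mcs[, "total"]),
                        sections, masks, list(detection = config$detection))
      dapi_opt <- select_optimum(dapi)
      det_reg <- config$detection
      det_reg$threshold <- dapi_opt$value
      detection_opts[[reg]] <- det_reg
      ds <- run_sweep(sweep_spec("classifier.dsred_threshold",
                                 opt$dsred_grid[1:2], step = opt$dsred_grid[3],
                                 channel = "DsRed", annotations = rr,
                                 manual_counts = mcs[, "dsred"]),
                      sections, masks, list(detection = det_reg))
      gf <- run_sweep(sweep_spec("classifier.gfp_threshold",
                                 opt$gfp_grid[1:2], step = opt$gfp_grid[3],
                                 channel = "GFP", annotations = rr,
                                 manual_counts = mcs[, "gfp"]),
                      sections, masks, list(detection = det_reg))
      classifiers[[reg]] <- classifier_params(select_optimum(ds)$value,
                                              select_optimum(gf)$value,
                                              region = reg)
      for (nm in c("dapi", "dsred", "gfp")) {
        res <- switch(nm, dapi = dapi, dsred = ds, gfp = gf)
        rp <- file.path(out, "results", paste0("sweep_", reg, "_", nm, ".csv"))
        write_sweep_report(res, rp); note(rp)
      }
      sweep_reports[[reg]] <- list(dapi = dapi, dsred = ds, gfp = gf)
    }
    cp <- file.path(out, "results", "classifiers.json")
    write_classifiers(classifiers, cp); note(cp)
  } else {
    classifiers <- config$classifiers
    missing <- setdiff(region_names, names(classifiers))
    if (length(missing)) {
      stop("no classifier for region(s): ", paste(missing, collapse = ", "))
    }
    detection_opts <- setNames(rep(list(config$detection),
                                   length(region_names)), region_names)
  }

  # ---- stage 4: detect, classify, quantify ---------------------------------
  quants <- list()
  for (id in names(sections)) {
    for (reg in region_names) {
      rmask <- region_masks[[id]][[reg]]
      if (!any(rmask$mask)) next
      dets <- detect_cells(sections[[id]], detection_opts[[reg]], rmask)
      dets <- classify_cells(dets, classifiers[[reg]])
      dp <- file.path(out, "detections", paste0(id, "_", reg, ".csv"))
      write_detections(dets, dp); note(dp)
      quants[[paste(id, reg)]] <- quantify_region(drop_labels(dets), rmask,
                                                  section = id, region = reg)
    }
  }
  quants <- do.call(rbind, quants)
  rownames(quants) <- NULL
  qp <- file.path(out, "results", "measurements.csv")
  write_measurements(quants, qp); note(qp)
  sp <- file.path(out, "results", "summary.csv")
  write.csv(summarize_quantifications(quants), sp, row.names = FALSE); note(sp)

  manifest <- list(
    package = "periglia",
    version = as.character(utils::packageVersion("periglia")),
    seed = config$seed,
    detection = unclass(config$detection),
    tissue = unclass(config$tissue),
    vessels = unclass(config$vessels),
    classifiers = lapply(classifiers, unclass),
    files = lapply(setNames(files, sub(paste0("^", out, "/?"), "", files)),
                   function(f) unname(md5sum(f))))
  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
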