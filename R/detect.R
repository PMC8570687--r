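# DAPI nucleus detection, watershed splitting of touching nuclei, fixed-width
# cell expansion and per-channel intensity measurement. The operator chain is
# fixed and documented: optional resample -> optional median filter ->
# optional background subtraction (white top-hat) -> Gaussian smooth ->
# inclusive threshold -> fill single-pixel holes -> distance-transform
# watershed -> area filter -> centroid-in-mask filter. Detections are sorted
# by (y, x) centroid so identical inputs give identical outputs.

#' Nucleus-detection parameters
#'
#' Defaults follow the conventional fluorescence cell-detection settings for
#' this kind of tissue: no resampling, no background subtraction (genetically
#' encoded reporters give a clean signal), no median filter, Gaussian
#' sigma 1.5 px, nucleus area in [10, 400] um^2, and a 2 um cell expansion.
#' The intensity threshold has no universal default and must be supplied
#' (typically from a sweep optimum).
#'
#' @param threshold DAPI intensity threshold (inclusive, required).
#' @param requested_pixel_size_um resample the detection channel to this
#'   pixel size first; `NULL` keeps native resolution.
#' @param background_radius_um rolling-ball-style background subtraction
#'   radius (white top-hat); 0 disables.
#' @param median_radius_um median prefilter radius; 0 disables.
#' @param sigma_px Gaussian smoothing sigma in pixels.
#' @param min_area_um2,max_area_um2 accepted nucleus area range.
#' @param cell_expansion_um ring width grown around each nucleus.
#' @param watershed_tolerance watershed intensity tolerance (px of distance).
#' @return object of class `detection_params`.
#' @export
detection_params <- function(threshold,
                             requested_pixel_size_um = NULL,
                             background_radius_um = 0,
                             median_radius_um = 0,
                             sigma_px = 1.5,
                             min_area_um2 = 10, max_area_um2 = 400,
                             cell_expansion_um = 2.0,
                             watershed_tolerance = 1) {
  stopifnot(threshold >= 0, background_radius_um >= 0, median_radius_um >= 0,
            sigma_px >= 0, min_area_um2 <= max_area_um2,
            cell_expansion_um >= 0)
  structure(list(threshold = threshold,
                 requested_pixel_size_um = requested_pixel_size_um,
                 background_radius_um = background_radius_um,
                 median_radius_um = median_radius_um,
                 sigma_px = sigma_px, min_area_um2 = min_area_um2,
                 max_area_um2 = max_area_um2,
                 cell_expansion_um = cell_expansion_um,
                 watershed_tolerance = watershed_tolerance),
            class = "detection_params")
}

new_cell_detections <- function(table, nucleus_labels, cell_labels,
                                pixel_size_um) {
  structure(list(table = table, nucleus_labels = nucleus_labels,
                 cell_labels = cell_labels, pixel_size_um = pixel_size_um),
            class = "cell_detections")
}

#' @export
print.cell_detections <- function(x, ...) {
  cat(sprintf("<cell_detections> %d cell(s), %.4g um/px\n",
              nrow(x$table), x$pixel_size_um))
  if (nrow(x$table) && !all(is.na(x$table$class))) {
    print(table(x$table$class))
  }
  invisible(x)
}

empty_detection_table <- function(channel_names) {
  cols <- c("id", "x_um", "y_um", "nucleus_area_um2", "cell_area_um2",
            paste0(channel_names, "_nucleus"), paste0(channel_names, "_cell"),
            "class")
  tab <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  tab$class <- character(0)
  tab
}

# fill isolated background pixels completely surrounded by foreground
fill_single_pixel_holes <- function(bin) {
  k <- matrix(1, 3, 3); k[2, 2] <- 0
  neigh <- imageData(EBImage::filter2(EBImage::Image(bin * 1), k, boundary = 0))
  bin | (!bin & neigh > 7.5)
}

#' Detect DAPI-stained nuclei
#'
#' Runs the fixed detection chain on the DAPI channel and returns one
#' detection per nucleus. Touching nuclei are split by a watershed on the
#' distance transform; merged nuclei that present a single distance maximum
#' remain one detection. Components whose area falls outside
#' `[min_area, max_area]` or whose centroid lies outside `within` are
#' discarded.
#'
#' @param img a `section_image` with a DAPI channel.
#' @param p a [detection_params()].
#' @param within optional `binary_mask` restricting detections (centroid
#'   test); `NULL` accepts the whole frame.
#' @return a `cell_detections` object (cell regions initialized to the
#'   nucleus regions; see [expand_cells()]).
#' @export
detect_nuclei <- function(img, p, within = NULL) {
  if (!"DAPI" %in% names(img$channels)) stop("DAPI channel is required")
  s <- img$pixel_size_um
  x <- get_channel(img, "DAPI")
  native_dim <- dim(x)

  resampled <- !is.null(p$requested_pixel_size_um) &&
    abs(p$requested_pixel_size_um - s) > 1e-9
  if (resampled) {
    f <- s / p$requested_pixel_size_um
    x <- imageData(EBImage::resize(EBImage::Image(x),
                                   w = round(native_dim[1] * f),
                                   h = round(native_dim[2] * f)))
    s_det <- p$requested_pixel_size_um
  } else {
    s_det <- s
  }
  if (p$median_radius_um > 0) {
    size <- max(1L, round(p$median_radius_um / s_det))
    x <- imageData(EBImage::medianFilter(EBImage::Image(x / 65535),
                                         size = size)) * 65535
  }
  if (p$background_radius_um > 0) {
    r_px <- p$background_radius_um / s_det
    bgk <- disc_kernel(r_px)
    x <- x - imageData(EBImage::opening(EBImage::Image(x), bgk))
  }
  if (p$sigma_px > 0) x <- EBImage::gblur(x, sigma = p$sigma_px)
  bin <- x >= p$threshold
  bin <- fill_single_pixel_holes(bin)

  if (!any(bin)) {
    return(new_cell_detections(empty_detection_table(names(img$channels)),
                               matrix(0L, native_dim[1], native_dim[2]),
                               matrix(0L, native_dim[1], native_dim[2]), s))
  }
  ext <- max(1L, round(sqrt(p$min_area_um2 / pi) / s_det))
  dm <- EBImage::distmap(EBImage::Image(bin))
  lab <- imageData(EBImage::watershed(dm, tolerance = p$watershed_tolerance,
                                      ext = ext))
  storage.mode(lab) <- "integer"
  if (resampled) {
    # map labels back to the native grid (nearest neighbour)
    lab <- imageData(EBImage::resize(EBImage::Image(lab), w = native_dim[1],
                                     h = native_dim[2], filter = "none"))
    storage.mode(lab) <- "integer"
  }
  n <- max(lab)
  areas_px <- tabulate(lab[lab > 0], nbins = n)
  keep <- which(areas_px * s^2 >= p$min_area_um2 &
                areas_px * s^2 <= p$max_area_um2)
  if (!length(keep)) {
    return(new_cell_detections(empty_detection_table(names(img$channels)),
                               matrix(0L, native_dim[1], native_dim[2]),
                               matrix(0L, native_dim[1], native_dim[2]), s))
  }
  cent <- label_centroids_um(lab, n, s)
  if (!is.null(within)) {
    inside <- centroid_in_mask(cent$x, cent$y, within)
    keep <- keep[inside[keep]]
  }
  if (!length(keep)) {
    return(new_cell_detections(empty_detection_table(names(img$channels)),
                               matrix(0L, native_dim[1], native_dim[2]),
                               matrix(0L, native_dim[1], native_dim[2]), s))
  }
  # deterministic ordering: sort by (y, x) centroid
  ord <- keep[order(cent$y[keep], cent$x[keep])]
  remap <- integer(n)
  remap[ord] <- seq_along(ord)
  lab <- matrix(ifelse(lab > 0, remap[pmax(lab, 1L)], 0L), nrow(lab))
  storage.mode(lab) <- "integer"

  tab <- empty_detection_table(names(img$channels))
  tab <- tab[seq_along(ord), , drop = FALSE]
  tab$id <- seq_along(ord)
  tab$x_um <- cent$x[ord]; tab$y_um <- cent$y[ord]
  tab$nucleus_area_um2 <- areas_px[ord] * s^2
  tab$cell_area_um2 <- tab$nucleus_area_um2
  tab$class <- NA_character_
  rownames(tab) <- NULL
  new_cell_detections(tab, lab, lab, s)
}

label_centroids_um <- function(lab, n, s) {
  nz <- which(lab > 0)
  l <- lab[nz]
  rows <- ((nz - 1L) %% nrow(lab)) + 1L
  cols <- ((nz - 1L) %/% nrow(lab)) + 1L
  cnt <- tabulate(l, nbins = n)
  x <- (rowsum(as.numeric(cols), l)[, 1] / cnt[sort(unique(l))] - 0.5) * s
  y <- (rowsum(as.numeric(rows), l)[, 1] / cnt[sort(unique(l))] - 0.5) * s
  ux <- uy <- rep(NA_real_, n)
  ux[sort(unique(l))] <- x
  uy[sort(unique(l))] <- y
  list(x = ux, y = uy)
}

centroid_in_mask <- function(x_um, y_um, mask) {
  d <- dim(mask$mask); s <- mask$pixel_size_um
  r <- pmin(pmax(floor(y_um / s) + 1L, 1L), d[1])
  c <- pmin(pmax(floor(x_um / s) + 1L, 1L), d[2])
  out <- mask$mask[(c - 1L) * d[1] + r]
  out[is.na(out)] <- FALSE
  out
}

#' Grow each nucleus into a cell region
#'
#' Dilates every nucleus by `expansion_um`, with competing expansions meeting
#' at the midline (nearest-nucleus partition, computed by geodesic
#' propagation) and the result clipped to `within`. Nucleus pixels always
#' belong to their own cell; cell regions of distinct detections are
#' disjoint.
#'
#' @param dets a `cell_detections` from [detect_nuclei()].
#' @param expansion_um ring width in micrometres (default: value used at
#'   detection time, 2 um).
#' @param within optional `binary_mask` clipping the expansion.
#' @return the updated `cell_detections`.
#' @export
expand_cells <- function(dets, expansion_um = 2.0, within = NULL) {
  s <- dets$pixel_size_um
  nuc <- dets$nucleus_labels
  if (expansion_um <= 0 || nrow(dets$table) == 0) {
    dets$cell_labels <- nuc
    dets$table$cell_area_um2 <- dets$table$nucleus_area_um2
    return(dets)
  }
  e_px <- expansion_um / s
  nucmask <- nuc > 0
  grow <- imageData(EBImage::dilate(EBImage::Image(nucmask),
                                    disc_kernel(e_px))) > 0
  if (!is.null(within)) grow <- grow & within$mask
  grow <- grow | nucmask
  cell <- imageData(EBImage::propagate(EBImage::Image(0, dim(nuc)),
                                       seeds = EBImage::Image(nuc),
                                       mask = grow))
  storage.mode(cell) <- "integer"
  dets$cell_labels <- cell
  areas <- tabulate(cell[cell > 0], nbins = max(nrow(dets$table), 1))
  dets$table$cell_area_um2 <- areas[dets$table$id] * s^2
  dets
}

#' Measure per-channel mean intensities over nucleus and cell regions
#'
#' Means are computed on the raw (unsmoothed) channel values.
#'
#' @param dets a `cell_detections` (after [expand_cells()] if ring means are
#'   wanted; otherwise cell means equal nucleus means).
#' @param img the `section_image` the detections came from.
#' @return the updated `cell_detections` with `<channel>_nucleus` and
#'   `<channel>_cell` columns filled in.
#' @export
measure_intensities <- function(dets, img) {
  if (nrow(dets$table) == 0) return(dets)
  for (ch in names(img$channels)) {
    v <- img$channels[[ch]]
    dets$table[[paste0(ch, "_nucleus")]] <-
      label_means(dets$nucleus_labels, v, nrow(dets$table))
    dets$table[[paste0(ch, "_cell")]] <-
      label_means(dets$cell_labels, v, nrow(dets$table))
  }
  dets
}

label_means <- function(lab, values, n) {
  nz <- lab > 0
  l <- lab[nz]
  sums <- rowsum(values[nz], l)
  cnt <- tabulate(l, nbins = n)
  out <- rep(NA_real_, n)
  out[as.integer(rownames(sums))] <- sums[, 1]
  out / cnt
}

#' Detect, expand and measure in one call
#'
#' Convenience wrapper chaining [detect_nuclei()], [expand_cells()] and
#' [measure_intensities()] with the expansion width from `p`.
#'
#' @inheritParams detect_nuclei
#' @return a measured `cell_detections`.
#' @export
detect_cells <- function(img, p, within = NULL) {
  dets <- detect_nuclei(img, p, within)
  dets <- expand_cells(dets, p$cell_expansion_um, within)
  measure_intensities(dets, img)
}

#' Drop label rasters to free memory
#'
#' Quantification only needs the measurement table; for many-section runs the
#' label images can be discarded once intensities are measured.
#' @param dets a `cell_detections`.
#' @return the object without label rasters.
#' @export
drop_labels <- function(dets) {
  dets$nucleus_labels <- NULL
  dets$cell_labels <- NULL
  dets
}

#' Export detections as a CSV table
#' @param dets a `cell_detections`; @param path output CSV.
#' @export
write_detections <- function(dets, path) {
  write.csv(dets$table, path, row.names = FALSE)
  invisible(path)
}
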