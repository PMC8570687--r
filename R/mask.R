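# Tissue-area and large-vessel pixel classification with morphological
# cleanup. The fixed pipeline order is: channel combination -> Gaussian
# prefilter -> inclusive threshold -> fill holes smaller than min_hole ->
# drop components smaller than min_area -> erode by erode_um -> drop
# fragments smaller than min_fragment. Threshold comparison is >= throughout.

#' Mask-classifier parameters
#'
#' Defaults are the conventional whole-section tissue classifier: average of
#' all channels, Gaussian sigma 2 px, threshold 50, minimum area
#' 1,000,000 um^2, minimum hole 1000 um^2, 40 um erosion, fragments under
#' 10,000 um^2 removed.
#'
#' @param channels `"average"` (mean of all channels) or a single channel
#'   name (e.g. `"DsRed"` for the vessel classifier).
#' @param sigma_px Gaussian prefilter sigma in pixels.
#' @param threshold intensity threshold (inclusive).
#' @param min_area_um2 components smaller than this are dropped.
#' @param min_hole_um2 holes smaller than this are filled.
#' @param erode_um erosion radius (disc) in micrometres; 0 disables.
#' @param min_fragment_um2 post-erosion fragments smaller than this are
#'   dropped; 0 disables.
#' @return object of class `mask_params`.
#' @export
mask_params <- function(channels = "average", sigma_px = 2.0, threshold = 50,
                        min_area_um2 = 1e6, min_hole_um2 = 1000,
                        erode_um = 40, min_fragment_um2 = 10000) {
  stopifnot(sigma_px >= 0, min_area_um2 >= 0, min_hole_um2 >= 0,
            erode_um >= 0, min_fragment_um2 >= 0)
  structure(list(channels = channels, sigma_px = sigma_px,
                 threshold = threshold, min_area_um2 = min_area_um2,
                 min_hole_um2 = min_hole_um2, erode_um = erode_um,
                 min_fragment_um2 = min_fragment_um2),
            class = "mask_params")
}

#' Vessel-classifier parameters (DsRed channel)
#'
#' Convenience wrapper for [mask_params()] with the large-vessel defaults:
#' DsRed channel, sigma 2 px, threshold 400, minimum size 150 um^2, minimum
#' hole 1000 um^2, no erosion, no fragment removal.
#' @param ... overrides passed to [mask_params()].
#' @export
vessel_params <- function(...) {
  args <- list(channels = "DsRed", sigma_px = 2.0, threshold = 400,
               min_area_um2 = 150, min_hole_um2 = 1000, erode_um = 0,
               min_fragment_um2 = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(mask_params, args)
}

#' Construct a binary mask tied to an image geometry
#' @param mask logical matrix; @param pixel_size_um μm per pixel.
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(mask, pixel_size_um) {
  stopifnot(is.matrix(mask), pixel_size_um > 0)
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, pixel_size_um = pixel_size_um),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<binary_mask> %d x %d px, %.4g um/px, %.4g mm^2 foreground\n",
              d[1], d[2], x$pixel_size_um, mask_area_mm2(x)))
  invisible(x)
}

#' Foreground area of a mask in mm^2
#' @param mask a `binary_mask`.
#' @export
mask_area_mm2 <- function(mask) {
  sum(mask$mask) * mask$pixel_size_um^2 / 1e6
}

# binary disc structuring element with an explicit pixel-set definition
# (dx^2 + dy^2 <= r^2), shared with the test oracles
disc_kernel <- function(r_px) {
  r <- max(0L, as.integer(round(r_px)))
  g <- -r:r
  k <- outer(g^2, g^2, "+") <= r_px^2 + 1e-9
  storage.mode(k) <- "integer"
  k
}

fill_small_holes <- function(bin, max_hole_px) {
  if (max_hole_px <= 0) return(bin)
  inv <- !bin
  lab <- EBImage::bwlabel(inv + 0)
  if (max(lab) == 0) return(bin)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  fill <- which(areas < max_hole_px)
  fill <- setdiff(fill, border)
  if (length(fill)) bin[matrix(lab %in% fill, nrow(bin))] <- TRUE
  bin
}

drop_small_components <- function(bin, min_px) {
  if (min_px <= 0 || !any(bin)) return(bin)
  lab <- EBImage::bwlabel(bin + 0)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  drop <- which(areas < min_px)
  if (length(drop)) bin[matrix(lab %in% drop, nrow(bin))] <- FALSE
  bin
}

run_mask_pipeline <- function(x, s, p) {
  if (p$sigma_px > 0) x <- EBImage::gblur(x, sigma = p$sigma_px)
  bin <- x >= p$threshold
  bin <- fill_small_holes(bin, p$min_hole_um2 / s^2)
  bin <- drop_small_components(bin, p$min_area_um2 / s^2)
  if (p$erode_um > 0) {
    r_px <- p$erode_um / s
    bin <- imageData(EBImage::erode(EBImage::Image(bin), disc_kernel(r_px))) > 0
  }
  bin <- drop_small_components(bin, p$min_fragment_um2 / s^2)
  if (!any(bin)) {
    warning("mask is empty after filtering", call. = FALSE)
  }
  bin
}

#' Detect the tissue area of a section
#'
#' Pixel classification on the average of all channels followed by the fixed
#' cleanup chain (hole filling, minimum area, erosion, fragment removal).
#'
#' @param img a `section_image`.
#' @param p a [mask_params()] with `channels = "average"`.
#' @return a `binary_mask`.
#' @export
detect_tissue <- function(img, p = mask_params()) {
  if (!identical(p$channels, "average")) {
    stop("tissue detection uses the average of all channels")
  }
  x <- Reduce(`+`, img$channels) / length(img$channels)
  binary_mask(run_mask_pipeline(x, img$pixel_size_um, p), img$pixel_size_um)
}

#' Detect large marker-bright vessels
#'
#' Pixel classification on a single channel (DsRed by default), intended to
#' exclude large DsRed-positive vessels (vascular smooth muscle) from the
#' pericyte analysis.
#'
#' @param img a `section_image`.
#' @param p a [mask_params()] naming a single channel (see [vessel_params()]).
#' @return a `binary_mask`.
#' @export
detect_vessels <- function(img, p = vessel_params()) {
  if (identical(p$channels, "average")) {
    stop("vessel detection uses a single channel (typically DsRed)")
  }
  x <- get_channel(img, p$channels)
  binary_mask(run_mask_pipeline(x, img$pixel_size_um, p), img$pixel_size_um)
}

#' Subtract one mask from another
#'
#' `a AND NOT b` — e.g. removing the vessel mask from the tissue mask.
#'
#' @param a,b `binary_mask` objects of identical shape.
#' @return a `binary_mask`.
#' @export
mask_subtract <- function(a, b) {
  if (!identical(dim(a$mask), dim(b$mask))) {
    stop("mask shapes differ: cannot subtract")
  }
  binary_mask(a$mask & !b$mask, a$pixel_size_um)
}

#' Intersect a tissue mask with region annotations
#'
#' Rasterizes each region polygon (pixel coordinates) and intersects it with
#' the mask; regions that are pairwise disjoint yield pairwise disjoint masks.
#'
#' @param tissue a `binary_mask`.
#' @param regions an `annotation_set` with `role = "region"` features.
#' @param names optional region names to extract (default: all); an unknown
#'   name is an error.
#' @return named list of `binary_mask` objects.
#' @export
intersect_regions <- function(tissue, regions, names = NULL) {
  feats <- annotation_features(regions, role = "region")
  have <- vapply(feats, `[[`, "", "name")
  if (is.null(names)) names <- have
  missing <- setdiff(names, have)
  if (length(missing)) {
    stop("unknown region name(s): ", paste(missing, collapse = ", "))
  }
  out <- lapply(names, function(nm) {
    f <- feats[[match(nm, have)]]
    raster <- rasterize_polygon(f$parts, dim(tissue$mask))
    binary_mask(tissue$mask & raster, tissue$pixel_size_um)
  })
  setNames(out, names)
}

#' Write a binary mask as an 8-bit TIFF raster
#' @param mask a `binary_mask`; @param path output path.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(mask$mask * 1.0, path, bits.per.sample = 8L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Export mask components as polygon annotations
#'
#' Traces the boundary of every connected component (pixel-resolution
#' contours) and returns them as an annotation set, e.g. for interchange
#' with whole-slide annotation tools.
#'
#' @param mask a `binary_mask`; @param name annotation name;
#' @param role annotation role (`"tissue"` or `"vessels"`).
#' @return an `annotation_set` with one multi-part feature (or an empty set
#'   if the mask is empty).
#' @export
mask_to_annotations <- function(mask, name = "Tissue", role = "tissue") {
  lab <- EBImage::bwlabel(mask$mask + 0)
  if (max(lab) == 0) {
    return(annotation_set(pixel_size_um = mask$pixel_size_um))
  }
  contours <- EBImage::ocontour(EBImage::Image(lab))
  parts <- lapply(contours, function(m) {
    # ocontour indexes along (dim1, dim2) = (row, col) 0-based
    list(outer = cbind(x = m[, 2] + 0.5, y = m[, 1] + 0.5), holes = list())
  })
  parts <- Filter(function(p) nrow(p$outer) >= 3 &&
                    polygon_area(p$outer) > 0 && ring_is_simple(p$outer), parts)
  annotation_set(list(list(name = name, role = role, parts = parts)),
                 pixel_size_um = mask$pixel_size_um, validate = FALSE)
}
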