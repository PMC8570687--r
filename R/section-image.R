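# Multi-channel section images. Pixels are arbitrary 16-bit-like counts in
# [0, 65535], stored as one numeric matrix per channel (matrix[row, col] =
# [y, x]). Physical scale is micrometres per pixel.

#' Construct a section image
#'
#' @param channels named list of numeric matrices (same dimensions); expected
#'   order and names are DAPI, DsRed, GFP but any unique names are accepted.
#' @param pixel_size_um micrometres per pixel (> 0).
#' @param source optional path the image was read from.
#' @return object of class `section_image`.
#' @export
section_image <- function(channels, pixel_size_um, source = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1)
  if (is.null(names(channels)) || anyDuplicated(names(channels))) {
    stop("channels must have unique names")
  }
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop("all channels must share the same dimensions")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 source = source), class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<section_image> %d x %d px, %.4g um/px, channels: %s\n",
              d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.section_image <- function(x) dim(x$channels[[1]])

#' Extract one channel matrix
#' @param img a `section_image`; @param name channel name.
#' @return numeric matrix.
#' @export
get_channel <- function(img, name) {
  if (!name %in% names(img$channels)) {
    stop("channel '", name, "' not present (have: ",
         paste(names(img$channels), collapse = ", "), ")")
  }
  img$channels[[name]]
}

#' Crop a section image to a rectangle given in micrometres
#'
#' The crop is aligned to whole pixels (floor/ceiling of the requested
#' extent). Returns the cropped image plus the origin of the crop in
#' micrometres, so detections can be mapped back to section coordinates.
#'
#' @param img a `section_image`.
#' @param x_um,y_um top-left corner (μm); @param w_um,h_um extents (μm).
#' @return list with `image` (the crop) and `origin_um` `c(x, y)`.
#' @export
crop_section <- function(img, x_um, y_um, w_um, h_um) {
  s <- img$pixel_size_um
  d <- dim(img)
  c0 <- max(0L, floor(x_um / s)); r0 <- max(0L, floor(y_um / s))
  c1 <- min(d[2], ceiling((x_um + w_um) / s))
  r1 <- min(d[1], ceiling((y_um + h_um) / s))
  if (c1 <= c0 || r1 <= r0) stop("crop rectangle lies outside the image")
  ch <- lapply(img$channels, function(m) m[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE])
  list(image = section_image(ch, s, source = img$source),
       origin_um = c(x = c0 * s, y = r0 * s))
}

#' Write a section image as a multi-page TIFF with a JSON sidecar
#'
#' One 16-bit grayscale page per channel. Channel names and the physical
#' pixel size are recorded in `<path>.json`; `read_section()` restores them
#' from there.
#'
#' @param img a `section_image`; @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_section <- function(img, path) {
  pages <- lapply(img$channels, function(m) {
    m <- pmin(pmax(round(m), 0), 65535)
    m / 65535
  })
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  sidecar <- list(channels = names(img$channels),
                  pixel_size_um = img$pixel_size_um)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-channel TIFF section image
#'
#' Requires at least three channels/pages. Pixel size comes from the JSON
#' sidecar written by [write_section()], from TIFF resolution metadata when
#' present, or from `pixel_size_override`; it is an error if none is
#' available. Channel names come from the sidecar or default to
#' DAPI, DsRed, GFP (in page order).
#'
#' @param path TIFF file; @param pixel_size_override μm/px, overrides any
#'   stored value; @param channel_names optional explicit names.
#' @return a `section_image`.
#' @export
read_section <- function(path, pixel_size_override = NULL,
                         channel_names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) {
      # planar multi-channel page: split into one matrix per plane
      lapply(seq_len(dim(p)[3]), function(k) p[, , k])
    } else {
      list(p)
    }
  })
  mats <- do.call(c, pages)
  if (length(mats) < 3) {
    stop("section images need >= 3 channels, found ", length(mats), ": ", path)
  }
  info <- attributes(mats[[1]])
  mats <- lapply(mats, function(m) {
    storage.mode(m) <- "double"
    attributes(m) <- list(dim = dim(m))  # strip TIFF info attributes
    m
  })
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else NULL
  if (is.null(channel_names)) {
    channel_names <- if (!is.null(sidecar$channels)) sidecar$channels
                     else c("DAPI", "DsRed", "GFP")[seq_along(mats)]
  }
  if (length(channel_names) != length(mats)) {
    stop("channel name count (", length(channel_names),
         ") does not match channel count (", length(mats), ")")
  }
  pixel_size <- pixel_size_override
  if (is.null(pixel_size) && !is.null(sidecar$pixel_size_um)) {
    pixel_size <- sidecar$pixel_size_um
  }
  if (is.null(pixel_size) && !is.null(info$x.resolution) &&
      is.finite(info$x.resolution) && info$x.resolution > 0) {
    # resolution in px per unit; centimetres -> micrometres
    per_um <- if (identical(info$resolution.unit, "cm")) {
      info$x.resolution / 1e4
    } else {
      info$x.resolution / 25400
    }
    pixel_size <- 1 / per_um
  }
  if (is.null(pixel_size)) {
    stop("no pixel size stored for ", path,
         " and no pixel_size_override given")
  }
  names(mats) <- channel_names
  section_image(mats, pixel_size, source = path)
}
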