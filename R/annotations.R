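# Annotation sets: named polygonal regions (possibly multi-part, with holes)
# plus optional manual count points, in 0-based pixel coordinates. The GeoJSON
# dialect matches common whole-slide annotation tooling: polygon features carry
# properties.classification$name and properties.role; count points carry
# properties.channel.

#' Construct an annotation set
#'
#' @param features list of features; each feature is
#'   `list(name, role, parts)` where `parts` is a list of
#'   `list(outer = n x 2 matrix, holes = list of matrices)` in pixel
#'   coordinates (0-based, origin top-left, y down). A bare matrix is
#'   promoted to a single-part polygon without holes.
#' @param points optional data.frame with columns `x`, `y`, `channel`
#'   (manual count points).
#' @param pixel_size_um optional micrometres per pixel, carried as an
#'   attribute so μm-sized constructions (e.g. test rectangles) can be
#'   made from pixel-based sets.
#' @param validate check ring simplicity and name uniqueness (default TRUE).
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(features = list(), points = NULL,
                           pixel_size_um = NULL, validate = TRUE) {
  features <- lapply(features, function(f) {
    if (is.matrix(f$parts) || (is.list(f$parts) && !is.null(f$parts$outer))) {
      f$parts <- list(normalize_part(f$parts))
    } else {
      f$parts <- lapply(f$parts, normalize_part)
    }
    f
  })
  if (validate) {
    for (i in seq_along(features)) {
      f <- features[[i]]
      if (is.null(f$name) || is.null(f$role)) {
        stop("feature ", i, ": every annotation needs a name and a role")
      }
      for (part in f$parts) {
        for (ring in c(list(part$outer), part$holes)) {
          if (nrow(ring) < 3 || polygon_area(ring) == 0 || !ring_is_simple(ring)) {
            stop("feature ", i, " ('", f$name, "'): invalid (self-intersecting ",
                 "or degenerate) polygon ring")
          }
        }
      }
    }
    key <- vapply(features, function(f) paste0(f$role, "/", f$name), "")
    if (anyDuplicated(key)) stop("annotation names must be unique within a role")
  }
  if (!is.null(points)) {
    stopifnot(all(c("x", "y", "channel") %in% names(points)))
    points <- data.frame(x = as.numeric(points$x), y = as.numeric(points$y),
                         channel = as.character(points$channel))
  }
  structure(list(features = features, points = points),
            pixel_size_um = pixel_size_um, class = "annotation_set")
}

normalize_part <- function(part) {
  if (is.matrix(part)) part <- list(outer = part, holes = list())
  part$outer <- drop_closing_vertex(as.matrix(part$outer))
  part$holes <- lapply(if (is.null(part$holes)) list() else part$holes,
                       function(h) drop_closing_vertex(as.matrix(h)))
  part
}

drop_closing_vertex <- function(m) {
  colnames(m) <- c("x", "y")
  n <- nrow(m)
  if (n > 1 && all(m[1, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  m
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set>", length(x$features), "feature(s)")
  if (!is.null(x$points)) cat(",", nrow(x$points), "count point(s)")
  cat("\n")
  for (f in x$features) {
    cat(sprintf("  %-10s %-14s %d part(s)\n", f$role, f$name, length(f$parts)))
  }
  invisible(x)
}

#' Extract features of one role (optionally one name)
#' @param set an `annotation_set`; @param role role to keep;
#' @param name optional name filter.
#' @return list of features.
#' @export
annotation_features <- function(set, role = NULL, name = NULL) {
  fs <- set$features
  if (!is.null(role)) fs <- Filter(function(f) f$role == role, fs)
  if (!is.null(name)) fs <- Filter(function(f) f$name == name, fs)
  fs
}

#' Read annotations from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon / MultiPolygon features (regions,
#' tissue, vessels, test rectangles) and Point features (manual counts).
#'
#' @param path GeoJSON file.
#' @return an `annotation_set`.
#' @export
read_annotations <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection: ", path)
  }
  features <- list(); pts <- list()
  for (i in seq_along(gj$features)) {
    ft <- gj$features[[i]]
    geom <- ft$geometry
    props <- ft$properties
    name <- if (!is.null(props$classification$name)) props$classification$name
            else props$name
    role <- if (!is.null(props$role)) props$role else "region"
    ring_mat <- function(ring) {
      m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
      drop_closing_vertex(m)
    }
    if (geom$type == "Point") {
      xy <- as.numeric(unlist(geom$coordinates))
      pts[[length(pts) + 1]] <- data.frame(
        x = xy[1], y = xy[2],
        channel = if (!is.null(props$channel)) props$channel else NA_character_)
    } else if (geom$type == "Polygon") {
      rings <- lapply(geom$coordinates, ring_mat)
      features[[length(features) + 1]] <- list(
        name = name, role = role,
        parts = list(list(outer = rings[[1]], holes = rings[-1])))
    } else if (geom$type == "MultiPolygon") {
      parts <- lapply(geom$coordinates, function(poly) {
        rings <- lapply(poly, ring_mat)
        list(outer = rings[[1]], holes = rings[-1])
      })
      features[[length(features) + 1]] <- list(name = name, role = role,
                                               parts = parts)
    } else {
      stop("feature ", i, ": unsupported geometry type '", geom$type, "'")
    }
  }
  tryCatch(
    annotation_set(features,
                   points = if (length(pts)) do.call(rbind, pts) else NULL),
    error = function(e) stop("invalid geometry in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
}

#' Write annotations to GeoJSON
#' @param set an `annotation_set`; @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(set, path) {
  close_ring <- function(m) {
    m <- rbind(m, m[1, , drop = FALSE])
    lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  }
  feats <- lapply(set$features, function(f) {
    coords <- lapply(f$parts, function(part) {
      c(list(close_ring(part$outer)), lapply(part$holes, close_ring))
    })
    geom <- if (length(coords) == 1) {
      list(type = "Polygon", coordinates = coords[[1]])
    } else {
      list(type = "MultiPolygon", coordinates = coords)
    }
    list(type = "Feature", geometry = geom,
         properties = list(classification = list(name = f$name), role = f$role))
  })
  if (!is.null(set$points) && nrow(set$points)) {
    for (i in seq_len(nrow(set$points))) {
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        geometry = list(type = "Point",
                        coordinates = c(set$points$x[i], set$points$y[i])),
        properties = list(role = "count", channel = set$points$channel[i]))
    }
  }
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
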