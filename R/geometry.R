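# Planar geometry primitives shared by the annotation, masking and counting code.
#
# Conventions (used everywhere in the package):
#   * image rasters are matrices indexed [row, col] = [y, x], 1-based;
#   * pixel (r, c) covers the half-open square [c-1, c) x [r-1, r) in 0-based
#     pixel coordinates; its center is (c - 0.5, r - 0.5);
#   * polygons are n x 2 matrices of (x, y) vertices, open (last != first),
#     in either pixel or micrometre coordinates depending on the caller;
#   * point-in-polygon uses the even-odd ray-casting rule. Points exactly on
#     an edge follow the half-open asymmetry of that rule (edges on the
#     lexicographically lower side of the polygon count as inside). This is
#     the single convention referred to by the counting operations.

#' Test points against a polygon (even-odd ray casting)
#'
#' Vectorized over points; loops over polygon edges. The boundary convention
#' is the standard half-open ray-casting rule, applied identically wherever
#' the package needs point membership (manual-count emulation, rasterization,
#' centroid-in-region assignment).
#'
#' @param x,y numeric vectors of point coordinates.
#' @param poly n x 2 matrix of polygon vertices (open ring).
#' @return logical vector, `TRUE` for points inside the polygon.
#' @export
point_in_polygon <- function(x, y, poly) {
  poly <- as.matrix(poly)
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3)
  px <- poly[, 1]; py <- poly[, 2]
  n <- nrow(poly)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Signed and absolute polygon area (shoelace formula)
#' @param poly n x 2 vertex matrix (open ring).
#' @return absolute area in squared input units.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Proper intersection test for two segments (shared endpoints do not count).
segments_cross <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
}

# A ring is simple if no two non-adjacent edges properly intersect. O(n^2);
# annotation polygons are small.
ring_is_simple <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  idx <- rbind(seq_len(n), c(seq_len(n)[-1], 1))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (share a vertex)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_cross(poly[idx[1, i], ], poly[idx[2, i], ],
                         poly[idx[1, j], ], poly[idx[2, j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Does an axis-aligned rectangle lie fully inside a polygon part (outer ring
# minus holes)? Checks corner membership, edge crossings against every ring,
# and that no hole vertex falls inside the rectangle.
rect_inside_part <- function(x0, y0, w, h, part) {
  corners <- rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h))
  if (!all(point_in_polygon(corners[, 1], corners[, 2], part$outer))) return(FALSE)
  for (hole in part$holes) {
    if (any(point_in_polygon(corners[, 1], corners[, 2], hole))) return(FALSE)
    if (any(point_in_polygon(hole[, 1], hole[, 2],
                             rect_polygon(x0, y0, w, h)))) return(FALSE)
  }
  rect <- rect_polygon(x0, y0, w, h)
  rings <- c(list(part$outer), part$holes)
  for (ring in rings) {
    n <- nrow(ring)
    for (i in seq_len(n)) {
      a <- ring[i, ]; b <- ring[if (i == n) 1 else i + 1, ]
      for (k in 1:4) {
        c1 <- rect[k, ]; c2 <- rect[if (k == 4) 1 else k + 1, ]
        if (segments_cross(a, b, c1, c2)) return(FALSE)
      }
    }
  }
  TRUE
}

#' Axis-aligned rectangle as a polygon
#' @param x0,y0 lower corner; @param w,h extents.
#' @return 4 x 2 vertex matrix (open ring, counter-clockwise in y-down space).
#' @export
rect_polygon <- function(x0, y0, w, h) {
  cbind(x = c(x0, x0 + w, x0 + w, x0), y = c(y0, y0, y0 + h, y0 + h))
}

#' Rasterize a polygon (with optional holes) onto a pixel grid
#'
#' A pixel belongs to the mask when its center (c - 0.5, r - 0.5), in the
#' same 0-based pixel coordinates as the polygon, is inside the outer ring
#' and outside every hole (even-odd rule over all rings).
#'
#' @param parts list of parts, each `list(outer = matrix, holes = list())`,
#'   coordinates in pixels; a bare matrix is accepted as a single outer ring.
#' @param dim `c(nrow, ncol)` of the target raster.
#' @return logical matrix of dimension `dim`.
#' @export
rasterize_polygon <- function(parts, dim) {
  if (is.matrix(parts)) parts <- list(list(outer = parts, holes = list()))
  if (!is.null(parts$outer)) parts <- list(parts)  # a single bare part
  out <- matrix(FALSE, dim[1], dim[2])
  for (part in parts) {
    rings <- c(list(part$outer), part$holes)
    bb <- apply(do.call(rbind, rings), 2, range)
    cs <- max(1L, floor(bb[1, 1] + 0.5)):min(dim[2], ceiling(bb[2, 1] + 0.5))
    rs <- max(1L, floor(bb[1, 2] + 0.5)):min(dim[1], ceiling(bb[2, 2] + 0.5))
    if (!length(cs) || !length(rs)) next
    xs <- rep(cs - 0.5, each = length(rs))
    ys <- rep(rs - 0.5, times = length(cs))
    inside <- logical(length(xs))
    for (ring in rings) inside <- xor(inside, point_in_polygon(xs, ys, ring))
    sub <- matrix(inside, length(rs), length(cs))
    out[rs, cs] <- out[rs, cs] | sub
  }
  out
}

# Half-open rectangle membership in micrometre coordinates: x0 <= x < x0 + w.
point_in_rect <- function(x, y, x0, y0, w, h) {
  x >= x0 & x < x0 + w & y >= y0 & y < y0 + h
}
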