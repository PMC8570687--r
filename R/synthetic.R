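# Synthetic brain-section generator. Produces multi-channel (DAPI/DsRed/GFP)
# rasters with exhaustive ground truth: DAPI-stained nuclei at region-dependent
# densities, DsRed-positive pericyte somata sitting on a capillary network plus
# occasional large DsRed-bright vessels, GFP-positive microglia with thin
# ramified processes, region-dependent background, brighter tissue edges, and
# Gaussian read noise. Intensities are arbitrary 16-bit-like counts in
# [0, 65535]. Morphology is cosmetic: downstream classification is intensity
# based, so foreground amplitudes are what matters and they are drawn from
# truncated normals (clamped at +/- 2 SD) so the class structure is learnable
# by thresholding.

#' Default region layout: four square regions in a 2 x 2 arrangement
#'
#' Region polygons are in micrometres. The layout leaves room for the tissue
#' margin, the edge-brightening band, and the 40 um tissue-mask erosion, so
#' all configured cells survive masking.
#'
#' @param width_um,height_um section extent; @param inset_um distance from the
#'   image border to the region block; @param gap_um gap between regions.
#' @return named list of polygon matrices (μm).
#' @export
default_brain_regions <- function(width_um = 1300, height_um = 1300,
                                  inset_um = 120, gap_um = 100) {
  w <- (width_um - 2 * inset_um - gap_um) / 2
  h <- (height_um - 2 * inset_um - gap_um) / 2
  at <- function(ix, iy) rect_polygon(inset_um + ix * (w + gap_um),
                                      inset_um + iy * (h + gap_um), w, h)
  list(cortex = at(0, 0), hippocampus = at(1, 0),
       thalamus = at(0, 1), hypothalamus = at(1, 1))
}

#' Configuration for the synthetic-section generator
#'
#' Defaults emulate the study conditions the pipeline is designed for: cell
#' densities giving roughly 50-150 nuclei per 300 x 200 um test annotation,
#' per-region pericyte fractions of a few percent (highest in the thalamus)
#' and microglia fractions of 3-6 percent (highest in the cortex), and
#' channel intensities scaled so that the useful classification thresholds
#' fall in the conventional grid ranges (DAPI 50-1000, DsRed 200-550,
#' GFP 100-450).
#'
#' @param width_um,height_um physical extent (μm).
#' @param pixel_size_um micrometres per pixel.
#' @param tissue_margin_um width of the empty slide border around the tissue
#'   rectangle.
#' @param regions named list of region polygons in μm (non-overlapping).
#' @param nucleus_density named vector, nuclei per mm^2 per region.
#' @param pericyte_fraction,microglia_fraction named vectors, fraction of
#'   nuclei per region (sum <= 1 per region).
#' @param nucleus_radius_um `c(mean, sd)` of nucleus radius (μm).
#' @param intensity list of intensity parameters (see Details).
#' @param capillary_density_mm_per_mm2 total capillary length per tissue area.
#' @param large_vessel_count number of large DsRed-bright vessels.
#' @param dim_fraction,dim_factor fraction of nuclei rendered dim (emulating
#'   out-of-focus nuclei) and their amplitude multiplier.
#' @param touching_fraction fraction of nuclei placed as deliberately touching
#'   pairs (exercises watershed splitting and dual-classification artifacts).
#' @param min_separation_factor minimum centre distance between non-touching
#'   nuclei, as a multiple of the radius sum.
#' @param noise_sd Gaussian read-noise SD (intensity counts).
#' @param seed integer RNG seed; identical configs give bit-identical output.
#'
#' @details `intensity` entries: `outside` (slide background per channel),
#' `background` (in-tissue background per channel; either one named vector or
#' a list keyed by region name plus `"tissue"` for non-region tissue),
#' `dapi_fg`, `dsred_fg`, `gfp_fg` (`c(mean, sd)` foreground amplitude above
#' background of nuclei, pericyte somata and microglia somata), `capillary`,
#' `process`, `vessel` (flat amplitudes of capillary lines, microglial
#' processes and large vessels), `edge_amp` and `edge_width_um` (additive
#' brightening ramp inside the tissue boundary). The DsRed soma amplitude is
#' kept low enough that background + amplitude stays below the large-vessel
#' pixel-classifier threshold (400) after smoothing: only the rendered
#' vessels may enter the vessel mask, never pericyte somata.
#' @return object of class `section_config`.
#' @export
section_config <- function(width_um = 1300, height_um = 1300,
                           pixel_size_um = 0.65,
                           tissue_margin_um = 50,
                           regions = default_brain_regions(width_um, height_um),
                           nucleus_density = c(cortex = 1900, hippocampus = 2100,
                                               thalamus = 1500, hypothalamus = 1600),
                           pericyte_fraction = c(cortex = 0.0268, hippocampus = 0.0177,
                                                 thalamus = 0.0620, hypothalamus = 0.0237),
                           microglia_fraction = c(cortex = 0.0554, hippocampus = 0.0405,
                                                  thalamus = 0.0399, hypothalamus = 0.0323),
                           nucleus_radius_um = c(mean = 3.2, sd = 0.35),
                           intensity = list(),
                           capillary_density_mm_per_mm2 = 1.0,
                           large_vessel_count = 2,
                           dim_fraction = 0.02, dim_factor = 0.5,
                           touching_fraction = 0.02,
                           min_separation_factor = 1.2,
                           noise_sd = 8, seed = 1L) {
  default_intensity <- list(
    outside = c(DAPI = 5, DsRed = 5, GFP = 5),
    background = c(DAPI = 20, DsRed = 100, GFP = 60),
    dapi_fg = c(mean = 500, sd = 40),
    dsred_fg = c(mean = 250, sd = 20),
    gfp_fg = c(mean = 250, sd = 25),
    capillary = 150, process = 110, vessel = 1500,
    edge_amp = 80, edge_width_um = 25)
  intensity <- modifyList(default_intensity, intensity)
  cfg <- structure(list(
    width_um = width_um, height_um = height_um, pixel_size_um = pixel_size_um,
    tissue_margin_um = tissue_margin_um, regions = regions,
    nucleus_density = nucleus_density,
    pericyte_fraction = pericyte_fraction,
    microglia_fraction = microglia_fraction,
    nucleus_radius_um = nucleus_radius_um, intensity = intensity,
    capillary_density_mm_per_mm2 = capillary_density_mm_per_mm2,
    large_vessel_count = large_vessel_count,
    dim_fraction = dim_fraction, dim_factor = dim_factor,
    touching_fraction = touching_fraction,
    min_separation_factor = min_separation_factor,
    noise_sd = noise_sd, seed = as.integer(seed)), class = "section_config")
  validate_section_config(cfg)
  cfg
}

validate_section_config <- function(cfg) {
  stopifnot(cfg$pixel_size_um > 0, cfg$width_um > 0, cfg$height_um > 0)
  rn <- names(cfg$regions)
  if (is.null(rn) || anyDuplicated(rn)) stop("regions must be uniquely named")
  for (v in c("nucleus_density", "pericyte_fraction", "microglia_fraction")) {
    if (!all(rn %in% names(cfg[[v]]))) {
      stop(v, " must be named for every region")
    }
  }
  if (any(cfg$nucleus_density < 0)) stop("densities must be >= 0")
  pf <- cfg$pericyte_fraction[rn]; mf <- cfg$microglia_fraction[rn]
  if (any(pf < 0 | pf > 1 | mf < 0 | mf > 1 | pf + mf > 1)) {
    stop("class fractions must lie in [0, 1] with pericyte + microglia <= 1")
  }
  # regions must be pairwise disjoint: no vertex containment, no edge crossing
  polys <- lapply(cfg$regions, as.matrix)
  nr <- length(polys)
  if (nr > 1) {
    for (i in 1:(nr - 1)) for (j in (i + 1):nr) {
      a <- polys[[i]]; b <- polys[[j]]
      if (any(point_in_polygon(a[, 1], a[, 2], b)) ||
          any(point_in_polygon(b[, 1], b[, 2], a)) ||
          polys_edges_cross(a, b)) {
        stop("region polygons overlap: ", rn[i], " and ", rn[j])
      }
    }
  }
  invisible(cfg)
}

polys_edges_cross <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) {
    p1 <- a[i, ]; p2 <- a[if (i == na) 1 else i + 1, ]
    for (j in seq_len(nb)) {
      if (segments_cross(p1, p2, b[j, ], b[j %% nb + 1, ])) return(TRUE)
    }
  }
  FALSE
}

# truncated-normal draw, clamped to mean +/- 2 sd (keeps classes separable)
rnorm_clamped <- function(n, mean, sd) {
  pmin(pmax(rnorm(n, mean, sd), mean - 2 * sd), mean + 2 * sd)
}

# Patch builders: each returns a small sub-raster (rows, cols, values) or an
# index set that the caller max-combines into a layer in its own frame --
# mutating a big matrix across a function boundary would copy all of it.

# isotropic radial profile patch (pixel-center coords)
radial_patch <- function(d, x_um, y_um, s, radius_px, amp, core_frac = 0.7,
                         tail_frac = 0.3) {
  cc <- x_um / s + 0.5; rr <- y_um / s + 0.5
  ext <- ceiling(radius_px * 2)
  cs <- max(1, floor(cc - ext)):min(d[2], ceiling(cc + ext))
  rs <- max(1, floor(rr - ext)):min(d[1], ceiling(rr + ext))
  if (!length(cs) || !length(rs)) return(NULL)
  dist <- sqrt(outer((rs - rr)^2, (cs - cc)^2, "+"))
  core <- core_frac * radius_px
  sigma <- max(tail_frac * radius_px, 0.5)
  prof <- exp(-pmax(dist - core, 0)^2 / (2 * sigma^2))
  list(rs = rs, cs = cs, vals = amp * prof)
}

# elliptical plateau patch (theta radians, semi-axes in px)
ellipse_patch <- function(d, x_um, y_um, s, a_px, b_px, theta, amp,
                          tail_px = 1.5) {
  cc <- x_um / s + 0.5; rr <- y_um / s + 0.5
  ext <- ceiling(max(a_px, b_px) + 3 * tail_px)
  cs <- max(1, floor(cc - ext)):min(d[2], ceiling(cc + ext))
  rs <- max(1, floor(rr - ext)):min(d[1], ceiling(rr + ext))
  if (!length(cs) || !length(rs)) return(NULL)
  dx <- matrix(rep(cs - cc, each = length(rs)), length(rs))
  dy <- matrix(rep(rs - rr, times = length(cs)), length(rs))
  u <- sqrt((( dx * cos(theta) + dy * sin(theta)) / a_px)^2 +
            ((-dx * sin(theta) + dy * cos(theta)) / b_px)^2)
  over <- pmax(u - 1, 0) * b_px
  prof <- exp(-over^2 / (2 * tail_px^2))
  prof[u <= 1] <- 1
  list(rs = rs, cs = cs, vals = amp * prof)
}

# flat polyline of given width; vertices in μm; returns flat pixel indices
polyline_patch <- function(d, verts_um, s, width_um) {
  pts <- NULL
  for (i in seq_len(nrow(verts_um) - 1)) {
    p <- verts_um[i, ]; q <- verts_um[i + 1, ]
    len <- sqrt(sum((q - p)^2))
    n <- max(2L, ceiling(len / (0.4 * s)))
    t <- seq(0, 1, length.out = n)
    pts <- rbind(pts, cbind(p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2])))
  }
  half <- max(width_um / 2 / s, 0.5)
  k <- ceiling(half)
  off <- expand.grid(dr = -k:k, dc = -k:k)
  off <- off[off$dr^2 + off$dc^2 <= half^2, , drop = FALSE]
  ccol <- round(pts[, 1] / s + 0.5); crow <- round(pts[, 2] / s + 0.5)
  rows <- rep(crow, each = nrow(off)) + off$dr
  cols <- rep(ccol, each = nrow(off)) + off$dc
  keep <- rows >= 1 & rows <= d[1] & cols >= 1 & cols <= d[2]
  unique((cols[keep] - 1L) * d[1] + rows[keep])
}

# jittered random-walk polyline starting at (x, y), in μm
random_walk_um <- function(x, y, n_steps, step_um, theta0, jitter = 0.5) {
  theta <- theta0
  out <- matrix(NA_real_, n_steps + 1, 2)
  out[1, ] <- c(x, y)
  for (i in seq_len(n_steps)) {
    theta <- theta + rnorm(1, 0, jitter)
    out[i + 1, ] <- out[i, ] + step_um * c(cos(theta), sin(theta))
  }
  out
}

#' Generate a synthetic section with ground truth
#'
#' @param config a [section_config()].
#' @return list with `image` (a `section_image`), `cells` (data.frame
#'   `id, x_um, y_um, radius_um, class, region` — the ground truth; class is
#'   one of `pericyte`, `microglia`, `negative`), and `annotations`
#'   (an `annotation_set` holding the region polygons in pixel coordinates).
#' @export
generate_section <- function(config) {
  validate_section_config(config)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  s <- config$pixel_size_um
  W <- config$width_um; H <- config$height_um
  ncol_px <- round(W / s); nrow_px <- round(H / s)
  if (nrow_px * ncol_px > 4200^2) stop("section exceeds the supported raster size")
  dims <- c(nrow_px, ncol_px)
  m <- config$tissue_margin_um
  it <- config$intensity

  # ---- large vessels (first, so nuclei can avoid their footprint) ----------
  vessel_layer <- matrix(0, dims[1], dims[2])
  for (v in seq_len(config$large_vessel_count)) {
    start <- c(runif(1, m + 100, W - m - 100), runif(1, m + 100, H - m - 100))
    walk <- random_walk_um(start[1], start[2], n_steps = 25, step_um = 8,
                           theta0 = runif(1, 0, 2 * pi), jitter = 0.25)
    walk[, 1] <- pmin(pmax(walk[, 1], m + 20), W - m - 20)
    walk[, 2] <- pmin(pmax(walk[, 2], m + 20), H - m - 20)
    idx <- polyline_patch(dims, walk, s, width_um = runif(1, 12, 20))
    vessel_layer[idx] <- pmax(vessel_layer[idx], it$vessel)
  }
  vessel_footprint <- vessel_layer > 0

  # ---- nucleus placement ---------------------------------------------------
  rn <- names(config$regions)
  minf <- config$min_separation_factor
  in_vessel <- function(x, y) {
    r <- pmin(pmax(round(y / s + 0.5), 1), dims[1])
    c <- pmin(pmax(round(x / s + 0.5), 1), dims[2])
    vessel_footprint[(c - 1) * dims[1] + r]
  }
  n_by_region <- vapply(rn, function(reg) {
    a_mm2 <- polygon_area(as.matrix(config$regions[[reg]])) / 1e6
    rpois(1, config$nucleus_density[[reg]] * a_mm2)
  }, 0)
  n_max <- sum(n_by_region)
  accx <- accy <- accr <- numeric(n_max)
  cls <- chr_region <- character(n_max)
  cnt <- 0L
  for (reg in rn) {
    poly <- as.matrix(config$regions[[reg]])
    n_total <- n_by_region[[reg]]
    if (n_total == 0) next
    n_pairs <- min(round(config$touching_fraction * n_total / 2), n_total %/% 2)
    n_free <- n_total - n_pairs
    radii <- rnorm_clamped(n_total, config$nucleus_radius_um[["mean"]],
                           config$nucleus_radius_um[["sd"]])
    radii <- pmax(radii, 1.5)
    probs <- c(config$pericyte_fraction[[reg]], config$microglia_fraction[[reg]])
    classes <- sample(c("pericyte", "microglia", "negative"), n_total,
                      replace = TRUE, prob = c(probs, 1 - sum(probs)))
    bb <- apply(poly, 2, range)
    region_first <- cnt + 1L  # first cell of this region (for pair hosts)
    # rejection sampling in vectorized batches
    placed_i <- 0L
    for (batch in seq_len(60)) {
      if (placed_i >= n_free) break
      nb <- max(200L, 3L * (n_free - placed_i))
      xs <- runif(nb, bb[1, 1], bb[2, 1]); ys <- runif(nb, bb[1, 2], bb[2, 2])
      ok <- point_in_polygon(xs, ys, poly) & !in_vessel(xs, ys)
      for (k in which(ok)) {
        if (placed_i >= n_free) break
        i <- placed_i + 1L
        sel <- seq_len(cnt)
        if (cnt > 0L &&
            any((accx[sel] - xs[k])^2 + (accy[sel] - ys[k])^2 <
                (minf * (accr[sel] + radii[i]))^2)) next
        cnt <- cnt + 1L; placed_i <- i
        accx[cnt] <- xs[k]; accy[cnt] <- ys[k]; accr[cnt] <- radii[i]
        cls[cnt] <- classes[i]; chr_region[cnt] <- reg
      }
    }
    if (placed_i < n_free) {
      stop("nucleus placement failed in region '", reg, "'")
    }
    # deliberately touching pairs: partner placed next to a random host
    for (k in seq_len(n_pairs)) {
      i <- n_free + k
      placed <- FALSE
      for (try in seq_len(300)) {
        h <- sample(region_first:cnt, 1)
        ang <- runif(1, 0, 2 * pi)
        dist <- 0.95 * (accr[h] + radii[i])
        x <- accx[h] + dist * cos(ang); y <- accy[h] + dist * sin(ang)
        if (!point_in_polygon(x, y, poly)) next
        if (in_vessel(x, y)) next
        sel <- setdiff(seq_len(cnt), h)
        if (length(sel) &&
            any((accx[sel] - x)^2 + (accy[sel] - y)^2 <
                (minf * (accr[sel] + radii[i]))^2)) next
        placed <- TRUE
        break
      }
      if (!placed) stop("nucleus placement failed in region '", reg, "'")
      cnt <- cnt + 1L
      accx[cnt] <- x; accy[cnt] <- y; accr[cnt] <- radii[i]
      cls[cnt] <- classes[i]; chr_region[cnt] <- reg
    }
  }
  n_cells <- cnt
  keep <- seq_len(cnt)
  accx <- accx[keep]; accy <- accy[keep]; accr <- accr[keep]
  cls <- cls[keep]; chr_region <- chr_region[keep]
  cells <- data.frame(id = seq_len(n_cells), x_um = accx, y_um = accy,
                      radius_um = accr, class = cls, region = chr_region,
                      stringsAsFactors = FALSE)

  # ---- DAPI nuclei ---------------------------------------------------------
  dapi_layer <- matrix(0, dims[1], dims[2])
  dapi_amp <- rnorm_clamped(n_cells, it$dapi_fg[["mean"]], it$dapi_fg[["sd"]])
  dim_flag <- runif(n_cells) < config$dim_fraction
  dapi_amp[dim_flag] <- dapi_amp[dim_flag] * config$dim_factor
  for (i in seq_len(n_cells)) {
    p <- radial_patch(dims, accx[i], accy[i], s, radius_px = accr[i] / s,
                      amp = dapi_amp[i])
    if (!is.null(p)) {
      dapi_layer[p$rs, p$cs] <- pmax(dapi_layer[p$rs, p$cs], p$vals)
    }
  }

  # ---- capillary network + pericyte somata (DsRed) -------------------------
  dsred_layer <- vessel_layer
  peri <- which(cls == "pericyte")
  peri_theta <- runif(length(peri), 0, pi)
  cap_len_used <- 0
  for (k in seq_along(peri)) {
    i <- peri[k]
    len <- runif(1, 50, 80)
    th <- peri_theta[k]
    seg <- rbind(c(accx[i] - len / 2 * cos(th), accy[i] - len / 2 * sin(th)),
                 c(accx[i] + len / 2 * cos(th), accy[i] + len / 2 * sin(th)))
    idx <- polyline_patch(dims, seg, s, width_um = 2.5)
    dsred_layer[idx] <- pmax(dsred_layer[idx], it$capillary)
    cap_len_used <- cap_len_used + len
  }
  tissue_area_mm2 <- (W - 2 * m) * (H - 2 * m) / 1e6
  target_um <- config$capillary_density_mm_per_mm2 * tissue_area_mm2 * 1000
  n_bg_caps <- max(0, round((target_um - cap_len_used) / 65))
  for (k in seq_len(n_bg_caps)) {
    x0 <- runif(1, m + 10, W - m - 10); y0 <- runif(1, m + 10, H - m - 10)
    walk <- random_walk_um(x0, y0, n_steps = 3, step_um = runif(1, 15, 25),
                           theta0 = runif(1, 0, 2 * pi), jitter = 0.3)
    idx <- polyline_patch(dims, walk, s, width_um = 2.5)
    dsred_layer[idx] <- pmax(dsred_layer[idx], it$capillary)
  }
  dsred_amp <- rnorm_clamped(length(peri), it$dsred_fg[["mean"]],
                             it$dsred_fg[["sd"]])
  for (k in seq_along(peri)) {
    i <- peri[k]
    p <- ellipse_patch(dims, accx[i], accy[i], s, a_px = (accr[i] + 4) / s,
                       b_px = (accr[i] + 3) / s, theta = peri_theta[k],
                       amp = dsred_amp[k])
    if (!is.null(p)) {
      dsred_layer[p$rs, p$cs] <- pmax(dsred_layer[p$rs, p$cs], p$vals)
    }
  }

  # ---- microglia somata + processes (GFP) ----------------------------------
  gfp_layer <- matrix(0, dims[1], dims[2])
  micro <- which(cls == "microglia")
  gfp_amp <- rnorm_clamped(length(micro), it$gfp_fg[["mean"]],
                           it$gfp_fg[["sd"]])
  for (k in seq_along(micro)) {
    i <- micro[k]
    n_proc <- sample(2:5, 1)
    for (p in seq_len(n_proc)) {
      walk <- random_walk_um(accx[i], accy[i], n_steps = sample(8:16, 1),
                             step_um = 2, theta0 = runif(1, 0, 2 * pi))
      idx <- polyline_patch(dims, walk, s, width_um = 1.3)
      gfp_layer[idx] <- pmax(gfp_layer[idx], it$process)
    }
    p <- radial_patch(dims, accx[i], accy[i], s,
                      radius_px = (accr[i] + 3) / s, amp = gfp_amp[k],
                      core_frac = 0.85, tail_frac = 0.15)
    if (!is.null(p)) {
      gfp_layer[p$rs, p$cs] <- pmax(gfp_layer[p$rs, p$cs], p$vals)
    }
  }

  # ---- compose channels ----------------------------------------------------
  xc <- (seq_len(dims[2]) - 0.5) * s
  yc <- (seq_len(dims[1]) - 0.5) * s
  in_tissue_x <- xc >= m & xc < W - m
  in_tissue_y <- yc >= m & yc < H - m
  tissue_mat <- outer(in_tissue_y, in_tissue_x, "&")
  edge_dist <- outer(pmin(yc - m, H - m - yc), pmin(xc - m, W - m - xc), pmin)
  ramp <- it$edge_amp * pmax(0, 1 - edge_dist / it$edge_width_um)
  ramp[!tissue_mat] <- 0

  region_rasters <- NULL
  bg_is_list <- is.list(it$background)
  if (bg_is_list) {
    region_rasters <- lapply(config$regions, function(p) {
      rasterize_polygon(as.matrix(p) / s, dims)
    })
  }
  bg_for <- function(ch, reg) {
    if (!bg_is_list) return(it$background[[ch]])
    src <- if (!is.null(it$background[[reg]])) it$background[[reg]]
           else it$background[["tissue"]]
    src[[ch]]
  }
  layers <- list(DAPI = dapi_layer, DsRed = dsred_layer, GFP = gfp_layer)
  channels <- lapply(c(DAPI = "DAPI", DsRed = "DsRed", GFP = "GFP"), function(ch) {
    base <- matrix(it$outside[[ch]], dims[1], dims[2])
    base[tissue_mat] <- bg_for(ch, "tissue")
    if (bg_is_list) {
      for (reg in rn) base[region_rasters[[reg]]] <- bg_for(ch, reg)
    }
    img <- base + ramp + layers[[ch]]
    img <- img + rnorm(length(img), 0, config$noise_sd)
    matrix(pmin(pmax(round(img), 0), 65535), dims[1], dims[2])
  })

  region_features <- lapply(rn, function(reg) {
    list(name = reg, role = "region",
         parts = list(list(outer = as.matrix(config$regions[[reg]]) / s,
                           holes = list())))
  })
  list(image = section_image(channels, s),
       cells = cells,
       annotations = annotation_set(region_features, pixel_size_um = s))
}

#' Place one axis-aligned test rectangle inside each region
#'
#' Emulates the placement of small manual-counting annotations (default
#' 300 x 200 um) inside each brain region. Rectangles are sampled uniformly
#' and must be fully contained in the region polygon.
#'
#' @param regions an `annotation_set` holding `role = "region"` features
#'   (pixel coordinates), e.g. from [generate_section()].
#' @param size_um `c(width, height)` of each rectangle in micrometres.
#' @param seed RNG seed for placement.
#' @param pixel_size_um μm per pixel; defaults to the attribute carried by
#'   `regions`.
#' @return an `annotation_set` of `role = "test-rect"` rectangles (pixel
#'   coordinates), one per region, named after the region.
#' @export
generate_test_annotations <- function(regions, size_um = c(300, 200), seed = 1L,
                                      pixel_size_um = attr(regions, "pixel_size_um")) {
  if (is.null(pixel_size_um)) {
    stop("pixel_size_um is required (not carried by this annotation set)")
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  s <- pixel_size_um
  w_px <- size_um[1] / s; h_px <- size_um[2] / s
  feats <- list()
  for (f in annotation_features(regions, role = "region")) {
    areas <- vapply(f$parts, function(p) polygon_area(p$outer), 0)
    placed <- FALSE
    for (try in seq_len(500)) {
      part <- f$parts[[sample.int(length(f$parts), 1, prob = areas)]]
      bb <- apply(part$outer, 2, range)
      if (bb[2, 1] - bb[1, 1] < w_px || bb[2, 2] - bb[1, 2] < h_px) break
      x0 <- runif(1, bb[1, 1], bb[2, 1] - w_px)
      y0 <- runif(1, bb[1, 2], bb[2, 2] - h_px)
      # exact fit: degenerate sampling interval means the rect IS the bbox
      if (rect_inside_part(x0, y0, w_px, h_px, part) ||
          rect_equals_part(x0, y0, w_px, h_px, part)) {
        feats[[length(feats) + 1]] <- list(
          name = f$name, role = "test-rect",
          parts = list(list(outer = rect_polygon(x0, y0, w_px, h_px),
                            holes = list())))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("region '", f$name, "' cannot contain a ", size_um[1], " x ",
           size_um[2], " um test annotation")
    }
  }
  annotation_set(feats, pixel_size_um = s)
}

# a rectangle equal to a rectangular region counts as contained
rect_equals_part <- function(x0, y0, w, h, part) {
  if (length(part$holes) || nrow(part$outer) != 4) return(FALSE)
  bb <- apply(part$outer, 2, range)
  isTRUE(all.equal(unname(c(bb[1, 1], bb[1, 2], bb[2, 1] - bb[1, 1],
                            bb[2, 2] - bb[1, 2])),
                   c(x0, y0, w, h), tolerance = 1e-9)) &&
    isTRUE(all.equal(polygon_area(part$outer), w * h, tolerance = 1e-9))
}

#' Ground-truth counts inside a polygon (manual-count stand-in)
#'
#' Counts ground-truth cells whose centroid falls inside the polygon, using
#' the package's single point-in-polygon convention (even-odd ray casting).
#'
#' @param cells ground-truth data.frame from [generate_section()].
#' @param polygon n x 2 vertex matrix in micrometres.
#' @return named integer vector `c(total, dsred, gfp)`.
#' @export
ground_truth_counts <- function(cells, polygon) {
  if (nrow(cells) == 0) {
    return(c(total = 0L, dsred = 0L, gfp = 0L))
  }
  inside <- point_in_polygon(cells$x_um, cells$y_um, polygon)
  c(total = sum(inside),
    dsred = sum(inside & cells$class == "pericyte"),
    gfp = sum(inside & cells$class == "microglia"))
}

#' Tabulate test rectangles in micrometres
#'
#' Convenience accessor turning a `role = "test-rect"` annotation set into a
#' data.frame consumable by [sweep_spec()].
#'
#' @param rects annotation set from [generate_test_annotations()].
#' @param section section identifier to attach to every row.
#' @return data.frame with columns `section, region, x_um, y_um, w_um, h_um`.
#' @export
test_rect_table <- function(rects, section = "section1") {
  s <- attr(rects, "pixel_size_um")
  if (is.null(s)) stop("annotation set does not carry a pixel size")
  rows <- lapply(annotation_features(rects, role = "test-rect"), function(f) {
    bb <- apply(f$parts[[1]]$outer, 2, range)
    data.frame(section = section, region = f$name,
               x_um = bb[1, 1] * s, y_um = bb[1, 2] * s,
               w_um = (bb[2, 1] - bb[1, 1]) * s,
               h_um = (bb[2, 2] - bb[1, 2]) * s,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
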