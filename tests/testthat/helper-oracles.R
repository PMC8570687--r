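# Brute-force oracles, written independently of the package internals.
# All are plain per-point / per-pixel loops; slow but unambiguous.

# scalar crossing-number point-in-polygon (loop over points)
pip_oracle <- function(x, y, poly) {
  vapply(seq_along(x), function(k) {
    inside <- FALSE
    n <- nrow(poly)
    j <- n
    for (i in seq_len(n)) {
      xi <- poly[i, 1]; yi <- poly[i, 2]
      xj <- poly[j, 1]; yj <- poly[j, 2]
      if ((yi > y[k]) != (yj > y[k])) {
        xint <- (xj - xi) * (y[k] - yi) / (yj - yi) + xi
        if (x[k] < xint) inside <- !inside
      }
      j <- i
    }
    inside
  }, TRUE)
}

# per-pixel binary erosion with an explicit offset set (dx^2+dy^2 <= r^2)
erode_oracle <- function(mask, r_px) {
  r <- as.integer(round(r_px))
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r_px^2 + 1e-9, ]
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (!mask[i, j]) next
      keep <- TRUE
      for (k in seq_len(nrow(offs))) {
        ii <- i + offs$dr[k]; jj <- j + offs$dc[k]
        if (ii < 1 || ii > nrow(mask) || jj < 1 || jj > ncol(mask) ||
            !mask[ii, jj]) {
          keep <- FALSE
          break
        }
      }
      out[i, j] <- keep
    }
  }
  out
}

# per-pixel logical oracles
subtract_oracle <- function(a, b) {
  out <- matrix(FALSE, nrow(a), ncol(a))
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    out[i, j] <- a[i, j] && !b[i, j]
  }
  out
}
intersect_oracle <- function(a, b) {
  out <- matrix(FALSE, nrow(a), ncol(a))
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    out[i, j] <- a[i, j] && b[i, j]
  }
  out
}

# mean intensity over the pixels of one label, by explicit loop
label_mean_oracle <- function(lab, values, id) {
  tot <- 0; n <- 0
  for (i in seq_len(nrow(lab))) for (j in seq_len(ncol(lab))) {
    if (lab[i, j] == id) {
      tot <- tot + values[i, j]
      n <- n + 1
    }
  }
  tot / n
}

# greedy nearest-neighbour matching of detections to ground-truth centroids
match_detections <- function(det_tab, cells, max_dist_um = 3) {
  if (nrow(det_tab) == 0 || nrow(cells) == 0) {
    return(list(matched = integer(0), recall = 0,
                spurious = nrow(det_tab)))
  }
  d2 <- outer(det_tab$x_um, cells$x_um, "-")^2 +
        outer(det_tab$y_um, cells$y_um, "-")^2
  matched_det <- rep(NA_integer_, nrow(cells))
  used <- rep(FALSE, nrow(det_tab))
  ord <- order(apply(d2, 2, min))
  for (k in ord) {
    cand <- order(d2[, k])
    for (i in cand) {
      if (d2[i, k] > max_dist_um^2) break
      if (!used[i]) {
        used[i] <- TRUE
        matched_det[k] <- i
        break
      }
    }
  }
  list(matched = matched_det,
       recall = mean(!is.na(matched_det)),
       spurious = sum(!used))
}
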