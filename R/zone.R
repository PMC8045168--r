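# ---- planar polygon utilities (frame coordinates, mm) ----

poly_area_signed <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]) / 2
}

poly_centroid <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  cr <- p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((p[, 1] + p[i2, 1]) * cr), sum((p[, 2] + p[i2, 2]) * cr)) / (6 * a)
}

# even-odd point-in-polygon, vectorized over query points (qx, qy)
points_in_poly <- function(qx, qy, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(qx))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > qy) != (yj > qy)) &
      (qx < (xj - xi) * (qy - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# min distance from query points to the polygon boundary
dist_to_poly_boundary <- function(qx, qy, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, length(qx))
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]
    ex <- poly[i, 1] - x1; ey <- poly[i, 2] - y1
    len2 <- ex^2 + ey^2
    if (len2 < 1e-18) { j <- i; next }
    t <- pmin(1, pmax(0, ((qx - x1) * ex + (qy - y1) * ey) / len2))
    d2 <- pmin(d2, (qx - (x1 + t * ex))^2 + (qy - (y1 + t * ey))^2)
    j <- i
  }
  sqrt(d2)
}

# Sutherland-Hodgman clip against half-plane {p : n . p <= c}
clip_halfplane <- function(poly, nrm, cval) {
  s <- poly %*% nrm - cval
  n <- nrow(poly)
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- s[i] <= 1e-12; pj_in <- s[j] <= 1e-12
    if (pi_in) out <- rbind(out, poly[i, ])
    if (pi_in != pj_in) {
      t <- s[i] / (s[i] - s[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# 8-connected components of a logical matrix, by run merging (union-find).
label_components8 <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  runs <- list(); col_runs <- vector("list", ny)
  for (j in seq_len(ny)) {
    r <- rle(mask[, j])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values)
    if (length(sel)) {
      ids <- length(runs) + seq_along(sel)
      for (k in seq_along(sel))
        runs[[ids[k]]] <- c(starts[sel[k]], ends[sel[k]], j)
      col_runs[[j]] <- ids
    }
  }
  nr <- length(runs)
  if (nr == 0L) return(list(labels = matrix(0L, nx, ny), n = 0L))
  parent <- seq_len(nr)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (j in 2:max(2L, ny)) {
    if (j > ny) break
    for (a in col_runs[[j]]) for (b in col_runs[[j - 1L]]) {
      # 8-connectivity: vertical ranges touching within one pixel
      if (runs[[a]][1] <= runs[[b]][2] + 1L && runs[[b]][1] <= runs[[a]][2] + 1L)
        parent[find(a)] <- find(b)
    }
  }
  roots <- vapply(seq_len(nr), find, integer(1))
  comp <- match(roots, unique(roots))
  labels <- matrix(0L, nx, ny)
  for (k in seq_len(nr)) {
    rn <- runs[[k]]
    labels[rn[1]:rn[2], rn[3]] <- comp[k]
  }
  list(labels = labels, n = length(unique(roots)))
}

# ---- safe zone ----

# sub-pixel outline (0.5-level contour of the pixel-center indicator) of a
# logical pixel mask; returns the largest ring, counter-clockwise
mask_to_polygon <- function(mask, fr) {
  ucs <- fr$umin + (seq_len(fr$nx) - 0.5) * fr$spacing
  vcs <- fr$vmin + (seq_len(fr$ny) - 0.5) * fr$spacing
  # pad so the contour closes around boundary-touching components
  z <- matrix(0, fr$nx + 2, fr$ny + 2)
  z[2:(fr$nx + 1), 2:(fr$ny + 1)] <- mask * 1
  xs <- c(ucs[1] - fr$spacing, ucs, ucs[fr$nx] + fr$spacing)
  ys <- c(vcs[1] - fr$spacing, vcs, vcs[fr$ny] + fr$spacing)
  cl <- grDevices::contourLines(xs, ys, z, levels = 0.5)
  if (length(cl) == 0L) stop("no corridor: contour tracing failed")
  rings <- lapply(cl, function(cc) cbind(cc$x, cc$y))
  areas <- vapply(rings, function(r) abs(poly_area_signed(r)), numeric(1))
  ring <- rings[[which.max(areas)]]
  if (poly_area_signed(ring) < 0) ring <- ring[rev(seq_len(nrow(ring))), ]
  simplify_ring(ring)
}

# drop collinear run vertices (contours along pixel rows produce many)
simplify_ring <- function(ring, tol = 1e-9) {
  n <- nrow(ring)
  if (n < 5) return(ring)
  prev <- rbind(ring[n, ], ring[-n, ])
  nxt <- rbind(ring[-1, ], ring[1, ])
  cr <- (ring[, 1] - prev[, 1]) * (nxt[, 2] - ring[, 2]) -
    (ring[, 2] - prev[, 2]) * (nxt[, 1] - ring[, 1])
  keep <- abs(cr) > tol
  if (sum(keep) < 4) return(ring)
  ring[keep, , drop = FALSE]
}

#' Extract the safe-zone polygon from a corridor map
#'
#' Takes the largest 8-connected component of safe pixels and traces its
#' outline to a sub-pixel polygon (0.5-level contour of the pixel-center
#' indicator). The zone's area, centroid and principal axes (from the
#' second moments of the safe pixels) are attached.
#'
#' @param map a [safe_map()].
#' @return object of class `safe_zone`: `polygon` (ring matrix in frame mm
#'   coordinates), `area` (mm^2), `centroid`, `axes` (rows: major, minor
#'   unit vectors), `n_pixels`, `frame`.
#' @export
extract_safe_zone <- function(map) {
  if (!any(map$safe)) stop("no corridor: map has no safe pixels")
  lab <- label_components8(map$safe)
  sizes <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$n)
  keep <- which.max(sizes)
  mask <- lab$labels == keep
  if (sum(mask) < 4L)
    stop("no corridor: largest safe component is degenerate (",
         sum(mask), " px)")
  fr <- map$frame
  ucs <- fr$umin + (seq_len(fr$nx) - 0.5) * fr$spacing
  vcs <- fr$vmin + (seq_len(fr$ny) - 0.5) * fr$spacing
  ring <- mask_to_polygon(mask, fr)
  pts <- cbind(ucs[row(mask)[mask]], vcs[col(mask)[mask]])
  cv <- stats::cov(pts)
  eg <- eigen(cv, symmetric = TRUE)
  axes <- t(eg$vectors)            # rows: major then minor
  # deterministic sign: major axis points toward positive v (or positive u)
  for (k in 1:2) {
    s <- if (abs(axes[k, 2]) > 1e-9) sign(axes[k, 2]) else sign(axes[k, 1])
    axes[k, ] <- axes[k, ] * s
  }
  structure(list(polygon = ring, area = abs(poly_area_signed(ring)),
                 centroid = poly_centroid(ring), axes = axes,
                 n_pixels = sum(mask), frame = fr),
            class = "safe_zone")
}

#' @export
print.safe_zone <- function(x, ...) {
  cat(sprintf("safe_zone: area %.2f mm^2 (%d px), centroid (%.2f, %.2f)\n",
              x$area, x$n_pixels, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Split the safe zone evenly into medial and lateral halves
#'
#' The split line is perpendicular to the zone's major principal axis; its
#' offset along that axis is found by bisection so the two halves have equal
#' area. The half nearer the projected acromioclavicular facet is labelled
#' medial; without a landmark the half with the smaller coordinate along the
#' major axis is medial.
#'
#' @param zone a [safe_zone()].
#' @param facet_uv optional in-plane (u, v) coordinates of the AC facet.
#' @return list with `medial` and `lateral` (each: `polygon`, `area`,
#'   `centroid`), plus `line` (list of `point`, `normal`).
#' @export
split_zone <- function(zone, facet_uv = NULL) {
  m <- zone$axes[1, ]                 # major axis: halves separated along it
  proj <- zone$polygon %*% m
  lo <- min(proj); hi <- max(proj)
  target <- zone$area / 2
  area_below <- function(o) {
    h <- clip_halfplane(zone$polygon, m, o)
    if (nrow(h) < 3) 0 else abs(poly_area_signed(h))
  }
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (area_below(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < 1e-9) break
  }
  o <- (lo + hi) / 2
  h1 <- clip_halfplane(zone$polygon, m, o)    # m . p <= o
  h2 <- clip_halfplane(zone$polygon, -m, -o)
  mk <- function(p) list(polygon = p, area = abs(poly_area_signed(p)),
                         centroid = poly_centroid(p))
  h1 <- mk(h1); h2 <- mk(h2)
  if (is.null(facet_uv)) {
    medial_first <- sum(h1$centroid * m) < sum(h2$centroid * m)
  } else {
    medial_first <- sum((h1$centroid - facet_uv)^2) <
      sum((h2$centroid - facet_uv)^2)
  }
  out <- if (medial_first) list(medial = h1, lateral = h2)
         else list(medial = h2, lateral = h1)
  out$line <- list(point = zone$centroid + (o - sum(zone$centroid * m)) * m,
                   normal = m)
  out
}

#' Maximum inscribed circle of a planar region
#'
#' Grid search over the distance-to-boundary field followed by local
#' simplex polish; the reported radius is accurate to about 0.05 mm for
#' well-resolved regions. Ties are broken toward the smallest (u, then v)
#' center.
#'
#' @param poly ring matrix (two columns, mm).
#' @return list with `center` (length 2) and `radius` (mm).
#' @export
max_inscribed_circle <- function(poly) {
  if (is.list(poly) && !is.null(poly$polygon)) poly <- poly$polygon
  if (nrow(poly) < 3 || abs(poly_area_signed(poly)) < 1e-9)
    stop("degenerate region: cannot inscribe a circle")
  bb <- apply(poly, 2, range)
  span <- pmax(bb[2, ] - bb[1, ], 1e-6)
  h <- max(min(span) / 48, 0.08)
  gx <- seq(bb[1, 1] + h / 2, bb[2, 1], by = h)
  gy <- seq(bb[1, 2] + h / 2, bb[2, 2], by = h)
  qx <- rep(gx, times = length(gy))
  qy <- rep(gy, each = length(gx))
  keep <- points_in_poly(qx, qy, poly)
  if (!any(keep)) stop("degenerate region: no interior grid point")
  qx <- qx[keep]; qy <- qy[keep]
  d <- dist_to_poly_boundary(qx, qy, poly)
  # tie-break: smallest u then v among near-maximal candidates
  near <- which(d > max(d) - 1e-9)
  best <- near[order(qx[near], qy[near])][1]
  sd_fun <- function(p) {
    db <- dist_to_poly_boundary(p[1], p[2], poly)
    if (points_in_poly(p[1], p[2], poly)) -db else db
  }
  op <- stats::optim(c(qx[best], qy[best]), sd_fun, method = "Nelder-Mead",
                     control = list(reltol = 1e-10, maxit = 400))
  cen <- op$par; rad <- -op$value
  if (rad < d[best]) { cen <- c(qx[best], qy[best]); rad <- d[best] }
  list(center = cen, radius = rad)
}
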