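# Independent oracles used across the suite.
#
# march_classify() re-derives the per-pixel ray classification by marching
# the *analytic* inside() predicate of a generated solid in fixed steps —
# it never touches the package's triangle ray caster, so agreement between
# the two is a genuine cross-check.

# classify every pixel of a safe_map's frame by ray marching the predicate
march_classify <- function(inside, map, step = 0.2) {
  fr <- map$frame
  ucs <- fr$umin + (seq_len(fr$nx) - 0.5) * fr$spacing
  vcs <- fr$vmin + (seq_len(fr$ny) - 0.5) * fr$spacing
  uu <- rep(ucs, times = fr$ny)
  vv <- rep(vcs, each = fr$nx)
  base <- outer(uu, fr$u) + outer(vv, fr$v)
  base <- sweep(base, 2, fr$origin, "+")
  tr <- range(c(map$tin, map$tout), na.rm = TRUE) + c(-5, 5)
  ts <- seq(tr[1], tr[2], by = step)
  np <- length(uu)
  n_runs <- integer(np); cur <- numeric(np); run1 <- numeric(np)
  prev <- rep(FALSE, np)
  for (t in ts) {
    P <- base + outer(rep(t, np), fr$d)
    inb <- inside(P)
    entering <- inb & !prev
    leaving <- !inb & prev
    n_runs[entering] <- n_runs[entering] + 1L
    cur[inb] <- cur[inb] + step
    run1[leaving & n_runs == 1L] <- cur[leaving & n_runs == 1L]
    cur[leaving] <- 0
    prev <- inb
  }
  run1[prev & n_runs == 1L] <- cur[prev & n_runs == 1L]
  count <- matrix(n_runs, fr$nx, fr$ny)
  chord <- matrix(run1, fr$nx, fr$ny)
  safe <- count == 1L & chord >= map$min_chord
  list(count = count, chord = chord, safe = safe)
}

# fraction of pixels whose safe flag matches the oracle's
oracle_agreement <- function(subject_or_inside, map, step = 0.2) {
  inside <- if (is.function(subject_or_inside)) subject_or_inside
            else subject_or_inside$truth$inside
  orc <- march_classify(inside, map, step = step)
  mean(orc$safe == map$safe)
}

# brute-force maximum inscribed circle: coarse full grid then a fine local
# grid (honest refinement of the same exhaustive search)
brute_mic <- function(poly, h_coarse = 0.05, h_fine = 0.01) {
  bb <- apply(poly, 2, range)
  grid_best <- function(x0, x1, y0, y1, h) {
    gx <- seq(x0, x1, by = h); gy <- seq(y0, y1, by = h)
    qx <- rep(gx, times = length(gy)); qy <- rep(gy, each = length(gx))
    keep <- acroplan:::points_in_poly(qx, qy, poly)
    qx <- qx[keep]; qy <- qy[keep]
    d <- acroplan:::dist_to_poly_boundary(qx, qy, poly)
    i <- which.max(d)
    c(qx[i], qy[i], d[i])
  }
  cb <- grid_best(bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], h_coarse)
  fb <- grid_best(cb[1] - 2 * h_coarse, cb[1] + 2 * h_coarse,
                  cb[2] - 2 * h_coarse, cb[2] + 2 * h_coarse, h_fine)
  list(center = fb[1:2], radius = fb[3])
}

# deterministic rigid rotation used by equivariance checks
rot3 <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

angle_between_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

# 12-triangle axis-aligned cuboid (closed, outward-oriented)
cuboid_mesh <- function(lx = 1, ly = 1, lz = 1) {
  v <- as.matrix(expand.grid(x = c(0, lx), y = c(0, ly), z = c(0, lz)))
  # outward-CCW quads over expand.grid vertex order (x fastest)
  quads <- rbind(c(1, 5, 7, 3), c(2, 4, 8, 6), c(1, 2, 6, 5),
                 c(3, 7, 8, 4), c(1, 3, 4, 2), c(5, 6, 8, 7))
  f <- rbind(quads[, c(1, 2, 3)], quads[, c(1, 3, 4)])
  triangle_mesh(v, f)
}
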