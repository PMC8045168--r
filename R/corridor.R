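unit3 <- function(x) {
  n <- sqrt(sum(x^2))
  if (n < 1e-12) stop("zero-length direction")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# An in-plane axis pair for viewing direction d. The u axis is the
# component of the superior reference direction (up_hint) orthogonal to d,
# so "up" in the projected frame is reproducibly superior; v = d x u.
frame_axes <- function(d, up_hint = NULL) {
  d <- unit3(d)
  if (is.null(up_hint)) {
    up_hint <- c(0, 0, 0)
    up_hint[which.min(abs(d))] <- 1
  }
  u <- up_hint - sum(up_hint * d) * d
  if (sqrt(sum(u^2)) < 1e-6)
    stop("up_hint is parallel to the viewing direction")
  u <- unit3(u)
  list(u = u, v = cross3(d, u), d = d)
}

#' Projection frame for parallel-ray queries
#'
#' Pixel grid on the plane orthogonal to the viewing direction `d`, sized to
#' cover the mesh silhouette plus one pixel of padding. Pixel (i, j) has
#' in-plane coordinates `(umin + (i - 0.5) s, vmin + (j - 0.5) s)` and the
#' ray `origin + uc * u + vc * v + t * d`.
#'
#' @param mesh a [triangle_mesh()].
#' @param dir viewing direction (normalized internally).
#' @param spacing pixel size in mm (must be <= 1).
#' @param up_hint superior reference direction fixing the in-plane u axis;
#'   `NULL` picks a coordinate axis.
#' @param grid_offset in-plane shift of the pixel lattice, in pixels
#'   (used for anti-aliased area estimates).
#' @return object of class `projection_frame`.
#' @export
projection_frame <- function(mesh, dir, spacing = 0.25, up_hint = NULL,
                             grid_offset = c(0, 0)) {
  if (spacing <= 0 || spacing > 1)
    stop("spacing must be in (0, 1] mm")
  ax <- frame_axes(dir, up_hint)
  origin <- colMeans(mesh$vertices)
  rel <- sweep(mesh$vertices, 2, origin)
  pu <- rel %*% ax$u
  pv <- rel %*% ax$v
  pad <- spacing
  umin <- min(pu) - pad + grid_offset[1] * spacing
  vmin <- min(pv) - pad + grid_offset[2] * spacing
  nx <- ceiling((max(pu) + pad - umin) / spacing)
  ny <- ceiling((max(pv) + pad - vmin) / spacing)
  structure(list(origin = origin, u = ax$u, v = ax$v, d = ax$d,
                 spacing = spacing, umin = umin, vmin = vmin,
                 nx = as.integer(nx), ny = as.integer(ny)),
            class = "projection_frame")
}

# 3D point of an in-plane coordinate at depth t
frame_point <- function(frame, uc, vc, t = 0) {
  frame$origin + uc * frame$u + vc * frame$v + t * frame$d
}

# in-plane coordinates of 3D points (rows)
frame_project <- function(frame, pts) {
  pts <- matrix(pts, ncol = 3)
  rel <- sweep(pts, 2, frame$origin)
  cbind(rel %*% frame$u, rel %*% frame$v)
}

#' In-bone intervals of a single ray
#'
#' Casts the ray `origin + t * dir` through a watertight solid and returns
#' the ordered, disjoint parameter intervals where the ray is inside bone.
#' Grazing hits are resolved by deterministic sub-ray jitter; geometry still
#' marginal after four retries raises an error.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param origin ray origin (mm).
#' @param dir ray direction (normalized internally).
#' @param .validated internal: skip the watertightness precondition check.
#' @return two-column matrix of (t_in, t_out) rows, strictly increasing;
#'   zero rows for a miss.
#' @export
solid_intervals <- function(mesh, origin, dir, .validated = FALSE) {
  if (!.validated) {
    rep_v <- mesh$provenance$validation
    if (is.null(rep_v)) rep_v <- validate_mesh(mesh)
    if (!rep_v$watertight)
      stop("solid_intervals requires a watertight mesh")
  }
  ax <- frame_axes(dir)
  ts <- cpp_ray_hits(mesh$vertices, mesh$faces - 1L, as.numeric(origin),
                     ax$u, ax$v, ax$d, 0, 0, 1e-3)
  matrix(ts, ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("t_in", "t_out")))
}

#' Safe-corridor map along a viewing direction
#'
#' Casts one ray per pixel of a [projection_frame()] and classifies each:
#' a pixel is *safe* when its ray traverses exactly one continuous in-bone
#' segment whose chord is at least `min_chord` mm — the corridor a straight
#' screw can occupy without breaching and re-entering cortex. This is the
#' computed analogue of the translucent oval seen when rendering the bone
#' semi-transparent down the axis of the distal acromion.
#'
#' @param mesh watertight [triangle_mesh()].
#' @param dir viewing direction.
#' @param spacing pixel size in mm (default 0.25, must be <= 1).
#' @param min_chord minimum in-bone chord for a safe pixel (mm, default 10).
#' @param up_hint superior reference direction (see [projection_frame()]).
#' @param frame optionally a pre-built frame (overrides the geometry args).
#' @param .validated internal: skip the watertightness check.
#' @return object of class `safe_map`: the frame plus per-pixel matrices
#'   `count` (in-bone interval count, -1 = unresolved grazing), `chord`,
#'   `tin`, `tout` (single-interval pixels only) and logical `safe`.
#' @export
safe_map <- function(mesh, dir, spacing = 0.25, min_chord = 10,
                     up_hint = NULL, frame = NULL, .validated = FALSE) {
  if (min_chord < 0) stop("min_chord must be >= 0")
  if (!.validated) {
    rep_v <- mesh$provenance$validation
    if (is.null(rep_v)) rep_v <- validate_mesh(mesh)
    if (!rep_v$watertight) stop("safe_map requires a watertight mesh")
  }
  if (is.null(frame))
    frame <- projection_frame(mesh, dir, spacing = spacing, up_hint = up_hint)
  res <- cpp_safe_map(mesh$vertices, mesh$faces - 1L,
                      frame$origin, frame$u, frame$v, frame$d,
                      frame$umin, frame$vmin, frame$nx, frame$ny,
                      frame$spacing)
  safe <- res$count == 1L & !is.na(res$chord) & res$chord >= min_chord
  structure(list(frame = frame, count = res$count, chord = res$chord,
                 tin = res$tin, tout = res$tout, safe = safe,
                 min_chord = min_chord),
            class = "safe_map")
}

#' @export
print.safe_map <- function(x, ...) {
  cat(sprintf("safe_map: %d x %d px at %.3g mm, safe area %.2f mm^2\n",
              x$frame$nx, x$frame$ny, x$frame$spacing, safe_area(x)))
  invisible(x)
}

#' Safe area of a corridor map
#'
#' Number of safe pixels times the pixel area.
#'
#' @param map a [safe_map()].
#' @return area in mm^2.
#' @export
safe_area <- function(map) {
  sum(map$safe) * map$frame$spacing^2
}

#' Aligned corridor area (the direction-search objective)
#'
#' Area of pixels whose single in-bone chord reaches at least `threshold`
#' mm (by default `frac` of the map's own maximum chord). Unlike the raw
#' safe area — which for a convex rod *grows* when the view tilts off-axis,
#' because tilting adds a band of obliquely-traversing pixels — the area
#' above a long-chord threshold is maximal when the view aligns with the
#' corridor, mirroring the visual criterion of rotating until the entry and
#' exit outlines coincide. During direction search the threshold is frozen
#' from the longest chord seen across the whole coarse sweep, so candidate
#' views compete on one common scale (a side view has uniformly short
#' chords and scores zero rather than renormalizing to itself).
#'
#' @param map a [safe_map()].
#' @param frac fraction of the maximum chord that qualifies (default 0.75).
#' @param threshold absolute chord threshold in mm; overrides `frac`.
#' @return area in mm^2 (0 when no pixel qualifies).
#' @export
aligned_area <- function(map, frac = 0.75, threshold = NULL) {
  ok <- map$count == 1L & !is.na(map$chord)
  if (!any(ok)) return(0)
  thr <- if (is.null(threshold)) max(map$min_chord, frac * max(map$chord[ok]))
         else max(map$min_chord, threshold)
  sum(ok & map$chord >= thr) * map$frame$spacing^2
}

# rotate d0 by (ax, ay) degrees along the geodesics spanned by (u0, v0)
rotate_dir <- function(d0, u0, v0, ax_deg, ay_deg) {
  ang <- sqrt(ax_deg^2 + ay_deg^2)
  if (ang < 1e-12) return(d0)
  e <- unit3(ax_deg * u0 + ay_deg * v0)
  unit3(cos(ang * pi / 180) * d0 + sin(ang * pi / 180) * e)
}

#' Optimize the viewing direction of the screw corridor
#'
#' Coarse spherical grid search inside a cone around the anatomical
#' initialization, followed by deterministic pattern-search refinement. The
#' objective is the [aligned_area()] averaged over two half-pixel-shifted
#' grids (which suppresses pixel-quantization noise near the optimum).
#'
#' @param mesh watertight [triangle_mesh()].
#' @param init initial direction, roughly along the distal acromion axis.
#' @param up_hint superior reference direction for the projection frames.
#' @param cone_half_angle search cone half-angle around `init` (deg).
#' @param coarse_step coarse grid step (deg).
#' @param refine_tol refinement terminates below this step (deg).
#' @param spacing pixel size used during the search (mm).
#' @param final_spacing pixel size of the returned map (defaults to
#'   `spacing`).
#' @param min_chord safe-chord threshold (mm).
#' @param align_frac chord fraction of the alignment objective.
#' @return list with `direction`, `map` (a [safe_map()] at the optimum),
#'   `objective` (mm^2) and `offsets_deg` (position within the cone).
#' @export
optimize_direction <- function(mesh, init, up_hint = NULL,
                               cone_half_angle = 30, coarse_step = 3,
                               refine_tol = 0.5, spacing = 0.5,
                               final_spacing = NULL, min_chord = 10,
                               align_frac = 0.75) {
  rep_v <- mesh$provenance$validation
  if (is.null(rep_v)) rep_v <- validate_mesh(mesh)
  if (!rep_v$watertight) stop("optimize_direction requires a watertight mesh")
  ax0 <- frame_axes(init, up_hint)
  chord_memo <- new.env(parent = emptyenv())
  # the two half-pixel-shifted maps of one candidate direction; cached as
  # chord vectors of single-interval pixels so the coarse sweep can be
  # re-scored once the global chord scale is known
  map_chords <- function(ax_deg, ay_deg) {
    key <- sprintf("%.6f_%.6f", ax_deg, ay_deg)
    if (!is.null(chord_memo[[key]])) return(chord_memo[[key]])
    d <- rotate_dir(ax0$d, ax0$u, ax0$v, ax_deg, ay_deg)
    ch <- lapply(list(c(0, 0), c(0.5, 0.5)), function(go) {
      fr <- projection_frame(mesh, d, spacing = spacing, up_hint = up_hint,
                             grid_offset = go)
      m <- safe_map(mesh, d, frame = fr, min_chord = min_chord,
                    .validated = TRUE)
      m$chord[m$count == 1L & !is.na(m$chord)]
    })
    chord_memo[[key]] <- ch
    ch
  }
  score <- function(ax_deg, ay_deg, thr) {
    ch <- map_chords(ax_deg, ay_deg)
    mean(vapply(ch, function(v) sum(v >= thr), numeric(1))) * spacing^2
  }
  steps <- seq(-cone_half_angle, cone_half_angle, by = coarse_step)
  grid <- expand.grid(ax = steps, ay = steps)
  grid <- grid[grid$ax^2 + grid$ay^2 <= cone_half_angle^2 + 1e-9, ]
  cmax <- max(0, vapply(seq_len(nrow(grid)), function(i) {
    max(0, unlist(map_chords(grid$ax[i], grid$ay[i])))
  }, numeric(1)))
  thr <- max(min_chord, align_frac * cmax)
  vals <- mapply(score, grid$ax, grid$ay, MoreArgs = list(thr = thr))
  best_i <- which.max(vals)
  best <- c(grid$ax[best_i], grid$ay[best_i])
  best_val <- vals[best_i]
  if (best_val <= 0)
    stop("no corridor: zero aligned area everywhere in the search cone")
  step <- coarse_step / 2
  nbrs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  while (step >= refine_tol) {
    moved <- FALSE
    repeat {
      cand <- sweep(nbrs * step, 2, best, "+")
      cand <- cand[rowSums(cand^2) <= cone_half_angle^2 + 1e-9, , drop = FALSE]
      if (nrow(cand) == 0) break
      cv <- apply(cand, 1, function(p) score(p[1], p[2], thr))
      if (max(cv) > best_val + 1e-9) {
        k <- which.max(cv)
        best <- cand[k, ]; best_val <- cv[k]; moved <- TRUE
      } else break
    }
    step <- step / 2
  }
  d <- rotate_dir(ax0$d, ax0$u, ax0$v, best[1], best[2])
  fs <- if (is.null(final_spacing)) spacing else final_spacing
  map <- safe_map(mesh, d, spacing = fs, min_chord = min_chord,
                  up_hint = up_hint, .validated = TRUE)
  list(direction = d, map = map, objective = best_val, offsets_deg = best,
       chord_threshold = thr)
}

#' Raise the safe-chord threshold of an existing map
#'
#' Recomputes the safe flag at a higher minimum chord without re-casting
#' any rays. Used to restrict the corridor to the long-chord oval the
#' screws occupy (the direction-search threshold), while the map's original
#' `min_chord` remains the hard safety floor.
#'
#' @param map a [safe_map()].
#' @param min_chord new (higher) chord threshold in mm.
#' @return the updated `safe_map`.
#' @export
map_with_min_chord <- function(map, min_chord) {
  if (min_chord < map$min_chord)
    stop("min_chord can only be raised, not lowered, on an existing map")
  map$min_chord <- min_chord
  map$safe <- map$count == 1L & !is.na(map$chord) & map$chord >= min_chord
  map
}

#' Export a safe map as a portable graymap plus JSON sidecar
#'
#' Writes `<prefix>.pgm` (plain P2: 0 = background, 96 = bone but unsafe,
#' 255 = safe) and `<prefix>.json` describing the frame (origin, axes,
#' spacing, grid extent) so the image can be mapped back to mm coordinates.
#'
#' @param map a [safe_map()].
#' @param prefix output path prefix.
#' @return the pgm path, invisibly.
#' @export
write_safe_map <- function(map, prefix) {
  img <- matrix(0L, map$frame$nx, map$frame$ny)
  img[map$count != 0L] <- 96L
  img[map$safe] <- 255L
  pgm <- paste0(prefix, ".pgm")
  con <- file(pgm, "w")
  writeLines(c("P2", sprintf("%d %d", map$frame$nx, map$frame$ny), "255"), con)
  # image rows top-to-bottom = decreasing v
  for (j in rev(seq_len(map$frame$ny)))
    writeLines(paste(img[, j], collapse = " "), con)
  close(con)
  side <- list(origin = map$frame$origin, u = map$frame$u, v = map$frame$v,
               d = map$frame$d, spacing = map$frame$spacing,
               umin = map$frame$umin, vmin = map$frame$vmin,
               nx = map$frame$nx, ny = map$frame$ny,
               min_chord = map$min_chord)
  jsonlite::write_json(side, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(pgm)
}
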