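#' Fit a screw cylinder along the corridor at a given zone position
#'
#' The screw axis is the corridor ray through `center` (frame coordinates);
#' its entry is the ray's near cortex intersection (the viewer's side of the
#' axial perspective) and its length the full in-bone chord, i.e. the tip
#' just penetrates the far cortex, flush with it. Containment of the whole
#' cylinder inside the solid is verified by sampling the lateral surface
#' (24 angles x axial stations every 1.25 mm, sampled 0.05 mm inside the
#' nominal radius); when the check fails, the radius shrinks in 0.05 mm
#' steps (at most 10) before giving up.
#'
#' @param mesh watertight [triangle_mesh()].
#' @param frame the corridor [projection_frame()].
#' @param center in-plane (u, v) position of the screw axis (mm).
#' @param radius nominal screw radius (mm).
#' @param side optional label (`"medial"` / `"lateral"`).
#' @param contain_tol containment sampling tolerance (mm, default 0.05).
#' @return object of class `screw_plan`: `side`, `entry` (3D mm),
#'   `direction`, `diameter`, `length`, `axis_uv`, `t_in`, `t_out`.
#' @export
fit_screw <- function(mesh, frame, center, radius, side = NA_character_,
                      contain_tol = 0.05) {
  origin <- frame_point(frame, center[1], center[2], 0)
  iv <- solid_intervals(mesh, origin, frame$d)
  if (nrow(iv) != 1L)
    stop("screw axis ray is not safe: ", nrow(iv), " in-bone intervals")
  t_in <- unname(iv[1, 1]); t_out <- unname(iv[1, 2])
  len <- t_out - t_in
  for (k in 0:10) {
    r_try <- radius - k * 0.05
    if (r_try <= 0) break
    if (cylinder_contained(mesh, frame, center, t_in, t_out, r_try,
                           contain_tol)) {
      return(structure(list(side = side,
                            entry = frame_point(frame, center[1], center[2],
                                                t_in),
                            direction = frame$d, diameter = 2 * r_try,
                            length = len, axis_uv = as.numeric(center),
                            t_in = t_in, t_out = t_out),
                       class = "screw_plan"))
    }
  }
  stop("fit error: cylinder containment failed even after shrinking radius")
}

# Lateral-surface sampling containment check. The shaft is sampled away
# from the two cortices (margin 1.5 radii): where the exit cortex crosses
# the screw axis obliquely, the tip that "just penetrates" it protrudes on
# one side exactly as a clinical bicortical screw does, so the end regions
# are not held to the containment rule.
cylinder_contained <- function(mesh, frame, center, t_in, t_out, radius,
                               tol = 0.05) {
  r_s <- radius - tol
  if (r_s <= 0) return(TRUE)
  len <- t_out - t_in
  cap_eps <- min(max(1, 1.5 * radius), len / 4)
  ts <- seq(t_in + cap_eps, t_out - cap_eps,
            length.out = max(2, ceiling(len / 1.25)))
  n_ang <- max(24, ceiling(2 * pi * radius / 0.4))
  ang <- seq(0, 2 * pi, length.out = n_ang + 1)[-(n_ang + 1)]
  uu <- rep(center[1] + r_s * cos(ang), times = length(ts))
  vv <- rep(center[2] + r_s * sin(ang), times = length(ts))
  tt <- rep(ts, each = length(ang))
  P <- sweep(outer(uu, frame$u) + outer(vv, frame$v) + outer(tt, frame$d),
             2, frame$origin, "+")
  all(cpp_points_inside(mesh$vertices, mesh$faces - 1L, P, frame$d))
}

#' @export
print.screw_plan <- function(x, ...) {
  cat(sprintf("screw_plan [%s]: diameter %.2f mm, length %.1f mm\n",
              x$side, x$diameter, x$length))
  cat(sprintf("  entry (%.1f, %.1f, %.1f), direction (%.3f, %.3f, %.3f)\n",
              x$entry[1], x$entry[2], x$entry[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Plan the two fixation screws in a safe zone
#'
#' Splits the zone evenly ([split_zone()]), refines each half to the pixels
#' whose in-bone interval actually covers the screw's axial span (a long
#' safe chord elsewhere along the ray is no use to a screw crossing the
#' whole corridor), fits the maximal inscribed circle of each refined half
#' ([max_inscribed_circle()]), and fits a screw on each axis
#' ([fit_screw()]). If the two parallel axes are closer than the sum of
#' radii plus `clearance`, both radii shrink proportionally until the gap
#' rule holds.
#'
#' @param mesh watertight [triangle_mesh()].
#' @param map the corridor [safe_map()] the zone was extracted from.
#' @param zone a [safe_zone()].
#' @param landmarks optional [landmark_set()] used to label the medial half.
#' @param clearance required gap between screw surfaces (mm, default 0:
#'   mutually tangent maximal screws are allowed).
#' @param min_diameter smallest clinically useful screw (mm, default 2);
#'   below it planning fails.
#' @return list with `medial` and `lateral` `screw_plan`s and `halves`
#'   (the [split_zone()] output).
#' @export
plan_two_screws <- function(mesh, map, zone, landmarks = NULL,
                            clearance = 0, min_diameter = 2) {
  frame <- map$frame
  facet_uv <- if (!is.null(landmarks))
    drop(frame_project(frame, landmarks$ac_facet)) else NULL
  halves <- split_zone(zone, facet_uv = facet_uv)
  mic_m <- coverage_inscribed(mesh, map, halves, "medial")
  mic_l <- coverage_inscribed(mesh, map, halves, "lateral")
  gap <- sqrt(sum((mic_m$center - mic_l$center)^2))
  need <- mic_m$radius + mic_l$radius + clearance
  if (gap < need - 1e-9) {
    scale <- (gap - clearance) / (mic_m$radius + mic_l$radius)
    if (scale <= 0) stop("no corridor for two screws: axes too close")
    mic_m$radius <- mic_m$radius * scale
    mic_l$radius <- mic_l$radius * scale
  }
  if (2 * mic_m$radius < min_diameter || 2 * mic_l$radius < min_diameter)
    stop("no corridor for two screws: half-zone too small for a ",
         min_diameter, " mm screw")
  list(medial = fit_screw(mesh, frame, mic_m$center, mic_m$radius,
                          side = "medial"),
       lateral = fit_screw(mesh, frame, mic_l$center, mic_l$radius,
                           side = "lateral"),
       halves = halves)
}

# Maximal inscribed circle of one zone half, restricted to pixels whose
# in-bone interval covers the screw's axial span. The span is probed at the
# half's unrestricted inscribed center; the same end margins the
# containment check uses (1.5 radii, at least 1 mm) are allowed at the two
# cortices.
coverage_inscribed <- function(mesh, map, halves, side) {
  half <- halves[[side]]
  fr <- map$frame
  mic0 <- max_inscribed_circle(half$polygon)
  iv <- solid_intervals(mesh, frame_point(fr, mic0$center[1], mic0$center[2],
                                          0), fr$d, .validated = TRUE)
  if (nrow(iv) != 1L)
    stop("screw axis ray is not safe in the ", side, " half")
  m <- max(1, 1.5 * mic0$radius)
  cov <- map$count == 1L & !is.na(map$tin) &
    map$tin <= iv[1, 1] + m & map$tout >= iv[1, 2] - m
  # restrict to this half of the split
  ucs <- fr$umin + (seq_len(fr$nx) - 0.5) * fr$spacing
  vcs <- fr$vmin + (seq_len(fr$ny) - 0.5) * fr$spacing
  ln <- halves$line
  s_half <- sign(sum((half$centroid - ln$point) * ln$normal))
  s_pix <- outer((ucs - ln$point[1]) * ln$normal[1],
                 (vcs - ln$point[2]) * ln$normal[2], "+")
  cov <- cov & (s_pix * s_half >= 0)
  if (!any(cov))
    stop("no corridor: ", side, " half has no span-covering pixels")
  lab <- label_components8(cov)
  sizes <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$n)
  mask <- lab$labels == which.max(sizes)
  if (sum(mask) < 4L)
    stop("no corridor: ", side, " half coverage region is degenerate")
  mic <- max_inscribed_circle(mask_to_polygon(mask, fr))
  if (mic$radius > mic0$radius) mic0 else mic
}

#' Serialize screw plans to JSON
#'
#' @param screws list with `medial` and `lateral` `screw_plan`s.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_screw_plans <- function(screws, path) {
  enc <- function(s) list(side = s$side, entry = s$entry,
                          direction = s$direction, diameter = s$diameter,
                          length = s$length, axis_uv = s$axis_uv)
  jsonlite::write_json(list(medial = enc(screws$medial),
                            lateral = enc(screws$lateral)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
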