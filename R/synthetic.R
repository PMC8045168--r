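# Parametric acromion-like solids with exact ground truth.
#
# All shapes come from one swept-solid builder: an elliptical cross-section
# a(z) x b(z) extruded along z from the distal (anterior) tip at z = 0,
# optionally with a linear taper, an oblique posterior end cut (the medial
# side of the acromion runs on into the scapular spine, so it is longer), a
# flattened superior strip (the surface plane A is fitted on), smooth
# low-frequency surface bumps, and a circular-arc bend of the whole rod
# about an oblique horizontal axis (mixing inferior and medial curvature).
# The builder returns both the mesh and an exact analytic inside() predicate
# for the same solid, which is what the voxel ray-marching oracle in the
# test-suite marches through.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

build_swept_solid <- function(a, b, length, taper = 1, end_slope = 0,
                              arc_deg = 0, arc_azimuth_deg = 0,
                              flat_depth = 0, flat_tilt_deg = 0,
                              flat_window = NULL, noise_amp = 0, seed = 1L,
                              n_theta = 48L, n_rings = 48L) {
  stopifnot(a > 0, b > 0, length > 0, taper > 0, taper <= 1)
  xref <- -0.45 * a
  L_end <- function(x) length - end_slope * (x - xref)
  a_of <- function(z) a * (1 - (1 - taper) * pmax(0, z) / length)
  b_of <- function(z) b * (1 - (1 - taper) * pmax(0, z) / length)

  # smooth sinusoidal surface bumps (sum of 3 circumferential/axial modes)
  if (noise_amp > 0) {
    nz <- local_seed(seed, {
      w <- stats::runif(3); w <- w / sum(w)
      list(w = w, m = sample(2:5, 3), q = sample(1:3, 3),
           ph = stats::runif(3, 0, 2 * pi), pz = stats::runif(3, 0, 2 * pi))
    })
    eta <- function(theta, z) {
      out <- 0
      for (k in 1:3)
        out <- out + nz$w[k] * cos(nz$m[k] * theta + nz$ph[k]) *
          cos(pi * nz$q[k] * z / length + nz$pz[k])
      noise_amp * out
    }
  } else eta <- function(theta, z) rep(0, base::length(theta))

  if (flat_depth > 0) {
    if (is.null(flat_window)) flat_window <- c(1.5, min(13.5, length * 0.3))
    z0 <- flat_window[1]; z1 <- flat_window[2]
    zc <- (z0 + z1) / 2
    c0 <- (1 - flat_depth) * b_of(zc)
    tt <- tan(flat_tilt_deg * pi / 180)
    ytop <- function(z) c0 - tt * (z - zc) +
      1.7 * (pmax(0, z - z1) + pmax(0, z0 - z))
  } else {
    ytop <- function(z) rep(Inf, base::length(z))
    zc <- NA_real_
  }

  # centerline cut length and the bend map
  Lcl <- L_end(0)
  phi <- arc_deg * pi / 180
  psi <- arc_azimuth_deg * pi / 180
  if (phi > 1e-9) {
    Rb <- Lcl / phi
    if (Rb < 3 * a)
      stop("parameter error: arc too tight for the cross-section ",
           "(self-intersecting sweep)")
    bend_fwd <- function(P) {
      x <- P[, 1] * cos(psi) - P[, 2] * sin(psi)
      y <- P[, 1] * sin(psi) + P[, 2] * cos(psi)
      z <- P[, 3]
      yb <- -Rb + (Rb + y) * cos(z / Rb)
      zb <- (Rb + y) * sin(z / Rb)
      cbind(x * cos(psi) + yb * sin(psi), -x * sin(psi) + yb * cos(psi), zb)
    }
    bend_inv <- function(P) {
      x <- P[, 1] * cos(psi) - P[, 2] * sin(psi)
      yb <- P[, 1] * sin(psi) + P[, 2] * cos(psi)
      zb <- P[, 3]
      y <- sqrt((yb + Rb)^2 + zb^2) - Rb
      z <- Rb * atan2(zb, yb + Rb)
      cbind(x * cos(psi) + y * sin(psi), -x * sin(psi) + y * cos(psi), z)
    }
  } else {
    bend_fwd <- identity
    bend_inv <- identity
  }

  # ring vertices: fixed-point for z = f * L_end(x(z)) (the oblique end cut)
  thetas <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  fs <- (seq_len(n_rings + 1) - 1) / n_rings
  th <- rep(thetas, times = n_rings + 1)
  f <- rep(fs, each = n_theta)
  z <- f * length
  for (it in 1:40) {
    x <- (a_of(z) + eta(th, z)) * cos(th)
    znew <- f * L_end(x)
    if (max(abs(znew - z)) < 1e-11) { z <- znew; break }
    z <- znew
  }
  az <- a_of(z); bz <- b_of(z); e <- eta(th, z)
  x <- (az + e) * cos(th)
  y_raw <- (bz + e) * sin(th)
  yt <- ytop(z)
  clamped <- y_raw > yt + 1e-9
  y <- pmin(y_raw, yt)
  V <- cbind(x, y, z)

  nv_ring <- n_theta * (n_rings + 1)
  front <- colMeans(V[seq_len(n_theta), , drop = FALSE])
  back <- colMeans(V[(nv_ring - n_theta + 1):nv_ring, , drop = FALSE])
  V <- rbind(V, front, back)
  cF <- nv_ring + 1L; cB <- nv_ring + 2L

  idx <- function(i, j) (i - 1L) * n_theta + j
  jj <- seq_len(n_theta)
  j2 <- c(jj[-1], 1L)
  F_list <- vector("list", n_rings + 2)
  for (i in seq_len(n_rings)) {
    A <- idx(i, jj); B <- idx(i, j2); C <- idx(i + 1L, j2); D <- idx(i + 1L, jj)
    F_list[[i]] <- rbind(cbind(A, B, C), cbind(A, C, D))
  }
  F_list[[n_rings + 1]] <- cbind(cF, idx(1L, j2), idx(1L, jj))
  F_list[[n_rings + 2]] <- cbind(cB, idx(n_rings + 1L, jj),
                                 idx(n_rings + 1L, j2))
  faces <- do.call(rbind, F_list)

  mesh <- triangle_mesh(bend_fwd(V), faces,
                        provenance = list(source = "swept_solid"))

  inside <- function(P) {
    P <- matrix(P, ncol = 3)
    Q <- bend_inv(P)
    x <- Q[, 1]; y <- Q[, 2]; z <- Q[, 3]
    ok <- z >= -1e-9 & z <= L_end(x) + 1e-9
    zc2 <- pmax(0, pmin(z, length))
    azq <- a_of(zc2); bzq <- b_of(zc2)
    thq <- atan2(y / bzq, x / azq)
    eq <- eta(thq, zc2)
    r2 <- (x / (azq + eq))^2 + (y / (bzq + eq))^2
    ok & r2 <= 1 & y <= ytop(zc2)
  }

  list(mesh = mesh, inside = inside, bend_fwd = bend_fwd,
       clamped = c(clamped, FALSE, FALSE), z_unbent = c(z, 0, max(z)),
       Lcl = Lcl, zc_flat = zc,
       flat_tilt_deg = flat_tilt_deg, flat_window = flat_window,
       a = a, b = b, length = length)
}

# truth record shared by the oracle shapes and the acromion generator
swept_truth <- function(sw) {
  chord_end <- drop(sw$bend_fwd(matrix(c(0, 0, sw$Lcl), 1)))
  chord <- unit3(chord_end)
  tip_tangent <- c(0, 0, 1)
  out <- list(chord_dir = chord, tip_tangent = tip_tangent,
              chord_length = sqrt(sum(chord_end^2)), Lcl = sw$Lcl,
              inside = sw$inside)
  if (!is.na(sw$zc_flat)) {
    # exact normal of the bent flat strip at the patch center, by mapping
    # two tangent directions of the unbent flat plane through the bend
    tt <- tan(sw$flat_tilt_deg * pi / 180)
    h <- 1e-4
    base <- matrix(c(0, 0, sw$zc_flat,
                     h, 0, sw$zc_flat,
                     0, -tt * h, sw$zc_flat + h), 3, 3, byrow = TRUE)
    B <- sw$bend_fwd(base)
    nA <- unit3(cross3(B[2, ] - B[1, ], B[3, ] - B[1, ]))
    if (nA[2] < 0) nA <- -nA
    out$planeA_normal <- nA
    out$alpha_deg <- asin(min(1, abs(sum(chord * nA)))) * 180 / pi
    w <- tip_tangent - sum(tip_tangent * nA) * nA
    nB <- unit3(cross3(nA, unit3(w)))
    out$beta_deg <- asin(min(1, abs(sum(chord * nB)))) * 180 / pi
  }
  out
}

#' Solid circular cylinder oracle shape
#'
#' Extruded disc along z with landmarks: anterior edge at (r, 0, 0), facet
#' point at (-r, 0, L/4), superior patch = the top band of the lateral
#' surface over the distal half.
#'
#' @param r radius (mm).
#' @param L length (mm).
#' @param n_theta,n_rings mesh resolution.
#' @return list with `mesh`, `landmarks`, `truth` (axis, chord, exact
#'   `inside()` predicate).
#' @export
make_solid_cylinder <- function(r, L, n_theta = 64L, n_rings = 40L) {
  stopifnot(r > 0, L > 0)
  sw <- build_swept_solid(a = r, b = r, length = L,
                          n_theta = n_theta, n_rings = n_rings)
  lm <- band_landmarks(sw, half_width = r, tip_pt = c(r, 0, 0),
                       facet_pt = c(-r, 0, L / 4))
  list(mesh = sw$mesh, landmarks = lm, truth = swept_truth(sw))
}

#' Solid elliptic rod oracle shape
#'
#' Extruded ellipse (semi-axes `a >= b`) along z; the axial safe area is
#' exactly pi a b.
#'
#' @param a,b semi-axes (mm), `a >= b`.
#' @param L length (mm).
#' @param n_theta,n_rings mesh resolution.
#' @return list with `mesh`, `landmarks`, `truth`.
#' @export
make_elliptic_rod <- function(a, b, L, n_theta = 64L, n_rings = 40L) {
  stopifnot(a >= b, b > 0, L > 0)
  sw <- build_swept_solid(a = a, b = b, length = L,
                          n_theta = n_theta, n_rings = n_rings)
  lm <- band_landmarks(sw, half_width = b, tip_pt = c(a, 0, 0),
                       facet_pt = c(-a, 0, L / 4))
  list(mesh = sw$mesh, landmarks = lm, truth = swept_truth(sw))
}

#' Curved rod oracle shape
#'
#' Elliptic rod bent along a circular arc; rays crossing the concavity
#' traverse two in-bone segments, the breach pattern the corridor
#' classifier must flag.
#'
#' @param a,b semi-axes (mm).
#' @param L centerline length (mm).
#' @param arc_deg total arc angle (deg).
#' @param azimuth_deg bend-plane azimuth (0 = bend toward -y).
#' @param n_theta,n_rings mesh resolution.
#' @return list with `mesh`, `landmarks`, `truth`.
#' @export
make_curved_rod <- function(a, b, L, arc_deg, azimuth_deg = 0,
                            n_theta = 64L, n_rings = 64L) {
  sw <- build_swept_solid(a = a, b = b, length = L, arc_deg = arc_deg,
                          arc_azimuth_deg = azimuth_deg,
                          n_theta = n_theta, n_rings = n_rings)
  lm <- band_landmarks(sw, half_width = b, tip_pt = c(a, 0, 0),
                       facet_pt = c(-a, 0, L / 4))
  list(mesh = sw$mesh, landmarks = lm, truth = swept_truth(sw))
}

# top-band landmark construction for the un-flattened oracle shapes
band_landmarks <- function(sw, half_width, tip_pt, facet_pt) {
  V <- sw$mesh$vertices
  b_loc <- half_width
  band <- which(V[, 2] >= b_loc * cos(pi / 12) - 1e-9 &
                sw$z_unbent <= sw$length / 2 + 1e-9)
  nearest <- function(p) {
    which.min(rowSums(sweep(V, 2, p)^2))
  }
  landmark_set(ac_facet = V[nearest(facet_pt), ],
               anterior_edge = V[nearest(tip_pt), ],
               superior_patch = band, mesh = sw$mesh)
}

#' Parameters of one synthetic acromion
#'
#' The distal acromion is modelled as a curved, tapering rod: elliptical
#' cross-section (`a` = half-width, mediolateral; `b` = half-thickness,
#' the "canal" minor semi-axis that caps the screw diameter), rod length
#' measured at the medial screw station, an oblique posterior end cut
#' (`end_slope`, mm of extra length per mm toward medial — the medial side
#' continues into the scapular spine), a circular-arc bend (`arc_deg` total,
#' `arc_azimuth_deg` mixing inferior with medial curvature), a flattened
#' superior strip over `flat_window` mm (depth `flat_depth` of the local
#' half-thickness, tilted by `flat_tilt_deg`:
#' positive tilts it downward going posterior, and the slightly negative
#' default makes it rise posteriorly so that, combined with the inferior
#' curvature, the screw course dips below the strip — the surface plane A
#' is fitted on), and smooth sinusoidal surface bumps of
#' amplitude `noise_amp` mm.
#'
#' @param a,b cross-section semi-axes at the tip (mm).
#' @param length rod length at the medial screw station (mm).
#' @param taper semi-axis fraction remaining at the posterior end.
#' @param end_slope oblique end-cut slope (mm/mm).
#' @param arc_deg,arc_azimuth_deg centerline bend (deg).
#' @param flat_depth,flat_tilt_deg,flat_window superior flat strip.
#' @param facet_offset AC-facet landmark position along the medial surface
#'   (mm from the tip).
#' @param noise_amp surface bump amplitude (mm, must stay below a fifth of
#'   the smallest semi-axis).
#' @param seed integer seed for the surface bumps.
#' @param n_theta,n_rings mesh resolution.
#' @return validated parameter list of class `acromion_params`.
#' @export
acromion_params <- function(a = 9.2, b = 2.9, length = 51, taper = 0.88,
                            end_slope = 0.85, arc_deg = 10,
                            arc_azimuth_deg = 40, flat_depth = 0.14,
                            flat_tilt_deg = -6, flat_window = c(2, 12),
                            facet_offset = 6, noise_amp = 0.12, seed = 1L,
                            n_theta = 40L, n_rings = 48L) {
  p <- as.list(environment())
  min_semi <- min(a, b) * taper - noise_amp
  if (min_semi <= 1) stop("parameter error: semi-axes must stay above 1 mm")
  if (arc_deg < 0 || arc_deg > 90)
    stop("parameter error: arc_deg must be in [0, 90]")
  if (noise_amp >= min(a, b) * taper / 5)
    stop("parameter error: noise_amp too large for the cross-section")
  if (flat_depth < 0 || flat_depth > 0.5)
    stop("parameter error: flat_depth must be in [0, 0.5]")
  structure(p, class = "acromion_params")
}

#' Generate one synthetic acromion
#'
#' Deterministic given the parameter seed. The returned ground truth holds
#' the chord direction of the bent centerline (the ideal corridor axis),
#' the distal tangent (the anatomical axis reference), the analytic normal
#' of the flattened strip at the patch center, and the implied downdip
#' (alpha) and inclination (beta) angles, plus the exact `inside()`
#' predicate of the solid.
#'
#' @param params an [acromion_params()].
#' @return list with `mesh`, `landmarks`, `truth`, `params`.
#' @export
generate_acromion <- function(params = acromion_params()) {
  stopifnot(inherits(params, "acromion_params"))
  p <- params
  sw <- build_swept_solid(a = p$a, b = p$b, length = p$length,
                          taper = p$taper, end_slope = p$end_slope,
                          arc_deg = p$arc_deg,
                          arc_azimuth_deg = p$arc_azimuth_deg,
                          flat_depth = p$flat_depth,
                          flat_tilt_deg = p$flat_tilt_deg,
                          flat_window = p$flat_window,
                          noise_amp = p$noise_amp, seed = p$seed,
                          n_theta = p$n_theta, n_rings = p$n_rings)
  V <- sw$mesh$vertices
  patch <- which(sw$clamped & sw$z_unbent >= p$flat_window[1] - 1e-9 &
                 sw$z_unbent <= p$flat_window[2] + 1e-9)
  if (length(patch) < 30) {
    # widen to near-flat vertices so the plane fit stays overdetermined
    zc <- (p$flat_window[1] + p$flat_window[2]) / 2
    near <- which(sw$z_unbent >= p$flat_window[1] &
                  sw$z_unbent <= p$flat_window[2] &
                  V[, 2] > 0.6 * p$b)
    patch <- union(patch, near)
  }
  zf <- p$facet_offset
  facet_unbent <- c(-(p$a * (1 - (1 - p$taper) * zf / p$length)), 0, zf)
  facet_pt <- drop(sw$bend_fwd(matrix(facet_unbent, 1)))
  tip_ids <- which(sw$z_unbent < 1e-6)
  tip_top <- tip_ids[which.max(V[tip_ids, 2])]
  nearest <- function(pnt) which.min(rowSums(sweep(V, 2, pnt)^2))
  lm <- landmark_set(ac_facet = V[nearest(facet_pt), ],
                     anterior_edge = V[tip_top, ],
                     superior_patch = patch, mesh = sw$mesh)
  truth <- swept_truth(sw)
  list(mesh = sw$mesh, landmarks = lm, truth = truth, params = p)
}

#' Cohort specification for the synthetic study population
#'
#' Per-sex normal distributions (mean, SD) for the tip semi-axes and rod
#' length, shared distributions for the remaining shape parameters; all
#' draws truncated at 3 SD and clamped to hard validity bounds.
#'
#' @param n_male,n_female group sizes.
#' @param seed master seed; every downstream draw derives from it.
#' @param male,female,shared optional overrides: named lists of `c(mean,
#'   sd)` entries (`a`, `b`, `length` per sex; `taper`, `end_slope`,
#'   `arc_deg`, `arc_azimuth_deg`, `flat_tilt_deg` shared).
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_male = 50, n_female = 50, seed = 1L,
                        male = list(), female = list(), shared = list()) {
  def_m <- list(a = c(9.2, 0.9), b = c(2.9, 0.4), length = c(51, 4))
  def_f <- list(a = c(7.8, 0.8), b = c(2.0, 0.3), length = c(42, 4))
  def_s <- list(taper = c(0.88, 0.04), end_slope = c(0.85, 0.12),
                arc_deg = c(10, 4), arc_azimuth_deg = c(40, 15),
                flat_tilt_deg = c(-6, 2.5))
  structure(list(n_male = n_male, n_female = n_female, seed = as.integer(seed),
                 male = utils::modifyList(def_m, male),
                 female = utils::modifyList(def_f, female),
                 shared = utils::modifyList(def_s, shared)),
            class = "cohort_spec")
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- stats::runif(n, stats::pnorm(-3), stats::pnorm(3))
  pmin(hi, pmax(lo, mean + sd * stats::qnorm(u)))
}

#' Sample a synthetic cohort
#'
#' Reproducible from the master seed: the full parameter table is drawn
#' first, then each subject's mesh is generated from its own derived seed.
#'
#' @param spec a [cohort_spec()].
#' @return list of subjects, each a list with `id`, `sex`, `mesh`,
#'   `landmarks`, `truth`, `params`.
#' @export
sample_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_male + spec$n_female
  if (spec$n_male < 1 || spec$n_female < 1)
    stop("each sex group needs at least one subject")
  sex <- c(rep("M", spec$n_male), rep("F", spec$n_female))
  tab <- local_seed(spec$seed, {
    draw <- function(par, lo, hi) {
      m <- ifelse(sex == "M", spec$male[[par]][1], spec$female[[par]][1])
      s <- ifelse(sex == "M", spec$male[[par]][2], spec$female[[par]][2])
      rnorm_trunc(n, m, s, lo, hi)
    }
    drawS <- function(par, lo, hi)
      rnorm_trunc(n, spec$shared[[par]][1], spec$shared[[par]][2], lo, hi)
    data.frame(
      a = draw("a", 4, 14), b = draw("b", 1.35, 4.5),
      length = draw("length", 25, 70),
      taper = drawS("taper", 0.75, 1), end_slope = drawS("end_slope", 0.2, 1.3),
      arc_deg = drawS("arc_deg", 1, 22),
      arc_azimuth_deg = drawS("arc_azimuth_deg", -30, 75),
      flat_tilt_deg = drawS("flat_tilt_deg", -12, 2),
      seed = sample.int(.Machine$integer.max - 1L, n))
  })
  lapply(seq_len(n), function(i) {
    p <- acromion_params(a = tab$a[i], b = tab$b[i], length = tab$length[i],
                         taper = tab$taper[i], end_slope = tab$end_slope[i],
                         arc_deg = tab$arc_deg[i],
                         arc_azimuth_deg = tab$arc_azimuth_deg[i],
                         flat_tilt_deg = tab$flat_tilt_deg[i],
                         seed = tab$seed[i])
    subj <- generate_acromion(p)
    subj$id <- sprintf("%s%03d", sex[i], i)
    subj$sex <- sex[i]
    subj
  })
}
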