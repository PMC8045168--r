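disc_map <- function(r = 6, L = 40, spacing = 0.25) {
  cyl <- make_solid_cylinder(r, L)
  m <- safe_map(cyl$mesh, c(0, 0, 1), spacing = spacing, min_chord = 10,
                up_hint = c(0, 1, 0))
  list(shape = cyl, map = m)
}

test_that("the safe zone of a disc map is a disc polygon", {
  dm <- disc_map(5, 40)
  z <- extract_safe_zone(dm$map)
  expect_equal(z$area, pi * 25, tolerance = 0.03)
  expect_equal(z$centroid, c(0, 0), tolerance = 0.1, ignore_attr = TRUE)
})

test_that("zone extraction keeps the largest component and rejects slivers", {
  dm <- disc_map(5, 40, spacing = 0.5)
  m <- dm$map
  # graft a small fake second component into the safe mask
  m2 <- m
  m2$safe[1:3, 1:3] <- TRUE
  z <- extract_safe_zone(m2)
  expect_equal(z$area, pi * 25, tolerance = 0.05)
  # a lone safe pixel is not a corridor
  m3 <- m
  m3$safe[] <- FALSE
  m3$safe[10, 10] <- TRUE
  expect_error(extract_safe_zone(m3), "no corridor")
  m3$safe[10, 10] <- FALSE
  expect_error(extract_safe_zone(m3), "no corridor")
})

test_that("split_zone bisects areas and translates with the zone", {
  e <- make_elliptic_rod(8, 4, 40)
  m <- safe_map(e$mesh, c(0, 0, 1), spacing = 0.25, min_chord = 10,
                up_hint = c(0, 1, 0))
  z <- extract_safe_zone(m)
  sp <- split_zone(z)
  expect_equal(sp$medial$area, pi * 16, tolerance = 0.02)
  expect_equal(sp$medial$area + sp$lateral$area, z$area, tolerance = 1e-6)
  expect_lt(abs(sp$medial$area - sp$lateral$area) / z$area, 0.01)

  # translation equivariance: shift the polygon, halves shift identically
  z2 <- z
  z2$polygon <- sweep(z$polygon, 2, c(5, 5), "+")
  z2$centroid <- z$centroid + c(5, 5)
  sp2 <- split_zone(z2)
  expect_equal(sp2$medial$area, sp$medial$area, tolerance = 1e-6)
  expect_equal(sp2$medial$centroid, sp$medial$centroid + c(5, 5),
               tolerance = 1e-6)
})

test_that("split_zone bisects an asymmetric zone to within 1%", {
  # egg-shaped region: half-disc glued to a half-ellipse
  th1 <- seq(-pi / 2, pi / 2, length.out = 120)
  th2 <- seq(pi / 2, 3 * pi / 2, length.out = 120)
  poly <- rbind(cbind(5 * cos(th1), 5 * sin(th1)),
                cbind(12 * cos(th2), 5 * sin(th2)))
  pts <- poly[seq(1, nrow(poly), 4), ]
  zone <- structure(list(polygon = poly,
                         area = abs(acroplan:::poly_area_signed(poly)),
                         centroid = acroplan:::poly_centroid(poly),
                         axes = rbind(c(1, 0), c(0, 1))),
                    class = "safe_zone")
  sp <- split_zone(zone)
  expect_lt(abs(sp$medial$area - sp$lateral$area) / zone$area, 0.01)
})

test_that("max_inscribed_circle matches closed forms and the brute oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  mic <- max_inscribed_circle(sq)
  expect_equal(mic$radius, 0.5, tolerance = 1e-3)
  expect_equal(mic$center, c(0.5, 0.5), tolerance = 1e-3, ignore_attr = TRUE)

  th <- seq(0, pi, length.out = 180)
  half_disc <- rbind(cbind(10 * cos(th), 10 * sin(th)))
  mic <- max_inscribed_circle(half_disc)
  oracle <- brute_mic(half_disc)
  expect_equal(mic$radius, 5, tolerance = 0.012)  # exact r/2 closed form
  expect_equal(mic$radius, oracle$radius, tolerance = 0.01)
  expect_equal(mic$center[2], 5, tolerance = 0.05)

  th <- seq(0, 2 * pi, length.out = 240)[-240]
  ell <- cbind(10 * cos(th), 5 * sin(th))
  mic <- max_inscribed_circle(ell)
  expect_equal(mic$radius, 5, tolerance = 0.01)
  expect_equal(mic$center, c(0, 0), tolerance = 0.1, ignore_attr = TRUE)

  expect_error(max_inscribed_circle(rbind(c(0, 0), c(1, 0))), "degenerate")
})

test_that("max_inscribed_circle agrees with the brute oracle on random polygons", {
  withr::local_seed(7)
  for (k in 1:20) {
    nv <- sample(5:9, 1)
    ang <- sort(stats::runif(nv, 0, 2 * pi))
    rad <- stats::runif(nv, 2, 6)
    poly <- cbind(rad * cos(ang), rad * sin(ang))  # star-shaped polygon
    mic <- max_inscribed_circle(poly)
    oracle <- brute_mic(poly)
    expect_equal(mic$radius, oracle$radius, tolerance = 0.051)
  }
})

test_that("fit_screw takes the full bicortical chord and verifies containment", {
  dm <- disc_map(5, 40)
  scr <- fit_screw(dm$shape$mesh, dm$map$frame, c(0, 0), radius = 4)
  expect_equal(scr$length, 40, tolerance = 1e-6)
  expect_equal(scr$diameter, 8)
  expect_equal(scr$entry[3], 0, tolerance = 1e-6)  # anterior cap z = 0
  # an oversized screw shrinks (or errors) rather than breaching
  scr2 <- tryCatch(fit_screw(dm$shape$mesh, dm$map$frame, c(2, 0),
                             radius = 4),
                   error = function(e) e)
  if (!inherits(scr2, "error")) expect_lt(scr2$diameter, 8)
  # off the bone entirely
  expect_error(fit_screw(dm$shape$mesh, dm$map$frame, c(10, 10), radius = 1),
               "not safe")
})

test_that("two planned screws on a cylinder realize the half-disc rule", {
  dm <- disc_map(6, 40)
  z <- extract_safe_zone(dm$map)
  scr <- plan_two_screws(dm$shape$mesh, dm$map, z,
                         landmarks = dm$shape$landmarks)
  expect_equal(scr$medial$diameter, 6, tolerance = 0.02 * 6)
  expect_equal(scr$lateral$diameter, 6, tolerance = 0.02 * 6)
  expect_equal(scr$medial$length, 40, tolerance = 1e-6)
  expect_equal(scr$lateral$length, 40, tolerance = 1e-6)
  # medial screw sits on the facet side (facet at x = -6)
  expect_lt(scr$medial$entry[1], scr$lateral$entry[1])
  # maximality: inflating the diameter by 0.2 mm must breach
  expect_false(acroplan:::cylinder_contained(
    dm$shape$mesh, dm$map$frame, scr$medial$axis_uv,
    scr$medial$t_in, scr$medial$t_out,
    scr$medial$diameter / 2 + 0.1))
})

test_that("a positive clearance shrinks touching screws to keep the gap", {
  dm <- disc_map(6, 40)
  z <- extract_safe_zone(dm$map)
  scr0 <- plan_two_screws(dm$shape$mesh, dm$map, z)
  scr <- plan_two_screws(dm$shape$mesh, dm$map, z, clearance = 0.5)
  gap <- sqrt(sum((scr$medial$axis_uv - scr$lateral$axis_uv)^2))
  expect_gte(gap + 1e-6,
             scr$medial$diameter / 2 + scr$lateral$diameter / 2 + 0.5)
  expect_lt(scr$medial$diameter, scr0$medial$diameter)
})

test_that("screw lengths are stable under pixel-size changes", {
  e <- make_elliptic_rod(8, 4, 40)
  lens <- vapply(c(0.5, 0.25), function(sp) {
    m <- safe_map(e$mesh, c(0, 0, 1), spacing = sp, min_chord = 10,
                  up_hint = c(0, 1, 0))
    z <- extract_safe_zone(m)
    scr <- plan_two_screws(e$mesh, m, z)
    c(scr$medial$length, scr$lateral$length)
  }, numeric(2))
  expect_lt(max(abs(lens[, 1] - lens[, 2])), 0.2)
})

test_that("half-zones too small for a 2 mm screw are refused", {
  dm <- disc_map(1.6, 30)   # inscribed circle of a half-disc: r/2 = 0.8 mm
  z <- extract_safe_zone(dm$map)
  expect_error(plan_two_screws(dm$shape$mesh, dm$map, z), "2 mm")
})

test_that("screw plans serialize to JSON and back", {
  dm <- disc_map(6, 40)
  z <- extract_safe_zone(dm$map)
  scr <- plan_two_screws(dm$shape$mesh, dm$map, z)
  path <- withr::local_tempfile(fileext = ".json")
  write_screw_plans(scr, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$medial$diameter, scr$medial$diameter)
  expect_equal(unlist(back$lateral$entry), scr$lateral$entry,
               tolerance = 1e-12, ignore_attr = TRUE)
})
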