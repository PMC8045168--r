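cyl5 <- make_solid_cylinder(5, 40)

test_that("solid_intervals classifies axial rays through a cylinder", {
  iv <- solid_intervals(cyl5$mesh, c(1, 1, -10), c(0, 0, 1))
  expect_equal(nrow(iv), 1L)
  expect_equal(unname(iv[1, 2] - iv[1, 1]), 40, tolerance = 1e-6)
  # miss
  expect_equal(nrow(solid_intervals(cyl5$mesh, c(10, 0, -10), c(0, 0, 1))),
               0L)
  # non-watertight input is refused
  open <- triangle_mesh(cyl5$mesh$vertices, cyl5$mesh$faces[-1, ])
  expect_error(solid_intervals(open, c(0, 0, -1), c(0, 0, 1)), "watertight")
})

test_that("rays through a curved rod's concavity see two in-bone segments", {
  cr <- make_curved_rod(7, 5, 60, arc_deg = 90)
  # view along the centerline chord; the concave side crosses two limbs
  d <- cr$truth$chord_dir
  m <- safe_map(cr$mesh, d, spacing = 0.5, min_chord = 10,
                up_hint = c(0, 1, 0))
  two <- which(m$count == 2L)
  expect_gt(length(two), 50)
  expect_true(all(!m$safe[two]))
  orc <- march_classify(cr$truth$inside, m, step = 0.2)
  agree_two <- mean(orc$count[two] == 2L)
  expect_gt(agree_two, 0.95)
})

test_that("axial safe area of an elliptic rod matches pi*a*b", {
  e <- make_elliptic_rod(8, 4, 40)
  m <- safe_map(e$mesh, c(0, 0, 1), spacing = 0.25, min_chord = 0,
                up_hint = c(0, 1, 0))
  expect_equal(safe_area(m), pi * 8 * 4, tolerance = 0.02)
  # every interior chord equals the extrusion length
  expect_equal(max(abs(m$chord[m$safe] - 40)), 0, tolerance = 1e-6)
})

test_that("side-on views cannot satisfy a chord bound above the diameter", {
  m <- safe_map(cyl5$mesh, c(1, 0, 0), spacing = 0.25, min_chord = 20,
                up_hint = c(0, 1, 0))
  expect_equal(safe_area(m), 0)
})

test_that("safe area is monotone in min_chord and bounded by silhouette", {
  e <- make_elliptic_rod(8, 4, 40)
  for (d in list(c(0, 0, 1), c(0.3, 0.1, 1), c(1, 0, 0.3))) {
    m0 <- safe_map(e$mesh, d, spacing = 0.5, min_chord = 0,
                   up_hint = c(0, 1, 0))
    silhouette <- sum(m0$count > 0L) * 0.25
    areas <- vapply(c(0, 5, 15, 30, 45), function(mc)
      safe_area(map_with_min_chord(m0, mc)), numeric(1))
    expect_true(all(diff(areas) <= 0))
    expect_true(all(areas <= silhouette + 1e-9))
  }
})

test_that("interval counts and chords are rigid-motion equivariant", {
  R <- rot3(0.4, -0.7, 1.1)
  shift <- c(13, -4, 8)
  cr <- make_curved_rod(6, 4, 50, arc_deg = 45)
  moved <- transform_mesh(cr$mesh, R, shift)
  origins <- rbind(c(1, 1, -10), c(-2, 0.5, -10), c(3.5, -1, -5))
  dirs <- rbind(c(0, 0, 1), c(0.1, 0.05, 1), c(0.05, -0.1, 1))
  for (k in seq_len(nrow(origins))) {
    d <- acroplan:::unit3(dirs[k, ])
    iv1 <- solid_intervals(cr$mesh, origins[k, ], d)
    iv2 <- solid_intervals(moved, drop(R %*% origins[k, ]) + shift,
                           drop(R %*% d))
    expect_equal(nrow(iv1), nrow(iv2))
    if (nrow(iv1) > 0) expect_equal(iv1, iv2, tolerance = 1e-6)
  }
})

test_that("safe_area is pixel count times pixel area", {
  fake <- structure(list(frame = list(spacing = 0.5),
                         safe = matrix(c(rep(TRUE, 100), rep(FALSE, 60)),
                                       16, 10)),
                    class = "safe_map")
  expect_equal(safe_area(fake), 25)
  fake$safe[] <- FALSE
  expect_equal(safe_area(fake), 0)
})

test_that("halving the pixel size changes the elliptic safe area < 2%", {
  e <- make_elliptic_rod(8, 4, 40)
  a1 <- safe_area(safe_map(e$mesh, c(0, 0, 1), spacing = 0.5,
                           min_chord = 0, up_hint = c(0, 1, 0)))
  a2 <- safe_area(safe_map(e$mesh, c(0, 0, 1), spacing = 0.25,
                           min_chord = 0, up_hint = c(0, 1, 0)))
  expect_lt(abs(a2 - a1) / a1, 0.02)
})

test_that("direction search recovers the extrusion axis and is equivariant", {
  e <- make_elliptic_rod(8, 4, 40)
  init <- acroplan:::unit3(c(sin(10 * pi / 180), 0, cos(10 * pi / 180)))
  opt <- optimize_direction(e$mesh, init, up_hint = c(0, 1, 0))
  expect_lt(angle_between_deg(opt$direction, c(0, 0, 1)), 1)

  R <- rot3(0.3, 0.5, -0.2)
  moved <- transform_mesh(e$mesh, R)
  opt2 <- optimize_direction(moved, drop(R %*% init),
                             up_hint = drop(R %*% c(0, 1, 0)))
  expect_lt(angle_between_deg(opt2$direction, drop(R %*% opt$direction)), 1)
})

test_that("a curved rod supports a smaller aligned corridor than a straight one", {
  straight <- make_elliptic_rod(7, 5, 50)
  curved <- make_curved_rod(7, 5, 50, arc_deg = 60)
  o_s <- optimize_direction(straight$mesh, c(0, 0, 1), up_hint = c(0, 1, 0),
                            cone_half_angle = 15)
  o_c <- optimize_direction(curved$mesh, curved$truth$chord_dir,
                            up_hint = c(0, 1, 0), cone_half_angle = 15)
  expect_lt(o_c$objective, o_s$objective)
})

test_that("safe maps export to PGM with a frame sidecar", {
  m <- safe_map(cyl5$mesh, c(0, 0, 1), spacing = 0.5, min_chord = 10,
                up_hint = c(0, 1, 0))
  prefix <- file.path(withr::local_tempdir(), "map")
  write_safe_map(m, prefix)
  img <- readLines(paste0(prefix, ".pgm"))
  expect_equal(img[1], "P2")
  expect_equal(as.integer(strsplit(img[2], " ")[[1]]),
               c(m$frame$nx, m$frame$ny))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  expect_equal(side$spacing, 0.5)
  expect_equal(unlist(side$d), m$frame$d, tolerance = 1e-12,
               ignore_attr = TRUE)
})
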