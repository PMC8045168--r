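box_patch_fixture <- function(noise = 0) {
  m <- cuboid_mesh(20, 6, 40)
  top <- which(m$vertices[, 2] == 6)
  # densify the top face so the plane fit is overdetermined
  gx <- seq(1, 19, by = 2); gz <- seq(1, 39, by = 2)
  extra <- cbind(rep(gx, times = length(gz)), 6,
                 rep(gz, each = length(gx)))
  if (noise > 0) {
    withr::local_seed(1)
    extra[, 2] <- extra[, 2] + stats::runif(nrow(extra), -noise, noise)
  }
  V <- rbind(m$vertices, extra)
  lm <- landmark_set(ac_facet = c(0, 3, 10), anterior_edge = c(20, 3, 0),
                     superior_patch = c(top, 8 + seq_len(nrow(extra))))
  # landmark_set checked separately; build mesh carrying the extra points
  # as isolated vertices (fine for plane fitting)
  list(mesh = triangle_mesh(V, m$faces), landmarks = lm)
}

test_that("plane A fits the superior patch with a superior normal", {
  fx <- box_patch_fixture()
  pl <- fit_plane_A(fx$mesh, fx$landmarks)
  expect_equal(abs(pl$normal), c(0, 1, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(pl$normal[2], 1)   # oriented superiorly, not inferiorly

  fxn <- box_patch_fixture(noise = 0.1)
  pln <- fit_plane_A(fxn$mesh, fxn$landmarks)
  expect_lt(angle_between_deg(pln$normal, c(0, 1, 0)), 1)
})

test_that("degenerate patches are rejected", {
  fx <- box_patch_fixture()
  lm2 <- fx$landmarks
  lm2$superior_patch <- lm2$superior_patch[1:3]
  # three corner vertices of the box top are not collinear; force collinear
  coll <- landmark_set(c(0, 3, 10), c(20, 3, 0),
                       superior_patch = c(9, 10, 11))
  mesh2 <- triangle_mesh(rbind(fx$mesh$vertices,
                               c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                         fx$mesh$faces)
  n <- nrow(mesh2$vertices)
  coll$superior_patch <- c(n - 2L, n - 1L, n)
  expect_error(fit_plane_A(mesh2, coll), "collinear")
  expect_error(landmark_set(c(0, 0, 0), c(1, 1, 1), superior_patch = 1:2),
               "at least 3")
})

test_that("plane B construction matches the hand construction and rotates", {
  plA <- reference_plane(c(0, 0, 0), c(0, 0, 1))
  zone <- structure(list(centroid = c(0, 0)), class = "safe_zone")
  e <- make_elliptic_rod(6, 3, 30)
  fr <- projection_frame(e$mesh, c(0, 1, 0), up_hint = c(0, 0, 1))
  plB <- define_plane_B(plA, zone, fr, axis_ref = c(0, 1, 0))
  expect_equal(abs(plB$normal), c(1, 0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  # axis parallel to the plane A normal leaves plane B undefined
  expect_error(define_plane_B(plA, zone, fr, axis_ref = c(0, 0, 1)),
               "undefined")
  # rotating every ingredient rotates plane B's normal identically
  R <- rot3(0.2, -0.4, 0.9)
  plA2 <- reference_plane(c(0, 0, 0), drop(R %*% c(0, 0, 1)))
  fr2 <- projection_frame(transform_mesh(e$mesh, R), drop(R %*% c(0, 1, 0)),
                          up_hint = drop(R %*% c(0, 0, 1)))
  plB2 <- define_plane_B(plA2, zone, fr2, axis_ref = drop(R %*% c(0, 1, 0)))
  expect_equal(abs(sum(plB2$normal * drop(R %*% plB$normal))), 1,
               tolerance = 1e-9)
})

test_that("screw-plane angles follow the closed forms", {
  pl <- reference_plane(c(0, 0, 0), c(0, 0, 1))
  expect_equal(screw_plane_angle(c(1, 0, 0), pl), 0)
  expect_equal(screw_plane_angle(c(0, 0, 1), pl), 90)
  expect_equal(screw_plane_angle(c(0, 1, 1) / sqrt(2), pl), 45,
               tolerance = 1e-9)
})

test_that("entry-point distances are Euclidean and side-labelled", {
  lm <- landmark_set(c(0, 0, 0), c(10, 0, 0), superior_patch = 1:5)
  mk <- function(entry) structure(list(entry = entry, direction = c(0, 0, 1),
                                       diameter = 4, length = 40),
                                  class = "screw_plan")
  screws <- list(medial = mk(c(3, 4, 0)), lateral = mk(c(0, 0, 0)))
  L <- landmark_distances(screws, lm)
  expect_equal(unname(L["L1"]), 5)            # 3-4-5
  expect_equal(unname(L["L3"]), 0)            # entry on the landmark
  expect_equal(unname(L["L4"]), 10)
  # swapping sides swaps the L1/L2 and L3/L4 roles
  Lsw <- landmark_distances(list(medial = screws$lateral,
                                 lateral = screws$medial), lm)
  expect_equal(unname(Lsw[c("L3", "L4")]), unname(L[c("L1", "L2")]))
})

test_that("measurement rows are rigid-motion invariant", {
  cyl <- make_solid_cylinder(5, 40)
  m <- safe_map(cyl$mesh, c(0, 0, 1), spacing = 0.25, min_chord = 10,
                up_hint = c(0, 1, 0))
  z <- extract_safe_zone(m)
  screws <- plan_two_screws(cyl$mesh, m, z, landmarks = cyl$landmarks)
  plA <- fit_plane_A(cyl$mesh, cyl$landmarks)
  plB <- define_plane_B(plA, z, m$frame, axis_ref = c(0, 0, 1))
  row <- measure_subject(screws, cyl$landmarks, plA, plB, "s", "M")
  # screws run along z, plane A normal ~ y: alpha must vanish
  expect_lt(row$alpha, 1e-6)
  expect_lt(row$beta, 1e-6)
  expect_equal(row$ms_length, 40, tolerance = 1e-6)

  # transform all measurement inputs by one rigid motion
  R <- rot3(-0.8, 0.3, 0.5); shift <- c(5, -9, 2)
  txp <- function(p) drop(R %*% p) + shift
  txs <- function(s) {
    s$entry <- txp(s$entry); s$direction <- drop(R %*% s$direction); s
  }
  lm2 <- landmark_set(txp(cyl$landmarks$ac_facet),
                      txp(cyl$landmarks$anterior_edge),
                      cyl$landmarks$superior_patch)
  plA2 <- reference_plane(txp(plA$point), drop(R %*% plA$normal))
  plB2 <- reference_plane(txp(plB$point), drop(R %*% plB$normal))
  row2 <- measure_subject(list(medial = txs(screws$medial),
                               lateral = txs(screws$lateral)),
                          lm2, plA2, plB2, "s", "M")
  expect_equal(as.numeric(row2[, 3:12]), as.numeric(row[, 3:12]),
               tolerance = 1e-6)
})

test_that("the measured downdip tracks the generator's plate geometry", {
  a <- generate_acromion(acromion_params(noise_amp = 0, seed = 3))
  res <- run_subject(subject = a, subject_id = "t", sex = "M")
  expect_equal(res$measurement$alpha, a$truth$alpha_deg, tolerance = 2,
               ignore_attr = TRUE)
  expect_lt(angle_between_deg(res$direction, a$truth$chord_dir), 5)
})

test_that("landmark files round-trip through the JSON schema", {
  lm <- landmark_set(c(1.5, 2, 3), c(-4, 0, 0.25), superior_patch = 5:40)
  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, path)
  back <- read_landmarks(path)
  expect_equal(back$ac_facet, lm$ac_facet)
  expect_equal(back$superior_patch, lm$superior_patch)
  expect_error(read_landmarks(file.path(tempdir(), "missing-landmarks.json")),
               "missing-landmarks.json")
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(ac_facet = c(1, 2, 3)), bad)
  expect_error(read_landmarks(bad), "missing field")
})
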