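#' Landmark annotations on a bone mesh
#'
#' @param ac_facet 3D point (mm) representing the acromioclavicular
#'   articular facet.
#' @param anterior_edge 3D point (mm) on the distal anterior edge of the
#'   acromion (the leading edge).
#' @param superior_patch integer vertex indices of the flat superior distal
#'   surface used to fit the reference plane (at least 30).
#' @param mesh optional [triangle_mesh()]; when given, landmark points are
#'   checked to lie near the surface (warning beyond 2 mm of any vertex).
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(ac_facet, anterior_edge, superior_patch,
                         mesh = NULL) {
  ac_facet <- as.numeric(ac_facet)
  anterior_edge <- as.numeric(anterior_edge)
  superior_patch <- as.integer(superior_patch)
  if (length(ac_facet) != 3L || length(anterior_edge) != 3L)
    stop("landmarks must be 3D points")
  if (length(superior_patch) < 3L)
    stop("superior_patch needs at least 3 vertex indices")
  if (!is.null(mesh)) {
    if (max(superior_patch) > nrow(mesh$vertices) || min(superior_patch) < 1L)
      stop("superior_patch indices out of range")
    for (p in list(ac_facet, anterior_edge)) {
      dmin <- sqrt(min(rowSums(sweep(mesh$vertices, 2, p)^2)))
      if (dmin > 2) warning("landmark point is ", round(dmin, 1),
                            " mm from the nearest mesh vertex")
    }
  }
  structure(list(ac_facet = ac_facet, anterior_edge = anterior_edge,
                 superior_patch = superior_patch),
            class = "landmark_set")
}

#' Read / write the landmark JSON schema
#'
#' Schema: `{"ac_facet": [x,y,z], "anterior_edge": [x,y,z],
#' "superior_patch": [1-based vertex indices]}`.
#'
#' @param path JSON file path.
#' @param landmarks a [landmark_set()] (for writing).
#' @return a [landmark_set()] / the path, invisibly.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("ac_facet", "anterior_edge", "superior_patch"))
    if (is.null(j[[f]])) stop("landmark file missing field: ", f)
  landmark_set(j$ac_facet, j$anterior_edge, j$superior_patch)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(unclass(landmarks), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' Reference plane (point + unit normal)
#'
#' @param point a 3D point on the plane (mm).
#' @param normal plane normal (normalized internally).
#' @return object of class `reference_plane`.
#' @export
reference_plane <- function(point, normal) {
  structure(list(point = as.numeric(point), normal = unit3(normal)),
            class = "reference_plane")
}

# area-weighted vertex normals
vertex_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  vn <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    for (c3 in 1:3) {
      acc <- rowsum(fn[, c3], F[, k])
      vn[as.integer(rownames(acc)), c3] <- vn[as.integer(rownames(acc)), c3] +
        acc
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

#' Fit the superior reference plane (plane A)
#'
#' Total-least-squares plane through the superior patch vertices, normal
#' oriented superiorly (positive dot product with the mean outward vertex
#' normal of the patch).
#'
#' @param mesh a [triangle_mesh()].
#' @param landmarks a [landmark_set()] with a valid `superior_patch`.
#' @return a [reference_plane()].
#' @export
fit_plane_A <- function(mesh, landmarks) {
  idx <- landmarks$superior_patch
  P <- mesh$vertices[idx, , drop = FALSE]
  if (nrow(P) < 3L) stop("degenerate plane: fewer than 3 patch vertices")
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate plane: collinear patch")
  n <- sv$v[, 3]
  vn <- colMeans(vertex_normals(mesh)[idx, , drop = FALSE])
  if (sum(n * vn) < 0) n <- -n
  reference_plane(ctr, n)
}

#' Define the sagittal reference plane (plane B)
#'
#' Plane through the safe-zone centroid, perpendicular to plane A, and
#' containing the projection of the anatomical long-axis reference onto
#' plane A. The inclination of the planned screw course relative to this
#' plane is then a pure medial/lateral deviation from the anatomical axis.
#'
#' @param planeA a [reference_plane()] from [fit_plane_A()].
#' @param zone a [safe_zone()].
#' @param frame the [projection_frame()] the zone lives in.
#' @param axis_ref the anatomical long-axis direction (e.g. the landmark
#'   initialization of the corridor search).
#' @return a [reference_plane()].
#' @export
define_plane_B <- function(planeA, zone, frame, axis_ref) {
  nA <- planeA$normal
  w <- axis_ref - sum(axis_ref * nA) * nA
  if (sqrt(sum(w^2)) < 1e-6)
    stop("plane B undefined: axis reference is parallel to plane A normal")
  nB <- unit3(cross3(nA, unit3(w)))
  ctr3 <- frame_point(frame, zone$centroid[1], zone$centroid[2], 0)
  reference_plane(ctr3, nB)
}

#' Angle between a screw and a reference plane
#'
#' Reported in degrees in \[0, 90\]: 0 for a screw lying in the plane, 90
#' for a screw along the plane normal.
#'
#' @param screw a `screw_plan` (or a bare direction vector).
#' @param plane a [reference_plane()].
#' @return angle in degrees.
#' @export
screw_plane_angle <- function(screw, plane) {
  d <- if (is.list(screw)) screw$direction else screw
  s <- abs(sum(unit3(d) * plane$normal))
  asin(min(1, s)) * 180 / pi
}

#' Entry-point distances to the anatomical landmarks
#'
#' Straight-line 3D distances from the screw entry points to the AC facet
#' and to the anterior (leading) edge: L1/L2 for the medial screw, L3/L4
#' for the lateral screw.
#'
#' @param screws list with `medial` and `lateral` `screw_plan`s.
#' @param landmarks a [landmark_set()].
#' @return named numeric vector `c(L1, L2, L3, L4)` in mm.
#' @export
landmark_distances <- function(screws, landmarks) {
  d <- function(p, q) sqrt(sum((p - q)^2))
  c(L1 = d(screws$medial$entry, landmarks$ac_facet),
    L2 = d(screws$medial$entry, landmarks$anterior_edge),
    L3 = d(screws$lateral$entry, landmarks$ac_facet),
    L4 = d(screws$lateral$entry, landmarks$anterior_edge))
}

#' Assemble one subject's measurement row
#'
#' Both screws share the corridor direction, so a single alpha (downdip
#' against plane A) and beta (inclination against plane B) pair describes
#' the subject.
#'
#' @param screws list with `medial` and `lateral` `screw_plan`s.
#' @param landmarks a [landmark_set()].
#' @param planeA,planeB [reference_plane()]s.
#' @param subject_id identifier stored in the row.
#' @param sex `"M"` or `"F"` (or `NA`).
#' @return one-row [tibble::tibble()] with lengths, diameters, L1-L4,
#'   alpha, beta.
#' @export
measure_subject <- function(screws, landmarks, planeA, planeB,
                            subject_id = NA_character_, sex = NA_character_) {
  L <- landmark_distances(screws, landmarks)
  alpha <- screw_plane_angle(screws$medial, planeA)
  beta <- screw_plane_angle(screws$medial, planeB)
  out <- tibble::tibble(
    subject = subject_id, sex = sex,
    ms_length = screws$medial$length, ms_diameter = screws$medial$diameter,
    ls_length = screws$lateral$length, ls_diameter = screws$lateral$diameter,
    L1 = L[["L1"]], L2 = L[["L2"]], L3 = L[["L3"]], L4 = L[["L4"]],
    alpha = alpha, beta = beta)
  stopifnot(all(unlist(out[, 3:12]) >= 0), alpha <= 90, beta <= 90)
  out
}
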