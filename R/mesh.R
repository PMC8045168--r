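#' Triangle surface mesh
#'
#' Container for a triangulated bone surface. Coordinates are always in
#' millimetres, in a right-handed patient-like frame. For solid (ray
#' interval) queries the mesh must be watertight and consistently oriented
#' with positive signed volume; [validate_mesh()] reports both.
#'
#' The planning pipeline was developed for right-sided bones; left-sided
#' inputs must be mirrored by the caller before loading.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param provenance optional list noting source path and units handling.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, provenance = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) == 0L || nrow(vertices) == 0L)
    stop("degenerate input: empty mesh")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, provenance = provenance),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [mm]: x %.1f..%.1f  y %.1f..%.1f  z %.1f..%.1f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  cat(sprintf("  signed volume: %.2f mm^3\n", mesh_volume(x)))
  invisible(x)
}

#' Signed enclosed volume of a closed mesh
#'
#' Sum of signed tetrahedron volumes against the origin; positive for a
#' watertight mesh with outward-oriented faces.
#'
#' @param mesh a [triangle_mesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  # scalar triple product a . (b x c)
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Validate a surface mesh
#'
#' Reports (never raises) the solid-query preconditions: watertightness
#' (every undirected edge shared by exactly two faces), consistent outward
#' orientation (each directed edge used once and signed volume > 0), and the
#' number of connected components.
#'
#' @param mesh a [triangle_mesh()].
#' @return list with `watertight`, `oriented`, `n_components`,
#'   `signed_volume`, and `ok` (watertight and oriented and one component).
#' @export
validate_mesh <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  key_dir <- paste(e[, 1], e[, 2])
  key_und <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  und_tab <- table(key_und)
  watertight <- all(und_tab == 2L)
  vol <- mesh_volume(mesh)
  oriented <- !anyDuplicated(key_dir) && vol > 0
  n_components <- mesh_components(mesh)$n
  list(watertight = watertight, oriented = oriented,
       n_components = n_components, signed_volume = vol,
       ok = watertight && oriented && n_components == 1L)
}

# Connected components over vertex adjacency (union-find).
# Returns list(n, face_component).
mesh_components <- function(mesh) {
  nv <- nrow(mesh$vertices)
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  F <- mesh$faces
  for (k in seq_len(nrow(F))) {
    a <- find(F[k, 1]); b <- find(F[k, 2]); c <- find(F[k, 3])
    parent[b] <- a
    parent[find(c)] <- find(a)
  }
  roots_f <- vapply(F[, 1], find, integer(1))
  used <- unique(roots_f)
  list(n = length(used), face_component = match(roots_f, used))
}

#' Apply a rigid (or affine) transform to a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @param rotation 3x3 matrix applied to vertex coordinates.
#' @param translation length-3 offset added after rotation.
#' @return transformed `triangle_mesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  V <- mesh$vertices %*% t(rotation)
  V <- sweep(V, 2, translation, "+")
  triangle_mesh(V, mesh$faces, mesh$provenance)
}

# Drop all but the largest-volume connected component (warns when pruning).
keep_largest_component <- function(mesh) {
  comp <- mesh_components(mesh)
  if (comp$n <= 1L) return(mesh)
  vols <- vapply(seq_len(comp$n), function(k) {
    abs(mesh_volume(triangle_mesh(mesh$vertices,
                                  mesh$faces[comp$face_component == k, ,
                                             drop = FALSE])))
  }, numeric(1))
  keep <- which.max(vols)
  warning(sprintf("mesh has %d components; keeping largest by volume", comp$n))
  F <- mesh$faces[comp$face_component == keep, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  remap <- match(F, used)
  dim(remap) <- dim(F)
  triangle_mesh(mesh$vertices[used, , drop = FALSE], remap, mesh$provenance)
}
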