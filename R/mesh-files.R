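#' Read a surface mesh from STL or PLY
#'
#' Supports binary and ASCII STL and ASCII PLY. Coordinates are converted to
#' millimetres; files stored in metres are rescaled by 1000 via `units = "m"`.
#' Duplicate vertices (STL stores one triplet per facet corner) are merged by
#' exact coordinate identity. A validation report is attached as the
#' `validation` element of the mesh provenance.
#'
#' @param path file path ending in `.stl` or `.ply`.
#' @param units `"mm"` (default) or `"m"`.
#' @return a [triangle_mesh()].
#' @export
load_mesh <- function(path, units = c("mm", "m")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    stl = read_stl(path),
    ply = read_ply_ascii(path),
    stop("unsupported mesh format: .", ext, " (expected STL or PLY)"))
  if (nrow(mesh$faces) == 0L) stop("degenerate input: mesh has no faces")
  if (units == "m") mesh$vertices <- mesh$vertices * 1000
  mesh <- triangle_mesh(mesh$vertices, mesh$faces,
                        provenance = list(path = path, units = units))
  mesh$provenance$validation <- validate_mesh(mesh)
  mesh
}

#' Write a surface mesh to STL (ASCII or binary) or PLY (ASCII)
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path; format chosen by extension.
#' @param binary write binary STL (ignored for PLY).
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, binary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl" && binary) write_stl_binary(mesh, path)
  else if (ext == "stl") write_stl_ascii(mesh, path)
  else if (ext == "ply") write_ply_ascii(mesh, path)
  else stop("unsupported mesh format: .", ext)
  invisible(path)
}

face_normals <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# Merge per-facet vertex triplets into an indexed mesh (exact identity).
index_soup <- function(tri_coords) {
  key <- paste(tri_coords[, 1], tri_coords[, 2], tri_coords[, 3])
  idx <- match(key, key)          # first occurrence per distinct coordinate
  used <- sort(unique(idx))
  verts <- tri_coords[used, , drop = FALSE]
  faces <- matrix(match(idx, used), ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_stl <- function(path) {
  size <- file.info(path)$size
  if (is.na(size) || size < 15) stop("format error: truncated STL file")
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 5)
  is_ascii <- identical(rawToChar(head), "solid")
  if (is_ascii) {
    # an 84-byte-header binary file can also start with "solid"; check that
    # an ASCII body actually follows
    txt_probe <- tryCatch(readLines(path, n = 3, warn = FALSE),
                          error = function(e) character())
    is_ascii <- any(grepl("facet|endsolid", txt_probe))
  }
  if (is_ascii) return(read_stl_ascii(path))
  if (size < 84) stop("format error: truncated STL file")
  seek(con, 80)
  nfac <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  expected <- 84 + 50 * as.numeric(nfac)
  if (nfac <= 0 || size < expected) stop("format error: truncated STL file")
  coords <- matrix(NA_real_, nrow = 3 * nfac, ncol = 3)
  for (f in seq_len(nfac)) {
    rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "raw", n = 2)
    coords[(3 * f - 2):(3 * f), ] <- matrix(rec[4:12], ncol = 3, byrow = TRUE)
  }
  if (anyNA(coords)) stop("format error: truncated STL file")
  index_soup(coords)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("format error: malformed ASCII STL")
  if (!any(grepl("endsolid", lines)))
    stop("format error: truncated STL file")
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]))
  coords <- do.call(rbind, nums)
  if (anyNA(coords)) stop("format error: malformed ASCII STL")
  index_soup(coords)
}

write_stl_ascii <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  n <- face_normals(V, F)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  body <- character(7 * nrow(F))
  for (f in seq_len(nrow(F))) {
    i <- 7 * (f - 1)
    body[i + 1] <- sprintf(" facet normal %.9g %.9g %.9g",
                           n[f, 1], n[f, 2], n[f, 3])
    body[i + 2] <- "  outer loop"
    for (k in 1:3) {
      p <- V[F[f, k], ]
      body[i + 2 + k] <- sprintf("   vertex %.9g %.9g %.9g", p[1], p[2], p[3])
    }
    body[i + 6] <- "  endloop"
    body[i + 7] <- " endfacet"
  }
  writeLines(body, con)
  writeLines("endsolid mesh", con)
}

write_stl_binary <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  n <- face_normals(V, F)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
  for (f in seq_len(nrow(F))) {
    rec <- c(n[f, ], t(V[F[f, ], ]))
    writeBin(as.numeric(rec), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || lines[1] != "ply")
    stop("format error: not a PLY file")
  if (!grepl("ascii", lines[2]))
    stop("format error: only ASCII PLY is supported")
  endh <- match("end_header", lines)
  if (is.na(endh)) stop("format error: truncated PLY header")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("format error: malformed PLY header")
  if (length(lines) < endh + nv + nf) stop("format error: truncated PLY file")
  vparts <- strsplit(trimws(lines[(endh + 1):(endh + nv)]), "\\s+")
  verts <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
  fparts <- strsplit(trimws(lines[(endh + nv + 1):(endh + nv + nf)]), "\\s+")
  faces <- t(vapply(fparts, function(p) {
    if (as.integer(p[1]) != 3L) stop("format error: non-triangular PLY face")
    as.integer(p[2:4]) + 1L
  }, integer(3)))
  if (anyNA(verts) || anyNA(faces)) stop("format error: malformed PLY body")
  list(vertices = verts, faces = faces)
}

write_ply_ascii <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(F)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
}
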