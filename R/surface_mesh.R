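#' Triangulated surface mesh
#'
#' The geometric substrate for all morphometry: a triangle mesh in a common
#' coordinate frame, in millimetres.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, columns indexing
#'   `vertices` (1-based).
#' @param name label carried through IO and clipping.
#' @param validate run [validate_surface_mesh()] on the result.
#' @return An object of class `surface_mesh`.
#' @seealso [read_mesh()], [write_mesh()], [mesh_area()]
#' @export
surface_mesh <- function(vertices, faces, name = "", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stopf("vertices must have 3 columns")
  if (ncol(faces) != 3L) stopf("faces must have 3 columns")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  m <- structure(list(vertices = vertices, faces = faces,
                      name = as.character(name)[1L]),
                 class = "surface_mesh")
  if (validate) validate_surface_mesh(m)
  m
}

#' Validate a surface mesh
#'
#' Checks the invariants every mesh in the pipeline must satisfy: finite
#' coordinates, at least 3 vertices and 1 face, valid vertex indices, and
#' no degenerate triangle with area at or below 1e-9 mm^2.
#'
#' @param mesh a `surface_mesh`.
#' @return `mesh`, invisibly; errors on violation.
#' @export
validate_surface_mesh <- function(mesh) {
  if (!inherits(mesh, "surface_mesh")) stopf("not a surface_mesh")
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(v) < 3L) stopf("mesh validation: fewer than 3 vertices")
  if (nrow(f) < 1L) stopf("mesh validation: no faces")
  if (!all(is.finite(v))) stopf("mesh validation: non-finite vertex coordinates")
  if (min(f) < 1L || max(f) > nrow(v))
    stopf("mesh validation: face references an invalid vertex index")
  a <- face_areas(mesh)
  if (any(a <= 1e-9))
    stopf("mesh validation: %d degenerate face(s) with area <= 1e-9 mm^2",
          sum(a <= 1e-9))
  invisible(mesh)
}

## Per-triangle areas (mm^2), vectorised.
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - p1
  e2 <- v[f[, 3L], , drop = FALSE] - p1
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh
#'
#' @param mesh a `surface_mesh`.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh '%s': %d vertices, %d faces, area %.2f mm^2>\n",
              x$name, nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Merge coincident vertices
#'
#' Vertices closer than `tol` are collapsed to a single vertex and faces
#' remapped; triangles that become degenerate (repeated indices or area at
#' or below 1e-9 mm^2) are dropped with a warning. STL files store each
#' triangle with its own three vertices, so this runs after every read.
#'
#' @param mesh a `surface_mesh`.
#' @param tol merge tolerance in mm.
#' @return a `surface_mesh` with shared vertices.
#' @export
merge_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  f <- matrix(map[mesh$faces], ncol = 3L)
  bad <- f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]
  out <- surface_mesh(newv, f[!bad, , drop = FALSE], mesh$name, validate = FALSE)
  a <- face_areas(out)
  deg <- a <= 1e-9
  if (any(bad) || any(deg))
    warnf("dropped %d degenerate face(s) while merging vertices",
          sum(bad) + sum(deg))
  out$faces <- out$faces[!deg, , drop = FALSE]
  out
}

#' Read a triangle mesh from an STL file
#'
#' Accepts binary and ASCII STL. Duplicate vertices are merged within
#' 1e-6 mm and degenerate triangles dropped (with a warning), so the
#' returned mesh always satisfies [validate_surface_mesh()].
#'
#' @param path file path.
#' @param name mesh label; defaults to the file name without extension.
#' @return a `surface_mesh`.
#' @export
read_mesh <- function(path, name = NULL) {
  if (!file.exists(path)) stopf("mesh file not found: %s", path)
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 15L) stopf("not a readable STL file: %s", path)
  mesh <- if (is_ascii_stl(raw)) read_stl_ascii(raw, name) else read_stl_binary(raw, path, name)
  mesh <- merge_vertices(mesh, tol = 1e-6)
  validate_surface_mesh(mesh)
  mesh
}

## An STL is ASCII when it starts with "solid" AND its byte count does not
## match the binary layout (84 + 50 * n). Some binary writers also start
## with "solid", hence the size check.
is_ascii_stl <- function(raw) {
  head <- rawToChar(raw[seq_len(min(5L, length(raw)))])
  if (!identical(tolower(head), "solid")) return(FALSE)
  if (length(raw) >= 84L) {
    n <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
    if (!is.na(n) && n >= 0 && length(raw) == 84L + 50 * as.numeric(n))
      return(FALSE)
  }
  TRUE
}

read_stl_ascii <- function(raw, name) {
  txt <- strsplit(rawToChar(raw), "\r?\n")[[1L]]
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stopf("malformed ASCII STL: vertex lines missing or not in triples")
  nums <- suppressWarnings(
    as.numeric(unlist(strsplit(trimws(sub("^\\s*vertex\\s+", "", vl)), "\\s+"))))
  if (anyNA(nums) || length(nums) != 3L * length(vl))
    stopf("malformed ASCII STL: non-numeric vertex coordinates")
  v <- matrix(nums, ncol = 3L, byrow = TRUE)
  f <- matrix(seq_len(nrow(v)), ncol = 3L, byrow = TRUE)
  surface_mesh(v, f, name, validate = FALSE)
}

read_stl_binary <- function(raw, path, name) {
  if (length(raw) < 84L) stopf("truncated binary STL: %s", path)
  n <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
  if (is.na(n) || n < 1L || length(raw) < 84L + 50 * as.numeric(n))
    stopf("binary STL facet count inconsistent with file size: %s", path)
  ## Each 50-byte record: 12 little-endian float32 then 2 attribute bytes.
  rec0 <- 84L + 50L * (seq_len(n) - 1L)
  idx <- rep(rec0, each = 48L) + seq_len(48L)
  fl <- readBin(raw[idx], "numeric", n = 12L * n, size = 4L, endian = "little")
  m <- matrix(fl, ncol = 12L, byrow = TRUE)  # normal xyz, v1, v2, v3
  v <- matrix(t(m[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  f <- matrix(seq_len(3L * n), ncol = 3L, byrow = TRUE)
  surface_mesh(v, f, name, validate = FALSE)
}

#' Write a triangle mesh to an STL file
#'
#' Binary STL by default (compact); ASCII on request.
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param format `"binary"` or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  validate_surface_mesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  len <- sqrt(nx^2 + ny^2 + nz^2)
  len[len == 0] <- 1
  nrm <- cbind(nx, ny, nz) / len
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", mesh$name), con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", p1[i, 1], p1[i, 2], p1[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", p2[i, 1], p2[i, 2], p2[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", p3[i, 1], p3[i, 2], p3[i, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", mesh$name), con)
    return(invisible(path))
  }
  n <- nrow(f)
  floats <- as.numeric(t(cbind(nrm, p1, p2, p3)))  # 12 per facet
  fraw <- writeBin(floats, raw(), size = 4L, endian = "little")
  out <- raw(84L + 50L * n)
  hdr <- charToRaw(sprintf("iomorph STL %s", mesh$name))
  out[seq_len(min(80L, length(hdr)))] <- hdr[seq_len(min(80L, length(hdr)))]
  out[81:84] <- writeBin(as.integer(n), raw(), size = 4L, endian = "little")
  rec0 <- 84L + 50L * (seq_len(n) - 1L)
  idx <- rep(rec0, each = 48L) + seq_len(48L)
  out[idx] <- fraw
  writeBin(out, path)
  invisible(path)
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh a `surface_mesh`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 offset (mm).
#' @return the transformed mesh.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2L, vec3(translation, "translation"), "+")
  surface_mesh(v, mesh$faces, mesh$name, validate = FALSE)
}
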