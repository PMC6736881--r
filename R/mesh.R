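#' Simple triangulated mesh
#'
#' Minimal triangle-mesh container: `vertices` (n x 3, mm), `faces` (m x 3,
#' 1-based vertex indices) and optional per-vertex `normals`. Degenerate
#' (zero-area) faces are dropped at construction.
#'
#' @param vertices n x 3 matrix.
#' @param faces m x 3 integer matrix.
#' @param normals optional n x 3 matrix.
#' @return object of class `mesh3d_simple`.
#' @export
mesh3d_simple <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop("vertices must be n x 3")
  if (any(faces < 1 | faces > nrow(vertices))) stop("face index out of range")
  a <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area2 <- sqrt(rowSums(cr^2))
  faces <- faces[area2 > 1e-12, , drop = FALSE]
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "mesh3d_simple")
}

#' @export
print.mesh3d_simple <- function(x, ...) {
  cat("Mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  invisible(x)
}

#' Read or write a mesh as ASCII PLY
#'
#' Supports ASCII PLY with vertex properties x, y, z (extra scalar
#' properties are written back for colormapped exports) and triangular
#' faces.
#'
#' @param path file path.
#' @return `read_ply` returns a [mesh3d_simple].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (!grepl("^ply", lines[1])) stop("not a PLY file")
  hdr_end <- which(lines == "end_header")[1]
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("format ascii", hdr))) stop("only ASCII PLY supported")
  nv <- as.integer(sub(".*element vertex ", "", grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face ", "", grep("element face", hdr, value = TRUE)[1]))
  vl <- lines[(hdr_end + 1):(hdr_end + nv)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(v) as.numeric(v[1:3])))
  fl <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(v) {
    v <- as.integer(v)
    if (v[1] != 3) stop("only triangular faces supported")
    v[2:4] + 1L
  }))
  mesh3d_simple(verts, faces)
}

#' @rdname read_ply
#' @param mesh a [mesh3d_simple].
#' @param scalars optional named numeric vector/column (one value per
#'   vertex) written as an extra `quality` property (e.g. deviation values
#'   for colormapped display).
#' @export
write_ply <- function(mesh, path, scalars = NULL) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nv),
           "property float x", "property float y", "property float z",
           if (!is.null(scalars)) "property float quality",
           paste("element face", nf),
           "property list uchar int vertex_indices", "end_header")
  v <- mesh$vertices
  vl <- if (is.null(scalars))
    sprintf("%.8g %.8g %.8g", v[, 1], v[, 2], v[, 3])
  else sprintf("%.8g %.8g %.8g %.8g", v[, 1], v[, 2], v[, 3], scalars)
  fl <- sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                mesh$faces[, 3] - 1L)
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}

#' Read or write a mesh as Wavefront OBJ
#'
#' @param path file path.
#' @return `read_obj` returns a [mesh3d_simple].
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                                 function(v) as.numeric(v[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(v) {
    idx <- as.integer(sub("/.*", "", v[2:4]))
    idx
  }))
  mesh3d_simple(verts, faces)
}

#' @rdname read_obj
#' @param mesh a [mesh3d_simple].
#' @export
write_obj <- function(mesh, path) {
  v <- mesh$vertices
  writeLines(c(sprintf("v %.8g %.8g %.8g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3])),
             path)
  invisible(path)
}

# Angle-agnostic area-weighted outward vertex normals. Orientation follows
# the face winding; for the package's generated ellipsoid meshes winding is
# outward.
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    n[, 1] <- n[, 1] + tabulate2(f[, j], fn[, 1], nrow(v))
    n[, 2] <- n[, 2] + tabulate2(f[, j], fn[, 2], nrow(v))
    n[, 3] <- n[, 3] + tabulate2(f[, j], fn[, 3], nrow(v))
  }
  len <- sqrt(rowSums(n^2))
  len[len < 1e-300] <- 1
  n / len
}

tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Latitude-longitude ellipsoid mesh
#'
#' Deterministic triangulated ellipsoid used as a synthetic skull-like test
#' surface; outward-wound faces.
#'
#' @param radii length-3 semi-axes (mm).
#' @param n_lat,n_lon grid resolution.
#' @param center length-3 center.
#' @return a [mesh3d_simple].
#' @export
ellipsoid_mesh <- function(radii = c(70, 90, 65), n_lat = 16, n_lon = 24,
                           center = c(0, 0, 0)) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 2)[2:(n_lat + 1)]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  g <- expand.grid(lon = lon, lat = lat)
  ring <- cbind(cos(g$lat) * cos(g$lon), cos(g$lat) * sin(g$lon), sin(g$lat))
  verts <- rbind(ring, c(0, 0, -1), c(0, 0, 1))
  south <- nrow(verts) - 1L; north <- nrow(verts)
  faces <- list()
  at <- function(i, j) (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  for (i in seq_len(n_lat - 1)) for (j in seq_len(n_lon)) {
    faces[[length(faces) + 1]] <- c(at(i, j), at(i, j + 1), at(i + 1, j))
    faces[[length(faces) + 1]] <- c(at(i, j + 1), at(i + 1, j + 1), at(i + 1, j))
  }
  for (j in seq_len(n_lon)) {
    faces[[length(faces) + 1]] <- c(south, at(1, j + 1), at(1, j))
    faces[[length(faces) + 1]] <- c(north, at(n_lat, j), at(n_lat, j + 1))
  }
  verts <- sweep(sweep(verts, 2, radii, `*`), 2, center, `+`)
  mesh3d_simple(verts, do.call(rbind, faces))
}
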