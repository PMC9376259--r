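#' Triangulated surface mesh
#'
#' Constructs a surface mesh from vertex coordinates (in mm) and triangle
#' faces. Vertex indices are 1-based inside R; file formats keep their native
#' 0-based convention at the I/O boundary.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix with three 1-based vertex indices per row.
#'   May have zero rows for point sets that carry no triangulation.
#' @return An object of class `surface_mesh` with elements `vertices` and
#'   `faces`.
#' @export
surface_mesh <- function(vertices, faces = matrix(integer(0), 0, 3)) {
  vertices <- as_coord_matrix(vertices, "vertices")
  dimnames(vertices) <- NULL
  if (nrow(vertices) < 1L) stop_arg("a mesh needs at least one vertex")
  faces <- as.matrix(faces)
  dimnames(faces) <- NULL
  if (length(faces) == 0L) faces <- matrix(integer(0), 0, 3)
  if (ncol(faces) != 3L) stop_arg("faces must have 3 columns")
  storage.mode(faces) <- "integer"
  if (nrow(faces)) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop_arg("face indices out of range [1, %d]", nrow(vertices))
    degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
             faces[, 2] == faces[, 3]
    if (any(degen))
      stop_arg("degenerate face (repeated vertex index) at row %d",
               which(degen)[1])
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Icosphere generator
#'
#' Builds a geodesic sphere by recursive midpoint subdivision of an
#' icosahedron, projecting every vertex back onto the sphere. Subdivision
#' level n yields 10 * 4^n + 2 vertices and 20 * 4^n faces.
#'
#' @param subdivisions non-negative integer, at most 7.
#' @param radius sphere radius in mm.
#' @return A `surface_mesh`.
#' @export
make_icosphere <- function(subdivisions = 0L, radius = 100) {
  if (length(subdivisions) != 1L || is.na(subdivisions) || subdivisions < 0)
    stop_arg("subdivisions must be a non-negative integer")
  if (subdivisions > 7) stop_arg("subdivisions > 7 not supported (size guard)")
  if (radius <= 0) stop_arg("radius must be positive")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2),  c(1, 2, 8),   c(1, 8, 11),  c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7),  c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3),  c(4, 3, 7),   c(4, 7, 9),   c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11),  c(9, 7, 8),   c(10, 9, 2))
  for (i in seq_len(subdivisions)) {
    res <- subdivide_once(v, f)
    v <- res$v; f <- res$f
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  surface_mesh(v, f)
}

# One 4-to-1 midpoint subdivision; midpoints shared between faces are reused.
subdivide_once <- function(v, f) {
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  nf <- nrow(f)
  keys <- c(edge_key(f[, 1], f[, 2]), edge_key(f[, 2], f[, 3]),
            edge_key(f[, 3], f[, 1]))
  uk <- unique(keys)
  mid_id <- match(keys, uk) + nrow(v)
  ab <- matrix(as.integer(unlist(strsplit(uk, " "))), ncol = 2, byrow = TRUE)
  mids <- (v[ab[, 1], , drop = FALSE] + v[ab[, 2], , drop = FALSE]) / 2
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m31 <- mid_id[2 * nf + seq_len(nf)]
  newf <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
                cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  list(v = rbind(v, mids), f = newf)
}

#' Mean nearest-vertex distance
#'
#' Average, over all vertices, of the Euclidean distance from each vertex to
#' its closest other vertex. On the standard fsaverage template this statistic
#' is about 0.54 mm per hemisphere, an order of magnitude finer than typical
#' functional voxel sizes -- the motivation for downsampling to label space.
#'
#' @param mesh a `surface_mesh`.
#' @return mean nearest-neighbour distance in mm.
#' @export
mean_nearest_vertex_distance <- function(mesh) {
  v <- mesh$vertices
  if (nrow(v) < 2L) stop_arg("need at least 2 vertices")
  mean(nearest_dist(v))
}

#' Per-vertex surface area
#'
#' Distributes each triangle's area equally over its three corners, so the
#' vertex areas sum exactly to the total mesh area. Used to report cluster
#' extents in mm^2.
#'
#' @param mesh a `surface_mesh` with at least one face.
#' @return numeric vector, one area (mm^2) per vertex.
#' @export
vertex_areas <- function(mesh) {
  if (nrow(mesh$faces) == 0L) stop_arg("mesh has no faces")
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  fa <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  out <- numeric(nrow(v))
  third <- fa / 3
  for (j in 1:3) {
    acc <- tapply(third, f[, j], sum)
    idx <- as.integer(names(acc))
    out[idx] <- out[idx] + as.numeric(acc)
  }
  out
}

total_area <- function(mesh) sum(vertex_areas(mesh))
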