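## Vectorized simplex geometry shared by the mesh and OMT modules.

#' Signed volumes of tetrahedra
#'
#' @param verts n x 3 coordinate matrix.
#' @param tets T x 4 index matrix.
#' @return numeric vector of signed volumes \eqn{\det[b-a, c-a, d-a]/6}.
#' @export
tetVolumes <- function(verts, tets) {
  a <- verts[tets[, 1], , drop = FALSE]
  b <- verts[tets[, 2], , drop = FALSE] - a
  c <- verts[tets[, 3], , drop = FALSE] - a
  d <- verts[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
   b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
   b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])) / 6
}

#' Areas of triangles
#'
#' @param verts n x 3 coordinate matrix.
#' @param faces F x 3 index matrix.
#' @return numeric vector of (unsigned) triangle areas.
#' @export
triangleAreas <- function(verts, faces) {
  n <- triangleNormals(verts, faces)
  sqrt(rowSums(n * n)) / 2
}

# Unnormalized normals (cross products); |n| = 2 * area.
triangleNormals <- function(verts, faces) {
  a <- verts[faces[, 1], , drop = FALSE]
  u <- verts[faces[, 2], , drop = FALSE] - a
  v <- verts[faces[, 3], , drop = FALSE] - a
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# Row-wise cross product.
rowCross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

rowNorms <- function(m) sqrt(rowSums(m * m))

# Normalize rows to unit 2-norm.
rowUnit <- function(m) m / rowNorms(m)

# Corner cotangents of image triangles: returns F x 3 matrix, column k is
# the cotangent of the angle at vertex k of each face.
triangleCotangents <- function(verts, faces) {
  p1 <- verts[faces[, 1], , drop = FALSE]
  p2 <- verts[faces[, 2], , drop = FALSE]
  p3 <- verts[faces[, 3], , drop = FALSE]
  cotAt <- function(a, b, c) {        # angle at a, edges to b and c
    u <- b - a; v <- c - a
    dot <- rowSums(u * v)
    crs <- rowNorms(rowCross(u, v))
    dot / pmax(crs, .Machine$double.xmin)
  }
  cbind(cotAt(p1, p2, p3), cotAt(p2, p1, p3), cotAt(p3, p1, p2))
}

# Area of spherical triangles (vertices on the unit sphere) via the
# signed-solid-angle formula of van Oosterom & Strackee.
sphericalTriangleAreas <- function(verts, faces) {
  a <- verts[faces[, 1], , drop = FALSE]
  b <- verts[faces[, 2], , drop = FALSE]
  c <- verts[faces[, 3], , drop = FALSE]
  num <- rowSums(a * rowCross(b, c))
  den <- 1 + rowSums(a * b) + rowSums(b * c) + rowSums(a * c)
  2 * atan2(num, den)
}

# Sorted-face key (double-precision exact for < 2^17 vertices).
faceKeys <- function(faces, nv) {
  nv <- as.numeric(nv)
  a <- as.numeric(pmin(faces[, 1], faces[, 2], faces[, 3]))
  c0 <- as.numeric(pmax(faces[, 1], faces[, 2], faces[, 3]))
  b <- as.numeric(faces[, 1]) + as.numeric(faces[, 2]) +
    as.numeric(faces[, 3]) - a - c0
  (a - 1) + nv * ((b - 1) + nv * (c0 - 1))
}
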