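# Low-level geometric primitives shared by the phantom generator and the
# forward solver: icosphere triangulations, triangle/tetrahedron measures,
# and dihedral-angle quality metrics.  All coordinates are in millimetres.

#' Geodesic sphere triangulation (icosphere)
#'
#' Subdivides a regular icosahedron `n_subdiv` times, projecting every new
#' vertex onto the unit sphere.  The construction is fully deterministic:
#' the same `n_subdiv` always yields bit-identical vertices and faces.
#'
#' @param n_subdiv Number of 4-to-1 subdivision passes (0 = icosahedron).
#'   Levels 0..4 give 12, 42, 162, 642, 2562 vertices.
#' @return List with `vertices` (V x 3, unit norm) and `faces` (F x 3,
#'   1-based vertex indices, consistently outward oriented).
#' @export
icosphere <- function(n_subdiv = 3) {
  stopifnot(is.numeric(n_subdiv), n_subdiv >= 0)
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(n_subdiv)) {
    nv <- nrow(v)
    # midpoint index cache keyed on the ordered vertex pair
    key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
    e1 <- key(f[, 1], f[, 2]); e2 <- key(f[, 2], f[, 3]); e3 <- key(f[, 3], f[, 1])
    ek <- unique(c(e1, e2, e3))
    mid_of <- stats::setNames(seq_along(ek) + nv, ek)
    pa <- ek %/% (nv + 1); pb <- ek %% (nv + 1)
    mids <- (v[pa, , drop = FALSE] + v[pb, , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m1 <- mid_of[as.character(e1)]; m2 <- mid_of[as.character(e2)]
    m3 <- mid_of[as.character(e3)]
    f <- rbind(
      cbind(f[, 1], m1, m3),
      cbind(f[, 2], m2, m1),
      cbind(f[, 3], m3, m2),
      cbind(m1, m2, m3)
    )
  }
  dimnames(v) <- NULL; dimnames(f) <- NULL
  list(vertices = v, faces = f)
}

#' Triangle areas of a surface
#' @param vertices V x 3 coordinate matrix.
#' @param faces F x 3 index matrix.
#' @return Numeric vector of triangle areas (squared input units).
#' @export
triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Signed tetrahedron volumes
#' @param nodes N x 3 coordinate matrix.
#' @param elems M x 4 index matrix.
#' @return Signed volumes; positive for right-handed node ordering.
#' @export
tet_volumes <- function(nodes, elems) {
  p1 <- nodes[elems[, 1], , drop = FALSE]
  a <- nodes[elems[, 2], , drop = FALSE] - p1
  b <- nodes[elems[, 3], , drop = FALSE] - p1
  c3 <- nodes[elems[, 4], , drop = FALSE] - p1
  cx <- b[, 2] * c3[, 3] - b[, 3] * c3[, 2]
  cy <- b[, 3] * c3[, 1] - b[, 1] * c3[, 3]
  cz <- b[, 1] * c3[, 2] - b[, 2] * c3[, 1]
  (a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6
}

# Minimum dihedral angle (degrees) over all elements.  Used as the mesh
# quality gate; slivers drive this towards zero.
min_dihedral_deg <- function(nodes, elems) {
  # face normals of the four faces per tet; dihedral between face pairs
  # sharing an edge.  Angle between inward normals = pi - dihedral.
  faces_local <- rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
  nrm <- vector("list", 4)
  for (i in 1:4) {
    fi <- faces_local[i, ]
    p1 <- nodes[elems[, fi[1]], , drop = FALSE]
    a <- nodes[elems[, fi[2]], , drop = FALSE] - p1
    b <- nodes[elems[, fi[3]], , drop = FALSE] - p1
    n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
    nrm[[i]] <- n / sqrt(rowSums(n^2))
  }
  worst <- rep(180, nrow(elems))
  for (i in 1:3) for (j in (i + 1):4) {
    cosv <- rowSums(nrm[[i]] * nrm[[j]])
    cosv <- pmin(1, pmax(-1, cosv))
    ang <- 180 - acos(cosv) * 180 / pi  # dihedral between the two faces
    worst <- pmin(worst, ang)
  }
  min(worst)
}

# Euler characteristic V - E + F of a triangulated surface.
euler_characteristic <- function(faces) {
  v <- length(unique(as.vector(faces)))
  ed <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  e <- nrow(unique(ed))
  v - e + nrow(faces)
}

# Restore the caller's RNG state after running expr under a fixed seed.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child-seed derivation: one master seed feeds every stochastic
# stage (lesions, gPC sampling, validation) through distinct streams.
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(stream)
  as.integer(s %% 2147483647)
}
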