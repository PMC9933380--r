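## Low-level triangle-mesh and plane-section geometry.
## Coordinates are millimetres throughout; meshes are (vertices, faces) lists
## with counter-clockwise (outward) face winding.

#' Subdivided icosphere mesh on the unit sphere
#'
#' Builds a geodesic sphere by recursive 4-way subdivision of an icosahedron,
#' with every vertex projected back onto the unit sphere. Subdivision level 4
#' gives 2562 vertices / 5120 triangles, the package default for phantoms.
#'
#' @param subdiv Integer subdivision level (>= 0).
#' @return List with `vertices` (n x 3 matrix) and `faces` (m x 3 integer
#'   matrix, 1-based, outward winding).
#' @export
icosphere <- function(subdiv = 4L) {
  stopifnot(length(subdiv) == 1L, subdiv >= 0L)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdiv)) {
    n_v <- nrow(v)
    ea <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(ea[, 1], ea[, 2]), pmax(ea[, 1], ea[, 2]))
    uk <- unique(key)
    idx <- match(key, uk)
    ue <- ea[!duplicated(key), , drop = FALSE]
    mid <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    v <- rbind(v, mid)
    m12 <- n_v + idx[seq_len(nrow(f))]
    m23 <- n_v + idx[nrow(f) + seq_len(nrow(f))]
    m31 <- n_v + idx[2 * nrow(f) + seq_len(nrow(f))]
    f <- rbind(
      cbind(f[, 1], m12, m31),
      cbind(f[, 2], m23, m12),
      cbind(f[, 3], m31, m23),
      cbind(m12, m23, m31))
  }
  dimnames(v) <- NULL
  list(vertices = v, faces = f)
}

#' Enclosed volume of a closed triangle mesh
#'
#' Divergence-theorem (signed tetrahedron) volume; positive for outward
#' winding.
#'
#' @param vertices n x 3 vertex matrix (mm).
#' @param faces m x 3 integer face matrix.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(vertices, faces) {
  p1 <- vertices[faces[, 1], , drop = FALSE]
  p2 <- vertices[faces[, 2], , drop = FALSE]
  p3 <- vertices[faces[, 3], , drop = FALSE]
  # scalar triple product p1 . (p2 x p3) per face
  cx <- p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]
  cy <- p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]
  cz <- p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1]
  sum(p1[, 1] * cx + p1[, 2] * cy + p1[, 3] * cz) / 6
}

## Intersection of a triangle mesh with a plane.
## Returns the intersection segments in plane (u,v) coordinates, oriented so
## that traversing each segment start -> end runs counter-clockwise around the
## section (plane normal out of the page), plus the mesh-edge ids each
## endpoint lies on (used for chaining into an ordered polygon).
## NULL when the plane misses the mesh.
mesh_plane_segments <- function(vertices, faces, origin, normal, u, v) {
  h <- (vertices[, 1] - origin[1]) * normal[1] +
       (vertices[, 2] - origin[2]) * normal[2] +
       (vertices[, 3] - origin[3]) * normal[3]
  # nudge vertices lying exactly in the plane to keep crossings transversal
  eps <- 1e-9
  h[abs(h) < eps] <- eps
  s1 <- h[faces[, 1]] > 0
  s2 <- h[faces[, 2]] > 0
  s3 <- h[faces[, 3]] > 0
  cross_f <- which((s1 != s2) | (s2 != s3))
  if (length(cross_f) == 0L) return(NULL)
  fc <- faces[cross_f, , drop = FALSE]
  # per crossing face, the lone vertex on its own side is `apex`
  a1 <- s1[cross_f]; a2 <- s2[cross_f]; a3 <- s3[cross_f]
  lone <- integer(length(cross_f))
  lone[a1 != a2 & a1 != a3] <- 1L
  lone[a2 != a1 & a2 != a3] <- 2L
  lone[a3 != a1 & a3 != a2] <- 3L
  i_ap <- fc[cbind(seq_along(lone), lone)]
  nxt <- c(2L, 3L, 1L)
  i_b <- fc[cbind(seq_along(lone), nxt[lone])]
  i_c <- fc[cbind(seq_along(lone), nxt[nxt[lone]])]
  # crossings on edges (apex,b) and (c,apex); with CCW winding the in-plane
  # direction (apex,b)-crossing -> (c,apex)-crossing is consistent when the
  # apex is on the positive side, reversed otherwise
  interp <- function(i, j) {
    t <- h[i] / (h[i] - h[j])
    vertices[i, , drop = FALSE] + t * (vertices[j, , drop = FALSE] - vertices[i, , drop = FALSE])
  }
  p_ab <- interp(i_ap, i_b)
  p_ca <- interp(i_c, i_ap)
  ap_pos <- h[i_ap] > 0
  p <- p_ab; q <- p_ca
  p[!ap_pos, ] <- p_ca[!ap_pos, ]; q[!ap_pos, ] <- p_ab[!ap_pos, ]
  ekey <- function(i, j) pmin(i, j) * (nrow(vertices) + 1) + pmax(i, j)
  e_p <- ekey(i_ap, i_b); e_q <- ekey(i_c, i_ap)
  ep <- e_p; eq <- e_q
  ep[!ap_pos] <- e_q[!ap_pos]; eq[!ap_pos] <- e_p[!ap_pos]
  to_uv <- function(pts) cbind(
    (pts[, 1] - origin[1]) * u[1] + (pts[, 2] - origin[2]) * u[2] + (pts[, 3] - origin[3]) * u[3],
    (pts[, 1] - origin[1]) * v[1] + (pts[, 2] - origin[2]) * v[2] + (pts[, 3] - origin[3]) * v[3])
  list(p = to_uv(p), q = to_uv(q), edge_p = ep, edge_q = eq)
}

## Area/perimeter straight from oriented segments (no chaining needed):
## each segment is one polygon edge, so the shoelace sum over segments is the
## signed area and the summed segment lengths the perimeter.
segments_measures <- function(seg) {
  if (is.null(seg)) return(NULL)
  area <- sum(seg$p[, 1] * seg$q[, 2] - seg$q[, 1] * seg$p[, 2]) / 2
  per <- sum(sqrt(rowSums((seg$q - seg$p)^2)))
  list(area = abs(area), perimeter = per)
}

## Chain oriented intersection segments into one ordered closed polygon
## (matrix of (u,v) vertices). Segments sharing a mesh edge are consecutive.
chain_segments <- function(seg) {
  m <- nrow(seg$p)
  nxt <- match(seg$edge_q, seg$edge_p)  # segment whose start lies on my end
  ord <- integer(m)
  ord[1] <- 1L
  cur <- 1L
  for (k in 2:m) {
    cur <- nxt[cur]
    if (is.na(cur) || cur == 1L) break
    ord[k] <- cur
  }
  ord <- ord[ord != 0L]
  seg$p[ord, , drop = FALSE]
}

## Shoelace signed area of an ordered polygon (n x 2).
polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_perimeter <- function(xy) {
  j <- c(seq_len(nrow(xy))[-1], 1L)
  sum(sqrt((xy[j, 1] - xy[, 1])^2 + (xy[j, 2] - xy[, 2])^2))
}

## Rotation matrix about unit axis `ax` by `deg` degrees (Rodrigues).
rotation_about <- function(ax, deg) {
  th <- deg * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Export a mesh as ASCII PLY
#'
#' @param mesh List with `vertices` and `faces` as from [icosphere()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    paste("element vertex", nrow(mesh$vertices)),
    "property float x", "property float y", "property float z",
    paste("element face", nrow(mesh$faces)),
    "property list uchar int vertex_indices", "end_header"), con)
  writeLines(paste(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}
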