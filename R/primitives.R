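# Analytic test primitives: icosphere, box, capped cylinder. These carry
# closed-form volumes/normals and anchor the geometry tests.

#' Icosphere (subdivided icosahedron projected to a sphere)
#'
#' @param radius sphere radius.
#' @param center 3D center.
#' @param subdivisions midpoint-subdivision rounds (0 = icosahedron;
#'   4 gives 2562 vertices / 5120 faces).
#' @return a watertight [trimesh()] with outward normals.
#' @export
mesh_icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_key <- new.env(hash = TRUE)
    nv0 <- nrow(v)
    mids <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_key[[key]]
      if (!is.null(id)) return(id)
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      mids[[length(mids) + 1L]] <<- m
      id <- nv0 + length(mids)
      edge_key[[key]] <- id
      id
    }
    newf <- matrix(0L, 4L * nrow(f), 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[(4 * i - 3):(4 * i), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, mids))
    f <- newf
  }
  vv <- sweep(v * radius, 2L, center, `+`)
  mesh <- trimesh(vv, f, clean = FALSE)
  if (signed_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  compute_vertex_normals(mesh, "outward")
}

#' Axis-aligned box mesh
#'
#' @param lo,hi opposite corners.
#' @return a watertight [trimesh()] (8 vertices, 12 faces), outward
#'   winding.
#' @export
mesh_box <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  g <- expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                   z = c(lo[3], hi[3]))
  v <- as.matrix(g)
  # corners: index = 1 + x + 2 y + 4 z (bit order from expand.grid)
  quads <- rbind(
    c(1, 2, 4, 3),  # z = lo
    c(5, 7, 8, 6),  # z = hi
    c(1, 5, 6, 2),  # y = lo
    c(3, 4, 8, 7),  # y = hi
    c(1, 3, 7, 5),  # x = lo
    c(2, 6, 8, 4))  # x = hi
  f <- rbind(quads[, c(1, 2, 3)], quads[, c(1, 3, 4)])
  mesh <- trimesh(v, f, clean = FALSE)
  if (signed_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  compute_vertex_normals(mesh, "outward")
}

#' Capped cylinder mesh
#'
#' A closed cylinder of given radius and length along an axis, with flat
#' cap fans.
#'
#' @param radius cylinder radius.
#' @param length cylinder length.
#' @param center 3D center of the axis midpoint.
#' @param axis axis direction (normalized internally).
#' @param n_segments vertices around the circumference.
#' @param n_rings vertex rings along the axis.
#' @return a watertight [trimesh()] with outward normals.
#' @export
mesh_cylinder <- function(radius = 1, length = 20, center = c(0, 0, 0),
                          axis = c(0, 0, 1), n_segments = 32L, n_rings = 41L) {
  axis <- axis / sqrt(sum(axis^2))
  fr <- tangent_frame(matrix(axis, 1L, 3L))
  t1 <- fr$t1[1, ]; t2 <- fr$t2[1, ]
  theta <- seq(0, 2 * pi, length.out = n_segments + 1L)[-(n_segments + 1L)]
  zs <- seq(-length / 2, length / 2, length.out = n_rings)
  ring <- outer(cos(theta), t1) + outer(sin(theta), t2)
  v <- do.call(rbind, lapply(zs, function(z) {
    sweep(ring * radius, 2L, center + axis * z, `+`)
  }))
  idx <- function(r, s) (r - 1L) * n_segments + ((s - 1L) %% n_segments) + 1L
  f <- list()
  for (r in seq_len(n_rings - 1L))
    for (s in seq_len(n_segments)) {
      a <- idx(r, s); b <- idx(r, s + 1L)
      c2 <- idx(r + 1L, s + 1L); d <- idx(r + 1L, s)
      f[[length(f) + 1L]] <- rbind(c(a, b, c2), c(a, c2, d))
    }
  bottom <- nrow(v) + 1L
  top <- nrow(v) + 2L
  v <- rbind(v, center - axis * (length / 2), center + axis * (length / 2))
  for (s in seq_len(n_segments)) {
    f[[length(f) + 1L]] <- rbind(c(bottom, idx(1L, s + 1L), idx(1L, s)),
                                 c(top, idx(n_rings, s), idx(n_rings, s + 1L)))
  }
  mesh <- trimesh(v, do.call(rbind, f), clean = FALSE)
  if (signed_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  compute_vertex_normals(mesh, "outward")
}
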