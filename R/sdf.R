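# Shape diameter function: per-vertex local thickness estimated from the
# lengths of rays cast inside a cone around the inward normal to the
# opposite side of the mesh. Dendrites are thin, the soma is thick, so the
# SDF distribution separates them.

# directions in a cone of half-angle `cone_angle` around each row of
# `axes`. The polar angle is jitter-stratified over [0, cone_angle]
# (denser near the axis than solid-angle sampling - the axial chord is
# the quantity being estimated - and low-variance across seeds); the
# azimuth is uniform. Returns list(dir, angle).
cone_directions_block <- function(axes, cone_angle, n_rays) {
  nv <- nrow(axes)
  strata <- matrix(rep(seq_len(n_rays) - 1L, each = nv), nv, n_rays)
  theta <- cone_angle * (strata + matrix(runif(nv * n_rays), nv, n_rays)) / n_rays
  z <- cos(theta)
  phi <- matrix(2 * pi * runif(nv * n_rays), nv, n_rays)
  r <- sin(theta)
  fr <- tangent_frame(axes)
  cx <- r * cos(phi)
  cy <- r * sin(phi)
  dir <- matrix(0, nv * n_rays, 3L)
  for (k in 1:3) {
    d <- cx * fr$t1[, k] + cy * fr$t2[, k] + z * fr$n[, k]
    dir[, k] <- as.vector(t(d))
  }
  list(dir = dir, angle = as.vector(t(acos(pmin(1, pmax(-1, z))))))
}

# robust aggregation of ray lengths: drop rays deviating from the median
# by more than one standard deviation, then average with weights inverse
# to the ray's angle from the cone axis. The weight is floored at
# angle_floor (a fixed fraction of the cone angle) so no single near-axis
# ray dominates the estimate.
aggregate_ray_lengths <- function(len, angle, angle_floor = 1e-3) {
  ok <- is.finite(len)
  len <- len[ok]; angle <- angle[ok]
  if (length(len) == 0L) return(NA_real_)
  if (length(len) > 2L) {
    med <- median(len)
    s <- sd(len)
    keep <- abs(len - med) <= s
    if (any(keep)) { len <- len[keep]; angle <- angle[keep] }
  }
  w <- 1 / pmax(angle, angle_floor)
  sum(w * len) / sum(w)
}

#' Shape diameter at one vertex
#'
#' Casts `n_rays` rays inside a cone of half-angle `cone_angle` around the
#' vertex's inward normal (polar angle uniform in `[0, cone_angle]`, so
#' sampling is denser near the axis whose chord is the quantity being
#' estimated); each ray's length is the distance to its first
#' hit on the opposite side of the mesh. Rays deviating from the median
#' length by more than one standard deviation are discarded and the
#' surviving lengths are averaged with weights inverse to the ray's angle
#' from the cone axis.
#'
#' @param mesh a watertight [trimesh()].
#' @param vertex_index 1-based vertex index.
#' @param cone_angle cone half-angle in radians (default `pi/3`, 60
#'   degrees). Near 0 the estimate approaches the chord length along the
#'   inward normal (the local diameter).
#' @param n_rays rays per vertex (default 30).
#' @param ignore_within self-hit epsilon.
#' @return local diameter estimate (length units).
#' @export
sdf_vertex <- function(mesh, vertex_index, cone_angle = pi / 3, n_rays = 30L,
                       ignore_within = NULL) {
  nrm <- vertex_normal_oriented(mesh, "inward")[vertex_index, , drop = FALSE]
  if (is.null(ignore_within)) ignore_within <- default_ignore_within(mesh)
  cd <- cone_directions_block(nrm, cone_angle, n_rays)
  origins <- matrix(mesh$vertices[vertex_index, ], n_rays, 3L, byrow = TRUE)
  res <- cast_rays(mesh, origins, cd$dir, ignore_within = ignore_within)
  if (!any(res$hit))
    stop("no ray hit the opposite surface from vertex ", vertex_index,
         " (is the mesh open?)")
  aggregate_ray_lengths(res$distance, cd$angle, angle_floor = cone_angle / 10)
}

#' Per-vertex shape diameter field
#'
#' [sdf_vertex()] applied to every vertex with one shared seeded
#' generator; deterministic given (mesh, parameters, seed).
#'
#' @param mesh a watertight [trimesh()].
#' @param cone_angle cone half-angle in radians.
#' @param n_rays rays per vertex.
#' @param seed RNG seed.
#' @param ignore_within self-hit epsilon.
#' @param block_size vertices per batch (memory knob only).
#' @return object of class `sdf_field`: list with `values` (one local
#'   diameter per vertex), `cone_angle`, `n_rays`, `seed`.
#' @export
sdf_field <- function(mesh, cone_angle = pi / 3, n_rays = 30L, seed = 1L,
                      ignore_within = NULL, block_size = 4000L) {
  normals <- vertex_normal_oriented(mesh, "inward")
  if (is.null(ignore_within)) ignore_within <- default_ignore_within(mesh)
  nv <- n_vertices(mesh)
  bvh <- mesh_bvh(mesh)
  values <- numeric(nv)
  set.seed(seed)
  for (start in seq(1L, nv, by = block_size)) {
    idx <- start:min(start + block_size - 1L, nv)
    cd <- cone_directions_block(normals[idx, , drop = FALSE], cone_angle, n_rays)
    origins <- mesh$vertices[rep(idx, each = n_rays), , drop = FALSE]
    res <- cpp_raycast(bvh, origins, cd$dir, ignore_within)
    for (b in seq_along(idx)) {
      rows <- ((b - 1L) * n_rays + 1L):(b * n_rays)
      hit <- res$hit[rows]
      if (!any(hit))
        stop("no ray hit the opposite surface from vertex ", idx[b],
             " (is the mesh open?)")
      values[idx[b]] <- aggregate_ray_lengths(res$distance[rows][hit],
                                              cd$angle[rows][hit],
                                              angle_floor = cone_angle / 10)
    }
  }
  structure(list(values = values, cone_angle = cone_angle, n_rays = n_rays,
                 seed = seed),
            class = "sdf_field")
}

#' @export
print.sdf_field <- function(x, ...) {
  cat("shape diameter field: ", length(x$values), " vertices, ",
      x$n_rays, " rays/vertex, cone half-angle ",
      round(x$cone_angle * 180 / pi, 1), " deg (seed ", x$seed, ")\n", sep = "")
  print(summary(x$values))
  invisible(x)
}
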