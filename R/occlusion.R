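# Per-vertex ambient occlusion by hemisphere ray sampling: for vertex i,
# A_i = N_i / N, the fraction of N uniformly sampled hemisphere rays from
# the vertex that hit the mesh. Exposed surface gives A close to 0,
# vertices inside an enclosure give A close to 1.

# orthonormal frame (t1, t2, n) for each unit normal (rows)
tangent_frame <- function(normals) {
  n <- matrix(normals, ncol = 3L)
  # pick the axis least aligned with n to build a stable tangent
  ref <- matrix(0, nrow(n), 3L)
  use_x <- abs(n[, 1]) < 0.9
  ref[use_x, 1] <- 1
  ref[!use_x, 2] <- 1
  t1 <- cbind(n[, 2] * ref[, 3] - n[, 3] * ref[, 2],
              n[, 3] * ref[, 1] - n[, 1] * ref[, 3],
              n[, 1] * ref[, 2] - n[, 2] * ref[, 1])
  t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cbind(n[, 2] * t1[, 3] - n[, 3] * t1[, 2],
              n[, 3] * t1[, 1] - n[, 1] * t1[, 3],
              n[, 1] * t1[, 2] - n[, 2] * t1[, 1])
  list(t1 = t1, t2 = t2, n = n)
}

#' Uniform directions on a hemisphere
#'
#' Draws `n` directions uniformly distributed over the solid angle of the
#' hemisphere centred on `normal` (so the expected component along the
#' normal is 1/2). With `cosine_weighted = TRUE` the directions follow a
#' cosine density instead (an alternative sampling law, off by default).
#' Uses R's global random number generator; seed with [set.seed()] for
#' reproducibility.
#'
#' @param normal unit 3-vector the hemisphere is oriented along.
#' @param n number of directions (>= 1).
#' @param cosine_weighted sample proportional to the cosine of the polar
#'   angle rather than uniformly over solid angle.
#' @return an `n x 3` matrix of unit directions `d` with `d . normal >= 0`.
#' @export
sample_hemisphere <- function(normal, n, cosine_weighted = FALSE) {
  if (n < 1) stop("n must be >= 1")
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-6) stop("normal must be unit length")
  u1 <- runif(n)
  phi <- 2 * pi * runif(n)
  z <- if (cosine_weighted) sqrt(u1) else u1
  r <- sqrt(pmax(0, 1 - z^2))
  fr <- tangent_frame(matrix(normal, 1L, 3L))
  outer(r * cos(phi), fr$t1[1, ]) + outer(r * sin(phi), fr$t2[1, ]) +
    outer(z, fr$n[1, ])
}

# directions for many vertices at once: canonical samples rotated into each
# vertex frame; z ~ U(0,1) per (vertex, ray)
hemisphere_directions_block <- function(normals, n_rays, cosine_weighted = FALSE) {
  nv <- nrow(normals)
  u1 <- matrix(runif(nv * n_rays), nv, n_rays)
  phi <- matrix(2 * pi * runif(nv * n_rays), nv, n_rays)
  z <- if (cosine_weighted) sqrt(u1) else u1
  r <- sqrt(pmax(0, 1 - z^2))
  fr <- tangent_frame(normals)
  cx <- r * cos(phi)
  cy <- r * sin(phi)
  # result: (nv * n_rays) x 3, vertex-major (ray varies fastest)
  dir <- matrix(0, nv * n_rays, 3L)
  for (k in 1:3) {
    d <- cx * fr$t1[, k] + cy * fr$t2[, k] + z * fr$n[, k]
    dir[, k] <- as.vector(t(d))
  }
  dir
}

#' Ambient occlusion factor of one vertex
#'
#' Traces `n_rays` rays from the vertex into the hemisphere oriented along
#' the vertex normal and returns the fraction that hit the mesh (hits
#' within the self-hit epsilon are disregarded). The result is always an
#' integer multiple of `1/n_rays`.
#'
#' @param mesh a [trimesh()] with per-vertex normals (see
#'   [compute_vertex_normals()]).
#' @param vertex_index 1-based vertex index.
#' @param n_rays number of hemisphere rays.
#' @param orientation hemisphere orientation: `"outward"` (default,
#'   exposure-to-ambient-light semantics) or `"inward"`.
#' @param directions optional explicit `n x 3` matrix of unit sample
#'   directions, overriding the random hemisphere (for worked examples and
#'   diagnostics); `n_rays` is then taken from its row count.
#' @param ignore_within self-hit epsilon; default `1e-4` of the
#'   bounding-box diagonal.
#' @return scalar occlusion factor in `[0, 1]`.
#' @export
occlusion_factor <- function(mesh, vertex_index, n_rays = 128,
                             orientation = c("outward", "inward"),
                             directions = NULL, ignore_within = NULL) {
  orientation <- match.arg(orientation)
  if (vertex_index < 1 || vertex_index > n_vertices(mesh))
    stop("vertex_index out of range")
  nrm <- vertex_normal_oriented(mesh, orientation)[vertex_index, ]
  if (any(!is.finite(nrm)))
    stop("vertex ", vertex_index, " has no defined normal")
  if (is.null(directions)) {
    directions <- sample_hemisphere(nrm, n_rays)
  } else {
    directions <- matrix(as.double(directions), ncol = 3L)
    n_rays <- nrow(directions)
  }
  if (is.null(ignore_within)) ignore_within <- default_ignore_within(mesh)
  origins <- matrix(mesh$vertices[vertex_index, ], n_rays, 3L, byrow = TRUE)
  res <- cast_rays(mesh, origins, directions, ignore_within = ignore_within)
  sum(res$hit) / n_rays
}

vertex_normal_oriented <- function(mesh, orientation) {
  if (is.null(mesh$normals)) mesh <- compute_vertex_normals(mesh, orientation)
  if (mesh$orientation == orientation) mesh$normals else -mesh$normals
}

#' Per-vertex ambient occlusion field
#'
#' Applies [occlusion_factor()] to every vertex with a single seeded
#' generator; the result is reproducible given (mesh, n_rays, seed).
#'
#' @param mesh a [trimesh()].
#' @param n_rays rays per vertex (default 128).
#' @param seed RNG seed.
#' @param orientation hemisphere orientation, see [occlusion_factor()].
#' @param ignore_within self-hit epsilon.
#' @param block_size vertices per ray-casting batch (memory knob; does not
#'   affect results).
#' @return an object of class `occlusion_field`: list with `values` (one
#'   occlusion factor per vertex), `n_rays` and `seed`.
#' @export
occlusion_field <- function(mesh, n_rays = 128, seed = 1L,
                            orientation = c("outward", "inward"),
                            ignore_within = NULL, block_size = 2000L) {
  orientation <- match.arg(orientation)
  if (n_rays < 1) stop("n_rays must be >= 1")
  normals <- vertex_normal_oriented(mesh, orientation)
  if (is.null(ignore_within)) ignore_within <- default_ignore_within(mesh)
  nv <- n_vertices(mesh)
  bvh <- mesh_bvh(mesh)
  values <- numeric(nv)
  set.seed(seed)
  for (start in seq(1L, nv, by = block_size)) {
    idx <- start:min(start + block_size - 1L, nv)
    dirs <- hemisphere_directions_block(normals[idx, , drop = FALSE], n_rays)
    origins <- mesh$vertices[rep(idx, each = n_rays), , drop = FALSE]
    res <- cpp_raycast(bvh, origins, dirs, ignore_within)
    hits <- matrix(res$hit, length(idx), n_rays, byrow = TRUE)
    values[idx] <- rowSums(hits) / n_rays
  }
  structure(list(values = values, n_rays = n_rays, seed = seed,
                 orientation = orientation),
            class = "occlusion_field")
}

#' @export
print.occlusion_field <- function(x, ...) {
  cat("ambient occlusion field: ", length(x$values), " vertices, ",
      x$n_rays, " rays/vertex (seed ", x$seed, ")\n", sep = "")
  print(summary(x$values))
  invisible(x)
}
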