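# Ray casting and closest-point queries against a triangle mesh, through a
# bounding-volume hierarchy built in C++. The brute-force path iterates
# every triangle and is kept as the reference the BVH must agree with.

mesh_bvh <- function(mesh) {
  if (n_faces(mesh) == 0L) stop("cannot build BVH: mesh has no faces")
  cpp_bvh_build(mesh$vertices, mesh$faces - 1L)
}

default_ignore_within <- function(mesh) 1e-4 * bbox_diagonal(mesh)

#' Cast a single ray against a mesh
#'
#' Returns the nearest intersection along the ray beyond `ignore_within`
#' (hits closer than this are skipped, so a ray leaving a surface does not
#' immediately hit its own triangle). Rays are infinite.
#'
#' @param mesh a [trimesh()].
#' @param origin 3D ray origin.
#' @param direction unit 3-vector.
#' @param ignore_within skip hits closer than this along the ray; default
#'   `1e-4` of the bounding-box diagonal.
#' @param method `"bvh"` (accelerated, default) or `"brute"` (exhaustive
#'   triangle iteration; the reference implementation).
#' @return a list with `hit` (logical), `distance`, `face` (1-based index)
#'   and `point` (the intersection, or `NULL` when missed).
#' @export
cast_ray <- function(mesh, origin, direction, ignore_within = NULL,
                     method = c("bvh", "brute")) {
  method <- match.arg(method)
  len <- sqrt(sum(direction^2))
  if (len < 1e-12) stop("ray direction has zero length")
  if (abs(len - 1) > 1e-6) stop("ray direction must be a unit vector")
  if (is.null(ignore_within)) ignore_within <- default_ignore_within(mesh)
  if (ignore_within < 0) stop("ignore_within must be >= 0")
  res <- cast_rays(mesh, matrix(origin, 1L, 3L), matrix(direction, 1L, 3L),
                   ignore_within = ignore_within, method = method)
  hit <- res$hit[1]
  list(hit = hit,
       distance = if (hit) res$distance[1] else NA_real_,
       face = if (hit) res$face[1] else NA_integer_,
       point = if (hit) origin + direction * res$distance[1] else NULL)
}

#' Cast a batch of rays against a mesh
#'
#' @param mesh a [trimesh()].
#' @param origins,directions matrices with one ray per row; directions must
#'   be unit vectors.
#' @inheritParams cast_ray
#' @return list of vectors `hit`, `distance`, `face` (NA where missed).
#' @export
cast_rays <- function(mesh, origins, directions, ignore_within = NULL,
                      method = c("bvh", "brute")) {
  method <- match.arg(method)
  if (is.null(ignore_within)) ignore_within <- default_ignore_within(mesh)
  origins <- matrix(as.double(origins), ncol = 3L)
  directions <- matrix(as.double(directions), ncol = 3L)
  if (method == "brute") {
    cpp_raycast_brute(mesh$vertices, mesh$faces - 1L, origins, directions,
                      ignore_within)
  } else {
    bvh <- mesh_bvh(mesh)
    cpp_raycast(bvh, origins, directions, ignore_within)
  }
}

#' Minimum distance from points to a mesh surface
#'
#' The true point-to-surface distance: faces, edges and vertices of every
#' triangle are all considered, not vertex-to-vertex distances only.
#'
#' @param points a 3-vector or an `n x 3` matrix of query points.
#' @param mesh a [trimesh()] with at least one face.
#' @param method `"bvh"` (accelerated) or `"brute"` (reference).
#' @return numeric vector of distances, one per query point.
#' @export
point_to_surface_distance <- function(points, mesh, method = c("bvh", "brute")) {
  method <- match.arg(method)
  if (n_faces(mesh) == 0L) stop("mesh has no faces; distance undefined")
  points <- matrix(as.double(points), ncol = 3L)
  if (method == "brute")
    cpp_closest_brute(mesh$vertices, mesh$faces - 1L, points)
  else
    cpp_closest(mesh_bvh(mesh), points)$distance
}

# closest surface points (used by the signed distance coloring)
closest_surface_points <- function(points, mesh) {
  points <- matrix(as.double(points), ncol = 3L)
  cpp_closest(mesh_bvh(mesh), points)
}
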