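# Mesh comparison metrics: vertex-to-surface distances eps(p, S2), the
# asymmetric and symmetric RMSE built on them, the volume-quotient MAQ,
# and distance-colored mesh exports for visual inspection of cutoffs.

#' Root-mean-square vertex-to-surface distance
#'
#' `RMSE(S1, S2)` is the square root of the mean, over the vertices `p` of
#' `S1`, of the squared minimum Euclidean distance `eps(p, S2)` from `p` to
#' the full surface of `S2` (faces, edges and vertices all considered).
#' Asymmetric: `rmse(S1, S2)` generally differs from `rmse(S2, S1)`.
#' Distances are in the input length units.
#'
#' @param S1,S2 [trimesh()] objects with at least one face each.
#' @return scalar RMSE (length units).
#' @seealso [rmse_symmetric()]
#' @export
rmse <- function(S1, S2) {
  if (n_faces(S1) == 0L || n_faces(S2) == 0L)
    stop("both meshes must have at least one face")
  eps <- point_to_surface_distance(S1$vertices, S2)
  sqrt(mean(eps^2))
}

#' Symmetric RMSE between two meshes
#'
#' `max(rmse(S1, S2), rmse(S2, S1))`; zero exactly when the surfaces
#' coincide.
#'
#' @inheritParams rmse
#' @return scalar symmetric RMSE; attributes `rmse_12` and `rmse_21` carry
#'   the two asymmetric values.
#' @export
rmse_symmetric <- function(S1, S2) {
  r12 <- rmse(S1, S2)
  r21 <- rmse(S2, S1)
  structure(max(r12, r21), rmse_12 = r12, rmse_21 = r21)
}

#' Mean absolute quotient of paired volumes (MAQ)
#'
#' For two lists of volumes of the same `M` meshes processed by two
#' techniques, `MAQ_{1,2} = mean(|T1_i / T2_i - 1|)` estimates the
#' proportional volume difference of using one technique in place of the
#' other; `MAQ_S = max(MAQ_{1,2}, MAQ_{2,1})` is its symmetric form.
#' Values are fractions (0.0433 corresponds to 4.33%).
#'
#' @param volumes_1,volumes_2 equal-length vectors of positive volumes.
#' @return object of class `volume_comparison` with `maq_12`, `maq_21`,
#'   `maq_sym`, the input volumes and `M`.
#' @export
maq <- function(volumes_1, volumes_2) {
  volumes_1 <- as.double(volumes_1)
  volumes_2 <- as.double(volumes_2)
  if (length(volumes_1) != length(volumes_2))
    stop("volume lists must have equal length")
  if (length(volumes_1) < 1L) stop("need at least one volume pair")
  if (any(volumes_1 <= 0) || any(volumes_2 <= 0))
    stop("volumes must be strictly positive")
  maq_12 <- mean(abs(volumes_1 / volumes_2 - 1))
  maq_21 <- mean(abs(volumes_2 / volumes_1 - 1))
  structure(list(volumes_1 = volumes_1, volumes_2 = volumes_2,
                 M = length(volumes_1),
                 maq_12 = maq_12, maq_21 = maq_21,
                 maq_sym = max(maq_12, maq_21)),
            class = "volume_comparison")
}

#' @export
print.volume_comparison <- function(x, ...) {
  cat(sprintf("volume comparison over M = %d meshes\n", x$M))
  cat(sprintf("  MAQ(1,2) = %.4f (%.2f%%)\n", x$maq_12, 100 * x$maq_12))
  cat(sprintf("  MAQ(2,1) = %.4f (%.2f%%)\n", x$maq_21, 100 * x$maq_21))
  cat(sprintf("  MAQ_S    = %.4f (%.2f%%)\n", x$maq_sym, 100 * x$maq_sym))
  invisible(x)
}

#' Color a mesh by its distance to a second mesh
#'
#' Attaches to each vertex of `S1` its distance to the surface of `S2`.
#' With `signing = "normal_signed"` the sign is that of the offset vector
#' (from the closest point on `S2` to the vertex) projected on `S1`'s
#' outward vertex normal: positive (outside `S2`) shades red, negative
#' shades blue, near-zero shades green. The color ramp is linear between
#' the 5th and 95th percentile of the absolute values.
#'
#' @inheritParams rmse
#' @param signing `"unsigned"` or `"normal_signed"`.
#' @return `S1` with per-vertex `scalars` (the signed or unsigned
#'   distances) and `colors` (0-255 RGB matrix) attributes, ready for
#'   [write_mesh()] PLY export.
#' @export
distance_colored_mesh <- function(S1, S2,
                                  signing = c("unsigned", "normal_signed")) {
  signing <- match.arg(signing)
  cl <- closest_surface_points(S1$vertices, S2)
  values <- cl$distance
  if (signing == "normal_signed") {
    nrm <- vertex_normal_oriented(S1, "outward")
    offset <- S1$vertices - cl$point
    values <- values * sign(rowSums(offset * nrm))
  }
  hi <- quantile(abs(values), 0.95, names = FALSE)
  lo <- quantile(abs(values), 0.05, names = FALSE)
  span <- max(hi - lo, 1e-300)
  t <- pmin(1, pmax(0, (abs(values) - lo) / span)) * sign(values + (values == 0))
  # -1 -> blue, 0 -> green, +1 -> red
  red <- as.integer(round(255 * pmax(0, t)))
  blue <- as.integer(round(255 * pmax(0, -t)))
  green <- as.integer(round(255 * (1 - abs(t))))
  out <- S1
  attr(out, "vertex_scalars") <- values
  attr(out, "vertex_colors") <- cbind(red, green, blue)
  out
}
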