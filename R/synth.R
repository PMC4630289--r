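# Synthetic neuron fixtures: an implicit-surface union of a spherical soma
# and capsule (hemispherically capped cylinder) dendrites, meshed by
# marching tetrahedra, with per-vertex ground-truth labels and injectable
# damage (hole, cavity, interior artifact vertices) emulating what
# intracellular injection does to reconstructed surfaces.

#' Specification of a synthetic neuron fixture
#'
#' The default geometry mimics a pyramidal cell at desk scale: a spherical
#' soma of radius 10 (length units; microns for real data), four thin
#' basal dendrites (radius 1, length 25) pointing into the lower
#' half-space and one thicker apical dendrite (radius 2, length 30)
#' pointing up. The soma radius must exceed every dendrite radius and the
#' apical radius must be at least the largest basal radius (the premise
#' the thickness-based segmentation exploits).
#'
#' @param soma_radius sphere radius.
#' @param basal list of `list(radius, length, direction)` dendrites.
#' @param apical a `list(radius, length, direction)` dendrite, or `NULL`.
#' @param spacing marching-tetrahedra grid spacing (approximately the
#'   output edge length).
#' @param seed stored fixture seed (meshing itself is deterministic).
#' @return object of class `neuron_spec`.
#' @export
neuron_spec <- function(soma_radius = 10,
                        basal = default_basal(),
                        apical = list(radius = 2, length = 30,
                                      direction = c(0, 0, 1)),
                        spacing = 0.8, seed = 1L) {
  norm_dend <- function(d) {
    d$direction <- d$direction / sqrt(sum(d$direction^2))
    d
  }
  basal <- lapply(basal, norm_dend)
  if (!is.null(apical)) apical <- norm_dend(apical)
  all_d <- c(basal, if (!is.null(apical)) list(apical))
  radii <- vapply(all_d, `[[`, 0, "radius")
  if (length(radii) && any(radii >= soma_radius))
    stop("soma_radius must exceed every dendrite radius")
  if (!is.null(apical) && length(basal) &&
      apical$radius < max(vapply(basal, `[[`, 0, "radius")))
    stop("apical radius must be >= the largest basal radius")
  # dendrites must attach to the soma without mutual intersection
  if (length(all_d) > 1L) {
    dirs <- t(vapply(all_d, `[[`, numeric(3), "direction"))
    ang_rad <- asin(pmin(1, radii / soma_radius))
    for (i in seq_len(length(all_d) - 1L))
      for (j in (i + 1L):length(all_d)) {
        sep <- acos(pmin(1, pmax(-1, sum(dirs[i, ] * dirs[j, ]))))
        if (sep < ang_rad[i] + ang_rad[j] + 0.05)
          stop("dendrites ", i, " and ", j, " overlap at their soma attachment")
      }
  }
  structure(list(soma_radius = soma_radius, basal = basal, apical = apical,
                 spacing = spacing, seed = as.integer(seed)),
            class = "neuron_spec")
}

default_basal <- function() {
  dirs <- rbind(c(1, 1, -1), c(-1, 1, -1), c(1, -1, -1), c(-1, -1, -1))
  apply(dirs, 1L, function(d) list(radius = 1, length = 25, direction = d),
        simplify = FALSE)
}

# distance to a capsule (segment a..b with radius r); negative inside
capsule_distance <- function(px, py, pz, a, b, r) {
  bax <- b[1] - a[1]; bay <- b[2] - a[2]; baz <- b[3] - a[3]
  bb <- bax^2 + bay^2 + baz^2
  pax <- px - a[1]; pay <- py - a[2]; paz <- pz - a[3]
  h <- pmin(1, pmax(0, (pax * bax + pay * bay + paz * baz) / bb))
  sqrt((pax - bax * h)^2 + (pay - bay * h)^2 + (paz - baz * h)^2) - r
}

# signed distances from grid/query points to every primitive; columns:
# soma, apical (if any), basals
neuron_primitive_distances <- function(spec, px, py, pz) {
  cols <- list(sqrt(px^2 + py^2 + pz^2) - spec$soma_radius)
  prims <- c(if (!is.null(spec$apical)) list(spec$apical), spec$basal)
  for (d in prims) {
    a <- c(0, 0, 0)
    b <- d$direction * (spec$soma_radius + d$length)
    cols[[length(cols) + 1L]] <- capsule_distance(px, py, pz, a, b, d$radius)
  }
  do.call(cbind, cols)
}

neuron_primitive_labels <- function(spec) {
  c("soma", if (!is.null(spec$apical)) "apical_dendrite",
    rep("basal_dendrite", length(spec$basal)))
}

#' Generate a synthetic neuron mesh with ground truth
#'
#' Meshes the implicit union of the soma sphere and dendrite capsules by
#' marching tetrahedra at the spec's grid spacing. Every vertex gets a
#' ground-truth label from the primitive whose surface it lies on (ties go
#' to the soma).
#'
#' @param spec a [neuron_spec()].
#' @return list of class `neuron_fixture` with `mesh` (watertight
#'   [trimesh()] with outward normals), `truth` (list: `labels` factor per
#'   vertex, `damage` record, `spec`).
#' @export
make_neuron <- function(spec = neuron_spec()) {
  stopifnot(inherits(spec, "neuron_spec"))
  h <- spec$spacing
  # grid bounds: union of primitive bounding boxes + margin
  lo <- rep(-spec$soma_radius, 3); hi <- rep(spec$soma_radius, 3)
  prims <- c(if (!is.null(spec$apical)) list(spec$apical), spec$basal)
  for (d in prims) {
    tip <- d$direction * (spec$soma_radius + d$length)
    lo <- pmin(lo, tip - d$radius); hi <- pmax(hi, tip + d$radius)
  }
  lo <- lo - 3 * h; hi <- hi + 3 * h
  dims <- as.integer(ceiling((hi - lo) / h)) + 1L
  xs <- lo[1] + h * (seq_len(dims[1]) - 1L)
  ys <- lo[2] + h * (seq_len(dims[2]) - 1L)
  zs <- lo[3] + h * (seq_len(dims[3]) - 1L)
  # evaluate the union field in z-slabs to bound memory
  field <- numeric(prod(dims))
  nxy <- dims[1] * dims[2]
  gx <- rep(xs, times = dims[2])
  gy <- rep(ys, each = dims[1])
  for (k in seq_len(dims[3])) {
    d <- neuron_primitive_distances(spec, gx, gy, rep(zs[k], nxy))
    field[((k - 1L) * nxy + 1L):(k * nxy)] <- do.call(pmin, asplit(d, 2L))
  }
  mc <- cpp_marching_tetrahedra(field, dims, lo, h, 0)
  mesh <- trimesh(mc$vertices, mc$faces, clean = FALSE)
  mesh <- largest_component(mesh)
  wt <- is_watertight(mesh)
  if (!wt) stop("fixture meshing failed: surface not watertight (",
                attr(wt, "boundary_edges"), " boundary edges)")
  mesh <- compute_vertex_normals(mesh, "outward")
  dv <- abs(neuron_primitive_distances(spec, mesh$vertices[, 1],
                                       mesh$vertices[, 2], mesh$vertices[, 3]))
  prim_lab <- neuron_primitive_labels(spec)
  # soma is column 1: which.min takes the first minimum, so ties go to soma
  labels <- factor(prim_lab[apply(dv, 1L, which.min)],
                   levels = c("soma", "basal_dendrite", "apical_dendrite",
                              "artifact"))
  structure(list(mesh = mesh,
                 truth = list(labels = labels,
                              damage = list(hole_faces = integer(0),
                                            cavity_vertices = integer(0),
                                            interior_vertices = integer(0)),
                              spec = spec)),
            class = "neuron_fixture")
}

#' @export
print.neuron_fixture <- function(x, ...) {
  cat("synthetic neuron fixture\n")
  print(x$mesh)
  print(table(x$truth$labels))
  invisible(x)
}

#' Inject injection-style damage into a fixture mesh
#'
#' Emulates the damage intracellular injection leaves on reconstructed
#' surfaces: a hole (faces deleted inside a spherical cap of the soma), a
#' cavity (a patch of soma vertices displaced inward), and interior
#' artifact vertices (small floating triangles strictly inside the soma).
#' Everything is recorded in the ground-truth damage record.
#'
#' @param fixture a [make_neuron()] result.
#' @param hole_cap_degrees angular radius of the deleted cap (0 = no
#'   hole; must be < 90).
#' @param cavity_depth inward displacement of the cavity patch center
#'   (0 = no cavity).
#' @param cavity_cap_degrees angular radius of the cavity patch.
#' @param n_interior_points number of interior artifact points (each
#'   becomes one small floating triangle).
#' @param seed RNG seed for damage placement.
#' @return the modified `neuron_fixture` (damaged mesh + updated truth).
#' @export
inject_defects <- function(fixture, hole_cap_degrees = 0, cavity_depth = 0,
                           cavity_cap_degrees = 25, n_interior_points = 0L,
                           seed = 1L) {
  stopifnot(inherits(fixture, "neuron_fixture"))
  if (hole_cap_degrees >= 90) stop("hole cap must be smaller than a hemisphere")
  mesh <- fixture$mesh
  truth <- fixture$truth
  spec <- truth$spec
  set.seed(seed)
  if (hole_cap_degrees == 0 && cavity_depth == 0 && n_interior_points == 0L)
    return(fixture)

  soma_dirs <- free_soma_directions(spec, 2L)
  radii <- sqrt(rowSums(mesh$vertices^2))
  vdir <- mesh$vertices / radii

  if (hole_cap_degrees > 0) {
    cap_dir <- soma_dirs[1, ]
    ang <- acos(pmin(1, pmax(-1, vdir %*% cap_dir)))
    on_soma <- truth$labels == "soma" & abs(radii - spec$soma_radius) <
      0.2 * spec$soma_radius
    in_cap <- on_soma & (ang < hole_cap_degrees * pi / 180)
    face_in <- in_cap[mesh$faces[, 1]] & in_cap[mesh$faces[, 2]] &
      in_cap[mesh$faces[, 3]]
    truth$damage$hole_faces <- which(face_in)
    mesh$faces <- mesh$faces[!face_in, , drop = FALSE]
  }
  if (cavity_depth > 0) {
    cav_dir <- soma_dirs[2, ]
    ang <- acos(pmin(1, pmax(-1, vdir %*% cav_dir)))
    cap <- cavity_cap_degrees * pi / 180
    on_soma <- truth$labels == "soma" & abs(radii - spec$soma_radius) <
      0.2 * spec$soma_radius
    in_patch <- which(on_soma & (ang < cap))
    falloff <- cos(pi / 2 * ang[in_patch] / cap)  # 1 at center, 0 at rim
    mesh$vertices[in_patch, ] <- mesh$vertices[in_patch, ] -
      vdir[in_patch, ] * (cavity_depth * falloff)
    truth$damage$cavity_vertices <- in_patch
  }
  if (n_interior_points > 0L) {
    # artifact points uniform in a ball of radius 0.6 R (strictly inside)
    r <- 0.6 * spec$soma_radius * runif(n_interior_points)^(1 / 3)
    u <- matrix(rnorm(3L * n_interior_points), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    centers <- u * r
    tri_size <- spec$spacing / 2
    newv <- matrix(0, 3L * n_interior_points, 3L)
    for (i in seq_len(n_interior_points)) {
      fr <- tangent_frame(matrix(u[i, ], 1L, 3L))
      newv[(3 * i - 2):(3 * i), ] <- rbind(
        centers[i, ],
        centers[i, ] + tri_size * fr$t1[1, ],
        centers[i, ] + tri_size * fr$t2[1, ])
    }
    first <- n_vertices(mesh)
    newf <- matrix(first + seq_len(3L * n_interior_points), ncol = 3L,
                   byrow = TRUE)
    added <- first + seq_len(3L * n_interior_points)
    mesh$vertices <- rbind(mesh$vertices, newv)
    mesh$faces <- rbind(mesh$faces, newf)
    mesh$normals <- NULL
    truth$damage$interior_vertices <- added
    labels <- as.character(truth$labels)
    truth$labels <- factor(c(labels, rep("artifact", length(added))),
                           levels = levels(truth$labels))
  }
  mesh <- trimesh(mesh$vertices, mesh$faces, clean = FALSE)
  mesh <- compute_vertex_normals(mesh, "outward")
  structure(list(mesh = mesh, truth = truth), class = "neuron_fixture")
}

# soma-surface directions at a safe angle from every dendrite attachment
free_soma_directions <- function(spec, n) {
  prims <- c(if (!is.null(spec$apical)) list(spec$apical), spec$basal)
  dirs <- if (length(prims))
    t(vapply(prims, `[[`, numeric(3), "direction")) else matrix(0, 0, 3)
  ang_rad <- if (length(prims))
    asin(pmin(1, vapply(prims, `[[`, 0, "radius") / spec$soma_radius)) else
      numeric(0)
  out <- matrix(0, n, 3L)
  found <- 0L
  for (attempt in 1:500) {
    cand <- rnorm(3)
    cand <- cand / sqrt(sum(cand^2))
    ok <- TRUE
    if (nrow(dirs)) {
      sep <- acos(pmin(1, pmax(-1, dirs %*% cand)))
      ok <- all(sep > ang_rad + 0.8) # ~45 deg clearance past attachment
    }
    if (ok && found > 0L) {
      prev <- acos(pmin(1, pmax(-1, out[seq_len(found), , drop = FALSE] %*% cand)))
      ok <- all(prev > 1.2) # keep damage sites apart
    }
    if (ok) {
      found <- found + 1L
      out[found, ] <- cand
      if (found == n) return(out)
    }
  }
  stop("could not place damage sites away from dendrites")
}
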