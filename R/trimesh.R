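#' Indexed triangle mesh
#'
#' Constructs a `trimesh`, the container every stage of the pipeline
#' consumes: an `n x 3` matrix of vertex positions, an `m x 3` integer
#' matrix of 1-based vertex indices per triangular face, and optionally
#' per-vertex unit normals with an explicit orientation convention.
#'
#' Faces with repeated vertex indices and exact duplicate faces are dropped
#' (with a message) when `clean = TRUE`. Isolated (face-less) vertices are
#' kept; remove them explicitly with [prune_isolated_vertices()].
#'
#' @param vertices numeric matrix, one 3D point per row.
#' @param faces integer matrix, one triangle (three 1-based vertex indices)
#'   per row.
#' @param normals optional numeric matrix of per-vertex unit normals.
#' @param orientation which way `normals` point: `"outward"` (default) or
#'   `"inward"`.
#' @param clean drop degenerate (repeated-index) and duplicate faces.
#' @return an object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, normals = NULL,
                    orientation = c("outward", "inward"), clean = TRUE) {
  orientation <- match.arg(orientation)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) == 0L) faces <- matrix(integer(0), 0L, 3L)
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range [1, ", nrow(vertices), "]")
    if (clean) {
      rep_idx <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
        faces[, 2] == faces[, 3]
      if (any(rep_idx)) {
        message("dropping ", sum(rep_idx), " face(s) with repeated vertex indices")
        faces <- faces[!rep_idx, , drop = FALSE]
      }
      key <- apply(faces, 1L, function(f) paste(sort(f), collapse = "-"))
      dup <- duplicated(key)
      if (any(dup)) {
        message("dropping ", sum(dup), " duplicate face(s)")
        faces <- faces[!dup, , drop = FALSE]
      }
    }
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    if (!all(dim(normals) == dim(vertices)))
      stop("normals must match vertices in dimension")
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6))
      stop("normals must be unit length (max deviation ",
           format(max(abs(len - 1))), ")")
  }
  structure(list(vertices = vertices, faces = faces, normals = normals,
                 orientation = orientation),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  wt <- tryCatch(is_watertight(x), error = function(e) NA)
  cat("trimesh: ", nrow(x$vertices), " vertices, ", nrow(x$faces), " faces",
      if (isTRUE(wt)) ", watertight" else "", "\n", sep = "")
  bb <- apply(x$vertices, 2L, range)
  cat("  bbox: [", paste(sprintf("%.3g", bb[1, ]), collapse = ", "), "] to [",
      paste(sprintf("%.3g", bb[2, ]), collapse = ", "), "]\n", sep = "")
  if (!is.null(x$normals))
    cat("  per-vertex normals: ", x$orientation, "-facing\n", sep = "")
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

#' Bounding-box diagonal length
#' @param mesh a [trimesh()].
#' @return scalar length of the axis-aligned bounding-box diagonal.
#' @export
bbox_diagonal <- function(mesh) {
  r <- apply(mesh$vertices, 2L, range)
  sqrt(sum((r[2, ] - r[1, ])^2))
}

#' Remove vertices not referenced by any face
#' @param mesh a [trimesh()].
#' @return the pruned mesh (re-indexed).
#' @export
prune_isolated_vertices <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  keep <- logical(n_vertices(mesh))
  keep[used] <- TRUE
  subset_vertices(mesh, keep)
}

# keep the given vertices, drop every face touching a dropped vertex
subset_vertices <- function(mesh, keep) {
  stopifnot(length(keep) == n_vertices(mesh))
  new_index <- cumsum(keep)
  face_keep <- keep[mesh$faces[, 1]] & keep[mesh$faces[, 2]] & keep[mesh$faces[, 3]]
  faces <- mesh$faces[face_keep, , drop = FALSE]
  faces[] <- new_index[faces]
  trimesh(mesh$vertices[keep, , drop = FALSE], faces,
          normals = if (!is.null(mesh$normals))
            mesh$normals[keep, , drop = FALSE],
          orientation = mesh$orientation, clean = FALSE)
}

# undirected edge matrix (2 columns, sorted within row), one row per face edge
mesh_edge_matrix <- function(faces) {
  e <- rbind(faces[, c(1, 2), drop = FALSE],
             faces[, c(2, 3), drop = FALSE],
             faces[, c(3, 1), drop = FALSE])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Is every edge shared by exactly two faces?
#'
#' @param mesh a [trimesh()].
#' @return `TRUE` or `FALSE`, with attributes `boundary_edges` (edges on one
#'   face only) and `nonmanifold_edges` (edges on three or more faces).
#'   Watertightness is per-edge: disjoint closed components together are
#'   still watertight.
#' @export
is_watertight <- function(mesh) {
  if (n_faces(mesh) == 0L) {
    res <- FALSE
    attr(res, "boundary_edges") <- 0L
    attr(res, "nonmanifold_edges") <- 0L
    return(res)
  }
  e <- mesh_edge_matrix(mesh$faces)
  key <- e[, 1] * (n_vertices(mesh) + 1) + e[, 2]
  tab <- table(key)
  boundary <- sum(tab == 1L)
  nonmanifold <- sum(tab > 2L)
  res <- boundary == 0L && nonmanifold == 0L
  attr(res, "boundary_edges") <- as.integer(boundary)
  attr(res, "nonmanifold_edges") <- as.integer(nonmanifold)
  res
}

count_boundary_edges <- function(mesh) {
  attr(is_watertight(mesh), "boundary_edges")
}

face_cross_products <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

face_areas <- function(mesh) {
  0.5 * sqrt(rowSums(face_cross_products(mesh)^2))
}

signed_volume <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  triple <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) +
    v1[, 2] * (v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]) +
    v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  sum(triple) / 6
}

#' Enclosed volume of a watertight mesh
#'
#' Signed-tetrahedron (divergence theorem) summation over faces: the
#' absolute value of one sixth of the summed scalar triple products of each
#' face's vertices. Invariant under rigid motion.
#'
#' @param mesh a watertight [trimesh()].
#' @return enclosed volume (length units cubed).
#' @export
mesh_volume <- function(mesh) {
  if (n_faces(mesh) == 0L) stop("mesh has no faces; volume undefined")
  wt <- is_watertight(mesh)
  if (!wt)
    stop("mesh is not watertight (", attr(wt, "boundary_edges"),
         " boundary edge(s), ", attr(wt, "nonmanifold_edges"),
         " non-manifold edge(s)); volume undefined")
  abs(signed_volume(mesh))
}

#' Area-weighted per-vertex normals
#'
#' Each vertex normal is the normalized area-weighted average of its
#' incident face normals. Outward is defined by counter-clockwise winding
#' viewed from outside; the result is flipped, if necessary, so that the
#' stored normals match `orientation`, using the sign of the signed volume
#' as the outward-ness witness.
#'
#' @param mesh a [trimesh()] with at least one face.
#' @param orientation `"outward"` (default) or `"inward"`.
#' @return the mesh with `normals` and `orientation` set.
#' @export
compute_vertex_normals <- function(mesh, orientation = c("outward", "inward")) {
  orientation <- match.arg(orientation)
  if (n_faces(mesh) == 0L) stop("cannot compute normals: mesh has no faces")
  fcross <- face_cross_products(mesh) # length = 2 * area, direction = winding normal
  acc <- matrix(0, n_vertices(mesh), 3L)
  for (c in 1:3) {
    s <- rowsum(fcross, group = mesh$faces[, c], reorder = FALSE)
    idx <- as.integer(rownames(s))
    acc[idx, ] <- acc[idx, ] + s
  }
  # winding-derived normals point outward iff the signed volume is positive
  flip <- if (signed_volume(mesh) < 0) -1 else 1
  if (orientation == "inward") flip <- -flip
  acc <- acc * flip
  len <- sqrt(rowSums(acc^2))
  zero <- len < 1e-300
  if (any(zero)) {
    # isolated or fully cancelling vertices: give an arbitrary unit normal
    acc[zero, ] <- matrix(rep(c(0, 0, 1), each = sum(zero)), ncol = 3L)
    len[zero] <- 1
  }
  mesh$normals <- acc / len
  mesh$orientation <- orientation
  mesh
}

# per-face connected-component labels (faces connected through shared vertices)
face_components <- function(mesh) {
  if (n_faces(mesh) == 0L) return(integer(0))
  g <- igraph::graph_from_edgelist(
    rbind(mesh$faces[, 1:2, drop = FALSE], mesh$faces[, 2:3, drop = FALSE]),
    directed = FALSE)
  comp <- igraph::components(g)$membership
  comp[mesh$faces[, 1]]
}

# keep only the faces of the largest connected component, prune the rest
largest_component <- function(mesh) {
  comp <- face_components(mesh)
  if (length(unique(comp)) <= 1L) return(mesh)
  keep_comp <- as.integer(names(which.max(table(comp))))
  mesh$faces <- mesh$faces[comp == keep_comp, , drop = FALSE]
  prune_isolated_vertices(mesh)
}

euler_characteristic <- function(mesh) {
  ne <- nrow(unique(mesh_edge_matrix(mesh$faces)))
  n_vertices(mesh) - ne + n_faces(mesh)
}
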