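# Two-step soma segmentation from the shape diameter distribution:
# step 1 strips the thin basal dendrites, step 2 strips the apical
# dendrite from what remains - unless the apical went with the basals in
# step 1, in which case the second mixture shows no separation and the
# step is skipped.

#' Segment soma, basal and apical dendrites from a shape diameter field
#'
#' Step 1 fits a two-component Gaussian mixture to all SDF values; vertices
#' below the equiprobable boundary (thin regions) are labeled
#' `basal_dendrite` and set aside. Step 2 refits on the surviving vertices'
#' values; vertices below the new boundary are labeled `apical_dendrite`
#' and the rest `soma`. When the step-2 fit shows no dendrite-like
#' structure (the apical dendrite was already absorbed in step 1, or there
#' is none), no vertices are relabeled and the skip is recorded. When even
#' step 1 shows no such structure (no dendrites at all), every vertex is
#' labeled `soma` with a warning.
#'
#' A mixture fit only counts as dendrite-like structure when (a) the
#' component means are separated by at least one pooled standard deviation,
#' (b) the upper mean is at least `min_thickness_ratio` times the lower
#' mean, and (c) the thin component carries at least `min_weight` of the
#' mass. The ratio criterion encodes the method's premise that dendrites
#' are substantially thinner than the soma: without it, the smooth
#' within-soma thickness gradient near dendrite attachments can pass the
#' separation test and the clustering would cut the soma in half. The
#' weight criterion keeps a thin ring of junction vertices from counting
#' as a dendrite.
#'
#' @param mesh a [trimesh()] (used only for dimension checking).
#' @param sdf an [sdf_field()] for `mesh`.
#' @param gmm_restarts,seed mixture-fit controls.
#' @param min_thickness_ratio minimum upper/lower component mean ratio for
#'   a split to count as soma-versus-dendrite (default 2: a dendrite is at
#'   most half as thick as what it is cut from).
#' @param min_weight minimum mixing weight of the thin component (default
#'   0.05).
#' @return object of class `soma_segmentation`: `labels` (factor with
#'   levels `soma`, `basal_dendrite`, `apical_dendrite`), `step1_model`,
#'   `step1_threshold`, `step2_model`, `step2_threshold`, `step2_skipped`,
#'   `step1_skipped`.
#' @export
segment_soma <- function(mesh, sdf, gmm_restarts = 5L, seed = 1L,
                         min_thickness_ratio = 2, min_weight = 0.05) {
  values <- sdf$values
  if (length(values) != n_vertices(mesh))
    stop("sdf field does not match mesh vertex count")
  labels <- factor(rep("soma", length(values)),
                   levels = c("soma", "basal_dendrite", "apical_dendrite"))
  dendrite_like <- function(model) {
    !model$low_separation &&
      model$means[2] >= min_thickness_ratio * model$means[1] &&
      model$weights[1] >= min_weight
  }

  step1 <- fit_gmm2(values, n_restarts = gmm_restarts,
                    seed = derive_seed(seed, 11L))
  step1_skipped <- !dendrite_like(step1)
  step1_thr <- NULL
  step2 <- NULL
  step2_thr <- NULL
  step2_skipped <- TRUE
  if (step1_skipped) {
    warning("step 1: no separation in the shape diameter distribution; ",
            "labeling every vertex as soma")
  } else {
    step1_thr <- decision_boundary(step1)
    basal <- values <= step1_thr$value
    labels[basal] <- "basal_dendrite"
    surviving <- values[!basal]
    if (sum(!basal) >= 4L && var(surviving) > 0) {
      step2 <- fit_gmm2(surviving, n_restarts = gmm_restarts,
                        seed = derive_seed(seed, 12L))
      if (dendrite_like(step2)) {
        step2_thr <- decision_boundary(step2)
        apical <- !basal & values <= step2_thr$value
        labels[apical] <- "apical_dendrite"
        step2_skipped <- FALSE
      }
    }
  }
  structure(list(labels = labels,
                 step1_model = step1, step1_threshold = step1_thr,
                 step1_skipped = step1_skipped,
                 step2_model = step2, step2_threshold = step2_thr,
                 step2_skipped = step2_skipped,
                 sdf = sdf, seed = seed),
            class = "soma_segmentation")
}

#' @export
print.soma_segmentation <- function(x, ...) {
  cat("soma segmentation (two-step shape-diameter clustering)\n")
  print(table(x$labels))
  if (x$step1_skipped) {
    cat("step 1: skipped (no separation: no dendrites detected)\n")
  } else {
    cat("step 1 threshold:", format(x$step1_threshold$value), "\n")
    if (x$step2_skipped)
      cat("step 2: skipped (no separation: apical absorbed in step 1 or absent)\n")
    else
      cat("step 2 threshold:", format(x$step2_threshold$value), "\n")
  }
  invisible(x)
}

#' Extract the soma submesh and close it
#'
#' Keeps the faces whose three vertices are all labeled `soma` (a face is
#' removed as soon as any of its vertices is removed), takes the largest
#' connected component if the soma label set is not edge-connected
#' (logged), and closes the resulting open mesh by the same
#' indicator-function reconstruction used by the repair stage, from the
#' submesh's vertices and re-estimated normals.
#'
#' @param mesh the segmented [trimesh()].
#' @param segmentation a [segment_soma()] result (or a factor of labels).
#' @param resolution,padding,smoothing_width reconstruction controls, see
#'   [reconstruct_closed_surface()].
#' @return a watertight [trimesh()] of the closed soma.
#' @export
extract_and_close_soma <- function(mesh, segmentation, resolution = 96L,
                                   padding = 0.15, smoothing_width = 1.5) {
  labels <- if (inherits(segmentation, "soma_segmentation"))
    segmentation$labels else segmentation
  if (length(labels) != n_vertices(mesh))
    stop("labels must have one entry per vertex")
  soma <- labels == "soma"
  if (!any(soma)) stop("empty soma label set; nothing to extract")
  sub <- subset_vertices(mesh, soma)
  if (n_faces(sub) == 0L) stop("soma label set spans no complete face")
  comp <- face_components(sub)
  if (length(unique(comp)) > 1L) {
    message("soma submesh has ", length(unique(comp)),
            " components; keeping the largest")
    sub <- largest_component(sub)
  }
  sub <- prune_isolated_vertices(sub)
  sub <- compute_vertex_normals(sub, "outward")
  reconstruct_closed_surface(sub$vertices, sub$normals,
                             normals_point = "outward",
                             resolution = resolution, padding = padding,
                             smoothing_width = smoothing_width)
}
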