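test_that("soma, basal and apical are recovered on the default fixture", {
  fx <- neuron_default()
  sdf <- sdf_field(fx$mesh, seed = 1L)
  seg <- segment_soma(fx$mesh, sdf, seed = 1L)
  gt <- fx$truth$labels
  pred_soma <- seg$labels == "soma"
  recall <- sum(pred_soma & gt == "soma") / sum(gt == "soma")
  precision <- sum(pred_soma & gt == "soma") / sum(pred_soma)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.9)
  basal_recall <- mean(seg$labels[gt == "basal_dendrite"] == "basal_dendrite")
  expect_gte(basal_recall, 0.90)
})

test_that("a bare sphere yields an all-soma labeling with step-1 skip", {
  fx <- sphere_fixture()
  sdf <- sdf_field(fx$mesh, seed = 2L)
  expect_warning(seg <- segment_soma(fx$mesh, sdf, seed = 2L),
                 "no separation")
  expect_true(seg$step1_skipped)
  expect_true(all(seg$labels == "soma"))
})

test_that("an apical as thin as the basals is absorbed in step 1", {
  spec <- neuron_spec(apical = list(radius = 1, length = 30,
                                    direction = c(0, 0, 1)))
  fx <- make_neuron(spec)
  sdf <- sdf_field(fx$mesh, seed = 3L)
  seg <- segment_soma(fx$mesh, sdf, seed = 3L)
  gt <- fx$truth$labels
  # both dendrite kinds group together: the apical goes with the basals
  expect_gte(mean(seg$labels[gt == "apical_dendrite"] == "basal_dendrite"),
             0.9)
  expect_true(seg$step2_skipped)
  # the soma is still recovered
  expect_gte(sum(seg$labels == "soma" & gt == "soma") / sum(gt == "soma"), 0.95)
})

test_that("step 2 relabels a genuine surviving apical cluster", {
  # three well-separated thickness populations crafted so step 1 cuts
  # between basal and apical, leaving the apical for step 2
  s <- mesh_icosphere(1, subdivisions = 4L) # 2562 vertices
  nv <- nrow(s$vertices)
  set.seed(6)
  n_basal <- 1700L; n_apical <- 350L
  values <- c(rnorm(n_basal, 2, 0.15), rnorm(n_apical, 8, 0.5),
              rnorm(nv - n_basal - n_apical, 16, 1))
  sdf <- structure(list(values = values, cone_angle = pi / 3, n_rays = 30L,
                        seed = 6L), class = "sdf_field")
  seg <- segment_soma(s, sdf, seed = 6L)
  expect_false(seg$step1_skipped)
  expect_false(seg$step2_skipped)
  expect_gt(seg$step1_threshold$value, 2)
  expect_lt(seg$step1_threshold$value, 8)
  expect_gt(seg$step2_threshold$value, 8)
  expect_lt(seg$step2_threshold$value, 16)
  expect_gte(mean(seg$labels[1:n_basal] == "basal_dendrite"), 0.95)
  apical_idx <- (n_basal + 1L):(n_basal + n_apical)
  expect_gte(mean(seg$labels[apical_idx] == "apical_dendrite"), 0.95)
  soma_idx <- (n_basal + n_apical + 1L):nv
  expect_gte(mean(seg$labels[soma_idx] == "soma"), 0.95)
})

test_that("segmentation accuracy holds across randomized fixtures", {
  set.seed(99)
  recalls <- precisions <- vol_errs <- numeric(0)
  for (i in 1:5) {
    sr <- runif(1, 8, 12)
    br <- runif(1, 0.8, 1.3)
    ar <- runif(1, 1.8, 2.6)
    basal_dirs <- rbind(c(1, 1, -1), c(-1, 1, -1), c(1, -1, -1), c(-1, -1, -1))
    basal <- apply(basal_dirs, 1L, function(d)
      list(radius = br, length = 25, direction = d), simplify = FALSE)
    sp <- neuron_spec(soma_radius = sr, basal = basal,
                      apical = list(radius = ar, length = 30,
                                    direction = c(0, 0, 1)))
    f <- make_neuron(sp)
    sg <- segment_soma(f$mesh, sdf_field(f$mesh, seed = i), seed = i)
    g <- f$truth$labels
    ps <- sg$labels == "soma"
    recalls <- c(recalls, sum(ps & g == "soma") / sum(g == "soma"))
    precisions <- c(precisions, sum(ps & g == "soma") / sum(ps))
    soma <- extract_and_close_soma(f$mesh, sg, resolution = 64L)
    expect_true(is_watertight(soma))
    vol_errs <- c(vol_errs, abs(mesh_volume(soma) / (4 / 3 * pi * sr^3) - 1))
  }
  expect_gte(mean(recalls), 0.9)
  expect_gte(mean(precisions), 0.9)
  expect_true(all(vol_errs < 0.15))
})

test_that("closing the whole mesh is identity-like and labels must match", {
  fx <- sphere_fixture()
  labels <- factor(rep("soma", nrow(fx$mesh$vertices)),
                   levels = c("soma", "basal_dendrite", "apical_dendrite"))
  closed <- extract_and_close_soma(fx$mesh, labels, resolution = 64L)
  expect_true(is_watertight(closed))
  expect_lt(abs(mesh_volume(closed) / mesh_volume(fx$mesh) - 1), 0.05)
  expect_error(extract_and_close_soma(fx$mesh, labels[1:5]), "per vertex")
  empty <- factor(rep("basal_dendrite", nrow(fx$mesh$vertices)),
                  levels = levels(labels))
  expect_error(extract_and_close_soma(fx$mesh, empty), "empty soma")
})

test_that("segmentation is deterministic end to end", {
  fx <- neuron_default()
  s1 <- segment_soma(fx$mesh, sdf_field(fx$mesh, seed = 4L), seed = 4L)
  s2 <- segment_soma(fx$mesh, sdf_field(fx$mesh, seed = 4L), seed = 4L)
  expect_identical(s1$labels, s2$labels)
})
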