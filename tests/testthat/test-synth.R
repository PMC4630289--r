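test_that("the default fixture is watertight with voxel-oracle volume", {
  fx <- neuron_default()
  expect_true(is_watertight(fx$mesh))
  expect_setequal(levels(fx$truth$labels),
                  c("soma", "basal_dendrite", "apical_dendrite", "artifact"))
  expect_identical(length(fx$truth$labels), nrow(fx$mesh$vertices))

  # independent voxel-counting oracle for the union volume: re-derived
  # sphere/capsule distances, not the generator's code path
  spec <- fx$truth$spec
  h <- 0.4
  xs <- seq(-14, 14, by = h); ys <- xs; zs <- seq(-14, 41, by = h)
  g <- expand.grid(x = xs, y = ys, z = zs)
  inside <- sqrt(g$x^2 + g$y^2 + g$z^2) < spec$soma_radius
  caps <- c(list(spec$apical), spec$basal)
  for (d in caps) {
    b <- d$direction * (spec$soma_radius + d$length)
    t <- pmin(1, pmax(0, (g$x * b[1] + g$y * b[2] + g$z * b[3]) / sum(b^2)))
    dist <- sqrt((g$x - b[1] * t)^2 + (g$y - b[2] * t)^2 + (g$z - b[3] * t)^2)
    inside <- inside | (dist < d$radius)
  }
  oracle_vol <- sum(inside) * h^3
  expect_lt(abs(mesh_volume(fx$mesh) / oracle_vol - 1), 0.10)
})

test_that("a dendrite-free spec gives a sphere with analytic volume", {
  fx <- sphere_fixture()
  expect_true(is_watertight(fx$mesh))
  expect_lt(abs(mesh_volume(fx$mesh) / (4 / 3 * pi * 1000) - 1), 0.02)
  expect_true(all(fx$truth$labels == "soma"))
})

test_that("fixture generation is deterministic", {
  f1 <- make_neuron(neuron_spec(spacing = 1.2))
  f2 <- make_neuron(neuron_spec(spacing = 1.2))
  expect_identical(f1$mesh$vertices, f2$mesh$vertices)
  expect_identical(f1$mesh$faces, f2$mesh$faces)
  expect_identical(f1$truth$labels, f2$truth$labels)
})

test_that("label areas track primitive surface areas", {
  fx <- neuron_default()
  spec <- fx$truth$spec
  # soma fraction of total area (analytic, ignoring junction overlap)
  r <- spec$soma_radius
  a_soma <- 4 * pi * r^2
  a_api <- 2 * pi * spec$apical$radius * (spec$apical$length + spec$apical$radius)
  a_bas <- sum(vapply(spec$basal, function(d)
    2 * pi * d$radius * (d$length + d$radius), 0))
  frac_analytic <- a_soma / (a_soma + a_api + a_bas)
  frac_labels <- mean(fx$truth$labels == "soma")
  expect_lt(abs(frac_labels / frac_analytic - 1), 0.2)
})

test_that("invalid specs are rejected", {
  expect_error(neuron_spec(soma_radius = 1.5,
                           apical = list(radius = 2, length = 10,
                                         direction = c(0, 0, 1))),
               "must exceed")
  expect_error(neuron_spec(apical = list(radius = 0.5, length = 10,
                                         direction = c(0, 0, 1))),
               "apical radius")
  near <- list(list(radius = 1, length = 20, direction = c(0, 0, -1)),
               list(radius = 1, length = 20, direction = c(0.05, 0, -1)))
  expect_error(neuron_spec(basal = near, apical = NULL), "overlap")
})

test_that("a hole opens the rim the cap construction predicts", {
  fx <- sphere_fixture()
  dmg <- inject_defects(fx, hole_cap_degrees = 25, seed = 9L)
  wt <- is_watertight(dmg$mesh)
  expect_false(wt)
  # boundary edges = edges shared between a removed and a kept face
  removed <- dmg$truth$damage$hole_faces
  e_all <- somamesh:::mesh_edge_matrix(fx$mesh$faces)
  key <- paste(e_all[, 1], e_all[, 2])
  in_cap <- rep(seq_len(nrow(fx$mesh$faces)) %in% removed, times = 3L)
  rim <- intersect(unique(key[in_cap]), unique(key[!in_cap]))
  expect_identical(attr(wt, "boundary_edges"), length(rim))
})

test_that("interior-point injection keeps the shell closed", {
  fx <- sphere_fixture()
  dmg <- inject_defects(fx, n_interior_points = 25L, seed = 3L)
  added <- dmg$truth$damage$interior_vertices
  expect_identical(length(added), 75L) # one floating triangle per point
  expect_true(all(dmg$truth$labels[added] == "artifact"))
  # the original shell's edges are still all paired: only floating
  # triangles (each watertight-violating on its own rim) were added
  shell_faces <- dmg$mesh$faces[seq_len(nrow(fx$mesh$faces)), ]
  shell <- trimesh(dmg$mesh$vertices, shell_faces, clean = FALSE)
  expect_true(is_watertight(shell))
  # all injected points are strictly inside the soma
  r <- sqrt(rowSums(dmg$mesh$vertices[added, ]^2))
  expect_true(all(r < fx$truth$spec$soma_radius))
})

test_that("a zero-parameter damage call is the identity", {
  fx <- sphere_fixture()
  out <- inject_defects(fx, seed = 1L)
  expect_identical(out$mesh$vertices, fx$mesh$vertices)
  expect_identical(out$mesh$faces, fx$mesh$faces)
  expect_error(inject_defects(fx, hole_cap_degrees = 120), "hemisphere")
})
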