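test_that("RMSE vanishes exactly on identical meshes", {
  s <- icosphere_r10()
  expect_identical(rmse(s, s), 0)
  expect_identical(as.numeric(rmse_symmetric(s, s)), 0)
})

test_that("RMSE equals the offset between parallel plane patches", {
  s1 <- plane_patch(0, 1, 0, 1, z = 1, n = 12L)
  s2 <- plane_patch(-1, 2, -1, 2, z = 0, n = 12L) # margin keeps feet interior
  expect_equal(rmse(s1, s2), 1.0, tolerance = 1e-6)
})

test_that("concentric spheres give the radial offset, symmetrically", {
  a <- mesh_icosphere(10, subdivisions = 4L)
  b <- mesh_icosphere(10.5, subdivisions = 4L)
  expect_equal(as.numeric(rmse_symmetric(a, b)), 0.5, tolerance = 0.02)
  # symmetry under argument swap
  expect_equal(as.numeric(rmse_symmetric(a, b)),
               as.numeric(rmse_symmetric(b, a)), tolerance = 1e-12)
  # definition: max of the two asymmetric directions
  expect_equal(as.numeric(rmse_symmetric(a, b)),
               max(rmse(a, b), rmse(b, a)), tolerance = 1e-12)
})

test_that("coarse-versus-dense tessellation error dominates one direction", {
  coarse <- mesh_icosphere(10, subdivisions = 1L)
  dense <- mesh_icosphere(10, subdivisions = 4L)
  r_cd <- rmse(coarse, dense)
  r_dc <- rmse(dense, coarse)
  expect_gte(as.numeric(rmse_symmetric(coarse, dense)), r_cd)
  expect_equal(as.numeric(rmse_symmetric(coarse, dense)), max(r_cd, r_dc),
               tolerance = 1e-12)
})

test_that("vertex-to-surface RMSE never exceeds vertex-to-vertex RMSE", {
  set.seed(13)
  a <- mesh_icosphere(10, subdivisions = 2L)
  b <- mesh_icosphere(10.4, subdivisions = 3L)
  eps_surf <- point_to_surface_distance(a$vertices, b)
  eps_vv <- apply(a$vertices, 1L, function(p)
    sqrt(min(colSums((t(b$vertices) - p)^2))))
  expect_true(all(eps_surf <= eps_vv + 1e-12))
  expect_lte(rmse(a, b), sqrt(mean(eps_vv^2)))
})

test_that("MAQ arithmetic, identities and scale-freeness hold", {
  expect_identical(maq(c(2), c(1))$maq_12, 1.0)
  expect_identical(maq(c(2), c(1))$maq_21, 0.5)
  expect_identical(maq(c(2), c(1))$maq_sym, 1.0)

  v <- c(10, 20, 30, 40, 50)
  expect_identical(maq(v, v)$maq_sym, 0)

  m <- maq(v, 1.05 * v)
  expect_equal(m$maq_21, 0.05, tolerance = 1e-12)
  expect_equal(m$maq_12, abs(1 / 1.05 - 1), tolerance = 1e-12)
  expect_equal(m$maq_sym, 0.05, tolerance = 1e-12)

  # scale-free: multiplying every volume by c > 0 changes nothing
  set.seed(14)
  a <- runif(7, 100, 5000); b <- runif(7, 100, 5000)
  m1 <- maq(a, b); m2 <- maq(a * 137.5, b * 137.5)
  expect_equal(m1$maq_sym, m2$maq_sym, tolerance = 1e-12)

  expect_error(maq(c(1, 2), c(1)), "equal length")
  expect_error(maq(c(1, -2), c(1, 2)), "positive")
})

test_that("distance coloring is green on identity, one-signed on inflation", {
  s <- mesh_icosphere(5, subdivisions = 2L)
  same <- distance_colored_mesh(s, s)
  expect_true(all(abs(attr(same, "vertex_scalars")) < 1e-12))
  expect_true(all(attr(same, "vertex_colors")[, 2] == 255))

  big <- mesh_icosphere(6, subdivisions = 2L)
  signed <- distance_colored_mesh(big, s, signing = "normal_signed")
  expect_true(all(attr(signed, "vertex_scalars") > 0)) # uniformly outside
  inside <- distance_colored_mesh(s, big, signing = "normal_signed")
  expect_true(all(attr(inside, "vertex_scalars") < 0))
})

test_that("a differing dendrite cutoff lights up at the right place", {
  fx <- neuron_default()
  gt <- fx$truth$labels
  # soma plus a long vs short apical stump: cut the apical dendrite at
  # different heights
  keep_long <- gt == "soma" | (gt == "apical_dendrite" & fx$mesh$vertices[, 3] < 16)
  keep_short <- gt == "soma" | (gt == "apical_dendrite" & fx$mesh$vertices[, 3] < 11)
  long <- somamesh:::subset_vertices(fx$mesh, keep_long)
  short <- somamesh:::subset_vertices(fx$mesh, keep_short)
  colored <- distance_colored_mesh(long, short, signing = "normal_signed")
  vals <- attr(colored, "vertex_scalars")
  big_idx <- which(abs(vals) > quantile(abs(vals), 0.95))
  # the large-distance vertices lie on the differing stump (high z)
  expect_gte(mean(long$vertices[big_idx, 3] > 10), 0.9)
})
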