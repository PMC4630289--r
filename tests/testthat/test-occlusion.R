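test_that("hemisphere sampling is solid-angle uniform and oriented", {
  set.seed(1)
  d <- sample_hemisphere(c(0, 0, 1), 1e4)
  # E[cos(theta)] = 1/2 for solid-angle-uniform sampling
  expect_equal(mean(d[, 3]), 0.5, tolerance = 0.02)
  expect_true(all(d[, 3] >= 0))
  expect_equal(sqrt(rowSums(d^2)), rep(1, 1e4), tolerance = 1e-9)

  # arbitrary orientation: every sample on the correct side
  nrm <- c(1, -2, 0.5) / sqrt(sum(c(1, -2, 0.5)^2))
  set.seed(2)
  d2 <- sample_hemisphere(nrm, 500)
  expect_true(all(d2 %*% nrm >= 0))

  set.seed(3); a <- sample_hemisphere(c(0, 1, 0), 64)
  set.seed(3); b <- sample_hemisphere(c(0, 1, 0), 64)
  expect_identical(a, b)
  expect_error(sample_hemisphere(c(0, 0, 1), 0), ">= 1")
})

test_that("occlusion is 0 on a convex surface and 1 inside an enclosure", {
  s <- unit_icosphere4()
  ao <- occlusion_field(s, n_rays = 32, seed = 1L)
  expect_true(all(ao$values == 0))

  # probe vertex at the center of a closed box: every ray hits
  box <- mesh_box(c(-1, -1, -1), c(1, 1, 1))
  probe <- trimesh(rbind(box$vertices, c(0, 0, 0)), box$faces)
  probe <- compute_vertex_normals(probe, "outward")
  set.seed(4)
  a <- occlusion_factor(probe, nrow(probe$vertices), n_rays = 64)
  expect_equal(a, 1)
})

test_that("an 8-ray scene with 3 blocked rays gives factor 3/8", {
  # eight sample directions fanned over the hemisphere around +z;
  # three small walls each block exactly one of the first three rays
  az <- (0:7) * pi / 4
  el <- pi / 4
  dirs <- cbind(cos(az) * cos(el), sin(az) * cos(el), sin(el))
  blocked <- 1:3
  v <- matrix(0, 0, 3)
  f <- matrix(integer(0), 0, 3)
  for (i in blocked) {
    center <- 2 * dirs[i, ]
    fr <- somamesh:::tangent_frame(matrix(dirs[i, ], 1, 3))
    tri <- rbind(center + 0.5 * fr$t1[1, ],
                 center - 0.5 * fr$t1[1, ] + 0.5 * fr$t2[1, ],
                 center - 0.5 * fr$t1[1, ] - 0.5 * fr$t2[1, ])
    f <- rbind(f, nrow(v) + 1:3)
    v <- rbind(v, tri)
  }
  # the evaluated vertex itself (isolated, normal defaults to +z)
  v <- rbind(v, c(0, 0, 0))
  scene <- compute_vertex_normals(trimesh(v, f), "outward")
  a <- occlusion_factor(scene, nrow(v), directions = dirs, ignore_within = 1e-6)
  expect_equal(a, 3 / 8)
})

test_that("occlusion separates injected interior vertices from the surface", {
  fx <- sphere_fixture()
  dmg <- inject_defects(fx, n_interior_points = 40L, seed = 5L)
  # main shell is still watertight: only floating triangles were added
  ao <- occlusion_field(dmg$mesh, n_rays = 64, seed = 2L)
  interior <- dmg$truth$damage$interior_vertices
  expect_gte(mean(ao$values[interior] >= 0.9), 0.95)
  exterior <- which(dmg$truth$labels == "soma")
  expect_lte(quantile(ao$values[exterior], 0.95), 0.1)
})

test_that("occlusion values are count ratios and reproducible", {
  fx <- sphere_fixture()
  dmg <- inject_defects(fx, n_interior_points = 15L, seed = 6L)
  n_rays <- 32L
  ao1 <- occlusion_field(dmg$mesh, n_rays = n_rays, seed = 3L)
  ao2 <- occlusion_field(dmg$mesh, n_rays = n_rays, seed = 3L)
  expect_identical(ao1$values, ao2$values)
  # every value is an integer multiple of 1/N
  expect_true(all(abs(ao1$values * n_rays - round(ao1$values * n_rays)) < 1e-12))
  expect_true(all(ao1$values >= 0 & ao1$values <= 1))
})

test_that("enclosing the mesh in a shell never decreases occlusion", {
  s <- mesh_icosphere(2, subdivisions = 2L)
  shell <- mesh_icosphere(6, subdivisions = 2L)
  enclosed <- trimesh(rbind(s$vertices, shell$vertices),
                      rbind(s$faces, shell$faces + nrow(s$vertices)))
  enclosed <- compute_vertex_normals(enclosed, "outward")
  # identical ray directions per vertex on both meshes
  set.seed(9)
  for (vi in sample.int(nrow(s$vertices), 25L)) {
    dirs <- sample_hemisphere(s$normals[vi, ], 32L)
    a_free <- occlusion_factor(s, vi, directions = dirs)
    a_enc <- occlusion_factor(enclosed, vi, directions = dirs)
    expect_gte(a_enc, a_free)
  }
})
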