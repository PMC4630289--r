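test_that("vertex dropping removes incident faces and reports the boundary", {
  s <- icosphere_r10()
  labels <- factor(rep("below", nrow(s$vertices)), levels = c("below", "above"))
  expect_mesh_equal(drop_vertices(s, labels), s)

  # one removed vertex opens a fan: boundary edge count = vertex degree
  vi <- 43L
  degree <- sum(s$faces == vi)
  labels[vi] <- "above"
  opened <- drop_vertices(s, labels)
  expect_identical(nrow(opened$vertices), nrow(s$vertices) - 1L)
  expect_identical(nrow(opened$faces), nrow(s$faces) - degree)
  expect_identical(attr(opened, "boundary_edges"), as.integer(degree))

  expect_error(drop_vertices(s, factor(rep("above", nrow(s$vertices)),
                                       levels = c("below", "above"))),
               "fewer than 4")
})

test_that("oriented sphere samples reconstruct to the analytic ball", {
  set.seed(10)
  dirs <- random_unit_vectors(2000L)
  rec <- reconstruct_closed_surface(dirs * 10, dirs, normals_point = "outward",
                                    resolution = 64L)
  expect_true(is_watertight(rec))
  expect_equal(mesh_volume(rec), 4 / 3 * pi * 1000, tolerance = 0.05)
  info <- attr(rec, "reconstruction")
  expect_lt(info$mean_point_distance, 2 * info$spacing)
})

test_that("reconstruction closes holes and keeps genus zero", {
  set.seed(11)
  dirs <- random_unit_vectors(4000L)
  # delete a 30-degree cap of samples: simulates an opened surface
  keep <- dirs[, 3] < cos(30 * pi / 180)
  # the closing bulge extends past the sample bounding box at the pole, so
  # the cap case needs more padding than a full surface does
  rec <- reconstruct_closed_surface(dirs[keep, ] * 10, dirs[keep, ],
                                    normals_point = "outward",
                                    resolution = 64L, padding = 0.2)
  expect_true(is_watertight(rec))
  expect_identical(somamesh:::euler_characteristic(rec), 2L)

  # refining the grid does not worsen the fit (10% slack)
  rec_fine <- reconstruct_closed_surface(dirs[keep, ] * 10, dirs[keep, ],
                                         normals_point = "outward",
                                         resolution = 128L, padding = 0.2)
  d_coarse <- attr(rec, "reconstruction")$mean_point_distance
  d_fine <- attr(rec_fine, "reconstruction")$mean_point_distance
  expect_lt(d_fine, d_coarse * 1.1)
})

test_that("degenerate point sets are rejected", {
  set.seed(12)
  flat <- cbind(runif(100), runif(100), 0)
  nrm <- matrix(rep(c(0, 0, 1), each = 100), ncol = 3L)
  expect_error(reconstruct_closed_surface(flat, nrm), "coplanar")
  expect_error(reconstruct_closed_surface(flat[1:10, ], nrm[1:10, ]),
               "at least 50")
})

test_that("repair restores a damaged sphere to its pristine shape", {
  fx <- sphere_fixture()
  dmg <- damaged_sphere_fixture()
  expect_false(is_watertight(dmg$mesh))
  repaired <- repair_soma(dmg$mesh, seed = 1L, grid_resolution = 64L)
  expect_true(is_watertight(repaired))
  v0 <- mesh_volume(fx$mesh)
  expect_lt(abs(mesh_volume(repaired) / v0 - 1), 0.10)
  # the repair never moves the surface far
  expect_lt(as.numeric(rmse_symmetric(fx$mesh, repaired)),
            3 * attr(repaired, "reconstruction")$spacing)

  report <- attr(repaired, "repair_report")
  # >= 95% of the injected interior vertices were removed, <= 5% of the
  # clean exterior was
  ao <- occlusion_field(dmg$mesh, n_rays = report$ao_rays,
                        seed = report$stage_seeds[["occlusion"]])
  removed <- ao$values > report$threshold
  interior <- dmg$truth$damage$interior_vertices
  clean_ext <- setdiff(which(dmg$truth$labels == "soma"),
                       dmg$truth$damage$cavity_vertices)
  expect_gte(mean(removed[interior]), 0.95)
  expect_lte(mean(removed[clean_ext]), 0.05)
})

test_that("repairing a pristine convex mesh is near-identity", {
  fx <- sphere_fixture()
  expect_warning(repaired <- repair_soma(fx$mesh, seed = 2L,
                                         grid_resolution = 64L),
                 "no appreciable artifact cluster")
  expect_true(is_watertight(repaired))
  expect_lt(abs(mesh_volume(repaired) / mesh_volume(fx$mesh) - 1), 0.05)
})

test_that("repair is deterministic under a fixed seed", {
  dmg <- damaged_sphere_fixture()
  r1 <- repair_soma(dmg$mesh, seed = 5L, grid_resolution = 48L)
  r2 <- repair_soma(dmg$mesh, seed = 5L, grid_resolution = 48L)
  expect_identical(r1$vertices, r2$vertices)
  expect_identical(r1$faces, r2$faces)
})
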