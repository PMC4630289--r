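test_that("constructor validates faces and cleans degenerate input", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m <- trimesh(v, rbind(c(1, 2, 3), c(1, 2, 4)))
  expect_s3_class(m, "trimesh")
  expect_error(trimesh(v, rbind(c(1, 2, 5))), "out of range")
  expect_message(trimesh(v, rbind(c(1, 2, 3), c(1, 1, 2))), "repeated")
  expect_message(trimesh(v, rbind(c(1, 2, 3), c(2, 3, 1))), "duplicate")
  expect_error(trimesh(v, rbind(c(1, 2, 3)),
                       normals = matrix(c(2, 0, 0), 4, 3, byrow = TRUE)),
               "unit length")
})

test_that("watertightness is detected per edge with diagnostics", {
  s <- icosphere_r10()
  wt <- is_watertight(s)
  expect_true(wt)
  expect_identical(attr(wt, "boundary_edges"), 0L)

  open_s <- s
  open_s$faces <- open_s$faces[-1, , drop = FALSE]
  wt2 <- is_watertight(open_s)
  expect_false(wt2)
  expect_identical(attr(wt2, "boundary_edges"), 3L)

  # two disjoint closed spheres in one mesh are still watertight
  s2 <- mesh_icosphere(1, center = c(30, 0, 0), subdivisions = 2L)
  both <- trimesh(rbind(s$vertices, s2$vertices),
                  rbind(s$faces, s2$faces + nrow(s$vertices)))
  expect_true(is_watertight(both))
})

test_that("mesh volume matches closed forms and is rigid-motion invariant", {
  expect_equal(mesh_volume(mesh_box()), 1.0, tolerance = 1e-12)
  s <- unit_icosphere4()
  expect_equal(mesh_volume(s), 4 * pi / 3, tolerance = 0.01)

  # translation invariance
  t1 <- s
  t1$vertices <- sweep(t1$vertices, 2L, c(100, -50, 3), `+`)
  expect_equal(mesh_volume(t1), mesh_volume(s), tolerance = 1e-9)

  # rotation invariance
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  t2 <- s
  t2$vertices <- s$vertices %*% t(R)
  expect_equal(mesh_volume(t2), mesh_volume(s), tolerance = 1e-9)

  # uniform scaling by s scales volume by s^3
  t3 <- s
  t3$vertices <- s$vertices * 2.5
  expect_equal(mesh_volume(t3), mesh_volume(s) * 2.5^3, tolerance = 1e-9)

  # volume is undefined on open meshes
  open_s <- s
  open_s$faces <- open_s$faces[-1, , drop = FALSE]
  expect_error(mesh_volume(open_s), "not watertight")
})

test_that("vertex normals are area-weighted, unit and orientable", {
  s <- unit_icosphere4()
  m <- compute_vertex_normals(s, "outward")
  radial <- m$vertices / sqrt(rowSums(m$vertices^2))
  ang <- acos(pmin(1, rowSums(m$normals * radial)))
  expect_lt(max(ang), 2 * pi / 180) # within 2 degrees of radial

  mi <- compute_vertex_normals(s, "inward")
  ang_in <- acos(pmin(1, rowSums(mi$normals * (-radial))))
  expect_lt(max(ang_in), 2 * pi / 180)

  # flat fan of coplanar triangles: all normals equal the plane normal
  p <- plane_patch(0, 1, 0, 1, 0, n = 4L)
  pn <- compute_vertex_normals(p, "outward")
  expect_lt(max(abs(abs(pn$normals[, 3]) - 1)), 1e-6)

  expect_error(compute_vertex_normals(trimesh(matrix(0, 1, 3),
                                              matrix(integer(0), 0, 3))),
               "no faces")
})

test_that("isolated vertices survive construction and can be pruned", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(5, 5, 5))
  m <- trimesh(v, rbind(c(1, 2, 3)))
  expect_identical(nrow(m$vertices), 4L)
  p <- prune_isolated_vertices(m)
  expect_identical(nrow(p$vertices), 3L)
  expect_identical(p$faces, rbind(1:3))
})
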