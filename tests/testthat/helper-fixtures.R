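# Shared fixtures, built once per test run and memoised. Everything is
# generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

unit_icosphere4 <- function() cached("ico4", function() mesh_icosphere(1, subdivisions = 4L))
icosphere_r10 <- function() cached("ico10", function() mesh_icosphere(10, subdivisions = 3L))

# default pyramidal-cell fixture
neuron_default <- function() cached("neuron", function() make_neuron(neuron_spec()))

# bare sphere fixture (no dendrites) via the implicit-surface generator
sphere_fixture <- function() {
  cached("sphere_fx", function() {
    make_neuron(neuron_spec(basal = list(), apical = NULL, spacing = 0.8))
  })
}

damaged_sphere_fixture <- function() {
  cached("damaged_fx", function() {
    inject_defects(sphere_fixture(), hole_cap_degrees = 25, cavity_depth = 1.5,
                   n_interior_points = 60L, seed = 7L)
  })
}

# rectangular patch of fine triangles over [x0,x1] x [y0,y1] at height z
plane_patch <- function(x0, x1, y0, y1, z, n = 10L) {
  xs <- seq(x0, x1, length.out = n + 1L)
  ys <- seq(y0, y1, length.out = n + 1L)
  v <- cbind(rep(xs, times = n + 1L), rep(ys, each = n + 1L), z)
  idx <- function(i, j) (j - 1L) * (n + 1L) + i
  f <- list()
  for (j in seq_len(n))
    for (i in seq_len(n)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      cc <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
      f[[length(f) + 1L]] <- rbind(c(a, b, cc), c(a, cc, d))
    }
  trimesh(v, do.call(rbind, f), clean = FALSE)
}

# uniform-area random sample of points on a mesh surface
sample_surface_points <- function(mesh, n, seed = 1L) {
  set.seed(seed)
  areas <- somamesh:::face_areas(mesh)
  fi <- sample.int(length(areas), n, replace = TRUE, prob = areas)
  u <- runif(n); v <- runif(n)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
  a <- mesh$vertices[mesh$faces[fi, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[fi, 2], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[fi, 3], , drop = FALSE]
  a + u * (b - a) + v * (cc - a)
}

random_unit_vectors <- function(n) {
  m <- matrix(rnorm(3 * n), ncol = 3L)
  m / sqrt(rowSums(m^2))
}

expect_mesh_equal <- function(m1, m2, tol = 1e-5) {
  expect_equal(dim(m1$vertices), dim(m2$vertices))
  expect_identical(m1$faces, m2$faces)
  expect_lt(max(abs(m1$vertices - m2$vertices)), tol)
}
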