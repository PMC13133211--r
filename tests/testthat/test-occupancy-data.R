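test_that("normalize_mesh centres, scales isotropically and inverts", {
  cube <- fixture_cube(center = c(5, 5, 5), side = 10)
  nm <- normalize_mesh(cube, padding = 0)
  bb <- mesh_bbox(nm$mesh)
  expect_equal(bb[2, ] - bb[1, ], rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(colMeans(bb), rep(0, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  back <- denormalize_points(nm$mesh$vertices, nm$transform)
  expect_lt(max(abs(back - cube$vertices)), 1e-9)

  # anisotropic box: longest side 1, aspect preserved
  box <- fixture_cube()
  box$vertices <- sweep(box$vertices, 2, c(4, 2, 1), "*")
  nb <- normalize_mesh(box, padding = 0)
  ext <- mesh_bbox(nb$mesh)[2, ] - mesh_bbox(nb$mesh)[1, ]
  expect_equal(ext, c(1, 0.5, 0.25), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(normalize_mesh(cube, padding = 0.5), "padding")
  degen <- trimesh(matrix(0, 3, 3), rbind(c(1, 2, 3)), validate = FALSE)
  expect_error(normalize_mesh(degen), "zero-extent")
})

test_that("ray-parity labels agree with oracles and handle edge cases", {
  spec <- primitive_spec("sphere", radius = 0.4, resolution = 4)
  m <- make_primitive(spec)
  set.seed(1)
  P <- matrix(stats::runif(3 * 10000, -0.5, 0.5), ncol = 3)
  lab <- occupancy_labels(m, P)
  expect_gte(mean(lab == analytic_occupancy(spec, P)), 0.999)
  expect_equal(occupancy_labels(m, rbind(c(2, 2, 2))), 0L) # outside bbox
  expect_equal(occupancy_labels(m, rbind(colMeans(m$vertices))), 1L)
  open <- trimesh(m$vertices, m$faces[-1, ])
  expect_error(occupancy_labels(open, P[1:3, ]), "watertight")
})

test_that("parity is invariant to the ray direction", {
  m <- make_primitive(primitive_spec("torus", resolution = 2))
  set.seed(4)
  P <- matrix(stats::runif(3 * 200, -0.45, 0.45), ncol = 3)
  base <- NULL
  for (r in 1:5) {
    d <- matrix(stats::rnorm(3), 1)
    d <- d / sqrt(sum(d^2))
    D <- matrix(d, nrow(P), 3, byrow = TRUE)
    par <- cpp_ray_crossings(m$vertices, m$faces, P, D) %% 2L
    if (is.null(base)) base <- par else expect_equal(par, base)
  }
})

test_that("pool labels match a brute-force winding-number oracle", {
  m <- make_primitive(primitive_spec("ellipsoid", radii = c(0.35, 0.25, 0.2),
                                     resolution = 2))
  set.seed(9)
  P <- matrix(stats::runif(3 * 1000, -0.5, 0.5), ncol = 3)
  expect_equal(occupancy_labels(m, P), winding_inside(m, P))
})

test_that("training-point pools are seeded, sized and label-calibrated", {
  m <- fixture_sphere_mesh()
  n <- 20000L
  pool <- sample_training_points(m, n_pool = n, t_batch = 1024L, seed = 3)
  # inside fraction ~ Bernoulli(mesh volume / box volume); 3-sigma band
  p0 <- mesh_volume(m)
  expect_lt(abs(mean(pool$labels) - p0), 3 * sqrt(p0 * (1 - p0) / n))
  pool2 <- sample_training_points(m, n_pool = n, t_batch = 1024L, seed = 3)
  expect_identical(pool$points, pool2$points)

  b1 <- draw_occupancy_batch(pool, 5L)
  b2 <- draw_occupancy_batch(pool, 5L)
  expect_identical(b1$points, b2$points)
  expect_false(identical(b1$points, draw_occupancy_batch(pool, 6L)$points))
  full <- draw_occupancy_batch(pool, 1L, t_batch = n)
  expect_setequal(full$points[, 1], pool$points[, 1])
  expect_error(sample_training_points(m, n_pool = 100, t_batch = 200),
               "exceed")
})

test_that("voxelize marks surface+interior and converges with resolution", {
  m <- fixture_sphere_mesh()
  va <- 4 / 3 * pi * 0.4^3
  errs <- sapply(c(16L, 32L, 64L), function(res) {
    g <- voxelize(m, res)
    expect_s3_class(g, "voxel_grid")
    # the far corner voxel is empty
    expect_false(g$values[1, 1, 1])
    # centre-inside mask approximates volume (10% even at 16^3)
    vin <- sum(attr(g, "interior")) * g$pitch^3
    expect_lt(abs(vin - va) / va, 0.1)
    abs(sum(g$values) * g$pitch^3 - va)
  })
  expect_true(all(diff(errs) < 0)) # strictly decreasing occupied-volume error
  expect_error(voxelize(m, 1L), "at least 2")
})

test_that("occupancy pools round-trip through the portable container", {
  m <- fixture_sphere_mesh()
  pool <- sample_training_points(m, n_pool = 500L, t_batch = 64L, seed = 1,
                                 source_id = "rt")
  stem <- tempfile()
  write_occupancy_pool(pool, stem)
  p2 <- read_occupancy_pool(stem)
  expect_equal(p2$labels, pool$labels)
  expect_equal(p2$points, pool$points, tolerance = 1e-6) # float32
  expect_equal(p2$source_id, "rt")
  unlink(paste0(stem, c(".json", ".bin")))
})
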