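test_that("primitive meshes match closed-form volumes and topology", {
  sph <- make_primitive(primitive_spec("sphere", radius = 0.4,
                                       resolution = 4))
  expect_true(is_watertight(sph))
  expect_equal(mesh_volume(sph), 4 / 3 * pi * 0.4^3, tolerance = 0.01)

  ell <- make_primitive(primitive_spec("ellipsoid",
                                       radii = c(0.4, 0.3, 0.2),
                                       resolution = 4))
  expect_equal(mesh_volume(ell), 4 / 3 * pi * 0.4 * 0.3 * 0.2,
               tolerance = 0.01)

  tor <- make_primitive(primitive_spec("torus", ring_radius = 0.3,
                                       tube_radius = 0.1, resolution = 4))
  expect_true(is_watertight(tor))
  expect_equal(mesh_euler(tor), 0) # genus 1

  cap <- make_primitive(primitive_spec("capsule", radius = 0.1,
                                       a = c(0, 0, -0.2), b = c(0, 0, 0.2),
                                       resolution = 4))
  expect_true(is_watertight(cap))
  expect_equal(mesh_volume(cap), pi * 0.1^2 * 0.4 + 4 / 3 * pi * 0.1^3,
               tolerance = 0.01)
  for (m in list(sph, ell, tor, cap)) expect_silent(mesh_check(m))
  expect_error(primitive_spec("sphere", radius = -1), "positive")
})

test_that("primitive generation is deterministic", {
  s <- primitive_spec("torus", resolution = 2)
  expect_identical(make_primitive(s, seed = 5)$vertices,
                   make_primitive(s, seed = 5)$vertices)
})

test_that("analytic occupancy gives exact membership", {
  s <- primitive_spec("sphere", radius = 0.4)
  expect_equal(analytic_occupancy(s, rbind(c(0, 0, 0))), 1L)
  expect_equal(analytic_occupancy(s, rbind(c(0.5, 0, 0))), 0L)
  t <- primitive_spec("torus", ring_radius = 0.3, tube_radius = 0.1)
  expect_equal(analytic_occupancy(t, rbind(c(0.3, 0, 0))), 1L) # tube centre
  expect_equal(analytic_occupancy(t, rbind(c(0, 0, 0))), 0L)   # hole
  cap <- primitive_spec("capsule", radius = 0.1, a = c(0, 0, -0.2),
                        b = c(0, 0, 0.2))
  expect_equal(analytic_occupancy(cap, rbind(c(0, 0, 0.25))), 1L) # cap dome
  expect_equal(analytic_occupancy(cap, rbind(c(0.15, 0, 0))), 0L)
})

test_that("toy thorax has labelled, watertight, disjoint parts", {
  th <- fixture_thorax()
  expect_s3_class(th, "part_mesh")
  expect_equal(sort(part_names(th)),
               sort(c("spine", "rib_pair_01", "rib_pair_02", "rib_pair_03")))
  expect_equal(length(th$part_of_face), nrow(th$mesh$faces))
  for (p in part_names(th)) expect_true(is_watertight(part_submesh(th, p)))
  expect_true(is_watertight(th$mesh))
  # determinism
  th2 <- make_toy_thorax(3, 4, 0, seed = 2)
  expect_identical(th$mesh$vertices, th2$mesh$vertices)
})

test_that("jitter perturbs rib geometry deterministically across seeds", {
  cents <- sapply(1:5, function(s) {
    th <- make_toy_thorax(2, 3, jitter = 0.02, seed = 10 + s)
    ids <- part_vertex_ids(th, "rib_pair_01")
    colMeans(th$mesh$vertices[ids, ])
  })
  # centroids differ between seeds
  expect_gt(max(apply(cents, 1, stats::sd)), 0)
})

test_that("deform_known returns exact ground-truth displacements", {
  m <- fixture_sphere_mesh()
  tr <- deform_known(m, "translation", 0.1, seed = 1)
  expect_equal(sqrt(rowSums(tr$displacement^2)),
               rep(0.1, nrow(m$vertices)), tolerance = 1e-12)
  expect_equal(tr$mesh$vertices, m$vertices + tr$displacement)

  z <- deform_known(m, "translation", 0, seed = 1)
  expect_equal(z$mesh$vertices, m$vertices)
  expect_true(all(z$displacement == 0))

  bd <- deform_known(m, "bend", 0.05, seed = 2)
  expect_lte(max(sqrt(rowSums(bd$displacement^2))),
             0.05 * bbox_diagonal(m) + 1e-12)

  th <- fixture_thorax()
  pa <- deform_known(th, "part_articulation", 0.05, seed = 3)
  ids <- part_vertex_ids(th, pa$moved_part)
  expect_equal(sqrt(rowSums(pa$displacement[ids, , drop = FALSE]^2)),
               rep(0.05, length(ids)), tolerance = 1e-12)
  expect_true(all(pa$displacement[-ids, ] == 0))
  expect_error(deform_known(th$mesh, "part_articulation", 0.05),
               "part_mesh")
})

test_that("part meshes round-trip through PLY + JSON sidecar", {
  th <- fixture_thorax()
  path <- tempfile(fileext = ".ply")
  write_part_mesh(th, path)
  th2 <- read_part_mesh(path)
  expect_equal(th2$part_of_face, th$part_of_face)
  expect_equal(th2$mesh$faces, th$mesh$faces, ignore_attr = TRUE)
  unlink(c(path, paste0(path, ".parts.json")))
})
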