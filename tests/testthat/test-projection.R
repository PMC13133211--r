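test_that("sphere chords match the analytic chord length", {
  m <- fixture_sphere_mesh()
  img <- render_projection(m, 0, size = 128)
  for (d in c(0, 0.1, 0.2, 0.3)) {
    i <- round((d + 0.5) * 128 + 0.5)
    u <- (i - 0.5) / 128 - 0.5 # actual ray offset for that pixel
    expect_equal(img$raw[i, 65], 2 * sqrt(0.4^2 - u^2), tolerance = 0.02)
  }
  expect_equal(img$raw[2, 2], 0)            # ray misses the sphere
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  expect_error(render_projection(trimesh(m$vertices, m$faces[-1, ]), 0, 32),
               "watertight")
})

test_that("summed chords reproduce mesh volume (Cavalieri)", {
  m <- make_primitive(primitive_spec("ellipsoid", radii = c(0.35, 0.28, 0.2),
                                     resolution = 3))
  img <- render_projection(m, 33, size = 128)
  vol <- sum(img$raw) / 128^2
  expect_equal(vol, mesh_volume(m), tolerance = 0.02)
})

test_that("rendering commutes with rotation about the vertical axis", {
  m <- make_primitive(primitive_spec("ellipsoid", radii = c(0.4, 0.25, 0.2),
                                     resolution = 2))
  th <- 25 * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  i1 <- render_projection(m, 25, size = 64)
  i2 <- render_projection(transform_mesh(m, rotation = Rz), 0, size = 64)
  expect_lt(max(abs(i1$raw - i2$raw)), 1e-9)
})

test_that("clahe keeps range, fixes constants, preserves local ranks", {
  expect_equal(stats::sd(clahe(matrix(0.5, 64, 64), 2, 4)), 0)
  set.seed(2)
  r <- matrix(stats::runif(64 * 64), 64)
  out <- clahe(r, 2, 4)
  expect_true(all(out >= 0 & out <= 1))
  # monotone ramp: rank order preserved within each tile
  ramp <- matrix(rep(seq(0, 1, length.out = 64), 64), 64)
  cr <- clahe(ramp, 2, 4)
  for (tile in list(1:16, 17:32)) {
    expect_gte(stats::cor(as.vector(ramp[tile, tile]),
                          as.vector(cr[tile, tile]),
                          method = "spearman"), 0.999)
  }
  expect_error(clahe(r, 2, tiles = 100), "tiles")
})

test_that("part bounding boxes are tight, ordered and view-axis invariant", {
  # one-cube 'part': box equals the projected face extents
  cube <- fixture_cube(center = c(0.1, 0, -0.05), side = 0.3)
  pm <- part_mesh(cube, rep("cube", nrow(cube$faces)))
  bx <- project_part_bboxes(pm, 0)
  expect_equal(bx$width, 0.3, tolerance = 1e-12)
  expect_equal(bx$height, 0.3, tolerance = 1e-12)
  expect_equal(bx$center_x, 0.6, tolerance = 1e-12)
  expect_equal(bx$center_y, 0.55, tolerance = 1e-12)

  # translation along the view axis (y at angle 0) leaves the box unchanged
  cube2 <- cube
  cube2$vertices[, 2] <- cube2$vertices[, 2] + 0.2
  bx2 <- project_part_bboxes(part_mesh(cube2, rep("cube", nrow(cube2$faces))), 0)
  expect_equal(bx2[, -1], bx[, -1], ignore_attr = TRUE)

  # thorax ribs order top-to-bottom in image y as their 3D height falls
  th <- fixture_thorax()
  bx3 <- project_part_bboxes(th, 0)
  ribs <- bx3[grepl("rib", bx3$part), ]
  z3 <- sapply(ribs$part,
               function(p) mean(th$mesh$vertices[part_vertex_ids(th, p), 3]))
  expect_equal(order(ribs$center_y), order(-z3))
})

test_that("PGM images round-trip through the CLI reader", {
  m <- fixture_sphere_mesh()
  img <- render_projection(m, 0, size = 32)
  path <- tempfile(fileext = ".pgm")
  write_pgm(img, path)
  back <- skelrec:::.read_pgm(path)
  expect_equal(back, img$pixels, tolerance = 2e-5) # 16-bit quantisation
  unlink(path)
})
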