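test_that("voxelized IoU handles identity, disjoint and offset pairs", {
  m <- fixture_sphere_mesh()
  expect_equal(as.numeric(iou_voxelized(m, m, pitch = 1 / 32)), 1)
  far <- transform_mesh(m, translation = c(5, 0, 0))
  expect_equal(as.numeric(iou_voxelized(m, far, pitch = 1 / 8)), 0)
  c1 <- fixture_cube()
  c2 <- fixture_cube(center = c(0.5, 0, 0))
  expect_equal(as.numeric(iou_voxelized(c1, c2, pitch = 1 / 64)), 1 / 3,
               tolerance = 0.05)
  empty <- trimesh(matrix(0, 0, 3), matrix(0L, 0, 3), validate = FALSE)
  expect_error(iou_voxelized(empty, empty), "empty")
})

test_that("surface sampling is area-weighted and on-face", {
  m <- fixture_cube()
  n <- 100000L
  s <- sample_surface(m, n, seed = 1)
  expect_equal(nrow(s$points), n)
  # every sample lies on some face plane of the cube
  on_plane <- apply(abs(abs(s$points) - 0.5), 1, min)
  expect_lt(max(on_plane), 1e-9)
  # per-face counts proportional to area (equal areas here): chi-square
  counts <- tabulate(s$face, nbins = nrow(m$faces))
  chi2 <- sum((counts - n / 12)^2 / (n / 12))
  expect_lt(chi2, stats::qchisq(0.999, df = 11))
  expect_identical(sample_surface(m, 100, seed = 2)$points,
                   sample_surface(m, 100, seed = 2)$points)
  degen <- trimesh(matrix(0, 3, 3), rbind(c(1, 2, 3)), validate = FALSE)
  expect_error(sample_surface(degen, 10), "zero-area")
})

test_that("chamfer matches closed forms and the brute-force oracle", {
  P <- rbind(c(0, 0, 0))
  G <- rbind(c(1, 0, 0))
  expect_equal(chamfer_l1(P, P), 0)
  expect_equal(chamfer_l1(P, G), 2)      # both directed terms are 1
  expect_equal(chamfer_l1(P, G, halved = TRUE), 1)
  set.seed(3)
  P <- matrix(stats::runif(300), 100)
  G <- matrix(stats::runif(300), 100)
  brute <- function(A, B) mean(apply(A, 1, function(p)
    min(colSums(abs(t(B) - p)))))
  expect_equal(chamfer_l1(P, G), brute(P, G) + brute(G, P),
               tolerance = 1e-12)
  expect_error(chamfer_l1(P[0, , drop = FALSE], G), "non-empty")
})

test_that("fscore matches constructed precision/recall cases", {
  set.seed(4)
  G <- matrix(stats::runif(300), 100)
  expect_equal(as.numeric(fscore(G, G, 0.02)), 1)
  expect_equal(as.numeric(fscore(G, G + 10, 0.02)), 0)
  # P covers half of G exactly: precision 1, recall 0.5 -> F = 2/3
  P <- G[1:50, ]
  G2 <- rbind(G[1:50, ], G[51:100, ] + 5)
  f <- fscore(P, G2, 0.02)
  expect_equal(attr(f, "precision"), 1)
  expect_equal(attr(f, "recall"), 0.5)
  expect_equal(as.numeric(f), 2 / 3)
  # monotone non-decreasing in t
  Q <- matrix(stats::runif(300), 100)
  fs <- sapply(c(0.01, 0.05, 0.2, 1), function(t)
    as.numeric(fscore(Q, G, t)))
  expect_true(all(diff(fs) >= 0))
  expect_error(fscore(G, G, 0), "positive")
})

test_that("normal consistency matches alignment extremes and chance", {
  m <- fixture_sphere_mesh()
  s <- sample_surface(m, 2000, seed = 5)
  expect_equal(normal_consistency(s, s), 1)
  orth <- s
  # rotate each normal 90 degrees within a tangent plane of z
  orth$normals <- cbind(-s$normals[, 2], s$normals[, 1], 0)
  orth$normals <- orth$normals / sqrt(rowSums(orth$normals^2))
  expect_lt(normal_consistency(
    list(points = s$points, normals = orth$normals), s), 0.05)
  # independent uniform orientations -> E|cos| = 0.5
  set.seed(6)
  rn <- function(n) {
    v <- matrix(stats::rnorm(3 * n), ncol = 3)
    v / sqrt(rowSums(v^2))
  }
  n <- 10000
  a <- list(points = matrix(stats::runif(3 * n), ncol = 3), normals = rn(n))
  b <- list(points = matrix(stats::runif(3 * n), ncol = 3), normals = rn(n))
  expect_equal(normal_consistency(a, b), 0.5, tolerance = 0.02)
  bad <- s; bad$normals[1, ] <- 0
  expect_error(normal_consistency(bad, s), "zero-length")
})

test_that("axis errors vanish under identity and rigid motion, and read out pure offsets", {
  m <- make_primitive(primitive_spec("ellipsoid", radii = c(0.35, 0.3, 0.2),
                                     resolution = 2))
  expect_equal(axis_errors(m, m), c(maxe = 0, maye = 0, maze = 0),
               tolerance = 1e-12)
  ang <- 8 * pi / 180
  Rz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
              c(0, 0, 1))
  moved <- transform_mesh(m, rotation = Rz, translation = c(0.05, -0.02, 0.03))
  expect_lt(max(axis_errors(moved, m)), 5e-4) # ICP cancels the motion
  # offset well below the vertex spacing, so nearest-neighbour pairing
  # recovers the true correspondence and reads out the pure offset
  shifted <- transform_mesh(m, translation = c(0, 0, 0.02))
  ax <- axis_errors(shifted, m, align = FALSE)
  expect_equal(unname(ax), c(0, 0, 0.02), tolerance = 1e-9)
})

test_that("evaluate_pair bundles the metric family with provenance", {
  m <- fixture_sphere_mesh()
  rep <- evaluate_pair(m, m, n_samples = 3000L, pitch = 1 / 32, seed = 2)
  expect_equal(rep$iou, 1)
  expect_equal(rep$chamfer_l1, 0)
  expect_equal(rep$fscore, 1)
  expect_equal(rep$nc, 1)
  expect_equal(c(rep$maxe, rep$maye, rep$maze), c(0, 0, 0),
               tolerance = 1e-12)
  # lossless serialization round trip
  path <- tempfile(fileext = ".json")
  write_metrics_report(rep, path)
  rep2 <- read_metrics_report(path)
  expect_equal(rep2$chamfer_l1, rep$chamfer_l1)
  expect_equal(rep2$pitch, rep$pitch)
  unlink(path)
})

test_that("metrics are invariant to a common rigid transform", {
  m1 <- fixture_sphere_mesh()
  m2 <- make_primitive(primitive_spec("ellipsoid",
                                      radii = c(0.42, 0.38, 0.36),
                                      resolution = 3))
  base <- evaluate_pair(m1, m2, n_samples = 5000L, pitch = 1 / 32, seed = 3)
  ang <- 0.4
  Rz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
              c(0, 0, 1))
  t1 <- transform_mesh(m1, rotation = Rz, translation = c(0.1, 0.2, -0.05))
  t2 <- transform_mesh(m2, rotation = Rz, translation = c(0.1, 0.2, -0.05))
  moved <- evaluate_pair(t1, t2, n_samples = 5000L, pitch = 1 / 32, seed = 3)
  expect_equal(moved$chamfer_l1, base$chamfer_l1, tolerance = 0.02)
  expect_equal(moved$fscore, base$fscore, tolerance = 0.02)
  expect_equal(moved$nc, base$nc, tolerance = 0.02)
  expect_equal(moved$iou, base$iou, tolerance = 0.05)
  expect_equal(moved$maze, base$maze, tolerance = 5e-3)
})

test_that("two independently seeded evaluations are stable", {
  m1 <- fixture_sphere_mesh()
  m2 <- make_primitive(primitive_spec("sphere", radius = 0.38,
                                      resolution = 3))
  r1 <- evaluate_pair(m1, m2, n_samples = 20000L, pitch = 1 / 32, seed = 10)
  r2 <- evaluate_pair(m1, m2, n_samples = 20000L, pitch = 1 / 32, seed = 77)
  expect_lt(abs(r1$chamfer_l1 - r2$chamfer_l1) / r1$chamfer_l1, 0.01)
})
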