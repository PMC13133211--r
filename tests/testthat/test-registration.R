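test_that("ICP recovers known rigid transforms", {
  m <- make_primitive(primitive_spec("ellipsoid", radii = c(0.4, 0.3, 0.2),
                                     resolution = 2))
  tf0 <- icp_rigid(m$vertices, m$vertices)
  expect_equal(tf0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tf0$translation, c(0, 0, 0), tolerance = 1e-9)

  ang <- 10 * pi / 180
  Rz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
              c(0, 0, 1))
  tf1 <- icp_rigid(m$vertices, m$vertices %*% t(Rz))
  rot_err <- acos(pmin(1, (sum(diag(t(tf1$rotation) %*% Rz)) - 1) / 2))
  expect_lt(rot_err * 180 / pi, 0.1)

  tf2 <- icp_rigid(m$vertices, sweep(m$vertices, 2, c(0.1, 0, 0), "+"))
  expect_equal(tf2$translation, c(0.1, 0, 0), tolerance = 1e-6)

  line <- cbind(seq(0, 1, length.out = 10), 0, 0)
  expect_error(icp_rigid(line, line), "collinear|degenerate")
})

test_that("geodesic distances follow the edge graph", {
  m <- fixture_sphere_mesh()
  d <- geodesic_distances(m, from = m$faces[1, 1])
  b <- m$faces[1, 2]
  expect_equal(d[1, b],
               sqrt(sum((m$vertices[m$faces[1, 1], ] -
                           m$vertices[b, ])^2)),
               tolerance = 1e-12)
  # straight strip: geodesic equals Euclidean along the path
  n <- 10
  v <- rbind(cbind(seq_len(n), 0, 0), cbind(seq_len(n) - 0.5, 1, 0))
  f <- do.call(rbind, lapply(seq_len(n - 1), function(i)
    rbind(c(i, i + 1, n + i), c(i + 1, n + i + 1, n + i))))
  strip <- trimesh(v, f, validate = FALSE)
  ds <- geodesic_distances(strip, from = 1L)
  expect_equal(ds[1, n], n - 1, tolerance = 1e-12)
  expect_error(geodesic_distances(m, from = integer(0)), "empty")
})

test_that("icosphere graph geodesics stay above the great circle and approach it", {
  # graph shortest paths upper-bound the true geodesic at every level;
  # they approach (without monotonicity -- the lattice direction set
  # changes under subdivision) the great-circle length pi * r
  ds <- sapply(1:3, function(res) {
    s <- make_primitive(primitive_spec("sphere", radius = 1,
                                       resolution = res))
    anti <- which.min(rowSums(sweep(s$vertices, 2,
                                    -s$vertices[1, ], "-")^2))
    geodesic_distances(s, from = 1L)[1, anti]
  })
  expect_true(all(ds >= pi * (1 - 1e-9)))
  expect_lt(ds[3] / pi - 1, 0.08)
})

test_that("coherence kernels are Gaussian, PSD and well approximated", {
  set.seed(4)
  P <- matrix(stats::rnorm(600), 200)
  K <- build_kernel(P, beta = 1.5, type = "euclidean")
  G <- skelrec:::.kernel_mat(K)
  expect_equal(diag(G), rep(1, 200), tolerance = 1e-9)
  expect_equal(G[1, 2], exp(-sum((P[1, ] - P[2, ])^2) / (2 * 1.5^2)),
               tolerance = 1e-9)
  Kinf <- build_kernel(P, beta = 1e9, type = "euclidean")
  expect_true(all(abs(skelrec:::.kernel_mat(Kinf) - 1) < 1e-9))
  # truncation error bounded by the discarded spectrum
  eg <- eigen(G, symmetric = TRUE)
  for (k in c(10L, 50L)) {
    Kk <- build_kernel(P, beta = 1.5, type = "euclidean", k = k)
    err <- max(abs(skelrec:::.kernel_mat(Kk) - G))
    expect_lte(err, eg$values[k + 1] * 200 + 1e-9)
  }
  # geodesic kernel: cross-component entries are exactly zero
  two <- merge_meshes(list(fixture_cube(c(0, 0, 0), 0.3),
                           fixture_cube(c(1, 0, 0), 0.3)))
  Kg <- build_kernel(two, beta = 10, type = "geodesic")
  Gg <- skelrec:::.kernel_mat(Kg)
  expect_lt(max(abs(Gg[1:8, 9:16])), 1e-9)
  expect_error(build_kernel(P, beta = 0), "positive")
})

test_that("CPD recovers identity, bends, and tolerates outliers", {
  cap <- make_primitive(primitive_spec("capsule", radius = 0.12,
                                       a = c(0, 0, -0.3), b = c(0, 0, 0.3),
                                       resolution = 2))
  idr <- cpd_nonrigid(cap, cap$vertices, max_iter = 50L)
  expect_lt(mean(sqrt(rowSums(idr$displacement^2))),
            1e-3 * bbox_diagonal(cap))

  dk <- deform_known(cap, "bend", 0.05, seed = 4)
  bd <- cpd_nonrigid(cap, dk$mesh$vertices, w = 0, max_iter = 100L)
  err <- mean(sqrt(rowSums((bd$mesh$vertices - dk$mesh$vertices)^2)))
  expect_lte(err, 0.1 * 0.05)
  expect_identical(bd$mesh$faces, cap$faces)

  # outliers: 20% junk points with w = 0.1. The outlier-free run
  # converges to machine precision, so a relative inflation bound is
  # vacuous; assert the registration stays accurate in absolute terms
  set.seed(5)
  n_out <- round(0.2 * nrow(cap$vertices))
  junk <- matrix(stats::runif(3 * n_out, -0.5, 0.5), ncol = 3)
  ro <- cpd_nonrigid(cap, rbind(dk$mesh$vertices, junk), w = 0.1,
                     max_iter = 100L)
  err_o <- mean(sqrt(rowSums((ro$mesh$vertices - dk$mesh$vertices)^2)))
  clean <- cpd_nonrigid(cap, dk$mesh$vertices, w = 0.1, max_iter = 100L)
  err_c <- mean(sqrt(rowSums((clean$mesh$vertices - dk$mesh$vertices)^2)))
  expect_lt(err_c, 1e-4)
  expect_lte(err_o, 0.05 * bbox_diagonal(cap))
})

test_that("the EM objective is non-increasing on fixture runs", {
  cap <- make_primitive(primitive_spec("capsule", radius = 0.12,
                                       a = c(0, 0, -0.25), b = c(0, 0, 0.25),
                                       resolution = 2))
  dk <- deform_known(cap, "bend", 0.05, seed = 4)
  for (w in c(0, 0.1)) {
    r <- cpd_nonrigid(cap, dk$mesh$vertices, w = w, max_iter = 100L)
    nll <- r$nll
    expect_true(all(diff(nll) <= 1e-8 * pmax(abs(nll[-length(nll)]), 1)))
  }
})

test_that("wide kernels drive displacement variance toward rigidity", {
  cap <- make_primitive(primitive_spec("capsule", radius = 0.1,
                                       a = c(0, 0, -0.2), b = c(0, 0, 0.2),
                                       resolution = 2))
  tr <- deform_known(cap, "translation", 0.08, seed = 6)
  r <- cpd_nonrigid(cap, tr$mesh$vertices, beta = 1000, max_iter = 50L)
  v <- apply(r$displacement, 2, stats::var)
  expect_lt(max(v), 1e-6) # near-uniform displacement field
})

test_that("geodesic-kernel registration preserves topology and zeros", {
  th <- fixture_thorax()
  r <- gbcpd_nonrigid(th, th$mesh$vertices, max_iter = 50L,
                      pre_align = FALSE)
  expect_identical(r$mesh$faces, th$mesh$faces)
  expect_equal(nrow(r$mesh$vertices), nrow(th$mesh$vertices))
  expect_lt(mean(sqrt(rowSums(r$displacement^2))),
            1e-3 * bbox_diagonal(th$mesh))
  expect_error(gbcpd_nonrigid(th, th$mesh$vertices, strict = TRUE),
               "disconnected template part: spine")
})

test_that("assemble_template extracts exactly the detected parts", {
  th <- fixture_thorax()
  full <- assemble_template(th, part_names(th))
  expect_equal(nrow(full$mesh$faces), nrow(th$mesh$faces))
  sub <- assemble_template(th, c("spine", "rib_pair_01"))
  expect_setequal(unique(sub$part_of_face), c("spine", "rib_pair_01"))
  expect_equal(nrow(sub$mesh$faces),
               sum(th$part_of_face %in% c("spine", "rib_pair_01")))
  expect_true(is_watertight(sub$mesh))
  expect_error(assemble_template(th, character(0)), "empty")
  expect_error(assemble_template(th, "femur"), "unknown part")
})
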