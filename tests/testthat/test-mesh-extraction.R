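test_that("evaluate_grid matches direct point queries", {
  f <- function(p) rep(0.7, nrow(p))
  g <- evaluate_grid(f, 8)
  expect_true(all(g$values == 0.7))
  fs <- fixture_sphere_field()
  g2 <- evaluate_grid(fs, 16)
  set.seed(1)
  idx <- cbind(sample(17, 100, TRUE), sample(17, 100, TRUE),
               sample(17, 100, TRUE))
  pos <- (idx - 1) * g2$pitch - 0.5
  expect_equal(g2$values[idx], fs(pos), tolerance = 1e-6)
})

test_that("marching cubes interpolates, respects symmetry, closes surfaces", {
  # linear ramp crossing tau at x = 0.3 -> planar mesh there
  ramp <- function(p) p[, 1]
  g <- evaluate_grid(ramp, 16)
  m <- marching_cubes(g, 0.3)
  expect_gt(nrow(m$faces), 0)
  expect_lt(max(abs(m$vertices[, 1] - 0.3)), g$pitch / 100)

  # reflection-symmetric field -> symmetric vertex set
  fs <- fixture_sphere_field()
  ms <- marching_cubes(evaluate_grid(fs, 16), 0.2)
  refl <- ms$vertices; refl[, 1] <- -refl[, 1]
  nn <- cpp_nn(ms$vertices, refl, 2L)
  expect_lt(max(nn$dist), 1e-9)
  expect_true(is_watertight(ms))
  expect_silent(mesh_check(ms))

  expect_warning(m0 <- marching_cubes(evaluate_grid(function(p)
    rep(0, nrow(p)), 8), 0.2), "empty")
  expect_equal(nrow(m0$faces), 0)
})

test_that("MISE equals dense extraction and queries fewer points", {
  fs <- fixture_sphere_field(r = 0.3)
  dense <- marching_cubes(evaluate_grid(fs, 64), 0.2)
  mm <- mise_extract(fs, mise_config(16L, 64L, 0.2, simplify_faces = 0L))
  expect_identical(mesh_signature(dense), mesh_signature(mm))
  expect_lt(attr(mm, "n_queries"), 65^3)
  expect_equal(mesh_volume(mm), 4 / 3 * pi * (0.3 + 0.02 * log(4))^3,
               tolerance = 0.02)
  # whole-domain-outside field -> empty mesh with warning
  expect_warning(me <- mise_extract(function(p) rep(0.01, nrow(p)),
                                    mise_config(8L, 16L, 0.2,
                                                simplify_faces = 0L)),
                 "empty")
  expect_equal(nrow(me$faces), 0)
})

test_that("extracted volume is monotone in the threshold", {
  fs <- fixture_sphere_field(r = 0.3, k = 0.05)
  vols <- sapply(c(0.2, 0.4, 0.6), function(tau) {
    mesh_volume(marching_cubes(evaluate_grid(fs, 32), tau))
  })
  expect_true(all(diff(vols) < 0))
})

test_that("simplification respects targets and preserves shape", {
  fs <- fixture_sphere_field(r = 0.35)
  dense <- marching_cubes(evaluate_grid(fs, 64), 0.2)
  expect_gt(nrow(dense$faces), 18000)
  expect_identical(simplify(dense, nrow(dense$faces) + 10), dense)
  simp <- simplify(dense, 2000L)
  expect_lte(nrow(simp$faces), 2000L)
  expect_true(is_watertight(simp))
  expect_equal(mesh_euler(simp), 2)  # genus preserved
  expect_equal(mesh_volume(simp), mesh_volume(dense), tolerance = 0.01)
  expect_warning(tiny <- simplify(dense, 1L), "clamped")
})

test_that("gradient refinement pulls vertices back to the level set", {
  fs <- fixture_sphere_field(r = 0.3)
  m <- marching_cubes(evaluate_grid(fs, 32), 0.2)
  # already on the level set: refinement barely moves anything
  # vertices come from linear interpolation on a 32-cell grid, so they
  # sit within a fraction of a pitch of the level set already
  r0 <- refine(m, fs, steps = 3, step_size = 1 / 64, tau = 0.2)
  expect_lt(max(sqrt(rowSums((r0$vertices - m$vertices)^2))), 1 / 128)
  # perturbed vertices recover: mean residual drops by >= 50%
  set.seed(3)
  mp <- m
  mp$vertices <- mp$vertices + matrix(stats::rnorm(length(m$vertices),
                                                   sd = 0.004), ncol = 3)
  before <- mean(abs(fs(mp$vertices) - 0.2))
  ref <- refine(mp, fs, steps = 30, step_size = 1 / 64, tau = 0.2)
  expect_lt(attr(ref, "mean_residual"), 0.5 * before)
  # zero step size is the identity
  expect_identical(refine(mp, fs, steps = 5, step_size = 0)$vertices,
                   mp$vertices)
})
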