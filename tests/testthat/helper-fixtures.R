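# Shared fixtures, all built in code.

# axis-aligned unit cube (12 triangles, outward orientation)
fixture_cube <- function(center = c(0, 0, 0), side = 1) {
  v <- as.matrix(expand.grid(x = c(-0.5, 0.5), y = c(-0.5, 0.5),
                             z = c(-0.5, 0.5))) * side
  v <- sweep(v, 2, center, "+")
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  trimesh(v, f)
}

# smooth logistic sphere field: crosses tau = 0.2 at radius r02(r, k)
fixture_sphere_field <- function(r = 0.35, k = 0.02, center = c(0, 0, 0)) {
  function(p) {
    d <- sqrt(rowSums(sweep(p, 2, center, "-")^2))
    1 / (1 + exp((d - r) / k))
  }
}

# random smooth multi-blob field, resolved at a 32-cell grid
fixture_blob_field <- function(seed) {
  set.seed(seed)
  ctrs <- matrix(stats::runif(9, -0.2, 0.2), 3)
  wid <- stats::runif(3, 0.05, 0.15)
  function(p) {
    v <- rep(0, nrow(p))
    for (i in 1:3)
      v <- v + exp(-rowSums(sweep(p, 2, ctrs[i, ], "-")^2) / (2 * wid[i]^2))
    pmin(v, 1)
  }
}

# order-independent triangle-set signature for mesh equality
mesh_signature <- function(m, digits = 10) {
  v <- m$vertices
  fmt <- paste0("%.", digits, "f")
  tri <- apply(m$faces, 1, function(r) {
    paste(sort(sprintf(paste(fmt, fmt, fmt, sep = ","),
                       v[r, 1], v[r, 2], v[r, 3])), collapse = ";")
  })
  sort(tri)
}

# generalized winding number (Van Oosterom solid angles); independent
# inside/outside oracle for watertight meshes
winding_inside <- function(mesh, points) {
  V <- mesh$vertices
  F <- mesh$faces
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    a <- sweep(V[F[, 1], , drop = FALSE], 2, p, "-")
    b <- sweep(V[F[, 2], , drop = FALSE], 2, p, "-")
    c <- sweep(V[F[, 3], , drop = FALSE], 2, p, "-")
    la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2)); lc <- sqrt(rowSums(c^2))
    num <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
    den <- la * lb * lc + rowSums(a * b) * lc + rowSums(b * c) * la +
      rowSums(a * c) * lb
    w <- sum(2 * atan2(num, den)) / (4 * pi)
    as.integer(abs(w) > 0.5)
  }, 1L)
}

# shared small phantom cache (built once per test run)
.fix_env <- new.env()
fixture_thorax <- function() {
  if (is.null(.fix_env$thorax))
    .fix_env$thorax <- make_toy_thorax(3, 4, 0, seed = 2)
  .fix_env$thorax
}
fixture_sphere_mesh <- function() {
  if (is.null(.fix_env$sphere))
    .fix_env$sphere <- make_primitive(primitive_spec("sphere", radius = 0.4,
                                                     resolution = 3))
  .fix_env$sphere
}
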