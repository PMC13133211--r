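#' Primitive shape specifications
#'
#' Analytic oracle shapes used to validate every downstream stage:
#' sphere, ellipsoid, torus (genus 1) and capsule. Sizes are chosen so
#' the shape fits the unit box after normalization.
#'
#' @param kind one of `"sphere"`, `"ellipsoid"`, `"torus"`, `"capsule"`.
#' @param center shape centre (3-vector).
#' @param radius sphere/capsule tube radius.
#' @param radii ellipsoid semi-axes (3-vector).
#' @param ring_radius torus centreline radius (axis = z).
#' @param tube_radius torus tube radius.
#' @param a,b capsule segment endpoints.
#' @param resolution positive integer controlling mesh fidelity
#'   (icosphere subdivisions; grid multiplier for torus/capsule).
#' @return object of class `primitive_spec`.
#' @export
primitive_spec <- function(kind = c("sphere", "ellipsoid", "torus", "capsule"),
                           center = c(0, 0, 0), radius = 0.4,
                           radii = c(0.4, 0.3, 0.2),
                           ring_radius = 0.3, tube_radius = 0.1,
                           a = c(0, 0, -0.25), b = c(0, 0, 0.25),
                           resolution = 4L) {
  kind <- match.arg(kind)
  if (resolution < 1) stop("resolution must be a positive integer")
  sizes <- switch(kind,
    sphere = radius,
    ellipsoid = radii,
    torus = c(ring_radius, tube_radius),
    capsule = c(radius, sqrt(sum((b - a)^2))))
  if (any(sizes <= 0)) stop("all size parameters must be strictly positive")
  structure(list(kind = kind, center = center, radius = radius,
                 radii = radii, ring_radius = ring_radius,
                 tube_radius = tube_radius, a = a, b = b,
                 resolution = as.integer(resolution)),
            class = "primitive_spec")
}

# --- primitive mesh builders -------------------------------------------

.icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
             c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
             c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
             c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1)) + 1L
  trimesh(V, F)
}

.subdivide_sphere <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  nv <- nrow(V)
  key <- function(a, b) (pmin(a, b) - 1) * as.double(nv) + pmax(a, b)
  ek <- unique(c(key(F[, 1], F[, 2]), key(F[, 2], F[, 3]), key(F[, 3], F[, 1])))
  mid_id <- stats::setNames(seq_along(ek) + nv, as.character(ek))
  ea <- floor((ek - 1) / nv) + 1
  eb <- (ek - 1) %% nv + 1
  MV <- (V[ea, , drop = FALSE] + V[eb, , drop = FALSE]) / 2
  MV <- MV / sqrt(rowSums(MV^2))
  m12 <- mid_id[as.character(key(F[, 1], F[, 2]))]
  m23 <- mid_id[as.character(key(F[, 2], F[, 3]))]
  m31 <- mid_id[as.character(key(F[, 3], F[, 1]))]
  NF <- rbind(cbind(F[, 1], m12, m31), cbind(F[, 2], m23, m12),
              cbind(F[, 3], m31, m23), cbind(m12, m23, m31))
  trimesh(rbind(V, MV), NF)
}

.icosphere <- function(subdiv) {
  m <- .icosahedron()
  for (i in seq_len(subdiv)) m <- .subdivide_sphere(m)
  m
}

# closed parametric grid (nu around, rows = rings) -> quads -> triangles
.torus_mesh <- function(R, r, nu, nv) {
  u <- 2 * pi * (0:(nu - 1)) / nu
  v <- 2 * pi * (0:(nv - 1)) / nv
  g <- expand.grid(iu = 0:(nu - 1), iv = 0:(nv - 1))
  uu <- u[g$iu + 1]; vv <- v[g$iv + 1]
  V <- cbind((R + r * cos(vv)) * cos(uu), (R + r * cos(vv)) * sin(uu),
             r * sin(vv))
  id <- function(iu, iv) (iv %% nv) * nu + (iu %% nu) + 1L
  iu <- g$iu; iv <- g$iv
  f1 <- cbind(id(iu, iv), id(iu + 1, iv), id(iu + 1, iv + 1))
  f2 <- cbind(id(iu, iv), id(iu + 1, iv + 1), id(iu, iv + 1))
  m <- trimesh(V, rbind(f1, f2))
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# capsule along +z, segment length L, radius r; lat-long with pole fans
.capsule_mesh_z <- function(L, r, n_theta, n_rings) {
  phi_bot <- seq(-pi / 2, 0, length.out = n_rings + 1)[-1]
  phi_top <- seq(0, pi / 2, length.out = n_rings + 1)[-(n_rings + 1)]
  rings <- rbind(cbind(r * cos(phi_bot), -L / 2 + r * sin(phi_bot)),
                 cbind(r * cos(phi_top), L / 2 + r * sin(phi_top)))
  nr <- nrow(rings)
  th <- 2 * pi * (0:(n_theta - 1)) / n_theta
  V <- do.call(rbind, lapply(seq_len(nr), function(i) {
    cbind(rings[i, 1] * cos(th), rings[i, 1] * sin(th), rings[i, 2])
  }))
  bot <- nrow(V) + 1L
  top <- nrow(V) + 2L
  V <- rbind(V, c(0, 0, -L / 2 - r), c(0, 0, L / 2 + r))
  id <- function(i, j) (i - 1L) * n_theta + (j - 1L) %% n_theta + 1L
  F <- list()
  for (j in 1:n_theta) { # bottom fan
    F[[length(F) + 1L]] <- c(bot, id(1, j + 1), id(1, j))
  }
  for (i in 1:(nr - 1)) {
    for (j in 1:n_theta) {
      F[[length(F) + 1L]] <- c(id(i, j), id(i, j + 1), id(i + 1, j + 1))
      F[[length(F) + 1L]] <- c(id(i, j), id(i + 1, j + 1), id(i + 1, j))
    }
  }
  for (j in 1:n_theta) { # top fan
    F[[length(F) + 1L]] <- c(top, id(nr, j), id(nr, j + 1))
  }
  m <- trimesh(V, do.call(rbind, F))
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

.rot_z_to <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  c2 <- sum(z * axis)
  if (abs(c2 + 1) < 1e-12) return(diag(c(1, -1, -1)))
  vx <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
  diag(3) + vx + vx %*% vx / (1 + c2)
}

#' Build a watertight mesh for a primitive
#'
#' Deterministic given the spec (the seed is recorded for provenance but
#' primitives need no randomness).
#' @param spec a [primitive_spec()].
#' @param seed integer, recorded in the `seed` attribute.
#' @return a `trimesh`.
#' @export
make_primitive <- function(spec, seed = 0L) {
  if (!inherits(spec, "primitive_spec")) stop("spec must be a primitive_spec")
  res <- spec$resolution
  m <- switch(spec$kind,
    sphere = transform_mesh(.icosphere(res), scale = spec$radius,
                            translation = spec$center),
    ellipsoid = {
      s <- .icosphere(res)
      s$vertices <- sweep(s$vertices, 2, spec$radii, "*")
      transform_mesh(s, translation = spec$center)
    },
    torus = transform_mesh(
      .torus_mesh(spec$ring_radius, spec$tube_radius, 16L * res, 12L * res),
      translation = spec$center),
    capsule = {
      axis <- spec$b - spec$a
      L <- sqrt(sum(axis^2))
      m0 <- .capsule_mesh_z(L, spec$radius, 8L * res, 2L * res)
      transform_mesh(m0, rotation = .rot_z_to(axis),
                     translation = (spec$a + spec$b) / 2)
    })
  attr(m, "seed") <- seed
  m
}

#' Exact analytic inside/outside membership for a primitive
#' @param spec a [primitive_spec()].
#' @param points n x 3 matrix of query points.
#' @return integer vector of 0/1 labels.
#' @export
analytic_occupancy <- function(spec, points) {
  if (!inherits(spec, "primitive_spec")) stop("spec must be a primitive_spec")
  p <- sweep(as.matrix(points), 2, spec$center, "-")
  inside <- switch(spec$kind,
    sphere = rowSums(p^2) <= spec$radius^2,
    ellipsoid = rowSums(sweep(p, 2, spec$radii, "/")^2) <= 1,
    torus = (sqrt(p[, 1]^2 + p[, 2]^2) - spec$ring_radius)^2 + p[, 3]^2 <=
      spec$tube_radius^2,
    capsule = {
      q <- as.matrix(points)
      ab <- spec$b - spec$a
      t <- pmin(1, pmax(0, (sweep(q, 2, spec$a, "-") %*% ab) / sum(ab^2)))
      cl <- outer(as.vector(t), ab) + matrix(spec$a, nrow(q), 3, byrow = TRUE)
      rowSums((q - cl)^2) <= spec$radius^2
    })
  as.integer(inside)
}

# --- part-labelled meshes ----------------------------------------------

#' Part-labelled meshes
#'
#' Wraps a `trimesh` with one part identifier per face; every part
#' sub-mesh must itself be watertight.
#' @param mesh a `trimesh`.
#' @param part_of_face character vector, one label per face.
#' @param validate check per-part watertightness.
#' @export
part_mesh <- function(mesh, part_of_face, validate = TRUE) {
  if (length(part_of_face) != nrow(mesh$faces))
    stop("need exactly one part label per face")
  pm <- structure(list(mesh = mesh, part_of_face = as.character(part_of_face)),
                  class = "part_mesh")
  if (validate) {
    for (p in part_names(pm)) {
      if (!is_watertight(part_submesh(pm, p)))
        stop("part sub-mesh not watertight: ", p)
    }
  }
  pm
}

#' @export
print.part_mesh <- function(x, ...) {
  cat(sprintf("part_mesh: %d parts (%s), %d faces total\n",
              length(part_names(x)), paste(part_names(x), collapse = ", "),
              nrow(x$mesh$faces)))
  invisible(x)
}

#' @rdname part_mesh
#' @export
part_names <- function(pm) unique(pm$part_of_face)

#' Extract one part as a standalone mesh
#' @param pm a `part_mesh`.
#' @param part part name.
#' @export
part_submesh <- function(pm, part) {
  keep <- pm$part_of_face == part
  if (!any(keep)) stop("unknown part: ", part)
  F <- pm$mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(pm$mesh$vertices))
  remap[used] <- seq_along(used)
  trimesh(pm$mesh$vertices[used, , drop = FALSE],
          matrix(remap[F], ncol = 3))
}

#' Vertex indices (into the full mesh) belonging to a part
#' @rdname part_submesh
#' @export
part_vertex_ids <- function(pm, part) {
  keep <- pm$part_of_face == part
  sort(unique(as.vector(pm$mesh$faces[keep, , drop = FALSE])))
}

# bend a +z capsule onto an arc of radius R_arc (x-z plane through origin)
.bend_arc <- function(V, R_arc) {
  phi <- V[, 3] / R_arc
  cbind((R_arc + V[, 1]) * cos(phi) - R_arc, V[, 2],
        (R_arc + V[, 1]) * sin(phi))
}

.make_rib <- function(R_arc, tube_r, span, azimuth, z, n_theta = 16L,
                      n_rings = 4L) {
  L <- R_arc * span
  m <- .capsule_mesh_z(L, tube_r, n_theta, n_rings)
  v <- .bend_arc(m$vertices, R_arc)
  v <- cbind(v[, 1] + R_arc, v[, 2], v[, 3]) # curvature centre -> origin
  # place arc in the horizontal plane: map (x, y, z) -> (x, z, y)
  v <- v[, c(1, 3, 2)]
  rot <- rbind(c(cos(azimuth), -sin(azimuth), 0),
               c(sin(azimuth), cos(azimuth), 0), c(0, 0, 1))
  v <- v %*% t(rot)
  v[, 3] <- v[, 3] + z
  m2 <- trimesh(v, m$faces)
  if (mesh_volume(m2) < 0) m2$faces <- m2$faces[, c(1, 3, 2)]
  m2
}

#' Procedural toy thorax phantom
#'
#' A vertical stack of capsule "vertebrae" (part `"spine"`) surrounded
#' by curved capsule rib pairs (`"rib_pair_01"`, ...). Parts are pairwise
#' disjoint and individually watertight, which is what the part-aware
#' registration stage relies on. `jitter` perturbs rib arc radius and
#' height deterministically from `seed`; a jitter draw that makes parts
#' collide is rejected and regenerated from `seed + 1` (logged).
#'
#' @param n_rib_pairs number of rib pairs (>= 1).
#' @param n_vertebrae number of vertebral capsules (>= 1).
#' @param jitter non-negative perturbation scale (box units).
#' @param seed integer seed.
#' @return a [part_mesh()].
#' @export
make_toy_thorax <- function(n_rib_pairs = 3L, n_vertebrae = 4L, jitter = 0,
                            seed = 0L) {
  if (n_rib_pairs < 1 || n_vertebrae < 1) stop("need at least 1 rib pair and 1 vertebra")
  if (jitter < 0) stop("jitter must be non-negative")
  for (attempt in 0:9) {
    s <- seed + attempt
    pm <- .build_thorax(n_rib_pairs, n_vertebrae, jitter, s)
    if (!is.null(pm)) {
      if (attempt > 0)
        message("toy thorax: parts collided; regenerated with seed ", s)
      attr(pm, "seed") <- s
      return(pm)
    }
  }
  stop("toy thorax parts collide after 10 attempts; reduce jitter")
}

.build_thorax <- function(n_rib_pairs, n_vertebrae, jitter, seed) {
  set.seed(seed)
  meshes <- list(); labels <- list()
  span_z <- 0.8
  sv <- span_z / n_vertebrae
  rv <- min(0.045, sv * 0.22)
  zc <- seq(-span_z / 2 + sv / 2, span_z / 2 - sv / 2, length.out = n_vertebrae)
  spine <- lapply(zc, function(z) {
    half <- max(sv * 0.3 - rv, 0.005)
    make_primitive(primitive_spec("capsule", radius = rv,
                                  a = c(0, 0, z - half), b = c(0, 0, z + half),
                                  resolution = 2L))
  })
  meshes[[1L]] <- merge_meshes(spine)
  labels[[1L]] <- rep("spine", nrow(meshes[[1L]]$faces))

  zr <- if (n_rib_pairs == 1) 0 else
    seq(-0.3, 0.3, length.out = n_rib_pairs)
  span <- 140 * pi / 180
  for (k in seq_len(n_rib_pairs)) {
    R_arc <- 0.28 * (1 + jitter * stats::runif(1, -1, 1))
    z_k <- zr[k] + jitter * stats::runif(1, -1, 1) * 0.5
    tube_r <- min(0.025, if (n_rib_pairs > 1) 0.35 * diff(zr[1:2]) else 0.025)
    right <- .make_rib(R_arc, tube_r, span, pi / 2, z_k)
    left <- .make_rib(R_arc, tube_r, span, -pi / 2, z_k)
    pair <- merge_meshes(list(right, left))
    meshes[[k + 1L]] <- pair
    labels[[k + 1L]] <- rep(sprintf("rib_pair_%02d", k), nrow(pair$faces))
  }

  # collision check: minimum inter-part vertex distance
  for (i in seq_along(meshes)) {
    for (j in seq_along(meshes)) {
      if (j <= i) next
      nn <- cpp_nn(meshes[[i]]$vertices, meshes[[j]]$vertices, 2L)
      if (min(nn$dist) < 5e-3) return(NULL)
    }
  }
  part_mesh(merge_meshes(meshes), unlist(labels), validate = FALSE)
}

#' Apply a known smooth deformation with ground truth
#'
#' Fixture generator for the registration stage: deforms a mesh and
#' returns the exact per-vertex displacement that was applied.
#' `"translation"` moves every vertex by `magnitude` along a seeded
#' direction; `"bend"` displaces along x by a smooth quadratic profile of
#' height, with maximum displacement `magnitude *` bounding-box diagonal;
#' `"part_articulation"` (requires a [part_mesh()]) moves one seeded rib
#' pair rigidly by `magnitude` while everything else stays fixed -- the
#' failure mode that motivates geodesic rather than Euclidean motion
#' coherence in registration.
#'
#' @param mesh a `trimesh` or `part_mesh`.
#' @param mode one of `"translation"`, `"bend"`, `"part_articulation"`.
#' @param magnitude displacement scale (box units).
#' @param seed integer seed.
#' @return list with elements `mesh` (same class as input),
#'   `displacement` (n x 3 ground-truth per-vertex displacement) and
#'   `moved_part` (for part articulation).
#' @export
deform_known <- function(mesh, mode = c("translation", "bend",
                                        "part_articulation"),
                         magnitude, seed = 0L) {
  mode <- match.arg(mode)
  is_pm <- inherits(mesh, "part_mesh")
  tm <- if (is_pm) mesh$mesh else mesh
  n <- nrow(tm$vertices)
  set.seed(seed)
  moved <- NULL
  if (mode == "translation") {
    d <- stats::rnorm(3)
    d <- d / sqrt(sum(d^2))
    D <- matrix(magnitude * d, n, 3, byrow = TRUE)
  } else if (mode == "bend") {
    diag_len <- bbox_diagonal(tm)
    bb <- mesh_bbox(tm)
    t <- if (bb[2, 3] > bb[1, 3])
      2 * (tm$vertices[, 3] - bb[1, 3]) / (bb[2, 3] - bb[1, 3]) - 1 else
      rep(0, n)
    D <- cbind(magnitude * diag_len * t^2, 0, 0)
  } else {
    if (!is_pm) stop("part_articulation requires a part_mesh")
    ribs <- setdiff(part_names(mesh), "spine")
    if (!length(ribs)) stop("no rib parts to articulate")
    moved <- ribs[1 + (seed %% length(ribs))]
    ids <- part_vertex_ids(mesh, moved)
    ang <- stats::runif(1, 0, 2 * pi)
    d <- c(cos(ang), sin(ang), 0)
    D <- matrix(0, n, 3)
    D[ids, ] <- matrix(magnitude * d, length(ids), 3, byrow = TRUE)
  }
  out <- trimesh(tm$vertices + D, tm$faces, validate = FALSE)
  res_mesh <- if (is_pm) part_mesh(out, mesh$part_of_face, validate = FALSE)
              else out
  list(mesh = res_mesh, displacement = D, moved_part = moved)
}

#' Write / read a part-labelled mesh (PLY + JSON sidecar)
#'
#' The sidecar maps each part name to the 1-based face index range(s)
#' occupied by its faces.
#' @param pm a [part_mesh()].
#' @param path PLY path; the sidecar is written at `<path>.parts.json`.
#' @export
write_part_mesh <- function(pm, path) {
  write_ply(pm$mesh, path)
  r <- rle(pm$part_of_face)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- lapply(seq_along(r$values), function(i)
    list(part = r$values[i], from = starts[i], to = ends[i]))
  jsonlite::write_json(runs, paste0(path, ".parts.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_part_mesh
#' @export
read_part_mesh <- function(path) {
  mesh <- read_ply(path)
  runs <- jsonlite::read_json(paste0(path, ".parts.json"))
  labels <- character(nrow(mesh$faces))
  for (r in runs) labels[r$from:r$to] <- r$part
  part_mesh(mesh, labels, validate = FALSE)
}
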