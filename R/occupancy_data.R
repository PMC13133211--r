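#' Centre and scale a mesh into the unit bounding box
#'
#' Isotropic scaling: the longest axis spans `1 - 2 * padding` and the
#' centroid of the bounding box moves to the origin, so all geometry lies
#' inside the canonical padded cube `[-0.5, 0.5]^3`. The affine transform
#' is returned and invertible.
#'
#' @param mesh a `trimesh`.
#' @param padding fraction of the unit box kept clear on each side
#'   (in `[0, 0.5)`); headroom for isosurface boundary handling.
#' @return list with `mesh` (normalized) and `transform`
#'   (`list(scale, center)` such that `v_norm = scale * (v - center)`).
#' @export
normalize_mesh <- function(mesh, padding = 0.05) {
  if (padding < 0 || padding >= 0.5) stop("padding must lie in [0, 0.5)")
  if (!nrow(mesh$vertices)) stop("empty mesh")
  bb <- mesh_bbox(mesh)
  extent <- bb[2, ] - bb[1, ]
  if (max(extent) <= 0) stop("zero-extent mesh cannot be normalized")
  center <- colMeans(bb)
  scale <- (1 - 2 * padding) / max(extent)
  v <- sweep(mesh$vertices, 2, center, "-") * scale
  list(mesh = trimesh(v, mesh$faces, validate = FALSE),
       transform = list(scale = scale, center = center))
}

#' Invert a normalization transform
#' @param points n x 3 matrix in normalized coordinates.
#' @param transform the `transform` element from [normalize_mesh()].
#' @export
denormalize_points <- function(points, transform) {
  sweep(as.matrix(points) / transform$scale, 2, transform$center, "+")
}

#' Ray-parity inside/outside labels
#'
#' A point is inside iff a ray cast from it crosses the surface an odd
#' number of times. To be robust against rays that graze edges or
#' vertices (which do occur with axis-aligned meshes), each point casts
#' `n_rays` pseudo-random ray directions seeded by `(seed, point index)`
#' and takes a majority vote.
#'
#' @param mesh a watertight `trimesh`.
#' @param points n x 3 matrix of query points.
#' @param n_rays odd number of rays per point.
#' @param seed integer seed for the ray directions.
#' @return integer vector of 0/1 labels.
#' @export
occupancy_labels <- function(mesh, points, n_rays = 3L, seed = 0L) {
  wt <- is_watertight(mesh)
  if (!isTRUE(wt)) {
    oe <- attr(wt, "open_edges")
    stop("occupancy_labels requires a watertight mesh; open edges: ",
         paste(apply(oe, 1, paste, collapse = "-"), collapse = ", "))
  }
  points <- as.matrix(points)
  labels <- integer(nrow(points))
  # quick reject outside the bounding box
  bb <- mesh_bbox(mesh)
  inbox <- points[, 1] >= bb[1, 1] & points[, 1] <= bb[2, 1] &
    points[, 2] >= bb[1, 2] & points[, 2] <= bb[2, 2] &
    points[, 3] >= bb[1, 3] & points[, 3] <= bb[2, 3]
  if (any(inbox)) {
    labels[inbox] <- cpp_ray_parity_labels(mesh$vertices, mesh$faces,
                                           points[inbox, , drop = FALSE],
                                           as.integer(n_rays), as.double(seed))
  }
  labels
}

#' Uniform occupancy supervision pool
#'
#' Samples `n_pool` points uniformly in the padded unit cube
#' `[-0.5, 0.5]^3`, labels them once by ray parity, and supports
#' deterministic `t_batch`-point subsets per training step via
#' [draw_occupancy_batch()]. Sampling covers the whole padded cube (not
#' just the mesh bounding box) so the pool contains negatives near the
#' box boundary.
#'
#' @param mesh a normalized watertight `trimesh`.
#' @param n_pool pool size (default 100,000).
#' @param t_batch default subset size per training example (default 2,048).
#' @param seed integer seed.
#' @param source_id identifier recorded with the pool.
#' @return object of class `occupancy_pool` with elements `points`
#'   (n_pool x 3), `labels`, `t_batch`, `seed`, `source_id`.
#' @export
sample_training_points <- function(mesh, n_pool = 100000L, t_batch = 2048L,
                                   seed = 0L, source_id = "phantom") {
  if (t_batch > n_pool) stop("t_batch must not exceed n_pool")
  set.seed(seed)
  pts <- matrix(stats::runif(3 * n_pool, -0.5, 0.5), ncol = 3)
  labels <- occupancy_labels(mesh, pts, seed = seed)
  structure(list(points = pts, labels = labels, t_batch = as.integer(t_batch),
                 seed = as.integer(seed), source_id = source_id),
            class = "occupancy_pool")
}

#' @export
print.occupancy_pool <- function(x, ...) {
  cat(sprintf("occupancy_pool '%s': %d points, %.1f%% inside, t_batch=%d\n",
              x$source_id, nrow(x$points), 100 * mean(x$labels), x$t_batch))
  invisible(x)
}

#' Deterministic without-replacement subset of a pool
#' @param pool an `occupancy_pool`.
#' @param batch_index integer; the same `(pool seed, batch_index)` always
#'   yields the same subset.
#' @param t_batch subset size (defaults to the pool's `t_batch`).
#' @return list with `points` and `labels`.
#' @export
draw_occupancy_batch <- function(pool, batch_index = 1L, t_batch = NULL) {
  t_batch <- if (is.null(t_batch)) pool$t_batch else as.integer(t_batch)
  n <- nrow(pool$points)
  if (t_batch > n) stop("t_batch must not exceed the pool size")
  set.seed(pool$seed * 1009L + batch_index)
  idx <- sample.int(n, t_batch)
  list(points = pool$points[idx, , drop = FALSE], labels = pool$labels[idx])
}

#' Voxel grids
#'
#' Container for binary occupancy grids and probability grids: `values`
#' is an array, `origin` the world position of the grid corner with index
#' (1,1,1) (voxel grids: corner of the first voxel cube; corner-sampled
#' field grids: position of the first sample), `pitch` the spacing.
#' @param values numeric/logical array.
#' @param origin length-3 world position.
#' @param pitch positive voxel edge length.
#' @param kind `"voxel"` (cell-centred binary) or `"corner"`
#'   (corner-sampled scalar field).
#' @export
voxel_grid <- function(values, origin, pitch, kind = "voxel") {
  if (pitch <= 0) stop("pitch must be positive")
  structure(list(values = values, origin = origin, pitch = pitch,
                 kind = kind), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid (%s): %s, pitch %.4g, origin (%.3g, %.3g, %.3g)\n",
              x$kind, paste(dim(x$values), collapse = " x "), x$pitch,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# voxelization over an arbitrary box; shared by voxelize() and IoU.
# Returns both the conservative mask (interior-or-surface) and the
# volume-faithful interior (centre-inside) mask.
.voxelize_box <- function(mesh, dims, origin, pitch) {
  surf <- cpp_surface_voxels(mesh$vertices, mesh$faces, as.integer(dims),
                             as.double(origin), pitch)
  centers_origin <- origin + pitch / 2
  interior <- cpp_grid_parity(mesh$vertices, mesh$faces, as.integer(dims),
                              as.double(centers_origin), pitch) == 1L
  list(union = array(surf | interior, dim = dims),
       interior = array(interior, dim = dims))
}

#' Binary voxelization of a normalized mesh
#'
#' The occupied mask (`values`) marks a voxel iff its cube intersects the
#' mesh surface or its centre lies inside the mesh -- the conservative
#' convention used for supervision grids. The centre-inside mask, whose
#' occupied volume converges to the mesh volume with error O(pitch), is
#' kept alongside as the `interior` attribute and is what volumetric
#' comparisons (IoU) use.
#' @param mesh a normalized watertight `trimesh` (inside the unit box).
#' @param resolution voxels per axis (default 32).
#' @return a [voxel_grid()] covering `[-0.5, 0.5]^3`.
#' @export
voxelize <- function(mesh, resolution = 32L) {
  if (resolution < 2) stop("resolution must be at least 2")
  wt <- is_watertight(mesh)
  if (!isTRUE(wt)) stop("voxelize requires a watertight mesh")
  pitch <- 1 / resolution
  vals <- .voxelize_box(mesh, rep(as.integer(resolution), 3),
                        rep(-0.5, 3), pitch)
  g <- voxel_grid(vals$union, rep(-0.5, 3), pitch, kind = "voxel")
  attr(g, "interior") <- vals$interior
  g
}

# ------------------------------------------------ pool container IO ---

#' Persist occupancy pools (portable two-file container)
#'
#' Layout (documented so any language can read it): `<stem>.json` holds
#' `{"n", "source_id", "seed", "t_batch", "dtype_points": "float32-le",
#' "dtype_labels": "uint8", "bin": "<stem>.bin"}`; `<stem>.bin` holds the
#' points as `n * 3` little-endian float32 values in row-major order
#' (x, y, z per point) followed by `n` uint8 labels.
#' @param pool an `occupancy_pool`.
#' @param stem output path without extension.
#' @export
write_occupancy_pool <- function(pool, stem) {
  n <- nrow(pool$points)
  meta <- list(n = n, source_id = pool$source_id, seed = pool$seed,
               t_batch = pool$t_batch, dtype_points = "float32-le",
               dtype_labels = "uint8", bin = paste0(basename(stem), ".bin"))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE)
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(pool$points)), con, size = 4, endian = "little")
  writeBin(as.raw(pool$labels), con)
  invisible(stem)
}

#' @rdname write_occupancy_pool
#' @export
read_occupancy_pool <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  con <- file(file.path(dirname(stem), meta$bin), "rb")
  on.exit(close(con))
  pts <- readBin(con, "numeric", n = 3 * meta$n, size = 4, endian = "little")
  labels <- as.integer(readBin(con, "raw", n = meta$n))
  structure(list(points = matrix(pts, ncol = 3, byrow = TRUE),
                 labels = labels, t_batch = meta$t_batch, seed = meta$seed,
                 source_id = meta$source_id), class = "occupancy_pool")
}
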