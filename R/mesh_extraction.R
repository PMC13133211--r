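#' Multiresolution isosurface extraction configuration
#'
#' Extraction starts from a coarse corner-sampled grid, recursively
#' subdivides only "active" voxels (those whose 8 corners are not all on
#' the same side of the threshold, plus their face neighbours), runs
#' marching cubes at the final resolution, then optionally simplifies
#' (quadric edge collapse) and refines vertices along the field
#' gradient.
#'
#' @param init_res initial grid resolution per axis (default 32).
#' @param final_res final resolution; power-of-two multiple of
#'   `init_res` (default 128).
#' @param tau occupancy threshold in (0, 1) (default 0.2, trading a
#'   little over-inclusiveness for completeness of thin structures).
#' @param simplify_faces target face count after simplification
#'   (0 disables).
#' @param refine_steps gradient-refinement iterations (0 disables).
#' @param refine_step_size maximum vertex move per iteration (box
#'   units); defaults to half the final-resolution pitch.
#' @export
mise_config <- function(init_res = 32L, final_res = 128L, tau = 0.2,
                        simplify_faces = 10000L, refine_steps = 0L,
                        refine_step_size = NULL) {
  if (final_res < init_res) stop("final_res must be >= init_res")
  r <- final_res / init_res
  if (abs(log2(r) - round(log2(r))) > 1e-9)
    stop("final_res must be a power-of-two multiple of init_res")
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  if (is.null(refine_step_size)) refine_step_size <- 0.5 / final_res
  structure(list(init_res = as.integer(init_res),
                 final_res = as.integer(final_res), tau = tau,
                 simplify_faces = as.integer(simplify_faces),
                 refine_steps = as.integer(refine_steps),
                 refine_step_size = refine_step_size),
            class = "mise_config")
}

#' Evaluate a field on a corner-sampled grid
#'
#' @param field function mapping an n x 3 matrix to n values.
#' @param resolution cells per axis; corners are sampled, so the value
#'   array has `resolution + 1` entries per axis.
#' @param box lower/upper bound of the cube domain.
#' @return a [voxel_grid()] of kind `"corner"`.
#' @export
evaluate_grid <- function(field, resolution, box = c(-0.5, 0.5)) {
  n <- resolution + 1L
  xs <- seq(box[1], box[2], length.out = n)
  pts <- as.matrix(expand.grid(x = xs, y = xs, z = xs))
  vals <- field(pts)
  voxel_grid(array(vals, c(n, n, n)), rep(box[1], 3),
             (box[2] - box[1]) / resolution, kind = "corner")
}

#' Marching cubes on a corner-sampled grid
#'
#' Isosurface vertices are linearly interpolated onto the threshold
#' crossing along lattice edges and welded exactly by edge identity, so
#' closed isosurfaces yield watertight meshes. Ambiguous faces are
#' resolved by the bilinear asymptotic decider (consistent between
#' neighbouring cells). Faces are oriented outward (enclosing the
#' `value >= tau` region with positive signed volume).
#'
#' @param grid a [voxel_grid()] of kind `"corner"` (values at lattice
#'   points).
#' @param tau threshold.
#' @return a `trimesh` (possibly empty, with a warning, when the field
#'   never crosses `tau`).
#' @export
marching_cubes <- function(grid, tau) {
  vals <- grid$values
  d <- dim(vals)
  if (any(d < 2)) stop("grid must have resolution of at least 2 per axis")
  if (tau <= min(vals) || tau > max(vals)) {
    warning("threshold outside the field's value range; empty mesh")
    return(trimesh(matrix(0, 0, 3), matrix(0L, 0, 3), validate = FALSE))
  }
  res <- cpp_marching_cubes(as.double(vals), as.integer(d),
                            as.double(grid$origin), grid$pitch, tau)
  if (!nrow(res$vertices)) {
    warning("empty isosurface")
    return(trimesh(matrix(0, 0, 3), matrix(0L, 0, 3), validate = FALSE))
  }
  trimesh(res$vertices, res$faces, validate = FALSE)
}

#' Multiresolution isosurface extraction
#'
#' Equivalent to dense marching cubes at `final_res` whenever the
#' isosurface is resolved at `init_res` (no feature thinner than a
#' coarse voxel), but only evaluates the field near the surface. The
#' number of field evaluations is recorded in the `n_queries` attribute;
#' the dense equivalent would use `(final_res + 1)^3`.
#'
#' @param field function mapping an n x 3 matrix to n probabilities.
#' @param config a [mise_config()].
#' @param box domain bounds.
#' @return a `trimesh` with attributes `n_queries` and `tau`.
#' @export
mise_extract <- function(field, config = mise_config(), box = c(-0.5, 0.5)) {
  R <- config$final_res
  tau <- config$tau
  n1 <- R + 1L
  pitch <- (box[2] - box[1]) / R
  vals <- rep(NA_real_, n1^3)
  lin <- function(i, j, k) 1L + i + n1 * (j + n1 * k) # 0-based ijk
  pos_of <- function(idx0) { # 0-based linear -> coordinates
    i <- idx0 %% n1
    j <- (idx0 %/% n1) %% n1
    k <- idx0 %/% (n1 * n1)
    cbind(box[1] + i * pitch, box[1] + j * pitch, box[1] + k * pitch)
  }
  nq <- 0L
  eval_at <- function(lin_idx) {
    todo <- lin_idx[is.na(vals[lin_idx])]
    todo <- unique(todo)
    if (length(todo)) {
      vals[todo] <<- field(pos_of(todo - 1L))
      nq <<- nq + length(todo)
    }
  }

  s <- R %/% config$init_res # current stride
  # coarse lattice
  cidx <- as.matrix(expand.grid(i = seq(0L, R, by = s), j = seq(0L, R, by = s),
                                k = seq(0L, R, by = s)))
  eval_at(lin(cidx[, 1], cidx[, 2], cidx[, 3]))
  # cells at the current level, as 0-based origin indices
  cg <- seq(0L, R - s, by = s)
  cells <- as.matrix(expand.grid(i = cg, j = cg, k = cg))

  corner_off <- function(s) as.matrix(expand.grid(di = c(0L, s), dj = c(0L, s),
                                                  dk = c(0L, s)))
  active_mask <- function(cells, s) {
    off <- corner_off(s)
    any_in <- rep(FALSE, nrow(cells))
    any_out <- rep(FALSE, nrow(cells))
    for (r in seq_len(nrow(off))) {
      v <- vals[lin(cells[, 1] + off[r, 1], cells[, 2] + off[r, 2],
                    cells[, 3] + off[r, 3])]
      any_in <- any_in | (v >= tau)
      any_out <- any_out | (v < tau)
    }
    any_in & any_out
  }

  while (s > 1L) {
    act <- active_mask(cells, s)
    active <- cells[act, , drop = FALSE]
    if (nrow(active)) {
      # include face neighbours before subdivision (guards thin parts)
      nb <- rbind(cbind(active[, 1] - s, active[, 2], active[, 3]),
                  cbind(active[, 1] + s, active[, 2], active[, 3]),
                  cbind(active[, 1], active[, 2] - s, active[, 3]),
                  cbind(active[, 1], active[, 2] + s, active[, 3]),
                  cbind(active[, 1], active[, 2], active[, 3] + s),
                  cbind(active[, 1], active[, 2], active[, 3] - s))
      nb <- nb[nb[, 1] >= 0 & nb[, 2] >= 0 & nb[, 3] >= 0 &
                 nb[, 1] <= R - s & nb[, 2] <= R - s & nb[, 3] <= R - s,
               , drop = FALSE]
      active <- unique(rbind(active, nb))
    }
    if (!nrow(active)) break
    h <- s %/% 2L
    # evaluate the full (stride h) sublattice of each active cell
    off <- as.matrix(expand.grid(di = c(0L, h, s), dj = c(0L, h, s),
                                 dk = c(0L, h, s)))
    pts <- do.call(rbind, lapply(seq_len(nrow(off)), function(r) {
      cbind(active[, 1] + off[r, 1], active[, 2] + off[r, 2],
            active[, 3] + off[r, 3])
    }))
    eval_at(lin(pts[, 1], pts[, 2], pts[, 3]))
    # children become the next level's cells
    ch <- as.matrix(expand.grid(di = c(0L, h), dj = c(0L, h), dk = c(0L, h)))
    cells <- do.call(rbind, lapply(seq_len(nrow(ch)), function(r) {
      cbind(active[, 1] + ch[r, 1], active[, 2] + ch[r, 2],
            active[, 3] + ch[r, 3])
    }))
    s <- h
  }

  # fill unevaluated corners from their coarse ancestor (same side of tau),
  # then close the active set: every final-level cube that straddles tau in
  # the filled array must have all 8 corners truly evaluated, otherwise its
  # triangles could differ from the dense extraction. Iterate until stable.
  fill_na <- function(v) {
    na <- which(is.na(v))
    if (length(na)) {
      s0 <- R %/% config$init_res
      idx0 <- na - 1L
      i <- (idx0 %% n1) %/% s0 * s0
      j <- ((idx0 %/% n1) %% n1) %/% s0 * s0
      k <- (idx0 %/% (n1 * n1)) %/% s0 * s0
      v[na] <- vals[lin(i, j, k)]
    }
    v
  }
  cg1 <- seq(0L, R - 1L)
  fcells <- as.matrix(expand.grid(i = cg1, j = cg1, k = cg1))
  off1 <- corner_off(1L)
  repeat {
    filled <- fill_na(vals)
    any_in <- rep(FALSE, nrow(fcells)); any_out <- any_in
    corner_lin <- matrix(0L, nrow(fcells), 8L)
    for (r in 1:8) {
      li <- lin(fcells[, 1] + off1[r, 1], fcells[, 2] + off1[r, 2],
                fcells[, 3] + off1[r, 3])
      corner_lin[, r] <- li
      v <- filled[li]
      any_in <- any_in | (v >= tau)
      any_out <- any_out | (v < tau)
    }
    strad <- any_in & any_out
    need <- unique(as.vector(corner_lin[strad, , drop = FALSE]))
    need <- need[is.na(vals[need])]
    if (!length(need)) break
    eval_at(need)
  }
  grid <- voxel_grid(array(filled, c(n1, n1, n1)), rep(box[1], 3), pitch,
                     kind = "corner")
  mesh <- marching_cubes(grid, tau)
  if (config$simplify_faces > 0 && nrow(mesh$faces) > config$simplify_faces)
    mesh <- simplify(mesh, config$simplify_faces)
  if (config$refine_steps > 0 && nrow(mesh$vertices))
    mesh <- refine(mesh, field, config$refine_steps,
                   config$refine_step_size, tau = tau)
  attr(mesh, "n_queries") <- nq
  attr(mesh, "tau") <- tau
  mesh
}

#' Quadric edge-collapse simplification
#'
#' Reduces the face count to at most `target_faces` while preserving
#' watertightness (collapses violating the manifold link condition or
#' flipping normals are rejected). The surface deviation introduced is
#' logged in the `hausdorff_est` attribute (sampled estimate).
#'
#' @param mesh a watertight `trimesh`.
#' @param target_faces desired maximum face count.
#' @param max_passes greedy threshold-ramp passes.
#' @return simplified `trimesh`.
#' @export
simplify <- function(mesh, target_faces, max_passes = 100L) {
  if (target_faces >= nrow(mesh$faces)) return(mesh)
  if (target_faces < 4) {
    warning("target below minimum closed surface; clamped to 4")
    target_faces <- 4L
  }
  res <- cpp_simplify(mesh$vertices, mesh$faces, as.integer(target_faces),
                      as.integer(max_passes))
  out <- trimesh(res$vertices, res$faces, validate = FALSE)
  # sampled one-sided deviation estimate, for the log
  n <- min(2000L, nrow(out$vertices))
  if (n > 0 && nrow(mesh$vertices)) {
    nn <- cpp_nn(mesh$vertices, out$vertices[seq_len(n), , drop = FALSE], 2L)
    attr(out, "hausdorff_est") <- max(nn$dist)
  }
  out
}

#' Gradient refinement of isosurface vertices
#'
#' Moves each vertex along the (finite-difference) field gradient toward
#' the `tau` level set with a damped Newton step, capped at
#' `step_size` per iteration; iterations that would increase the mean
#' residual `|field(v) - tau|` back off, so the mean residual is
#' non-increasing.
#'
#' @param mesh a `trimesh` whose vertices lie near the level set.
#' @param field the scalar field.
#' @param steps iteration count.
#' @param step_size maximum move per iteration (box units).
#' @param tau level-set threshold.
#' @param h finite-difference half-step (defaults to `step_size / 2`).
#' @return refined `trimesh`.
#' @export
refine <- function(mesh, field, steps = 30L, step_size = 1 / 256, tau = 0.2,
                   h = NULL) {
  if (steps <= 0 || step_size == 0 || !nrow(mesh$vertices)) return(mesh)
  if (is.null(h)) h <- step_size / 2
  V <- mesh$vertices
  resid <- function(V) abs(field(V) - tau)
  cur <- mean(resid(V))
  scale <- 1.0
  for (it in seq_len(steps)) {
    n <- nrow(V)
    E <- rbind(V + matrix(c(h, 0, 0), n, 3, byrow = TRUE),
               V - matrix(c(h, 0, 0), n, 3, byrow = TRUE),
               V + matrix(c(0, h, 0), n, 3, byrow = TRUE),
               V - matrix(c(0, h, 0), n, 3, byrow = TRUE),
               V + matrix(c(0, 0, h), n, 3, byrow = TRUE),
               V - matrix(c(0, 0, h), n, 3, byrow = TRUE))
    fe <- field(E)
    g <- cbind(fe[1:n] - fe[(n + 1):(2 * n)],
               fe[(2 * n + 1):(3 * n)] - fe[(3 * n + 1):(4 * n)],
               fe[(4 * n + 1):(5 * n)] - fe[(5 * n + 1):(6 * n)]) / (2 * h)
    g2 <- rowSums(g^2)
    if (all(g2 < 1e-20)) {
      warning("zero field gradient everywhere; refine is a no-op")
      break
    }
    f0 <- field(V)
    step <- -(f0 - tau) / pmax(g2, 1e-20) * g * scale
    sn <- sqrt(rowSums(step^2))
    too_big <- sn > step_size
    step[too_big, ] <- step[too_big, ] * (step_size / sn[too_big])
    Vn <- V + step
    newr <- mean(resid(Vn))
    if (newr <= cur + 1e-15) {
      V <- Vn
      cur <- newr
    } else {
      scale <- scale / 2 # back off rather than overshoot
      if (scale < 1e-4) break
    }
  }
  out <- trimesh(V, mesh$faces, validate = FALSE)
  attr(out, "mean_residual") <- cur
  out
}
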