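#' Rigid transforms
#' @param rotation proper orthogonal 3 x 3 matrix.
#' @param translation length-3 vector.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper orthogonal (det = +1)")
  structure(list(rotation = rotation, translation = translation, scale = 1),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param points n x 3 matrix.
#' @param tf a `rigid_transform`.
#' @export
apply_rigid <- function(points, tf) {
  sweep(as.matrix(points) %*% t(tf$rotation), 2, tf$translation, "+")
}

#' Point-to-point iterative closest point
#'
#' Alternates nearest-neighbour correspondence with the least-squares
#' (Kabsch) rotation/translation estimate; the mean correspondence
#' distance is non-increasing and iteration stops at `tol` relative
#' improvement or `max_iter`.
#'
#' @param source,target n x 3 / m x 3 point matrices (at least 3
#'   non-collinear points each).
#' @param max_iter iteration cap.
#' @param tol relative improvement tolerance.
#' @return a [rigid_transform()] mapping source onto target, with
#'   attributes `mean_dist` and `iterations`.
#' @export
icp_rigid <- function(source, target, max_iter = 50L, tol = 1e-8) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) < 3 || nrow(target) < 3)
    stop("ICP needs at least 3 points per set")
  if (min(svd(scale(source, scale = FALSE))$d) < 1e-12 * max(abs(source)))
    stop("degenerate (collinear) source point set")
  # centroid pre-alignment makes pure translations exact and gives the
  # nearest-neighbour step a sane starting correspondence
  Rc <- diag(3); tc <- colMeans(target) - colMeans(source)
  prev <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    S <- sweep(source %*% t(Rc), 2, tc, "+")
    nn <- cpp_nn(target, S, 2L)
    md <- mean(nn$dist)
    corr <- target[nn$idx, , drop = FALSE]
    sc <- colMeans(S); cc <- colMeans(corr)
    H <- crossprod(sweep(S, 2, sc, "-"), sweep(corr, 2, cc, "-"))
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    Rstep <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    tstep <- cc - as.vector(Rstep %*% sc)
    Rc <- Rstep %*% Rc
    tc <- as.vector(Rstep %*% tc) + tstep
    if (it >= max_iter || abs(prev - md) <= tol * max(md, 1e-30)) break
    prev <- md
  }
  out <- rigid_transform(Rc, tc)
  attr(out, "mean_dist") <- md
  attr(out, "iterations") <- it
  out
}

#' Geodesic distances along a mesh's edge graph
#'
#' Shortest-path distances with Euclidean edge weights (polyhedral
#' graph geodesics). Distances across disconnected components (e.g.
#' between separate anatomical parts) are infinite.
#'
#' @param mesh a `trimesh`.
#' @param from optional vertex indices restricting the source set.
#' @return |from| x n distance matrix.
#' @export
geodesic_distances <- function(mesh, from = NULL) {
  if (!is.null(from) && !length(from)) stop("empty source vertex subset")
  F <- mesh$faces
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$vertices) - igraph::vcount(g)))
  if (is.null(from)) from <- seq_len(nrow(mesh$vertices))
  igraph::distances(g, v = from, weights = w, algorithm = "dijkstra")
}

#' Motion-coherence kernels
#'
#' Gaussian kernel `G_ij = exp(-d_ij^2 / (2 beta^2))` on either
#' Euclidean point distances or mesh geodesic distances (the latter
#' decouples parts that are close in space but far along -- or off --
#' the surface: infinite geodesic distance gives exactly zero
#' coupling). Eigenvalues are clipped at zero so the kernel is always
#' positive semi-definite; `k > 0` returns the truncated rank-k
#' spectral factorisation used for large point sets.
#'
#' @param x n x 3 point matrix (Euclidean) or a `trimesh` (geodesic).
#' @param beta kernel width (same units as the points).
#' @param type `"euclidean"` or `"geodesic"`.
#' @param k low-rank order (0 = full kernel; clamped to n).
#' @return list of class `coherence_kernel` with either `G` (full) or
#'   `Q`, `lambda` (rank-k factors, `G ~ Q diag(lambda) Q'`).
#' @export
build_kernel <- function(x, beta, type = c("euclidean", "geodesic"), k = 0L) {
  type <- match.arg(type)
  if (beta <= 0) stop("beta must be positive")
  if (type == "geodesic") {
    if (!is.trimesh(x)) stop("geodesic kernel needs a trimesh")
    d <- geodesic_distances(x)
    n <- nrow(d)
  } else {
    pts <- if (is.trimesh(x)) x$vertices else as.matrix(x)
    n <- nrow(pts)
    d <- as.matrix(stats::dist(pts))
  }
  G <- exp(-(d / beta)^2 / 2)
  G[!is.finite(d)] <- 0
  G <- (G + t(G)) / 2
  if (k > n) k <- n
  eg <- eigen(G, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (k > 0) {
    structure(list(Q = eg$vectors[, seq_len(k), drop = FALSE],
                   lambda = ev[seq_len(k)], n = n, beta = beta, type = type,
                   rank = as.integer(k)), class = "coherence_kernel")
  } else {
    structure(list(G = eg$vectors %*% (ev * t(eg$vectors)), n = n,
                   beta = beta, type = type, rank = 0L),
              class = "coherence_kernel")
  }
}

# kernel-vector products and full materialisation
.kernel_mat <- function(K) {
  if (K$rank > 0) K$Q %*% (K$lambda * t(K$Q)) else K$G
}

#' Non-rigid coherent point drift
#'
#' The source points act as Gaussian-mixture centroids drifting toward
#' the target: the E-step computes responsibilities under an isotropic
#' GMM with a uniform outlier component of weight `w`; the M-step
#' solves the coherence-regularised linear system for the displacement
#' coefficients (`lambda` weighting the kernel norm) and re-estimates
#' the mixture variance `sigma2`. The negative log-likelihood is
#' tracked per iteration and is non-increasing (up to numerical
#' tolerance) on well-posed problems.
#'
#' @param source a watertight `trimesh` (faces carried through) or an
#'   n x 3 point matrix.
#' @param target m x 3 matrix of target points.
#' @param beta kernel width in units of the source's RMS radius (root
#'   mean squared distance to the centroid), the canonical CPD scaling:
#'   the coherence length must be commensurate with the shape, not with
#'   the mesh tessellation, or the field degenerates to per-point motion
#'   that overfits outliers.
#' @param lambda coherence regularisation weight.
#' @param w outlier weight in [0, 1).
#' @param max_iter,tol EM iteration cap and relative NLL tolerance.
#' @param kernel `"euclidean"` or `"geodesic"`.
#' @param K optionally a precomputed [build_kernel()] result.
#' @param k low-rank order used when the source is large (0 = auto:
#'   rank 50 above 800 points).
#' @return list of class `deformation_field`: `displacement` (n x 3),
#'   `mesh` (deformed source, when the source was a mesh), `sigma2`,
#'   `nll` (per-iteration trace), `converged`, plus the
#'   hyper-parameters.
#' @export
cpd_nonrigid <- function(source, target, beta = 2.0, lambda = 2.0, w = 0.1,
                         max_iter = 100L, tol = 1e-5,
                         kernel = c("euclidean", "geodesic"), K = NULL,
                         k = 0L, sigma2 = NULL) {
  kernel <- match.arg(kernel)
  is_mesh <- is.trimesh(source)
  Y <- if (is_mesh) source$vertices else as.matrix(source)
  X <- as.matrix(target)
  if (!nrow(Y) || !nrow(X)) stop("source and target must be non-empty")
  M <- nrow(Y); N <- nrow(X)
  rms <- sqrt(mean(rowSums(sweep(Y, 2, colMeans(Y), "-")^2)))
  beta_abs <- beta * max(rms, 1e-12)
  if (is.null(K)) {
    if (k <= 0 && M > 800) k <- 50L
    K <- build_kernel(if (kernel == "geodesic") source else Y, beta_abs,
                      type = kernel, k = k)
  }
  G <- .kernel_mat(K)

  W <- matrix(0, M, 3)
  TY <- Y
  if (is.null(sigma2))
    sigma2 <- sum(outer(rowSums(X^2), rep(1, M)) +
                    outer(rep(1, N), rowSums(Y^2)) -
                    2 * X %*% t(Y)) / (3 * M * N)
  nll_trace <- numeric(0)
  converged <- FALSE
  x2 <- rowSums(X^2)
  for (it in seq_len(max_iter)) {
    # E-step: responsibilities P (M x N)
    d2 <- outer(rowSums(TY^2), rep(1, N)) + outer(rep(1, M), x2) -
      2 * TY %*% t(X)
    num <- exp(-d2 / (2 * sigma2))
    cden <- (2 * pi * sigma2)^1.5 * w * M / ((1 - w) * N)
    den <- colSums(num) + cden
    nll <- -sum(log(den * (1 - w) / M / (2 * pi * sigma2)^1.5))
    nll_trace <- c(nll_trace, nll)
    P <- sweep(num, 2, den, "/")
    P1 <- rowSums(P)
    Np <- sum(P1)
    PX <- P %*% X
    # M-step: (diag(P1) G + lambda sigma2 I) W = PX - diag(P1) Y
    B <- PX - P1 * Y
    c0 <- lambda * sigma2
    if (K$rank > 0) { # Woodbury with G = Q diag(lam) Q'
      U <- P1 * K$Q
      Mi <- diag(c0 / K$lambda, K$rank) + t(K$Q) %*% U
      W <- (B - U %*% solve(Mi, t(K$Q) %*% B)) / c0
    } else {
      A <- P1 * G
      diag(A) <- diag(A) + c0
      W <- solve(A, B)
    }
    TY <- Y + G %*% W
    s2new <- (sum(colSums(P) * x2) - 2 * sum(PX * TY) +
                sum(P1 * rowSums(TY^2))) / (3 * Np)
    sigma2 <- max(s2new, 1e-12)
    if (sigma2 <= 1e-10) { converged <- TRUE; break }
    if (it > 1) {
      d <- abs(nll_trace[it - 1] - nll)
      if (d <= tol * max(abs(nll), 1)) { converged <- TRUE; break }
    }
  }
  disp <- G %*% W
  out <- list(displacement = disp, sigma2 = sigma2, nll = nll_trace,
              converged = converged, beta = beta, lambda = lambda, w = w,
              kernel_type = K$type, rank = K$rank)
  if (is_mesh)
    out$mesh <- trimesh(Y + disp, source$faces, validate = FALSE)
  else out$points <- Y + disp
  class(out) <- "deformation_field"
  out
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("deformation_field: %d vertices, %s kernel (rank %d), %d EM iters, sigma2 %.3g%s\n",
              nrow(x$displacement), x$kernel_type, x$rank, length(x$nll),
              x$sigma2, if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Geodesic-kernel CPD for part-labelled templates
#'
#' Registers an assembled template (source) onto the coarse
#' reconstruction (target) with motion coherence measured along the
#' template surface: geodesic distance is infinite between disconnected
#' parts, so the kernel decouples them exactly, letting one rib pair
#' move without dragging its spatial neighbours -- while each part
#' still deforms smoothly. The template topology is preserved.
#'
#' @param template a [part_mesh()] whose parts are each connected.
#' @param target m x 3 matrix (vertices of the coarse mesh) or a
#'   `trimesh`.
#' @param beta,lambda,w,max_iter,tol,k as in [cpd_nonrigid()].
#' @param pre_align run [icp_rigid()] before the non-rigid EM.
#' @param strict error when a part is not a single connected surface.
#'   Off by default: anatomical stand-ins legitimately use parts made of
#'   several closed components (a capsule stack for the spine, two arcs
#'   per rib pair), and the geodesic kernel simply treats each component
#'   as its own coherence unit.
#' @return a `deformation_field` whose `mesh` keeps the template's
#'   vertex count and face list (plus `part_of_face` carried through in
#'   `parts`).
#' @export
gbcpd_nonrigid <- function(template, target, beta = 2.0, lambda = 2.0,
                           w = 0.1, max_iter = 100L, tol = 1e-5, k = 0L,
                           pre_align = TRUE, strict = FALSE, sigma2 = NULL) {
  if (!inherits(template, "part_mesh")) stop("template must be a part_mesh")
  if (strict) {
    for (p in part_names(template)) {
      sub <- part_submesh(template, p)
      d <- geodesic_distances(sub, from = 1L)
      if (any(!is.finite(d)))
        stop("disconnected template part: ", p)
    }
  }
  tm <- template$mesh
  X <- if (is.trimesh(target)) target$vertices else as.matrix(target)
  if (pre_align) {
    tf <- icp_rigid(tm$vertices, X)
    tm <- trimesh(apply_rigid(tm$vertices, tf), tm$faces, validate = FALSE)
  }
  if (is.null(sigma2)) {
    # source and target are rigidly pre-aligned here, so initialise the
    # mixture variance at the residual correspondence scale instead of
    # the full pairwise spread: the wide default lets curve-like parts
    # slide tangentially along themselves during annealing
    nn <- cpp_nn(X, tm$vertices, 2L)
    rms <- sqrt(mean(rowSums(sweep(tm$vertices, 2,
                                   colMeans(tm$vertices), "-")^2)))
    sigma2 <- mean(nn$dist^2) + (0.05 * rms)^2
  }
  res <- cpd_nonrigid(tm, X, beta = beta, lambda = lambda, w = w,
                      max_iter = max_iter, tol = tol, kernel = "geodesic",
                      k = k, sigma2 = sigma2)
  res$parts <- template$part_of_face
  res
}

#' Assemble a template from detected parts
#'
#' Extracts the union sub-mesh of exactly the named parts from a part
#' library, preserving labels -- the stand-in for building a
#' subject-specific template from 2D detections.
#'
#' @param library a [part_mesh()] holding all parts.
#' @param parts character vector of detected part names (non-empty).
#' @return a [part_mesh()] restricted to `parts`.
#' @export
assemble_template <- function(library, parts) {
  if (!length(parts)) stop("empty detection list: no parts to assemble")
  unknown <- setdiff(parts, part_names(library))
  if (length(unknown)) stop("unknown part name(s): ",
                            paste(unknown, collapse = ", "))
  keep <- library$part_of_face %in% parts
  F <- library$mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(library$mesh$vertices))
  remap[used] <- seq_along(used)
  part_mesh(trimesh(library$mesh$vertices[used, , drop = FALSE],
                    matrix(remap[F], ncol = 3)),
            library$part_of_face[keep], validate = FALSE)
}
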