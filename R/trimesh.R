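#' Triangle mesh objects
#'
#' A `trimesh` is the universal currency between pipeline stages: a list
#' with an `n x 3` numeric `vertices` matrix and an `m x 3` integer
#' `faces` matrix (1-based, counter-clockwise when viewed from outside,
#' so the signed volume of a closed mesh is positive).
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates.
#' @param faces m x 3 integer matrix of vertex indices (1-based).
#' @param validate check index bounds and degenerate faces.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (validate && nrow(faces)) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
              faces[, 1] == faces[, 3]))
      stop("degenerate faces (repeated vertex index)")
  }
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- mesh_bbox(x)
  cat(sprintf("  bbox [%.3g, %.3g] x [%.3g, %.3g] x [%.3g, %.3g]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' @export
is.trimesh <- function(x) inherits(x, "trimesh")

#' Axis-aligned bounding box
#' @param mesh a `trimesh`.
#' @return 2 x 3 matrix, rows = (min, max).
#' @export
mesh_bbox <- function(mesh) {
  rbind(apply(mesh$vertices, 2, min), apply(mesh$vertices, 2, max))
}

#' @rdname mesh_bbox
#' @export
bbox_diagonal <- function(mesh) {
  bb <- mesh_bbox(mesh)
  sqrt(sum((bb[2, ] - bb[1, ])^2))
}

#' Signed volume of a closed mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for
#' consistently outward-oriented watertight meshes.
#' @param mesh a `trimesh`.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
        a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
        a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Per-face unit normals and areas
#' @param mesh a `trimesh`.
#' @return list with `normals` (m x 3) and `areas` (length m).
#' @export
face_normals <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  list(normals = n / pmax(len, 1e-300), areas = len / 2)
}

# directed edge keys for watertightness / Euler computations
.edge_keys <- function(faces, nv) {
  fr <- c(faces[, 1], faces[, 2], faces[, 3])
  to <- c(faces[, 2], faces[, 3], faces[, 1])
  list(from = fr, to = to,
       directed = (fr - 1) * as.double(nv) + to,
       undirected = (pmin(fr, to) - 1) * as.double(nv) + pmax(fr, to))
}

#' Watertightness check
#'
#' A mesh is watertight when every undirected edge is shared by exactly
#' two faces and every directed edge appears exactly once (consistent
#' orientation). Disjoint unions of closed components count as
#' watertight.
#' @param mesh a `trimesh`.
#' @return logical; attribute `open_edges` lists offending edges.
#' @export
is_watertight <- function(mesh) {
  if (!nrow(mesh$faces)) return(FALSE)
  ek <- .edge_keys(mesh$faces, nrow(mesh$vertices))
  und <- table(ek$undirected)
  dir_dup <- anyDuplicated(ek$directed) > 0
  bad <- und != 2
  ok <- !any(bad) && !dir_dup
  if (!ok) {
    keys <- as.double(names(und)[bad])
    nv <- nrow(mesh$vertices)
    open <- cbind(floor((keys - 1) / nv) + 1, (keys - 1) %% nv + 1)
    attr(ok, "open_edges") <- utils::head(open, 20)
  }
  ok
}

#' Euler characteristic (V - E + F)
#' @param mesh a `trimesh`.
#' @export
mesh_euler <- function(mesh) {
  ek <- .edge_keys(mesh$faces, nrow(mesh$vertices))
  nE <- length(unique(ek$undirected))
  nV <- length(unique(as.vector(mesh$faces)))
  nV - nE + nrow(mesh$faces)
}

#' Validate the full trimesh invariant set
#'
#' Errors unless the mesh is watertight, consistently oriented with
#' positive signed volume, and free of zero-area faces.
#' @param mesh a `trimesh`.
#' @export
mesh_check <- function(mesh) {
  wt <- is_watertight(mesh)
  if (!wt) {
    oe <- attr(wt, "open_edges")
    stop("mesh is not watertight; offending edges (vertex pairs): ",
         paste(apply(oe, 1, paste, collapse = "-"), collapse = ", "))
  }
  if (mesh_volume(mesh) <= 0) stop("mesh orientation is inverted (signed volume <= 0)")
  fa <- face_normals(mesh)$areas
  if (any(fa < 1e-14)) stop("mesh has zero-area faces")
  invisible(TRUE)
}

#' Merge meshes into one (disjoint union)
#' @param meshes list of `trimesh` objects.
#' @export
merge_meshes <- function(meshes) {
  off <- 0L
  vs <- list(); fs <- list()
  for (m in meshes) {
    vs[[length(vs) + 1L]] <- m$vertices
    fs[[length(fs) + 1L]] <- m$faces + off
    off <- off + nrow(m$vertices)
  }
  trimesh(do.call(rbind, vs), do.call(rbind, fs))
}

#' Apply an affine map to a mesh
#' @param mesh a `trimesh`.
#' @param rotation 3 x 3 matrix (default identity).
#' @param translation length-3 offset.
#' @param scale scalar.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1) {
  v <- scale * (mesh$vertices %*% t(rotation))
  v <- sweep(v, 2, translation, "+")
  trimesh(v, mesh$faces, validate = FALSE)
}

# ---------------------------------------------------------------- IO ---

#' Read and write meshes (PLY and OBJ)
#'
#' `write_ply` writes ASCII or binary little-endian PLY; `read_ply` reads
#' both. OBJ support covers `v`/`f` records only.
#' @param mesh a `trimesh`.
#' @param path file path.
#' @param binary write binary little-endian PLY.
#' @export
write_ply <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  fmt <- if (binary) "binary_little_endian" else "ascii"
  hdr <- c("ply", paste("format", fmt, "1.0"),
           paste("element vertex", nv),
           "property float x", "property float y", "property float z",
           paste("element face", nf),
           "property list uchar int vertex_indices", "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 4, endian = "little")
    # per face: uchar 3 then three int32
    F0 <- mesh$faces - 1L
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(F0[i, ], con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(format(mesh$vertices, digits = 9, trim = TRUE,
                              scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- readLines(con, 1)
    hdr <- c(hdr, ln)
    if (ln == "end_header") break
  }
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  binary <- any(grepl("binary_little_endian", hdr))
  if (binary) {
    v <- readBin(con, "numeric", n = 3 * nv, size = 4, endian = "little")
    V <- matrix(v, ncol = 3, byrow = TRUE)
    F <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", 1))
      idx <- readBin(con, "integer", n = cnt, size = 4, endian = "little")
      F[i, ] <- idx[1:3] + 1L
    }
  } else {
    vl <- readLines(con, nv)
    V <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                               function(x) as.numeric(x[1:3])))
    fl <- readLines(con, nf)
    F <- do.call(rbind, lapply(strsplit(fl, "\\s+"),
                               function(x) as.integer(x[2:4]) + 1L))
  }
  trimesh(V, F)
}

#' @rdname write_ply
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_obj <- function(path) {
  ln <- readLines(path)
  vl <- grep("^v ", ln, value = TRUE)
  fl <- grep("^f ", ln, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                             function(x) as.numeric(x[2:4])))
  F <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
    as.integer(sub("/.*", "", x[2:4]))
  }))
  trimesh(V, F)
}
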