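#' Synthetic radiograph rendering (parallel beam)
#'
#' Orthographic ray casting through a watertight mesh with binary unit
#' density: each pixel accumulates the chord length of its ray through
#' the mesh interior (exact for watertight meshes -- crossing depths are
#' sorted and paired, no volume sampling). The displayed intensity is
#' `1 - L / L_max` with `L_max` the box diagonal, so bone appears bright
#' on a white-to-dark scale, mimicking a radiograph.
#'
#' Geometry: rays travel along the viewing direction obtained by
#' rotating the +y axis by `angle` degrees about the vertical z axis;
#' `angle = 0` is the anterior-posterior view. The image is square over
#' the unit box: horizontal axis `u` along the rotated x axis, vertical
#' axis along z (first matrix index = u, second = z, both increasing).
#'
#' @param mesh a normalized watertight `trimesh` (inside the unit box).
#' @param angle view angle in degrees, `[0, 360)`.
#' @param size image side in pixels (default 224, the model input size).
#' @param rays_per_pixel supersampling factor per axis (1 = one central
#'   ray per pixel).
#' @return object of class `projection_image`: `pixels` (size x size in
#'   `[0, 1]`), `raw` (chord lengths, box units), `view_angle`,
#'   `geometry = "parallel"`, `source_id`.
#' @export
render_projection <- function(mesh, angle = 0, size = 224L,
                              rays_per_pixel = 1L, source_id = "mesh") {
  wt <- is_watertight(mesh)
  if (!isTRUE(wt)) stop("render_projection requires a watertight mesh")
  angle <- angle %% 360
  th <- angle * pi / 180
  e_u <- c(cos(th), sin(th), 0)      # image horizontal axis
  e_d <- c(-sin(th), cos(th), 0)     # ray direction (view axis)
  ss <- as.integer(rays_per_pixel)
  n <- size * ss
  # sub-pixel centres in [-0.5, 0.5]; tiny offset avoids symmetry grazing
  uu <- (seq_len(n) - 0.5) / n - 0.5 + 1.3e-7
  ww <- (seq_len(n) - 0.5) / n - 0.5 + 0.7e-7
  g <- expand.grid(u = uu, w = ww)
  O <- outer(g$u, e_u) + cbind(0, 0, g$w) - matrix(e_d, nrow(g), 3, byrow = TRUE)
  D <- matrix(e_d, nrow(g), 3, byrow = TRUE)
  chord <- cpp_ray_chords(mesh$vertices, mesh$faces, O, D)
  raw <- matrix(chord, n, n) # [u, w]
  if (ss > 1L) { # average ss x ss blocks
    raw <- apply(array(raw, c(ss, size, ss, size)), c(2, 4), mean)
  }
  pixels <- 1 - raw / sqrt(3)
  structure(list(pixels = pixels, raw = raw, view_angle = angle,
                 geometry = "parallel", size = as.integer(size),
                 source_id = source_id), class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("projection_image '%s': %d x %d, angle %.1f deg, %s beam\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels), x$view_angle,
              x$geometry))
  invisible(x)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Classic CLAHE: the image is divided into `tiles x tiles` regions, a
#' clipped histogram equalization mapping is computed per tile (excess
#' counts redistributed uniformly), and each pixel is remapped by
#' bilinear interpolation between the four surrounding tile mappings.
#' Intensities stay in `[0, 1]`; within one tile the mapping is
#' monotone, so local rank order is preserved.
#'
#' @param image a `projection_image` (or plain matrix in `[0, 1]`).
#' @param clip_limit histogram clip limit as a multiple of the mean bin
#'   count (typical 2-4).
#' @param tiles number of tiles per axis.
#' @param bins histogram resolution.
#' @return same type as `image`, contrast-enhanced.
#' @export
clahe <- function(image, clip_limit = 2.0, tiles = 8L, bins = 256L) {
  is_pi <- inherits(image, "projection_image")
  px <- if (is_pi) image$pixels else image
  n <- nrow(px)
  if (tiles > n) stop("tiles must not exceed the image size")
  if (clip_limit <= 0) stop("clip_limit must be positive")
  # tile index boundaries
  bounds <- round(seq(0, n, length.out = tiles + 1))
  centers <- (bounds[-1] + bounds[-(tiles + 1)]) / 2 # in pixel units
  q <- pmin(pmax(floor(px * bins), 0), bins - 1) # bin index 0..bins-1
  # per-tile clipped-CDF mapping: bins -> [0, 1]
  maps <- array(0, c(tiles, tiles, bins))
  for (ti in seq_len(tiles)) {
    for (tj in seq_len(tiles)) {
      sub <- q[(bounds[ti] + 1):bounds[ti + 1],
               (bounds[tj] + 1):bounds[tj + 1]]
      h <- tabulate(as.vector(sub) + 1L, nbins = bins)
      npix <- length(sub)
      clip <- max(1, clip_limit * npix / bins)
      excess <- sum(pmax(h - clip, 0))
      h <- pmin(h, clip) + excess / bins
      cdf <- cumsum(h) / npix
      maps[ti, tj, ] <- cdf
    }
  }
  # bilinear interpolation between tile mappings
  ij <- as.matrix(expand.grid(i = seq_len(n), j = seq_len(n)))
  tpos_i <- approx(centers, seq_len(tiles), xout = ij[, 1] - 0.5,
                   rule = 2)$y
  tpos_j <- approx(centers, seq_len(tiles), xout = ij[, 2] - 0.5,
                   rule = 2)$y
  i0 <- pmin(floor(tpos_i), tiles - 1); i0 <- pmax(i0, 1)
  j0 <- pmin(floor(tpos_j), tiles - 1); j0 <- pmax(j0, 1)
  fi <- pmin(pmax(tpos_i - i0, 0), 1)
  fj <- pmin(pmax(tpos_j - j0, 0), 1)
  b <- as.vector(q) + 1L
  idx <- function(ti, tj) maps[cbind(ti, tj, b)]
  out <- (1 - fi) * (1 - fj) * idx(i0, j0) + fi * (1 - fj) * idx(i0 + 1, j0) +
    (1 - fi) * fj * idx(i0, j0 + 1) + fi * fj * idx(i0 + 1, j0 + 1)
  out <- matrix(pmin(pmax(out, 0), 1), n, n)
  if (is_pi) {
    image$pixels <- out
    image
  } else out
}

#' Forward-project per-part 2D bounding boxes
#'
#' Ground-truth stand-in for a 2D detector: each part's vertices are
#' projected with the same parallel geometry as [render_projection()]
#' and the tight axis-aligned bounds are returned in normalized image
#' coordinates (y increasing downward, as in detector formats).
#' Translating a part along the view axis leaves its box unchanged.
#'
#' @param pmesh a [part_mesh()] (normalized).
#' @param angle view angle in degrees.
#' @param size nominal image side in pixels (default 512, the detection
#'   image size; boxes are normalized so this only sets provenance).
#' @return data frame with columns `part`, `center_x`, `center_y`,
#'   `width`, `height` (all in `[0, 1]`).
#' @export
project_part_bboxes <- function(pmesh, angle = 0, size = 512L) {
  th <- (angle %% 360) * pi / 180
  e_u <- c(cos(th), sin(th), 0)
  out <- list()
  for (p in part_names(pmesh)) {
    ids <- part_vertex_ids(pmesh, p)
    if (!length(ids)) {
      warning("part has no faces, skipped: ", p)
      next
    }
    V <- pmesh$mesh$vertices[ids, , drop = FALSE]
    u <- as.vector(V %*% e_u) + 0.5
    v <- 0.5 - V[, 3] # image y grows downward
    out[[length(out) + 1L]] <- data.frame(
      part = p, center_x = mean(range(u)), center_y = mean(range(v)),
      width = diff(range(u)), height = diff(range(v)))
  }
  res <- do.call(rbind, out)
  attr(res, "size") <- as.integer(size)
  attr(res, "view_angle") <- angle %% 360
  res
}

#' Write an image as 16-bit PGM; write boxes in detector text format
#'
#' PGM (portable graymap, `P2`/`P5`) stands in for PNG here: it is an
#' equally standard single-channel format with no external encoder
#' dependency. Boxes are written one per line as
#' `<class index> <center_x> <center_y> <width> <height>` with a JSON
#' class map alongside.
#' @param image a `projection_image` or matrix in `[0, 1]`.
#' @param path output path (`.pgm`).
#' @param ascii write plain-text `P2` instead of binary `P5`.
#' @export
write_pgm <- function(image, path, ascii = FALSE) {
  px <- if (inherits(image, "projection_image")) image$pixels else image
  v <- round(pmin(pmax(t(px[, ncol(px):1]), 0), 1) * 65535) # row-major, top row first
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(nrow(px), ncol(px)), "65535"), con)
    write(as.integer(t(v)), con, ncolumns = 16)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(nrow(px), ncol(px)), "65535"), con)
    # PGM 16-bit is big-endian
    writeBin(as.integer(as.vector(t(v))), con, size = 2, endian = "big")
  }
  invisible(path)
}

#' @rdname write_pgm
#' @param boxes data frame from [project_part_bboxes()].
#' @param stem output stem; writes `<stem>.txt` and `<stem>.classes.json`.
#' @export
write_boxes <- function(boxes, stem) {
  classes <- unique(boxes$part)
  cls <- match(boxes$part, classes) - 1L
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", cls, boxes$center_x,
                   boxes$center_y, boxes$width, boxes$height)
  writeLines(lines, paste0(stem, ".txt"))
  jsonlite::write_json(as.list(stats::setNames(seq_along(classes) - 1L, classes)),
                       paste0(stem, ".classes.json"), auto_unbox = TRUE)
  invisible(stem)
}
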