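#' Default end-to-end run configuration
#'
#' A nested configuration covering every pipeline stage; every
#' stochastic stage derives its own seed from the global `seed`, the
#' snapshot is written to the run directory, and all artifact hashes go
#' into the manifest, so a run is reproducible from its config alone.
#' The defaults are a desk-scale smoke setting (8 phantoms, 64 px
#' images, tiny network); raise the sizes for a full run.
#'
#' @param seed global seed.
#' @param out_dir output directory.
#' @return nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("skelrec_run_")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    phantoms = list(n = 8L, kinds = c("ellipsoid", "capsule", "sphere"),
                    resolution = 3L),
    occupancy = list(n_pool = 20000L, t_batch = 256L),
    projection = list(size = 64L, angle = 0, clahe = FALSE,
                      train_angles = c(0, 45, 90, 135, 180, 225, 270, 315)),
    model = list(img_size = 64L, enc_widths = c(8L, 16L, 32L, 48L),
                 c_dim = 64L, h_dim = 64L, n_blocks = 5L, z_dim = 8L,
                 q_dim = 16L),
    train = list(lr = 1.5e-3, lr_final = 2e-4, t_points = 256L,
                 epochs = 2000L, batch_size = 0L),
    split = list(train = 0.7, val = 0.15, test = 0.15),
    extraction = list(init_res = 16L, final_res = 64L, tau = 0.2,
                      simplify_faces = 10000L, refine_steps = 0L),
    registration = list(beta = 2, lambda = 2, w = 0.1, max_iter = 100L,
                        tol = 1e-5, kernel = "geodesic",
                        drop_part_prob = 0),
    metrics = list(n_samples = 20000L, pitch = 1 / 64, t = 0.02)
  ), class = "run_config")
}

#' Read / write run configurations (JSON)
#' @param config a `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  for (nm in names(x)) {
    if (is.list(base[[nm]]) && is.list(x[[nm]]))
      base[[nm]][names(x[[nm]])] <- x[[nm]]
    else base[[nm]] <- x[[nm]]
  }
  base
}

# seeded phantom spec for slot i of a run
.phantom_spec <- function(cfg, i) {
  set.seed(cfg$seed * 1000L + i)
  kinds <- cfg$phantoms$kinds
  k <- kinds[1 + (i - 1) %% length(kinds)]
  res <- cfg$phantoms$resolution
  switch(k,
    sphere = primitive_spec("sphere", radius = stats::runif(1, 0.22, 0.42),
                            center = c(stats::runif(2, -0.06, 0.06),
                                       stats::runif(1, -0.15, 0.15)),
                            resolution = res),
    ellipsoid = primitive_spec("ellipsoid",
                               radii = stats::runif(3, 0.16, 0.44),
                               center = c(stats::runif(2, -0.05, 0.05),
                                          stats::runif(1, -0.1, 0.1)),
                               resolution = res),
    capsule = {
      ax <- stats::rnorm(3)
      ax <- ax / sqrt(sum(ax^2)) * stats::runif(1, 0.18, 0.3)
      primitive_spec("capsule", radius = stats::runif(1, 0.1, 0.18),
                     a = -ax, b = ax, resolution = res)
    },
    torus = primitive_spec("torus", ring_radius = stats::runif(1, 0.22, 0.3),
                           tube_radius = stats::runif(1, 0.06, 0.12),
                           resolution = res))
}

.manifest_add <- function(manifest, path, role) {
  manifest[[length(manifest) + 1L]] <-
    list(path = path, role = role, md5 = unname(tools::md5sum(path)))
  manifest
}

#' End-to-end coarse reconstruction run
#'
#' Phantoms -> occupancy pools -> projections -> network training ->
#' field inference -> multiresolution extraction -> metric reports,
#' split train/val/test at the phantom level. Writes meshes (PLY),
#' images (PGM), per-phantom metric reports and a manifest with MD5
#' hashes to `config$out_dir`.
#'
#' @param config a [default_config()]-style `run_config`.
#' @param quiet suppress progress messages.
#' @return list with `model`, `log`, `reports` (per phantom),
#'   `split`, `meshes` (reconstructed), `gt` (ground-truth meshes),
#'   `dataset`, `manifest_path`.
#' @export
run_x2b <- function(config = default_config(), quiet = FALSE) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(cfg, file.path(cfg$out_dir, "config.json"))
  manifest <- list()
  say <- function(...) if (!quiet) message(sprintf(...))

  n <- cfg$phantoms$n
  say("[phantoms] generating %d phantoms", n)
  specs <- lapply(seq_len(n), function(i) .phantom_spec(cfg, i))
  gt <- lapply(specs, make_primitive)
  say("[data] pools (%d points) and projections (%d px)",
      cfg$occupancy$n_pool, cfg$projection$size)
  dataset <- lapply(seq_len(n), function(i) {
    id <- sprintf("phantom_%02d", i)
    img <- render_projection(gt[[i]], cfg$projection$angle,
                             size = cfg$projection$size, source_id = id)
    if (isTRUE(cfg$projection$clahe)) img <- clahe(img)
    pool <- sample_training_points(gt[[i]], n_pool = cfg$occupancy$n_pool,
                                   t_batch = cfg$occupancy$t_batch,
                                   seed = cfg$seed * 100L + i,
                                   source_id = id)
    list(image = img, pool = pool, id = id)
  })
  for (i in seq_len(n)) {
    mp <- file.path(cfg$out_dir, sprintf("%s_gt.ply", dataset[[i]]$id))
    write_ply(gt[[i]], mp)
    manifest <- .manifest_add(manifest, mp, "gt_mesh")
    ip <- file.path(cfg$out_dir, sprintf("%s.pgm", dataset[[i]]$id))
    write_pgm(dataset[[i]]$image, ip)
    manifest <- .manifest_add(manifest, ip, "projection")
  }

  # phantom-level split
  set.seed(cfg$seed)
  perm <- sample(n)
  n_train <- max(1L, round(cfg$split$train * n))
  n_val <- min(n - n_train, max(0L, round(cfg$split$val * n)))
  split <- list(train = perm[seq_len(n_train)],
                val = if (n_val > 0) perm[n_train + seq_len(n_val)] else integer(0),
                test = if (n_train + n_val < n)
                  perm[(n_train + n_val + 1):n] else integer(0))

  say("[train] %d epochs on %d phantoms", cfg$train$epochs, n_train)
  mcfg <- do.call(occ_config, cfg$model)
  model0 <- occ_model(mcfg, seed = cfg$seed)
  tc <- train_config(lr = cfg$train$lr, lr_final = cfg$train$lr_final,
                     t_points = cfg$train$t_points,
                     epochs = cfg$train$epochs,
                     batch_size = cfg$train$batch_size, seed = cfg$seed)
  tr <- train(dataset, tc, model = model0, val_idx = split$val)
  save_occ_model(tr$model, file.path(cfg$out_dir, "model"))
  manifest <- .manifest_add(manifest, file.path(cfg$out_dir, "model.json"),
                            "model_config")

  say("[extract+evaluate] %d phantoms", n)
  mise <- mise_config(init_res = cfg$extraction$init_res,
                      final_res = cfg$extraction$final_res,
                      tau = cfg$extraction$tau,
                      simplify_faces = cfg$extraction$simplify_faces,
                      refine_steps = cfg$extraction$refine_steps)
  meshes <- vector("list", n)
  reports <- vector("list", n)
  for (i in seq_len(n)) {
    f <- infer_field(dataset[[i]]$image, tr$model)
    rec <- mise_extract(f, mise)
    meshes[[i]] <- rec
    if (nrow(rec$faces)) {
      rp <- file.path(cfg$out_dir, sprintf("%s_rec.ply", dataset[[i]]$id))
      write_ply(rec, rp)
      manifest <- .manifest_add(manifest, rp, "reconstruction")
      reports[[i]] <- evaluate_pair(rec, gt[[i]],
                                    n_samples = cfg$metrics$n_samples,
                                    pitch = cfg$metrics$pitch,
                                    t = cfg$metrics$t,
                                    seed = cfg$seed + i)
      jp <- file.path(cfg$out_dir, sprintf("%s_report.json", dataset[[i]]$id))
      write_metrics_report(reports[[i]], jp)
      manifest <- .manifest_add(manifest, jp, "report")
    }
  }
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  list(model = tr$model, log = tr$log, reports = reports, split = split,
       meshes = meshes, gt = gt, dataset = dataset, specs = specs,
       manifest_path = manifest_path, config = cfg)
}

#' Registration-refined reconstruction run
#'
#' The refinement flow on part-labelled phantoms: forward-project
#' ground-truth part boxes (detection stand-in, with optional seeded
#' part drop-out) -> assemble the template from the detected parts ->
#' rigid ICP pre-alignment -> geodesic-kernel non-rigid registration
#' onto the coarse mesh -> metrics for both the coarse and the
#' registered mesh, so the refinement gain (or cost) is explicit.
#'
#' @param template a [part_mesh()] template library.
#' @param coarse the coarse reconstruction (`trimesh`): a network
#'   output or any stand-in.
#' @param gt ground-truth `trimesh` to evaluate against.
#' @param config a `run_config` (registration and metrics blocks used).
#' @param quiet suppress progress messages.
#' @return list with `registered` (mesh), `coarse_report`,
#'   `registered_report`, `detected` (part names), `field`
#'   (deformation), `manifest_path`.
#' @export
run_x2br <- function(template, coarse, gt, config = default_config(),
                     quiet = FALSE) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list()

  boxes <- project_part_bboxes(template, cfg$projection$angle)
  detected <- boxes$part
  if (cfg$registration$drop_part_prob > 0) {
    set.seed(cfg$seed + 7L)
    keep <- stats::runif(length(detected)) >= cfg$registration$drop_part_prob
    if (!any(keep)) keep[1] <- TRUE
    detected <- detected[keep]
  }
  say("[template] %d/%d parts detected", length(detected), nrow(boxes))
  tpl <- assemble_template(template, detected)

  say("[register] %s kernel", cfg$registration$kernel)
  if (cfg$registration$kernel == "geodesic") {
    df <- gbcpd_nonrigid(tpl, coarse, beta = cfg$registration$beta,
                         lambda = cfg$registration$lambda,
                         w = cfg$registration$w,
                         max_iter = cfg$registration$max_iter,
                         tol = cfg$registration$tol)
  } else {
    tf <- icp_rigid(tpl$mesh$vertices, coarse$vertices)
    pre <- trimesh(apply_rigid(tpl$mesh$vertices, tf), tpl$mesh$faces,
                   validate = FALSE)
    df <- cpd_nonrigid(pre, coarse$vertices, beta = cfg$registration$beta,
                       lambda = cfg$registration$lambda,
                       w = cfg$registration$w,
                       max_iter = cfg$registration$max_iter,
                       tol = cfg$registration$tol, kernel = "euclidean")
  }
  registered <- df$mesh

  say("[evaluate] coarse and registered")
  coarse_report <- evaluate_pair(coarse, gt,
                                 n_samples = cfg$metrics$n_samples,
                                 pitch = cfg$metrics$pitch,
                                 t = cfg$metrics$t, seed = cfg$seed)
  registered_report <- evaluate_pair(registered, gt,
                                     n_samples = cfg$metrics$n_samples,
                                     pitch = cfg$metrics$pitch,
                                     t = cfg$metrics$t, seed = cfg$seed)
  rp <- file.path(cfg$out_dir, "registered.ply")
  write_ply(registered, rp)
  manifest <- .manifest_add(manifest, rp, "registered_mesh")
  prov <- list(kernel = cfg$registration$kernel,
               beta = cfg$registration$beta,
               lambda = cfg$registration$lambda, w = cfg$registration$w,
               max_iter = cfg$registration$max_iter,
               tol = cfg$registration$tol, detected = detected,
               em_iterations = length(df$nll), sigma2 = df$sigma2)
  pp <- file.path(cfg$out_dir, "registration.json")
  jsonlite::write_json(prov, pp, auto_unbox = TRUE, digits = NA)
  manifest <- .manifest_add(manifest, pp, "registration_provenance")
  manifest_path <- file.path(cfg$out_dir, "refine_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  list(registered = registered, coarse_report = coarse_report,
       registered_report = registered_report, detected = detected,
       field = df, manifest_path = manifest_path)
}
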