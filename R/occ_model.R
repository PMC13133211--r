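#' Occupancy-field network configuration
#'
#' The model maps a single projection image plus a 3D query point to the
#' probability that the point lies inside the bone. Architecture: a
#' 4-stage hierarchical convolutional encoder (non-overlapping strided
#' patch convolutions with stage-wise downsampling) compresses the image
#' into a `c_dim`-dimensional code; a decoder of residual dense blocks
#' conditioned by per-channel scale/shift (FiLM-style conditional
#' normalization, gamma/beta generated from the image code) predicts a
#' logit per query point; a permutation-invariant variational encoder
#' infers a Gaussian latent code used only during training.
#'
#' Defaults follow the full-scale design (224 input, 1024-d code, hidden
#' width 256, 5 blocks); tests scale the widths down.
#'
#' @param img_size input image side (pixels).
#' @param enc_widths channel widths of the 4 encoder stages.
#' @param c_dim image code dimension.
#' @param h_dim decoder hidden width.
#' @param n_blocks number of conditioned residual blocks.
#' @param z_dim latent code dimension.
#' @param q_dim width of the variational encoder.
#' @return list of class `occ_config`.
#' @export
occ_config <- function(img_size = 224L, enc_widths = c(48L, 96L, 192L, 384L),
                       c_dim = 1024L, h_dim = 256L, n_blocks = 5L,
                       z_dim = 64L, q_dim = 128L) {
  patches <- c(4L, 2L, 2L, 2L)
  if (img_size %% 32 != 0) stop("img_size must be a multiple of 32")
  structure(list(img_size = as.integer(img_size), patches = patches,
                 enc_widths = as.integer(enc_widths), c_dim = as.integer(c_dim),
                 h_dim = as.integer(h_dim), n_blocks = as.integer(n_blocks),
                 z_dim = as.integer(z_dim), q_dim = as.integer(q_dim)),
            class = "occ_config")
}

#' Initialise an occupancy-field model
#' @param cfg an [occ_config()].
#' @param seed integer seed for the parameter draw.
#' @return list of class `occ_model` with `cfg`, `params`, `trained`.
#' @export
occ_model <- function(cfg = occ_config(), seed = 0L) {
  set.seed(seed)
  p <- list()
  cin <- 1L
  for (s in 1:4) {
    nin <- cfg$patches[s]^2 * cin
    p[[paste0("We", s)]] <- .he_init(nin, cfg$enc_widths[s])
    p[[paste0("be", s)]] <- numeric(cfg$enc_widths[s])
    cin <- cfg$enc_widths[s]
  }
  p$Wc <- .he_init(cin, cfg$c_dim)
  p$bc <- numeric(cfg$c_dim)
  h <- cfg$h_dim
  p$Wp <- .he_init(3L, h)
  p$bp <- numeric(h)
  p$Wz <- matrix(0, cfg$z_dim, h) # latent enters additively; start silent
  for (b in seq_len(cfg$n_blocks)) {
    p[[paste0("G1_", b)]] <- matrix(0, cfg$c_dim, h) # gamma = 1 at init
    p[[paste0("g1_", b)]] <- rep(1, h)
    p[[paste0("B1_", b)]] <- matrix(0, cfg$c_dim, h)
    p[[paste0("b1_", b)]] <- numeric(h)
    p[[paste0("W1_", b)]] <- .he_init(h, h)
    p[[paste0("w1_", b)]] <- numeric(h)
    p[[paste0("G2_", b)]] <- matrix(0, cfg$c_dim, h)
    p[[paste0("g2_", b)]] <- rep(1, h)
    p[[paste0("B2_", b)]] <- matrix(0, cfg$c_dim, h)
    p[[paste0("b2_", b)]] <- numeric(h)
    p[[paste0("W2_", b)]] <- .he_init(h, h) / cfg$n_blocks # mild residual scaling
    p[[paste0("w2_", b)]] <- numeric(h)
  }
  p$Gf <- matrix(0, cfg$c_dim, h)
  p$gf <- rep(1, h)
  p$Bf <- matrix(0, cfg$c_dim, h)
  p$bf <- numeric(h)
  p$Wo <- .he_init(h, 1L) / 10
  p$bo <- 0
  q <- cfg$q_dim
  p$Q1 <- .he_init(4L, q)
  p$q1 <- numeric(q)
  p$Q2 <- .he_init(q + cfg$c_dim, q)
  p$q2 <- numeric(q)
  p$Qmu <- matrix(0, q, cfg$z_dim)
  p$qmu <- numeric(cfg$z_dim)
  p$Qlv <- matrix(0, q, cfg$z_dim)
  p$qlv <- numeric(cfg$z_dim)
  structure(list(cfg = cfg, params = p, trained = FALSE), class = "occ_model")
}

#' @export
print.occ_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("occ_model: %s, %d parameters, img %d, code %d, hidden %d x %d blocks%s\n",
              if (x$trained) "trained" else "untrained", np, x$cfg$img_size,
              x$cfg$c_dim, x$cfg$h_dim, x$cfg$n_blocks,
              if (x$trained) "" else " (warning: untrained)"))
  invisible(x)
}

# --- encoder -----------------------------------------------------------
# Feature maps are matrices of shape (H*W*B) x C with row index
# (loc - 1) * B + b; non-overlapping patch convolutions are gathers +
# one matrix multiply, so the backward pass is a scatter.

.enc_gather_idx <- function(H, W, p, B) {
  Ho <- H %/% p; Wo <- W %/% p
  # out loc = (ho-1)*Wo + wo ; in loc = (h-1)*W + w
  out <- matrix(0L, Ho * Wo * B, p * p)
  k <- 0L
  for (dh in seq_len(p)) {
    for (dw in seq_len(p)) {
      k <- k + 1L
      g <- expand.grid(b = seq_len(B), wo = seq_len(Wo), ho = seq_len(Ho))
      h <- (g$ho - 1L) * p + dh
      w <- (g$wo - 1L) * p + dw
      inloc <- (h - 1L) * W + w
      outrow <- ((g$ho - 1L) * Wo + g$wo - 1L) * B + g$b
      out[outrow, k] <- (inloc - 1L) * B + g$b
    }
  }
  out
}

.enc_forward <- function(model, images, want_cache = FALSE) {
  cfg <- model$cfg
  p <- model$params
  if (!is.list(images)) images <- list(images)
  B <- length(images)
  S <- cfg$img_size
  for (im in images) {
    px <- if (inherits(im, "projection_image")) im$pixels else im
    if (!all(dim(px) == c(S, S)))
      stop(sprintf("image size mismatch: got %d x %d, config expects %d",
                   nrow(px), ncol(px), S))
  }
  # X: (S*S*B) x 1, row (loc-1)*B + b
  X <- matrix(0, S * S * B, 1)
  for (b in seq_len(B)) {
    px <- images[[b]]
    if (inherits(px, "projection_image")) px <- px$pixels
    X[seq(b, S * S * B, by = B), 1] <- as.vector(t(px)) # loc = (i1-1)*S + i2
  }
  H <- S; W <- S
  cache <- list(B = B, stages = list())
  for (s in 1:4) {
    ps <- cfg$patches[s]
    idx <- .enc_gather_idx(H, W, ps, B)
    C <- ncol(X)
    Xp <- matrix(0, nrow(idx), ps * ps * C)
    for (k in seq_len(ps * ps)) {
      Xp[, ((k - 1) * C + 1):(k * C)] <- X[idx[, k], , drop = FALSE]
    }
    Z <- sweep(Xp %*% p[[paste0("We", s)]], 2, p[[paste0("be", s)]], "+")
    if (want_cache) cache$stages[[s]] <- list(idx = idx, Xp = Xp, Z = Z,
                                              Cin = C, nrow_in = nrow(X))
    X <- .relu(Z)
    H <- H %/% ps; W <- W %/% ps
  }
  nloc <- H * W
  grp <- rep(seq_len(B), nloc)
  M <- rowsum(X, grp) / nloc
  Cenc <- sweep(M %*% p$Wc, 2, p$bc, "+")
  if (want_cache) {
    cache$X4 <- X; cache$grp <- grp; cache$nloc <- nloc; cache$M <- M
    attr(Cenc, "cache") <- cache
  }
  Cenc
}

.enc_backward <- function(model, cache, dC, grads) {
  p <- model$params
  grads$Wc <- grads$Wc + t(cache$M) %*% dC
  grads$bc <- grads$bc + colSums(dC)
  dM <- dC %*% t(p$Wc)
  dX <- dM[cache$grp, , drop = FALSE] / cache$nloc
  for (s in 4:1) {
    st <- cache$stages[[s]]
    dZ <- dX * (st$Z > 0)
    grads[[paste0("We", s)]] <- grads[[paste0("We", s)]] + t(st$Xp) %*% dZ
    grads[[paste0("be", s)]] <- grads[[paste0("be", s)]] + colSums(dZ)
    dXp <- dZ %*% t(p[[paste0("We", s)]])
    dXprev <- matrix(0, st$nrow_in, st$Cin)
    C <- st$Cin
    for (k in seq_len(ncol(st$idx))) {
      dXprev[st$idx[, k], ] <- dXp[, ((k - 1) * C + 1):(k * C), drop = FALSE]
    }
    dX <- dXprev
  }
  grads
}

#' Encode a projection image into its conditioning vector
#' @param image a `projection_image` or matrix matching the config size.
#' @param model an [occ_model()].
#' @return numeric vector of length `c_dim`.
#' @export
encode_image <- function(image, model) {
  as.vector(.enc_forward(model, list(image)))
}

# --- decoder -----------------------------------------------------------
# Batched over samples: P is (B*T) x 3 with rows grouped by sample,
# C is B x c_dim, Z is B x z_dim.

.film <- function(H, C, G, gb, B_, bb, rix) {
  Gam <- sweep(C %*% G, 2, gb, "+")
  Bet <- sweep(C %*% B_, 2, bb, "+")
  H * Gam[rix, , drop = FALSE] + Bet[rix, , drop = FALSE]
}

.dec_forward <- function(model, P, Z, C, want_cache = FALSE) {
  cfg <- model$cfg
  p <- model$params
  B <- nrow(C)
  T <- nrow(P) / B
  rix <- rep(seq_len(B), each = T)
  H <- sweep(P %*% p$Wp, 2, p$bp, "+") + (Z %*% p$Wz)[rix, , drop = FALSE]
  cache <- list(B = B, T = T, rix = rix, P = P, H0in = H, blocks = list())
  for (b in seq_len(cfg$n_blocks)) {
    T1 <- .film(H, C, p[[paste0("G1_", b)]], p[[paste0("g1_", b)]],
                p[[paste0("B1_", b)]], p[[paste0("b1_", b)]], rix)
    A1 <- .relu(T1)
    U1 <- sweep(A1 %*% p[[paste0("W1_", b)]], 2, p[[paste0("w1_", b)]], "+")
    T2 <- .film(U1, C, p[[paste0("G2_", b)]], p[[paste0("g2_", b)]],
                p[[paste0("B2_", b)]], p[[paste0("b2_", b)]], rix)
    A2 <- .relu(T2)
    U2 <- sweep(A2 %*% p[[paste0("W2_", b)]], 2, p[[paste0("w2_", b)]], "+")
    if (want_cache)
      cache$blocks[[b]] <- list(Hin = H, T1 = T1, A1 = A1, U1 = U1,
                                T2 = T2, A2 = A2)
    H <- H + U2
  }
  Tf <- .film(H, C, p$Gf, p$gf, p$Bf, p$bf, rix)
  Af <- .relu(Tf)
  L <- as.vector(Af %*% p$Wo + p$bo)
  if (want_cache) {
    cache$Hfin <- H; cache$Tf <- Tf; cache$Af <- Af
    attr(L, "cache") <- cache
  }
  L
}

# backward through one FiLM layer; returns list(dH, grads, dC)
.film_backward <- function(dT, Hin, C, G, B_, rix, B, grads, gn, bn, Gn, Bn, dC) {
  dGam <- rowsum(dT * Hin, rix)
  dBet <- rowsum(dT, rix)
  grads[[Gn]] <- grads[[Gn]] + t(C) %*% dGam
  grads[[gn]] <- grads[[gn]] + colSums(dGam)
  grads[[Bn]] <- grads[[Bn]] + t(C) %*% dBet
  grads[[bn]] <- grads[[bn]] + colSums(dBet)
  dC <- dC + dGam %*% t(G) + dBet %*% t(B_)
  list(dC = dC, grads = grads)
}

.dec_backward <- function(model, cache, dL, C, grads) {
  cfg <- model$cfg
  p <- model$params
  rix <- cache$rix
  B <- cache$B
  dL <- matrix(dL, ncol = 1)
  grads$Wo <- grads$Wo + t(cache$Af) %*% dL
  grads$bo <- grads$bo + sum(dL)
  dAf <- dL %*% t(p$Wo)
  dTf <- dAf * (cache$Tf > 0)
  dC <- matrix(0, B, cfg$c_dim)
  fb <- .film_backward(dTf, cache$Hfin, C, p$Gf, p$Bf, rix, B, grads,
                       "gf", "bf", "Gf", "Bf", dC)
  grads <- fb$grads; dC <- fb$dC
  Gamf <- sweep(C %*% p$Gf, 2, p$gf, "+")
  dH <- dTf * Gamf[rix, , drop = FALSE]
  for (b in rev(seq_len(cfg$n_blocks))) {
    bl <- cache$blocks[[b]]
    dU2 <- dH # residual branch
    grads[[paste0("W2_", b)]] <- grads[[paste0("W2_", b)]] + t(bl$A2) %*% dU2
    grads[[paste0("w2_", b)]] <- grads[[paste0("w2_", b)]] + colSums(dU2)
    dA2 <- dU2 %*% t(p[[paste0("W2_", b)]])
    dT2 <- dA2 * (bl$T2 > 0)
    fb <- .film_backward(dT2, bl$U1, C, p[[paste0("G2_", b)]],
                         p[[paste0("B2_", b)]], rix, B, grads,
                         paste0("g2_", b), paste0("b2_", b),
                         paste0("G2_", b), paste0("B2_", b), dC)
    grads <- fb$grads; dC <- fb$dC
    Gam2 <- sweep(C %*% p[[paste0("G2_", b)]], 2, p[[paste0("g2_", b)]], "+")
    dU1 <- dT2 * Gam2[rix, , drop = FALSE]
    grads[[paste0("W1_", b)]] <- grads[[paste0("W1_", b)]] + t(bl$A1) %*% dU1
    grads[[paste0("w1_", b)]] <- grads[[paste0("w1_", b)]] + colSums(dU1)
    dA1 <- dU1 %*% t(p[[paste0("W1_", b)]])
    dT1 <- dA1 * (bl$T1 > 0)
    fb <- .film_backward(dT1, bl$Hin, C, p[[paste0("G1_", b)]],
                         p[[paste0("B1_", b)]], rix, B, grads,
                         paste0("g1_", b), paste0("b1_", b),
                         paste0("G1_", b), paste0("B1_", b), dC)
    grads <- fb$grads; dC <- fb$dC
    Gam1 <- sweep(C %*% p[[paste0("G1_", b)]], 2, p[[paste0("g1_", b)]], "+")
    dH <- dH + dT1 * Gam1[rix, , drop = FALSE] # through film1 into Hin
  }
  # input projection
  grads$Wp <- grads$Wp + t(cache$P) %*% dH
  grads$bp <- grads$bp + colSums(dH)
  dZsum <- rowsum(dH, rix)
  grads$Wz <- grads$Wz # updated by caller with dZ
  list(grads = grads, dC = dC, dZsum = dZsum)
}

#' Decode occupancy logits for query points
#'
#' Deterministic given `(points, z, c)`; pointwise, so evaluation is
#' permutation-equivariant and independent of batching.
#' @param points T x 3 matrix of query points in the padded unit box.
#' @param z latent vector (length `z_dim`), use zeros at inference.
#' @param c image encoding (length `c_dim`).
#' @param model an [occ_model()].
#' @return numeric vector of T logits.
#' @export
decode_logits <- function(points, z, c, model) {
  points <- as.matrix(points)
  if (any(!is.finite(points))) stop("NaN/Inf in query points")
  .dec_forward(model, points, matrix(z, 1), matrix(c, 1))
}

#' Sigmoid occupancy probability
#' @param logits numeric vector of logits.
#' @export
occupancy_prob <- function(logits) stats::plogis(logits)

#' Mean binary cross-entropy in stable logit form
#' @param logits numeric vector.
#' @param labels 0/1 vector.
#' @export
bce_loss <- function(logits, labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  mean(.bce_logits(logits, labels))
}

# --- variational encoder ----------------------------------------------

.qenc_forward <- function(model, P, o, cvec, want_cache = FALSE) {
  p <- model$params
  U0 <- cbind(P, o)
  Z1 <- sweep(U0 %*% p$Q1, 2, p$q1, "+")
  A1 <- .relu(Z1)
  m <- colMeans(A1)
  gin <- matrix(c(m, cvec), 1)
  Z2 <- sweep(gin %*% p$Q2, 2, p$q2, "+")
  A2 <- .relu(Z2)
  mu <- as.vector(A2 %*% p$Qmu + matrix(p$qmu, 1))
  lv <- as.vector(A2 %*% p$Qlv + matrix(p$qlv, 1))
  out <- list(mu = mu, lv = lv)
  if (want_cache) out$cache <- list(U0 = U0, Z1 = Z1, A1 = A1, gin = gin,
                                    Z2 = Z2, A2 = A2)
  out
}

.qenc_backward <- function(model, cache, dmu, dlv, grads) {
  p <- model$params
  grads$Qmu <- grads$Qmu + t(cache$A2) %*% matrix(dmu, 1)
  grads$qmu <- grads$qmu + dmu
  grads$Qlv <- grads$Qlv + t(cache$A2) %*% matrix(dlv, 1)
  grads$qlv <- grads$qlv + dlv
  dA2 <- matrix(dmu, 1) %*% t(p$Qmu) + matrix(dlv, 1) %*% t(p$Qlv)
  dZ2 <- dA2 * (cache$Z2 > 0)
  grads$Q2 <- grads$Q2 + t(cache$gin) %*% dZ2
  grads$q2 <- grads$q2 + as.vector(dZ2)
  dgin <- dZ2 %*% t(p$Q2)
  q <- model$cfg$q_dim
  dm <- dgin[1, seq_len(q)]
  dcv <- dgin[1, -seq_len(q)]
  Tn <- nrow(cache$A1)
  dA1 <- matrix(dm, Tn, q, byrow = TRUE) / Tn
  dZ1 <- dA1 * (cache$Z1 > 0)
  grads$Q1 <- grads$Q1 + t(cache$U0) %*% dZ1
  grads$q1 <- grads$q1 + colSums(dZ1)
  list(grads = grads, dc = dcv)
}

# --- ELBO --------------------------------------------------------------

#' Negative-ELBO training loss
#'
#' Mean over the batch of `KL(q(z | points, labels, c) || N(0, I)) +
#' (1/T) * sum BCE(logits, labels)`, with one reparameterised latent
#' sample per training step. All points of a sample share one
#' conditioning image.
#'
#' @param batch list of samples; each sample is a list with `points`
#'   (T x 3), `labels` (0/1), and `image`.
#' @param model an [occ_model()].
#' @param eps optional B x z_dim matrix of latent noise (zeros give the
#'   posterior mean; `NULL` draws standard normals).
#' @param want_grads also compute parameter gradients (internal use).
#' @return scalar loss with attributes `kl` and `bce`; when
#'   `want_grads`, a list with `loss` and `grads`.
#' @export
elbo_loss <- function(batch, model, eps = NULL, want_grads = FALSE) {
  if (!length(batch)) stop("empty batch")
  cfg <- model$cfg
  B <- length(batch)
  Tn <- nrow(batch[[1]]$points)
  if (is.null(eps)) eps <- matrix(stats::rnorm(B * cfg$z_dim), B)
  C <- .enc_forward(model, lapply(batch, `[[`, "image"), want_cache = TRUE)
  enc_cache <- attr(C, "cache")
  C <- unclass(C); attr(C, "cache") <- NULL

  qs <- vector("list", B)
  Z <- matrix(0, B, cfg$z_dim)
  kl <- numeric(B)
  for (i in seq_len(B)) {
    qs[[i]] <- .qenc_forward(model, batch[[i]]$points, batch[[i]]$labels,
                             C[i, ], want_cache = want_grads)
    Z[i, ] <- qs[[i]]$mu + exp(0.5 * qs[[i]]$lv) * eps[i, ]
    kl[i] <- 0.5 * sum(qs[[i]]$mu^2 + exp(qs[[i]]$lv) - 1 - qs[[i]]$lv)
  }
  P <- do.call(rbind, lapply(batch, `[[`, "points"))
  o <- unlist(lapply(batch, `[[`, "labels"))
  L <- .dec_forward(model, P, Z, C, want_cache = want_grads)
  dec_cache <- attr(L, "cache"); L <- as.vector(L)
  bce <- sum(.bce_logits(L, o)) / (B * Tn)
  loss <- mean(kl) + bce
  attr(loss, "kl") <- mean(kl)
  attr(loss, "bce") <- bce
  if (!want_grads) return(loss)

  grads <- .zeros_like(model$params)
  dL <- (stats::plogis(L) - o) / (B * Tn)
  db <- .dec_backward(model, dec_cache, dL, C, grads)
  grads <- db$grads
  dC <- db$dC
  dZ <- db$dZsum
  grads$Wz <- grads$Wz + t(Z) %*% dZ
  dZq <- dZ %*% t(model$params$Wz)
  for (i in seq_len(B)) {
    dmu <- dZq[i, ] + qs[[i]]$mu / B
    dlv <- dZq[i, ] * eps[i, ] * 0.5 * exp(0.5 * qs[[i]]$lv) +
      0.5 * (exp(qs[[i]]$lv) - 1) / B
    qb <- .qenc_backward(model, qs[[i]]$cache, dmu, dlv, grads)
    grads <- qb$grads
    dC[i, ] <- dC[i, ] + qb$dc
  }
  grads <- .enc_backward(model, enc_cache, dC, grads)
  list(loss = loss, grads = grads)
}

# --- training ----------------------------------------------------------

#' Training configuration
#'
#' Adam with the conventional defaults: learning rate 1e-4,
#' beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8; 2,048 query points per
#' sample per step, redrawn from each sample's pool every step.
#' @param lr learning rate.
#' @param lr_final optional final learning rate; when set, the rate
#'   decays linearly from `lr` to `lr_final` over training.
#' @param beta1,beta2,eps Adam moment decay rates and stabiliser.
#' @param batch_size samples per step (0 = whole training set).
#' @param t_points query points per sample per step.
#' @param epochs passes over the training set.
#' @param seed integer seed controlling all training randomness.
#' @export
train_config <- function(lr = 1e-4, lr_final = NULL, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8, batch_size = 0L,
                         t_points = 2048L, epochs = 10L, seed = 0L) {
  stopifnot(lr > 0, beta1 > 0, beta2 > 0, eps > 0, t_points > 0, epochs >= 1)
  structure(list(lr = lr, lr_final = lr_final, beta1 = beta1, beta2 = beta2,
                 eps = eps, batch_size = as.integer(batch_size),
                 t_points = as.integer(t_points),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Train the occupancy-field network
#'
#' @param dataset list of samples, each a list with `image` (a
#'   `projection_image` or matrix) and `pool` (an `occupancy_pool`).
#' @param config a [train_config()].
#' @param model optionally a pre-initialised [occ_model()]; otherwise a
#'   default-config model seeded from `config$seed`.
#' @param val_idx indices of validation samples (held out of updates;
#'   split at the phantom level by the caller).
#' @return list with `model` (trained) and `log` (per-epoch data frame
#'   with train/val loss), plus the config and seed for provenance.
#' @export
train <- function(dataset, config = train_config(), model = NULL,
                  val_idx = integer(0)) {
  if (is.null(model)) model <- occ_model(seed = config$seed)
  cfg <- model$cfg
  train_idx <- setdiff(seq_along(dataset), val_idx)
  if (!length(train_idx)) stop("no training samples")
  bs <- if (config$batch_size <= 0) length(train_idx) else
    min(config$batch_size, length(train_idx))
  opt <- .adam_init(model$params)
  set.seed(config$seed)
  log <- list()
  step <- 0L
  make_batch <- function(idx, step) {
    lapply(idx, function(i) {
      d <- draw_occupancy_batch(dataset[[i]]$pool,
                                batch_index = step * 131L + i,
                                t_batch = config$t_points)
      list(points = d$points, labels = d$labels, image = dataset[[i]]$image)
    })
  }
  eval_loss <- function(idx) {
    if (!length(idx)) return(NA_real_)
    b <- make_batch(idx, 0L)
    as.numeric(elbo_loss(b, model, eps = matrix(0, length(idx), cfg$z_dim)))
  }
  init_train <- eval_loss(train_idx)
  init_val <- eval_loss(val_idx)
  for (ep in seq_len(config$epochs)) {
    perm <- sample(train_idx)
    ep_losses <- c()
    for (start in seq(1, length(perm), by = bs)) {
      idx <- perm[start:min(start + bs - 1, length(perm))]
      step <- step + 1L
      batch <- make_batch(idx, step)
      res <- elbo_loss(batch, model, want_grads = TRUE)
      if (!is.finite(as.numeric(res$loss)))
        stop(sprintf("training diverged at step %d (loss %g); last lr %g",
                     step, as.numeric(res$loss), config$lr))
      lr <- if (is.null(config$lr_final)) config$lr else
        config$lr + (config$lr_final - config$lr) * (ep - 1) /
          max(config$epochs - 1, 1)
      up <- .adam_step(model$params, res$grads, opt, lr,
                       config$beta1, config$beta2, config$eps)
      model$params <- up$params
      opt <- up$state
      ep_losses <- c(ep_losses, as.numeric(res$loss))
    }
    log[[ep]] <- data.frame(epoch = ep, train_loss = mean(ep_losses),
                            val_loss = eval_loss(val_idx))
  }
  model$trained <- TRUE
  log <- do.call(rbind, log)
  attr(log, "init_train_loss") <- init_train
  attr(log, "init_val_loss") <- init_val
  list(model = model, log = log, config = config, seed = config$seed)
}

#' Turn a trained model and an image into a queryable occupancy field
#'
#' Returns a closure `f(points)` giving occupancy probabilities, built
#' from the image encoding with the latent code fixed at the prior mean
#' (zero), so inference is deterministic. The closure captures only
#' immutable state.
#'
#' @param image a `projection_image` or matrix.
#' @param model a trained [occ_model()].
#' @return function mapping an n x 3 matrix to n probabilities.
#' @export
infer_field <- function(image, model) {
  if (!isTRUE(model$trained)) warning("model is untrained; field is noise")
  cvec <- encode_image(image, model)
  z0 <- numeric(model$cfg$z_dim)
  force(model)
  function(points) {
    occupancy_prob(decode_logits(as.matrix(points), z0, cvec, model))
  }
}

#' Save / load a model checkpoint
#'
#' Writes the parameter archive (RDS) next to a JSON snapshot of the
#' architecture configuration for provenance.
#' @param model an [occ_model()].
#' @param stem path stem; writes `<stem>.rds` and `<stem>.json`.
#' @export
save_occ_model <- function(model, stem) {
  saveRDS(model, paste0(stem, ".rds"))
  jsonlite::write_json(c(unclass(model$cfg), list(trained = model$trained)),
                       paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname save_occ_model
#' @export
load_occ_model <- function(stem) readRDS(paste0(stem, ".rds"))
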