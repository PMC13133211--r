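# Minimal neural-network plumbing: parameter initialisation and Adam.
# Parameters live in a flat named list of matrices/vectors; gradients
# mirror that structure. No external autodiff -- the occupancy model
# implements its own forward/backward passes in matrix algebra.

.he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

.zeros_like <- function(params) lapply(params, function(p) p * 0)

.adam_init <- function(params) {
  list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)
}

# one Adam update; returns list(params, state)
.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

.relu <- function(x) x * (x > 0)

# numerically stable BCE-with-logits, elementwise
.bce_logits <- function(logits, labels) {
  pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits)))
}
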