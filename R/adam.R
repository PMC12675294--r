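# First-order adaptive-moment (Adam) optimizer over a flat named list of
# parameter arrays. State lives in an environment so updates are in place.
adamInit <- function(params) {
  e <- new.env(parent = emptyenv())
  e$m <- lapply(params, function(p) p * 0)
  e$v <- lapply(params, function(p) p * 0)
  e$t <- 0L
  e
}

adamStep <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  params
}

# Adam over a plain numeric vector (used for per-shape latent codes).
adamVecInit <- function(n) {
  e <- new.env(parent = emptyenv())
  e$m <- numeric(n)
  e$v <- numeric(n)
  e$t <- 0L
  e
}

adamVecStep <- function(state, x, g, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  x - lr * (state$m / (1 - beta1^state$t)) /
    (sqrt(state$v / (1 - beta2^state$t)) + eps)
}
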