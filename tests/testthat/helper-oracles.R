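# Brute-force oracles and small fixture builders shared across the suite.
# Every oracle is a direct transcription of the measure definitions with
# explicit loops, independent of the package's vectorized implementations.

randomCloud <- function(m, with_normals = FALSE, label = "") {
  pts <- matrix(stats::runif(3 * m), m, 3)
  normals <- NULL
  if (with_normals) {
    normals <- matrix(stats::rnorm(3 * m), m, 3)
    normals <- normals / sqrt(rowSums(normals^2))
  }
  weightedPointCloud(pts, stats::runif(m, 0.5, 2), normals, label = label)
}

bruteChamfer <- function(a, b) {
  m <- nrow(a); mp <- nrow(b)
  fwd <- 0
  for (i in seq_len(m)) {
    best <- Inf
    for (j in seq_len(mp)) best <- min(best, sum((a[i, ] - b[j, ])^2))
    fwd <- fwd + best
  }
  bwd <- 0
  for (j in seq_len(mp)) {
    best <- Inf
    for (i in seq_len(m)) best <- min(best, sum((a[i, ] - b[j, ])^2))
    bwd <- bwd + best
  }
  fwd / m + bwd / mp
}

bruteWeightedChamfer <- function(a, wa, b, wb) {
  m <- nrow(a); mp <- nrow(b)
  fwd <- 0
  for (i in seq_len(m)) {
    best <- Inf
    for (j in seq_len(mp)) best <- min(best, sum((a[i, ] - b[j, ])^2))
    fwd <- fwd + wa[i] * best
  }
  bwd <- 0
  for (j in seq_len(mp)) {
    best <- Inf
    for (i in seq_len(m)) best <- min(best, sum((a[i, ] - b[j, ])^2))
    bwd <- bwd + wb[j] * best
  }
  fwd / m + bwd / mp
}

bruteNcd <- function(a, na_, b, nb, w_n) {
  m <- nrow(a); mp <- nrow(b)
  tot <- bruteChamfer(a, b)
  for (i in seq_len(m)) {
    j <- which.min(vapply(seq_len(mp), function(j) sum((a[i, ] - b[j, ])^2),
                          numeric(1)))
    tot <- tot + w_n / (2 * m) * (1 - sum(na_[i, ] * nb[j, ]))^2
  }
  for (j in seq_len(mp)) {
    i <- which.min(vapply(seq_len(m), function(i) sum((a[i, ] - b[j, ])^2),
                          numeric(1)))
    tot <- tot + w_n / (2 * mp) * (1 - sum(nb[j, ] * na_[i, ]))^2
  }
  tot
}

brutePcd <- function(a, na_, b, nb) {
  m <- nrow(a); mp <- nrow(b)
  fwd <- 0
  for (i in seq_len(m)) {
    best <- Inf
    for (j in seq_len(mp))
      best <- min(best, sum((a[i, ] - b[j, ]) * na_[i, ])^2)
    fwd <- fwd + best
  }
  bwd <- 0
  for (j in seq_len(mp)) {
    best <- Inf
    for (i in seq_len(m))
      best <- min(best, sum((a[i, ] - b[j, ]) * nb[j, ])^2)
    bwd <- bwd + best
  }
  fwd / m + bwd / mp
}

# Exact EMD between equal-size uniform clouds: enumerate all bipartite
# matchings (Birkhoff: the optimum of the balanced uniform OT problem is a
# permutation), cost = (1/M) * min over permutations of the summed squared
# distances.
allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

bruteEmd <- function(a, b) {
  m <- nrow(a)
  perms <- allPerms(m)
  best <- Inf
  for (r in seq_len(nrow(perms))) {
    cost <- sum((a - b[perms[r, ], , drop = FALSE])^2)
    best <- min(best, cost)
  }
  best / m
}

bruteNnDist <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i)
    sqrt(min(vapply(seq_len(nrow(b)), function(j)
      sum((a[i, ] - b[j, ])^2), numeric(1)))), numeric(1))
}

# Small randomized velocity model (nonzero head so the flow is nontrivial,
# scaled to keep the field contractive for the implicit solver).
tinyModel <- function(seed = 1L, head_sd = 0.05,
                      config = netConfig(fa_layers = 2L, fa_width = 8L,
                                         df_layers = 2L, df_width = 16L,
                                         n_e = 2L, n_z = 16L, g_z = 2L,
                                         K = 6L)) {
  set.seed(seed)
  model <- initVelocityModel(config)
  model$params[["head.W"]] <- matrix(stats::rnorm(config$df_width * 3,
                                                  sd = head_sd),
                                     config$df_width, 3L)
  model
}

# Builds a model whose velocity field is exactly v(x) = A x + b: one linear
# FA layer passing x through, no DF layers, head reading the identity
# channel of the encoder. Exercises the real forward/backward machinery
# against matrix closed forms.
linearFieldModel <- function(A, b) {
  cfg <- netConfig(fa_layers = 1L, fa_width = 3L, df_layers = 0L,
                   df_width = 0L, n_e = 1L, n_z = 8L, g_z = 1L, K = 10L)
  model <- initVelocityModel(cfg)
  W1 <- matrix(0, 3L + cfg$code_channels, 3L)
  W1[1:3, 1:3] <- diag(3)                 # u = x
  model$params[["fa1.W"]] <- W1
  model$params[["fa1.b"]] <- numeric(3L)
  hw <- matrix(0, cfg$fpe_width + cfg$code_channels, 3L)
  hw[1:3, ] <- t(A)                       # head reads the identity channel
  model$params[["head.W"]] <- hw
  model$params[["head.b"]] <- b
  model
}

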