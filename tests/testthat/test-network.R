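test_that("code grid reshape is the documented bijection", {
  z <- seq_len(256)
  grid <- reshapeCode(z, 2)
  expect_equal(dim(grid), c(8L, 32L))      # 2x2x2 nodes x 32 channels
  expect_identical(unreshapeCode(grid), as.numeric(z))
  expect_error(reshapeCode(seq_len(100), 3), "divisible")
  # g_z = 1: position-independent conditioning
  g1 <- reshapeCode(z[1:16], 1)
  expect_equal(dim(g1), c(1L, 16L))
  zb <- lerpCode(matrix(runif(9), 3, 3), g1)
  expect_equal(zb, matrix(z[1:16], 3, 16, byrow = TRUE))
})

test_that("trilinear code lookup: exact at nodes, mean at the centre,
           linear along axes, constant for constant grids", {
  set.seed(71)
  grid <- reshapeCode(rnorm(8 * 4), 2)
  # node (0,0,0) is grid row 1 by the documented layout
  expect_equal(as.numeric(lerpCode(c(0, 0, 0), grid)), grid[1, ])
  # all 8 corners against the documented node layout r-1 = (i*2+j)*2+k
  for (i in 0:1) for (j in 0:1) for (k in 0:1)
    expect_equal(as.numeric(lerpCode(c(i, j, k), grid)),
                 grid[(i * 2 + j) * 2 + k + 1, ])
  # cube centre: mean of the 8 corner vectors (expanded 8-term formula)
  expect_equal(as.numeric(lerpCode(c(0.5, 0.5, 0.5), grid)),
               colMeans(grid), tolerance = 1e-12)
  # constant grid
  cgrid <- reshapeCode(rep(rep(3.5, 4), 8), 2)
  expect_equal(lerpCode(matrix(runif(15), 5, 3), cgrid),
               matrix(3.5, 5, 4))
  # linearity along an axis-aligned segment
  t <- seq(0, 1, by = 0.1)
  vals <- lerpCode(cbind(t, 0.3, 0.7), grid)
  for (ch in 1:4) {
    fitted <- stats::lm(vals[, ch] ~ t)
    expect_lt(max(abs(stats::residuals(fitted))), 1e-12)
  }
  # clamping outside the cube
  expect_equal(as.numeric(lerpCode(c(-2, -2, -2), grid)), grid[1, ])
})

test_that("Fourier positional encoding layout and degenerate cases", {
  u <- matrix(runif(6, -1, 1), 2, 3)
  enc <- fourierEncode(u, n_e = 3)
  expect_equal(ncol(enc), (2 * 3 + 1) * 3)
  expect_equal(enc[, 1:3], u)
  expect_equal(enc[, 4:6], sin(pi * u))
  expect_equal(enc[, 7:9], cos(pi * u))
  expect_equal(enc[, 10:12], sin(2 * pi * u))
  expect_equal(enc[, 16:18], sin(4 * pi * u))
  # u = 0: identity 0, sines 0, cosines 1
  e0 <- fourierEncode(matrix(0, 1, 4), n_e = 2)
  expect_equal(as.numeric(e0), c(rep(0, 4), rep(0, 4), rep(1, 4),
                                 rep(0, 4), rep(1, 4)))
  expect_identical(fourierEncode(u, n_e = 0), u)
  # full-size configuration width
  expect_equal(netConfig()$fpe_width, 448L)
})

test_that("zero-initialized flow head yields the exact identity map", {
  set.seed(72)
  model <- initVelocityModel(netConfig(fa_layers = 2, fa_width = 8,
                                       df_layers = 2, df_width = 16,
                                       n_z = 16))
  z <- rnorm(16)
  x <- matrix(runif(30), 10, 3)
  expect_equal(velocity(x, z, model), matrix(0, 10, 3))
  traj <- forwardMap(x, model, z, K = 10)
  expect_equal(trajectoryEndpoint(traj), x)
})

test_that("batched velocity equals per-point evaluation and changes with
           the code", {
  model <- tinyModel(73)
  set.seed(73)
  z <- rnorm(16, sd = 0.3)
  x <- matrix(runif(18), 6, 3)
  vAll <- velocity(x, z, model)
  for (i in 1:6)
    expect_equal(as.numeric(velocity(x[i, ], z, model)), vAll[i, ],
                 tolerance = 1e-12)
  z2 <- rnorm(16, sd = 0.3)
  expect_gt(max(abs(velocity(x, z2, model) - vAll)), 0)
})

test_that("velocity network reverse-mode matches central differences", {
  model <- tinyModel(74, head_sd = 0.1)
  set.seed(74)
  z <- rnorm(16, sd = 0.3)
  grid <- reshapeCode(z, 2)
  x <- matrix(runif(12, 0.05, 0.95), 4, 3)
  dv <- matrix(rnorm(12), 4, 3)
  vf <- vascuflow:::velocityForward(x, grid, model)
  acc <- vascuflow:::zeroGrads(model)
  vb <- vascuflow:::velocityBackward(vf$cache, grid, model, dv, acc)
  h <- 1e-6
  f <- function(xx, gg, pp) {
    mm <- model
    mm$params <- pp
    sum(vascuflow:::velocityForward(xx, gg, mm)$v * dv)
  }
  for (i in 1:4) for (d in 1:3) {
    xp <- x; xp[i, d] <- xp[i, d] + h
    xm <- x; xm[i, d] <- xm[i, d] - h
    num <- (f(xp, grid, model$params) - f(xm, grid, model$params)) / (2 * h)
    expect_equal(vb$dx[i, d], num, tolerance = 1e-4)
  }
  for (idx in list(c(2, 1), c(7, 2))) {
    gp <- grid; gp[idx[1], idx[2]] <- gp[idx[1], idx[2]] + h
    gm <- grid; gm[idx[1], idx[2]] <- gm[idx[1], idx[2]] - h
    num <- (f(x, gp, model$params) - f(x, gm, model$params)) / (2 * h)
    expect_equal(vb$dgrid[idx[1], idx[2]], num, tolerance = 1e-4)
  }
  for (nm in c("fa1.W", "df2.W", "head.W", "df1.b")) {
    pp <- model$params; pm <- model$params
    if (is.matrix(pp[[nm]])) {
      pp[[nm]][2, 1] <- pp[[nm]][2, 1] + h
      pm[[nm]][2, 1] <- pm[[nm]][2, 1] - h
      ana <- acc$g[[nm]][2, 1]
    } else {
      pp[[nm]][2] <- pp[[nm]][2] + h
      pm[[nm]][2] <- pm[[nm]][2] - h
      ana <- acc$g[[nm]][2]
    }
    num <- (f(x, grid, pp) - f(x, grid, pm)) / (2 * h)
    expect_equal(ana, num, tolerance = 1e-4, label = nm)
  }
})

test_that("velocity field is empirically Lipschitz on the unit cube", {
  model <- tinyModel(75, head_sd = 0.05)
  set.seed(75)
  z <- rnorm(16, sd = 0.3)
  a <- matrix(runif(300), 100, 3)
  b <- a + matrix(rnorm(300, sd = 1e-4), 100, 3)
  va <- velocity(a, z, model)
  vb <- velocity(b, z, model)
  ratio <- sqrt(rowSums((va - vb)^2)) / sqrt(rowSums((a - b)^2))
  expect_true(all(is.finite(ratio)))
  expect_lt(max(ratio), 100)
})
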