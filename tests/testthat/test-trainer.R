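test_that("initialization: seed determinism and code variance 2/N_z", {
  shapes <- list(randomCloud(20), randomCloud(20))
  net <- netConfig(fa_layers = 2, fa_width = 8, df_layers = 2,
                   df_width = 16, n_z = 256)
  a <- initModelAndCodes(net, trainConfig(seed = 5), shapes)
  b <- initModelAndCodes(net, trainConfig(seed = 5), shapes)
  expect_identical(a$model$params, b$model$params)
  expect_identical(a$codes, b$codes)
  expect_equal(dim(a$codes), c(256L, 2L))
  # zero-velocity start: head zeroed, map is the identity
  expect_equal(velocity(matrix(0.5, 1, 3), a$codes[, 1], a$model),
               matrix(0, 1, 3))
  # Monte-Carlo check of the code initialization variance
  bigShapes <- lapply(1:40, function(i) randomCloud(3))
  cc <- initModelAndCodes(net, trainConfig(seed = 6), bigShapes)$codes
  expect_equal(stats::var(as.vector(cc)), 2 / 256, tolerance = 0.05)
})

test_that("kinetic-energy regularizer: closed form and re-integration", {
  set.seed(91)
  x <- matrix(runif(36), 12, 3)
  cvec <- c(0.2, -0.1, 0.05)
  # constant field both directions: 2 * M * K * ||c||^2
  cfg <- netConfig(fa_layers = 2, fa_width = 8, df_layers = 2,
                   df_width = 16, n_z = 16)
  model <- initVelocityModel(cfg)
  model$params[["head.b"]] <- cvec
  z <- rnorm(16)
  K <- 7
  fw <- forwardMap(x, model, z, K = K)
  bw <- inverseMapExplicit(x, model, z, K = K)
  expect_equal(regularizer(list(fw, bw)), 2 * 12 * K * sum(cvec^2),
               tolerance = 1e-9)
  # zero field
  model0 <- initVelocityModel(cfg)
  expect_equal(regularizer(forwardMap(x, model0, z, K = 5)), 0)
  # random model: logged velocities match a fresh re-evaluation
  rnd <- tinyModel(92, head_sd = 0.05)
  set.seed(92)
  z16 <- rnorm(16, sd = 0.3)
  fw2 <- forwardMap(x, rnd, z16, K = 5)
  re <- sum(vapply(seq_len(5), function(k)
    sum(velocity(fw2$states[[k]], z16, rnd)^2), numeric(1)))
  expect_equal(regularizer(fw2), re, tolerance = 1e-9)
})

test_that("total loss assembles data, code, parameter and kinetic terms", {
  cfg <- trainConfig(w_z = 1, w_theta = 0, w_v = 0)
  expect_equal(totalLoss(0, matrix(c(1, 0, 0), 3, 1), NULL, 0, cfg), 1)
  expect_equal(totalLoss(0, matrix(0, 3, 1), NULL, 5,
                         trainConfig(w_z = 0, w_v = 0)), 0)
  # arbitrary inputs vs a hand sum
  set.seed(93)
  errs <- runif(4)
  Z <- matrix(rnorm(12), 6, 2)
  params <- list(a = matrix(rnorm(4), 2), b = rnorm(3))
  cfg2 <- trainConfig(w_z = 1e-3, w_theta = 1e-2, w_v = 1e-4)
  expect_equal(totalLoss(errs, Z, params, 3.7, cfg2),
               mean(errs) + 1e-3 * sum(Z^2) +
                 1e-2 * (sum(params$a^2) + sum(params$b^2)) + 1e-4 * 3.7,
               tolerance = 1e-12)
})

test_that("two-stage adaptive point sampling", {
  set.seed(94)
  n <- 5000
  loss <- numeric(n)
  # all-zero loss at epoch 0: pure uniform, exactly M unique indices
  idx <- pointSample(n, loss, M = 2000, a = 0.15)
  expect_length(idx, 2000)
  expect_false(anyDuplicated(idx) > 0)
  # loss concentrated on 300 known indices: exactly those retained
  hot <- sample.int(n, 300)
  loss[hot] <- runif(300, 1, 2)
  idx2 <- pointSample(n, loss, M = 2000, a = 0.15)
  expect_length(idx2, 2000)
  expect_true(all(hot %in% idx2))
  expect_setequal(intersect(idx2[1:300], hot), hot)
  # a = 0: uniform regardless of the loss
  idx3 <- pointSample(n, loss, M = 2000, a = 0)
  expect_length(idx3, 2000)
  # M larger than the cloud: everything, with a warning
  expect_warning(idx4 <- pointSample(10, numeric(10), M = 50),
                 "exceeds")
  expect_identical(idx4, 1:10)
  # seeded reproducibility
  expect_identical(pointSample(n, loss, 100, 0.15, seed = 3),
                   pointSample(n, loss, 100, 0.15, seed = 3))
})

test_that("batch partition covers every shape exactly once", {
  b <- makeBatches(780, 8, seed = 1)
  expect_length(b, 97)
  sizes <- lengths(b)
  expect_equal(sum(sizes), 780)
  expect_equal(sort(unique(sizes)), c(8L, 9L))
  expect_equal(sum(sizes == 9), 4)
  expect_setequal(unlist(b), 1:780)
  expect_length(makeBatches(8, 8, seed = 2), 1)
  expect_identical(sort(makeBatches(5, 8, seed = 3)[[1]]), 1:5)
})

test_that("a batch update touches only that batch's codes and matches a
           finite-difference code gradient", {
  set.seed(95)
  shapes <- lapply(1:3, function(i) randomCloud(30, label = paste0("s", i)))
  template <- randomCloud(30, label = "t")
  net <- netConfig(fa_layers = 2, fa_width = 8, df_layers = 2,
                   df_width = 16, n_e = 2, n_z = 16, K = 4)
  cfg <- trainConfig(sample = 30, adaptive_fraction = 0, lr = 1e-3,
                     seed = 95)
  init <- initModelAndCodes(net, cfg, shapes)
  model <- init$model
  model$params[["head.W"]] <- matrix(rnorm(16 * 3, sd = 0.05), 16, 3)
  codes <- init$codes
  state <- list(theta = vascuflow:::adamInit(model$params),
                codeStates = lapply(1:3, function(i)
                  vascuflow:::adamVecInit(16)))
  lossState <- new.env()
  lossState$Ls <- lapply(shapes, function(s) numeric(30))
  lossState$LtShape <- lapply(1:3, function(i) numeric(30))
  lossState$Lt <- numeric(30)
  step <- vascuflow:::trainBatchStep(2L, shapes, template, model, codes,
                                     state, cfg, chamfer, lossState)
  expect_identical(step$codes[, 1], codes[, 1])
  expect_identical(step$codes[, 3], codes[, 3])
  expect_false(identical(step$codes[, 2], codes[, 2]))
  expect_false(identical(step$model$params, model$params))
  # loss decomposition: logged pieces recombine to the logged total
  expect_equal(step$loss,
               step$data + step$code_pen + step$theta_pen +
                 cfg$w_v * step$reg,
               tolerance = 1e-9)
})

test_that("self-registration of the template stays converged and training
           on a shifted shape reduces the error", {
  set.seed(96)
  template <- randomCloud(40, label = "t")
  net <- netConfig(fa_layers = 2, fa_width = 8, df_layers = 2,
                   df_width = 16, n_e = 2, n_z = 16, K = 4)
  # source identical to template: identity init is already optimal and the
  # data term must stay at machine level
  fitSelf <- train(list(template), template,
                   trainConfig(epochs = 10, batch = 1, sample = 40,
                               adaptive_fraction = 0, lr = 1e-4,
                               seed = 96), net)
  expect_lt(fitSelf$history$data[10], 1e-6)
  # rigidly shifted source: a short run must cut the bidirectional CD
  shifted <- weightedPointCloud(sweep(template$points, 2,
                                      c(0.08, -0.05, 0.04), "+"),
                                template$weights, label = "s")
  pre <- chamfer(shifted, template)$total + chamfer(template, shifted)$total
  fit <- train(list(shifted), template,
               trainConfig(epochs = 60, batch = 1, sample = 40,
                           adaptive_fraction = 0, lr = 3e-3, seed = 97),
               net)
  r <- registerShape(shifted, template, fit$model, fit$codes[, 1])
  post <- chamfer(r$mapped, template)$total +
    chamfer(r$inverse_mapped, shifted)$total
  expect_lt(post, 0.5 * pre)
})

test_that("training runs with the Sinkhorn measure (uniform sampling path)",
{
  set.seed(98)
  template <- randomCloud(12, label = "t")
  src <- weightedPointCloud(template$points +
                              matrix(rnorm(36, sd = 0.02), 12, 3),
                            label = "s")
  net <- netConfig(fa_layers = 1, fa_width = 8, df_layers = 1,
                   df_width = 8, n_e = 1, n_z = 8, K = 2)
  fit <- train(list(src), template,
               trainConfig(epochs = 3, batch = 1, sample = 12,
                           measure = "sd", seed = 98), net)
  expect_true(all(is.finite(fit$history$total)))
})

test_that("latent inference leaves the network parameters bitwise frozen", {
  set.seed(99)
  template <- randomCloud(25, label = "t")
  src <- weightedPointCloud(sweep(template$points, 2, c(0.05, 0, 0), "+"),
                            label = "s")
  model <- tinyModel(99, head_sd = 0.02,
                     config = netConfig(fa_layers = 2, fa_width = 8,
                                        df_layers = 2, df_width = 16,
                                        n_e = 2, n_z = 16, K = 4))
  before <- model$params
  res <- inferLatent(src, template, model,
                     trainConfig(sample = 25, lr = 1e-3),
                     adam_epochs = 5, lbfgs_epochs = 2, seed = 99)
  expect_identical(model$params, before)
  expect_length(res$code, 16)
  expect_true(is.finite(res$errors$direct$max_fld))
})
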