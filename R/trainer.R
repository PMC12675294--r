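#' Training configuration
#'
#' Hyperparameters of the joint optimization of network parameters and shape
#' codes. Defaults are the full-size values: 500 epochs, batch size 8,
#' 2000-point sub-clouds with adaptive fraction 0.15, learning rate 1e-3
#' shared by parameters and codes, loss weights `w_z = 1e-3` (code norm),
#' `w_v = 1e-4` (kinetic energy) and `w_theta = 0` (parameter norm, whose
#' value was never calibrated; the term is kept available).
#'
#' @param epochs,batch,sample,adaptive_fraction,lr training loop controls.
#' @param w_z,w_theta,w_v loss weights.
#' @param w_n normals penalty weight (NCD measure only).
#' @param measure attachment measure name (see [attachmentMeasure()]).
#' @param seed RNG seed governing initialization, batching and sampling.
#' @return a `train_config` list.
#' @export
trainConfig <- function(epochs = 500L, batch = 8L, sample = 2000L,
                        adaptive_fraction = 0.15, lr = 1e-3, w_z = 1e-3,
                        w_theta = 0, w_v = 1e-4, w_n = 1e-2,
                        measure = "cd", seed = 1L) {
  stopifnot(adaptive_fraction >= 0, adaptive_fraction < 1, batch >= 1,
            sample >= 1)
  structure(list(epochs = as.integer(epochs), batch = as.integer(batch),
                 sample = as.integer(sample),
                 adaptive_fraction = adaptive_fraction, lr = lr, w_z = w_z,
                 w_theta = w_theta, w_v = w_v, w_n = w_n, measure = measure,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize model and shape codes
#'
#' Kaiming-normal network initialization (zeroed flow head, so the initial
#' map is the identity) and one latent code per training shape drawn from
#' a zero-mean Gaussian with per-entry variance `2 / n_z`. Fully determined
#' by `config$seed`.
#'
#' @param net a [netConfig()].
#' @param config a [trainConfig()].
#' @param shapes list of training `weighted_point_cloud`s.
#' @return list with `model` (a `velocity_model`) and `codes`
#'   (`n_z x N_s` matrix, columns named by shape labels).
#' @export
initModelAndCodes <- function(net, config, shapes) {
  if (length(shapes) < 1L) stop("need at least one training shape")
  set.seed(config$seed)
  model <- initVelocityModel(net)
  ns <- length(shapes)
  codes <- matrix(stats::rnorm(net$n_z * ns, sd = sqrt(2 / net$n_z)),
                  nrow = net$n_z)
  labs <- vapply(seq_along(shapes), function(i)
    shapes[[i]]$label %||% sprintf("shape%02d", i), character(1L))
  labs[labs == ""] <- sprintf("shape%02d", which(labs == ""))
  colnames(codes) <- labs
  list(model = model, codes = codes)
}

#' Kinetic-energy regularizer
#'
#' Sum of squared logged velocities over all points and all integration
#' steps of the supplied trajectories (forward and backward passes both
#' contribute).
#'
#' @param trajectories a `flow_trajectory` or list of them.
#' @return nonnegative scalar.
#' @export
regularizer <- function(trajectories) {
  if (inherits(trajectories, "flow_trajectory"))
    trajectories <- list(trajectories)
  sum(vapply(trajectories, function(tr) {
    if (is.null(tr$velocities)) stop("trajectory carries no velocity log")
    sum(vapply(tr$velocities, function(v) sum(v^2), numeric(1L)))
  }, numeric(1L)))
}

#' Assemble the total training loss
#'
#' Mean bidirectional mapping error over the batch plus the code-norm,
#' parameter-norm and kinetic-energy penalties.
#'
#' @param batch_errors numeric vector of per-shape bidirectional errors.
#' @param codes the full code matrix (or a list of code vectors).
#' @param params the model parameter list (may be `NULL` when
#'   `w_theta = 0`).
#' @param L_reg kinetic-energy regularizer value.
#' @param config a [trainConfig()].
#' @return scalar loss.
#' @export
totalLoss <- function(batch_errors, codes, params, L_reg, config) {
  thetaPen <- if (config$w_theta > 0)
    config$w_theta * sum(vapply(params, function(p) sum(p^2), numeric(1L)))
  else 0
  mean(batch_errors) + config$w_z * sum(unlist(codes)^2) + thetaPen +
    config$w_v * L_reg
}

#' Two-stage adaptive point sampling
#'
#' Samples `M` unique point indices: the `floor(a M)` points with the
#' largest current pointwise loss are retained, the remaining
#' `ceiling((1 - a) M)` are drawn uniformly without replacement from the
#' rest. With `a = 0` or an all-zero loss state (epoch 0, or a measure with
#' no pointwise decomposition) the sample is fully uniform.
#'
#' @param cloud a `weighted_point_cloud` or an integer point count.
#' @param pointwise_loss numeric vector of per-point losses (full cloud
#'   length), or `NULL`.
#' @param M sample size.
#' @param a adaptive fraction in `[0, 1)`.
#' @param seed optional seed (uses the current RNG stream when `NULL`).
#' @return integer vector of `min(M, n)` unique indices.
#' @export
pointSample <- function(cloud, pointwise_loss = NULL, M, a = 0.15,
                        seed = NULL) {
  n <- if (is.numeric(cloud) && length(cloud) == 1L) as.integer(cloud)
       else nPoints(cloud)
  if (!is.null(seed)) set.seed(seed)
  if (M >= n) {
    if (M > n) warning("sample size exceeds cloud cardinality; using all points")
    return(seq_len(n))
  }
  if (a <= 0 || is.null(pointwise_loss) || all(pointwise_loss == 0))
    return(sample.int(n, M))
  if (length(pointwise_loss) != n)
    stop("pointwise loss length does not match cloud cardinality")
  nTop <- floor(a * M)
  retained <- order(pointwise_loss, decreasing = TRUE)[seq_len(nTop)]
  rest <- setdiff(seq_len(n), retained)
  c(retained, sample(rest, M - nTop))
}

#' Seed-shuffled batch partition
#'
#' Partitions `{1..N_s}` into batches after a random shuffle: the first
#' `N_s mod B` batches have size `B + 1`, the remainder size `B`, so every
#' shape appears exactly once per epoch.
#'
#' @param n_s number of shapes.
#' @param B nominal batch size.
#' @param seed optional seed.
#' @return list of integer index vectors whose lengths sum to `n_s`.
#' @export
makeBatches <- function(n_s, B, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n_s)
  if (n_s <= B) return(list(perm))
  r <- n_s %% B
  sizes <- c(rep(B + 1L, r), rep(B, (n_s - r * (B + 1L)) %/% B))
  split(perm, rep(seq_along(sizes), sizes))
}

subsetCloud <- function(cloud, idx) {
  weightedPointCloud(cloud$points[idx, , drop = FALSE],
                     cloud$weights[idx] / sum(cloud$weights[idx]),
                     if (!is.null(cloud$normals))
                       cloud$normals[idx, , drop = FALSE],
                     label = cloud$label)
}

cloudLike <- function(points, proto) {
  weightedPointCloud(points, proto$weights, proto$normals,
                     label = proto$label)
}

# Gradient of measure(A, B) wrt the points of A, dispatched by name.
measureGradFirst <- function(A, B, config) {
  if (config$measure %in% c("cd", "cdw", "ncd", "pcd"))
    chamferGradFirst(A, B, measure = config$measure, w_n = config$w_n)
  else
    sinkhornGradFirst(A, B, weighted = identical(config$measure, "sdw"))
}

# One batch of the training loop: returns loss pieces and applies updates.
# Shared by train() (all parameters) and inferLatent() (codes only).
trainBatchStep <- function(batchIdx, shapes, template, model, codes, state,
                           config, measureFn, lossState, updateTheta = TRUE,
                           lr = config$lr) {
  bb <- length(batchIdx)
  a <- config$adaptive_fraction
  M <- min(config$sample, nPoints(template))
  tIdx <- pointSample(template, lossState$Lt, M, a)
  Tb <- subsetCloud(template, tIdx)
  acc <- zeroGrads(model)
  dataErrs <- numeric(bb)
  regTotal <- 0
  dCodes <- vector("list", bb)
  for (q in seq_len(bb)) {
    i <- batchIdx[q]
    S <- shapes[[i]]
    sIdx <- pointSample(S, lossState$Ls[[i]], min(config$sample, nPoints(S)),
                        a)
    Sb <- subsetCloud(S, sIdx)
    grid <- reshapeCode(codes[, i], model$config$g_z)
    trajF <- forwardMap(Sb$points, model, grid, keep_cache = TRUE)
    trajB <- inverseMapExplicit(Tb$points, model, grid, keep_cache = TRUE)
    mappedS <- cloudLike(trajectoryEndpoint(trajF), Sb)
    mappedT <- cloudLike(trajectoryEndpoint(trajB), Tb)
    direct <- measureFn(mappedS, Tb)
    inverse <- measureFn(mappedT, Sb)
    dataErrs[q] <- direct$total + inverse$total
    regTotal <- regTotal + regularizer(list(trajF, trajB))
    dvF <- lapply(trajF$velocities, function(v) 2 * config$w_v * v)
    dvB <- lapply(trajB$velocities, function(v) 2 * config$w_v * v)
    gF <- measureGradFirst(mappedS, Tb, config) / bb
    gB <- measureGradFirst(mappedT, Sb, config) / bb
    fb <- forwardMapBackward(trajF, grid, model, gF, dvF, acc)
    ib <- inverseMapBackward(trajB, grid, model, gB, dvB, acc)
    dCodes[[q]] <- unreshapeCode(fb$dgrid + ib$dgrid) +
      2 * config$w_z * codes[, i]
    if (direct$supports_pointwise) {
      lossState$Ls[[i]][] <- 0
      lossState$Ls[[i]][sIdx] <- direct$pointwise_forward
      lossState$LtShape[[i]][] <- 0
      lossState$LtShape[[i]][tIdx] <- inverse$pointwise_forward
    }
  }
  if (updateTheta) {
    if (config$w_theta > 0)
      for (nm in names(model$params))
        acc$g[[nm]] <- acc$g[[nm]] + 2 * config$w_theta * model$params[[nm]]
    model$params <- adamStep(state$theta, model$params, acc$g, lr)
  }
  for (q in seq_len(bb)) {
    i <- batchIdx[q]
    codes[, i] <- adamVecStep(state$codeStates[[i]], codes[, i],
                              dCodes[[q]], lr)
  }
  loss <- totalLoss(dataErrs, codes, model$params, regTotal, config)
  list(model = model, codes = codes,
       loss = loss, data = mean(dataErrs), reg = regTotal,
       code_pen = config$w_z * sum(codes^2),
       theta_pen = if (config$w_theta > 0)
         config$w_theta * sum(vapply(model$params, function(p) sum(p^2),
                                     numeric(1L))) else 0)
}

#' Train the registration model
#'
#' Joint optimization of the velocity-field network and the per-shape latent
#' codes: per epoch, shapes are partitioned into seed-shuffled batches; per
#' batch, a template sub-cloud and per-shape source sub-clouds are drawn by
#' two-stage adaptive sampling, sources are forward-mapped, the template
#' sub-cloud is backward-mapped (modified Euler), the bidirectional
#' attachment loss plus penalties is assembled, and network parameters and
#' the batch's codes are updated by Adam. The template's adaptive-sampling
#' loss is the per-epoch average of the per-shape inverse pointwise losses.
#'
#' @param shapes list of source `weighted_point_cloud`s (unit-cube frame).
#' @param template the template `weighted_point_cloud`.
#' @param config a [trainConfig()].
#' @param net a [netConfig()].
#' @param verbose print a line every `verbose` epochs (0 = silent).
#' @return An object of class `svfd_fit`: `model`, `codes`, `history`
#'   (one row per epoch with loss components), `config`, `template_label`.
#' @export
train <- function(shapes, template, config = trainConfig(),
                  net = netConfig(), verbose = 0L) {
  init <- initModelAndCodes(net, config, shapes)
  model <- init$model
  codes <- init$codes
  ns <- length(shapes)
  state <- list(theta = adamInit(model$params),
                codeStates = lapply(seq_len(ns), function(i)
                  adamVecInit(net$n_z)))
  lossState <- new.env(parent = emptyenv())
  lossState$Ls <- lapply(shapes, function(s) numeric(nPoints(s)))
  lossState$LtShape <- lapply(seq_len(ns), function(i)
    numeric(nPoints(template)))
  lossState$Lt <- numeric(nPoints(template))
  measureFn <- attachmentMeasure(config$measure, w_n = config$w_n)
  hist <- vector("list", config$epochs)
  for (e in seq_len(config$epochs)) {
    batches <- makeBatches(ns, config$batch)
    lastStep <- NULL
    for (bIdx in batches) {
      step <- trainBatchStep(bIdx, shapes, template, model, codes, state,
                             config, measureFn, lossState)
      model <- step$model
      codes <- step$codes
      lastStep <- step
      if (!is.finite(step$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", e))
    }
    lossState$Lt <- Reduce(`+`, lossState$LtShape) / ns
    hist[[e]] <- data.frame(epoch = e, total = lastStep$loss,
                            data = lastStep$data,
                            code_penalty = lastStep$code_pen,
                            theta_penalty = lastStep$theta_pen,
                            reg = lastStep$reg)
    if (verbose > 0L && (e %% verbose == 0L || e == 1L))
      message(sprintf("epoch %4d | total %.6f | data %.6f | reg %.4g",
                      e, lastStep$loss, lastStep$data, lastStep$reg))
  }
  structure(list(model = model, codes = codes,
                 history = do.call(rbind, hist), config = config,
                 template_label = template$label),
            class = "svfd_fit")
}

#' @export
print.svfd_fit <- function(x, ...) {
  cat(sprintf("svfd_fit: %d shapes, %d epochs trained, final loss %.6g\n",
              ncol(x$codes), nrow(x$history),
              x$history$total[nrow(x$history)]))
  print(x$model)
  invisible(x)
}

#' Register a shape with a trained model
#'
#' Applies the forward map to the source and the backward (modified Euler by
#' default, implicit on request) map to the template under the given code,
#' and reports FLD/BLD summaries.
#'
#' @param S source cloud; `T_` template cloud.
#' @param model a `velocity_model`; `code` its latent code.
#' @param scheme backward integrator: `"explicit"` (modified Euler) or
#'   `"implicit"`.
#' @param inverse_transform optional `unit_cube_transform` for cm errors.
#' @return list with `mapped` and `inverse_mapped` clouds, both trajectory
#'   objects, and `errors` (FLD/BLD of the direct and inverse maps).
#' @export
registerShape <- function(S, T_, model, code,
                          scheme = c("explicit", "implicit"),
                          inverse_transform = NULL) {
  scheme <- match.arg(scheme)
  trajF <- forwardMap(S$points, model, code)
  trajB <- if (scheme == "explicit")
    inverseMapExplicit(T_$points, model, code)
  else inverseMapImplicit(T_$points, model, code)
  mapped <- cloudLike(trajectoryEndpoint(trajF), S)
  invMapped <- cloudLike(trajectoryEndpoint(trajB), T_)
  list(mapped = mapped, inverse_mapped = invMapped,
       forward_trajectory = trajF, backward_trajectory = trajB,
       errors = list(direct = fldBld(mapped, T_, inverse_transform),
                     inverse = fldBld(invMapped, S, inverse_transform)))
}

#' Test-time latent inference
#'
#' Optimizes only the latent code of an unseen shape against a frozen model:
#' 100 Adam epochs at 50x the training learning rate, then 10 quasi-Newton
#' (L-BFGS) epochs on a fixed sub-sample. On a line-search failure the best
#' Adam iterate is returned with `lbfgs_ok = FALSE`.
#'
#' @param test_cloud the unseen source cloud.
#' @param template the template cloud.
#' @param model the trained (frozen) `velocity_model`.
#' @param config a [trainConfig()]; `sample`, `lr`, `w_z`, `w_v`, `measure`
#'   are honoured.
#' @param adam_epochs,lbfgs_epochs phase lengths.
#' @param seed RNG seed for the sub-sampling.
#' @return list with `code`, `mapped`, `inverse_mapped`, `errors`
#'   (FLD/BLD), `history` of Adam losses, `lbfgs_ok`.
#' @export
inferLatent <- function(test_cloud, template, model,
                        config = trainConfig(), adam_epochs = 100L,
                        lbfgs_epochs = 10L, seed = 1L) {
  set.seed(seed)
  nz <- model$config$n_z
  z <- numeric(nz)
  measureFn <- attachmentMeasure(config$measure, w_n = config$w_n)
  M <- config$sample
  M <- min(M, nPoints(test_cloud), nPoints(template))
  lossGrad <- function(z, sIdx, tIdx) {
    Sb <- subsetCloud(test_cloud, sIdx)
    Tb <- subsetCloud(template, tIdx)
    grid <- reshapeCode(z, model$config$g_z)
    trajF <- forwardMap(Sb$points, model, grid, keep_cache = TRUE)
    trajB <- inverseMapExplicit(Tb$points, model, grid, keep_cache = TRUE)
    mappedS <- cloudLike(trajectoryEndpoint(trajF), Sb)
    mappedT <- cloudLike(trajectoryEndpoint(trajB), Tb)
    direct <- measureFn(mappedS, Tb)
    inverse <- measureFn(mappedT, Sb)
    reg <- regularizer(list(trajF, trajB))
    loss <- direct$total + inverse$total + config$w_z * sum(z^2) +
      config$w_v * reg
    acc <- zeroGrads(model)
    dvF <- lapply(trajF$velocities, function(v) 2 * config$w_v * v)
    dvB <- lapply(trajB$velocities, function(v) 2 * config$w_v * v)
    fb <- forwardMapBackward(trajF, grid, model,
                             measureGradFirst(mappedS, Tb, config), dvF,
                             acc)
    ib <- inverseMapBackward(trajB, grid, model,
                             measureGradFirst(mappedT, Sb, config), dvB,
                             acc)
    list(loss = loss,
         grad = unreshapeCode(fb$dgrid + ib$dgrid) + 2 * config$w_z * z)
  }
  st <- adamVecInit(nz)
  histLoss <- numeric(adam_epochs)
  for (e in seq_len(adam_epochs)) {
    sIdx <- pointSample(test_cloud, NULL, M, 0)
    tIdx <- pointSample(template, NULL, M, 0)
    lg <- lossGrad(z, sIdx, tIdx)
    histLoss[e] <- lg$loss
    z <- adamVecStep(st, z, lg$grad, 50 * config$lr)
  }
  # quasi-Newton fine-tuning on a fixed sub-sample
  sIdx <- pointSample(test_cloud, NULL, M, 0)
  tIdx <- pointSample(template, NULL, M, 0)
  lbfgsOk <- TRUE
  zAdam <- z
  res <- tryCatch(
    stats::optim(z, fn = function(p) lossGrad(p, sIdx, tIdx)$loss,
                 gr = function(p) lossGrad(p, sIdx, tIdx)$grad,
                 method = "L-BFGS-B",
                 control = list(maxit = as.integer(lbfgs_epochs))),
    error = function(e) NULL)
  if (is.null(res) || !all(is.finite(res$par))) {
    lbfgsOk <- FALSE
    z <- zAdam
  } else z <- res$par
  reg <- registerShape(test_cloud, template, model, z)
  list(code = z, mapped = reg$mapped, inverse_mapped = reg$inverse_mapped,
       errors = reg$errors, history = histLoss, lbfgs_ok = lbfgsOk)
}
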