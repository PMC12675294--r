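# Desk-scale registration world shared by the trainer, inference,
# generative and acceptance tests: a curved one-branch vessel template plus
# a 5-member cohort (4 training shapes, 1 held out), registered with the
# small network configuration. Training runs are cached per seed so the
# suite trains each seed at most once.

.toyCache <- new.env(parent = emptyenv())

toyNet <- function() {
  netConfig(fa_layers = 2L, fa_width = 32L, df_layers = 3L, df_width = 64L,
            n_e = 3L, n_z = 32L, g_z = 2L, K = 10L)
}

toyTrainConfig <- function(seed) {
  trainConfig(epochs = 150L, batch = 1L, sample = 500L, lr = 1e-3,
              seed = seed)
}

toyWorld <- function() {
  if (!is.null(.toyCache$world)) return(.toyCache$world)
  spec <- aortaSpec(n_circ = 10L, n_long = 16L, n_branches = 1L)
  meshes <- makeCohort(spec, 5L, variation_scale = 0.08, seed = 21L)
  pre <- preprocessCohort(makeTube(spec), meshes, margin = 0.05,
                          cpd = TRUE)
  world <- list(template = pre$template,
                train_shapes = pre$sources[1:4],
                holdout = pre$sources[[5L]],
                transform = pre$transform)
  .toyCache$world <- world
  world
}

toyFit <- function(seed = 7L) {
  key <- sprintf("fit%d", seed)
  if (!is.null(.toyCache[[key]])) return(.toyCache[[key]])
  w <- toyWorld()
  fit <- train(w$train_shapes, w$template, toyTrainConfig(seed), toyNet())
  .toyCache[[key]] <- fit
  fit
}

# mean bidirectional Chamfer distance of a cohort against the template
cohortBidirCd <- function(shapes, template, fit = NULL) {
  mean(vapply(seq_along(shapes), function(i) {
    if (is.null(fit)) {
      chamfer(shapes[[i]], template)$total +
        chamfer(template, shapes[[i]])$total
    } else {
      r <- registerShape(shapes[[i]], template, fit$model, fit$codes[, i])
      chamfer(r$mapped, template)$total +
        chamfer(r$inverse_mapped, shapes[[i]])$total
    }
  }, numeric(1)))
}
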