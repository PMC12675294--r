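#' Run configuration
#'
#' Nested configuration tying all modules into a reproducible run. Stored as
#' JSON; unknown sections or keys are rejected with their field path, and a
#' read/write round trip is lossless.
#'
#' @param preprocessing,net,training,attachment,inference,generation named
#'   lists overriding section defaults.
#' @param seed global RNG seed.
#' @param out_dir output directory for run artifacts.
#' @return a `run_config` list.
#' @export
runConfig <- function(preprocessing = list(), net = list(),
                      training = list(), attachment = list(),
                      inference = list(), generation = list(), seed = 1L,
                      out_dir = "run") {
  defaults <- list(
    preprocessing = list(margin = 0.05, cpd = TRUE, cpd_outlier = 0.1),
    net = unclass(netConfig())[c("fa_layers", "fa_width", "df_layers",
                                 "df_width", "n_e", "leaky_slope", "n_z",
                                 "g_z", "K")],
    training = unclass(trainConfig())[c("epochs", "batch", "sample",
                                        "adaptive_fraction", "lr", "w_z",
                                        "w_theta", "w_v", "w_n",
                                        "measure")],
    attachment = list(measure = "cd", w_n = 1e-2, epsilon = 1e-4,
                      scaling = 0.9),
    inference = list(adam_epochs = 100L, lbfgs_epochs = 10L),
    generation = list(n = 10L, snr = 0.05, interp_mode = "slerp"))
  sections <- list(preprocessing = preprocessing, net = net,
                   training = training, attachment = attachment,
                   inference = inference, generation = generation)
  cfg <- defaults
  for (sec in names(sections)) {
    override <- sections[[sec]]
    bad <- setdiff(names(override), names(defaults[[sec]]))
    if (length(bad) > 0L)
      stop(sprintf("unknown config key(s): %s",
                   paste0(sec, ".", bad, collapse = ", ")))
    cfg[[sec]][names(override)] <- override
  }
  cfg$seed <- as.integer(seed)
  cfg$out_dir <- out_dir
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as JSON
#' @param path JSON file path.
#' @return `readRunConfig` returns a `run_config`.
#' @export
readRunConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("preprocessing", "net", "training", "attachment", "inference",
             "generation", "seed", "out_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L)
    stop(sprintf("unknown config section(s): %s", paste(bad, collapse = ", ")))
  do.call(runConfig, raw)
}

#' @rdname readRunConfig
#' @param config a `run_config`.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Preprocess a cohort into the shared unit-cube frame
#'
#' Converts meshes to weighted point clouds, rigidly pre-aligns every source
#' to the template by CPD, fits one shared anisotropic unit-cube transform
#' over the whole cohort, and applies it.
#'
#' @param template a `surface_mesh` or `weighted_point_cloud`.
#' @param sources list of `surface_mesh`es or clouds.
#' @param margin unit-cube margin.
#' @param cpd run the rigid pre-alignment.
#' @param cpd_outlier CPD uniform outlier weight.
#' @return list with `template`, `sources` (clouds in the unit cube),
#'   `transform` (the shared `unit_cube_transform`), `cpd` (per-source
#'   `cpd_result`s or `NULL`).
#' @export
preprocessCohort <- function(template, sources, margin = 0.05, cpd = TRUE,
                             cpd_outlier = 0.1) {
  toCloud <- function(x, lab) {
    if (inherits(x, "surface_mesh")) meshToCloud(x, label = lab)
    else x
  }
  tmpl <- toCloud(template, "template")
  srcs <- lapply(seq_along(sources), function(i)
    toCloud(sources[[i]], sprintf("source%02d", i)))
  cpdRes <- NULL
  if (cpd) {
    cpdRes <- lapply(srcs, function(s)
      cpdRigid(s, tmpl, outlier_weight = cpd_outlier))
    srcs <- lapply(cpdRes, function(r) r$aligned)
  }
  tf <- fitUnitCube(c(list(tmpl), srcs), margin = margin)
  list(template = applyUnitCube(tf, tmpl),
       sources = lapply(srcs, function(s) applyUnitCube(tf, s)),
       transform = tf, cpd = cpdRes)
}

#' Evaluate a mapped cloud against a target
#'
#' JSON-able report with the configured measure value and FLD/BLD
#' summaries; with an inverse unit-cube transform the distances are in cm.
#'
#' @param mapped,target `weighted_point_cloud`s.
#' @param measure measure name (see [attachmentMeasure()]).
#' @param inverse_transform optional `unit_cube_transform`.
#' @return named list (report).
#' @export
evaluateClouds <- function(mapped, target, measure = "cd",
                           inverse_transform = NULL) {
  fn <- attachmentMeasure(measure)
  res <- fn(mapped, target)
  fb <- fldBld(mapped, target, inverse_transform)
  list(measure = measure, value = res$total,
       forward_term = res$forward_term, backward_term = res$backward_term,
       max_fld = fb$max_fld, mean_fld = fb$mean_fld,
       max_bld = fb$max_bld, mean_bld = fb$mean_bld,
       units = if (is.null(inverse_transform)) "unit-cube" else "cm")
}
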