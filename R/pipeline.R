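# End-to-end orchestration: generate -> morphometrics -> oxygen labels ->
# train -> score -> reports, with a JSON manifest recording the config,
# every seed consumed, and content hashes of all outputs. One master seed
# fans out to per-stage seeds through derive_seed() with fixed stage
# counters, so a rerun with the same config and master seed reproduces
# every CSV bit for bit.

STAGE_COUNTERS <- c(cohort = 1L, split = 2L, train = 3L, sweep = 4L)

#' Pipeline configuration
#'
#' @param n Cohort size.
#' @param base Generator [generator_config()] used as the jitter base.
#' @param jitter Named list of `c(lo, hi)` ranges ([default_cohort_jitter()]).
#' @param params Transport parameters ([transport_params()]).
#' @param spec Training specification ([chain_spec()]).
#' @param train_frac Train/test fraction.
#' @param learning_sizes Training-set sizes for the learning curve; `NULL`
#'   skips the learning-curve stage.
#' @param n_partitions Repartitionings for the stability stage; `NULL` skips.
#' @param write_masks Whether to write each mask as a PNG.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n = 500, base = generator_config(),
                            jitter = default_cohort_jitter(),
                            params = transport_params(),
                            spec = chain_spec(),
                            train_frac = 0.8,
                            learning_sizes = c(50, 100, 200, 300, 400),
                            n_partitions = 10,
                            write_masks = FALSE) {
  structure(list(n = n, base = base, jitter = jitter, params = params,
                 spec = spec, train_frac = train_frac,
                 learning_sizes = learning_sizes,
                 n_partitions = n_partitions, write_masks = write_masks),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments, except that the
#' cohort size is spelled `n_samples` (a bare `n` is boolean shorthand in
#' YAML 1.1); `base`, `params`
#' and `spec` are nested maps passed to their constructors; `jitter` maps
#' field names to `[lo, hi]` pairs. Missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  # cohort size key is `n_samples`: a bare `n` is YAML 1.1 boolean shorthand
  if (!is.null(y$n_samples)) args$n <- y$n_samples
  else if (!is.null(y[["FALSE"]])) args$n <- y[["FALSE"]]
  if (!is.null(y$train_frac)) args$train_frac <- y$train_frac
  if (!is.null(y$learning_sizes)) args$learning_sizes <- unlist(y$learning_sizes)
  if (!is.null(y$n_partitions)) args$n_partitions <- y$n_partitions
  if (!is.null(y$write_masks)) args$write_masks <- y$write_masks
  if (!is.null(y$base)) args$base <- do.call(generator_config, y$base)
  if (!is.null(y$params)) args$params <- do.call(transport_params, y$params)
  if (!is.null(y$spec)) args$spec <- do.call(chain_spec, y$spec)
  if (!is.null(y$jitter)) args$jitter <- lapply(y$jitter, unlist)
  do.call(pipeline_config, args)
}

#' Generate, measure and label a synthetic cohort
#'
#' Convenience wrapper chaining [generate_cohort()], [measure_cohort()] and
#' [solve_oxygen()]/[summarize_oxygen()] into the sample table consumed by
#' the model harness.
#'
#' @param n Cohort size.
#' @param base,jitter Generator base config and jitter ranges.
#' @param params Transport parameters.
#' @param master_seed Integer seed for the cohort.
#' @param spur_len_px Spur-pruning length for morphometrics.
#' @return List with `records` (data frame: `sample_id`, six metrics,
#'   `oxy_v`, `oxy_t`), `manifest` (per-mask sampled configs) and `masks`.
#' @export
synthesize_dataset <- function(n = 500, base = generator_config(),
                               jitter = default_cohort_jitter(),
                               params = transport_params(),
                               master_seed = 1L, spur_len_px = 5) {
  coh <- generate_cohort(base, n, jitter, master_seed)
  morph <- measure_cohort(coh$masks, coh$manifest$sample_id,
                          spur_len_px = spur_len_px)
  oxy <- do.call(rbind, lapply(coh$masks, function(m) {
    summarize_oxygen(solve_oxygen(m, params), m, c0 = params$c0)
  }))
  list(records = cbind(morph, oxy), manifest = coh$manifest,
       masks = coh$masks)
}

#' Run the full pipeline and write all stage outputs
#'
#' Stages: cohort generation (manifest CSV, optional mask PNGs),
#' morphometrics + oxygen labels (dataset CSV), five-architecture comparison
#' (CSV), whole-cohort VNQI scores and Pearson ranking (CSVs), optional
#' stability and learning-curve reports (CSVs), and a run manifest (JSON)
#' with config snapshot, per-stage seeds and md5 hashes of every output.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param master_seed Master seed; per-stage seeds are derived from it.
#' @return The run manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         master_seed = 1L) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(
    cohort = derive_seed(master_seed, STAGE_COUNTERS[["cohort"]]),
    split = derive_seed(master_seed, STAGE_COUNTERS[["split"]]),
    train = derive_seed(master_seed, STAGE_COUNTERS[["train"]])
  )
  outputs <- character(0)
  put <- function(df, name) {
    path <- file.path(outdir, name)
    write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  message("stage 1/5: generating cohort (n = ", config$n, ")")
  ds <- synthesize_dataset(config$n, config$base, config$jitter,
                           config$params, seeds$cohort)
  put(ds$manifest, "cohort_manifest.csv")
  if (isTRUE(config$write_masks)) {
    mask_dir <- file.path(outdir, "masks")
    dir.create(mask_dir, showWarnings = FALSE)
    for (i in seq_along(ds$masks)) {
      p <- file.path(mask_dir, paste0(ds$manifest$sample_id[i], ".png"))
      write_mask(ds$masks[[i]], p)
      outputs <- c(outputs, p)
    }
  }
  put(ds$records, "dataset.csv")

  message("stage 2/5: architecture comparison")
  spec <- config$spec; spec$rng_seed <- seeds$train
  comparison <- compare_architectures(ds$records, spec,
                                      split_seed = seeds$split,
                                      train_frac = config$train_frac)
  put(comparison, "architecture_comparison.csv")

  message("stage 3/5: VNQI scoring and Pearson ranking")
  sp <- split_dataset(ds$records, config$train_frac, seeds$split)
  chain <- fit_chain(sp$train, spec)
  vnqi_all <- predict_vnqi(chain, ds$records)
  put(cbind(ds$records["sample_id"], vnqi = vnqi_all), "vnqi_scores.csv")
  put(pearson_ranking(ds$records, vnqi_all, target = "oxy_t"),
      "pearson_ranking.csv")

  if (!is.null(config$n_partitions)) {
    message("stage 4/5: repartitioning stability")
    put(stability_analysis(ds$records, spec, config$n_partitions,
                           train_frac = config$train_frac),
        "stability.csv")
  }
  if (!is.null(config$learning_sizes)) {
    message("stage 5/5: learning curve")
    put(learning_curve(ds$records, spec, config$learning_sizes,
                       seed = seeds$train, train_frac = config$train_frac),
        "learning_curve.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("vnqi")),
    timestamp = format(Sys.time(), tz = "UTC"),
    master_seed = master_seed,
    stage_seeds = seeds,
    config = config_snapshot(config),
    chain_manifest = chain$manifest,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

config_snapshot <- function(config) {
  list(n = config$n, base = unclass(config$base),
       jitter = config$jitter, params = unclass(config$params),
       spec = unclass(config$spec), train_frac = config$train_frac,
       learning_sizes = config$learning_sizes,
       n_partitions = config$n_partitions)
}

#' Sweep one generator determinant and score each level
#'
#' Synthetic analog of varying one experimental determinant of network
#' formation (cell density, matrix stiffness, growth-factor supplementation)
#' while a trained chain scores the resulting cohorts. All other generator
#' fields stay at `base`; each level gets `n_per_level` masks, and a
#' per-level Pearson ranking (six metrics + VNQI vs measured OXY_T) is
#' computed.
#'
#' @param chain A fitted [fit_chain()] object used for scoring.
#' @param base Generator base configuration.
#' @param knob Name of the [generator_config()] field to sweep.
#' @param levels Numeric vector of at least two knob values.
#' @param n_per_level Masks per level.
#' @param params Transport parameters for the oracle labels.
#' @param master_seed Integer seed.
#' @return List with `scores` (data frame: level, sample_id, metrics,
#'   oxy_v, oxy_t, vnqi) and `pearson` (per-level ranking table).
#' @export
sweep_determinant <- function(chain, base = generator_config(), knob,
                              levels, n_per_level = 25,
                              params = transport_params(),
                              master_seed = 1L) {
  if (!knob %in% names(unclass(base))) stopf("unknown generator field '%s'", knob)
  if (length(levels) < 2) stopf("need at least 2 levels to sweep")
  out <- list()
  for (i in seq_along(levels)) {
    cfg <- unclass(base)
    cfg[[knob]] <- if (knob == "n_seed_points")
      as.integer(round(levels[i])) else levels[i]
    cfg <- do.call(generator_config, cfg)
    ds <- synthesize_dataset(n_per_level, cfg, jitter = list(),
                             params = params,
                             master_seed = derive_seed(master_seed, i))
    rec <- ds$records
    rec$vnqi <- predict_vnqi(chain, rec)
    rec <- cbind(level = levels[i], rec)
    out[[i]] <- rec
  }
  scores <- do.call(rbind, out)
  scores$group <- paste0(knob, "=", scores$level)
  pearson <- suppressWarnings(
    pearson_ranking(scores, scores$vnqi, target = "oxy_t", group = "group")
  )
  list(scores = scores[, setdiff(names(scores), "group")], pearson = pearson)
}
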