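#' Unified pipeline configuration
#'
#' Nests the phantom, preprocessing, detection and counting parameters
#' with a single base seed, so a whole run is reproducible from one
#' object. By default the next-image parameters mirror the phantom's
#' bleed-through parameters (matched subtraction recovers the in-section
#' signal exactly on noise-free data).
#'
#' @param phantom a [phantom_config].
#' @param preprocess a [preprocess_config]; defaults to parameters matched
#'   to `phantom`.
#' @param detect a [detect_config].
#' @param d_min minimum fitted-cell center separation, pixels; defaults
#'   to the phantom's declared minimum center spacing (the specimen's
#'   packing limit is prior knowledge, as a cell diameter is in tissue).
#' @param pad counting patch padding, pixels.
#' @param culture_n singleton cells in the culture calibration image.
#' @param seed base seed; stage seeds are derived deterministically.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            preprocess = NULL,
                            detect = detect_config(),
                            d_min = NULL, pad = 2, culture_n = 150,
                            seed = 1) {
  d_min <- d_min %||% phantom$min_sep_px
  preprocess <- preprocess %||%
    preprocess_config(next_blur_sigma = phantom$bleed_blur_sigma,
                      next_attenuation = phantom$bleed_fraction)
  stopifnot(inherits(phantom, "phantom_config"),
            inherits(preprocess, "preprocess_config"),
            inherits(detect, "detect_config"))
  if (d_min <= 0) stop("d_min must be positive")
  structure(list(phantom = phantom, preprocess = preprocess,
                 detect = detect, d_min = d_min, pad = pad,
                 culture_n = as.integer(culture_n),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config a [pipeline_config].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- do.call(phantom_config, y$phantom[setdiff(names(y$phantom), "preset")])
  pp <- do.call(preprocess_config, y$preprocess)
  dt <- do.call(detect_config, y$detect)
  pipeline_config(phantom = ph, preprocess = pp, detect = dt,
                  d_min = y$d_min, pad = y$pad, culture_n = y$culture_n,
                  seed = y$seed)
}

#' Run the detection and counting pipeline on a stack
#'
#' Preprocesses the stack, sets the high threshold from a culture image
#' (when supplied and not fixed in the configuration), segments clusters,
#' calibrates the single-cell model from the volume's own singleton
#' clusters, and counts cells per cluster.
#'
#' @param stack a [fluor_stack].
#' @param config a [pipeline_config].
#' @param culture optional culture [fluor_stack] (single slice of
#'   well-separated cells) used to calibrate the high threshold.
#' @return object of class `cryo_run` with `igray`, `detection`, `model`
#'   and `counts`.
#' @export
run_pipeline <- function(stack, config = pipeline_config(), culture = NULL) {
  igray <- preprocess_stack(stack, config$preprocess)
  culture_maxima <- NULL
  if (is.null(config$detect$t_h)) {
    if (is.null(culture))
      stop("detect config has no t_h: supply a culture stack to calibrate it")
    cig <- suppressWarnings(preprocess_stack(culture, config$preprocess))
    culture_maxima <- culture_cluster_maxima(cig, config$detect$c_low)
  }
  detection <- detect_clusters(igray, config$detect, culture_maxima)
  model <- calibrate_cell_model(igray, detection, d_min = config$d_min,
                                pad = config$pad)
  counts <- count_clusters(detection, igray, model, pad = config$pad,
                           seed = config$seed)
  structure(list(igray = igray, detection = detection, model = model,
                 counts = counts, config = config),
            class = "cryo_run")
}

#' @export
print.cryo_run <- function(x, ...) {
  cat("<cryo_run>\n")
  print(x$detection)
  print(x$model)
  print(x$counts)
  invisible(x)
}

#' Simulate, run and score one phantom study
#'
#' The evaluation harness: generates a phantom and a matched culture
#' image, runs the full pipeline, matches detected clusters to ground
#' truth and scores the counts. Stage seeds are derived from `seed`.
#'
#' @param config a [phantom_config] describing the study conditions.
#' @param detect a [detect_config].
#' @param seed integer seed controlling phantom, culture and fitting.
#' @param d_min minimum fitted-cell separation; defaults to the phantom's
#'   declared minimum center spacing (the specimen's packing limit is
#'   prior knowledge, as a cell diameter is for real tissue).
#' @param pad counting patch padding, pixels.
#' @param culture_n singleton cells in the culture image.
#' @return list of class `phantom_study`: `phantom`, `run`, `metrics`.
#' @export
run_phantom_study <- function(config = phantom_config(), detect = detect_config(),
                              seed = 1, d_min = NULL, pad = 2, culture_n = 150) {
  d_min <- d_min %||% config$min_sep_px
  cfg <- config
  cfg$seed <- seed
  pcfg <- pipeline_config(phantom = cfg, detect = detect, d_min = d_min,
                          pad = pad, culture_n = culture_n, seed = seed + 2L)
  phantom <- generate_phantom(cfg)
  ccfg <- cfg; ccfg$seed <- seed + 1L
  culture <- generate_culture_image(ccfg, n_cells = culture_n)
  run <- run_pipeline(phantom$stack, pcfg, culture = culture$stack)
  match <- match_to_truth(phantom$truth, run$detection$labels)
  metrics <- evaluate_counts(phantom$truth, run$counts, match)
  structure(list(phantom = phantom, run = run, metrics = metrics),
            class = "phantom_study")
}

#' @export
print.phantom_study <- function(x, ...) {
  print(x$metrics)
  invisible(x)
}

#' Pipeline commands with file-based interchange
#'
#' `cmd_simulate()` writes phantom and culture stacks (per-channel
#' multi-page TIFF), the ground-truth CSV and a manifest;
#' `cmd_run()` reads a stack, runs the pipeline and writes the cluster
#' table, counts, placements, calibrated model, threshold report and
#' manifest; `cmd_evaluate()` scores a counts CSV against a ground-truth
#' CSV and writes metrics JSON. Reruns with the same configuration and
#' seed are bit-identical.
#'
#' @param config a [pipeline_config] or a path to its YAML form.
#' @param out_dir output directory (created if missing).
#' @param stack_prefix,culture_prefix stack path prefixes as written by
#'   [write_stack()].
#' @param counts_path,truth_path,out_path CSV/JSON file paths.
#' @return invisibly, the main output path(s).
#' @name pipeline-commands
NULL

as_pipeline_config <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  config
}

write_manifest <- function(out_dir, config, stage, outputs) {
  yaml::write_yaml(list(stage = stage,
                        package_version = as.character(packageVersion("cryocount")),
                        outputs = outputs,
                        config = lapply(unclass(config), function(x)
                          if (is.list(x)) unclass(x) else x)),
                   file.path(out_dir, paste0("manifest_", stage, ".yaml")))
}

#' @rdname pipeline-commands
#' @export
cmd_simulate <- function(config, out_dir) {
  config <- as_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config$phantom
  cfg$seed <- config$seed
  phantom <- generate_phantom(cfg)
  ccfg <- cfg; ccfg$seed <- config$seed + 1L
  culture <- generate_culture_image(ccfg, n_cells = config$culture_n)
  write_stack(phantom$stack, file.path(out_dir, "phantom"))
  write_stack(culture$stack, file.path(out_dir, "culture"))
  write_ground_truth(phantom$truth, file.path(out_dir, "truth.csv"))
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  write_manifest(out_dir, config, "simulate",
                 c("phantom_red.tif", "phantom_green.tif", "culture_red.tif",
                   "culture_green.tif", "truth.csv", "config.yaml"))
  invisible(file.path(out_dir, "phantom"))
}

#' @rdname pipeline-commands
#' @export
cmd_run <- function(config, stack_prefix, out_dir, culture_prefix = NULL) {
  config <- as_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stack <- read_stack(stack_prefix)
  culture <- if (!is.null(culture_prefix)) read_stack(culture_prefix)
  run <- run_pipeline(stack, config, culture = culture)
  write.csv(run$detection$features, file.path(out_dir, "clusters.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(run$counts), file.path(out_dir, "counts.csv"),
            row.names = FALSE)
  pl <- attr(run$counts, "placements")
  if (!is.null(pl))
    write.csv(pl, file.path(out_dir, "placements.csv"), row.names = FALSE)
  yaml::write_yaml(list(sigma = run$model$sigma, I_t = run$model$I_t,
                        d_min = run$model$d_min, n_fits = run$model$n_fits),
                   file.path(out_dir, "model.yaml"))
  write.csv(threshold_report(run$detection, run$igray, stack),
            file.path(out_dir, "report.csv"), row.names = FALSE)
  write_manifest(out_dir, config, "run",
                 c("clusters.csv", "counts.csv", "placements.csv",
                   "model.yaml", "report.csv"))
  invisible(file.path(out_dir, "counts.csv"))
}

#' @rdname pipeline-commands
#' @export
cmd_evaluate <- function(counts_path, truth_path, out_path) {
  counts <- read.csv(counts_path)
  truth <- read_ground_truth(truth_path)
  match <- match_by_center(truth, counts)
  ev <- evaluate_counts(truth, counts, match)
  ss <- ev$sensitivity_specificity
  metrics <- list(total_true = ev$total_true, total_est = ev$total_est,
                  total_count_error = ev$total_count_error,
                  within_one = ev$within_one,
                  fleiss_kappa = ev$fleiss$kappa, fleiss_se = ev$fleiss$se,
                  cohen_kappa = ev$cohen$kappa,
                  mean_sensitivity = ss$mean_sensitivity,
                  min_specificity = ss$min_specificity,
                  per_class = ss$per_class,
                  n_missed = ev$n_missed, n_spurious = ev$n_spurious,
                  contingency = as.data.frame(as.table(ev$contingency)))
  jsonlite::write_json(metrics, out_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(out_path)
}
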