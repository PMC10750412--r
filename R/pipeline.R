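#' Run the end-to-end reconstruction pipeline
#'
#' Executes the full flow from a defective skull volume to an implant model:
#' normalize (optional Hounsfield windowing and Frankfort-plane crop) ->
#' down-sample -> completion network -> threshold -> enhancement network ->
#' threshold -> Boolean implant extraction -> morphological post-processing
#' -> STL / volume export, writing a machine-readable run manifest (inputs,
#' seeds, package version, stage timings, metrics) alongside the artifacts.
#'
#' The YAML config must name `input` (defective volume), `output_dir`,
#' `completion_checkpoint` and `enhancement_checkpoint`; optional keys with
#' defaults: `threshold` 0.45, `tolerance_scale` 1.02, `downsample_factor`
#' 4, `hounsfield_window` (windowing applied when the input is scalar),
#' `frankfort_index` 0, `opening_radius` 1, `keep_components` 1, `seed` 1,
#' `truth` (ground-truth implant volume for evaluation metrics).
#'
#' @param config_path Path to a YAML configuration file.
#' @return Invisibly, a list with `status` (0 on success) and `artifacts`
#'   (named file paths).
#' @export
run_pipeline <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  for (key in c("input", "output_dir", "completion_checkpoint",
                "enhancement_checkpoint")) {
    if (is.null(cfg[[key]]))
      stop("pipeline config is missing required key '", key, "'")
  }
  defaults <- list(threshold = 0.45, tolerance_scale = 1.02,
                   downsample_factor = 4L, frankfort_index = 0L,
                   opening_radius = 1, keep_components = 1L, seed = 1L,
                   hounsfield_window = c(1200, 1817))
  cfg <- modifyList(defaults, cfg)
  for (key in c("completion_checkpoint", "enhancement_checkpoint")) {
    if (!file.exists(cfg[[key]]))
      stop("checkpoint '", cfg[[key]], "' not found; train one with ",
           "train_model() / `craniofill train` or point '", key,
           "' at an existing .rds checkpoint")
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(cfg$seed))
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    message(sprintf("[craniofill] %-12s %7.2fs", name, timings[[name]]))
    out
  }

  vol <- stage("read", read_volume(cfg$input))
  if (!is_binary_volume(vol)) {
    vol <- stage("binarize", binarize_hounsfield(vol, cfg$hounsfield_window[1],
                                                 cfg$hounsfield_window[2]))
  }
  if (cfg$frankfort_index > 0)
    vol <- stage("crop", crop_below_plane(vol, cfg$frankfort_index))
  low <- stage("downsample", downsample_binary(vol, cfg$downsample_factor))

  comp <- as_cranionet(load_model(cfg$completion_checkpoint))
  enh <- as_cranionet(load_model(cfg$enhancement_checkpoint))
  completed_low <- stage("completion",
                         binarize_prediction(forward_completion(comp, low),
                                             cfg$threshold))
  completed_high <- stage("enhancement",
                          binarize_prediction(
                            forward_enhancement(enh, completed_low, vol),
                            cfg$threshold))
  implant <- stage("implant",
                   extract_implant(completed_high, vol, cfg$tolerance_scale))
  implant <- stage("postprocess",
                   postprocess_implant(implant, cfg$opening_radius,
                                       cfg$keep_components))

  paths <- list(
    completed_low = file.path(cfg$output_dir, "completed_low.nii.gz"),
    completed_high = file.path(cfg$output_dir, "completed_high.nii.gz"),
    implant_volume = file.path(cfg$output_dir, "implant.nii.gz"),
    implant_stl = file.path(cfg$output_dir, "implant.stl"),
    metrics = file.path(cfg$output_dir, "metrics.json"),
    manifest = file.path(cfg$output_dir, "manifest.json")
  )
  stage("export", {
    write_volume(completed_low, paths$completed_low)
    write_volume(completed_high, paths$completed_high)
    write_volume(implant, paths$implant_volume)
    if (n_ones(implant) > 0) export_mesh(implant, paths$implant_stl)
    else paths$implant_stl <- NULL
  })

  metrics <- list(implant_voxels = n_ones(implant),
                  implant_volume_mm3 = n_ones(implant) * prod(implant$spacing),
                  completed_voxels = n_ones(completed_high))
  if (!is.null(cfg$truth)) {
    truth <- read_volume(cfg$truth)
    metrics$sdi <- sdi(implant, truth)
    if (n_ones(implant) > 0)
      metrics$hd <- directed_hausdorff(truth, implant)
  }
  jsonlite::write_json(metrics, paths$metrics, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("craniofill")),
    config = cfg, seed = as.integer(cfg$seed),
    completion_init_seed = comp$init_seed,
    enhancement_init_seed = enh$init_seed,
    stage_seconds = as.list(timings), metrics = metrics,
    artifacts = paths
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(status = 0L, artifacts = paths))
}

as_cranionet <- function(x) {
  if (inherits(x, "cranionet_fit")) x$model
  else if (inherits(x, "cranionet")) x
  else stop("checkpoint does not contain a cranionet model")
}
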