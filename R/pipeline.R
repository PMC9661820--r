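#' Build a pipeline run configuration
#'
#' A single configuration object drives [run_pipeline()]. In `simulate`
#' mode a synthetic scene is generated; otherwise `stack_path` (and
#' optionally reference CSVs, a fluorescence TIFF, and external masks)
#' are read from disk. The seed governs every stochastic stage and is
#' echoed into the run record.
#'
#' @param simulate Generate a synthetic scene (default TRUE).
#' @param scene A [scene_params()] for simulate mode.
#' @param stack_path,fluorescence_path,cell_mask_path,aggregate_mask_path
#'   Input file paths for file mode (masks optional; when absent the
#'   classical segmenter is used).
#' @param ref_paths Character vector of reference-spectrum CSVs
#'   (limonene, cell body) for file mode; the background reference is
#'   estimated from the non-cell area of the stack.
#' @param unmix An [unmix_config()].
#' @param segmentation Named list of [segment_cells()] /
#'   [segment_aggregates()] parameters.
#' @param quantify Named list: `location_mode`, `rich_threshold`,
#'   `rich_norm`.
#' @param colocalize Enable MCC against the fluorescence channel when one
#'   is available.
#' @param seed Integer master seed.
#' @return An object of class `run_config`.
#' @export
pipeline_config <- function(simulate = TRUE, scene = scene_params(),
                            stack_path = NULL, fluorescence_path = NULL,
                            cell_mask_path = NULL, aggregate_mask_path = NULL,
                            ref_paths = NULL,
                            unmix = unmix_config(),
                            segmentation = list(smooth_sigma = 1,
                                                min_area_px = 30L,
                                                split = TRUE,
                                                tophat_radius_px = 4L,
                                                agg_threshold = 0.15,
                                                agg_min_area_px = 4L),
                            quantify = list(location_mode = "centroid",
                                            rich_threshold = NULL,
                                            rich_norm = 1),
                            colocalize = TRUE, seed = 1L) {
  if (!simulate && is.null(stack_path))
    stop("file mode needs stack_path", call. = FALSE)
  if (!simulate) {
    for (p in c(stack_path, fluorescence_path, cell_mask_path,
                aggregate_mask_path, ref_paths))
      if (!is.null(p) && !file.exists(p))
        stop("configured path does not exist: ", p, call. = FALSE)
  }
  if (simulate) scene$seed <- as.integer(seed)
  structure(list(simulate = simulate, scene = scene, stack_path = stack_path,
                 fluorescence_path = fluorescence_path,
                 cell_mask_path = cell_mask_path,
                 aggregate_mask_path = aggregate_mask_path,
                 ref_paths = ref_paths, unmix = unmix,
                 segmentation = segmentation, quantify = quantify,
                 colocalize = isTRUE(colocalize), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the [pipeline_config()] arguments;
#' `scene` and `unmix` sub-maps override individual defaults.
#'
#' @param path YAML file.
#' @param seed Optional seed override (e.g. from a `--seed` flag).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  scene <- do.call(scene_params, c(y$scene %||% list()))
  um <- do.call(unmix_config, c(y$unmix %||% list()))
  args <- y[setdiff(names(y), c("scene", "unmix"))]
  cfg <- do.call(pipeline_config, c(args, list(scene = scene, unmix = um)))
  if (!is.null(seed)) {
    cfg$seed <- as.integer(seed)
    if (cfg$simulate) cfg$scene$seed <- as.integer(seed)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' simulate (optional) -> unmix -> segment -> quantify -> colocalize
#' (optional), writing concentration maps, masks, feature tables,
#' summaries and a checksummed manifest into `outdir`. Deterministic
#' given the configuration seed. Any stage failure aborts with the stage
#' name.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @param quiet Suppress progress messages.
#' @return The manifest data.frame, invisibly; summaries are attached as
#'   the `"summaries"` attribute.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[hsrsquant] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  truth <- NULL; fluor <- NULL
  if (config$simulate) {
    say("simulate: ", config$scene$n_cells, " cells, seed ", config$seed)
    truth <- stage("simulate", generate_scene(config$scene))
    refs <- default_reference_set()
    rend <- stage("simulate", render_stack(truth, refs,
                                           seed = config$seed + 1L))
    stack <- rend$stack
    if (config$colocalize)
      fluor <- stage("simulate",
                     render_fluorescence(truth, seed = config$seed + 2L))
  } else {
    say("read: ", config$stack_path)
    stack <- stage("read", read_stack(config$stack_path))
    sp <- stage("read", lapply(config$ref_paths, read_spectrum_csv))
    bg <- stage("read", estimate_background_spectrum(stack))
    # CSVs are supplied in (limonene, cell body) order; background estimated
    refs <- stage("read", reference_set(c(sp, list(bg)),
      names = c("limonene", "cell_body", "background")[seq_len(length(sp) + 1L)]))
    if (!is.null(config$fluorescence_path))
      fluor <- stage("read", read_map(config$fluorescence_path))
  }

  say("unmix: lambda ", config$unmix$lam)
  maps <- stage("unmix", unmix_stack(stack, refs, config$unmix))

  sg <- config$segmentation
  say("segment")
  cells <- if (!config$simulate && !is.null(config$cell_mask_path)) {
    stage("segment", import_labels(config$cell_mask_path, "cell",
                                   pixel_size = stack$pixel_size))
  } else {
    summed <- window_sum(stack, spectral_window(min(stack$axis),
                                                max(stack$axis), "full"))
    stage("segment", segment_cells(summed, smooth_sigma = sg$smooth_sigma,
                                   min_area_px = sg$min_area_px,
                                   split = sg$split,
                                   pixel_size = stack$pixel_size))
  }
  aggs <- if (!config$simulate && !is.null(config$aggregate_mask_path)) {
    stage("segment", import_labels(config$aggregate_mask_path, "aggregate",
                                   cells_for_parenting = cells))
  } else {
    stage("segment", segment_aggregates(maps$maps$limonene, cells,
                                        tophat_radius_px = sg$tophat_radius_px,
                                        agg_threshold = sg$agg_threshold,
                                        min_area_px = sg$agg_min_area_px))
  }

  say("quantify: ", max(cells$labels, 0L), " cells, ",
      max(aggs$labels, 0L), " aggregates")
  qf <- config$quantify
  feats <- stage("quantify",
                 extract_cell_features(stack, maps, cells, aggs,
                                       fluorescence = fluor,
                                       location_mode = qf$location_mode,
                                       rich_threshold = qf$rich_threshold,
                                       rich_norm = qf$rich_norm))
  summ <- stage("quantify", population_summaries(feats$cells, feats$aggregates))

  coloc <- NULL
  if (config$colocalize && !is.null(fluor)) {
    say("colocalize")
    coloc <- stage("colocalize", {
      thr <- auto_threshold(fluor, "otsu", restrict = cells)
      mcc(maps$maps$limonene, fluor, thr, restrict = cells)
    })
    summ$mcc <- coloc$mcc
    summ$mcc_threshold <- coloc$threshold_used
  } else if (config$colocalize) {
    say("colocalize: no fluorescence channel available, skipped")
  }

  run_record <- list(seed = config$seed, simulate = config$simulate,
                     lambda = config$unmix$lam,
                     nonnegative = config$unmix$nonnegative,
                     normalize_refs = config$unmix$normalize_refs,
                     n_cells_detected = max(cells$labels, 0L),
                     n_aggregates_detected = max(aggs$labels, 0L))
  manifest <- stage("write",
    write_outputs(maps,
                  masks = list(cells = cells, aggregates = aggs),
                  tables = list(cell_features = feats$cells,
                                aggregate_features = feats$aggregates),
                  summaries = list(summary = summ, run_record = run_record),
                  outdir = outdir))
  say("done: ", nrow(manifest), " files in ", outdir)
  attr(manifest, "summaries") <- summ
  invisible(manifest)
}

#' Run the bundled seeded demo pipeline
#'
#' A small complete example: a 360 x 360 px scene with 40 cells at the
#' default population structure, unmixed, segmented, quantified and
#' colocalized, with all outputs manifested.
#'
#' @param outdir Output directory.
#' @param seed Integer seed.
#' @param quiet Suppress messages.
#' @return The manifest, invisibly (with `"summaries"` attribute).
#' @export
run_demo <- function(outdir, seed = 1L, quiet = FALSE) {
  cfg <- pipeline_config(
    simulate = TRUE,
    scene = scene_params(image_shape = c(360L, 360L), n_cells = 40L,
                         seed = seed),
    seed = seed)
  run_pipeline(cfg, outdir, quiet = quiet)
}
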