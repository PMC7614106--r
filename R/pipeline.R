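#' Pipeline configuration
#'
#' All thresholds are physical (um, days) so one configuration applies
#' across magnifications; the file form is YAML and round-trips losslessly.
#'
#' @param voxel_size_um micrometres per voxel `(z, y, x)`.
#' @param segmentation list: `method` (otsu/percentile/fixed), `param`,
#'   `smooth_sigma_um`, `min_component_voxels`, `fill_holes`.
#' @param tissue list: `method` (`"convex_hull"` or `"autofluorescence"`).
#' @param graph list: `min_spur_um`, `junction_exclude`, `smooth_window`,
#'   `merge_junction_scale` (0 disables junction merging).
#' @param metrics list: `bin_width_um`, `bin_cap_um`.
#' @param seed optional seed recorded with the run.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(voxel_size_um = c(2, 2, 2),
                            segmentation = list(), tissue = list(),
                            graph = list(), metrics = list(), seed = NULL) {
  cfg <- list(
    voxel_size_um = as.numeric(voxel_size_um),
    segmentation = utils::modifyList(
      list(method = "otsu", param = NULL, smooth_sigma_um = 0,
           min_component_voxels = 27L, fill_holes = FALSE),
      segmentation),
    tissue = utils::modifyList(list(method = "convex_hull"), tissue),
    graph = utils::modifyList(
      list(min_spur_um = 10, junction_exclude = 2L, smooth_window = 5L,
           merge_junction_scale = 2), graph),
    metrics = utils::modifyList(list(bin_width_um = 10, bin_cap_um = 100), metrics),
    seed = seed
  )
  stopifnot(length(cfg$voxel_size_um) == 3L, all(cfg$voxel_size_um > 0))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(voxel_size_um = y$voxel_size_um %||% c(2, 2, 2),
                  segmentation = y$segmentation %||% list(),
                  tissue = y$tissue %||% list(),
                  graph = y$graph %||% list(),
                  metrics = y$metrics %||% list(),
                  seed = y$seed)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.zero_network_metrics <- function(ln_volume = 0) {
  structure(list(
    total_length = 0, n_segments = 0L, n_branch_points = 0L, n_endpoints = 0L,
    n_networks = 0L, ln_volume = ln_volume,
    density_length = 0, density_count = 0,
    mean_segment_length = 0, mean_segment_width = 0,
    length_histogram = bin_distribution(numeric(0)),
    width_histogram = bin_distribution(numeric(0))
  ), class = "network_metrics")
}

#' Run the full 3D HEV quantification pipeline
#'
#' Executes segment -> skeletonize -> graph -> prune -> networks -> metrics
#' on one stack and collects every artifact with a provenance record
#' (configuration, auto-chosen threshold, package version) so that
#' user-guided parameter choices stay auditable.  A stage failure aborts
#' with the stage name and cause.  Deterministic at a fixed configuration.
#'
#' @param x a [volume_image], or a path to a TIFF stack readable by
#'   [read_stack()] (the configured voxel size is applied).
#' @param config a [pipeline_config].
#' @param output_dir if given, writes `metrics.json`, `metrics.csv`,
#'   `segments.csv`, `graph.am` and `provenance.yaml` there.
#' @param autofluorescence optional second-channel [volume_image] for the
#'   autofluorescence tissue method.
#' @return list with `metrics` ([summarize_network()] output), `graph`,
#'   `segments` (per-segment table), `vessel_mask`, `tissue`, `provenance`.
#' @export
run_pipeline <- function(x, config = pipeline_config(), output_dir = NULL,
                         autofluorescence = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  vol <- stage("read", {
    if (is.character(x)) read_stack(x, voxel_size = config$voxel_size_um)
    else if (inherits(x, "volume_image")) x
    else stop("input must be a volume_image or a TIFF path")
  })
  sg <- config$segmentation
  vol_s <- stage("preprocess", preprocess(vol, sg$smooth_sigma_um))
  mask <- stage("binarize", binarize(vol_s, sg$method, sg$param))
  threshold <- attr(mask, "threshold")
  mask <- stage("clean", clean_mask(mask, sg$min_component_voxels, sg$fill_holes))

  provenance <- list(config = unclass(config), threshold = threshold,
                     package = "hevquant",
                     package_version = as.character(utils::packageVersion("hevquant")))

  if (!any(mask$data)) {
    warning("no vessel signal after segmentation; emitting zero metrics")
    empty_graph <- build_graph(skeletonize(mask))
    out <- list(metrics = .zero_network_metrics(), graph = empty_graph,
                segments = segment_table(empty_graph), vessel_mask = mask,
                tissue = NULL, provenance = provenance)
  } else {
    skel <- stage("skeletonize", skeletonize(mask))
    graph <- stage("graph", {
      g <- build_graph(skel)
      g <- measure_lengths(g, smooth_window = config$graph$smooth_window)
      measure_widths(g, mask, config$graph$junction_exclude)
    })
    graph <- stage("prune", {
      g <- prune_spurs(graph, config$graph$min_spur_um)
      if (config$graph$merge_junction_scale > 0)
        g <- merge_close_junctions(g, config$graph$merge_junction_scale)
      g
    })
    graph <- stage("networks", identify_networks(graph))
    tissue <- stage("tissue", {
      if (config$tissue$method == "autofluorescence") {
        if (is.null(autofluorescence))
          stop("autofluorescence tissue method needs the second channel")
        tissue_mask(autofluorescence, "autofluorescence")
      } else tissue_mask(mask, "convex_hull")
    })
    metrics <- stage("metrics", summarize_network(
      graph, tissue, config$metrics$bin_width_um, config$metrics$bin_cap_um))
    out <- list(metrics = metrics, graph = graph, segments = segment_table(graph),
                vessel_mask = mask, tissue = tissue, provenance = provenance)
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_metrics(out$metrics, file.path(output_dir, "metrics.json"), "json")
    write_metrics(out$metrics, file.path(output_dir, "metrics.csv"), "csv")
    utils::write.csv(out$segments, file.path(output_dir, "segments.csv"),
                     row.names = FALSE)
    if (length(out$graph$segments))
      write_spatial_graph(out$graph, file.path(output_dir, "graph.am"))
    yaml::write_yaml(provenance, file.path(output_dir, "provenance.yaml"))
  }
  out
}
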