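# End-to-end pipeline: simulate -> segment -> quantify -> count -> compare,
# driven by one plain-list configuration that round-trips through YAML. Every
# random stage derives its stream from the single top-level seed by fixed
# offsets, so a full run is reproducible byte for byte.

#' Default pipeline configuration
#'
#' The bundled synthetic configuration: a ground-truthed three-cell stack
#' whose cells fuse into a basal structure, plus a two-condition count
#' experiment. Segmentation defaults are the pipeline's reference settings
#' (top-hat 50 x 50 x 3, sigma 1 x 1 x 0.5, threshold 500, EDT cutoff 2;
#' measurement top-hat (15, 15, 1); rolling ball radius 50).
#'
#' @param seed top-level RNG seed.
#' @return a nested list of class `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(
      stack = list(
        shape = c(96, 96, 16),
        n_cells = 3L,
        radii = c(6, 6, 2.5),
        peak = 3000,
        base_z_extent = 3L,
        base_intensity = 2000,
        background = c(80, 0.5, 0.5, 0),
        poisson_scale = 60,
        read_sd = 80
      ),
      counts = list(
        conditions = list(EM = 1, DI = 2),
        n_larvae = 18L,
        neuromasts_per_larva = 10L,
        baseline_rate = 0.5,
        progenitor_rate = 0.3,
        zero_inflation = 0.2,
        n_replicates = 1L,
        replicate_sd = 0,
        count_model = "zip",
        nb_size = 2
      )
    ),
    segmentation = list(
      tophat_footprint = c(50, 50, 3),
      gaussian_sigma = c(1, 1, 0.5),
      threshold = 500,
      edt_min = 2,
      edt_mode = "3d",
      min_object_voxels = 20L,
      connectivity_2d = 8L,
      traverse_from = "first_slice"
    ),
    quantify = list(
      tophat_footprint = c(15, 15, 1),
      rolling_ball_radius = 50
    ),
    stats = list(
      kind = "mature",
      control = "EM",
      alpha = 0.05,
      multi_method = "anova_dunnett",
      normalize = FALSE
    )
  ), class = "PipelineConfig")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a `PipelineConfig` list.
#' @param path YAML file path.
#' @return `write_pipeline_config`: invisibly, the path;
#'   `read_pipeline_config`: the `PipelineConfig`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "PipelineConfig")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}

# build a StackSpec from the config's simulate$stack section: n_cells
# ellipsoids on a ring, all fused into a basal disc at the bottom slices
config_stack_spec <- function(sc) {
  shape <- as.integer(sc$shape)
  n <- as.integer(sc$n_cells)
  r <- as.numeric(sc$radii)
  ctr <- shape[1:2] / 2
  ring <- min(shape[1:2]) / 4.8
  # cell bottoms dip one to two slices into the basal structure
  zc <- shape[3] - sc$base_z_extent + 2 - r[3]
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cells <- lapply(seq_len(n), function(i)
    cell_spec(c(ctr[1] + ring * sin(ang[i]), ctr[2] + ring * cos(ang[i]), zc),
              r, sc$peak))
  base <- base_spec(center_yx = ctr, radii_yx = ring + r[1:2] + 4,
                    z_extent = sc$base_z_extent,
                    intensity = sc$base_intensity, at_end = TRUE)
  stack_spec(shape, cells, base = base,
             background = as.numeric(sc$background),
             noise = noise_spec(sc$poisson_scale, sc$read_sd))
}

config_design <- function(cc, seed) {
  experiment_design(conditions = unlist(cc$conditions),
                    n_larvae = cc$n_larvae,
                    neuromasts_per_larva = cc$neuromasts_per_larva,
                    baseline_rate = cc$baseline_rate,
                    progenitor_rate = cc$progenitor_rate,
                    zero_inflation = cc$zero_inflation,
                    n_replicates = cc$n_replicates,
                    replicate_sd = cc$replicate_sd,
                    count_model = cc$count_model,
                    nb_size = cc$nb_size,
                    seed = seed)
}

stage <- function(report, name, expr) {
  t0 <- Sys.time()
  value <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  report$timings[[name]] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  list(report = report, value = value)
}

#' Run the full pipeline
#'
#' Simulates the configured stack and count experiment, segments the stack,
#' quantifies per-cell intensities, summarizes counts per larva, runs the
#' configured comparison, and writes every artifact (TIFFs, CSVs, JSON)
#' under `out_dir`, stamped with the configuration hash and seed. The whole
#' run is a pure function of `(config, out_dir)`.
#'
#' @param config a [pipeline_config()] (or one read from YAML).
#' @param out_dir output directory.
#' @return the run report (invisibly written to `report.json` as well):
#'   configuration hash, seed, per-stage timings, number of cells found and
#'   in truth, count summaries and the comparison result.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(!missing(out_dir))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  report <- list(config_hash = config_hash(config), seed = seed,
                 timings = list())

  # simulate
  st <- stage(report, "simulate", {
    spec <- config_stack_spec(config$simulate$stack)
    sim <- generate_stack(spec, seed = seed)
    counts <- generate_count_experiment(
      config_design(config$simulate$counts, seed = seed + 1000L))
    write_stack(sim$stack, file.path(out_dir, "stack"))
    write_labels(sim$truth$instance_labels,
                 file.path(out_dir, "truth_labels.tif"))
    write_counts(counts, file.path(out_dir, "counts.csv"))
    list(sim = sim, counts = counts)
  })
  report <- st$report; sim <- st$value$sim; counts <- st$value$counts

  # segment
  st <- stage(report, "segment", {
    params <- do.call(segmentation_params, config$segmentation)
    seg <- segment_cells(sim$stack, params)
    write_labels(seg, file.path(out_dir, "labels.tif"))
    seg
  })
  report <- st$report; seg <- st$value

  # quantify
  st <- stage(report, "quantify", {
    chans <- sim$stack$channels
    sub <- lapply(chans, tophat_bg_subtract,
                  footprint = config$quantify$tophat_footprint)
    meas <- if (seg$n_cells > 0) cell_mean_intensities(seg, sub)
            else data.frame(cell_id = integer(0), channel = character(0),
                            mean_intensity = numeric(0), n_voxels = integer(0),
                            source = character(0))
    write.csv(meas, file.path(out_dir, "cell_measurements.csv"),
              row.names = FALSE)
    meas
  })
  report <- st$report

  # count + compare
  st <- stage(report, "compare", {
    per_larva <- per_larva_average(counts, kind = config$stats$kind)
    if (isTRUE(config$stats$normalize))
      per_larva <- normalize_to_control(per_larva, config$stats$control)
    write.csv(per_larva, file.path(out_dir, "per_larva.csv"),
              row.names = FALSE)
    freq <- ionocyte_frequency(counts, kind = config$stats$kind,
                               by = "condition")
    conds <- unique(per_larva$condition)
    ctrl <- config$stats$control
    others <- setdiff(conds, ctrl)
    res <- if (length(conds) == 2) {
      compare_two_groups(per_larva$value[per_larva$condition == ctrl],
                         per_larva$value[per_larva$condition == others[1]],
                         alpha = config$stats$alpha,
                         names = c(ctrl, others[1]))
    } else {
      compare_multi_groups(split(per_larva$value, per_larva$condition),
                           method = config$stats$multi_method,
                           control = ctrl, alpha = config$stats$alpha)
    }
    jsonlite::write_json(
      list(test = res$test, statistic = res$statistic, p = res$p,
           groups = res$groups, posthoc = res$posthoc,
           frequency_pct = freq),
      file.path(out_dir, "stats.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
    list(per_larva = per_larva, frequency = freq, result = res)
  })
  report <- st$report

  report$n_cells_truth <- nrow(sim$truth$centroids)
  report$n_cells_found <- seg$n_cells
  report$n_label_voxels <- sum(seg$labels > 0)
  report$n_larvae <- nrow(st$value$per_larva)
  report$comparison_test <- st$value$result$test
  report$comparison_p <- st$value$result$p
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf(
    "pipeline done: %d/%d cells, %d larvae, %s p = %.4g",
    report$n_cells_found, report$n_cells_truth, report$n_larvae,
    report$comparison_test, report$comparison_p))
  invisible(report)
}
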