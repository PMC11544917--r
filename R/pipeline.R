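#' Default pipeline configuration
#'
#' Settings for a full simulate/preprocess/cluster/evaluate run on a
#' synthetic cohort: the six-archetype generator defaults, the 0.7/0.1/0.2
#' NH-stratified split, silhouette-guided k in \[2, 8\] per NH group, the
#' paper-style six-algorithm benchmark at 15- and 30-minute horizons.
#'
#' @param n_patients cohort size.
#' @param seed master seed.
#' @return Nested list understood by [run_pipeline()]; serializable as YAML.
#' @export
default_pipeline_config <- function(n_patients = 240L, seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(
      n_patients = as.integer(n_patients),
      shapes = c("stable_target", "stable_elevated", "downward_trend",
                 "upward_trend", "hypo_dip", "hypo_low_stable"),
      archetype_mix = NULL,
      noise_phi = 0.8, noise_sigma = 0.3, offset_sigma = 0.5,
      gap_rate_single = 0.02, gap_rate_long = 0.05),
    preprocess = list(nh_threshold = 3.9, nh_min_run = 3L,
                      split = c(0.7, 0.1, 0.2)),
    cluster = list(k_range = c(2L, 8L), k_fixed = NULL, stability_reps = 0L),
    forecast = list(
      algorithms = c("mtsc", "wmtsc", "holt", "gbt_global",
                     "rf_cluster", "gbt_cluster"),
      horizons = c(15L, 30L),
      hyperparameters = default_hyperparams()))
}

#' Load and validate a pipeline configuration from YAML
#'
#' Missing keys fall back to [default_pipeline_config()] values; unknown or
#' invalid keys raise a validation error naming them.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_pipeline_config(raw)
}

validate_pipeline_config <- function(raw) {
  base <- default_pipeline_config()
  bad <- setdiff(names(raw), names(base))
  if (length(bad)) {
    stop_glucluster(sprintf("unknown config keys: %s",
                            paste(bad, collapse = ", ")), "validation_error")
  }
  cfg <- utils::modifyList(base, raw, keep.null = TRUE)
  problems <- character(0)
  if (!is.numeric(cfg$seed)) problems <- c(problems, "seed")
  if (is.null(cfg$cohort$n_patients) || cfg$cohort$n_patients < 1) {
    problems <- c(problems, "cohort.n_patients")
  }
  if (abs(sum(cfg$preprocess$split) - 1) > 1e-9) {
    problems <- c(problems, "preprocess.split")
  }
  if (any(cfg$forecast$horizons %% 5 != 0) || any(cfg$forecast$horizons <= 0)) {
    problems <- c(problems, "forecast.horizons")
  }
  bad_algo <- setdiff(cfg$forecast$algorithms, names(ALGORITHM_LABELS))
  if (length(bad_algo)) problems <- c(problems, "forecast.algorithms")
  if (length(problems)) {
    stop_glucluster(sprintf("invalid config keys: %s",
                            paste(problems, collapse = ", ")),
                    "validation_error")
  }
  cfg
}

#' Run the full cluster-then-forecast pipeline
#'
#' Executes simulate, preprocess, cluster and evaluate in order, writing all
#' artifacts under `out_dir`: `cohort.csv` + `cohort_labels.csv`,
#' `segments.csv` (wide, with NH labels and roles), per-group
#' `cluster_<group>.json` / `medoids_<group>.csv`, `benchmark.csv`,
#' `per_step_mae.csv` and `manifest.json` (config hash and consumed seeds).
#' A stage whose outputs already exist under the same config hash is skipped,
#' so a rerun without changes is a no-op with an identical manifest.
#'
#' @param config configuration list ([default_pipeline_config()] or
#'   [load_pipeline_config()]).
#' @param out_dir artifact directory (created if absent).
#' @param quiet suppress per-stage log messages.
#' @return Invisibly, the benchmark table data.frame.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir, quiet = FALSE) {
  config <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- digest::digest(config, algo = "sha256")
  manifest_path <- file.path(out_dir, "manifest.json")
  old_hash <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)$config_hash
  } else NULL
  same <- identical(old_hash, hash)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  paths <- list(
    cohort = file.path(out_dir, "cohort.csv"),
    labels = file.path(out_dir, "cohort_labels.csv"),
    segments = file.path(out_dir, "segments.csv"),
    benchmark = file.path(out_dir, "benchmark.csv"),
    per_step = file.path(out_dir, "per_step_mae.csv"))
  fresh <- function(...) same && all(file.exists(unlist(list(...))))

  # -- simulate ---------------------------------------------------------
  if (fresh(paths$cohort, paths$labels)) {
    say("[simulate] up to date, skipped")
  } else {
    t0 <- proc.time()[3]
    arch <- default_archetypes(config$cohort$shapes)
    cc <- cohort_config(
      n_patients = config$cohort$n_patients, archetypes = arch,
      archetype_mix = config$cohort$archetype_mix,
      noise_phi = config$cohort$noise_phi,
      noise_sigma = config$cohort$noise_sigma,
      offset_sigma = config$cohort$offset_sigma,
      gap_rate_single = config$cohort$gap_rate_single,
      gap_rate_long = config$cohort$gap_rate_long,
      seed = config$seed)
    write_cohort_csv(generate_cohort(cc), paths$cohort, paths$labels)
    say("[simulate] %d segments written (%.1fs)", cc$n_patients,
        proc.time()[3] - t0)
  }

  # -- preprocess -------------------------------------------------------
  if (fresh(paths$segments)) {
    say("[preprocess] up to date, skipped")
  } else {
    t0 <- proc.time()[3]
    segs <- extract_nocturnal_segments(read_cgm_csv(paths$cohort))
    prep <- preprocess_cohort(
      segs, nh_threshold = config$preprocess$nh_threshold,
      nh_min_run = config$preprocess$nh_min_run,
      ratios = config$preprocess$split, seed = config$seed)
    seg_rows <- do.call(rbind, lapply(names(prep$sets), function(g) {
      s <- prep$sets[[g]]
      cbind(data.frame(patient_id = s$patient_id,
                       night_index = s$night_index,
                       nh_label = s$nh_label, role = s$role),
            as.data.frame(s$values))
    }))
    names(seg_rows)[-(1:4)] <- sprintf("g%02d",
                                       seq_len(ncol(seg_rows) - 4L) - 1L)
    utils::write.csv(seg_rows, paths$segments, row.names = FALSE,
                     quote = FALSE)
    say("[preprocess] kept %d / rejected %s (%.1fs)",
        prep$counts[["OK"]],
        paste(sprintf("%s=%d", names(prep$counts)[-1],
                      as.integer(prep$counts[-1])), collapse = " "),
        proc.time()[3] - t0)
  }

  # -- cluster + evaluate ----------------------------------------------
  set_all <- read_segments_csv(paths$segments)
  groups <- list()
  for (g in c("no_NH", "NH")) {
    rows <- if (g == "NH") set_all$nh_label else !set_all$nh_label
    if (!any(rows)) next
    groups[[g]] <- structure(
      list(values = set_all$values[rows, , drop = FALSE],
           patient_id = set_all$patient_id[rows],
           night_index = set_all$night_index[rows],
           nh_label = set_all$nh_label[rows],
           role = set_all$role[rows],
           series_length = set_all$series_length),
      class = "segment_set")
  }
  cpaths <- unlist(lapply(names(groups), function(g)
    file.path(out_dir, c(sprintf("cluster_%s.json", g),
                         sprintf("medoids_%s.csv", g)))))
  if (fresh(paths$benchmark, paths$per_step, cpaths)) {
    say("[cluster/evaluate] up to date, skipped")
    bench_df <- utils::read.csv(paths$benchmark)
  } else {
    t0 <- proc.time()[3]
    bench <- run_benchmark(
      groups, algorithms = config$forecast$algorithms,
      horizons_min = config$forecast$horizons,
      k_range = config$cluster$k_range,
      k_fixed = config$cluster$k_fixed,
      hyper = config$forecast$hyperparameters,
      stability_reps = config$cluster$stability_reps,
      seed = config$seed)
    for (g in names(bench$cluster_models)) {
      write_cluster_model(bench$cluster_models[[g]],
                          file.path(out_dir, sprintf("cluster_%s.json", g)),
                          file.path(out_dir, sprintf("medoids_%s.csv", g)))
    }
    utils::write.csv(bench$table, paths$benchmark, row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(bench$per_step, paths$per_step, row.names = FALSE,
                     quote = FALSE)
    bench_df <- bench$table
    say("[cluster/evaluate] %d rows, k = %s (%.1fs)", nrow(bench_df),
        paste(vapply(bench$cluster_models, `[[`, integer(1), "k"),
              collapse = "/"),
        proc.time()[3] - t0)
  }

  jsonlite::write_json(
    list(config_hash = hash, seed = config$seed,
         split_seeds = c(config$seed, config$seed + 1L),
         package = "glucluster",
         stages = c("simulate", "preprocess", "cluster", "evaluate")),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(bench_df)
}
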