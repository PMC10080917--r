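#' Validated run configuration
#'
#' Bundles every constant of a full synthetic experiment: generator
#' settings, bounds-detection settings, the axonopathy effect, cohort
#' sizes, and the statistical settings (`alpha`, `min_ais_per_device`).
#' Validation is aggregated: every problem is reported in one error.
#'
#' @param generator A [generator_config()].
#' @param bounds A [bounds_config()].
#' @param effect An [axonopathy_effect()].
#' @param n_replicates Independent replicates (devices) per arm.
#' @param cells_per_replicate Cells simulated per replicate.
#' @param effect_classes Localization classes the effect is applied to
#'   (default `"acd"`, the preferentially affected morphology).
#' @param alpha Significance level for outlier screening and tests.
#' @param min_ais_per_device Replicate inclusion threshold for dimension
#'   analysis.
#' @param line_width_px Perpendicular averaging width for profile
#'   extraction.
#' @param seed Base seed; every downstream draw derives from it.
#' @param out_dir Output directory for [run_simulate()].
#' @return A `run_config` list.
#' @export
run_config <- function(generator = generator_config(),
                       bounds = bounds_config(),
                       effect = axonopathy_effect(),
                       n_replicates = 6,
                       cells_per_replicate = 30,
                       effect_classes = "acd",
                       alpha = 0.05,
                       min_ais_per_device = 3,
                       line_width_px = 3,
                       seed = 1,
                       out_dir = NULL) {
  problems <- character()
  collect <- function(expr, what) {
    tryCatch(expr, error = function(e) {
      problems <<- c(problems, paste0(what, ": ", conditionMessage(e)))
      NULL
    })
  }
  if (!inherits(generator, "generator_config")) {
    generator <- collect(do.call(generator_config, as.list(generator)), "generator")
  }
  if (!inherits(bounds, "bounds_config")) {
    bounds <- collect(do.call(bounds_config, as.list(bounds)), "bounds")
  }
  if (!inherits(effect, "axonopathy_effect")) {
    effect <- collect(do.call(axonopathy_effect, as.list(effect)), "effect")
  }
  if (!is.numeric(n_replicates) || n_replicates < 0) {
    problems <- c(problems, "`n_replicates` must be >= 0")
  }
  if (!is.numeric(cells_per_replicate) || cells_per_replicate < 0) {
    problems <- c(problems, "`cells_per_replicate` must be >= 0")
  }
  if (!all(effect_classes %in% LOCALIZATION_CLASSES)) {
    problems <- c(problems, "`effect_classes` must be localization classes")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    problems <- c(problems, "`alpha` must lie in (0, 1)")
  }
  if (!is.numeric(min_ais_per_device) || min_ais_per_device < 1) {
    problems <- c(problems, "`min_ais_per_device` must be >= 1")
  }
  if (!is.numeric(line_width_px) || line_width_px < 1 ||
      as.integer(line_width_px) %% 2 == 0) {
    problems <- c(problems, "`line_width_px` must be an odd positive integer")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    problems <- c(problems, "`seed` must be a single integer")
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid run configuration:\n- ", paste(problems, collapse = "\n- ")))
  }
  structure(
    list(generator = generator, bounds = bounds, effect = effect,
         n_replicates = as.integer(n_replicates),
         cells_per_replicate = as.integer(cells_per_replicate),
         effect_classes = effect_classes, alpha = alpha,
         min_ais_per_device = as.integer(min_ais_per_device),
         line_width_px = as.integer(line_width_px),
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Simulate a cohort and write scenes, truth and manifest to disk
#'
#' Writes one two-page TIFF per neuron, the ground-truth CSV, the trace
#' CSV, and a JSON run manifest holding the package version, the verbatim
#' configuration, its hash and the seed. Reruns with the same configuration
#' produce identical files and an identical manifest hash.
#'
#' @param config A [run_config()] with `out_dir` set (created if missing).
#' @return Invisibly, the manifest list.
#' @export
run_simulate <- function(config) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config().")
  out_dir <- config$out_dir %||% abort("`config$out_dir` must be set.")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  n <- config$n_replicates * config$cells_per_replicate
  if (n == 0) abort("No neurons configured: empty cohort.")

  sims <- simulate_cohort(n, config$generator, config$seed)
  scale <- 65535
  files <- character(n)
  for (i in seq_len(n)) {
    files[i] <- file.path(out_dir, sprintf("scene_%04d.tif", i))
    write_scene_tiff(sims[[i]]$scene, files[i], scale = scale)
  }
  truth <- truth_table(purrr::map(sims, "truth"))
  write_truth_csv(truth, file.path(out_dir, "truth.csv"))
  traces <- purrr::list_rbind(purrr::map(sims, ~ traces_from_neuron(.x$truth)))
  write_traces_csv(traces, file.path(out_dir, "traces.csv"))

  manifest <- list(
    package = "aismorph",
    version = as.character(utils::packageVersion("aismorph")),
    seed = config$seed,
    n_neurons = n,
    intensity_scale = scale,
    config = unclass_deep(config[setdiff(names(config), "out_dir")]),
    config_hash = config_hash(config[setdiff(names(config), "out_dir")])
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

## internal: simulate -> extract -> quantify for one arm of one cell
measure_neuron <- function(truth, scene, config) {
  traces <- traces_from_neuron(truth)
  profiles <- extract_profiles(scene$marker, traces, truth$pixel_size,
                               line_width = config$line_width_px)
  quantify_ais(profiles, config$bounds)
}

#' Run the end-to-end synthetic axonopathy experiment
#'
#' The full pipeline on paired synthetic cohorts: each cell is simulated
#' once as "vehicle"; cells whose localization class is in
#' `effect_classes` are additionally re-rendered with the axonopathy
#' effect applied ("axonopathy" arm; all other cells enter that arm
#' unchanged, sharing their noise realization). Marker profiles are then
#' extracted along the ground-truth traces, AIS bounds quantified, and
#' dimension summaries, localization counts and truth-vs-recovered tables
#' assembled.
#'
#' @param config A [run_config()].
#' @return An `ais_experiment_report`: list with `measurements`, `truth`,
#'   `dimensions` (a [summarize_dimensions()] result over both arms),
#'   `shift_recovery`, `localization` (counts, proportions and the
#'   homogeneity test) and `config`.
#' @export
run_endtoend <- function(config = run_config()) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config().")
  n_cells <- config$n_replicates * config$cells_per_replicate
  if (n_cells == 0) abort("No neurons configured: empty report.")

  rows <- list()
  truth_rows <- list()
  cell <- 0L
  for (rep_i in seq_len(config$n_replicates)) {
    for (cell_i in seq_len(config$cells_per_replicate)) {
      cell <- cell + 1L
      id <- sprintf("r%02dc%03d", rep_i, cell_i)
      seed_i <- derive_seed(config$seed, 1000 + cell)
      sim <- with_stage("simulate", id, simulate_neuron(config$generator, seed_i, id))
      arms <- list(vehicle = sim)
      if (sim$truth$localization_class %in% config$effect_classes) {
        arms$axonopathy <- with_stage(
          "axonopathy", id,
          apply_axonopathy(sim$truth, config$effect, seed_i, config$generator)
        )
      } else {
        arms$axonopathy <- sim
      }
      for (arm in names(arms)) {
        tr <- arms[[arm]]$truth
        m <- with_stage("quantify", id, measure_neuron(tr, arms[[arm]]$scene, config))
        tt <- truth_table(tr) |> dplyr::filter(.data$is_ais)
        m <- m |>
          dplyr::left_join(
            tt |>
              dplyr::transmute(
                neuron_id = paste0(.data$neuron_id, "/", .data$neurite_id),
                true_start_um = .data$ais_start_um,
                true_length_um = .data$ais_length_um
              ),
            by = "neuron_id"
          ) |>
          dplyr::mutate(group_label = arm, replicate_id = rep_i, cell_id = id)
        rows[[length(rows) + 1]] <- m
        truth_rows[[length(truth_rows) + 1]] <- tt |>
          dplyr::mutate(group_label = arm, replicate_id = rep_i, cell_id = id)
      }
    }
  }
  measurements <- purrr::list_rbind(rows)
  truth <- purrr::list_rbind(truth_rows)

  dims <- summarize_dimensions(measurements, config$min_ais_per_device)

  counts <- truth |>
    dplyr::distinct(.data$group_label, .data$cell_id, .data$localization_class) |>
    dplyr::rename(neuron_id = "cell_id") |>
    count_localizations()
  props <- localization_proportions(counts)
  homog <- tryCatch(chi_square_homogeneity(counts), error = function(e) NULL)

  gm <- dims$group_means
  veh <- gm |>
    dplyr::filter(.data$group_label == "vehicle") |>
    dplyr::select("localization_class",
                  vehicle_start_um = "mean_start_um",
                  vehicle_length_um = "mean_length_um")
  trt <- gm |>
    dplyr::filter(.data$group_label == "axonopathy") |>
    dplyr::select("localization_class",
                  axonopathy_start_um = "mean_start_um",
                  axonopathy_length_um = "mean_length_um")
  shift_recovery <- dplyr::full_join(veh, trt, by = "localization_class") |>
    dplyr::mutate(
      recovered_shift_um = .data$vehicle_start_um - .data$axonopathy_start_um,
      length_change_um = .data$axonopathy_length_um - .data$vehicle_length_um,
      configured_shift_um = ifelse(
        .data$localization_class %in% config$effect_classes,
        config$effect$ais_start_shift, 0
      )
    )

  structure(
    list(measurements = measurements, truth = truth, dimensions = dims,
         shift_recovery = shift_recovery,
         localization = list(counts = counts, proportions = props,
                             homogeneity = homog),
         config = config),
    class = "ais_experiment_report"
  )
}

## internal: label stage failures with the stage name and offending cell
with_stage <- function(stage, neuron_id, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Stage '%s' failed for neuron %s: %s",
                  stage, neuron_id, conditionMessage(e)))
  })
}
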