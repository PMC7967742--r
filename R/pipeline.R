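#' Run the whole pipeline on a synthetic landscape
#'
#' Wires every stage end to end: synthetic-input generation, transition
#' calibration on the t0/t1 pair, hindcast validation of the automaton
#' (re-simulating t1 from t0 and scoring overall accuracy and kappa against
#' the observed t1), suitability-network training, per-scenario allocation
#' and habitat-quality scoring, and cross-scenario comparison. One global
#' seed is split deterministically into per-stage seeds. All outputs are
#' written under `out_dir` together with a JSON run manifest.
#'
#' @param config A list (or path to a YAML file) with optional keys `seed`,
#'   `shape`, `cell_size`, `scenarios` (default S1-S4), `interval_years`
#'   (calibration span, default 8), `horizon_years` (projection span,
#'   default 13), `hidden_size`, `sample_fraction`, `max_iter`, and any
#'   [synthetic_spec()] argument under `synthetic`.
#' @param out_dir Output directory (created if absent); `NULL` skips writing.
#' @return A list with `manifest`, `validation`, `transition`
#'   ([transition_matrix()]), `scenarios` (per-scenario [run_scenario()]
#'   results), `baseline_quality`, `comparison` and `summary` (one row per
#'   scenario).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 42L)
  scen_names <- config$scenarios %||% c("S1", "S2", "S3", "S4")
  interval <- config$interval_years %||% 8
  horizon <- config$horizon_years %||% 13
  n_steps <- horizon / interval
  t_start <- Sys.time()
  log_stage <- function(...) message(sprintf("[habscape %s] ", format(Sys.time(), "%H:%M:%S")),
                                     sprintf(...))

  synth_args <- config$synthetic %||% list()
  synth_args$shape <- as.integer(config$shape %||% synth_args$shape %||% c(120L, 120L))
  synth_args$cell_size <- config$cell_size %||% synth_args$cell_size %||% 30
  synth_args$seed <- derive_seed(seed, "synth")
  spec <- do.call(synthetic_spec, synth_args)
  log_stage("synth: generating %d x %d landscape", spec$shape[1], spec$shape[2])
  land <- generate_landscape_pair(spec)
  params <- read_parameter_tables(config$params_dir)

  log_stage("fit-transition: calibrating on the t0/t1 pair")
  ct <- crosstab_transitions(land$lu_t0, land$lu_t1)
  P <- estimate_transition_matrix(ct, interval_years = interval)

  log_stage("train-suitability: fitting the network")
  drivers <- normalize_drivers(land$drivers)
  samp <- sample_training_cells(land$lu_t1, drivers,
                                fraction = config$sample_fraction %||% 0.05,
                                seed = derive_seed(seed, "sample"))
  model <- train_suitability_model(samp$features, samp$labels,
                                   hidden_size = config$hidden_size %||% 12L,
                                   seed = derive_seed(seed, "train"),
                                   bounds = drivers$bounds)

  log_stage("validate: hindcasting t1 from t0")
  sp <- predict_suitability(model, drivers)
  w_bau <- stats::setNames(as.numeric(params$weights[params$weights$scenario == "S1",
                                                     habscape_classes()$name]),
                           habscape_classes()$name)
  hind <- run_allocation(sp, land$lu_t0,
                         demand_vector(class_counts(land$lu_t1),
                                       habscape_classes()$code),
                         w_bau, params$conversion$s1s2,
                         seed = derive_seed(seed, "hindcast"),
                         max_iter = config$max_iter %||% 300L)
  validation <- validate_map(hind$landuse, land$lu_t1)
  log_stage("validate: overall %.3f, kappa %.3f", validation$overall,
            validation$kappa)

  base_hq <- habitat_quality(land$lu_t1, subtype = land$subtype, params = params)
  base_sum <- summarize_quality(base_hq$Q)

  results <- list()
  for (nm in scen_names) {
    log_stage("simulate + quality: scenario %s", nm)
    cfg <- load_scenario(nm, params)
    results[[nm]] <- run_scenario(cfg, land$lu_t1, model, drivers,
                                  masks = land$masks, P = P, n_steps = n_steps,
                                  params = params,
                                  seed = derive_seed(seed, paste0("scenario_", nm)),
                                  max_iter = config$max_iter %||% 300L)
  }
  summary_tab <- do.call(rbind, lapply(results, `[[`, "summary"))
  rownames(summary_tab) <- NULL
  comparison <- compare_scenarios(base_hq$Q, lapply(results, `[[`, "Q"))

  manifest <- list(
    package = as.character(utils::packageVersion("habscape")),
    created = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    stage_seeds = list(synth = spec$seed,
                       sample = derive_seed(seed, "sample"),
                       train = derive_seed(seed, "train"),
                       hindcast = derive_seed(seed, "hindcast"),
                       scenarios = stats::setNames(
                         lapply(scen_names, function(nm)
                           derive_seed(seed, paste0("scenario_", nm))), scen_names)),
    shape = spec$shape, cell_size = spec$cell_size,
    scenarios = scen_names,
    validation = list(overall = validation$overall, kappa = validation$kappa),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_raster(land$lu_t0, file.path(out_dir, "landuse_t0.asc"))
    write_raster(land$lu_t1, file.path(out_dir, "landuse_t1.asc"))
    utils::write.csv(P$P, file.path(out_dir, "transition_matrix.csv"))
    for (nm in names(results)) {
      write_raster(results[[nm]]$allocation$landuse,
                   file.path(out_dir, sprintf("landuse_%s.asc", nm)))
      write_raster(results[[nm]]$Q, file.path(out_dir, sprintf("quality_%s.asc", nm)))
    }
    write_raster(base_hq$Q, file.path(out_dir, "quality_baseline.asc"))
    utils::write.csv(summary_tab, file.path(out_dir, "scenario_summary.csv"),
                     row.names = FALSE)
    outputs <- list.files(out_dir, full.names = TRUE)
    manifest$outputs <- stats::setNames(
      as.list(unname(tools::md5sum(outputs))), basename(outputs))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(manifest = manifest, land = land, transition = P, model = model,
       validation = validation,
       baseline_quality = list(Q = base_hq$Q, D = base_hq$D, summary = base_sum),
       scenarios = results, comparison = comparison, summary = summary_tab)
}
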