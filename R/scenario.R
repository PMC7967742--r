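#' Load a scenario configuration
#'
#' `"S1"` to `"S4"` load the four packaged planning scenarios
#' (business-as-usual, fast cultivated-land expansion, ecological security,
#' sustainable development); any other value is treated as a path to a user
#' YAML with the same keys (`name`, `demand_source`, `weights_row` or
#' `weights`, `conversion`, `restricted`, optionally `demand_areas`).
#'
#' @param name_or_path Scenario name or YAML path.
#' @param params Parameter bundle from [read_parameter_tables()].
#' @return Object of class `scenario_config` with fields `name`, `label`,
#'   `demand_source` (`"markov"` or `"table"`), `demand_areas` (named hm^2
#'   vector or NULL), `weights` (named per-class neighborhood weights),
#'   `allow` ([conversion_matrix()]), `restricted` (character subset of
#'   `"redline"`, `"farmland"`).
#' @export
load_scenario <- function(name_or_path, params = read_parameter_tables()) {
  if (name_or_path %in% c("S1", "S2", "S3", "S4")) {
    path <- system.file("extdata", paste0("scenario_", name_or_path, ".yaml"),
                        package = "habscape")
  } else {
    path <- name_or_path
    if (!file.exists(path)) stop("scenario file not found: ", path)
  }
  cfg <- yaml::read_yaml(path)
  for (field in c("name", "demand_source", "conversion")) {
    if (is.null(cfg[[field]])) stop("scenario config missing field: ", field)
  }
  if (!cfg[["demand_source"]] %in% c("markov", "table"))
    stop("field demand_source must be 'markov' or 'table'")
  cn <- habscape_classes()$name

  if (!is.null(cfg[["weights"]])) {
    w <- unlist(cfg[["weights"]])
    if (!all(cn %in% names(w))) stop("field weights must name all 8 classes")
    w <- w[cn]
  } else {
    row <- cfg[["weights_row"]] %||% cfg[["name"]]
    hit <- params$weights$scenario == row
    if (!any(hit)) stop("field weights_row: no row '", row,
                        "' in neighborhood_weights table")
    w <- stats::setNames(as.numeric(params$weights[hit, cn]), cn)
  }

  if (!cfg[["conversion"]] %in% names(params$conversion))
    stop("field conversion: unknown matrix id '", cfg[["conversion"]], "'")

  demand_areas <- NULL
  if (cfg[["demand_source"]] == "table") {
    if (!is.null(cfg[["demand_areas"]])) {
      demand_areas <- unlist(cfg[["demand_areas"]])
      if (!all(cn %in% names(demand_areas)))
        stop("field demand_areas must name all 8 classes")
      demand_areas <- demand_areas[cn]
    } else {
      hit <- params$demand_areas$scenario == cfg[["name"]]
      if (!any(hit)) stop("field demand_areas: no packaged row for scenario '",
                          cfg[["name"]], "'")
      demand_areas <- stats::setNames(as.numeric(params$demand_areas[hit, cn]), cn)
    }
  }

  restricted <- as.character(cfg[["restricted"]] %||% character(0))
  bad <- setdiff(restricted, c("redline", "farmland"))
  if (length(bad) > 0) stop("field restricted: unknown mask role(s): ",
                            paste(bad, collapse = ", "))

  structure(list(name = cfg[["name"]], label = cfg[["label"]] %||% cfg[["name"]],
                 demand_source = cfg[["demand_source"]],
                 demand_areas = demand_areas, weights = w,
                 allow = params$conversion[[cfg[["conversion"]]]],
                 conversion_id = cfg[["conversion"]],
                 restricted = restricted),
            class = "scenario_config")
}

# Frozen mask implied by a scenario: redline freezes every cell inside it;
# the permanent-farmland mask freezes only its cultivated cells (it protects
# cultivated land specifically, without pinning other classes).
scenario_frozen <- function(config, lu, masks) {
  frozen <- matrix(FALSE, nrow(lu$codes), ncol(lu$codes))
  cls <- lu$class_table
  for (role in config$restricted) {
    m <- masks[[role]]
    if (is.null(m)) stop("scenario ", config$name, " needs mask '", role,
                         "' but none was supplied")
    if (inherits(m, "restricted_mask")) m <- m$frozen
    if (role == "farmland") {
      m <- m & lu$codes == cls$code[cls$name == "cultivated"] & !lu$nodata
      m[is.na(m)] <- FALSE
    }
    frozen <- frozen | m
  }
  frozen & !lu$nodata
}

# Demand over the mutable cells: start from the full-landscape target,
# subtract the frozen cells' classes, clamp at zero and rebalance to the
# mutable-cell total by largest remainder.
demand_for_mutable <- function(full_counts, frozen_counts, n_mutable, classes) {
  d <- pmax(as.numeric(full_counts) - as.numeric(frozen_counts), 0)
  if (sum(d) == 0) stop("demand is exhausted by the frozen cells")
  d <- d / sum(d) * n_mutable
  demand_vector(largest_remainder_round(d, total = as.integer(n_mutable)), classes)
}

#' Run one scenario end to end
#'
#' Resolves the scenario's demand (Markov projection for the
#' business-as-usual path, the planning table otherwise, rescaled to the
#' landscape and net of frozen cells), allocates land use with the cellular
#' automaton and scores habitat quality on the result.
#'
#' @param config A [load_scenario()] configuration.
#' @param lu_base Starting [land_use_map()] (the later calibration date).
#' @param model A [train_suitability_model()] fit.
#' @param drivers The [driver_stack()] the model was trained on.
#' @param masks Named list of [restricted_mask()]s (`redline`, `farmland`)
#'   for scenarios that restrict areas.
#' @param P [transition_matrix()] for Markov-sourced demand (required for
#'   S1-style configs).
#' @param n_steps Projection steps for Markov demand (calibration intervals;
#'   may be fractional).
#' @param params Parameter bundle from [read_parameter_tables()].
#' @param seed Integer seed (deterministic output for fixed inputs + seed).
#' @param ... Passed to [run_allocation()] (`tol`, `max_iter`, `rule`, ...).
#' @return List with `allocation` ([run_allocation()] result), `D`, `Q`,
#'   and `summary` (one-row data.frame: scenario, mean and sd of quality,
#'   five grade percentages, iterations, converged).
#' @export
run_scenario <- function(config, lu_base, model, drivers, masks = list(),
                         P = NULL, n_steps = 13 / 8,
                         params = read_parameter_tables(), seed = 1L, ...) {
  stopifnot(inherits(config, "scenario_config"), inherits(lu_base, "land_use_map"))
  k <- lu_base$class_table$code
  frozen <- scenario_frozen(config, lu_base, masks)
  n_mut <- sum(!lu_base$nodata & !frozen)
  frozen_counts <- tabulate(match(lu_base$codes[frozen], k), nbins = length(k))
  n_tot <- sum(!lu_base$nodata)

  full <- if (config$demand_source == "markov") {
    if (is.null(P)) stop("scenario ", config$name,
                         " uses Markov demand but no transition matrix was given")
    project_state(class_counts(lu_base), P, n_steps)$counts
  } else {
    demand_from_areas(config$demand_areas, lu_base$cell_size,
                      total_cells = n_tot, classes = k)$counts
  }
  demand <- demand_for_mutable(full, frozen_counts, n_mut, k)

  sp <- predict_suitability(model, drivers)
  alloc <- run_allocation(sp, lu_base, demand, config$weights, config$allow,
                          frozen = frozen, seed = seed, ...)
  hq <- habitat_quality(alloc$landuse, params = params)
  s <- summarize_quality(hq$Q)
  grade_pct <- stats::setNames(s$grades$percent, s$grades$grade)
  summary_row <- data.frame(scenario = config$name, mean_q = s$mean, sd_q = s$sd,
                            t(grade_pct), iterations = alloc$iterations,
                            converged = alloc$converged,
                            check.names = FALSE)
  list(allocation = alloc, D = hq$D, Q = hq$Q, summary = summary_row)
}

#' Compare scenario quality maps against a baseline
#'
#' @param baseline A [quality_map()] (e.g. the later calibration date).
#' @param scenarios Named list of [quality_map()]s.
#' @param edges Change-class magnitudes (default `c(0.1, 0.4)`), giving the
#'   bins `< -0.4`, `-0.4..-0.1`, `-0.1..0.1`, `0.1..0.4`, `> 0.4`.
#' @return List with `change` (per scenario: `delta` raster, `classes`
#'   integer raster 1..5, `class_table` of bin percentages) and `ranking`
#'   (data.frame ordered by mean quality, with the High+Higher share).
#' @export
compare_scenarios <- function(baseline, scenarios, edges = c(0.1, 0.4)) {
  base <- if (inherits(baseline, "quality_map")) baseline$values else baseline
  stopifnot(length(edges) == 2, edges[1] > 0, edges[2] > edges[1])
  breaks <- c(-Inf, -edges[2], -edges[1], edges[1], edges[2], Inf)
  labels <- c(sprintf("< -%g", edges[2]),
              sprintf("-%g..-%g", edges[2], edges[1]),
              sprintf("-%g..%g", edges[1], edges[1]),
              sprintf("%g..%g", edges[1], edges[2]),
              sprintf("> %g", edges[2]))
  change <- lapply(scenarios, function(q) {
    v <- if (inherits(q, "quality_map")) q$values else q
    if (!identical(dim(v), dim(base))) stop("quality maps must share one shape")
    delta <- v - base
    cl <- matrix(findInterval(delta, breaks[-c(1, 6)]) + 1L, nrow(delta))
    cl[is.na(delta)] <- NA_integer_
    counts <- tabulate(cl[!is.na(cl)], nbins = 5L)
    list(delta = delta, classes = cl,
         class_table = data.frame(bin = labels, cells = counts,
                                  percent = 100 * counts / sum(counts)))
  })
  stats_tab <- do.call(rbind, lapply(names(scenarios), function(nm) {
    s <- summarize_quality(scenarios[[nm]])
    hh <- sum(s$grades$percent[s$grades$grade %in% c("High", "Higher")])
    data.frame(scenario = nm, mean_q = s$mean, high_higher_pct = hh)
  }))
  stats_tab <- stats_tab[order(-stats_tab$mean_q), ]
  stats_tab$rank_mean <- seq_len(nrow(stats_tab))
  list(change = change, ranking = stats_tab)
}
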