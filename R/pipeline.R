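#' Configuration for a full pipeline run
#'
#' Collects every tunable constant of the analysis in one place so no
#' threshold is hard-coded downstream: the thermal thresholds, the survival
#' and host-mask classification cutoffs, the quantile level, the warming
#' scenario deltas, the generator sizes and the seed.
#'
#' @param seed Integer seed for all random stages.
#' @param cold_threshold,dev_lower,dev_upper Thermal thresholds (degC).
#' @param permanent_min,marginal_min Survival class cutoffs (defaults 0.05,
#'   0.01).
#' @param host_min Host presence threshold (default 0.3).
#' @param tau Quantile level of the high-resistance model (default 0.85).
#' @param scenario_deltas Warming scenario increments in degC
#'   (default 1:6).
#' @param n_regimes Laboratory regimes (default 10).
#' @param n_lat,n_lon,years Climate grid dimensions and window label years.
#' @param n_records,n_sites,n_pesticides Meta-analysis design sizes.
#' @param truth A [truth_params()] for the generators.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L, cold_threshold = 11.0,
                            dev_lower = 7.4, dev_upper = 33.0,
                            permanent_min = 0.05, marginal_min = 0.01,
                            host_min = 0.3, tau = 0.85,
                            scenario_deltas = 1:6, n_regimes = 10,
                            n_lat = 31, n_lon = 4, years = 1967:1981,
                            n_records = 600, n_sites = 80,
                            n_pesticides = 10, truth = truth_params()) {
  stopifnot(permanent_min > marginal_min, marginal_min > 0,
            host_min >= 0, host_min <= 1, tau > 0, tau < 1)
  structure(list(seed = as.integer(seed), cold_threshold = cold_threshold,
                 dev_lower = dev_lower, dev_upper = dev_upper,
                 permanent_min = permanent_min, marginal_min = marginal_min,
                 host_min = host_min, tau = tau,
                 scenario_deltas = scenario_deltas, n_regimes = n_regimes,
                 n_lat = n_lat, n_lon = n_lon, years = years,
                 n_records = n_records, n_sites = n_sites,
                 n_pesticides = n_pesticides, truth = truth),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in dependency order on synthetic inputs:
#' generate laboratory regimes and survival observations; fit and rank the
#' nine candidate survival models; validate the selected model against
#' simulated field data; project the model onto a synthetic climate grid
#' (classification, areas, warming scenarios, marginal-belt trend); and run
#' the resistance meta-analysis (effect sizes, weighted means, level
#' frequencies, mixed-model Wald tests, quantile model, resistance map,
#' publication bias). All tables are written as CSV/JSON under `out_dir`
#' together with a manifest recording the configuration, seed, versions and
#' per-stage record counts. Runs are idempotent for a fixed config and
#' seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return The run manifest (list), invisibly; all artifacts on disk.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  thermal <- thermal_config(config$cold_threshold, config$dev_lower,
                            config$dev_upper)
  counts <- list()

  # --- laboratory stage ---------------------------------------------------
  regimes <- make_regimes(config$n_regimes, seed = config$seed)
  obs <- simulate_survival_experiment(regimes, config$truth,
                                      seed = config$seed, config = thermal)
  counts$lab_observations <- nrow(obs)
  utils::write.csv(obs, file.path(out_dir, "lab_observations.csv"),
                   row.names = FALSE)

  cmp <- compare_models(obs, seed = config$seed)
  utils::write.csv(as.data.frame(cmp),
                   file.path(out_dir, "model_comparison.csv"),
                   row.names = FALSE)
  model <- best_model(cmp)
  write_survival_model(model, file.path(out_dir, "survival_model.json"))

  field <- simulate_field_experiment(regimes, config$truth,
                                     seed = config$seed + 1L,
                                     config = thermal)
  counts$field_observations <- nrow(field)
  val <- validate_field(model, field)

  # --- range stage --------------------------------------------------------
  sim <- simulate_climate_grid(config$n_lat, config$n_lon, config$years,
                               config$truth, seed = config$seed)
  counts$grid_cells <- config$n_lat * config$n_lon
  base_years <- config$years[1]:(config$years[1] + 4L)
  final_years <- (max(config$years) - 4L):max(config$years)
  sv <- survival_grid(sim$grid, model, final_years, thermal)
  map <- classify_overwintering(sv, sim$host, sim$grid$lats, sim$grid$lons,
                                config$permanent_min, config$marginal_min,
                                config$host_min)
  write_overwinter_map(map, file.path(out_dir, "overwinter_map.csv"))
  exp_series <- expansion_series(sim$grid, model, sim$host, config$years,
                                 config$years[1], thermal)
  utils::write.csv(exp_series$yearly,
                   file.path(out_dir, "expansion_yearly.csv"),
                   row.names = FALSE)
  scen <- do.call(rbind, lapply(c(0, config$scenario_deltas), function(d) {
    g <- if (d == 0) sim$grid else warming_scenario(sim$grid, d)
    svd <- survival_grid(g, model, final_years, thermal)
    md <- classify_overwintering(svd, sim$host, g$lats, g$lons,
                                 config$permanent_min, config$marginal_min,
                                 config$host_min)
    data.frame(delta_t = d,
               area_ge5 = overwinter_area(md, config$permanent_min)$area_km2,
               area_ge1 = overwinter_area(md, config$marginal_min)$area_km2)
  }))
  utils::write.csv(scen, file.path(out_dir, "scenario_areas.csv"),
                   row.names = FALSE)
  trend <- tryCatch(
    marginal_belt_trend(sim$grid, model, sim$host, config$years,
                        config$years[1], thermal),
    error = function(e) NULL)

  # --- meta-analysis stage ------------------------------------------------
  rec <- simulate_resistance_records(
    config$n_records, config$truth, sim, seed = config$seed,
    n_sites = config$n_sites, n_pesticides = config$n_pesticides,
    config = thermal)
  counts$resistance_records <- nrow(rec)
  rec <- effect_sizes(rec)
  counts$imputed_variances <- sum(rec$imputed_v)
  ann <- annotate_sites(rec, sim$grid, model, thermal)
  counts$records_dropped_coverage <- attr(ann, "n_dropped")
  write_resistance_records(ann, file.path(out_dir, "effect_sizes.csv"))
  wmr <- weighted_mean_rr(ann)
  freqs <- level_frequencies(ann)
  anova_tab <- mixed_model_anova(ann, interactions = FALSE)
  utils::write.csv(anova_tab, file.path(out_dir, "anova_table.csv"),
                   row.names = FALSE)
  qm <- quantile_model(ann, tau = config$tau, seed = config$seed)
  lt_final <- Reduce(`+`, lapply(final_years, function(y)
    annual_ltdd_grid(sim$grid, y, thermal))) / length(final_years)
  rmap <- predict_resistance_map(qm, lt_final, sim$host, sim$grid$lats,
                                 sim$grid$lons, config$host_min)
  utils::write.csv(rmap, file.path(out_dir, "resistance_map.csv"),
                   row.names = FALSE)
  bias <- publication_bias(ann)

  # --- manifest -----------------------------------------------------------
  cfg_plain <- unclass(config)
  cfg_plain$truth <- unclass(cfg_plain$truth)
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("coldrange")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = .hash_string(as.character(cfg_json)),
    counts = counts,
    selected_model = list(predictor = model$spec$predictor,
                          form = model$spec$form,
                          coefficients = as.list(model$coefficients),
                          r2 = model$r2, aic = model$aic),
    field_validation = list(slope = val$slope, r2 = val$r2,
                            bias = val$bias, n = val$n),
    weighted_mean_rr = as.list(wmr),
    marginal_belt_trend = if (is.null(trend)) NULL else
      trend[c("slope", "r2", "p", "n_cells")],
    quantile_model = qm[c("slope", "intercept", "p_slope", "tau", "n")],
    publication_bias = bias[c("kendall_tau", "p")],
    anova = data.frame(source = anova_tab$source, chisq = anova_tab$chisq,
                       df = anova_tab$df, p = anova_tab$p),
    level_frequencies = as.data.frame.matrix(freqs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

# md5 of a string via a temp file (base tools only)
.hash_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}
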