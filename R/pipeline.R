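#' Pipeline run configuration
#'
#' Bundles every stage's configuration for an end-to-end run: the synthetic
#' world, the regression specification, the CRF and coefficient-draw
#' settings, valuation inputs and the projection ensemble.  Stages execute
#' in dependency order (`generate`, `exposure`, `panel`, `fit`, `burden`,
#' `value`, `project`); disabling a stage also disables everything
#' downstream of it.
#'
#' @param out_dir Output directory for stage artifacts and the manifest
#'   (`NULL` to keep results in memory only).
#' @param stages Character vector of enabled stages (prefix of the full
#'   order).
#' @param world Named list of [world_config()] overrides.
#' @param spec A [fhd_model_spec()].
#' @param crf A [crf_spec()].
#' @param n_draws Monte-Carlo draws for the mortality counterfactual.
#' @param vsl_base_usd2019,vsl_elasticity Valuation settings (see
#'   [vsl_spec()]).
#' @param n_models Climate models in the projection ensemble.
#' @param retirement_paths Named list (`APS`, `STEPS`) of tibbles
#'   (`year`, `n_retire`); `NULL` uses a default ladder (2.5% of the fleet
#'   per year from 2025 under APS, 1.5% from 2030 under STEPS).
#' @param seed Global seed; per-stage seeds are derived deterministically.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(out_dir = NULL,
                            stages = c("generate", "exposure", "panel", "fit",
                                       "burden", "value", "project"),
                            world = list(),
                            spec = fhd_model_spec(),
                            crf = crf_spec(),
                            n_draws = 1000L,
                            vsl_base_usd2019 = 7.0e6,
                            vsl_elasticity = 1,
                            n_models = 22L,
                            retirement_paths = NULL,
                            seed = 1L) {
  structure(list(out_dir = out_dir, stages = stages, world = world,
                 spec = spec, crf = crf, n_draws = as.integer(n_draws),
                 vsl_base_usd2019 = vsl_base_usd2019,
                 vsl_elasticity = vsl_elasticity,
                 n_models = as.integer(n_models),
                 retirement_paths = retirement_paths,
                 seed = as.integer(seed)),
            class = "run_config")
}

.stage_order <- c("generate", "exposure", "panel", "fit", "burden", "value",
                  "project")

#' Validate a run configuration
#'
#' Schema and cross-field validation with actionable messages; reports
#' rather than raises.
#'
#' @param config A [pipeline_config()] (or plain list in its shape).
#' @return A tibble of findings (`level` in `error`/`warning`/`info`,
#'   `message`) with attribute `valid` (no errors found).
#' @export
validate_run_config <- function(config) {
  notes <- list()
  add <- function(level, msg) notes[[length(notes) + 1L]] <<-
    tibble::tibble(level = level, message = msg)
  unknown <- setdiff(config$stages, .stage_order)
  if (length(unknown)) add("error", paste("unknown stages:",
                                          paste(unknown, collapse = ", ")))
  enabled <- .stage_order %in% config$stages
  if (any(enabled) && any(diff(which(enabled)) > 1L) ||
      (any(enabled) && which(enabled)[1L] != 1L && is.null(config$inputs))) {
    first_gap <- .stage_order[which(!enabled)[1L]]
    add("error", paste0("stage dependency missing: '", first_gap,
                        "' is disabled but a later stage is enabled"))
  }
  stochastic <- any(c("generate", "burden", "project") %in% config$stages)
  if (stochastic && (is.null(config$seed) || is.na(config$seed))) {
    add("error", "a seed is required when stochastic stages are enabled")
  }
  wc <- tryCatch({
    do.call(world_config, c(config$world, list(seed = config$seed %||% 1L)))
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(wc)) add("error", paste("world config invalid:", wc))
  win <- config$world$drought_window %||% 3L
  if (!win %in% c(1L, 3L, 6L, 9L, 12L)) {
    add("warning", paste("non-standard drought window:", win, "months"))
  }
  if (!is.null(config$out_dir) && !dir.exists(config$out_dir) &&
      !dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)) {
    add("error", paste("cannot create out_dir:", config$out_dir))
  }
  out <- if (length(notes)) dplyr::bind_rows(notes) else
    tibble::tibble(level = character(), message = character())
  attr(out, "valid") <- !any(out$level == "error")
  out
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic world:
#' generation, market drought exposure, panel assembly, the fixed-effects
#' fit, the Monte-Carlo mortality counterfactual, valuation, and the
#' scenario projections.  Every stage logs row counts in and out, and, when
#' `out_dir` is set, writes its tabular outputs as CSV plus a JSON manifest
#' with the config, the seed and MD5 hashes of all written files.
#' Re-running with an identical config and seed reproduces identical
#' artifacts.
#'
#' @param config A [pipeline_config()].
#' @return A list with the stage results (`world`, `exposure`, `panel`,
#'   `fit`, `draws`, `losses`, `paths`) and the `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  report <- validate_run_config(config)
  if (!attr(report, "valid")) {
    stop("invalid run config:\n  ",
         paste(report$message[report$level == "error"], collapse = "\n  "),
         call. = FALSE)
  }
  stages <- config$stages
  out_dir <- config$out_dir
  files <- character(0)
  log <- list()
  note <- function(stage, msg) log[[length(log) + 1L]] <<-
    list(stage = stage, message = msg)
  save_csv <- function(df, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  res <- list()

  if ("generate" %in% stages) {
    wcfg <- do.call(world_config, c(config$world, list(seed = config$seed)))
    res$world <- generate_world(wcfg)
    note("generate", sprintf("%d plants, %d months",
                             nrow(res$world$plants), length(wcfg$months)))
    save_csv(res$world$plants, "plant_registry.csv")
    save_csv(res$world$country_tables$gni, "gni_per_capita.csv")
  }
  if ("exposure" %in% stages) {
    w <- res$world
    hydro <- w$plants[w$plants$type == "hydro", ]
    res$exposure <- compute_market_exposure(
      w$runoff, w$basins, hydro, w$config$reference_years,
      window = w$config$drought_window, markets = w$markets)
    note("exposure", sprintf("%d market-months", nrow(res$exposure)))
    save_csv(res$exposure, "market_exposure.csv")
  }
  if ("panel" %in% stages) {
    w <- res$world
    comb <- w$plants[w$plants$type == "combustion", ]
    res$panel <- assemble_panel(comb, w$pm25, w$met, w$runoff, res$exposure,
                                w$fire, w$config$reference_years)
    note("panel", sprintf("%d plant-months, %d in analysis sample",
                          nrow(res$panel), sum(res$panel$analysis_sample)))
    save_csv(res$panel, "panel.csv")
  }
  if ("fit" %in% stages) {
    res$fit <- fit_fe_ols(res$panel, config$spec)
    note("fit", sprintf("beta = %.3f (se %.3f), N = %d, clusters = %d",
                        res$fit$coefficients[1L], res$fit$se[1L],
                        res$fit$n_obs, res$fit$n_clusters))
    save_csv(results_table(res$fit), "fit_results.csv")
  }
  if ("burden" %in% stages) {
    w <- res$world
    res$pop65 <- world_pop65(w)
    burden <- res$panel[res$panel$operational & !is.na(res$panel$fhd),
                        c("plant_id", "market", "year", "month", "fhd")]
    burden <- dplyr::inner_join(burden, res$pop65,
                                by = c("plant_id", "year"))
    bds <- beta_draw_spec(mean = unname(res$fit$coefficients[1L]),
                          sd = unname(res$fit$se[1L]),
                          n_draws = config$n_draws,
                          seed = stream_seed(config$seed, "draws"))
    res$draws <- monte_carlo_deaths(burden, config$crf, bds,
                                    level = "country-year")
    note("burden", sprintf("%d draw-units (%d draws)", nrow(res$draws),
                           config$n_draws))
    save_csv(aggregate_draws(res$draws, "region-year"), "deaths_region_year.csv")
  }
  if ("value" %in% stages) {
    w <- res$world
    vspec <- vsl_spec(config$vsl_base_usd2019, config$vsl_elasticity,
                      gni = w$country_tables$gni,
                      us_gni = w$country_tables$us_gni)
    res$losses <- monetize(res$draws, vspec)
    note("value", sprintf("total mean annual losses %.3g USD",
                          mean(tapply(res$losses$losses_usd2019,
                                      res$losses$draw, sum))))
    save_csv(dplyr::summarise(
      dplyr::group_by(res$losses, .data$market),
      mean_losses_usd2019 = sum(.data$losses_usd2019) /
        length(unique(.data$draw)), .groups = "drop"),
      "losses_country.csv")
    res$vsl_spec <- vspec
  }
  if ("project" %in% stages) {
    w <- res$world
    hydro <- w$plants[w$plants$type == "hydro", ]
    ens <- generate_runoff_ensemble(w, n_models = config$n_models,
                                    seed = config$seed)
    fhd_paths <- list()
    for (key in names(ens$grids)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
      pf <- projected_fhd(ens$grids[[key]], w$runoff, w$basins, hydro,
                          w$config$reference_years,
                          window = w$config$drought_window)
      pf$model_id <- parts[1L]; pf$ssp_rcp <- parts[2L]
      fhd_paths[[key]] <- pf
    }
    fhd_paths <- dplyr::bind_rows(fhd_paths)
    pop65_base <- dplyr::summarise(
      dplyr::group_by(res$pop65[res$pop65$year ==
                                  max(res$pop65$year), ], .data$plant_id),
      pop65 = .data$pop65[1L], .groups = "drop")
    comb <- w$plants[w$plants$type == "combustion", ]
    pop65_base$market <- comb$market[match(pop65_base$plant_id, comb$plant_id)]
    scal <- generate_scenario_scalings(w, seed = config$seed)
    rp <- config$retirement_paths %||% .default_retirement_paths(nrow(comb))
    rets <- list(
      APS = build_retirement_schedule(pop65_base, "APS", rp$APS),
      STEPS = build_retirement_schedule(pop65_base, "STEPS", rp$STEPS),
      RES = build_retirement_schedule(pop65_base, "RES"))
    base_year <- 2019L
    vsl_base <- tibble::tibble(
      country = w$markets,
      vsl_usd2019 = country_vsl(
        vsl_spec(config$vsl_base_usd2019, config$vsl_elasticity,
                 gni = w$country_tables$gni, us_gni = w$country_tables$us_gni),
        w$markets, rep(min(base_year, max(w$country_tables$gni$year)),
                       length(w$markets))))
    res$paths <- project_paths(fhd_paths, pop65_base, scal$demographic,
                               scal$economic, vsl_base, rets,
                               crf = config$crf,
                               beta = unname(res$fit$coefficients[1L]))
    note("project", sprintf("%d paths", attr(res$paths, "n_paths")))
    save_csv(res$paths, "scenario_paths.csv")
  }

  manifest <- list(
    package = "droughtpm",
    version = as.character(utils::packageVersion("droughtpm")),
    seed = config$seed,
    stages = stages,
    log = log,
    files = if (length(files)) {
      tibble::tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
    } else NULL)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res$manifest <- manifest
  invisible(res)
}

# Default retirement quantity ladders: APS retires 2.5% of the fleet per
# year from 2025, STEPS 1.5% from 2030; ladders never exceed the fleet.
.default_retirement_paths <- function(n_plants) {
  ladder <- function(start, frac) {
    per <- ceiling(frac * n_plants)
    n_years <- min(25L, ceiling(n_plants / per))
    tibble::tibble(year = start + seq_len(n_years) - 1L,
                   n_retire = pmin(per, n_plants - per * (seq_len(n_years) - 1L)))
  }
  list(APS = ladder(2025L, 0.025), STEPS = ladder(2030L, 0.015))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with top-level keys matching
#'   [pipeline_config()] arguments (`spec` and `crf` as plain lists of
#'   their constructor arguments).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("out_dir", "stages", "world", "n_draws", "vsl_base_usd2019",
              "vsl_elasticity", "n_models", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$spec)) args$spec <- do.call(fhd_model_spec, y$spec)
  if (!is.null(y$crf)) args$crf <- do.call(crf_spec, y$crf)
  do.call(pipeline_config, args)
}
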