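#' Pipeline configuration
#'
#' One configuration object drives the whole workflow: simulate (or load)
#' climate, prepare occurrences, screen collinearity, fit and cross-validate
#' per species, derive importance profiles and thresholds, project suitability
#' onto scenario grids, and stack richness. The single `seed` is the only
#' source of randomness; every stage derives child seeds from it via
#' [derive_seed()], so a rerun with the same configuration bit-reproduces all
#' outputs.
#'
#' @param seed integer pipeline seed (mandatory).
#' @param grid list of [generate_climate()] arguments (`n_rows`, `n_cols`,
#'   `spatial_corr_length`, `mask_fraction`).
#' @param n_species number of virtual species to generate when `species` is
#'   `NULL`.
#' @param species optional list of explicit species specs, each a list with
#'   `species_id`, `response`, `n_presences`, `detection_noise`.
#' @param scenarios list of scenario specs, each a list with `label`,
#'   `delta_temp`, `precip_factor` (and optional `lat_ramp`).
#' @param rf an [rf_config()]; its seed is overridden by the pipeline seed.
#' @param min_cells occurrence inclusion threshold.
#' @param collinearity_threshold,priority arguments of
#'   [screen_collinearity()].
#' @param k_zones number of reporting zones.
#' @param scheme richness class scheme, `"quintal"` or `"decadal"`.
#' @param detection_noise default detection noise for auto-generated species.
#' @param presence_range inclusive range from which auto-generated species
#'   draw their presence counts (log-uniform).
#' @param out_dir optional output directory; when given, [run_pipeline()]
#'   writes all CSV and raster artifacts there.
#' @return an `sdm_config` list.
#' @export
sdm_config <- function(seed,
                       grid = list(n_rows = 64, n_cols = 64,
                                   spatial_corr_length = 6, mask_fraction = 0.9),
                       n_species = 20, species = NULL,
                       scenarios = list(
                         list(label = "warm2-2050s", delta_temp = 2, precip_factor = 1.05),
                         list(label = "warm4-2090s", delta_temp = 4, precip_factor = 0.9)
                       ),
                       rf = rf_config(), min_cells = 2,
                       collinearity_threshold = 0.7,
                       priority = c("BIO1", "BIO14", "BIO2", "BIO12", "BIO3", "BIO13"),
                       k_zones = 12, scheme = "quintal",
                       detection_noise = 0.1, presence_range = c(2, 200),
                       out_dir = NULL) {
  if (missing(seed)) stop("a pipeline seed is mandatory")
  stopifnot(min_cells >= 0, k_zones >= 1,
            scheme %in% c("quintal", "decadal"))
  rf$seed <- as.integer(seed)
  structure(
    list(seed = as.integer(seed), grid = grid, n_species = n_species,
         species = species, scenarios = scenarios, rf = rf,
         min_cells = min_cells,
         collinearity_threshold = collinearity_threshold, priority = priority,
         k_zones = k_zones, scheme = scheme,
         detection_noise = detection_noise, presence_range = presence_range,
         out_dir = out_dir),
    class = "sdm_config"
  )
}

#' Bundled demonstration configuration
#'
#' Twenty virtual species on a 64 x 64 grid with two warming scenarios
#' (+2 degC / wetter by mid-century, +4 degC / drier by late century) and five
#' cross-validation repetitions -- small enough to run end to end in a couple
#' of minutes while exercising every stage.
#'
#' @param seed pipeline seed.
#' @param out_dir optional artifact directory.
#' @return an [sdm_config()].
#' @export
demo_config <- function(seed = 1, out_dir = NULL) {
  sdm_config(
    seed = seed,
    n_species = 20,
    rf = rf_config(n_repetitions = 5),
    presence_range = c(2, 120),
    out_dir = out_dir
  )
}

# draw n_species virtual-species specs with niches anchored on the grid's
# realized climate (log-uniform presence counts; 1-2 informative variables)
auto_species_specs <- function(config, grid) {
  specs <- vector("list", config$n_species)
  vars <- bio_variables()
  for (i in seq_len(config$n_species)) {
    set.seed(derive_seed(config$seed, paste0("species-spec/", i)))
    sid <- sprintf("vsp%02d", i)
    n_inf <- sample(1:2, 1)
    chosen <- sample(vars, n_inf)
    response <- list()
    for (v in chosen) {
      vals <- grid$layers[[v]][grid$mask]
      mu <- stats::quantile(vals, stats::runif(1, 0.15, 0.85), names = FALSE)
      # narrow ecological amplitudes, as for range-restricted species; the
      # spread produces a cohort covering the whole performance-class range
      sdv <- stats::sd(vals) * stats::runif(1, 0.04, 0.3)
      response[[v]] <- response_gaussian(mu, sdv)
    }
    lr <- log(config$presence_range)
    n_pres <- max(2L, round(exp(stats::runif(1, lr[1], lr[2]))))
    specs[[i]] <- list(species_id = sid, response = response,
                       n_presences = n_pres,
                       detection_noise = config$detection_noise)
  }
  specs
}

#' Run the full stacked-SDM pipeline
#'
#' Executes, in order: climate simulation (baseline plus scenarios), zone
#' partitioning, virtual-species generation, occurrence preparation,
#' collinearity screening, per-species cross-validation with permutation
#' importance and TSS-max threshold selection, mean-suitability projection
#' onto every grid, binarisation and richness stacking, zonal aggregation,
#' and richness-change analysis of each scenario against the baseline.
#' Cohort summaries mirror the per-species tables. When `config$out_dir` is
#' set, all tabular artifacts are written as CSV (plus ASCII rasters for the
#' climate layers and zones) and a JSON run manifest records the
#' configuration snapshot, software versions, per-stage timings, flags and
#' exclusions.
#'
#' @param config an [sdm_config()].
#' @param quiet suppress per-stage progress messages.
#' @return a `pipeline_result` list: `grids`, `zones`, `species_truth`,
#'   `occurrences` (with report), `screen`, `cv` (list of `cv_report`),
#'   `species_metrics`, `importance_profiles`, `performance_summary`,
#'   `importance_summary`, `surfaces`, `range_maps`, `richness` (per-label
#'   `richness_surface` + zone table), `changes`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "sdm_config"))
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(start, stage) {
    timings[[stage]] <<- round(as.numeric(difftime(Sys.time(), start, units = "secs")), 3)
  }

  # -- simulate ------------------------------------------------------------
  st <- tic()
  g <- config$grid
  baseline <- generate_climate(
    n_rows = g$n_rows, n_cols = g$n_cols,
    spatial_corr_length = g$spatial_corr_length %||% 6,
    seed = derive_seed(config$seed, "climate"),
    mask_fraction = g$mask_fraction %||% 0.9,
    label = "baseline"
  )
  grids <- c(
    list(baseline = baseline),
    stats::setNames(
      purrr::map(config$scenarios, function(sc) {
        generate_scenario(baseline, delta_temp = sc$delta_temp %||% 0,
                          precip_factor = sc$precip_factor %||% 1,
                          label = sc$label, lat_ramp = sc$lat_ramp %||% 0)
      }),
      purrr::map_chr(config$scenarios, "label")
    )
  )
  zones <- generate_zones(baseline, config$k_zones,
                          seed = derive_seed(config$seed, "zones"))
  specs <- config$species %||% auto_species_specs(config, baseline)
  species_truth <- purrr::map(specs, function(sp) {
    generate_virtual_species(
      baseline, sp$response, sp$n_presences,
      detection_noise = sp$detection_noise %||% config$detection_noise,
      seed = derive_seed(config$seed, paste0("presences/", sp$species_id)),
      species_id = sp$species_id
    )
  })
  names(species_truth) <- purrr::map_chr(species_truth, "species_id")
  points <- purrr::map_dfr(species_truth, species_points, grid = baseline)
  toc(st, "simulate")
  say(sprintf("simulated %d species on a %dx%d grid (%d scenarios)",
              length(species_truth), g$n_rows, g$n_cols, length(config$scenarios)))

  # -- prep ----------------------------------------------------------------
  st <- tic()
  occ <- suppressMessages(prepare_occurrences(points, baseline, config$min_cells))
  prep_report <- occurrence_report(occ)
  retained <- prep_report$species_id[!prep_report$excluded]
  toc(st, "prep")
  say(sprintf("occurrence prep: %d of %d species retained",
              length(retained), nrow(prep_report)))

  # -- screen --------------------------------------------------------------
  st <- tic()
  screen <- screen_collinearity(baseline, config$collinearity_threshold,
                                config$priority)
  variables <- screen$retained
  toc(st, "screen")
  say("collinearity screen retained: ", paste(variables, collapse = ", "))

  # -- fit / cross-validate ------------------------------------------------
  st <- tic()
  cv <- list()
  profiles <- list()
  for (sid in retained) {
    cells <- dplyr::filter(tibble::as_tibble(occ), .data$species_id == sid)
    cvr <- cross_validate(cells, baseline, config$rf, variables = variables,
                          species_id = sid)
    cv[[sid]] <- cvr
    raw <- stats::setNames(rep(0, length(bio_variables())), bio_variables())
    raw[names(cvr$importance_raw)] <- cvr$importance_raw
    profiles[[sid]] <- normalize_and_rank(raw, species_id = sid)
    say(sprintf("  %s: mean AUC %.3f%s", sid, mean(cvr$records$auc),
                if (length(cvr$flags)) paste0(" [", paste(cvr$flags, collapse = ","), "]") else ""))
  }
  species_metrics <- purrr::map_dfr(cv, glance)
  performance_summary <- if (nrow(species_metrics)) {
    summarize_performance(
      dplyr::select(species_metrics, "species_id", "auc", "tss", "kappa"))
  } else NULL
  importance_summary <- if (length(profiles)) summarize_importance(profiles) else NULL
  toc(st, "fit_cv")

  # -- project / richness --------------------------------------------------
  st <- tic()
  surfaces <- list()
  range_maps <- stats::setNames(vector("list", length(grids)), names(grids))
  for (sid in retained) {
    cells <- dplyr::filter(tibble::as_tibble(occ), .data$species_id == sid)
    surf <- predict_mean_suitability(cells, baseline, target_grids = grids,
                                     config = config$rf,
                                     variables = variables, species_id = sid)
    surfaces[[sid]] <- surf
    for (lab in names(grids)) {
      range_maps[[lab]][[sid]] <- binarize(surf[[lab]], cv[[sid]]$threshold)
    }
  }
  richness <- purrr::imap(range_maps, function(maps, lab) {
    surface <- stack_richness(maps %||% list(), label = lab,
                              dims = c(baseline$n_rows, baseline$n_cols))
    zone_table <- zonal_richness(maps %||% list(), zones, scheme = config$scheme)
    list(surface = surface, zone_table = zone_table)
  })
  changes <- purrr::imap(
    richness[setdiff(names(richness), "baseline")],
    function(r, lab) richness_change(richness$baseline$zone_table,
                                     r$zone_table, config$scheme)
  )
  toc(st, "richness")
  say("richness stacked for: ", paste(names(richness), collapse = ", "))

  manifest <- list(
    package_version = as.character(utils::packageVersion("stacksdm")),
    r_version = R.version.string,
    seed = config$seed,
    config = config[setdiff(names(config), "species")],
    n_species_defined = length(specs),
    n_species_retained = length(retained),
    exclusions = prep_report[prep_report$excluded,
                             c("species_id", "n_cells", "reason")],
    retained_variables = variables,
    rf_library_defaults = "randomForest: nodesize 1, maxnodes unlimited",
    flags = purrr::map(cv, "flags"),
    timings_sec = timings,
    total_sec = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
  )

  result <- structure(
    list(grids = grids, zones = zones, species_truth = species_truth,
         occurrences = occ, prep_report = prep_report, screen = screen,
         cv = cv, species_metrics = species_metrics,
         importance_profiles = profiles,
         performance_summary = performance_summary,
         importance_summary = importance_summary,
         surfaces = surfaces, range_maps = range_maps,
         richness = richness, changes = changes, manifest = manifest,
         config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_artifacts(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d species retained of %d, %d grid(s), %d zones\n",
              x$manifest$n_species_retained, x$manifest$n_species_defined,
              length(x$grids), length(x$zones$zone_ids)))
  if (nrow(x$species_metrics)) {
    cat(sprintf("cohort mean AUC %.3f; share AUC >= 0.8: %.1f%%\n",
                mean(x$species_metrics$auc), x$performance_summary$share_auc_ge_0.8))
  }
  invisible(x)
}

# write every tabular artifact; CSVs are the determinism contract
write_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_csv(x, file.path(dir, name))
  w(result$prep_report, "prep_report.csv")
  w(result$screen$correlations, "collinearity.csv")
  w(purrr::map_dfr(result$cv, "records"), "cv_records.csv")
  w(result$species_metrics, "species_metrics.csv")
  w(dplyr::bind_rows(purrr::map(result$importance_profiles, tibble::as_tibble)),
    "importance_profiles.csv")
  if (!is.null(result$performance_summary)) {
    w(result$performance_summary$class_table, "cohort_performance_classes.csv")
    w(result$performance_summary$metric_table, "cohort_metrics.csv")
  }
  if (!is.null(result$importance_summary)) {
    w(result$importance_summary$first_rank, "cohort_first_rank.csv")
    w(result$importance_summary$mean_rank, "cohort_mean_rank.csv")
    w(result$importance_summary$patterns, "cohort_patterns.csv")
  }
  for (lab in names(result$richness)) {
    w(result$richness[[lab]]$zone_table,
      paste0("richness_zones_", lab, ".csv"))
  }
  for (lab in names(result$changes)) {
    w(result$changes[[lab]]$deltas, paste0("richness_deltas_", lab, ".csv"))
    w(result$changes[[lab]]$transitions,
      paste0("richness_transitions_", lab, ".csv"))
  }
  w(species_truth_table(result$species_truth), "species_truth.csv")
  for (g in result$grids) write_climate_grid(g, file.path(dir, "climate"))
  write_zones(result$zones, dir,
              cell_size = result$grids$baseline$cell_size,
              origin = result$grids$baseline$origin)
  manifest <- result$manifest
  manifest$config$rf <- unclass(manifest$config$rf)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Human- and machine-readable run report
#'
#' Assembles the cohort tables (overall metrics, performance classes,
#' first-rank importance frequencies and mean ranks, pattern types) and the
#' per-scenario richness class tallies into a markdown document, and returns
#' the underlying tibbles. Errors if a needed artifact is absent from the
#' result, naming it.
#'
#' @param result a `pipeline_result`.
#' @param path optional file path for the markdown report.
#' @return invisibly, a list of the report tables (`metrics`, `classes`,
#'   `first_rank`, `mean_rank`, `patterns`, `richness_classes`).
#' @export
make_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  for (need in c("species_metrics", "performance_summary",
                 "importance_summary", "richness")) {
    if (is.null(result[[need]])) stop("missing artifact: ", need)
  }
  ps <- result$performance_summary
  is <- result$importance_summary
  richness_classes <- purrr::imap_dfr(result$richness, function(r, lab) {
    r$zone_table |>
      dplyr::count(.data$class_label, name = "n_zones") |>
      dplyr::mutate(scenario = lab, .before = 1)
  })

  fmt <- function(df) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                          \(x) round(x, 3)))
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, paste, collapse = " | "))
  }
  lines <- c(
    "# Stacked-SDM run report",
    "",
    sprintf("%d species retained; seed %d.",
            ps$n_species, result$config$seed),
    "",
    "## Overall model performance", "", fmt(ps$metric_table), "",
    sprintf("Share of species with mean AUC >= 0.8: %.1f%%", ps$share_auc_ge_0.8),
    "",
    "## Performance classes", "", fmt(ps$class_table), "",
    "## First-rank variable importance", "", fmt(is$first_rank), "",
    "## Mean variable ranks", "", fmt(is$mean_rank), "",
    "## Top-three variable patterns", "", fmt(is$patterns), "",
    "## Zone richness classes by scenario", "", fmt(richness_classes), ""
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(list(metrics = ps$metric_table, classes = ps$class_table,
                 first_rank = is$first_rank, mean_rank = is$mean_rank,
                 patterns = is$patterns, richness_classes = richness_classes,
                 text = lines))
}
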