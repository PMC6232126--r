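# Single entry point wiring the stages together, with a JSON run config, a
# manifest of every artifact written, and deterministic per-stage seeds
# derived from one master seed.

#' Build a run configuration
#'
#' @param cases path to a case CSV (see [read_cases()]).
#' @param period_start,period_end study period bounds.
#' @param fields named character vector/list of grid-file paths by variable
#'   (may be empty: climate stage is then skipped).
#' @param out_dir output directory (created if needed).
#' @param window_days,min_cases cluster construction parameters.
#' @param null_reps seasonal-null replicates for the cluster test.
#' @param tau_grid,delta_grid Knox threshold grids.
#' @param knox_reps Knox permutation replicates.
#' @param seasons seasons to composite over.
#' @param confidence composite confidence level.
#' @param traits traits for the forward-window median analysis.
#' @param trait_window_days forward window length.
#' @param spatial_label binary trait for the spatial Monte Carlo (`NULL`
#'   skips it).
#' @param spatial_reps spatial-test replicates.
#' @param seed master seed; every stage derives a substream from it.
#' @return a `run_config` list.
#' @export
run_config <- function(cases, period_start, period_end,
                       fields = list(), out_dir = "kd_run",
                       window_days = 7L, min_cases = 4L, null_reps = 500L,
                       tau_grid = 1:30,
                       delta_grid = c(1, 2, 5, 10, 20, 50, 100),
                       knox_reps = 999L,
                       seasons = c("ALL", "DJFMA", "MJJA"),
                       confidence = 0.95,
                       traits = c("age", "esr", "anc"),
                       trait_window_days = 10L,
                       spatial_label = "ggt_elevated", spatial_reps = 999L,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from JSON
#'
#' The JSON object mirrors the [run_config()] argument names; absent fields
#' take the defaults.
#'
#' @param path JSON file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_kd("unknown config field(s): %s", paste(unknown, collapse = ", "),
            class = "config_error")
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: temporal cluster construction with the seasonal
#' Monte Carlo null; the Knox permutation grid; event-lagged climate
#' composites for every supplied field, group and season (skipped with a
#' warning when no fields are given); forward-window trait regressions; and
#' the spatial label test. Every artifact is written under `out_dir` and
#' listed in the returned manifest (also written as `manifest.json`). Rerun
#' with the same config and inputs reproduces every seeded stage exactly.
#'
#' @param config a [run_config()] or path to a JSON config.
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly: list with `stages` (status per stage),
#'   `outputs` (paths), `seed`, and a parameter echo.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, fmt, ...) if (!quiet)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  outputs <- character()
  stages <- list()
  emit <- function(name, obj) {
    path <- file.path(config$out_dir, name)
    if (is.data.frame(obj)) data.table::fwrite(obj, path)
    else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                              na = "null", pretty = TRUE)
    outputs <<- c(outputs, path)
    path
  }

  period <- study_period(config$period_start, config$period_end)
  cases <- read_cases(config$cases, period)
  say("input", "%d cases read from %s", nrow(cases), config$cases)

  # -- clusters ---------------------------------------------------------------
  params <- cluster_params(config$window_days, config$min_cases)
  clusters <- find_temporal_clusters(cases, params)
  counts <- daily_counts(cases)
  profile <- seasonal_profile_from_counts(counts)
  ens <- seasonal_null_ensemble(nrow(cases), profile$weights, period, params,
                                n_reps = config$null_reps,
                                seed = substream_seed(config$seed, 10L))
  ctest <- cluster_excess_test(clusters, ens)
  emit("clusters.csv", as.data.frame(clusters))
  emit("cluster_test.json",
       ctest[c("observed_n_clusters", "null_mean", "null_sd", "t_statistic",
               "p_t_two_sided", "p_t_upper", "p_empirical", "degenerate",
               "n_reps")])
  stages$clusters <- "complete"
  say("clusters", "%d clusters; empirical p = %.4g", nrow(clusters),
      ctest$p_empirical)

  # -- knox -------------------------------------------------------------------
  kg <- knox_permutation_test(cases,
                              knox_thresholds(config$tau_grid,
                                              config$delta_grid),
                              n_reps = config$knox_reps,
                              seed = substream_seed(config$seed, 20L))
  emit("knox.csv", as.data.frame(kg))
  stages$knox <- "complete"
  say("knox", "min p = %.4g", min(kg$p_value))

  # -- composites -------------------------------------------------------------
  if (length(config$fields) == 0L) {
    warning("no climate fields supplied; composite stage skipped",
            call. = FALSE)
    stages$composites <- "skipped"
  } else {
    for (v in names(config$fields)) {
      field <- read_gridded(config$fields[[v]], v)
      clim <- day_of_year_climatology(field)
      an <- anomalies(field, clim)
      for (season in config$seasons) {
        groups <- resolve_event_groups(cases, clusters, season,
                                       seed = substream_seed(config$seed, 30L))
        for (g in names(groups)) {
          comp <- suppressWarnings(
            composite_anomaly(an, groups[[g]], confidence = config$confidence))
          if (is.null(comp)) next
          flat <- lapply(comp$bins, function(b)
            list(n = b$n, mean = b$mean, t = b$t, mask = b$mask))
          emit(sprintf("composite_%s_%s_%s.json", v, g, season),
               list(variable = v, group = g, season = season,
                    confidence = config$confidence, bins = flat))
        }
      }
    }
    stages$composites <- "complete"
    say("composites", "done for %d field(s)", length(config$fields))
  }

  # -- traits -----------------------------------------------------------------
  for (trait in config$traits) {
    pts <- tryCatch(
      conditional_window_medians(cases, trait, config$trait_window_days),
      kdspacetime_error = function(e) NULL)
    if (is.null(pts) || nrow(pts) < 3L) next
    edges <- if (trait == "age") "unit" else "deciles"
    bins <- bin_medians(pts, edges)
    reg <- list(points = trait_slope_regression(pts, "points"),
                bins = trait_slope_regression(bins, "bins"))
    emit(sprintf("trait_%s_points.csv", trait), as.data.frame(pts))
    emit(sprintf("trait_%s_bins.csv", trait), bins)
    emit(sprintf("trait_%s_regression.json", trait), reg)
  }
  stages$traits <- "complete"

  if (!is.null(config$spatial_label) &&
      config$spatial_label %in% names(cases) &&
      sum(cases[[config$spatial_label]], na.rm = TRUE) >= 2) {
    st <- spatial_label_permutation_test(cases, config$spatial_label,
                                         n_reps = config$spatial_reps,
                                         seed = substream_seed(config$seed, 40L))
    emit("spatial_label_test.json",
         st[c("trait", "statistic_name", "observed", "p_value",
              "n_positive", "n_reps")])
    stages$spatial_label <- "complete"
    say("spatial-label", "p = %.4g", st$p_value)
  } else stages$spatial_label <- "skipped"

  manifest <- list(package = "kdspacetime",
                   version = as.character(utils::packageVersion("kdspacetime")),
                   seed = config$seed,
                   n_cases = nrow(cases),
                   parameters = config[setdiff(names(config), "out_dir")],
                   stages = stages, outputs = outputs)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic case CSV), `clusters`, `knox`,
#' `composites`, `traits`, `spatial-label`, and `run` (the full pipeline
#' from a JSON config). Invoke from
#' `Rscript -e 'kdspacetime::kd_cli()' <subcommand> [options]`.
#'
#' @param args command-line arguments (default `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
kd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE))
    stop("the CLI requires the 'optparse' package", call. = FALSE)
  usage <- "usage: kd_cli <simulate|clusters|knox|composites|traits|spatial-label|run> [options]"
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[[1L]]; rest <- args[-1L]
  o <- function(...) optparse::make_option(...)
  getopts <- function(opts) optparse::parse_args(
    optparse::OptionParser(option_list = opts), args = rest)

  common <- list(
    o("--cases", type = "character", help = "case CSV path"),
    o("--start", type = "character", default = "2002-01-01"),
    o("--end", type = "character", default = "2017-04-15"),
    o("--seed", type = "integer", default = 1L),
    o("--out", type = "character", default = "."))

  switch(cmd,
    simulate = {
      opt <- getopts(c(common, list(
        o("--n-expected", type = "double", default = 1000),
        o("--burst-rate", type = "double", default = 2))))
      cfg <- case_sim_config(period = study_period(opt$start, opt$end),
                             n_expected = opt$`n-expected`,
                             burst_rate = opt$`burst-rate`, seed = opt$seed)
      path <- file.path(opt$out, "simulated_cases.csv")
      write_cases(simulate_cases(cfg), path)
      message("wrote ", path)
    },
    clusters = {
      opt <- getopts(c(common, list(
        o("--window", type = "integer", default = 7L),
        o("--min-cases", type = "integer", default = 4L),
        o("--null-reps", type = "integer", default = 500L))))
      period <- study_period(opt$start, opt$end)
      cases <- read_cases(opt$cases, period)
      params <- cluster_params(opt$window, opt$`min-cases`)
      cl <- find_temporal_clusters(cases, params)
      prof <- seasonal_profile_from_counts(daily_counts(cases))
      ens <- seasonal_null_ensemble(nrow(cases), prof$weights, period, params,
                                    n_reps = opt$`null-reps`, seed = opt$seed)
      ct <- cluster_excess_test(cl, ens)
      data.table::fwrite(as.data.frame(cl), file.path(opt$out, "clusters.csv"))
      jsonlite::write_json(
        ct[c("observed_n_clusters", "null_mean", "null_sd", "t_statistic",
             "p_t_two_sided", "p_t_upper", "p_empirical", "n_reps")],
        file.path(opt$out, "cluster_test.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
      print(ct)
    },
    knox = {
      opt <- getopts(c(common, list(
        o("--reps", type = "integer", default = 999L))))
      cases <- read_cases(opt$cases, study_period(opt$start, opt$end))
      kg <- knox_permutation_test(cases, n_reps = opt$reps, seed = opt$seed)
      data.table::fwrite(as.data.frame(kg), file.path(opt$out, "knox.csv"))
      print(kg)
    },
    composites = {
      opt <- getopts(c(common, list(
        o("--field", type = "character", help = "grid file path"),
        o("--variable", type = "character", default = "tmax"),
        o("--season", type = "character", default = "ALL"),
        o("--confidence", type = "double", default = 0.95))))
      cases <- read_cases(opt$cases, study_period(opt$start, opt$end))
      clusters <- find_temporal_clusters(cases)
      field <- read_gridded(opt$field, opt$variable)
      an <- anomalies(field, day_of_year_climatology(field))
      groups <- resolve_event_groups(cases, clusters, opt$season,
                                     seed = opt$seed)
      for (g in names(groups)) {
        comp <- suppressWarnings(
          composite_anomaly(an, groups[[g]], confidence = opt$confidence))
        if (is.null(comp)) next
        jsonlite::write_json(
          list(variable = opt$variable, group = g, season = opt$season,
               confidence = opt$confidence,
               bins = lapply(comp$bins, function(b)
                 list(n = b$n, mean = b$mean, t = b$t, mask = b$mask))),
          file.path(opt$out, sprintf("composite_%s_%s_%s.json",
                                     opt$variable, g, opt$season)),
          auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
      }
      message("composites written to ", opt$out)
    },
    traits = {
      opt <- getopts(c(common, list(
        o("--trait", type = "character", default = "age"),
        o("--window", type = "integer", default = 10L))))
      cases <- read_cases(opt$cases, study_period(opt$start, opt$end))
      pts <- conditional_window_medians(cases, opt$trait, opt$window)
      bins <- bin_medians(pts, if (opt$trait == "age") "unit" else "deciles")
      reg <- list(points = trait_slope_regression(pts, "points"),
                  bins = trait_slope_regression(bins, "bins"))
      data.table::fwrite(as.data.frame(pts),
                         file.path(opt$out, paste0("trait_", opt$trait,
                                                   "_points.csv")))
      jsonlite::write_json(reg, file.path(opt$out,
                                          paste0("trait_", opt$trait,
                                                 "_regression.json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      message(sprintf("%s: slope %.3f (points, p = %.3g)", opt$trait,
                      reg$points$slope, reg$points$p_slope))
    },
    `spatial-label` = {
      opt <- getopts(c(common, list(
        o("--label", type = "character", default = "ggt_elevated"),
        o("--reps", type = "integer", default = 999L))))
      cases <- read_cases(opt$cases, study_period(opt$start, opt$end))
      st <- spatial_label_permutation_test(cases, opt$label, opt$reps,
                                           opt$seed)
      print(st)
    },
    run = {
      opt <- getopts(list(o("--config", type = "character",
                            help = "JSON run config")))
      run_pipeline(opt$config)
    },
    { message(usage); return(invisible(1L)) })
  invisible(0L)
}
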