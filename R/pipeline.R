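write_manifest <- function(dir, stage, config = NULL, seed = NULL,
                           inputs = character(), outputs = character(),
                           counts = list()) {
  man <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("spcdopa")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = as.list(inputs),
    outputs = as.list(outputs),
    row_counts = counts
  )
  if (!is.null(config)) {
    cfgl <- unclass(config)
    cfgl$site_scale <- lapply(cfgl$site_scale, as.list)
    man$config <- cfgl
  }
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline stage: simulate
#'
#' Simulates a cohort and writes the dataset files (`events.csv`,
#' `port_entries.csv`, `photometry.csv`, `latents.csv`, `impulses.csv`,
#' `config.yaml`) plus a run manifest into `out_dir`.
#'
#' @param out_dir Output directory.
#' @param config An [sim_config()].
#' @param variant,sites,photometry_phases Passed to [simulate_cohort()].
#' @return The simulated `spc_dataset`, invisibly.
#' @export
run_simulate <- function(out_dir, config = sim_config(), variant = "main",
                         sites = names(config$site_scale),
                         photometry_phases = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- simulate_cohort(config, variant = variant, sites = sites,
                        photometry_phases = photometry_phases)
  write_events(ds$events, ds$port, out_dir)
  write_photometry(ds$photometry, file.path(out_dir, "photometry.csv"))
  data.table::fwrite(ds$latents, file.path(out_dir, "latents.csv"))
  data.table::fwrite(ds$impulses, file.path(out_dir, "impulses.csv"))
  save_config(config, file.path(out_dir, "config.yaml"))
  write_manifest(out_dir, "simulate", config = config, seed = config$seed,
                 outputs = c("events.csv", "port_entries.csv", "photometry.csv",
                             "latents.csv", "impulses.csv", "config.yaml"),
                 counts = list(events = nrow(ds$events),
                               photometry = nrow(ds$photometry),
                               port = nrow(ds$port)))
  invisible(ds)
}

#' Pipeline stage: preprocess
#'
#' Reads a simulated (or similarly formatted) dataset directory, runs the
#' preprocessing chain, and writes `normalized.csv` and
#' `fit_coefficients.csv`.
#'
#' @param in_dir Directory produced by [run_simulate()] (or containing the
#'   same file layout).
#' @param out_dir Output directory.
#' @return The `spc_normalized` object, invisibly.
#' @export
run_preprocess <- function(in_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  phot <- read_photometry(file.path(in_dir, "photometry.csv"))
  cfgp <- file.path(in_dir, "config.yaml")
  baseline_len <- if (file.exists(cfgp)) load_config(cfgp)$baseline_len else 10
  norm <- preprocess_photometry(phot, baseline_len = baseline_len)
  data.table::fwrite(norm$trials, file.path(out_dir, "normalized.csv"))
  data.table::fwrite(norm$fits, file.path(out_dir, "fit_coefficients.csv"))
  write_manifest(out_dir, "preprocess",
                 inputs = file.path(in_dir, "photometry.csv"),
                 outputs = c("normalized.csv", "fit_coefficients.csv"),
                 counts = list(samples = nrow(norm$trials),
                               fits = nrow(norm$fits)))
  invisible(norm)
}

#' Pipeline stage: quantify
#'
#' Reads normalized traces plus the event/port logs and writes the per-trial
#' response rows (`response_rows.csv`) and the preconditioning bin summary
#' (`bins.csv`).
#'
#' @param sim_dir Directory with `events.csv` / `port_entries.csv`.
#' @param norm_dir Directory with `normalized.csv`.
#' @param out_dir Output directory.
#' @return The response-row tibble, invisibly.
#' @export
run_quantify <- function(sim_dir, norm_dir, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  evp <- read_events(sim_dir)
  norm <- tibble::as_tibble(data.table::fread(file.path(norm_dir, "normalized.csv")))
  rows <- quantify_responses(norm, evp$events, evp$port)
  data.table::fwrite(rows, file.path(out_dir, "response_rows.csv"))
  bins <- tryCatch(phase_bins(rows), error = function(e) NULL)
  if (!is.null(bins)) data.table::fwrite(bins, file.path(out_dir, "bins.csv"))
  write_manifest(out_dir, "quantify",
                 inputs = c(file.path(sim_dir, "events.csv"),
                            file.path(norm_dir, "normalized.csv")),
                 outputs = c("response_rows.csv", "bins.csv"),
                 counts = list(rows = nrow(rows)))
  invisible(rows)
}

#' Pipeline stage: analyze
#'
#' Reads the response rows, builds subject summaries, applies the inclusion
#' rule, runs the group statistics and writes `subject_summaries.csv`,
#' `test_results.csv` and a short plain-text report (which also logs excluded
#' subjects and why).
#'
#' @param rows_dir Directory with `response_rows.csv`.
#' @param out_dir Output directory.
#' @param site Recording site for the dopamine contrasts.
#' @return The `spc_analysis` object, invisibly.
#' @export
run_analyze <- function(rows_dir, out_dir, site = "NAcc") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- tibble::as_tibble(data.table::fread(file.path(rows_dir,
                                                        "response_rows.csv")))
  res <- analyze_cohort(rows, site = site)
  data.table::fwrite(res$summaries, file.path(out_dir, "subject_summaries.csv"))
  data.table::fwrite(res$tests, file.path(out_dir, "test_results.csv"))
  rep_path <- file.path(out_dir, "report.txt")
  con <- file(rep_path, "w")
  writeLines(c(
    sprintf("subjects analyzed: %d; excluded by B >= 2D reminder rule: %s",
            nrow(res$included),
            if (length(res$excluded) == 0) "none"
            else paste(res$excluded, collapse = ", ")),
    sprintf("%-32s p = %.4g (n = %d)", res$tests$test, res$tests$p_value,
            res$tests$n)), con)
  close(con)
  write_manifest(out_dir, "analyze",
                 inputs = file.path(rows_dir, "response_rows.csv"),
                 outputs = c("subject_summaries.csv", "test_results.csv",
                             "report.txt"),
                 counts = list(subjects = nrow(res$summaries),
                               tests = nrow(res$tests)))
  invisible(res)
}

#' Run the full pipeline
#'
#' simulate -> preprocess -> quantify -> analyze, writing each stage into a
#' subdirectory of `out_dir`. Deterministic: the same configuration (and thus
#' seed) produces byte-identical CSV outputs.
#'
#' @inheritParams run_simulate
#' @param site Site passed to the analysis stage.
#' @return The final `spc_analysis`, invisibly.
#' @export
run_all <- function(out_dir, config = sim_config(), variant = "main",
                    sites = names(config$site_scale),
                    photometry_phases = NULL, site = sites[1]) {
  sim_d <- file.path(out_dir, "sim")
  pre_d <- file.path(out_dir, "preprocess")
  qua_d <- file.path(out_dir, "quantify")
  ana_d <- file.path(out_dir, "analyze")
  run_simulate(sim_d, config, variant, sites, photometry_phases)
  run_preprocess(sim_d, pre_d)
  run_quantify(sim_d, pre_d, qua_d)
  invisible(run_analyze(qua_d, ana_d, site = site))
}
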