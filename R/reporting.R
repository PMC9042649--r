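# Report writers: CSV/JSON mirrors of the per-patient, incremental and
# national result tables, the scenario table, and the PSA outputs, plus a
# run manifest. All numeric output is written at full precision ("." decimal,
# no thousands separators); rounding is presentation-only.

arm_row_fields <- c("expected_icu_days", "expected_ward_days",
                    "in_hospital_mortality", "readmission_proportion",
                    "sepsis_survivor_1yr", "cost_prediction", "cost_icu",
                    "cost_ward", "cost_readmission", "cost_longterm",
                    "cost_total", "qalys")

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  save_config(config, f)
  unname(tools::md5sum(f))
}

write_manifest <- function(out_dir, config, seed, files) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("septicost")),
    config_hash = config_hash(config),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    back_calculated_constants = list(
      icu_day = config$costs$icu_day,
      ward_day = config$costs$ward_day,
      longterm_cost_per_survivor = config$costs$longterm_cost_per_survivor),
    outputs = basename(files))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Write the base-case result tables
#'
#' Runs both arms and the incremental comparison and writes a CSV mirroring
#' the published base-case table (rows = outcomes and cost components;
#' columns = algorithm, comparator, incremental, national) plus a JSON
#' summary and a run manifest. Fails without writing partial output if the
#' configuration is invalid.
#'
#' @param config a `septicost_config`
#' @param out_dir output directory (created if needed)
#' @return invisibly, the list of files written
#' @export
write_base_case_report <- function(config, out_dir) {
  viol <- validate_config(config)
  if (length(viol) > 0) {
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inc <- incremental(config)
  tab <- data.frame(
    outcome = arm_row_fields,
    algorithm = vapply(arm_row_fields, function(f) inc$algorithm[[f]], numeric(1)),
    comparator = vapply(arm_row_fields, function(f) inc$comparator[[f]], numeric(1)),
    incremental = inc$per_patient[arm_row_fields],
    national = inc$national[arm_row_fields],
    row.names = NULL)
  csv <- file.path(out_dir, "base_case.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  summary <- list(
    per_patient = as.list(inc$per_patient),
    national = as.list(inc$national),
    lives_saved_national = inc$lives_saved_national,
    icu_days_saved_national = inc$icu_days_saved_national,
    ward_days_saved_national = inc$ward_days_saved_national,
    icer = inc$icer)
  js <- file.path(out_dir, "base_case.json")
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(csv, js)
  write_manifest(out_dir, config, seed = NA, files)
  invisible(files)
}

#' Write the deterministic scenario table
#'
#' @param config base-case configuration
#' @param out_dir output directory
#' @param specs scenario list (default [scenario_presets()])
#' @return invisibly, the list of files written
#' @export
write_scenario_report <- function(config, out_dir, specs = scenario_presets()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- run_scenario_table(config, specs)
  csv <- file.path(out_dir, "scenario_table.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  write_manifest(out_dir, config, seed = NA, csv)
  invisible(csv)
}

#' Write PSA draws and summary
#'
#' Writes one CSV row per draw (incremental cost, incremental QALYs,
#' dominance classification) and a JSON summary with the box-plot
#' statistics, the dominant fraction, and the fraction of simulations below
#' each willingness-to-pay threshold.
#'
#' @param config the configuration the PSA was run on
#' @param result a `septicost_psa`
#' @param out_dir output directory
#' @return invisibly, the list of files written
#' @export
write_psa_report <- function(config, result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "psa_draws.csv")
  utils::write.csv(result$draws, csv, row.names = FALSE)
  summary <- list(
    n_draws = result$n_draws,
    seed = result$seed,
    condition_on = result$condition_on,
    delta_cost_summary = as.list(result$summary),
    fraction_dominant = result$fraction_dominant,
    fraction_below_threshold = as.list(result$fraction_below_threshold),
    n_clamped = result$n_clamped)
  js <- file.path(out_dir, "psa_summary.json")
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(csv, js)
  write_manifest(out_dir, config, seed = result$seed, files)
  invisible(files)
}
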