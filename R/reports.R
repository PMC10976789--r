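pkg_version <- function() {
  as.character(utils::packageVersion("vabpcea"))
}

#' Run manifest
#'
#' Provenance record written next to every report bundle: configuration path
#' and MD5 hash, seed, package version, timestamp, the invoking command label
#' and every output file produced. A run is reproducible from its manifest
#' alone (same config, same seed, same command).
#'
#' @param command short command label (e.g. `"base_case"`).
#' @param config_path configuration file the run used (or `NA` for the
#'   built-in inputs).
#' @param seed integer seed used (or `NA`).
#' @param outputs character vector of output file paths.
#' @return named list (the manifest).
#' @export
run_manifest <- function(command, config_path = NA, seed = NA,
                         outputs = character()) {
  list(
    command = command,
    config = if (is.na(config_path)) "builtin" else config_path,
    config_md5 = if (is.na(config_path)) NA_character_
                 else unname(tools::md5sum(config_path)),
    seed = seed,
    package = "vabpcea",
    version = pkg_version(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs)
  )
}

write_manifest <- function(manifest, dir) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Write the base-case report bundle
#'
#' Summary table (per-arm totals, increments, ICER, INMB), the component
#' cost breakdown, and a manifest, as CSV plus JSON.
#'
#' @param params a `cea_parameters` object.
#' @param dir output directory (created if missing).
#' @param config_path configuration path recorded in the manifest.
#' @return the `cea_result`, invisibly; files land in `dir`.
#' @export
report_base_case <- function(params, dir, config_path = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- evaluate_ce(params)
  rec <- as_record(res)
  summary_csv <- file.path(dir, "base_case_summary.csv")
  utils::write.csv(
    data.frame(quantity = names(rec),
               value = vapply(rec, as.character, character(1))),
    summary_csv, row.names = FALSE)
  summary_json <- file.path(dir, "base_case_summary.json")
  jsonlite::write_json(rec, summary_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  breakdown_csv <- file.path(dir, "cost_breakdown.csv")
  cost_breakdown_table(params, breakdown_csv)
  outs <- c(summary_csv, summary_json, breakdown_csv)
  write_manifest(run_manifest("base_case", config_path, outputs = outs), dir)
  invisible(res)
}

#' Write the one-way sensitivity report bundle
#'
#' Tornado table as CSV (optionally a PNG tornado plot) plus manifest.
#'
#' @param params a `cea_parameters` object.
#' @param dir output directory.
#' @param plot also write `tornado.png`.
#' @param config_path configuration path recorded in the manifest.
#' @return the `cea_owsa`, invisibly.
#' @export
report_owsa <- function(params, dir, plot = FALSE, config_path = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tor <- run_owsa(params)
  csv <- file.path(dir, "tornado.csv")
  utils::write.csv(as.data.frame(tor), csv, row.names = FALSE)
  outs <- csv
  if (plot) {
    png_path <- file.path(dir, "tornado.png")
    grDevices::png(png_path, width = 900, height = 600)
    plot(tor); grDevices::dev.off()
    outs <- c(outs, png_path)
  }
  write_manifest(run_manifest("owsa", config_path, outputs = outs), dir)
  invisible(tor)
}

#' Write the probabilistic sensitivity report bundle
#'
#' CE-plane scatter and acceptability-curve CSVs (optionally PNG plots),
#' plus manifest.
#'
#' @param params a `cea_parameters` object.
#' @param dir output directory.
#' @param n_iter,seed Monte-Carlo size and seed.
#' @param plot also write PNG plots.
#' @param config_path configuration path recorded in the manifest.
#' @return the `cea_psa`, invisibly.
#' @export
report_psa <- function(params, dir, n_iter = 1000, seed = 1, plot = FALSE,
                       config_path = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  psa <- run_psa(params, n_iter = n_iter, seed = seed)
  plane <- file.path(dir, "ce_plane.csv")
  ceac <- file.path(dir, "ceac.csv")
  write_ce_plane(psa, plane); write_ceac(psa, ceac)
  opt <- file.path(dir, "probability_optimal.csv")
  utils::write.csv(data.frame(strategy = names(psa$p_optimal),
                              probability = unname(psa$p_optimal)),
                   opt, row.names = FALSE)
  outs <- c(plane, ceac, opt)
  if (plot) {
    for (ty in c("plane", "ceac")) {
      png_path <- file.path(dir, paste0("psa_", ty, ".png"))
      grDevices::png(png_path, width = 800, height = 600)
      plot(psa, type = ty); grDevices::dev.off()
      outs <- c(outs, png_path)
    }
  }
  write_manifest(run_manifest("psa", config_path, seed = seed,
                              outputs = outs), dir)
  invisible(psa)
}

#' Write synthetic model inputs
#'
#' Generates the synthetic life table and a simulated two-arm trial, writes
#' them as CSVs, and writes a ready-to-load configuration built from the
#' simulated estimates.
#'
#' @param dir output directory.
#' @param seed integer seed for the trial draw.
#' @param n_per_arm patients per simulated arm.
#' @return the generated `cea_parameters`, invisibly.
#' @export
report_simulate <- function(dir, seed = 1, n_per_arm = 360) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- reference_inputs()
  trial <- simulate_trial(
    true_cure = c(pt_est(base$arms$ctz_taz$efficacy$cure_first),
                  pt_est(base$arms$mepm$efficacy$cure_first)),
    true_mort = c(pt_est(base$arms$ctz_taz$efficacy$mort_first),
                  pt_est(base$arms$mepm$efficacy$mort_first)),
    n_per_arm = n_per_arm, seed = seed)
  lt_csv <- file.path(dir, "life_table.csv")
  write_life_table(base$life_table, lt_csv)
  trial_csv <- file.path(dir, "trial_summary.csv")
  write_trial_summary(trial, trial_csv)
  params <- parameters_from_trial(trial, base)
  cfg <- file.path(dir, "config.yaml")
  save_parameters(params, cfg)
  write_manifest(run_manifest("simulate", NA, seed = seed,
                              outputs = c(lt_csv, trial_csv, cfg)), dir)
  invisible(params)
}
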