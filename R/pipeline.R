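#' Run the full analysis pipeline
#'
#' Orchestrates every stage end to end: obtain plate data (simulate from the
#' config's `simulation` section, or read the CSV named by `config$input`),
#' correct and integrate the traces, subtract solvent controls, normalize to
#' the reference agonist, fit every condition (combined and per experiment),
#' summarize bias factors with significance, build the bias-plot series, and
#' assemble the report table. All outputs are returned and, when
#' `output_dir` is given, written as CSVs alongside a structured run log
#' that accounts for every input row and records every "n.d." decision.
#' Identical config and seed give byte-identical output files.
#'
#' @param config Configuration list (see [default_config()]) or the path of
#'   a YAML config file.
#' @param output_dir Directory for output files (created if needed), or
#'   `NULL` to skip writing.
#' @param seed Optional override of `config$seed`.
#' @return List with elements `responses` (normalized per-well responses),
#'   `fits`, `bias`, `plot_series`, `report`, and `log` (character vector).
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL,
                         seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  if (!is.null(config$input)) {
    plates <- read_plate_csv(config$input,
                             injection_time_s = config$injection_time_s)
    note("input: read %d rows from %s", nrow(plates), config$input)
  } else {
    spec <- spec_from_config(config)
    plates <- simulate_study(spec)
    note("input: simulated %d experiments (%d rows) with seed %d",
         spec$n_experiments, nrow(plates), spec$seed)
  }
  n_in <- nrow(plates)

  responses <- withCallingHandlers(
    process_plates(plates,
                   reference = config$reference,
                   injection_time = config$injection_time_s,
                   window_duration = config$auc_window_s),
    warning = function(w) {
      note("warning: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  n_wells <- length(unique(paste(plates$experiment_id, plates$well_id)))
  n_controls <- plates |>
    dplyr::filter(.data$is_solvent_control) |>
    dplyr::distinct(.data$experiment_id, .data$well_id) |>
    nrow()
  note("rows in: %d; wells: %d; control wells consumed: %d; response wells out: %d; wells dropped: %d",
       n_in, n_wells, n_controls, nrow(responses),
       n_wells - n_controls - nrow(responses))

  fits <- fit_study(responses)
  for (i in which(fits$status == "nd")) {
    note("nd fit: %s / %s / %s / %s (%s)", fits$compound[i], fits$pathway[i],
         fits$receptor_variant[i], fits$experiment_id[i],
         fits$nd_reason[i] %||% "unspecified")
  }

  bias <- summarize_bias(fits, reference = config$reference)
  for (i in which(bias$status == "nd")) {
    note("nd beta: %s / %s (%s)", bias$compound[i], bias$receptor_variant[i],
         bias$reason[i])
  }
  bias <- tryCatch(
    test_bias_significance(bias, reference = config$reference),
    error = function(e) {
      note("significance testing skipped: %s", conditionMessage(e))
      bias
    }
  )

  plot_compounds <- setdiff(unique(responses$compound), SOLVENT_LABEL)
  plot_series <- lapply(plot_compounds, function(cp) {
    tryCatch(bias_plot_series(responses, cp), error = function(e) {
      note("bias plot skipped for %s: %s", cp, conditionMessage(e))
      NULL
    })
  })
  plot_series <- Filter(Negate(is.null), plot_series)

  report <- report_table(fits, bias)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(report, file.path(output_dir, "report_table.csv"))
    fits_flat <- dplyr::select(fits, -"fit")
    readr::write_csv(fits_flat, file.path(output_dir, "fits.csv"))
    bias_flat <- bias |>
      dplyr::mutate(beta_per_experiment = vapply(
        .data$beta_per_experiment,
        function(b) paste(sprintf("%.10g", b), collapse = ";"),
        character(1)))
    readr::write_csv(bias_flat, file.path(output_dir, "bias_summary.csv"))
    readr::write_csv(bias_plot_table(plot_series),
                     file.path(output_dir, "bias_plot_series.csv"))
    writeLines(log, file.path(output_dir, "run_log.txt"))
    note("outputs written to %s", output_dir)
  }

  list(responses = responses, fits = fits, bias = bias,
       plot_series = plot_series, report = report, log = log)
}
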