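# Plate CSV format and YAML configuration.

#' Write a plate table to CSV
#'
#' Serializes a long-format plate table (one row per well per read) to CSV.
#' The format is the package's interchange schema; vendor plate-reader
#' exports must be converted to it first (see [convert_reader_export()]).
#'
#' @param plate Long plate tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  assert_columns(plate, PLATE_COLUMNS, "plate")
  readr::write_csv(plate[, PLATE_COLUMNS], path)
  invisible(path)
}

#' Read a plate CSV
#'
#' Parses and validates the long-format plate schema. Malformed rows --
#' missing values, negative concentrations or times, inconsistent
#' solvent-control flags, duplicate (well, time) readings -- are reported
#' with their line numbers.
#'
#' @param path CSV path.
#' @param injection_time_s Injection time in seconds to attach to the table
#'   (the schema itself stores only read times).
#' @return Long plate tibble at stage `"raw"`.
#' @export
read_plate_csv <- function(path, injection_time_s = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           experiment_id = readr::col_character(),
                           well_id = readr::col_character(),
                           compound = readr::col_character(),
                           pathway = readr::col_character(),
                           receptor_variant = readr::col_character(),
                           is_solvent_control = readr::col_logical(),
                           replicate = readr::col_integer(),
                           .default = readr::col_double()
                         ))
  assert_columns(raw, PLATE_COLUMNS, basename(path))
  # line numbers: header is line 1
  line_of <- function(idx) idx + 1L
  fail <- function(idx, what) {
    stop(sprintf("%s: %s at line(s) %s", basename(path), what,
                 paste(line_of(utils::head(idx, 5)), collapse = ", ")),
         call. = FALSE)
  }
  na_rows <- which(!stats::complete.cases(raw[, PLATE_COLUMNS]))
  if (length(na_rows) > 0) fail(na_rows, "missing or non-numeric value")
  neg_conc <- which(raw$concentration_molar < 0)
  if (length(neg_conc) > 0) fail(neg_conc, "negative concentration")
  neg_time <- which(raw$time_s < 0)
  if (length(neg_time) > 0) fail(neg_time, "negative time")
  bad_flag <- which(raw$is_solvent_control != (raw$concentration_molar == 0))
  if (length(bad_flag) > 0) {
    fail(bad_flag, "is_solvent_control inconsistent with concentration 0")
  }
  bad_pw <- which(!raw$pathway %in% PATHWAYS)
  if (length(bad_pw) > 0) fail(bad_pw, "unknown pathway")
  bad_var <- which(!raw$receptor_variant %in% VARIANTS)
  if (length(bad_var) > 0) fail(bad_var, "unknown receptor variant")
  dup <- which(duplicated(raw[, c("experiment_id", "well_id", "time_s")]))
  if (length(dup) > 0) fail(dup, "duplicate (well, time) reading")
  out <- raw
  if (!is.null(injection_time_s)) {
    attr(out, "injection_time_s") <- injection_time_s
  }
  set_stage(out, "raw")
}

#' Stub converter for vendor plate-reader exports
#'
#' Direct ingestion of instrument export files is out of scope; this stub
#' documents the target schema. Export your reader data to a long CSV with
#' columns `experiment_id`, `well_id`, `compound`, `concentration_molar`,
#' `pathway` (`barr2`/`miniGq`), `receptor_variant` (`WT`/`S159A`),
#' `replicate`, `is_solvent_control`, `time_s`, `luminescence`, then load it
#' with [read_plate_csv()].
#'
#' @param path Unused.
#' @export
convert_reader_export <- function(path) {
  stop(paste(
    "direct instrument-export ingestion is not implemented;",
    "convert to the long plate CSV schema (see ?convert_reader_export)",
    "and use read_plate_csv()"), call. = FALSE)
}

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], with a small
#' simulated study as the input. Fields: `reference` (reference agonist),
#' `injection_time_s`, `auc_window_s`, `input` (plate CSV path, or `NULL` to
#' simulate), `seed`, and `simulation` (arguments of [simulation_spec()],
#' with each compound as a list of `name`/`ec50`/`emax`/`hill`).
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(
    reference = "LSD",
    injection_time_s = 600,
    auc_window_s = 7200,
    input = NULL,
    seed = 1L,
    simulation = list(
      n_experiments = 3,
      n_replicate_wells = 2,
      read_interval = 60,
      equilibration_duration = 600,
      post_injection_duration = 7200,
      noise = list(sigma_well = 0.1, sigma_read = 100,
                   sigma_experiment = 0.15),
      kinetic = list(baseline = 1e4, rise_rate = 1 / 300, decay_rate = 1e-4),
      receptor_variant = "WT",
      compounds = list(
        list(name = "LSD",
             ec50 = list(barr2 = 1.29e-8, miniGq = 1.32e-8),
             emax = list(barr2 = 99.7, miniGq = 100)),
        list(name = "cmpdA",
             ec50 = list(barr2 = 1.11e-8, miniGq = 4.88e-8),
             emax = list(barr2 = 112, miniGq = 28))
      )
    )
  )
}

#' Read / write pipeline configuration
#'
#' YAML serialization of the configuration list; `read_config()` fills
#' unspecified fields with the defaults of [default_config()].
#'
#' @param path YAML file path.
#' @param config Configuration list.
#' @return `read_config()`: the configuration list; `write_config()`:
#'   `path`, invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

# Build a simulation_spec from the config's `simulation` section.
spec_from_config <- function(config) {
  sim <- config$simulation
  compounds <- lapply(sim$compounds, function(cc) {
    compound_spec(cc$name,
                  ec50 = unlist(cc$ec50),
                  emax = unlist(cc$emax),
                  hill = cc$hill %||% 1)
  })
  simulation_spec(
    compounds = compounds,
    reference = config$reference,
    concentrations = sim$concentrations %||% default_concentrations(),
    n_experiments = sim$n_experiments,
    n_replicate_wells = sim$n_replicate_wells,
    read_interval = sim$read_interval,
    equilibration_duration = sim$equilibration_duration,
    post_injection_duration = sim$post_injection_duration,
    noise = sim$noise,
    kinetic = sim$kinetic,
    receptor_variant = sim$receptor_variant %||% "WT",
    seed = config$seed %||% 1L
  )
}
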