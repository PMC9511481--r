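#' Trapezoidal area under a trace
#'
#' Integrates a time-value trace over a window by the trapezoid rule on the
#' observed time points, with linear interpolation at the window edges when
#' they fall between reads. Exact for piecewise-linear signals.
#'
#' @param times Strictly increasing time points (seconds).
#' @param values Trace values at `times`.
#' @param from,to Integration window in seconds; must lie within the trace
#'   span. Defaults to the full trace.
#' @return The integral in value-seconds.
#' @export
auc_trapezoid <- function(times, values, from = min(times), to = max(times)) {
  stopifnot(length(times) == length(values), length(times) >= 2)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (from < min(times) || to > max(times) || from >= to) {
    stop(sprintf(
      "integration window [%g, %g] outside trace span [%g, %g]",
      from, to, min(times), max(times)), call. = FALSE)
  }
  inside <- times > from & times < to
  t_sub <- c(from, times[inside], to)
  v_sub <- c(approx(times, values, xout = from)$y, values[inside],
             approx(times, values, xout = to)$y)
  sum(diff(t_sub) * (head(v_sub, -1) + tail(v_sub, -1)) / 2)
}

#' Correct traces for interwell variability
#'
#' Divides every reading of a well by that well's mean pre-injection
#' (equilibration-phase) signal, so each corrected trace has pre-injection
#' mean exactly 1. This removes multiplicative well-to-well differences in
#' cell number, substrate loading and optics before areas are compared.
#' Wells whose pre-injection mean is not positive cannot be scaled; they are
#' dropped with a warning naming the wells.
#'
#' @param plate Long-format plate tibble (see [simulate_experiment()] /
#'   [read_plate_csv()]).
#' @param injection_time Injection time in seconds; defaults to the table's
#'   `injection_time_s` attribute.
#' @param window Length in seconds of the pre-injection window used for the
#'   mean, ending at `injection_time`. Default: the full equilibration phase.
#' @return The plate tibble with corrected `luminescence`, at stage
#'   `"corrected"`.
#' @export
correct_interwell <- function(plate,
                              injection_time = attr(plate, "injection_time_s"),
                              window = NULL) {
  require_stage(plate, "raw", "correct_interwell")
  assert_columns(plate, PLATE_COLUMNS, "plate")
  if (is.null(injection_time)) {
    stop("injection_time is required (column attribute missing)", call. = FALSE)
  }
  w_start <- if (is.null(window)) -Inf else injection_time - window
  corrected <- plate |>
    dplyr::group_by(.data$experiment_id, .data$well_id) |>
    dplyr::mutate(
      .pre_mean = mean(.data$luminescence[.data$time_s < injection_time &
                                            .data$time_s >= w_start]),
      luminescence = .data$luminescence / .data$.pre_mean
    ) |>
    dplyr::ungroup()
  if (anyNA(corrected$.pre_mean)) {
    stop("some wells have no readings in the pre-injection window",
         call. = FALSE)
  }
  bad <- corrected$.pre_mean <= 0
  if (any(bad)) {
    bad_wells <- unique(corrected$well_id[bad])
    warning(sprintf(
      "dropping %d degenerate well(s) with non-positive pre-injection mean: %s",
      length(bad_wells), paste(bad_wells, collapse = ", ")), call. = FALSE)
    corrected <- corrected[!corrected$well_id %in% bad_wells, ]
  }
  corrected$.pre_mean <- NULL
  attr(corrected, "injection_time_s") <- injection_time
  set_stage(corrected, "corrected")
}

#' Compute per-well areas under the curve
#'
#' Integrates each corrected trace over the post-injection response window
#' (default: injection to injection + 2 h) by the trapezoid rule, producing
#' one AUC row per well.
#'
#' @param plate Corrected plate tibble from [correct_interwell()].
#' @param injection_time Injection time in seconds; defaults to the table's
#'   attribute.
#' @param window_duration Length of the integration window in seconds
#'   (default 7200).
#' @return A tibble with one row per well: the annotation columns plus
#'   `auc_raw`, at stage `"auc"`.
#' @export
compute_auc <- function(plate,
                        injection_time = attr(plate, "injection_time_s"),
                        window_duration = 7200) {
  require_stage(plate, "corrected", "compute_auc")
  assert_columns(plate, PLATE_COLUMNS, "plate")
  if (is.null(injection_time)) {
    stop("injection_time is required (column attribute missing)", call. = FALSE)
  }
  out <- plate |>
    dplyr::group_by(.data$experiment_id, .data$well_id, .data$compound,
                    .data$concentration_molar, .data$pathway,
                    .data$receptor_variant, .data$replicate,
                    .data$is_solvent_control) |>
    dplyr::summarise(
      auc_raw = auc_trapezoid(.data$time_s, .data$luminescence,
                              from = injection_time,
                              to = min(injection_time + window_duration,
                                       max(.data$time_s))),
      .groups = "drop"
    )
  set_stage(out, "auc")
}

#' Subtract matched solvent-control areas
#'
#' For every non-control well, subtracts the mean AUC of the matching
#' solvent-control wells (same experiment, pathway and receptor variant by
#' default). Control wells are consumed: they do not appear in the output.
#' Negative corrected areas are retained, not clipped.
#'
#' @param responses AUC tibble from [compute_auc()].
#' @param by Annotation columns defining the control match (default
#'   experiment, pathway and receptor variant).
#' @return The tibble of non-control wells with an added `auc_corrected`
#'   column, at stage `"solvent_subtracted"`.
#' @export
subtract_solvent <- function(responses,
                             by = c("experiment_id", "pathway",
                                    "receptor_variant")) {
  require_stage(responses, "auc", "subtract_solvent")
  assert_columns(responses, c(by, "is_solvent_control", "auc_raw"),
                 "responses")
  controls <- responses |>
    dplyr::filter(.data$is_solvent_control) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(.control_auc = mean(.data$auc_raw), .groups = "drop")
  wells <- dplyr::filter(responses, !.data$is_solvent_control)
  out <- dplyr::left_join(wells, controls, by = by)
  if (anyNA(out$.control_auc)) {
    miss <- out |>
      dplyr::filter(is.na(.data$.control_auc)) |>
      dplyr::distinct(dplyr::across(dplyr::all_of(by)))
    stop("no matching solvent control for condition(s): ",
         paste(apply(miss, 1, paste, collapse = "/"), collapse = "; "),
         call. = FALSE)
  }
  out$auc_corrected <- out$auc_raw - out$.control_auc
  out$.control_auc <- NULL
  set_stage(out, "solvent_subtracted")
}

#' Normalize responses to the reference agonist
#'
#' Sets the maximal response of the reference agonist to 100% within each
#' experiment (separately per pathway and receptor variant, since the two
#' assays are distinct) and expresses every corrected AUC as a percentage of
#' it. The reference maximal response is the mean corrected AUC of the
#' reference's plateau wells, i.e. its highest tested concentration in that
#' experiment unless `plateau_concentration` designates another one.
#'
#' @param responses Solvent-subtracted tibble from [subtract_solvent()].
#'   Re-normalizing an already-normalized table is allowed and idempotent.
#' @param reference Reference agonist label (default `"LSD"`).
#' @param plateau_concentration Optional molar concentration to use as the
#'   reference plateau instead of the highest tested one.
#' @return The tibble with an added/recomputed `response_normalized` column
#'   (percent of reference maximum), at stage `"normalized"`.
#' @export
normalize_to_reference <- function(responses, reference = "LSD",
                                   plateau_concentration = NULL) {
  require_stage(responses, c("solvent_subtracted", "normalized"),
                "normalize_to_reference")
  assert_columns(responses, c("experiment_id", "pathway", "receptor_variant",
                              "compound", "concentration_molar",
                              "auc_corrected"), "responses")
  grp <- c("experiment_id", "pathway", "receptor_variant")
  ref_max <- responses |>
    dplyr::filter(.data$compound == reference) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(df, key) {
      target <- plateau_concentration %||% max(df$concentration_molar)
      at_plateau <- df$auc_corrected[df$concentration_molar == target]
      if (length(at_plateau) == 0) {
        warning(sprintf(
          "reference '%s' has no wells at the plateau concentration in %s; falling back to its maximal per-concentration mean",
          reference, paste(unlist(key), collapse = "/")), call. = FALSE)
        means <- tapply(df$auc_corrected, df$concentration_molar, mean)
        tibble::tibble(.ref_max = max(means))
      } else {
        tibble::tibble(.ref_max = mean(at_plateau))
      }
    }) |>
    dplyr::ungroup()
  missing_exp <- responses |>
    dplyr::distinct(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::anti_join(ref_max, by = grp)
  if (nrow(missing_exp) > 0) {
    stop(sprintf(
      "reference agonist '%s' is absent from: %s", reference,
      paste(apply(missing_exp, 1, paste, collapse = "/"), collapse = "; ")),
      call. = FALSE)
  }
  out <- dplyr::left_join(responses, ref_max, by = grp)
  out$response_normalized <- 100 * out$auc_corrected / out$.ref_max
  out$.ref_max <- NULL
  set_stage(out, "normalized")
}

#' Run the full trace-to-response pipeline
#'
#' Convenience wrapper applying the fixed processing order: interwell
#' correction, AUC integration, solvent subtraction, normalization to the
#' reference agonist.
#'
#' @inheritParams correct_interwell
#' @inheritParams compute_auc
#' @inheritParams normalize_to_reference
#' @return Normalized per-well response tibble (stage `"normalized"`).
#' @export
process_plates <- function(plate,
                           reference = "LSD",
                           injection_time = attr(plate, "injection_time_s"),
                           window_duration = 7200,
                           plateau_concentration = NULL) {
  plate |>
    correct_interwell(injection_time = injection_time) |>
    compute_auc(injection_time = injection_time,
                window_duration = window_duration) |>
    subtract_solvent() |>
    normalize_to_reference(reference = reference,
                           plateau_concentration = plateau_concentration)
}
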