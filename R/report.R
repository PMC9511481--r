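# Report table assembly: one row per compound and receptor variant, with
# EC50 [CI] and Emax [CI] per pathway, the bias factor and its significance.

#' Assemble the functional-properties report table
#'
#' Formats combined fits and bias summaries into the familiar report layout:
#' per compound (and receptor variant), EC50 in nM with its 95% CI and Emax
#' in % with its CI for each assay, the bias factor (mean of per-experiment
#' values, to 3 decimals, `"n.d."` when undetermined), and significance
#' stars from the Dunn comparison.
#'
#' @param fits Fit table from [fit_study()] (confidence intervals attached
#'   to the combined rows).
#' @param bias Bias tibble from [summarize_bias()], optionally after
#'   [test_bias_significance()].
#' @return Tibble with formatted character columns `ec50_nM_barr2`,
#'   `emax_barr2`, `ec50_nM_miniGq`, `emax_miniGq`, `beta_factor`,
#'   `significance`, plus the numeric `beta_mean` and `beta_combined`.
#' @export
report_table <- function(fits, bias) {
  combined <- fits |>
    dplyr::filter(.data$experiment_id == "combined") |>
    dplyr::mutate(
      ec50_fmt = fmt_ci(.data$ec50 * 1e9, .data$ec50_lo * 1e9,
                        .data$ec50_hi * 1e9),
      emax_fmt = fmt_ci(.data$emax, .data$emax_lo, .data$emax_hi)
    ) |>
    dplyr::select("compound", "receptor_variant", "pathway",
                  "ec50_fmt", "emax_fmt")
  wide <- combined |>
    tidyr::pivot_wider(names_from = "pathway",
                       values_from = c("ec50_fmt", "emax_fmt"))
  bias_cols <- bias |>
    dplyr::mutate(
      beta_factor = fmt_beta(.data$beta_mean),
      significance = if ("significance" %in% names(bias)) {
        .data$significance
      } else ""
    ) |>
    dplyr::select("compound", "receptor_variant", "beta_factor",
                  "significance", "beta_mean", "beta_combined")
  wide |>
    dplyr::left_join(bias_cols, by = c("compound", "receptor_variant")) |>
    dplyr::rename(ec50_nM_barr2 = "ec50_fmt_barr2",
                  emax_barr2 = "emax_fmt_barr2",
                  ec50_nM_miniGq = "ec50_fmt_miniGq",
                  emax_miniGq = "emax_fmt_miniGq") |>
    dplyr::arrange(.data$receptor_variant, .data$compound)
}
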