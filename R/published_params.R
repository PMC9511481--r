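#' Published functional parameters of the phenethylamine panel
#'
#' Loads the published combined-fit potency/efficacy estimates for the
#' N-benzylphenethylamine panel (4a-d, 6a-f) and the reference agonists LSD
#' and serotonin at the 5-HT2A receptor, measured in NanoBiT-style
#' beta-arrestin-2 and miniGq recruitment assays. EC50 values are in nM with
#' 95% confidence bounds, Emax in percent of the LSD maximum. Rows flagged
#' `nd = TRUE` are parameters whose confidence interval (and hence bias
#' factor) could not be determined from the data. `beta_factor` is the
#' reported bias factor (mean of per-experiment values), repeated on both
#' pathway rows of a compound.
#'
#' These tables are worked-example inputs for the bias-statistics stage:
#' recomputing intrinsic relative activities, bias factors and
#' wild-type-vs-mutant fold-changes from them reproduces the reported
#' derived quantities.
#'
#' @param variant `"WT"` for the wild-type receptor or `"S159A"` for the
#'   mutant.
#' @return Tibble with columns `compound`, `pathway`, `ec50_nM`,
#'   `ec50_lo_nM`, `ec50_hi_nM`, `emax_pct`, `emax_lo_pct`, `emax_hi_pct`,
#'   `nd`, `beta_factor`.
#' @examples
#' published_params("WT")
#' @export
published_params <- function(variant = c("WT", "S159A")) {
  variant <- match.arg(variant)
  file <- system.file(
    "extdata",
    sprintf("published_params_%s.csv", tolower(variant)),
    package = "ligandbias", mustWork = TRUE
  )
  readr::read_csv(file, show_col_types = FALSE,
                  col_types = readr::cols(
                    compound = readr::col_character(),
                    pathway = readr::col_character(),
                    nd = readr::col_logical(),
                    .default = readr::col_double()
                  ))
}

#' Convert published parameters to a fit table
#'
#' Reshapes a [published_params()] tibble into the fit-table layout produced
#' by [fit_study()] (one `"combined"` row per compound and pathway), so the
#' bias machinery ([summarize_bias()], [compare_variants_table()]) can run
#' directly on reported values. EC50 is converted from nM to molar. Rows
#' The `statuses` policy controls how the published `nd` flag maps to fit
#' status. The flag marks parameters whose confidence interval could not be
#' determined; their bias factors are likewise undetermined, but their EC50
#' and Emax point estimates are still reported and are the basis of the
#' quoted potency fold-changes. Use `"ci"` (default) when feeding
#' [summarize_bias()] -- flagged rows become `"nd"` -- and `"point"` when
#' feeding [compare_variants_table()], where a row is `"nd"` only if the
#' point estimates themselves are missing.
#'
#' @param params Tibble from [published_params()].
#' @param variant Receptor variant label to attach.
#' @param statuses `"ci"` or `"point"`; see Details.
#' @return Fit-table tibble with columns `compound`, `pathway`,
#'   `receptor_variant`, `experiment_id`, `ec50`, `emax`, `status`.
#' @export
as_fit_table <- function(params, variant = "WT", statuses = c("ci", "point")) {
  assert_columns(params, c("compound", "pathway", "ec50_nM", "emax_pct", "nd"),
                 "params")
  statuses <- match.arg(statuses)
  nd <- if (statuses == "ci") {
    params$nd | is.na(params$ec50_nM) | is.na(params$emax_pct)
  } else {
    is.na(params$ec50_nM) | is.na(params$emax_pct)
  }
  tibble::tibble(
    compound = params$compound,
    pathway = params$pathway,
    receptor_variant = variant,
    experiment_id = "combined",
    ec50 = params$ec50_nM * 1e-9,
    emax = params$emax_pct,
    status = ifelse(nd, "nd", "ok")
  )
}
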