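# Intrinsic relative activity, bias factors, nonparametric significance,
# and WT-vs-mutant comparisons.

#' Intrinsic relative activity (RAi)
#'
#' Computes the pathway-specific intrinsic relative activity of a compound
#' versus the reference agonist:
#' `RAi = (Emax * EC50_ref) / (Emax_ref * EC50)`. A compound identical to
#' the reference has RAi exactly 1; the value is invariant to common
#' rescaling of the response axis and to the concentration unit, as long as
#' both fits use the same unit.
#'
#' @param fit,ref_fit `logistic_fit` objects (or any list with elements
#'   `ec50`, `emax`, `status`) for the compound and the reference agonist in
#'   the same pathway.
#' @return The RAi value as a numeric scalar; `NA` when either fit is not
#'   determined.
#' @export
compute_rai <- function(fit, ref_fit) {
  if (fit_is_nd(fit) || fit_is_nd(ref_fit)) return(NA_real_)
  (fit$emax * ref_fit$ec50) / (ref_fit$emax * fit$ec50)
}

fit_is_nd <- function(fit) {
  is.null(fit) || identical(fit$status, "nd") ||
    !is.finite(fit$ec50) || !is.finite(fit$emax)
}

#' Bias factor from two pathway RAi values
#'
#' Combines the intrinsic relative activities of the arrestin and G-protein
#' pathways into a bias factor `beta = log10(RAi_barr2 / RAi_miniGq)`.
#' The reference agonist's beta is 0 by construction; a positive value
#' indicates preference for beta-arrestin-2 recruitment over miniGq
#' recruitment relative to the reference, a negative value the opposite.
#'
#' @param rai_barr2 RAi in the beta-arrestin-2 assay.
#' @param rai_miniGq RAi in the miniGq assay.
#' @return Numeric beta; `NA` if either input is `NA`.
#' @export
compute_beta <- function(rai_barr2, rai_miniGq) {
  ifelse(is.na(rai_barr2) | is.na(rai_miniGq), NA_real_,
         log10(rai_barr2 / rai_miniGq))
}

# beta straight from the four (ec50, emax) pairs of one experiment;
# vectorized over rows.
beta_from_params <- function(ec50_a, emax_a, ec50_g, emax_g,
                             ref_ec50_a, ref_emax_a, ref_ec50_g, ref_emax_g) {
  rai_a <- (emax_a * ref_ec50_a) / (ref_emax_a * ec50_a)
  rai_g <- (emax_g * ref_ec50_g) / (ref_emax_g * ec50_g)
  log10(rai_a / rai_g)
}

#' Summarize bias factors per compound
#'
#' Computes, for every compound in a fit table, the per-experiment bias
#' factors (each experiment's fits against the same experiment's reference
#' fits), their arithmetic mean (the reported beta), and the combined beta
#' derived from the pooled-data fits. A compound needs `min_experiments`
#' experiments with determined fits in both pathways -- for itself and for
#' the reference -- to receive a beta; otherwise its status is `"nd"` with
#' the reason recorded.
#'
#' @param fits Fit table from [fit_study()] (columns `compound`, `pathway`,
#'   `receptor_variant`, `experiment_id`, `ec50`, `emax`, `status`).
#' @param reference Reference agonist label (default `"LSD"`).
#' @param min_experiments Minimum number of usable experiments (default 3).
#' @return A tibble with one row per (compound, receptor_variant):
#'   `beta_per_experiment` (list-column), `n_experiments`, `beta_mean`,
#'   `beta_combined`, `status`, `reason`.
#' @export
summarize_bias <- function(fits, reference = "LSD", min_experiments = 3) {
  assert_columns(fits, c("compound", "pathway", "receptor_variant",
                         "experiment_id", "ec50", "emax", "status"), "fits")
  if (!all(PATHWAYS %in% fits$pathway)) {
    stop("fit table must cover both pathways (barr2 and miniGq)",
         call. = FALSE)
  }
  out <- lapply(split(fits, fits$receptor_variant), function(fv) {
    ref <- fv[fv$compound == reference, ]
    if (nrow(ref) == 0) {
      stop(sprintf("reference agonist '%s' missing from the fit table",
                   reference), call. = FALSE)
    }
    compounds <- setdiff(unique(fv$compound), SOLVENT_LABEL)
    rows <- lapply(compounds, function(cp) {
      sub <- fv[fv$compound == cp, ]
      one_bias_row(cp, sub, ref, fv$receptor_variant[1], min_experiments)
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}

one_bias_row <- function(compound, sub, ref, variant, min_experiments) {
  get_par <- function(df, pw, eid, field) {
    v <- df[[field]][df$pathway == pw & df$experiment_id == eid &
                       df$status == "ok"]
    if (length(v) == 1 && is.finite(v)) v else NA_real_
  }
  exp_ids <- setdiff(unique(sub$experiment_id), "combined")
  beta_pe <- vapply(exp_ids, function(e) {
    beta_from_params(
      get_par(sub, "barr2", e, "ec50"), get_par(sub, "barr2", e, "emax"),
      get_par(sub, "miniGq", e, "ec50"), get_par(sub, "miniGq", e, "emax"),
      get_par(ref, "barr2", e, "ec50"), get_par(ref, "barr2", e, "emax"),
      get_par(ref, "miniGq", e, "ec50"), get_par(ref, "miniGq", e, "emax")
    )
  }, numeric(1))
  beta_pe <- beta_pe[is.finite(beta_pe)]
  beta_combined <- beta_from_params(
    get_par(sub, "barr2", "combined", "ec50"),
    get_par(sub, "barr2", "combined", "emax"),
    get_par(sub, "miniGq", "combined", "ec50"),
    get_par(sub, "miniGq", "combined", "emax"),
    get_par(ref, "barr2", "combined", "ec50"),
    get_par(ref, "barr2", "combined", "emax"),
    get_par(ref, "miniGq", "combined", "ec50"),
    get_par(ref, "miniGq", "combined", "emax")
  )
  ok <- length(beta_pe) >= min_experiments
  tibble::tibble(
    compound = compound,
    receptor_variant = variant,
    beta_per_experiment = list(unname(beta_pe)),
    n_experiments = length(beta_pe),
    beta_mean = if (ok) mean(beta_pe) else NA_real_,
    beta_combined = if (is.finite(beta_combined)) beta_combined else NA_real_,
    status = if (ok) "ok" else "nd",
    reason = if (ok) NA_character_ else sprintf(
      "only %d experiment(s) with determined fits in both pathways (need %d)",
      length(beta_pe), min_experiments)
  )
}

# Dunn's post hoc rank comparison after Kruskal-Wallis: pairwise z tests on
# group mean ranks computed from the joint midranks, with the standard tie
# correction. Only comparisons against the reference group are formed, then
# Holm-adjusted across them.
dunn_vs_reference <- function(values, groups, reference,
                              p_adjust_method = "holm") {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  if (!reference %in% groups) {
    stop("reference group absent from the data", call. = FALSE)
  }
  n_total <- length(values)
  r <- rank(values)  # midranks
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n_total - 1))
  var_unit <- n_total * (n_total + 1) / 12 - tie_term
  others <- setdiff(names(mean_rank), reference)
  z <- vapply(others, function(g) {
    se <- sqrt(var_unit * (1 / n_g[[g]] + 1 / n_g[[reference]]))
    if (se == 0) 0 else (mean_rank[[g]] - mean_rank[[reference]]) / se
  }, numeric(1))
  p_raw <- 2 * pnorm(-abs(z))
  p_raw[!is.finite(z)] <- 1
  tibble::tibble(
    compound = others,
    z = unname(z),
    p_raw = unname(p_raw),
    p_adjusted = unname(p.adjust(p_raw, method = p_adjust_method))
  )
}

#' Test bias factors for significance versus the reference
#'
#' Runs an omnibus Kruskal-Wallis test across all compounds' per-experiment
#' bias-factor sets (the reference included with its structural zeros),
#' followed by Dunn's post hoc rank comparison of each compound against the
#' reference group, adjusted for multiplicity (Holm by default). Significance
#' tiers follow the usual convention: `*` for p < 0.05, `**` for p < 0.01.
#'
#' @param bias Tibble from [summarize_bias()].
#' @param reference Reference agonist label (default `"LSD"`).
#' @param p_adjust_method Multiplicity adjustment over the
#'   compound-vs-reference comparisons (default `"holm"`).
#' @return `bias` with columns `p_vs_reference` and `significance` added,
#'   plus the omnibus Kruskal-Wallis p-value as attribute `kruskal_p`.
#' @export
test_bias_significance <- function(bias, reference = "LSD",
                                   p_adjust_method = "holm") {
  assert_columns(bias, c("compound", "beta_per_experiment", "status"), "bias")
  usable <- bias[bias$status == "ok" & bias$n_experiments > 0, ]
  if (length(unique(usable$compound)) < 2) {
    stop("at least 2 groups (reference + 1 compound) with determined betas are required",
         call. = FALSE)
  }
  values <- unlist(usable$beta_per_experiment)
  groups <- rep(usable$compound, lengths(usable$beta_per_experiment))
  kw_p <- if (var(values) == 0) 1 else {
    unname(kruskal.test(values, factor(groups))$p.value)
  }
  dunn <- dunn_vs_reference(values, groups, reference, p_adjust_method)
  out <- dplyr::left_join(
    bias,
    dplyr::select(dunn, "compound", p_vs_reference = "p_adjusted"),
    by = "compound"
  )
  out$p_vs_reference[out$compound == reference] <- NA_real_
  out$significance <- dplyr::case_when(
    is.na(out$p_vs_reference) ~ "",
    out$p_vs_reference < 0.01 ~ "**",
    out$p_vs_reference < 0.05 ~ "*",
    TRUE ~ ""
  )
  attr(out, "kruskal_p") <- kw_p
  out
}

#' Compare wild-type and mutant receptor fits
#'
#' Summarizes how a receptor mutation shifts a compound's pharmacology in one
#' pathway: the potency fold-change `EC50_mutant / EC50_WT` (> 1 means the
#' mutation reduces potency) and the efficacy drop `Emax_WT - Emax_mutant`
#' in percentage points.
#'
#' @param fit_wt,fit_mut `logistic_fit` objects (or lists with `ec50`,
#'   `emax`, `status`) for the same compound and pathway at the wild-type and
#'   mutated receptor.
#' @return A one-row tibble with `fold_change_potency`, `efficacy_drop` and
#'   `status` (`"nd"` when either fit is not determined).
#' @export
compare_variants <- function(fit_wt, fit_mut) {
  if (fit_is_nd(fit_wt) || fit_is_nd(fit_mut)) {
    return(tibble::tibble(fold_change_potency = NA_real_,
                          efficacy_drop = NA_real_, status = "nd"))
  }
  tibble::tibble(
    fold_change_potency = fit_mut$ec50 / fit_wt$ec50,
    efficacy_drop = fit_wt$emax - fit_mut$emax,
    status = "ok"
  )
}

#' Tabulate variant comparisons across compounds and pathways
#'
#' Joins the combined fits of two fit tables (wild type and mutant) by
#' compound and pathway and applies [compare_variants()] row-wise.
#'
#' @param fits_wt,fits_mut Fit tables from [fit_study()] (or built from
#'   published parameters) for the two receptor variants; only rows with
#'   `experiment_id == "combined"` are used.
#' @return Tibble with `compound`, `pathway`, `fold_change_potency`,
#'   `efficacy_drop`, `status`.
#' @export
compare_variants_table <- function(fits_wt, fits_mut) {
  pick <- function(df) {
    df |>
      dplyr::filter(.data$experiment_id == "combined") |>
      dplyr::select("compound", "pathway", "ec50", "emax", "status")
  }
  joined <- dplyr::inner_join(pick(fits_wt), pick(fits_mut),
                              by = c("compound", "pathway"),
                              suffix = c("_wt", "_mut"))
  joined |>
    dplyr::rowwise() |>
    dplyr::mutate(compare_variants(
      list(ec50 = .data$ec50_wt, emax = .data$emax_wt, status = .data$status_wt),
      list(ec50 = .data$ec50_mut, emax = .data$emax_mut, status = .data$status_mut)
    )) |>
    dplyr::ungroup() |>
    dplyr::select("compound", "pathway", "fold_change_potency",
                  "efficacy_drop", "status")
}
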