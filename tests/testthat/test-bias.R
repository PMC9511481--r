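# Published combined-fit parameters used repeatedly below (WT receptor,
# LSD reference): potency in nM, efficacy in % of the LSD maximum.
wt <- published_params("WT")
p_of <- function(df, cmpd, pw, field) df[[field]][df$compound == cmpd &
                                                    df$pathway == pw]

test_that("RAi is 1 for the reference itself and follows the defining ratio", {
  ref <- logistic_fit(1.29e-8, 99.7)
  expect_identical(compute_rai(ref, ref), 1)

  a_barr2 <- logistic_fit(11.1e-9, 112)
  lsd_barr2 <- logistic_fit(12.9e-9, 99.7)
  # hand arithmetic on the published cells: (112 * 12.9) / (99.7 * 11.1)
  expect_equal(compute_rai(a_barr2, lsd_barr2), 1.30555, tolerance = 1e-4)

  doubled <- compute_rai(logistic_fit(11.1e-9, 224), logistic_fit(12.9e-9, 199.4))
  expect_equal(doubled, compute_rai(a_barr2, lsd_barr2), tolerance = 1e-12)
})

test_that("beta is antisymmetric, zero at equality, and reproduces the published 4a value", {
  expect_identical(compute_beta(1.7, 1.7), 0)
  expect_equal(compute_beta(2, 0.5), -compute_beta(0.5, 2))

  rai_b <- compute_rai(
    logistic_fit(p_of(wt, "4a", "barr2", "ec50_nM"), p_of(wt, "4a", "barr2", "emax_pct")),
    logistic_fit(p_of(wt, "LSD", "barr2", "ec50_nM"), p_of(wt, "LSD", "barr2", "emax_pct")))
  rai_g <- compute_rai(
    logistic_fit(p_of(wt, "4a", "miniGq", "ec50_nM"), p_of(wt, "4a", "miniGq", "emax_pct")),
    logistic_fit(p_of(wt, "LSD", "miniGq", "ec50_nM"), p_of(wt, "LSD", "miniGq", "emax_pct")))
  beta <- compute_beta(rai_b, rai_g)
  expect_equal(beta, 1.240, tolerance = 0.01)
  # natural log would give ~2.85: the base-10 convention is load-bearing
  expect_false(abs(log(rai_b / rai_g) - 1.240) < 0.25)
})

test_that("bias summaries give the reference exactly zero and agree across methods without heterogeneity", {
  cmp <- compound_spec("A", ec50 = c(barr2 = 1.11e-8, miniGq = 4.88e-8),
                       emax = c(barr2 = 112, miniGq = 28))
  spec <- small_spec(list(lsd_like(), cmp), n_experiments = 3)
  fits <- fit_study(process_plates(simulate_study(spec)), ci = FALSE)
  bias <- summarize_bias(fits)

  ref_row <- bias[bias$compound == "LSD", ]
  expect_identical(unique(ref_row$beta_per_experiment[[1]]), 0)
  expect_identical(ref_row$beta_mean, 0)
  expect_identical(ref_row$beta_combined, 0)

  a_row <- bias[bias$compound == "A", ]
  expect_equal(a_row$beta_mean, a_row$beta_combined, tolerance = 1e-9)
  expect_equal(a_row$beta_mean, 1.2365, tolerance = 1e-3)
})

test_that("a truly unbiased compound has mean beta consistent with zero", {
  cmp <- compound_spec("U", ec50 = c(barr2 = 2e-8, miniGq = 2e-8),
                       emax = c(barr2 = 80, miniGq = 80))
  ref <- compound_spec("LSD", ec50 = c(barr2 = 1.3e-8, miniGq = 1.3e-8),
                       emax = c(barr2 = 100, miniGq = 100))
  betas <- vapply(1:60, function(s) {
    spec <- small_spec(list(ref, cmp), seed = s, read_interval = 480,
                       noise = list(sigma_well = 0.1, sigma_read = 60,
                                    sigma_experiment = 0.1),
                       n_experiments = 1)
    fits <- fit_study(process_plates(simulate_experiment(spec, 1)), ci = FALSE)
    bias <- summarize_bias(fits, min_experiments = 1)
    bias$beta_mean[bias$compound == "U"]
  }, numeric(1))
  betas <- betas[is.finite(betas)]
  expect_gt(length(betas), 40)
  expect_lt(abs(mean(betas)), 2 * sd(betas) / sqrt(length(betas)))
})

test_that("switching the reference shifts every beta by a per-study constant", {
  cmps <- list(
    lsd_like(),
    compound_spec("serotonin", ec50 = c(barr2 = 1.21e-8, miniGq = 1.3e-7),
                  emax = c(barr2 = 110, miniGq = 222)),
    compound_spec("A", ec50 = c(barr2 = 1.11e-8, miniGq = 4.88e-8),
                  emax = c(barr2 = 112, miniGq = 28)),
    compound_spec("B", ec50 = c(barr2 = 5e-8, miniGq = 2e-8),
                  emax = c(barr2 = 90, miniGq = 120))
  )
  spec <- small_spec(cmps, n_experiments = 3)
  resp <- process_plates(simulate_study(spec), reference = "LSD")
  fits <- fit_study(resp, ci = FALSE)
  b_lsd <- summarize_bias(fits, reference = "LSD")
  b_ser <- summarize_bias(fits, reference = "serotonin")
  joined <- dplyr::inner_join(
    dplyr::select(b_lsd, compound, beta_lsd = beta_mean),
    dplyr::select(b_ser, compound, beta_ser = beta_mean),
    by = "compound")
  shifts <- joined$beta_lsd - joined$beta_ser
  expect_lt(diff(range(shifts)), 1e-9)
})

test_that("RAi and beta are invariant to rescaling the normalized response axis", {
  fits <- as_fit_table(wt)
  rescaled <- dplyr::mutate(fits, emax = emax * 3.7)
  b1 <- summarize_bias(fits, min_experiments = 0)
  b2 <- summarize_bias(rescaled, min_experiments = 0)
  expect_equal(b1$beta_combined, b2$beta_combined, tolerance = 1e-12)
})

test_that("Kruskal-Wallis and Dunn behave correctly at the edges", {
  bias <- tibble::tibble(
    compound = c("LSD", "X"),
    receptor_variant = "WT",
    beta_per_experiment = list(c(0, 0, 0), c(5, 5, 5)),
    n_experiments = 3L,
    beta_mean = c(0, 5), beta_combined = c(0, 5),
    status = "ok", reason = NA_character_
  )
  out <- test_bias_significance(bias, reference = "LSD")
  expect_lt(out$p_vs_reference[out$compound == "X"], 0.05)
  # the observed configuration is the most extreme of all rank assignments
  expect_equal(exact_ranksum_p(c(0, 0, 0), c(5, 5, 5)), 2 / 20,
               tolerance = 1e-12)

  flat <- dplyr::mutate(bias,
                        beta_per_experiment = list(c(1, 1, 1), c(1, 1, 1)),
                        beta_mean = 1, beta_combined = 1)
  out2 <- test_bias_significance(flat, reference = "LSD")
  expect_equal(attr(out2, "kruskal_p"), 1)
  expect_equal(out2$p_vs_reference[out2$compound == "X"], 1)

  expect_error(test_bias_significance(bias[1, ], reference = "LSD"),
               "2 groups")
})

test_that("Dunn p-values order identically to exact permutation p-values", {
  set.seed(404)
  for (i in 1:10) {
    g1 <- round(rnorm(3), 2)
    g2 <- round(rnorm(3, mean = runif(1, 0, 3)), 2)
    g3 <- round(rnorm(3, mean = runif(1, 0, 3)), 2)
    dunn <- ligandbias:::dunn_vs_reference(
      c(g1, g2, g3), rep(c("ref", "a", "b"), each = 3), "ref",
      p_adjust_method = "none")
    exact <- c(a = exact_ranksum_p(g1, g2), b = exact_ranksum_p(g1, g3))
    ord_d <- order(dunn$p_raw[match(c("a", "b"), dunn$compound)])
    ord_e <- order(exact)
    if (abs(diff(exact)) > 1e-9) expect_equal(ord_d, ord_e)
  }
})

test_that("variant comparisons reproduce the published fold-changes", {
  expect_equal(compare_variants(logistic_fit(1e-8, 100), logistic_fit(1e-8, 100)),
               tibble::tibble(fold_change_potency = 1, efficacy_drop = 0,
                              status = "ok"))

  mut <- published_params("S159A")
  cmp <- function(cmpd, pw) {
    compare_variants(
      logistic_fit(p_of(wt, cmpd, pw, "ec50_nM"), p_of(wt, cmpd, pw, "emax_pct")),
      logistic_fit(p_of(mut, cmpd, pw, "ec50_nM"), p_of(mut, cmpd, pw, "emax_pct")))
  }
  r <- cmp("6a", "miniGq")       # "16-fold ... 53%"
  expect_equal(r$fold_change_potency, 16, tolerance = 0.01)
  expect_equal(r$efficacy_drop, 53, tolerance = 0.01)
  r <- cmp("serotonin", "barr2") # "55-fold and 33% in beta-arr2"
  expect_equal(r$fold_change_potency, 55, tolerance = 0.01)
  expect_equal(r$efficacy_drop, 33, tolerance = 0.02)

  nd <- compare_variants(logistic_fit(1e-8, 100),
                         logistic_fit(NA, NA, status = "nd"))
  expect_equal(nd$status, "nd")
  expect_true(is.na(nd$fold_change_potency))
})
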