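make_plate <- function(traces, injection_time = 600) {
  # traces: named list well_id -> list(times, values, compound, conc)
  rows <- lapply(names(traces), function(id) {
    tr <- traces[[id]]
    conc <- if (is.null(tr$conc)) 1e-8 else tr$conc
    tibble::tibble(
      experiment_id = "exp1", well_id = id,
      compound = if (is.null(tr$compound)) "A" else tr$compound,
      concentration_molar = conc,
      pathway = "barr2", receptor_variant = "WT", replicate = 1,
      is_solvent_control = conc == 0,
      time_s = tr$times, luminescence = tr$values
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "injection_time_s") <- injection_time
  out
}

test_that("interwell correction rescales each well to unit pre-injection mean", {
  t <- seq(0, 1200, by = 60)
  pl <- make_plate(list(
    const = list(times = t, values = rep(500, length(t))),
    step = list(times = t, values = ifelse(t < 600, 200, 600))
  ))
  cor <- correct_interwell(pl)
  expect_equal(cor$luminescence[cor$well_id == "const"],
               rep(1, length(t)))
  expect_equal(cor$luminescence[cor$well_id == "step" & cor$time_s >= 600],
               rep(3, sum(t >= 600)))
})

test_that("corrected pre-injection means have zero spread across a noisy plate", {
  spec <- small_spec(list(lsd_like()), seed = 11,
                     noise = list(sigma_well = 0.3, sigma_read = 80,
                                  sigma_experiment = 0.2))
  pl <- simulate_experiment(spec, 1)
  cor <- correct_interwell(pl)
  # brute-force recomputation per well
  pre_means <- tapply(
    cor$luminescence[cor$time_s < 600],
    cor$well_id[cor$time_s < 600], mean)
  expect_equal(unname(sd(pre_means) / mean(pre_means)), 0, tolerance = 1e-12)
  expect_equal(as.vector(pre_means), rep(1, length(pre_means)),
               tolerance = 1e-12)
})

test_that("degenerate wells (non-positive pre-injection mean) are dropped with a warning", {
  t <- seq(0, 1200, by = 60)
  pl <- make_plate(list(
    ok = list(times = t, values = rep(10, length(t))),
    dead = list(times = t, values = rep(0, length(t)))
  ))
  expect_warning(cor <- correct_interwell(pl), "dead")
  expect_false("dead" %in% cor$well_id)
})

test_that("trapezoidal AUC matches rectangle, triangle and the kinetic closed form", {
  t <- seq(0, 100, by = 5)
  expect_equal(auc_trapezoid(t, rep(7, length(t))), 7 * 100)
  expect_equal(auc_trapezoid(t, 7 * t / 100), 7 * 100 / 2)
  expect_equal(auc_trapezoid(t, rep(7, length(t)), from = 20, to = 30), 70)
  expect_error(auc_trapezoid(t, rep(1, length(t)), from = -5, to = 50),
               "outside")

  # simulated noiseless kinetic trace vs analytic integral, 60 s reads
  spec <- small_spec(list(lsd_like()), read_interval = 60,
                     pathways = "barr2")
  pl <- simulate_experiment(spec, 1)
  top <- pl[pl$compound == "LSD" & pl$concentration_molar == 2.5e-5 &
              pl$replicate == 1, ]
  got <- auc_trapezoid(top$time_s, top$luminescence, from = 600, to = 7800)
  occ <- 2.5e-5 / (2.5e-5 + 1.29e-8)
  want <- kinetic_auc_oracle(1e4, occ * 99.7 / 100, 1 / 300, 1e-4, 600, 7200)
  expect_lt(abs(got - want) / want, 1e-3)
})

test_that("AUC is linear in the trace on a shared grid", {
  t <- seq(0, 500, by = 20)
  v1 <- sin(t / 100) + 2
  v2 <- exp(-t / 300)
  a <- 2.5; b <- -0.7
  expect_equal(auc_trapezoid(t, a * v1 + b * v2),
               a * auc_trapezoid(t, v1) + b * auc_trapezoid(t, v2),
               tolerance = 1e-12)
})

test_that("solvent subtraction uses the mean of matched controls and consumes them", {
  tbl <- auc_table(dplyr::bind_rows(
    auc_row("A", 100),
    auc_row("solvent", 100, conc = 0),
    auc_row("B", 150),
    auc_row("solvent", 90, conc = 0, replicate = 2),
    auc_row("solvent", 110, conc = 0, replicate = 3)
  ))
  out <- subtract_solvent(tbl)
  expect_false(any(out$is_solvent_control))
  expect_equal(out$auc_corrected[out$compound == "A"], 100 - 100)
  expect_equal(out$auc_corrected[out$compound == "B"], 150 - 100)
})

test_that("a missing solvent control is reported with its condition", {
  tbl <- auc_table(dplyr::bind_rows(
    auc_row("A", 100),
    auc_row("solvent", 50, conc = 0),
    auc_row("B", 80, pathway = "miniGq")
  ))
  expect_error(subtract_solvent(tbl), "miniGq")
})

test_that("zero-efficacy compounds have corrected AUC centred on zero", {
  dead <- compound_spec("dead", ec50 = c(barr2 = 1e-8), emax = c(barr2 = 0))
  means <- vapply(1:100, function(s) {
    spec <- simulation_spec(
      list(compound_spec("LSD", c(barr2 = 1.29e-8), c(barr2 = 100)), dead),
      concentrations = c(1e-9, 1e-8, 1e-7, 1e-6),
      n_replicate_wells = 1, read_interval = 600,
      noise = list(sigma_well = 0.1, sigma_read = 150,
                   sigma_experiment = 0),
      pathways = "barr2", seed = s)
    resp <- simulate_experiment(spec, 1) |>
      correct_interwell() |>
      compute_auc() |>
      subtract_solvent()
    mean(resp$auc_corrected[resp$compound == "dead"])
  }, numeric(1))
  expect_lt(abs(mean(means)), 2 * sd(means) / sqrt(length(means)))
})

test_that("normalization fixes the reference plateau at 100% and is scale invariant", {
  cmp <- compound_spec("A", ec50 = c(barr2 = 2e-8, miniGq = 2e-8),
                       emax = c(barr2 = 150, miniGq = 150))
  spec <- small_spec(list(lsd_like(), cmp), seed = 3,
                     noise = list(sigma_well = 0.1, sigma_read = 60,
                                  sigma_experiment = 0))
  sub <- simulate_experiment(spec, 1) |>
    correct_interwell() |>
    compute_auc() |>
    subtract_solvent()
  norm <- normalize_to_reference(sub, reference = "LSD")
  plateau <- max(norm$concentration_molar)
  ref_top <- norm$response_normalized[norm$compound == "LSD" &
                                        norm$pathway == "barr2" &
                                        norm$concentration_molar == plateau]
  expect_equal(mean(ref_top), 100, tolerance = 1e-9)

  scaled <- sub
  scaled$auc_raw <- scaled$auc_raw * 7.3
  scaled$auc_corrected <- scaled$auc_corrected * 7.3
  norm2 <- normalize_to_reference(scaled, reference = "LSD")
  expect_equal(norm2$response_normalized, norm$response_normalized,
               tolerance = 1e-12)
})

test_that("normalization is idempotent and recovers a 150% top on noiseless data", {
  ref <- compound_spec("LSD", ec50 = c(barr2 = 1.3e-8, miniGq = 1.3e-8),
                       emax = c(barr2 = 100, miniGq = 100))
  cmp <- compound_spec("A", ec50 = c(barr2 = 2e-8, miniGq = 2e-8),
                       emax = c(barr2 = 150, miniGq = 150))
  spec <- small_spec(list(ref, cmp), n_experiments = 2)
  norm <- process_plates(simulate_study(spec), reference = "LSD")
  again <- normalize_to_reference(norm, reference = "LSD")
  expect_equal(again$response_normalized, norm$response_normalized)

  fit <- fit_logistic3(norm[norm$compound == "A" & norm$pathway == "barr2", ])
  expect_equal(fit$emax, 150, tolerance = 0.5 / 150)
})

test_that("the processing order is enforced", {
  spec <- small_spec(list(lsd_like()))
  pl <- simulate_experiment(spec, 1)
  expect_error(compute_auc(pl), "stage")
  cor <- correct_interwell(pl)
  expect_error(correct_interwell(cor), "stage")
  auc <- compute_auc(cor)
  expect_error(normalize_to_reference(auc), "stage")
  expect_error(compute_auc(auc), "stage")
})
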