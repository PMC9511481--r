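# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately brute-force / closed-form and shares no
# code with the package's own numerical paths.

# Three-parameter logistic, Hill slope 1.
logistic3 <- function(conc, bottom, top, ec50) {
  bottom + (top - bottom) / (1 + ec50 / conc)
}

# Closed-form integral of the simulator's kinetic model over the window
# [t_inj, t_inj + T]: baseline decay plus the agonist rise-decay term.
kinetic_auc_oracle <- function(baseline, effect, rise_rate, decay_rate,
                               t_inj, T) {
  base_part <- if (decay_rate == 0) baseline * T else {
    baseline * (exp(-decay_rate * t_inj) - exp(-decay_rate * (t_inj + T))) /
      decay_rate
  }
  kd <- decay_rate; kr <- rise_rate
  agonist_part <- baseline * effect *
    ((1 - exp(-kd * T)) / kd - (1 - exp(-(kr + kd) * T)) / (kr + kd))
  base_part + agonist_part
}

# Dense brute-force grid search over (bottom, top, log10 EC50) minimizing
# RSS; the independent optimizer oracle.
grid_fit_oracle <- function(conc, resp,
                            bottoms = seq(min(resp), max(resp), length.out = 41),
                            tops = seq(min(resp), 1.5 * max(resp), length.out = 61),
                            logec50s = seq(log10(min(conc)) - 1,
                                           log10(max(conc)) + 1, by = 0.05)) {
  best <- list(rss = Inf)
  for (g in logec50s) {
    w <- 1 / (1 + 10^(g) / conc)
    for (b in bottoms) {
      for (tt in tops) {
        rss <- sum((resp - b - (tt - b) * w)^2)
        if (rss < best$rss) best <- list(rss = rss, bottom = b, top = tt, g = g)
      }
    }
  }
  best
}

# Exact two-sided permutation p-value of the rank-sum difference between two
# groups, enumerating all assignments of the pooled values.
exact_ranksum_p <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  r <- rank(pooled)
  obs <- abs(mean(r[seq_len(n1)]) - mean(r[-seq_len(n1)]))
  combs <- utils::combn(length(pooled), n1)
  stats <- apply(combs, 2, function(idx) {
    abs(mean(r[idx]) - mean(r[-idx]))
  })
  mean(stats >= obs - 1e-12)
}

# Small simulation specs shared by tests.
lsd_like <- function() {
  compound_spec("LSD", ec50 = c(barr2 = 1.29e-8, miniGq = 1.32e-8),
                emax = c(barr2 = 99.7, miniGq = 100))
}

noiseless <- list(sigma_well = 0, sigma_read = 0, sigma_experiment = 0)

small_spec <- function(compounds, seed = 1, noise = noiseless,
                       read_interval = 240, n_experiments = 1,
                       pathways = c("barr2", "miniGq"), ...) {
  simulation_spec(compounds, reference = "LSD",
                  read_interval = read_interval,
                  n_experiments = n_experiments,
                  noise = noise, pathways = pathways, seed = seed, ...)
}

# Quietly build a hand-made AUC-stage table for the solvent-subtraction unit
# tests (the internal stage marker is set directly on purpose).
auc_table <- function(df) ligandbias:::set_stage(df, "auc")

auc_row <- function(compound, auc, experiment = "exp1", pathway = "barr2",
                    conc = 1e-8, replicate = 1) {
  tibble::tibble(
    experiment_id = experiment,
    well_id = paste0(experiment, "_", compound, "_", conc, "_", replicate),
    compound = compound,
    concentration_molar = conc,
    pathway = pathway,
    receptor_variant = "WT",
    replicate = replicate,
    is_solvent_control = compound == "solvent",
    auc_raw = auc
  )
}
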