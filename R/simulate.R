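#' Describe a compound for simulation
#'
#' A compound is defined by its generative potency and efficacy in each
#' recruitment pathway. Potency is the in-well concentration giving
#' half-maximal occupancy-driven response; efficacy is the plateau response as
#' a percentage of the reference agonist's maximal response.
#'
#' @param name Compound label.
#' @param ec50 Named numeric vector of true EC50 values in molar units, one
#'   entry per pathway (names from `c("barr2", "miniGq")`).
#' @param emax Named numeric vector of true Emax values in percent of the
#'   reference maximum, same names as `ec50`.
#' @param hill Hill slope of the generating occupancy curve (default 1, the
#'   slope also assumed by the fitting stage).
#' @return An object of class `compound_spec`.
#' @examples
#' compound_spec("LSD", ec50 = c(barr2 = 1.29e-8, miniGq = 1.32e-8),
#'               emax = c(barr2 = 99.7, miniGq = 100))
#' @export
compound_spec <- function(name, ec50, emax, hill = 1) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (is.null(names(ec50)) || is.null(names(emax))) {
    stop("ec50 and emax must be named by pathway", call. = FALSE)
  }
  pw <- union(names(ec50), names(emax))
  bad <- setdiff(pw, PATHWAYS)
  if (length(bad) > 0) {
    stop("unknown pathway name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(names(ec50), names(emax))) {
    stop("ec50 and emax must cover the same pathways", call. = FALSE)
  }
  if (any(!is.finite(ec50)) || any(ec50 <= 0)) {
    stop("true EC50 values must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(emax)) || any(emax < 0)) {
    stop("true Emax values must be nonnegative and finite", call. = FALSE)
  }
  if (!is.finite(hill) || hill <= 0) stop("hill must be positive", call. = FALSE)
  structure(list(name = name, ec50 = ec50, emax = emax, hill = hill),
            class = "compound_spec")
}

#' Default in-well concentration series
#'
#' The nine-point decade dilution series used throughout: 1 pM to 10 uM in
#' decade steps, topped with 25 uM, in molar units, sorted ascending.
#'
#' @return Numeric vector of molar concentrations.
#' @export
default_concentrations <- function() {
  c(1e-12, 1e-11, 1e-10, 1e-9, 1e-8, 1e-7, 1e-6, 1e-5, 2.5e-5)
}

#' Describe a synthetic plate study
#'
#' Collects everything the simulator needs: the compound panel, the plate
#' design (concentration series, replicate wells, number of independent
#' experiments), the kinetic profile of the luminescent signal, and the noise
#' model. Defaults emulate a NanoBiT-style recruitment study: a nine-point
#' decade series from 1 pM to 25 uM, duplicate wells, three independent
#' experiments, a 10 min equilibration phase, and 2 h of post-agonist
#' monitoring.
#'
#' @param compounds List of [compound_spec()] objects; must include the
#'   reference agonist.
#' @param reference Name of the reference agonist (default `"LSD"`).
#' @param concentrations Molar concentration series, strictly positive and
#'   sorted ascending.
#' @param n_experiments Number of independent experiments (default 3).
#' @param n_replicate_wells Wells per condition per experiment (default 2).
#' @param read_interval Seconds between plate reads (default 60).
#' @param equilibration_duration Seconds of pre-injection monitoring
#'   (default 600); the agonist is injected at the end of this phase.
#' @param post_injection_duration Seconds of post-injection monitoring
#'   (default 7200, i.e. 2 h).
#' @param noise List with elements `sigma_well` (sdlog of the per-well
#'   multiplicative lognormal scale), `sigma_read` (sd of additive Gaussian
#'   read noise, in counts), and `sigma_experiment` (sdlog of the
#'   per-experiment multiplicative lognormal scale). All must be >= 0.
#' @param kinetic List with elements `baseline` (pre-injection luminescence
#'   level in counts), `rise_rate` (1/s, agonist signal rise), and
#'   `decay_rate` (1/s, substrate-consumption decay applied to the whole
#'   signal).
#' @param pathways Pathways to simulate (default both assays).
#' @param receptor_variant `"WT"` or `"S159A"`.
#' @param seed Master integer seed; every random stream in the study is
#'   derived from it by counter-based splitting.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(compounds,
                            reference = "LSD",
                            concentrations = default_concentrations(),
                            n_experiments = 3,
                            n_replicate_wells = 2,
                            read_interval = 60,
                            equilibration_duration = 600,
                            post_injection_duration = 7200,
                            noise = list(sigma_well = 0.1, sigma_read = 100,
                                         sigma_experiment = 0.15),
                            kinetic = list(baseline = 1e4,
                                           rise_rate = 1 / 300,
                                           decay_rate = 1e-4),
                            pathways = PATHWAYS,
                            receptor_variant = "WT",
                            seed = 1L) {
  if (inherits(compounds, "compound_spec")) compounds <- list(compounds)
  stopifnot(length(compounds) >= 1)
  if (!all(vapply(compounds, inherits, logical(1), "compound_spec"))) {
    stop("compounds must be a list of compound_spec objects", call. = FALSE)
  }
  nm <- vapply(compounds, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate compound names", call. = FALSE)
  if (!reference %in% nm) {
    stop(sprintf("reference agonist '%s' is not among the compounds", reference),
         call. = FALSE)
  }
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be sorted strictly ascending", call. = FALSE)
  }
  stopifnot(n_experiments >= 1, n_replicate_wells >= 1)
  if (read_interval <= 0 || equilibration_duration <= 0 ||
      post_injection_duration <= 0) {
    stop("durations and read interval must be positive", call. = FALSE)
  }
  noise <- modifyList(list(sigma_well = 0.1, sigma_read = 100,
                           sigma_experiment = 0.15), as.list(noise))
  if (any(unlist(noise[c("sigma_well", "sigma_read", "sigma_experiment")]) < 0)) {
    stop("noise sigmas must be >= 0", call. = FALSE)
  }
  kinetic <- modifyList(list(baseline = 1e4, rise_rate = 1 / 300,
                             decay_rate = 1e-4), as.list(kinetic))
  if (kinetic$baseline <= 0 || kinetic$rise_rate <= 0 || kinetic$decay_rate < 0) {
    stop("kinetic parameters must be positive (decay_rate may be 0)",
         call. = FALSE)
  }
  pathways <- match.arg(pathways, PATHWAYS, several.ok = TRUE)
  receptor_variant <- match.arg(receptor_variant, VARIANTS)
  missing_pw <- Filter(function(cs) !all(pathways %in% names(cs$ec50)),
                       compounds)
  if (length(missing_pw) > 0) {
    stop("compound(s) lacking parameters for a simulated pathway: ",
         paste(vapply(missing_pw, `[[`, character(1), "name"), collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    compounds = setNames(compounds, nm),
    reference = reference,
    concentrations = as.numeric(concentrations),
    n_experiments = as.integer(n_experiments),
    n_replicate_wells = as.integer(n_replicate_wells),
    read_interval = read_interval,
    equilibration_duration = equilibration_duration,
    post_injection_duration = post_injection_duration,
    noise = noise,
    kinetic = kinetic,
    pathways = pathways,
    receptor_variant = receptor_variant,
    seed = as.integer(seed)
  ), class = "simulation_spec")
}

# Fractional receptor occupancy of the generating model.
occupancy <- function(conc, ec50, hill = 1) {
  ifelse(conc <= 0, 0, conc^hill / (conc^hill + ec50^hill))
}

# Noise-free time-luminescence profile of one well:
#   baseline decay  B * exp(-kd * t)
#   plus, after injection, an agonist term
#   B * effect * (1 - exp(-kr * (t - t_inj))) * exp(-kd * (t - t_inj))
# where effect = occupancy(c) * Emax / 100. The rise-then-decay envelope
# mimics live-cell split-luciferase complementation kinetics while staying
# analytically integrable.
expected_trace <- function(times, injection_time, kinetic, effect) {
  v <- kinetic$baseline * exp(-kinetic$decay_rate * times)
  post <- times >= injection_time
  if (any(post)) {
    dt <- times[post] - injection_time
    v[post] <- v[post] + kinetic$baseline * effect *
      (1 - exp(-kinetic$rise_rate * dt)) * exp(-kinetic$decay_rate * dt)
  }
  v
}

# Deterministic per-well layout of an experiment. Well counters are
# structural -- derived from (pathway, compound, concentration, replicate)
# indices -- so extending the design never renumbers existing wells.
well_layout <- function(spec) {
  n_conc <- length(spec$concentrations)
  rows <- list()
  for (pi in seq_along(spec$pathways)) {
    pw <- spec$pathways[pi]
    for (ci in seq_along(spec$compounds)) {
      cs <- spec$compounds[[ci]]
      for (ki in seq_len(n_conc)) {
        for (r in seq_len(spec$n_replicate_wells)) {
          rows[[length(rows) + 1L]] <- list(
            pathway = pw, compound = cs$name,
            concentration_molar = spec$concentrations[ki],
            replicate = r, is_solvent_control = FALSE,
            counter = ((pi * 512 + ci) * 64 + ki) * 16 + r
          )
        }
      }
    }
    # solvent-control wells for this pathway (compound index 0, conc index 0)
    for (r in seq_len(spec$n_replicate_wells)) {
      rows[[length(rows) + 1L]] <- list(
        pathway = pw, compound = SOLVENT_LABEL,
        concentration_molar = 0, replicate = r, is_solvent_control = TRUE,
        counter = (pi * 512 * 64) * 16 + r
      )
    }
  }
  rows
}

#' Simulate one plate experiment
#'
#' Generates the long-format trace table for a single independent experiment:
#' every (pathway, compound, concentration) condition in `n_replicate_wells`
#' wells plus matched solvent-control wells per pathway, each well carrying a
#' full kinetic time-luminescence trace. Noise has three components: a
#' per-experiment multiplicative lognormal scale, a per-well multiplicative
#' lognormal scale (the interwell variability the correction step removes),
#' and additive Gaussian read noise. Both lognormal scales have unit mean.
#' Output is deterministic given `(spec$seed, experiment_index)`.
#'
#' @param spec A [simulation_spec()].
#' @param experiment_index Positive integer identifying the experiment.
#' @return A tibble in the long plate format (columns `experiment_id`,
#'   `well_id`, `compound`, `concentration_molar`, `pathway`,
#'   `receptor_variant`, `replicate`, `is_solvent_control`, `time_s`,
#'   `luminescence`), with the injection time attached as attribute
#'   `injection_time_s`.
#' @export
simulate_experiment <- function(spec, experiment_index = 1L) {
  stopifnot(inherits(spec, "simulation_spec"), experiment_index >= 1)
  experiment_index <- as.integer(experiment_index)
  t_inj <- spec$equilibration_duration
  times <- seq(0, t_inj + spec$post_injection_duration,
               by = spec$read_interval)
  n_t <- length(times)
  if (sum(times >= t_inj) < 2) {
    stop("design yields fewer than 2 post-injection reads", call. = FALSE)
  }

  # per-experiment scale factor (unit-mean lognormal), counter 0
  s_exp <- with_local_seed(mix_seed(spec$seed, experiment_index, 0L), {
    sig <- spec$noise$sigma_experiment
    if (sig > 0) rlnorm(1, meanlog = -sig^2 / 2, sdlog = sig) else 1
  })

  layout <- well_layout(spec)
  exp_id <- sprintf("exp%d", experiment_index)
  blocks <- lapply(layout, function(w) {
    cs <- if (w$is_solvent_control) NULL else spec$compounds[[w$compound]]
    effect <- if (is.null(cs)) 0 else {
      occupancy(w$concentration_molar, cs$ec50[[w$pathway]], cs$hill) *
        cs$emax[[w$pathway]] / 100
    }
    mu <- expected_trace(times, t_inj, spec$kinetic, effect)
    vals <- with_local_seed(mix_seed(spec$seed, experiment_index, w$counter), {
      sw <- spec$noise$sigma_well
      s_well <- if (sw > 0) rlnorm(1, meanlog = -sw^2 / 2, sdlog = sw) else 1
      eps <- if (spec$noise$sigma_read > 0) {
        rnorm(n_t, 0, spec$noise$sigma_read)
      } else 0
      pmax(mu * s_exp * s_well + eps, 0)
    })
    tibble::tibble(
      experiment_id = exp_id,
      well_id = sprintf("%s_c%05d", exp_id, w$counter),
      compound = w$compound,
      concentration_molar = w$concentration_molar,
      pathway = w$pathway,
      receptor_variant = spec$receptor_variant,
      replicate = w$replicate,
      is_solvent_control = w$is_solvent_control,
      time_s = times,
      luminescence = vals
    )
  })
  out <- dplyr::bind_rows(blocks)
  attr(out, "injection_time_s") <- t_inj
  set_stage(out, "raw")
}

#' Simulate a full study of independent experiments
#'
#' Runs [simulate_experiment()] for experiments `1..n_experiments`, each with
#' its own independent inter-experiment scale factor, and binds them into one
#' long table.
#'
#' @param spec A [simulation_spec()].
#' @return A tibble in the long plate format covering all experiments, with
#'   attribute `injection_time_s`.
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  out <- dplyr::bind_rows(lapply(seq_len(spec$n_experiments), function(i) {
    simulate_experiment(spec, i)
  }))
  attr(out, "injection_time_s") <- spec$equilibration_duration
  set_stage(out, "raw")
}
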