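# Three-parameter logistic fitting with exact linear profiling.
#
# Model: response = bottom + (top - bottom) / (1 + EC50 / c), Hill slope 1.
# Writing w(c) = 1 / (1 + 10^(g - log10 c)) with g = log10 EC50, the model is
# response = bottom * (1 - w) + top * w: linear in (bottom, top) for fixed g.
# The fit therefore reduces to a 1-D profile over g solved by a deterministic
# grid scan plus golden-section refinement; the inner linear least squares is
# closed form. This both guarantees the grid-oracle bound (the scan *is* a
# grid search, then improves on it) and makes profile-likelihood confidence
# intervals cheap.

# Closed-form least squares of y on {1 - w, w}; falls back to the flat model
# when the design is numerically collinear (g far outside the data range).
profile_rss <- function(g, x, y) {
  w <- 1 / (1 + 10^(g - x))
  u <- 1 - w
  s11 <- sum(u * u); s12 <- sum(u * w); s22 <- sum(w * w)
  t1 <- sum(y * u); t2 <- sum(y * w)
  det <- s11 * s22 - s12 * s12
  if (!is.finite(det) || det <= 1e-12 * (s11 + s22)^2) {
    mu <- mean(y)
    return(list(rss = sum((y - mu)^2), bottom = mu, top = mu))
  }
  bottom <- (s22 * t1 - s12 * t2) / det
  top <- (s11 * t2 - s12 * t1) / det
  r <- y - bottom * u - top * w
  list(rss = sum(r * r), bottom = bottom, top = top)
}

# Minimize profile_rss over g: deterministic grid spanning the data range
# plus margin, then 1-D refinement around the best grid point.
minimize_logec50 <- function(x, y, step = 0.25, margin = 2) {
  grid <- seq(min(x) - margin, max(x) + margin, by = step)
  rss_grid <- vapply(grid, function(g) profile_rss(g, x, y)$rss, numeric(1))
  i <- which.min(rss_grid)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(function(g) profile_rss(g, x, y)$rss, c(lo, hi),
                  tol = 1e-10)
  if (opt$objective <= rss_grid[i]) {
    list(g = opt$minimum, rss = opt$objective)
  } else {
    list(g = grid[i], rss = rss_grid[i])
  }
}

#' Fit a three-parameter logistic concentration-response curve
#'
#' Least-squares fit of `response = bottom + (top - bottom) / (1 + EC50/c)`
#' with Hill slope fixed at 1; the three parameters are bottom, top (= Emax)
#' and log10 EC50. Optimization scans a deterministic grid of log10 EC50
#' values spanning the tested concentration range, solving the remaining two
#' parameters exactly by linear least squares at each grid point, and refines
#' the best point to convergence.
#'
#' The fit is reported as not determined (`status = "nd"`) when the curve is
#' not distinguishable from a flat line (the profile-likelihood interval of
#' the span top - bottom includes 0 at the 95% level), or when the fitted
#' EC50 lies above the highest tested concentration -- both hallmarks of a
#' response too weak to define a plateau.
#'
#' @param data A data frame with columns `concentration_molar` and
#'   `response` (or `response_normalized`), or a numeric vector of molar
#'   concentrations (then `response` must be the matching numeric vector).
#' @param response Optional numeric response vector when `data` is numeric.
#' @return An object of class `logistic_fit`: a list with elements `ec50`,
#'   `ec50_ci`, `emax`, `emax_ci`, `bottom`, `logec50`, `rss`, `n_points`,
#'   `status` (`"ok"` or `"nd"`), `nd_reason`, and the fitted data.
#'   Confidence intervals are `NA` until [confidence_intervals()] is applied.
#' @examples
#' conc <- rep(10^seq(-11, -6, by = 0.5), each = 2)
#' resp <- 100 / (1 + 1e-8 / conc)
#' fit_logistic3(conc, resp)
#' @export
fit_logistic3 <- function(data, response = NULL) {
  if (is.numeric(data)) {
    conc <- data
    resp <- response
  } else {
    rcol <- if ("response" %in% names(data)) "response" else "response_normalized"
    assert_columns(data, c("concentration_molar", rcol), "data")
    conc <- data$concentration_molar
    resp <- data[[rcol]]
  }
  stopifnot(length(conc) == length(resp))
  keep <- is.finite(conc) & is.finite(resp)
  conc <- conc[keep]; resp <- resp[keep]
  if (any(conc <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (length(unique(conc)) < 4) {
    stop("at least 4 distinct concentrations are required", call. = FALSE)
  }
  x <- log10(conc)
  y <- resp
  n <- length(y)

  best <- minimize_logec50(x, y)
  pars <- profile_rss(best$g, x, y)
  fit <- structure(list(
    ec50 = 10^best$g,
    ec50_ci = c(NA_real_, NA_real_),
    emax = pars$top,
    emax_ci = c(NA_real_, NA_real_),
    bottom = pars$bottom,
    logec50 = best$g,
    rss = best$rss,
    n_points = n,
    status = "ok",
    nd_reason = NA_character_,
    data = list(logconc = x, response = y)
  ), class = "logistic_fit")

  df <- n - 3
  if (df <= 0) {
    return(mark_nd(fit, "too few points for a 3-parameter fit"))
  }
  if (!is.finite(best$rss)) {
    return(mark_nd(fit, "optimization did not converge"))
  }
  # flatness: profile interval of the span includes 0 iff the flat model's
  # RSS is below the 95% profile threshold
  rss_flat <- sum((y - mean(y))^2)
  thr <- best$rss * (1 + qf(0.95, 1, df) / df)
  if (rss_flat <= thr) {
    return(mark_nd(fit, "response not distinguishable from flat"))
  }
  if (best$g > max(x)) {
    return(mark_nd(fit, "fitted EC50 above the highest tested concentration"))
  }
  fit
}

mark_nd <- function(fit, reason) {
  fit$status <- "nd"
  fit$nd_reason <- reason
  fit$ec50 <- NA_real_
  fit$emax <- NA_real_
  fit$bottom <- NA_real_
  fit$logec50 <- NA_real_
  fit$rss <- fit$rss %||% NA_real_
  fit$n_points <- fit$n_points %||% NA_integer_
  fit$ec50_ci <- c(NA_real_, NA_real_)
  fit$emax_ci <- c(NA_real_, NA_real_)
  fit
}

#' Construct a logistic fit from known parameter estimates
#'
#' Builds a `logistic_fit` object directly from EC50/Emax estimates, e.g.
#' published table values, so the bias statistics can be run on reported
#' parameters without the underlying traces.
#'
#' @param ec50 EC50 estimate (any consistent concentration unit).
#' @param emax Emax estimate in percent of the reference maximum.
#' @param bottom Lower asymptote (default 0).
#' @param status `"ok"` or `"nd"`.
#' @param ec50_ci,emax_ci Optional length-2 confidence bounds.
#' @return A `logistic_fit` object.
#' @export
logistic_fit <- function(ec50, emax, bottom = 0, status = c("ok", "nd"),
                         ec50_ci = c(NA_real_, NA_real_),
                         emax_ci = c(NA_real_, NA_real_)) {
  status <- match.arg(status)
  if (status == "ok" && (!is.finite(ec50) || ec50 <= 0)) {
    stop("ec50 must be positive for an ok fit", call. = FALSE)
  }
  structure(list(
    ec50 = if (status == "ok") ec50 else NA_real_,
    ec50_ci = ec50_ci,
    emax = if (status == "ok") emax else NA_real_,
    emax_ci = emax_ci,
    bottom = if (status == "ok") bottom else NA_real_,
    logec50 = if (status == "ok") log10(ec50) else NA_real_,
    rss = NA_real_, n_points = NA_integer_,
    status = status, nd_reason = NA_character_, data = NULL
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$status == "nd") {
    cat("<logistic_fit> n.d.",
        if (!is.na(x$nd_reason)) paste0(" (", x$nd_reason, ")"), "\n", sep = "")
  } else {
    cat(sprintf("<logistic_fit> EC50 = %s [%s-%s], Emax = %s [%s-%s], bottom = %s\n",
                fmt_sig3(x$ec50), fmt_sig3(x$ec50_ci[1]), fmt_sig3(x$ec50_ci[2]),
                fmt_sig3(x$emax), fmt_sig3(x$emax_ci[1]), fmt_sig3(x$emax_ci[2]),
                fmt_sig3(x$bottom)))
    if (!is.na(x$rss)) cat(sprintf("  RSS %.4g on %d points\n", x$rss, x$n_points))
  }
  invisible(x)
}

# Profile RSS of the top (Emax) parameter: minimize over (bottom, g) with top
# held fixed; the inner bottom solve is closed form, the g search reuses the
# grid-plus-refinement strategy.
profile_rss_top <- function(top_fixed, x, y, step = 0.5, margin = 2) {
  rss_g <- function(g) {
    w <- 1 / (1 + 10^(g - x))
    u <- 1 - w
    suu <- sum(u * u)
    z <- y - top_fixed * w
    b <- if (suu <= 1e-12 * length(u)) 0 else sum(z * u) / suu
    sum((z - b * u)^2)
  }
  grid <- seq(min(x) - margin, max(x) + margin, by = step)
  rg <- vapply(grid, rss_g, numeric(1))
  i <- which.min(rg)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(rss_g, c(lo, hi), tol = 1e-8)
  min(opt$objective, rg[i])
}

# Find where a monotone-beyond-the-minimum profile crosses the threshold.
profile_bound <- function(prss, at_min, thr, start, direction,
                          step = 0.25, max_steps = 60) {
  prev <- start
  for (k in seq_len(max_steps)) {
    cand <- start + direction * step * k
    if (prss(cand) >= thr) {
      root <- uniroot(function(v) prss(v) - thr, sort(c(prev, cand)),
                      tol = 1e-10)
      return(root$root)
    }
    prev <- cand
  }
  NA_real_  # unbounded within the search range
}

#' Profile-likelihood confidence intervals for a logistic fit
#'
#' Computes asymmetric profile-likelihood intervals for EC50 and Emax. A
#' parameter value lies inside the interval when its profiled residual sum of
#' squares stays below `RSS_min * (1 + qf(level, 1, n-3)/(n-3))`, the exact
#' F-based threshold for one profiled parameter. A bound that is not reached
#' within the search range is reported as `NA` (printed "n.d."), mirroring
#' parameters whose confidence limit cannot be determined from the data.
#'
#' @param fit A `logistic_fit` from [fit_logistic3()] with `status "ok"`.
#'   An `"nd"` fit passes through unchanged.
#' @param level Confidence level (default 0.95).
#' @param parameters Which intervals to compute (default both).
#' @return The fit with `ec50_ci` and/or `emax_ci` filled in.
#' @export
confidence_intervals <- function(fit, level = 0.95,
                                 parameters = c("ec50", "emax")) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (fit$status == "nd") return(fit)
  if (is.null(fit$data)) {
    stop("fit carries no data; confidence intervals require a fitted dataset",
         call. = FALSE)
  }
  parameters <- match.arg(parameters, several.ok = TRUE)
  x <- fit$data$logconc
  y <- fit$data$response
  n <- fit$n_points
  df <- n - 3
  scale <- max(sum(y^2), 1)
  if (fit$rss <= 1e-12 * scale) {
    # exact fit: the profile threshold collapses and so do the intervals
    if ("ec50" %in% parameters) fit$ec50_ci <- c(fit$ec50, fit$ec50)
    if ("emax" %in% parameters) fit$emax_ci <- c(fit$emax, fit$emax)
    return(fit)
  }
  thr <- fit$rss * (1 + qf(level, 1, df) / df)
  if ("ec50" %in% parameters) {
    prss_g <- function(g) profile_rss(g, x, y)$rss
    lo <- profile_bound(prss_g, fit$rss, thr, fit$logec50, -1)
    hi <- profile_bound(prss_g, fit$rss, thr, fit$logec50, +1)
    fit$ec50_ci <- c(10^lo, 10^hi)
  }
  if ("emax" %in% parameters) {
    prss_t <- function(tt) profile_rss_top(tt, x, y)
    espan <- max(abs(fit$emax), diff(range(y)), 1)
    estep <- 0.05 * espan
    lo <- profile_bound(prss_t, fit$rss, thr, fit$emax, -1, step = estep,
                        max_steps = 100)
    hi <- profile_bound(prss_t, fit$rss, thr, fit$emax, +1, step = estep,
                        max_steps = 100)
    fit$emax_ci <- c(lo, hi)
  }
  fit
}

#' Fit each experiment separately
#'
#' Fits the three-parameter logistic to each experiment's points alone,
#' returning one fit per `experiment_id`. Experiments failing the fitting
#' preconditions (e.g. fewer than 4 distinct concentrations) yield an `"nd"`
#' fit with the reason recorded rather than an error.
#'
#' @param data Tibble with columns `concentration_molar`,
#'   `response`/`response_normalized` and `experiment_id`.
#' @return Named list of `logistic_fit` objects, one per experiment.
#' @export
fit_per_experiment <- function(data) {
  assert_columns(data, "experiment_id", "data")
  ids <- sort(unique(data$experiment_id))
  fits <- lapply(ids, function(e) {
    sub <- data[data$experiment_id == e, , drop = FALSE]
    tryCatch(fit_logistic3(sub), error = function(err) {
      mark_nd(structure(list(data = NULL, n_points = nrow(sub)),
                        class = "logistic_fit"),
              conditionMessage(err))
    })
  })
  setNames(fits, ids)
}

#' One-row summary of a logistic fit
#'
#' @param fit A `logistic_fit`.
#' @return A one-row tibble with the fit's parameters and status.
#' @export
tidy_fit <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  tibble::tibble(
    ec50 = fit$ec50, ec50_lo = fit$ec50_ci[1], ec50_hi = fit$ec50_ci[2],
    emax = fit$emax, emax_lo = fit$emax_ci[1], emax_hi = fit$emax_ci[2],
    bottom = fit$bottom, rss = fit$rss,
    n_points = as.integer(fit$n_points %||% NA_integer_),
    status = fit$status, nd_reason = fit$nd_reason
  )
}

#' Fit every condition of a normalized study
#'
#' For each (compound, pathway, receptor variant) the pooled data of all
#' experiments is fitted (`experiment_id = "combined"`) alongside one fit per
#' individual experiment. Solvent-control rows are ignored. Confidence
#' intervals are attached to the combined fits.
#'
#' @param responses Normalized response tibble from
#'   [normalize_to_reference()], or any tibble with columns `compound`,
#'   `pathway`, `receptor_variant`, `experiment_id`, `concentration_molar`
#'   and `response`/`response_normalized`.
#' @param ci Compute profile confidence intervals for combined fits
#'   (default TRUE).
#' @return A tibble with one row per fit: `compound`, `pathway`,
#'   `receptor_variant`, `experiment_id` (`"combined"` or the experiment's
#'   id), the `tidy_fit` columns, and a `fit` list-column holding the
#'   `logistic_fit` objects.
#' @export
fit_study <- function(responses, ci = TRUE) {
  rcol <- if ("response" %in% names(responses)) "response" else "response_normalized"
  assert_columns(responses, c("compound", "pathway", "receptor_variant",
                              "experiment_id", "concentration_molar", rcol),
                 "responses")
  data <- responses |>
    dplyr::filter(!(.data$compound == SOLVENT_LABEL)) |>
    dplyr::rename(response = dplyr::all_of(rcol))
  conditions <- dplyr::distinct(data, .data$compound, .data$pathway,
                                .data$receptor_variant)
  rows <- lapply(seq_len(nrow(conditions)), function(i) {
    cond <- conditions[i, ]
    sub <- dplyr::semi_join(data, cond,
                            by = c("compound", "pathway", "receptor_variant"))
    combined <- tryCatch(fit_logistic3(sub), error = function(err) {
      mark_nd(structure(list(data = NULL, n_points = nrow(sub)),
                        class = "logistic_fit"), conditionMessage(err))
    })
    if (ci && combined$status == "ok") {
      combined <- confidence_intervals(combined)
    }
    per_exp <- fit_per_experiment(sub)
    fits <- c(list(combined = combined), per_exp)
    dplyr::bind_cols(
      cond[rep(1, length(fits)), ],
      tibble::tibble(experiment_id = names(fits)),
      dplyr::bind_rows(lapply(fits, tidy_fit)),
      tibble::tibble(fit = unname(fits))
    )
  })
  dplyr::bind_rows(rows)
}
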