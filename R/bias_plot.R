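# Qualitative bias plots: equimolar response pairs and their centered
# quadratic fit.

#' Pair equimolar responses from the two assays
#'
#' Builds the point set of a bias plot for one compound: for every
#' concentration tested in both assays, the mean normalized response in the
#' beta-arrestin-2 assay (x) is paired with the mean normalized response in
#' the miniGq assay (y), each with its standard error over the contributing
#' wells and experiments.
#'
#' @param responses_barr2,responses_miniGq Normalized response tibbles (or
#'   any data frames with `concentration_molar` and
#'   `response`/`response_normalized`), each restricted to one compound in
#'   one assay.
#' @return Tibble with one row per shared concentration:
#'   `concentration_molar`, `x`, `x_sem`, `n_x`, `y`, `y_sem`, `n_y`.
#' @export
pair_equimolar <- function(responses_barr2, responses_miniGq) {
  summarise_side <- function(df, label) {
    rcol <- if ("response" %in% names(df)) "response" else "response_normalized"
    assert_columns(df, c("concentration_molar", rcol), label)
    df |>
      dplyr::filter(.data$concentration_molar > 0) |>
      dplyr::group_by(.data$concentration_molar) |>
      dplyr::summarise(
        m = mean(.data[[rcol]]),
        sem = if (dplyr::n() > 1) sd(.data[[rcol]]) / sqrt(dplyr::n()) else NA_real_,
        n = dplyr::n(), .groups = "drop"
      )
  }
  a <- summarise_side(responses_barr2, "responses_barr2")
  g <- summarise_side(responses_miniGq, "responses_miniGq")
  paired <- dplyr::inner_join(a, g, by = "concentration_molar",
                              suffix = c("_x", "_y"))
  if (nrow(paired) < 3) {
    stop(sprintf(
      "only %d shared concentration(s) between the two assays; at least 3 are required",
      nrow(paired)), call. = FALSE)
  }
  paired |>
    dplyr::arrange(.data$concentration_molar) |>
    dplyr::transmute(
      concentration_molar = .data$concentration_molar,
      x = .data$m_x, x_sem = .data$sem_x, n_x = .data$n_x,
      y = .data$m_y, y_sem = .data$sem_y, n_y = .data$n_y
    )
}

#' Centered second-order polynomial fit
#'
#' Ordinary least squares of `y = a + b*(x - x_center) + c*(x - x_center)^2`
#' with `x_center` the mean of x, the curve drawn through bias-plot points.
#'
#' @param points Data frame with columns `x` and `y` (e.g. from
#'   [pair_equimolar()]); at least 3 points with non-identical x.
#' @return Object of class `centered_quadratic`: list with coefficients `a`,
#'   `b`, `c` and `x_center`.
#' @export
fit_centered_quadratic <- function(points) {
  assert_columns(points, c("x", "y"), "points")
  x <- points$x
  y <- points$y
  if (length(x) < 3) stop("at least 3 points are required", call. = FALSE)
  if (diff(range(x)) == 0) {
    stop("all x values are identical: the quadratic design is rank-deficient",
         call. = FALSE)
  }
  xc <- mean(x)
  d1 <- x - xc
  fit <- lm(y ~ d1 + I(d1^2))
  cf <- unname(coef(fit))
  structure(list(a = cf[1], b = cf[2], c = cf[3], x_center = xc),
            class = "centered_quadratic")
}

#' @export
predict.centered_quadratic <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  d <- x - object$x_center
  object$a + object$b * d + object$c * d^2
}

#' @export
print.centered_quadratic <- function(x, ...) {
  cat(sprintf(
    "<centered_quadratic> y = %.4g + %.4g*(x - %.4g) + %.4g*(x - %.4g)^2\n",
    x$a, x$b, x$x_center, x$c, x$x_center))
  invisible(x)
}

#' Bias-plot series for one compound
#'
#' Convenience wrapper producing the full numeric series behind one panel of
#' a bias plot: the equimolar point pairs of the compound and its centered
#' quadratic fit.
#'
#' @param responses Normalized response tibble covering both pathways.
#' @param compound Compound label.
#' @return List of class `bias_plot_series` with elements `compound`,
#'   `points` (tibble from [pair_equimolar()]) and `quad`
#'   (`centered_quadratic`).
#' @export
bias_plot_series <- function(responses, compound) {
  assert_columns(responses, c("compound", "pathway"), "responses")
  sub <- responses[responses$compound == compound, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop(sprintf("compound '%s' not found in the responses", compound),
         call. = FALSE)
  }
  points <- pair_equimolar(sub[sub$pathway == "barr2", , drop = FALSE],
                           sub[sub$pathway == "miniGq", , drop = FALSE])
  structure(list(compound = compound, points = points,
                 quad = fit_centered_quadratic(points)),
            class = "bias_plot_series")
}

#' Flatten bias-plot series to a table
#'
#' @param series A `bias_plot_series` or a list of them.
#' @return Tibble of the point pairs with the fitted quadratic's coefficients
#'   repeated per compound, suitable for CSV export.
#' @export
bias_plot_table <- function(series) {
  if (inherits(series, "bias_plot_series")) series <- list(series)
  dplyr::bind_rows(lapply(series, function(s) {
    dplyr::mutate(s$points, compound = s$compound,
                  quad_a = s$quad$a, quad_b = s$quad$b, quad_c = s$quad$c,
                  x_center = s$quad$x_center, .before = 1)
  }))
}

#' Render bias plots
#'
#' Thin ggplot2 layer over the numeric series: compound curve and points in
#' red against the reference curve in black, one panel per compound.
#'
#' @param series List of `bias_plot_series` for the compounds of interest.
#' @param reference_series `bias_plot_series` of the reference agonist.
#' @return A ggplot object.
#' @export
plot_bias <- function(series, reference_series) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  if (inherits(series, "bias_plot_series")) series <- list(series)
  pts <- bias_plot_table(series)
  curve_of <- function(s) {
    xr <- range(s$points$x)
    xs <- seq(xr[1], xr[2], length.out = 100)
    tibble::tibble(compound = s$compound, x = xs, y = predict(s$quad, xs))
  }
  curves <- dplyr::bind_rows(lapply(series, curve_of))
  ref_curve <- curve_of(reference_series)
  ref_all <- dplyr::bind_rows(lapply(series, function(s) {
    dplyr::mutate(ref_curve, compound = s$compound)
  }))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(data = ref_all, color = "black") +
    ggplot2::geom_line(data = curves, color = "red") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$y - .data$y_sem,
                                        ymax = .data$y + .data$y_sem),
                           width = 0, color = "red", na.rm = TRUE) +
    ggplot2::geom_point(color = "red", size = 1.5) +
    ggplot2::facet_wrap(~compound, scales = "free") +
    ggplot2::labs(x = "normalized AUC, βarr2 assay (%)",
                  y = "normalized AUC, miniGαq assay (%)")
}
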