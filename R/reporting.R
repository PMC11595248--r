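#' Linearised volume-change rate of a logistic phase
#'
#' Summarises a fitted phase as a single linear rate in mm^3/day.
#' Two conventions are supported:
#' \describe{
#'   \item{`from_zero`}{`V(t_end) / t_end` — the mean accumulation rate
#'     taking the lesion as absent at inoculation (used for the growth
#'     phase).}
#'   \item{`difference_quotient`}{`|V(t_start) - V(t_end)| / (t_end -
#'     t_start)` — the mean rate of change over an interval (used for the
#'     regression phase).}
#' }
#'
#' @param params A [logistic_params()].
#' @param conv A [cell_volume_conversion()].
#' @param t_start Interval start, days (ignored by `from_zero`).
#' @param t_end Interval end, days; must exceed `t_start` for
#'   `difference_quotient` and be > 0 for `from_zero`.
#' @param method `"from_zero"` or `"difference_quotient"`.
#' @param phase Optional label carried into the summary.
#' @return A list of class `rate_summary` with `phase`, `t_start`, `t_end`,
#'   `rate` (mm^3/day) and `method`.
#' @export
#' @examples
#' growth <- logistic_params(5.823, 0.146, 8.740e8)
#' linear_rate(growth, t_end = 21, method = "from_zero")       # ~222.7
#' regression <- logistic_params(5.909e-4, -0.360, 1.470e9)
#' linear_rate(regression, t_start = 21, t_end = 28,
#'             method = "difference_quotient")                  # ~574.7
linear_rate <- function(params, conv = cell_volume_conversion(),
                        t_start = 0, t_end,
                        method = c("from_zero", "difference_quotient"),
                        phase = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(params, "logistic_params"))
  if (method == "difference_quotient") {
    if (t_end <= t_start) {
      stop("'t_end' must exceed 't_start' for the difference quotient",
           call. = FALSE)
    }
    rate <- abs(volume_at(params, t_start, conv) -
                  volume_at(params, t_end, conv)) / (t_end - t_start)
  } else {
    if (t_end <= 0) stop("'t_end' must be > 0", call. = FALSE)
    t_start <- 0
    rate <- volume_at(params, t_end, conv) / t_end
  }
  structure(list(phase = phase, t_start = t_start, t_end = t_end,
                 rate = rate, method = method),
            class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("%s rate %.2f mm^3/day over days %g-%g (%s)\n",
              if (is.null(x$phase)) "Linear" else x$phase,
              x$rate, x$t_start, x$t_end, x$method))
  invisible(x)
}

#' Extrapolate the growth curve past the breakpoint
#'
#' Evaluates the fitted growth curve and the fitted regression curve on
#' each day from the breakpoint to `breakpoint + horizon_days`, showing
#' the disparity between the volume predicted by uninterrupted growth and
#' the regressing lesion model.
#'
#' @param growth Growth-phase [logistic_params()].
#' @param regression Regression-phase [logistic_params()].
#' @param conv A [cell_volume_conversion()].
#' @param horizon_days Days past the breakpoint; must be > 0. Default 7.
#' @param breakpoint_day Default 21.
#' @return A data.frame with `day`, `growth_volume`, `regression_volume`
#'   and `disparity = growth_volume - regression_volume`, in mm^3.
#' @export
extrapolate_growth <- function(growth, regression,
                               conv = cell_volume_conversion(),
                               horizon_days = 7, breakpoint_day = 21) {
  stopifnot(inherits(growth, "logistic_params"),
            inherits(regression, "logistic_params"))
  if (horizon_days <= 0) stop("'horizon_days' must be > 0", call. = FALSE)
  days <- seq(breakpoint_day, breakpoint_day + horizon_days, by = 1)
  if (days[length(days)] < breakpoint_day + horizon_days) {
    days <- c(days, breakpoint_day + horizon_days)
  }
  gv <- volume_at(growth, days, conv)
  rv <- volume_at(regression, days, conv)
  data.frame(day = days, growth_volume = gv, regression_volume = rv,
             disparity = gv - rv)
}

#' Site take rate of a longitudinal cohort
#'
#' Fraction of (animal, lesion) inoculation sites with `detected = TRUE`
#' on at least one scan day. Invariant to row order and to duplicated
#' scan days for the same site.
#'
#' @param table A data.frame with the [lesion_table] schema.
#' @return The take fraction in `[0, 1]`.
#' @export
take_rate <- function(table) {
  if (!is.data.frame(table) || !"detected" %in% names(table)) {
    stop("lesion table schema violation: missing column 'detected'",
         call. = FALSE)
  }
  if (nrow(table) == 0) stop("empty lesion table", call. = FALSE)
  ever <- stats::aggregate(detected ~ animal_id + lesion_id, data = table,
                           FUN = any)
  mean(ever$detected)
}

#' Two-phase kinetic report
#'
#' Bundles the headline summary quantities from a pair of fitted phases:
#' the growth-phase from-zero rate to the breakpoint, the regression-phase
#' difference-quotient rate over the follow-up week, the day-by-day growth
#' extrapolation, and the phase-continuity gap at the breakpoint.
#'
#' @param growth Growth-phase [logistic_params()].
#' @param regression Regression-phase [logistic_params()].
#' @param conv A [cell_volume_conversion()].
#' @param breakpoint_day Default 21.
#' @param horizon_days Default 7.
#' @return A list of class `kinetic_report` with `growth_rate`,
#'   `regression_rate` (both `rate_summary`), `extrapolation` (data.frame)
#'   and `continuity_gap_mm3`.
#' @export
kinetic_report <- function(growth, regression,
                           conv = cell_volume_conversion(),
                           breakpoint_day = 21, horizon_days = 7) {
  gr <- linear_rate(growth, conv, t_end = breakpoint_day,
                    method = "from_zero", phase = "growth")
  rr <- linear_rate(regression, conv, t_start = breakpoint_day,
                    t_end = breakpoint_day + horizon_days,
                    method = "difference_quotient", phase = "regression")
  ex <- extrapolate_growth(growth, regression, conv, horizon_days,
                           breakpoint_day)
  gap <- volume_at(growth, breakpoint_day, conv) -
    volume_at(regression, breakpoint_day, conv)
  structure(list(growth_rate = gr, regression_rate = rr,
                 extrapolation = ex, continuity_gap_mm3 = gap,
                 breakpoint_day = breakpoint_day),
            class = "kinetic_report")
}

#' @export
print.kinetic_report <- function(x, ...) {
  cat("Two-phase lesion kinetics\n")
  cat(sprintf("  growth:     %.2f mm^3/day (V(%g)/%g)\n",
              x$growth_rate$rate, x$breakpoint_day, x$breakpoint_day))
  cat(sprintf("  regression: %.2f mm^3/day over days %g-%g\n",
              x$regression_rate$rate, x$regression_rate$t_start,
              x$regression_rate$t_end))
  cat(sprintf("  continuity gap at day %g: %.2f mm^3\n",
              x$breakpoint_day, x$continuity_gap_mm3))
  last <- x$extrapolation[nrow(x$extrapolation), ]
  cat(sprintf("  day-%g disparity (extrapolated growth vs regression): %.1f mm^3\n",
              last$day, last$disparity))
  invisible(x)
}

#' Plot the two-phase model with per-lesion trajectories
#'
#' Convenience figure: the fitted growth curve up to the breakpoint, the
#' fitted regression curve beyond it, the growth extrapolation (dashed),
#' and optional observed per-lesion trajectories overlaid.
#'
#' @param growth,regression [logistic_params()] for the two phases.
#' @param observations Optional [lesion_table] data.frame of detected
#'   observations to overlay.
#' @param conv A [cell_volume_conversion()].
#' @param breakpoint_day Default 21.
#' @param horizon_days Extrapolation horizon; default 7.
#' @return A ggplot object.
#' @export
plot_two_phase <- function(growth, regression, observations = NULL,
                           conv = cell_volume_conversion(),
                           breakpoint_day = 21, horizon_days = 7) {
  tg <- seq(0, breakpoint_day, length.out = 200)
  tr <- seq(breakpoint_day, breakpoint_day + horizon_days, length.out = 100)
  curves <- rbind(
    data.frame(day = tg, volume = volume_at(growth, tg, conv),
               curve = "growth fit", linetype = "solid"),
    data.frame(day = tr, volume = volume_at(regression, tr, conv),
               curve = "regression fit", linetype = "solid"),
    data.frame(day = tr, volume = volume_at(growth, tr, conv),
               curve = "growth extrapolated", linetype = "dashed"))
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$day, y = .data$volume,
                                    colour = .data$curve,
                                    linetype = .data$linetype)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::scale_linetype_identity() +
    ggplot2::labs(x = "days since inoculation", y = "lesion volume (mm³)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(observations)) {
    det <- observations[observations$detected, , drop = FALSE]
    det$lesion <- paste(det$animal_id, det$lesion_id)
    p <- p + ggplot2::geom_line(
      data = det,
      ggplot2::aes(x = .data$day, y = .data$volume_mm3, group = .data$lesion),
      inherit.aes = FALSE, alpha = 0.25) +
      ggplot2::geom_point(
        data = det,
        ggplot2::aes(x = .data$day, y = .data$volume_mm3),
        inherit.aes = FALSE, alpha = 0.4, size = 0.8)
  }
  p
}

#' Reference two-phase parameter sets
#'
#' The packaged reference curves for the induced hepatic lesion model:
#' growth c = 5.823, kappa = 0.146 1/day, theta = 8.740e8 cells;
#' regression c = 5.909e-4, kappa = -0.360 1/day, theta = 1.470e9 cells.
#'
#' @param phase `"growth"` or `"regression"`.
#' @return A [logistic_params()].
#' @export
#' @examples
#' volume_at(reference_params("growth"), 21)
reference_params <- function(phase = c("growth", "regression")) {
  phase <- match.arg(phase)
  if (phase == "growth") {
    logistic_params(c = 5.823, kappa = 0.146, theta = 8.740e8)
  } else {
    logistic_params(c = 5.909e-4, kappa = -0.360, theta = 1.470e9)
  }
}
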