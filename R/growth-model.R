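#' Logistic curve parameters for one kinetic phase
#'
#' A lesion's cell count is modelled by the logistic ODE
#' \eqn{dN/dt = \kappa N (1 - N/\theta)}, whose closed-form solution under
#' the cell-to-volume conversion \eqn{N = \alpha V} is
#' \deqn{V(t) = \frac{\theta}{\alpha\,(1 + c\,e^{-\kappa t})}.}
#' One `logistic_params` object parameterises one phase (growth when
#' \eqn{\kappa > 0}, regression when \eqn{\kappa < 0}).
#'
#' @param c Dimensionless shape coefficient. Determines the starting point
#'   on the sigmoid: \eqn{N(0) = \theta/(1+c)}. Must satisfy `c > -1` for a
#'   positive, singularity-free curve on `t >= 0`.
#' @param kappa Growth-rate constant, units 1/day. Negative values encode
#'   regression. Must be finite.
#' @param theta Carrying capacity in cells. Must be strictly positive.
#'
#' @return An object of class `logistic_params`.
#' @seealso [volume_at()], [ode_rhs()], [integrate_ode()]
#' @export
#' @examples
#' gp <- logistic_params(c = 5.823, kappa = 0.146, theta = 8.740e8)
#' volume_at(gp, t = 21)
logistic_params <- function(c, kappa, theta) {
  stopifnot(is.numeric(c), length(c) == 1L,
            is.numeric(kappa), length(kappa) == 1L,
            is.numeric(theta), length(theta) == 1L)
  if (!is.finite(kappa)) {
    stop("invalid logistic parameters: 'kappa' must be finite (got ",
         kappa, ")", call. = FALSE)
  }
  if (!is.finite(theta) || theta <= 0) {
    stop("invalid logistic parameters: 'theta' must be > 0 (got ",
         theta, ")", call. = FALSE)
  }
  if (!is.finite(c) || c <= -1) {
    stop("invalid logistic parameters: 'c' must be > -1 for a positive, ",
         "singularity-free curve on t >= 0 (got ", c, ")", call. = FALSE)
  }
  structure(list(c = c, kappa = kappa, theta = theta),
            class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf("Logistic parameters: c = %.6g, kappa = %.6g 1/day, theta = %.6g cells\n",
              x$c, x$kappa, x$theta))
  invisible(x)
}

#' Cell-count / volume conversion factor
#'
#' Links imaging volume (mm^3) to modelled cell number via \eqn{N = \alpha V}.
#' The default is the cell density of normal swine liver parenchyma,
#' 146,997 +/- 15,738 cells/mm^3. The standard deviation is carried for
#' documentation and uncertainty propagation; point fits use `alpha` only.
#' 1 uL is treated as identical to 1 mm^3.
#'
#' @param alpha Cells per mm^3; must be > 0.
#' @param alpha_sd Standard deviation of `alpha`, cells per mm^3.
#' @return An object of class `cell_volume_conversion`.
#' @export
cell_volume_conversion <- function(alpha = 146997, alpha_sd = 15738) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(alpha_sd), length(alpha_sd) == 1L, alpha_sd >= 0)
  if (!is.finite(alpha) || alpha <= 0) {
    stop("invalid conversion: 'alpha' must be > 0 (got ", alpha, ")",
         call. = FALSE)
  }
  structure(list(alpha = alpha, alpha_sd = alpha_sd),
            class = "cell_volume_conversion")
}

#' Phase window around the growth/regression breakpoint
#'
#' Growth is assumed between inoculation and the breakpoint day; regression
#' from the breakpoint onward. The breakpoint day itself belongs to both
#' windows (both phase fits use it), so the windows are closed on both sides.
#'
#' @param breakpoint_day Day separating the two phases; default 21.
#' @return An object of class `phase_window`.
#' @seealso [select_phase()]
#' @export
phase_window <- function(breakpoint_day = 21) {
  stopifnot(is.numeric(breakpoint_day), length(breakpoint_day) == 1L)
  if (!is.finite(breakpoint_day) || breakpoint_day <= 0) {
    stop("invalid phase window: 'breakpoint_day' must be > 0 (got ",
         breakpoint_day, ")", call. = FALSE)
  }
  structure(list(breakpoint_day = breakpoint_day), class = "phase_window")
}

#' Lesion volume at time t under the logistic model
#'
#' Evaluates the closed-form logistic solution
#' \eqn{V(t) = \theta / (\alpha (1 + c e^{-\kappa t}))} in mm^3.
#' The curve is strictly increasing in `t` for `c > 0, kappa > 0`
#' (growth) and strictly decreasing for `c > 0, kappa < 0` (regression);
#' for `kappa > 0` it plateaus at the volume equivalent of the carrying
#' capacity, \eqn{\theta/\alpha}.
#'
#' @param params A [logistic_params()] object.
#' @param t Time(s) in days since inoculation; must be >= 0. Vectorised.
#' @param conv A [cell_volume_conversion()]; defaults to swine liver density.
#' @return Volume(s) in mm^3, strictly positive.
#' @export
#' @examples
#' gp <- logistic_params(5.823, 0.146, 8.740e8)
#' volume_at(gp, c(7, 14, 21))
volume_at <- function(params, t, conv = cell_volume_conversion()) {
  stopifnot(inherits(params, "logistic_params"),
            inherits(conv, "cell_volume_conversion"),
            is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("'t' must be finite and >= 0", call. = FALSE)
  }
  params$theta / (conv$alpha * (1 + params$c * exp(-params$kappa * t)))
}

#' Convert lesion volume to cell count
#'
#' Applies the linear conversion \eqn{N = \alpha V}.
#'
#' @param volume Volume(s) in mm^3, >= 0. Vectorised.
#' @param conv A [cell_volume_conversion()].
#' @return Cell count(s).
#' @export
#' @examples
#' cell_count(1)      # 146,997 cells in 1 mm^3 of liver parenchyma
#' cell_count(10000)  # ~1.47e9 cells in a 10 mL lesion
cell_count <- function(volume, conv = cell_volume_conversion()) {
  stopifnot(inherits(conv, "cell_volume_conversion"), is.numeric(volume))
  if (any(!is.finite(volume)) || any(volume < 0)) {
    stop("'volume' must be finite and >= 0", call. = FALSE)
  }
  conv$alpha * volume
}

#' Right-hand side of the logistic ODE
#'
#' \eqn{dN/dt = \kappa N (1 - N/\theta)} in cells/day. Zero at the fixed
#' points \eqn{N = 0} and \eqn{N = \theta}.
#'
#' @param n Cell count(s), >= 0. Vectorised.
#' @param params A [logistic_params()] object.
#' @return Instantaneous rate(s) of change, cells/day.
#' @export
ode_rhs <- function(n, params) {
  stopifnot(inherits(params, "logistic_params"), is.numeric(n))
  if (any(!is.finite(n)) || any(n < 0)) {
    stop("'n' must be finite and >= 0", call. = FALSE)
  }
  params$kappa * n * (1 - n / params$theta)
}

#' Numerically integrate the logistic ODE
#'
#' Classical fixed-step fourth-order Runge-Kutta integration (via
#' \pkg{deSolve}) of \eqn{dN/dt = \kappa N (1 - N/\theta)} from
#' \eqn{N(0) = n_0}. Serves as an independent numeric oracle for the
#' closed form used by [volume_at()]: on the parameter ranges of interest
#' the two agree to a relative tolerance of 1e-6.
#'
#' @param params A [logistic_params()] object.
#' @param n0 Initial cell count at `t = 0`; must be > 0.
#' @param t_grid Sorted, non-negative days at which the solution is returned.
#' @param step RK4 step size in days; default 0.01.
#' @return Cell counts at `t_grid`.
#' @export
integrate_ode <- function(params, n0, t_grid, step = 0.01) {
  stopifnot(inherits(params, "logistic_params"),
            is.numeric(n0), length(n0) == 1L,
            is.numeric(t_grid), length(t_grid) >= 1L)
  if (!is.finite(n0) || n0 <= 0) {
    stop("'n0' must be > 0", call. = FALSE)
  }
  if (any(!is.finite(t_grid)) || any(t_grid < 0)) {
    stop("'t_grid' must be finite and >= 0", call. = FALSE)
  }
  if (is.unsorted(t_grid, strictly = FALSE)) {
    stop("'t_grid' must be sorted in increasing order", call. = FALSE)
  }
  t_max <- max(t_grid)
  times <- sort(unique(c(seq(0, t_max, by = step), t_max, t_grid)))
  sol <- deSolve::ode(
    y = c(n = n0), times = times,
    func = function(t, y, parms) list(ode_rhs(y, params)),
    parms = NULL, method = "rk4"
  )
  sol[match(t_grid, sol[, "time"]), "n"]
}
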