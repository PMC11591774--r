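#' Rescaled-relaxation transform of a central trace
#'
#' Applies the diagnostic transform
#' \deqn{y(t) = \frac{-1}{\ln\left(1 - C(0,t)/C_0(0)\right)},}
#' which is exactly linear in time, with slope \eqn{4D/R^2}, when the central
#' concentration relaxes by normal 2D diffusion from a uniform disk of radius
#' `R`. Departure from linearity at early times is the signature of the
#' ballistic (wave-like) stage of telegraph transport.
#'
#' Points where the transform is undefined — `C >= C0` (logarithm of zero or
#' of a negative number) or `C <= 0` — are masked invalid, never imputed.
#'
#' @param trace a [center_trace_obj()].
#' @param C0 reference initial central concentration (default: the first
#'   trace value, matching the experimental convention of rescaling to unity
#'   at the central region at `t = 0`).
#' @return An object of class `rescaled_trace` with `times`, `values`
#'   (`NA` where invalid) and logical `valid_mask`.
#' @export
rescale_relaxation <- function(trace, C0 = trace$values[1]) {
  stopifnot(inherits(trace, "center_trace"))
  if (!is.numeric(C0) || length(C0) != 1L || !is.finite(C0) || C0 <= 0)
    stop("'C0' must be a single positive number")
  v <- trace$values
  valid <- v > 0 & v < C0
  y <- rep(NA_real_, length(v))
  y[valid] <- -1 / log(1 - v[valid] / C0)
  if (!any(valid)) stop("no point of the trace admits the rescaling transform")
  structure(list(times = trace$times, values = y, valid_mask = valid, C0 = C0),
            class = "rescaled_trace")
}

#' @export
print.rescaled_trace <- function(x, ...) {
  cat(sprintf("Rescaled trace: %d samples, %d valid, over [%g, %g] s\n",
              length(x$times), sum(x$valid_mask), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
plot.rescaled_trace <- function(x, ...) {
  graphics::plot(x$times[x$valid_mask], x$values[x$valid_mask], type = "l",
                 xlab = "time (s)", ylab = "-1 / ln(1 - C(0,t)/C0)", ...)
  invisible(x)
}

#' Central concentration of 2D disk diffusion
#'
#' Closed-form central value for normal 2D diffusion started from a uniform
#' disk of radius `R`:
#' \deqn{C(0, t) = C_0 \left(1 - e^{-R^2 / (4 D t)}\right), \quad C(0,0)=C_0.}
#' Serves as the analytic oracle for the parabolic solver branch and makes
#' the rescaled-relaxation transform exactly linear with slope \eqn{4D/R^2}.
#'
#' @param t time, s (vectorized, `t >= 0`).
#' @param D diffusion coefficient, mm^2/s (`> 0`).
#' @param ic an [initial_condition()] supplying `C0` and `R`.
#' @return Central concentration at `t`.
#' @export
disk_diffusion_center <- function(t, D, ic = initial_condition()) {
  stopifnot(inherits(ic, "initial_condition"))
  if (any(t < 0)) stop("'t' must be non-negative")
  if (!(D > 0)) stop("'D' must be positive")
  out <- ifelse(t > 0, ic$C0 * (1 - exp(-ic$R^2 / (4 * D * t))), ic$C0)
  as.numeric(out)
}

#' Roots of the sink-compensation quadratic
#'
#' Writing the solution of the telegraph-with-sink equation as
#' \eqn{C = \tilde C e^{-\alpha t}} removes the sink term exactly when
#' \eqn{\alpha(\tau\alpha - 1) = -k}, whose roots are
#' \deqn{\alpha_{1,2} = \frac{1 \mp \sqrt{1 - 4\tau k}}{2\tau}.}
#' The smaller root (returned first, computed in the cancellation-free form
#' \eqn{2k / (1 + \sqrt{1 - 4\tau k})}) is approximately `k` when
#' \eqn{4\tau k \ll 1} and governs the slow asymptotic decay.
#'
#' @param params a [transport_params()] with `tau > 0` and `4*tau*k <= 1`.
#' @return Numeric vector `c(alpha1, alpha2)`, smaller root first, units 1/s.
#' @examples
#' alpha_roots(transport_params(4e-5, 1, 1.5e-4))[1]  # ~ 1.50023e-4 ~ k
#' @export
alpha_roots <- function(params) {
  stopifnot(inherits(params, "transport_params"))
  if (params$tau <= 0) stop("'tau' must be positive")
  disc <- 1 - 4 * params$tau * params$k
  if (disc < 0) stop("4*tau*k > 1: roots are complex")
  sq <- sqrt(disc)
  a1 <- if (params$k == 0) 0 else 2 * params$k / (1 + sq)
  a2 <- (1 + sq) / (2 * params$tau)
  c(a1, a2)
}

#' Short-time propagation speed of the telegraph equation
#'
#' At short times the second time derivative dominates and the solution
#' spreads as a wave with finite velocity \eqn{v = \sqrt{D/\tau}}.
#'
#' @param params a [transport_params()] with `tau > 0`.
#' @return Wave speed, mm/s.
#' @examples
#' wave_speed(transport_params(4e-5, 1, 1.5e-4))  # 6.32e-3 mm/s
#' @export
wave_speed <- function(params) {
  stopifnot(inherits(params, "transport_params"))
  if (params$tau == 0) stop("'tau' = 0: signal speed is infinite")
  sqrt(params$D / params$tau)
}

#' Least-squares asymptote of a rescaled trace
#'
#' Fits an ordinary least-squares line to the valid points of a rescaled
#' trace inside a time window; under normal diffusion the slope estimates
#' \eqn{4D/R^2}. Least squares (not L1) is used deliberately: the asymptote
#' is a diagnostic of the late-time diffusive regime, not the model fit.
#'
#' @param rt a [rescale_relaxation()] result (or any list with `times`,
#'   `values`, `valid_mask`).
#' @param window numeric `c(t_a, t_b)` fitting interval, s.
#' @return Named numeric `c(slope, intercept)`, units 1/s and dimensionless.
#' @export
asymptotic_slope <- function(rt, window = c(300, 600)) {
  sel <- rt$valid_mask & rt$times >= window[1] & rt$times <= window[2]
  if (sum(sel) < 3L)
    stop("fewer than 3 valid points in the fitting window")
  fit <- stats::lm.fit(cbind(1, rt$times[sel]), rt$values[sel])
  c(slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]))
}

#' Ballistic-to-diffusive crossover time
#'
#' Operational definition of the crossover between the early wave-like stage
#' and the late diffusive stage: fit the linear asymptote of the rescaled
#' trace on a late window, then find the latest time at which the trace
#' deviates from that line by more than `tol` relative. After `t_cross` the
#' trace stays permanently within the tolerance band of the asymptote.
#'
#' @param rt a [rescale_relaxation()] result.
#' @param asymptote named numeric `c(slope, intercept)`; by default fitted
#'   with [asymptotic_slope()] on `window`.
#' @param tol relative deviation threshold (default 0.05).
#' @param window asymptote fitting window, s (default `c(300, 600)`).
#' @return An object of class `crossover_result` with `t_cross`, `slope`,
#'   `intercept`, `window` and `tol`. A trace that never leaves the band
#'   yields `t_cross` at the first sample; a trace that never settles into
#'   the band is an error.
#' @export
crossover_time <- function(rt, asymptote = NULL, tol = 0.05,
                           window = c(300, 600)) {
  if (is.null(asymptote)) asymptote <- asymptotic_slope(rt, window)
  slope <- asymptote[["slope"]]
  if (!(slope > 0)) stop("asymptote slope must be positive")
  tt <- rt$times[rt$valid_mask]
  vv <- rt$values[rt$valid_mask]
  line <- slope * tt + asymptote[["intercept"]]
  dev <- abs(vv - line) / abs(line)
  out <- which(dev > tol)
  if (!length(out)) {
    t_cross <- tt[1]
  } else if (max(out) == length(tt)) {
    stop("trace never settles within the tolerance band of the asymptote")
  } else {
    t_cross <- tt[max(out)]
  }
  structure(list(t_cross = t_cross, slope = slope,
                 intercept = asymptote[["intercept"]],
                 window = window, tol = tol),
            class = "crossover_result")
}

#' @export
print.crossover_result <- function(x, ...) {
  cat(sprintf(
    "Crossover at t = %g s (tol %g, asymptote slope %.4g 1/s on [%g, %g] s)\n",
    x$t_cross, x$tol, x$slope, x$window[1], x$window[2]))
  invisible(x)
}

#' Closed-form total-mass relaxation
#'
#' Under zero-flux boundaries the spatial term of the transport equation
#' integrates to zero, so the total amount `M(t)` obeys the linear ODE
#' \deqn{\tau M'' + M' + k M = 0, \quad M(0) = M_0,\; M'(0) = 0,}
#' whose solution is
#' \eqn{M(t) = M_0 (\alpha_2 e^{-\alpha_1 t} - \alpha_1 e^{-\alpha_2 t}) /
#' (\alpha_2 - \alpha_1)} with the [alpha_roots()] rates (and
#' \eqn{M_0 e^{-kt}} on the parabolic branch `tau = 0`). Used as an
#' independent check of the solver's discrete mass budget.
#'
#' @param t times, s.
#' @param params a [transport_params()].
#' @param M0 initial total amount.
#' @return `M(t)` at the requested times.
#' @export
mass_ode_solution <- function(t, params, M0 = 1) {
  stopifnot(inherits(params, "transport_params"))
  if (params$k == 0) return(rep(M0, length(t)))
  if (params$tau == 0) return(M0 * exp(-params$k * t))
  a <- alpha_roots(params)
  if (abs(a[2] - a[1]) < 1e-14)  # critically damped
    return(M0 * (1 + a[1] * t) * exp(-a[1] * t))
  M0 * (a[2] * exp(-a[1] * t) - a[1] * exp(-a[2] * t)) / (a[2] - a[1])
}
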