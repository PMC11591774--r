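#' Solver configuration
#'
#' Controls the explicit two-level time integration of the transport model.
#' The step size is chosen adaptively from [step_bounds()] and subdivided so
#' that every requested save time is hit exactly.
#'
#' @param t_end final simulation time, s.
#' @param save_every cadence of saved states, s (default 1, mirroring the
#'   1 fps image acquisition). Ignored when `save_times` is given.
#' @param save_times explicit vector of save times, s, increasing, first
#'   element `>= 0`.
#' @param dt_max hard upper bound on the time step, s.
#' @param safety CFL safety factor in (0, 1), applied to the stability bound.
#' @param neg_tol tolerated magnitude of negative discretization undershoot.
#' @param store_fields keep the full concentration fields at the save times
#'   (set `FALSE` to retain only the center trace and mass history, e.g.
#'   inside fitting loops).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(t_end = 600, save_every = 1, save_times = NULL,
                          dt_max = Inf, safety = 0.4, neg_tol = 1e-6,
                          store_fields = TRUE) {
  if (is.null(save_times)) {
    save_times <- seq(0, t_end, by = save_every)
  }
  save_times <- as.numeric(save_times)
  if (length(save_times) < 1L || any(diff(save_times) <= 0))
    stop("'save_times' must be non-empty and strictly increasing")
  if (save_times[1] < 0) stop("'save_times' must start at t >= 0")
  if (!(safety > 0 && safety < 1)) stop("'safety' must lie in (0, 1)")
  structure(list(t_end = max(save_times), save_times = save_times,
                 dt_max = dt_max, safety = safety, neg_tol = neg_tol,
                 store_fields = store_fields),
            class = "solver_config")
}

#' Maximum stable time step for the explicit scheme
#'
#' Combines the constraints that keep the explicit two-level update of the
#' first-order system \eqn{C_t = J}, \eqn{\tau J_t = D \nabla^2 C - J - k C}
#' stable: the wave CFL limit `spacing / sqrt(D/tau)`, the damping limit
#' `2 tau`, the mixed damping-diffusion limit `spacing^2 / (8 D)` (the von
#' Neumann bound for oscillatory modes of the damped wave system), the sink
#' limit `1/k`, and — on the parabolic branch `tau = 0` — the diffusive limit
#' `spacing^2 / (4 D)`. The minimum is scaled by the safety factor.
#'
#' @param params a [transport_params()].
#' @param grid a [build_grid()] object.
#' @param safety CFL safety factor (default 0.4).
#' @param dt_max cap returned when no transport constraint applies
#'   (`D = 0`, `tau = 0`, `k = 0`).
#' @return Maximum admissible time step, s.
#' @examples
#' g <- build_grid(10, 200)
#' step_bounds(transport_params(4e-5, 1, 1.5e-4), g)   # 0.8 s (damping bound)
#' step_bounds(transport_params(4e-5, 0, 0), g)        # 6.25 s (diffusive)
#' @export
step_bounds <- function(params, grid, safety = 0.4, dt_max = Inf) {
  stopifnot(inherits(params, "transport_params"),
            inherits(grid, "transport_grid"))
  h <- grid$spacing
  cand <- numeric(0)
  if (params$tau > 0) {
    if (params$D > 0) {
      cand <- c(cand,
                h / sqrt(params$D / params$tau),  # wave CFL
                h^2 / (8 * params$D))             # oscillatory-mode bound
    }
    cand <- c(cand, 2 * params$tau)               # damping
  } else if (params$D > 0) {
    cand <- c(cand, h^2 / (4 * params$D))         # parabolic diffusion
  }
  if (params$k > 0) cand <- c(cand, 1 / params$k)
  if (!length(cand)) return(dt_max)
  min(safety * min(cand), dt_max)
}

# 5-point Laplacian with zero-flux (mirror ghost) boundaries, units 1/mm^2
lap_cartesian <- function(C, h) {
  n <- nrow(C)
  up    <- C[c(1L, seq_len(n - 1L)), , drop = FALSE]
  down  <- C[c(seq_len(n - 1L) + 1L, n), , drop = FALSE]
  left  <- C[, c(1L, seq_len(n - 1L)), drop = FALSE]
  right <- C[, c(seq_len(n - 1L) + 1L, n), drop = FALSE]
  (up + down + left + right - 4 * C) / h^2
}

# conservative axisymmetric Laplacian (1/r d/dr (r dC/dr)) on cell-centered
# radii r_j = (j - 1/2) h; the r = 0 face carries zero flux by symmetry and
# the outer face zero flux by the mirror condition
lap_radial <- function(C, r, h) {
  M <- length(C)
  rf <- r + h / 2                       # face radii r_{j+1/2}
  flux <- c(0, rf[-M] * diff(C) / h, 0) # face fluxes, zero at both ends
  (flux[-1] - flux[-(M + 1)]) / (r * h)
}

field_laplacian <- function(values, grid) {
  if (grid$geometry == "cartesian-2d") {
    lap_cartesian(values, grid$spacing)
  } else {
    lap_radial(values, grid$r, grid$spacing)
  }
}

#' Integrate the modified Cattaneo transport equation
#'
#' Solves \deqn{\tau C_{tt} + b\, C_t = D \nabla^2 C - k C} with zero-flux
#' boundaries on a 2D Cartesian or axisymmetric radial grid, as the explicit
#' two-level first-order system \eqn{C_t = J}, \eqn{\tau J_t = D\nabla^2 C -
#' b J - k C}. On the parabolic branch (`tau = 0`, `b = 1`) it integrates
#' \eqn{C_t = D \nabla^2 C - k C} directly. The time step is chosen from
#' [step_bounds()] and subdivided to land exactly on every save time.
#'
#' @param params a [transport_params()].
#' @param ic an [initial_condition()]; ignored when `field0` is supplied.
#' @param grid a [build_grid()] object.
#' @param cfg a [solver_config()].
#' @param field0 optional initial `transport_field` (e.g. with a nonzero
#'   initial time derivative); defaults to [build_field()] of `ic` on `grid`.
#' @param damping damping coefficient `b` multiplying \eqn{C_t} (default 1;
#'   values other than 1 arise in the exponential-decomposition analysis of
#'   the sink term).
#' @return An object of class `transport_solution` with elements `fields`
#'   (list of `transport_field` at the save times, or `NULL` when
#'   `store_fields = FALSE`), `trace` (raw center-node [center_trace_obj()]),
#'   `mass` (total amount at the save times), `save_times`, and the inputs.
#' @examples
#' g <- build_grid(10, 100, geometry = "radial-1d")
#' sol <- solve_transport(transport_params(4e-5, 1, 1.5e-4),
#'                        initial_condition(), g,
#'                        solver_config(t_end = 60, save_every = 10))
#' sol$trace
#' @export
solve_transport <- function(params, ic, grid, cfg = solver_config(),
                            field0 = NULL, damping = 1) {
  stopifnot(inherits(params, "transport_params"),
            inherits(grid, "transport_grid"),
            inherits(cfg, "solver_config"))
  if (is.null(field0)) field0 <- build_field(ic, grid)
  dt_stable <- step_bounds(params, grid, safety = cfg$safety,
                           dt_max = cfg$dt_max)
  dt_stable <- min(dt_stable, cfg$dt_max)
  if (!is.finite(dt_stable) || dt_stable <= 0) {
    if (identical(dt_stable, Inf)) {
      dt_stable <- max(diff(c(0, cfg$save_times)))  # no transport: one step
    } else {
      stop("no stable time step obtainable for these parameters")
    }
  }

  C <- field0$values
  J <- field0$dvalues
  t <- field0$t
  parabolic <- params$tau == 0

  save_times <- cfg$save_times
  n_save <- length(save_times)
  fields <- if (cfg$store_fields) vector("list", n_save) else NULL
  center <- numeric(n_save)
  mass <- numeric(n_save)

  center_idx <- center_node_index(grid)
  record <- function(i) {
    if (cfg$store_fields) {
      fields[[i]] <<- new_field(C, J, t, grid, neg_tol = cfg$neg_tol)
    }
    center[i] <<- mean(C[center_idx])
    mass[i] <<- mass_of(C, grid)
  }

  i0 <- 1L
  if (save_times[1] == t) { record(1L); i0 <- 2L }

  for (i in seq.int(i0, length.out = n_save - i0 + 1L)) {
    t_target <- save_times[i]
    n_sub <- max(1L, ceiling((t_target - t) / dt_stable - 1e-12))
    dt <- (t_target - t) / n_sub
    for (step in seq_len(n_sub)) {
      L <- field_laplacian(C, grid)
      rhs <- params$D * L - params$k * C
      if (parabolic) {
        J <- rhs
        C <- C + dt * J
      } else {
        C_new <- C + dt * J
        J <- J + (dt / params$tau) * (rhs - damping * J)
        C <- C_new
      }
      if (anyNA(C) || any(!is.finite(C)))
        stop(sprintf("instability detected at t = %.4g s (dt = %.4g s)",
                     t + step * dt, dt))
    }
    t <- t_target
    neg <- min(C)
    if (neg < -cfg$neg_tol)
      stop(sprintf("negative concentration %.3g beyond tolerance %g at t = %g s",
                   neg, cfg$neg_tol, t))
    record(i)
  }

  structure(list(fields = fields,
                 trace = center_trace_obj(save_times, center,
                                          averaging_radius = 0),
                 mass = mass, save_times = save_times,
                 params = params, grid = grid, cfg = cfg,
                 damping = damping),
            class = "transport_solution")
}

#' @export
print.transport_solution <- function(x, ...) {
  cat(sprintf(
    "Transport solution: %d saved states over [%g, %g] s on %s grid (N = %d)\n",
    length(x$save_times), min(x$save_times), max(x$save_times),
    x$grid$geometry, x$grid$N))
  cat(sprintf("  center value: %.4f -> %.4f; mass: %.4g -> %.4g\n",
              x$trace$values[1], x$trace$values[length(x$trace$values)],
              x$mass[1], x$mass[length(x$mass)]))
  invisible(x)
}

# indices of the node(s) nearest the origin (4-fold tie on an even
# cell-centered Cartesian grid; their mean is the "central node" value)
center_node_index <- function(grid) {
  rr <- grid_radii(grid)
  which(rr <= min(rr) + 1e-12)
}

mass_of <- function(values, grid) {
  h <- grid$spacing
  if (grid$geometry == "cartesian-2d") {
    sum(values) * h^2
  } else {
    2 * pi * sum(values * grid$r) * h
  }
}

#' Total amount of marker in a field
#'
#' Discrete integral of the concentration: `sum(values) * spacing^2` on the
#' Cartesian grid, `2 pi * sum(values * r) * spacing` on the radial grid.
#'
#' @param field a `transport_field`.
#' @return Total amount, normalized units times mm^2.
#' @export
total_mass <- function(field) {
  stopifnot(inherits(field, "transport_field"))
  mass_of(field$values, field$grid)
}

#' Extract the averaged central-concentration trace from a solution
#'
#' For each saved state, averages the concentration over the nodes within
#' `averaging_radius` of the origin — the numerical counterpart of the mean
#' grayscale level over the pixels surrounding the spot center. When the
#' radius is smaller than the grid spacing the central node value is used
#' (on the even Cartesian grid, the mean of the four nodes tied nearest the
#' origin). On the radial grid the average is area-weighted.
#'
#' @param sol a [solve_transport()] result.
#' @param averaging_radius averaging disk radius, mm (`< L/2`).
#' @return A [center_trace_obj()].
#' @export
center_trace <- function(sol, averaging_radius = 0) {
  stopifnot(inherits(sol, "transport_solution"))
  if (averaging_radius < 0) stop("'averaging_radius' must be >= 0")
  if (averaging_radius > sol$grid$L / 2)
    stop("'averaging_radius' exceeds the half-domain L/2")
  if (averaging_radius < sol$grid$spacing) {
    return(center_trace_obj(sol$save_times, sol$trace$values,
                            averaging_radius = averaging_radius))
  }
  if (is.null(sol$fields))
    stop("fields were not stored; rerun with store_fields = TRUE ",
         "or use averaging_radius < spacing")
  rr <- grid_radii(sol$grid)
  sel <- rr <= averaging_radius
  vals <- vapply(sol$fields, function(f) {
    if (sol$grid$geometry == "cartesian-2d") {
      mean(f$values[sel])
    } else {
      sum(f$values[sel] * sol$grid$r[sel]) / sum(sol$grid$r[sel])
    }
  }, numeric(1))
  center_trace_obj(sol$save_times, vals, averaging_radius = averaging_radius)
}
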