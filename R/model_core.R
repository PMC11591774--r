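#' Transport parameters of the modified Cattaneo model
#'
#' Bundles the three coefficients of the telegraph-with-sink transport
#' equation \deqn{\tau \partial_t^2 C + \partial_t C = D \nabla^2 C - k C,}
#' which describes marker spread from a fluid-filled channel into a porous
#' hydrogel with flux relaxation and first-order loss into the bulk.
#'
#' @param D diffusion coefficient, mm^2/s.
#' @param tau relaxation time of the flux, s. `tau = 0` selects the parabolic
#'   (classical diffusion-with-sink) branch.
#' @param k leakage/sink rate, 1/s, representing outflow into the sample bulk
#'   or trapping in pores.
#'
#' @return An object of class `transport_params`.
#' @examples
#' transport_params(D = 4e-5, tau = 1, k = 1.5e-4)
#' @export
transport_params <- function(D = 4e-5, tau = 1, k = 1.5e-4) {
  for (nm in c("D", "tau", "k")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("'%s' must be a single finite non-negative number", nm))
    }
  }
  structure(list(D = D, tau = tau, k = k), class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat(sprintf("Transport parameters: D = %g mm^2/s, tau = %g s, k = %g 1/s\n",
              x$D, x$tau, x$k))
  invisible(x)
}

#' Smoothed-disk initial condition
#'
#' Parameters of the tanh-smoothed disk used as initial marker distribution,
#' \deqn{C(r, 0) = \frac{C_0}{2}\left[1 + \tanh\frac{R^2 - r^2}{s}\right].}
#' The smooth transition layer stands in for the soaked perivascular sheath
#' around the channel and keeps the finite-difference scheme stable.
#'
#' @param C0 initial central concentration, normalized units (default 1).
#' @param R channel radius, mm (default 0.9).
#' @param s sharpness of the decay from `C0` to zero, mm^2 (default 0.44,
#'   obtained by fitting the profile to the initial experimental recording).
#'
#' @return An object of class `initial_condition`.
#' @export
initial_condition <- function(C0 = 1, R = 0.9, s = 0.44) {
  if (!is.numeric(C0) || length(C0) != 1L || !is.finite(C0) || C0 <= 0)
    stop("'C0' must be a single finite positive number")
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("'R' must be a single finite positive number")
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    stop("'s' must be a single finite positive number")
  structure(list(C0 = C0, R = R, s = s), class = "initial_condition")
}

#' @export
print.initial_condition <- function(x, ...) {
  cat(sprintf("Smoothed-disk IC: C0 = %g, R = %g mm, s = %g mm^2\n",
              x$C0, x$R, x$s))
  invisible(x)
}

#' Evaluate the smoothed-disk initial profile
#'
#' @param r radial distance from the spot center, mm (vectorized, `r >= 0`).
#' @param ic an [initial_condition()].
#' @return Concentration at `r`, normalized units; monotone non-increasing
#'   in `r`, equal to `C0/2` exactly at `r = R`.
#' @examples
#' ic <- initial_condition()
#' initial_profile(c(0, 0.9, 5), ic)
#' @export
initial_profile <- function(r, ic) {
  stopifnot(inherits(ic, "initial_condition"))
  if (!is.numeric(r) || any(!is.finite(r))) stop("'r' must be finite numeric")
  if (any(r < 0)) stop("'r' must be non-negative")
  (ic$C0 / 2) * (1 + tanh((ic$R^2 - r^2) / ic$s))
}

#' Build a computational grid
#'
#' Constructs a regular equispaced grid over a square of side `L` centered at
#' the origin (the spot center). Nodes are cell-centered: spacing `h = L/N`
#' and coordinates `-L/2 + (i - 1/2) h`. The `radial-1d` geometry covers the
#' half-domain `(0, L/2]` by axial symmetry with `N/2` nodes of the same
#' spacing, at radii `(j - 1/2) h`.
#'
#' @param L side length of the square domain, mm (default 10).
#' @param N number of nodes per axis of the full square (default 200).
#' @param geometry `"cartesian-2d"` or `"radial-1d"`.
#' @return An object of class `transport_grid` with elements `L`, `N`,
#'   `spacing`, `geometry`, and node coordinates (`x` per axis, or radii `r`).
#' @examples
#' build_grid(10, 200)$spacing  # 0.05 mm
#' @export
build_grid <- function(L = 10, N = 200,
                       geometry = c("cartesian-2d", "radial-1d")) {
  geometry <- match.arg(geometry)
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("'L' must be a single positive number")
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N < 3 ||
      N != round(N))
    stop("'N' must be an integer >= 3")
  N <- as.integer(N)
  h <- L / N
  g <- list(L = L, N = N, spacing = h, geometry = geometry)
  if (geometry == "cartesian-2d") {
    g$x <- -L / 2 + (seq_len(N) - 0.5) * h
  } else {
    M <- as.integer(ceiling(N / 2))
    g$r <- (seq_len(M) - 0.5) * h
    g$M <- M
  }
  structure(g, class = "transport_grid")
}

#' @export
print.transport_grid <- function(x, ...) {
  cat(sprintf("Grid [%s]: L = %g mm, N = %d, spacing = %g mm\n",
              x$geometry, x$L, x$N, x$spacing))
  invisible(x)
}

#' Node radii of a grid
#'
#' Distance of every node from the origin: an `N x N` matrix for Cartesian
#' grids, a vector for radial grids.
#' @param grid a [build_grid()] object.
#' @return Numeric matrix or vector of radii, mm.
#' @export
grid_radii <- function(grid) {
  stopifnot(inherits(grid, "transport_grid"))
  if (grid$geometry == "cartesian-2d") {
    outer(grid$x, grid$x, function(x, y) sqrt(x^2 + y^2))
  } else {
    grid$r
  }
}

#' Discretize the initial condition onto a grid
#'
#' Evaluates [initial_profile()] at every node radius and assembles the
#' at-rest initial state: the temporal derivative field is zero (the marker
#' is stationary in the channel before leakage starts).
#'
#' @param ic an [initial_condition()].
#' @param grid a [build_grid()] object.
#' @param dvalues0 optional initial time-derivative field (same shape as the
#'   concentration values); defaults to zero everywhere.
#' @return An object of class `transport_field` with elements `values`,
#'   `dvalues` (units 1/s), `t` (s) and `grid`. Warns when the grid spacing
#'   is too coarse to resolve the tanh transition layer
#'   (`spacing > s / (2 R)`).
#' @export
build_field <- function(ic, grid, dvalues0 = NULL) {
  stopifnot(inherits(ic, "initial_condition"), inherits(grid, "transport_grid"))
  if (grid$spacing > ic$s / (2 * ic$R)) {
    warning(sprintf(
      "grid spacing %.4g mm exceeds transition-layer width s/(2R) = %.4g mm; ",
      grid$spacing, ic$s / (2 * ic$R)),
      "the initial profile is under-resolved")
  }
  rr <- grid_radii(grid)
  values <- initial_profile(as.vector(rr), ic)
  if (grid$geometry == "cartesian-2d") {
    values <- matrix(values, grid$N, grid$N)
  }
  dv <- if (is.null(dvalues0)) values * 0 else dvalues0
  if (!identical(dim(dv), dim(values)) || length(dv) != length(values))
    stop("'dvalues0' must match the shape of the concentration field")
  new_field(values, dv, t = 0, grid = grid)
}

# internal constructor with the non-negativity check applied everywhere
new_field <- function(values, dvalues, t, grid, neg_tol = 1e-6) {
  if (any(!is.finite(values))) stop("field values must be finite")
  if (any(values < -neg_tol))
    stop(sprintf("field has negative values beyond tolerance %g", neg_tol))
  structure(list(values = values, dvalues = dvalues, t = t, grid = grid),
            class = "transport_field")
}

#' @export
print.transport_field <- function(x, ...) {
  cat(sprintf("Field at t = %g s on %s grid (N = %d); range [%.4g, %.4g]\n",
              x$t, x$grid$geometry, x$grid$N,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Central-concentration trace
#'
#' Time series of the (optionally disk-averaged) concentration at the spot
#' center — the quantity recorded experimentally as the mean grayscale level
#' in the vicinity of the channel center.
#'
#' @param times sampling times, s, strictly increasing.
#' @param values averaged central concentration, normalized units.
#' @param averaging_radius radius of the central averaging disk, mm.
#' @return An object of class `center_trace`.
#' @export
center_trace_obj <- function(times, values, averaging_radius = 0) {
  if (length(times) != length(values))
    stop("'times' and 'values' must have the same length")
  if (length(times) && any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 averaging_radius = averaging_radius),
            class = "center_trace")
}

#' @export
print.center_trace <- function(x, ...) {
  cat(sprintf(
    "Center trace: %d samples over [%g, %g] s, averaging radius %g mm\n",
    length(x$times), min(x$times), max(x$times), x$averaging_radius))
  invisible(x)
}

#' @export
plot.center_trace <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l", xlab = "time (s)",
                 ylab = "central concentration (normalized)", ...)
  invisible(x)
}

#' @export
as.data.frame.center_trace <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values)
}

#' Read and write central-concentration traces as CSV
#'
#' Traces are exchanged as two-column CSV files `time_s,value` — the format
#' the quantification chain emits and the fitting stage consumes.
#'
#' @param path CSV file path.
#' @param averaging_radius recorded averaging radius, mm (written files store
#'   it in a comment-free side channel only through this argument).
#' @return [read_center_trace()] returns a [center_trace_obj()];
#'   `write_center_trace()` returns `path` invisibly.
#' @export
read_center_trace <- function(path, averaging_radius = 0) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("trace CSV must have columns 'time_s' and 'value'")
  center_trace_obj(df$time_s, df$value, averaging_radius = averaging_radius)
}

#' @rdname read_center_trace
#' @param trace a [center_trace_obj()].
#' @export
write_center_trace <- function(trace, path) {
  stopifnot(inherits(trace, "center_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
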