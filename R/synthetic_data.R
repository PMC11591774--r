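#' Acquisition settings of the synthetic recording
#'
#' Describes the emulated optical recording: an 8-bit grayscale camera at
#' 1 fps viewing the spot from above, with a linear mapping from marker
#' concentration to darkening of the image and additive Gaussian pixel noise
#' applied before quantization.
#'
#' @param fps frames per second (default 1).
#' @param duration recording length, s (default 600).
#' @param bit_depth bits per pixel (default 8).
#' @param pixel_size pixel pitch, mm/px (default 0.01).
#' @param frame_shape `c(rows, cols)` in px (default 401 x 401, a 4 mm field
#'   of view that keeps the corners marker-free for background estimation
#'   over a 600 s run).
#' @param background_level mean background grayscale level (default 200).
#' @param contrast grayscale levels of darkening per unit normalized
#'   concentration (default 150; the spot center then sits near level 54,
#'   well inside the 8-bit range).
#' @param noise_sigma additive Gaussian noise, grayscale levels (default 1).
#' @param seed RNG seed for the noise (default `NULL`: leave RNG state alone).
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(fps = 1, duration = 600, bit_depth = 8,
                             pixel_size = 0.01, frame_shape = c(401, 401),
                             background_level = 200, contrast = 150,
                             noise_sigma = 1, seed = NULL) {
  stopifnot(fps > 0, duration > 0, bit_depth > 0, pixel_size > 0,
            all(frame_shape >= 3), background_level > 0, contrast > 0,
            noise_sigma >= 0)
  structure(list(fps = fps, duration = duration, bit_depth = bit_depth,
                 pixel_size = pixel_size, frame_shape = frame_shape,
                 background_level = background_level, contrast = contrast,
                 noise_sigma = noise_sigma, seed = seed),
            class = "acquisition_spec")
}

#' Synthetic central-concentration trace
#'
#' Forward-model stand-in for the experimentally recorded relaxation of the
#' central concentration: the solver's normed central trace at a regular
#' sampling cadence, optionally with additive iid Gaussian noise.
#'
#' @param params a [transport_params()].
#' @param ic an [initial_condition()].
#' @param sampling_dt sampling interval, s (default 1).
#' @param duration trace length, s (default 600).
#' @param noise_sigma additive noise sd, normalized units (default 0).
#' @param seed RNG seed (ignored when `noise_sigma = 0`).
#' @param grid forward grid (default radial, L = 10 mm, N = 200).
#' @return A [center_trace_obj()], first value 1 plus noise.
#' @export
synth_center_trace <- function(params, ic = initial_condition(),
                               sampling_dt = 1, duration = 600,
                               noise_sigma = 0, seed = NULL,
                               grid = build_grid(10, 200,
                                                 geometry = "radial-1d")) {
  times <- seq(0, duration, by = sampling_dt)
  cfg <- solver_config(save_times = times, store_fields = FALSE)
  sol <- solve_transport(params, ic, grid, cfg)
  v <- sol$trace$values
  v <- v / v[1]
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + stats::rnorm(length(v), sd = noise_sigma)
  }
  center_trace_obj(times, v)
}

# bilinear interpolation of a cell-centered field onto pixel coordinates;
# separable: interpolate along rows, then along columns
interp_field_to_frame <- function(values, grid_x, row_mm, col_mm) {
  ix <- pmin(pmax(findInterval(row_mm, grid_x), 1L), length(grid_x) - 1L)
  wx <- (row_mm - grid_x[ix]) / (grid_x[ix + 1L] - grid_x[ix])
  tmp <- values[ix, , drop = FALSE] * (1 - wx) +
         values[ix + 1L, , drop = FALSE] * wx
  iy <- pmin(pmax(findInterval(col_mm, grid_x), 1L), length(grid_x) - 1L)
  wy <- (col_mm - grid_x[iy]) / (grid_x[iy + 1L] - grid_x[iy])
  tmp[, iy, drop = FALSE] * rep(1 - wy, each = nrow(tmp)) +
    tmp[, iy + 1L, drop = FALSE] * rep(wy, each = nrow(tmp))
}

#' Synthetic 8-bit time-lapse image stack with ground truth
#'
#' Emulates the optical recording of the spreading spot: solves the transport
#' model on the 2D Cartesian grid, maps concentration linearly to darkening
#' (`level = background - contrast * C`), adds Gaussian pixel noise, and
#' quantizes to the bit depth with clipping. Marker regions are darker than
#' the background. The returned ground truth carries the generating
#' parameters, the noiseless continuous (pre-noise, pre-quantization)
#' normalized center trace over the same central pixel disk used by the
#' quantification chain, and coarse-cadence concentration fields.
#'
#' @param params a [transport_params()].
#' @param ic an [initial_condition()].
#' @param spec an [acquisition_spec()].
#' @param grid simulation grid (default Cartesian, L = 10 mm, N = 200); its
#'   domain must cover the imaged field of view.
#' @param n_center pixels in the ground-truth central averaging disk
#'   (default 238, matching [quantify_stack()]).
#' @param truth_field_every cadence (s) of ground-truth concentration fields
#'   kept on the simulation grid (default 60).
#' @return List with `stack` (an [image_stack()]) and `truth` (list:
#'   `params`, `ic`, `spec`, `trace` — noiseless normalized center trace —
#'   and `fields`).
#' @export
synth_image_stack <- function(params, ic = initial_condition(),
                              spec = acquisition_spec(),
                              grid = build_grid(10, 200), n_center = 238,
                              truth_field_every = 60) {
  stopifnot(inherits(spec, "acquisition_spec"),
            grid$geometry == "cartesian-2d")
  row_mm <- frame_coords(spec$frame_shape[1], spec$pixel_size)
  col_mm <- frame_coords(spec$frame_shape[2], spec$pixel_size)
  if (max(abs(c(row_mm, col_mm))) > grid$L / 2)
    stop("the imaged field of view extends beyond the simulated domain")

  times <- seq(0, spec$duration, by = 1 / spec$fps)
  cfg <- solver_config(save_times = times, store_fields = TRUE)
  sol <- solve_transport(params, ic, grid, cfg)

  lvl_max <- 2^spec$bit_depth - 1
  if (!is.null(spec$seed)) set.seed(spec$seed)
  center_px <- c((spec$frame_shape[1] + 1) / 2, (spec$frame_shape[2] + 1) / 2)
  disk_idx <- nearest_pixel_index(spec$frame_shape, center_px, n_center)

  frames <- vector("list", length(times))
  truth_center <- numeric(length(times))
  clipped_frac <- 0
  for (i in seq_along(times)) {
    Cpx <- interp_field_to_frame(sol$fields[[i]]$values, grid$x,
                                 row_mm, col_mm)
    truth_center[i] <- mean(Cpx[disk_idx])
    noiseless <- spec$background_level - spec$contrast * Cpx
    if (i == 1L) {
      spot <- Cpx > 0.5 * ic$C0
      if (any(spot)) clipped_frac <- mean(noiseless[spot] < 0)
    }
    lev <- noiseless
    if (spec$noise_sigma > 0)
      lev <- lev + stats::rnorm(length(lev), sd = spec$noise_sigma)
    frames[[i]] <- matrix(as.integer(pmin(pmax(round(lev), 0), lvl_max)),
                          spec$frame_shape[1], spec$frame_shape[2])
  }
  if (clipped_frac > 0.1)
    warning(sprintf(
      "contrast too large: %.0f%% of the spot clips to level 0",
      100 * clipped_frac))

  keep <- which(times %% truth_field_every == 0)
  truth <- list(params = params, ic = ic, spec = spec,
                trace = center_trace_obj(times,
                                         truth_center / truth_center[1]),
                fields = sol$fields[keep])
  list(stack = image_stack(frames, bit_depth = spec$bit_depth,
                           timestamps = times,
                           pixel_size = spec$pixel_size),
       truth = truth)
}

#' Synthetic rescaled trace with a known breakpoint
#'
#' Fixture for the crossover estimator: a trace that equals the line
#' `slope * t + intercept` exactly for `t >= t_break` and deviates before the
#' break by a smooth relative offset
#' `offset_frac * (1 + ((t_break - t)/t_break)^2)` that exceeds the tolerance
#' band whenever `offset_frac > tol`.
#'
#' @param times sampling times, s (must not include 0 when `intercept = 0`).
#' @param t_break breakpoint, s, inside the time range.
#' @param slope asymptote slope, 1/s.
#' @param intercept asymptote intercept (default 0.005).
#' @param offset_frac relative pre-break offset (default 0.1).
#' @return A `rescaled_trace` object (all points valid).
#' @export
synth_breakpoint_trace <- function(times = seq(1, 600), t_break = 200,
                                   slope = 2e-4, intercept = 0.005,
                                   offset_frac = 0.1) {
  if (t_break < min(times) || t_break > max(times))
    stop("'t_break' must lie within the time range")
  line <- slope * times + intercept
  rel <- ifelse(times < t_break,
                offset_frac * (1 + ((t_break - times) / t_break)^2), 0)
  structure(list(times = times, values = line * (1 + rel),
                 valid_mask = rep(TRUE, length(times)), C0 = NA_real_),
            class = "rescaled_trace")
}
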