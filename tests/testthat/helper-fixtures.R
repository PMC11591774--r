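# shared fixtures: the study's parameter set and small grids for fast tests

study_params <- function() transport_params(D = 4e-5, tau = 1, k = 1.5e-4)
study_ic <- function() initial_condition(C0 = 1, R = 0.9, s = 0.44)

small_radial_grid <- function(N = 100) build_grid(10, N, geometry = "radial-1d")

# quadrature oracle: total amount of the smoothed-disk profile,
# 2*pi * integral of C(r) r dr over the half-domain
ic_mass_quadrature <- function(ic, r_max = 5) {
  2 * pi * stats::integrate(function(r) initial_profile(r, ic) * r,
                            0, r_max, rel.tol = 1e-10)$value
}

# small noiseless synthetic stack shared by imaging tests
tiny_stack <- function(duration = 30, noise_sigma = 0, seed = 11,
                       frame_shape = c(101, 101), pixel_size = 0.03,
                       contrast = 150) {
  spec <- acquisition_spec(duration = duration, frame_shape = frame_shape,
                           pixel_size = pixel_size, contrast = contrast,
                           noise_sigma = noise_sigma, seed = seed)
  synth_image_stack(study_params(), study_ic(), spec,
                    grid = build_grid(10, 100))
}
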