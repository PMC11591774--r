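test_that("step bounds reproduce the stability limits of the explicit scheme", {
  g <- build_grid(10, 200)
  # damping-limited case: 0.4 * 2 * tau
  expect_equal(step_bounds(transport_params(4e-5, 1, 1.5e-4), g), 0.8)
  # parabolic branch: 0.4 * h^2 / (4 D)
  expect_equal(step_bounds(transport_params(4e-5, 0, 0), g), 6.25)
  # no transport at all: the cap is returned
  expect_equal(step_bounds(transport_params(0, 0, 0), g, dt_max = 7), 7)
})

test_that("without transport the field never changes", {
  ic <- study_ic()
  g <- small_radial_grid()
  sol <- solve_transport(transport_params(0, 1, 0), ic, g,
                         solver_config(t_end = 100, save_every = 25,
                                       dt_max = 10))
  f0 <- build_field(ic, g)
  for (f in sol$fields) expect_equal(f$values, f0$values, tolerance = 1e-14)
})

test_that("zero-flux boundaries conserve mass exactly when there is no sink", {
  ic <- study_ic()
  for (g in list(small_radial_grid(), build_grid(10, 100))) {
    sol <- solve_transport(transport_params(4e-5, 1, 0), ic, g,
                           solver_config(t_end = 600, save_every = 150,
                                         store_fields = FALSE))
    expect_lt(max(abs(sol$mass - sol$mass[1])) / sol$mass[1], 1e-3)
  }
})

test_that("parabolic branch reproduces the closed-form disk-diffusion center", {
  ic <- initial_condition(C0 = 1, R = 0.9, s = 1e-3)
  g <- build_grid(10, 400, geometry = "radial-1d")
  sol <- suppressWarnings(
    solve_transport(transport_params(4e-5, 0, 0), ic, g,
                    solver_config(t_end = 600, save_every = 50,
                                  store_fields = FALSE)))
  sel <- sol$save_times >= 50
  ana <- disk_diffusion_center(sol$save_times[sel], 4e-5, ic)
  expect_lt(max(abs(sol$trace$values[sel] - ana) / ana), 0.02)
})

test_that("discrete total mass follows the closed-form mass ODE", {
  ic <- study_ic()
  for (p in list(study_params(), transport_params(4e-5, 2, 1e-3))) {
    sol <- solve_transport(p, ic, small_radial_grid(200),
                           solver_config(t_end = 600, save_every = 50,
                                         store_fields = FALSE))
    expected <- mass_ode_solution(sol$save_times, p, M0 = sol$mass[1])
    expect_lt(max(abs(sol$mass - expected) / expected), 0.01)
  }
})

test_that("radial and Cartesian solutions agree on the central trace", {
  p <- study_params(); ic <- study_ic()
  cfg <- solver_config(t_end = 600, save_every = 100, store_fields = FALSE)
  s1 <- solve_transport(p, ic, build_grid(10, 200, geometry = "radial-1d"), cfg)
  s2 <- solve_transport(p, ic, build_grid(10, 200), cfg)
  expect_lt(max(abs(s1$trace$values - s2$trace$values) / s2$trace$values),
            0.02)
})

test_that("a millisecond relaxation time is indistinguishable from pure diffusion", {
  ic <- study_ic()
  cfg <- solver_config(save_times = seq(10, 60, by = 10),
                       store_fields = FALSE)
  g <- small_radial_grid()
  s_tau <- solve_transport(transport_params(4e-5, 1e-3, 1.5e-4), ic, g, cfg)
  s_par <- solve_transport(transport_params(4e-5, 0, 1.5e-4), ic, g, cfg)
  expect_lt(max(abs(s_tau$trace$values - s_par$trace$values) /
                  s_par$trace$values), 0.005)
})

test_that("the exponential sink decomposition matches the rescaled telegraph equation", {
  p <- study_params(); ic <- study_ic()
  g <- build_grid(10, 200, geometry = "radial-1d")
  a1 <- alpha_roots(p)[1]
  cfg <- solver_config(t_end = 600, save_every = 100)
  sol3 <- solve_transport(p, ic, g, cfg)
  f0 <- build_field(ic, g)
  f0t <- build_field(ic, g, dvalues0 = a1 * f0$values)
  solt <- solve_transport(transport_params(p$D, p$tau, 0), ic, g, cfg,
                          field0 = f0t, damping = 1 - 2 * p$tau * a1)
  for (i in seq_along(cfg$save_times)) {
    lhs <- exp(a1 * cfg$save_times[i]) * sol3$fields[[i]]$values
    rhs <- solt$fields[[i]]$values
    expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-3)
  }
})

test_that("doubling the domain at fixed spacing leaves the central trace unchanged", {
  p <- study_params(); ic <- study_ic()
  cfg <- solver_config(t_end = 600, save_every = 100, store_fields = FALSE)
  s1 <- solve_transport(p, ic, build_grid(10, 200, geometry = "radial-1d"), cfg)
  s2 <- solve_transport(p, ic, build_grid(20, 400, geometry = "radial-1d"), cfg)
  expect_lt(max(abs(s1$trace$values - s2$trace$values) / s2$trace$values),
            1e-3)
})

test_that("total mass integrates uniform and empty fields exactly", {
  g <- build_grid(10, 50)
  f <- build_field(study_ic(), g)
  f$values[] <- 0.7
  expect_equal(total_mass(f), 100 * 0.7, tolerance = 1e-12)
  f$values[] <- 0
  expect_equal(total_mass(f), 0)
  # radial: uniform c over the half-domain disk of radius 5
  gr <- small_radial_grid()
  fr <- build_field(study_ic(), gr)
  fr$values[] <- 0.7
  expect_equal(total_mass(fr), pi * 25 * 0.7, tolerance = 1e-12)
})

test_that("center traces average the requested central disk", {
  p <- study_params(); ic <- study_ic()
  sol <- solve_transport(p, ic, build_grid(10, 100),
                         solver_config(t_end = 200, save_every = 20))
  tr0 <- center_trace(sol, 0)
  expect_equal(tr0$values, sol$trace$values)
  tr <- center_trace(sol, 0.1)
  expect_gte(tr$values[1], initial_profile(0.1, ic) - 1e-12)
  expect_lte(tr$values[1], initial_profile(0, ic) + 1e-12)
  expect_error(center_trace(sol, 6), "half-domain")
  # with a sink the central value relaxes monotonically after its plateau
  expect_true(all(diff(sol$trace$values) <= 1e-9))
  expect_gte(min(sol$trace$values), 0)
})
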