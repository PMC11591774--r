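test_that("the relaxation rescaling inverts the exponential exactly and masks invalid points", {
  tr <- center_trace_obj(1:4, c(1 - exp(-1), 1 - exp(-2), 1.2, -0.1))
  rt <- rescale_relaxation(tr, C0 = 1)
  expect_equal(rt$values[1], 1.0, tolerance = 1e-14)
  expect_equal(rt$values[2], 0.5, tolerance = 1e-14)
  expect_identical(rt$valid_mask, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(is.na(rt$values[3:4])))
  expect_error(rescale_relaxation(center_trace_obj(1:2, c(1.5, 2)), C0 = 1),
               "no point")
})

test_that("rescaled disk diffusion is the exact line 4D/R^2 * t", {
  ic <- study_ic(); D <- 4e-5
  # at early times 1 - C(0,t)/C0 underflows against machine epsilon and the
  # transform is masked; the machine-precision identity is asserted where
  # the subtraction is well conditioned
  tt <- seq(400, 3000, by = 50)
  tr <- center_trace_obj(tt, disk_diffusion_center(tt, D, ic))
  rt <- rescale_relaxation(tr, C0 = ic$C0)
  expect_true(all(rt$valid_mask))
  expect_lt(max(abs(rt$values - (4 * D / ic$R^2) * tt)), 1e-12)
  # and the fitted asymptote recovers the slope to 1e-6 relative
  asym <- asymptotic_slope(rt, window = range(tt))
  expect_equal(asym[["slope"]], 4 * D / ic$R^2, tolerance = 1e-6)
})

test_that("the disk-diffusion center solution matches an independent kernel quadrature", {
  ic <- study_ic(); D <- 4e-5
  expect_equal(disk_diffusion_center(0, D, ic), ic$C0)
  expect_equal(disk_diffusion_center(ic$R^2 / (4 * D), D, ic),
               ic$C0 * (1 - exp(-1)), tolerance = 1e-12)
  # oracle: integral of the 2D heat kernel over the uniform disk, at origin
  kernel_center <- function(t) {
    stats::integrate(function(r) r / (2 * D * t) * exp(-r^2 / (4 * D * t)),
                     0, ic$R, rel.tol = 1e-12)$value
  }
  for (t in c(100, 600, 3000)) {
    expect_equal(disk_diffusion_center(t, D, ic), kernel_center(t),
                 tolerance = 1e-9)
  }
  expect_equal(disk_diffusion_center(600, D, ic), 0.9997834,
               tolerance = 1e-6)
})

test_that("compensation roots solve the quadratic and satisfy Vieta's relations", {
  expect_equal(alpha_roots(transport_params(1, 1, 0)), c(0, 1))
  a <- alpha_roots(study_params())
  expect_equal(a[1], 1.500225e-4, tolerance = 1e-6)
  for (p in list(study_params(), transport_params(1, 2, 0.1),
                 transport_params(0, 0.5, 0.2))) {
    a <- alpha_roots(p)
    expect_lt(max(abs(a * (p$tau * a - 1) + p$k)), 1e-12)
    expect_equal(sum(a), 1 / p$tau, tolerance = 1e-12)
    expect_equal(prod(a), p$k / p$tau, tolerance = 1e-12)
  }
  expect_error(alpha_roots(transport_params(1, 1, 0.3)), "complex")
  # the slow decay factor stays near 1 over the full recording
  a1 <- alpha_roots(study_params())[1]
  expect_gt(exp(-a1 * 600), 0.9)
})

test_that("wave speed is sqrt(D/tau)", {
  expect_equal(wave_speed(study_params()), 6.32e-3, tolerance = 1e-3)
  expect_equal(wave_speed(transport_params(0, 1, 0)), 0)
  expect_equal(wave_speed(transport_params(4e-5, 4, 0)), 3.16e-3,
               tolerance = 1e-3)
  expect_error(wave_speed(transport_params(1, 0, 0)), "infinite")
})

test_that("asymptote fitting recovers exact lines and ignores masked points", {
  tt <- seq(0, 600, by = 1)
  rt <- list(times = tt, values = 3e-4 * tt + 0.01,
             valid_mask = rep(TRUE, length(tt)))
  asym <- asymptotic_slope(rt, c(100, 500))
  expect_equal(asym[["slope"]], 3e-4, tolerance = 1e-12)
  expect_equal(asym[["intercept"]], 0.01, tolerance = 1e-12)
  # subsampling the window by 2 leaves the slope unchanged
  keep <- seq(1, length(tt), by = 2)
  rt2 <- list(times = tt[keep], values = rt$values[keep],
              valid_mask = rep(TRUE, length(keep)))
  expect_equal(asymptotic_slope(rt2, c(100, 500))[["slope"]],
               asym[["slope"]], tolerance = 1e-3)
  rt$valid_mask[tt >= 100 & tt <= 500] <- FALSE
  rt$valid_mask[c(150, 250)] <- TRUE
  expect_error(asymptotic_slope(rt, c(100, 500)), "fewer than 3")
})

test_that("crossover detection finds constructed breakpoints", {
  # exactly linear trace: crossover at the first sample
  rt_lin <- synth_breakpoint_trace(times = seq(1, 600), t_break = 200,
                                   offset_frac = 0)
  expect_equal(crossover_time(rt_lin, tol = 0.05)$t_cross, 1)
  # pre-break offset exceeding the band: crossover at the breakpoint
  rt <- synth_breakpoint_trace(times = seq(1, 600), t_break = 200,
                               offset_frac = 0.1)
  cx <- crossover_time(rt, tol = 0.05)
  expect_lte(abs(cx$t_cross - 200), 1)
  # offset entirely below the band: first sample again
  rt_small <- synth_breakpoint_trace(times = seq(1, 600), t_break = 200,
                                     offset_frac = 0.02)
  expect_equal(crossover_time(rt_small, tol = 0.05)$t_cross, 1)
  # a trace that never settles is an error
  rt_bad <- rt
  rt_bad$values <- rt_bad$values * 1.2
  expect_error(crossover_time(rt_bad, asymptote = c(slope = 2e-4,
                                                    intercept = 0.005),
                              tol = 0.05),
               "never settles")
})
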