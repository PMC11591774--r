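test_that("background estimation averages marker-free regions", {
  frame <- matrix(200L, 101, 101)
  expect_equal(estimate_background(frame), 200)
  # dark spot in the middle, annulus and corners both avoid it
  rr <- sqrt(outer((1:101 - 51)^2, (1:101 - 51)^2, `+`))
  frame[rr < 20] <- 50L
  expect_equal(estimate_background(frame, list(type = "annulus",
                                               r_inner = 30)), 200)
  expect_equal(estimate_background(frame, list(type = "corners",
                                               frac = 0.15)), 200)
  expect_error(estimate_background(frame, list(type = "blob")), "unknown")
  # Monte-Carlo: with pixel noise the estimate is within 3 sigma / sqrt(n)
  set.seed(5)
  sigma <- 2
  noisy <- matrix(round(200 + rnorm(101 * 101, sd = sigma)), 101, 101)
  reg <- list(type = "annulus", r_inner = 30)
  n <- sum(sqrt(outer((1:101 - 51)^2, (1:101 - 51)^2, `+`)) >= 30)
  expect_lt(abs(estimate_background(noisy, reg) - 200), 3 * sigma / sqrt(n))
})

test_that("inversion subtracts the background and clips bright pixels", {
  expect_equal(subtract_invert(200, 200), 0)
  expect_equal(subtract_invert(150, 200), 50)
  expect_equal(subtract_invert(210, 200), 0)
})

test_that("centroids locate and track the spot", {
  ic <- study_ic()
  mk_map <- function(dr, dc) {
    rr <- sqrt(outer((1:101 - 51 - dr)^2, rep(1, 101)) +
               outer(rep(1, 101), (1:101 - 51 - dc)^2)) * 0.03
    matrix(initial_profile(as.vector(rr), ic), 101, 101)
  }
  c0 <- find_center(mk_map(0, 0))
  expect_lt(max(abs(c0 - c(51, 51))), 0.5)
  c1 <- find_center(mk_map(5, -3))
  expect_lt(max(abs(c1 - c0 - c(5, -3))), 0.5)
  expect_equal(unname(find_center(matrix(1, 7, 9))), c(4, 5))
  expect_error(find_center(matrix(0, 5, 5)), "all-zero")
})

test_that("cross-sections reproduce the generating radial profile", {
  # fine simulation grid so the comparison is quantization-limited
  ss <- synth_image_stack(study_params(), study_ic(),
                          acquisition_spec(duration = 5,
                                           frame_shape = c(101, 101),
                                           pixel_size = 0.03,
                                           noise_sigma = 0),
                          grid = build_grid(10, 400))
  bg <- estimate_background(ss$stack$frames[[1]])
  map <- subtract_invert(ss$stack$frames[[1]], bg)
  center <- find_center(map)
  pr <- extract_cross_section(map, center, ss$stack$pixel_size, w = 0)
  truth <- 150 * initial_profile(abs(pr$positions), study_ic())
  # noiseless: quantization plus background estimate leaves < ~1 level
  expect_lt(max(abs(pr$values - truth)), 1.1)
  # axisymmetric map gives a symmetric profile
  mid <- (length(pr$values) + 1) / 2
  expect_lt(max(abs(pr$values - rev(pr$values))), 2)
  expect_error(extract_cross_section(map, c(500, 50), 0.03), "outside")
  zero <- extract_cross_section(matrix(0, 11, 11), c(6, 6), 0.03)
  expect_true(all(zero$values == 0))
})

test_that("central disk averaging is exact on uniform and monotone maps", {
  u <- matrix(3.5, 51, 51)
  expect_equal(center_mean(u, c(26, 26), 238), 3.5)
  expect_equal(center_mean(u, c(26, 26), 1), 3.5)
  rr <- sqrt(outer((1:51 - 26)^2, rep(1, 51)) +
             outer(rep(1, 51), (1:51 - 26)^2))
  dec <- exp(-rr / 10)
  expect_equal(center_mean(dec, c(26, 26), 1), 1)
  expect_lte(center_mean(dec, c(26, 26), 238), dec[26, 26])
  expect_error(center_mean(u, c(26, 26), 1e6), "exceeds")
})

test_that("normalization fixes the initial center to one and cancels gain", {
  ss <- tiny_stack(duration = 10)
  q <- quantify_stack(ss$stack)
  expect_equal(q$trace$values[1], 1)
  # common gain about the background leaves normalized outputs unchanged
  g <- 1.5
  bg <- 200
  scaled <- lapply(ss$stack$frames, function(f) {
    matrix(as.integer(pmin(pmax(round(bg + g * (f - bg)), 0), 255)),
           nrow(f), ncol(f))
  })
  q2 <- quantify_stack(image_stack(scaled, timestamps = ss$stack$timestamps,
                                   pixel_size = ss$stack$pixel_size))
  expect_lt(max(abs(q2$trace$values - q$trace$values)), 0.01)
  # normalize_stack itself is exactly gain-invariant
  maps <- lapply(ss$stack$frames, function(f) subtract_invert(f, bg))
  cv <- vapply(maps, function(m) center_mean(m, c(51, 51)), numeric(1))
  n1 <- normalize_stack(maps, cv, ss$stack$timestamps)
  n2 <- normalize_stack(lapply(maps, `*`, 3), cv * 3, ss$stack$timestamps)
  expect_equal(n1$trace$values, n2$trace$values)
  expect_error(normalize_stack(maps, cv * 0, ss$stack$timestamps),
               "zero reference")
})

test_that("pseudocolor enhancement squares the normalized inverted intensity", {
  expect_equal(pseudocolor_enhance(200, 200), 0)
  expect_equal(pseudocolor_enhance(0, 200), 1)
  lv <- seq(0, 255)
  e <- pseudocolor_enhance(lv, 200)
  expect_true(all(diff(e) <= 0))
  expect_true(all(e >= 0 & e <= 1))
})

test_that("the quantification chain recovers the generator ground truth", {
  ss <- tiny_stack(duration = 60, noise_sigma = 1, seed = 3,
                   frame_shape = c(201, 201), pixel_size = 0.02)
  q <- quantify_stack(ss$stack)
  expect_lt(max(abs(q$trace$values - ss$truth$trace$values)), 0.02)
  # t = 0 normalized profile against the generating smoothed disk; the
  # central 238-px disk mean differs from the center value by < 1e-4, so the
  # center value serves as the normalization reference
  pr <- q$profiles[[1]]
  truth_prof <- initial_profile(abs(pr$positions), study_ic()) /
    initial_profile(0, study_ic())
  expect_lt(max(abs(pr$values - truth_prof)), 0.03)
})

test_that("image stacks survive a disk round trip in TIFF and PNG", {
  ss <- tiny_stack(duration = 3, frame_shape = c(41, 41))
  tf <- tempfile(fileext = ".tif")
  write_image_stack(ss$stack, tf)
  back <- read_image_stack(tf, fps = 1, pixel_size = ss$stack$pixel_size)
  expect_equal(back$frames, ss$stack$frames)
  dir <- tempfile()
  write_image_stack(ss$stack, dir)
  back2 <- read_image_stack(dir, fps = 1, pixel_size = ss$stack$pixel_size)
  expect_equal(back2$frames, ss$stack$frames)
  unlink(tf); unlink(dir, recursive = TRUE)
})
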