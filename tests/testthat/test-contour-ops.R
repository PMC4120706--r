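test_that("geometric mean is the exponential of the mean log frequency", {
  expect_equal(geometric_mean(formant_track(rep(500, 7))), 500)
  expect_equal(geometric_mean(formant_track(c(400, 900))), 600)
  expect_equal(geometric_mean(formant_track(c(250, 1000, 250, 1000))), 500)
  expect_error(geometric_mean(numeric(0)), "empty")
  expect_error(formant_track(c(500, -1)), "> 0")
})

test_that("depth scaling pivots on the geometric mean and leaves amplitudes alone", {
  tr <- formant_track(c(200, 800), amps = c(0.2, 0.9))
  flat <- scale_depth(tr, 0)
  expect_equal(flat$freqs, rep(400, 2))
  expect_equal(scale_depth(tr, 1)$freqs, tr$freqs)
  expect_equal(scale_depth(tr, 0.5)$freqs, 400 * c(0.5, 2)^0.5,
               tolerance = 1e-12)
  expect_equal(scale_depth(tr, 0.5)$amps, tr$amps)
  expect_error(scale_depth(tr, 1.2), "\\[0, 1\\]")
  expect_error(scale_depth(tr, -0.1), "\\[0, 1\\]")
})

test_that("depth scaling preserves the geometric mean and is log-linear", {
  set.seed(11)
  for (rep in 1:25) {
    tr <- random_track()
    g <- geometric_mean(tr)
    for (x in c(0, 0.25, 0.5, 0.75, 1)) {
      s <- scale_depth(tr, x)
      expect_lt(abs(geometric_mean(s) - g) / g, 1e-9)
      expect_equal(log(s$freqs / g), x * log(tr$freqs / g),
                   tolerance = 1e-12)
    }
  }
})

test_that("spectral inversion reflects about the geometric mean and is an involution", {
  tr <- formant_track(c(300, 1200))
  expect_equal(invert_about_gmean(tr)$freqs, c(1200, 300))
  g <- geometric_mean(tr)
  at_g <- formant_track(rep(g, 3))
  expect_equal(invert_about_gmean(at_g)$freqs, rep(g, 3))
  set.seed(12)
  for (rep in 1:20) {
    tr <- random_track()
    twice <- invert_about_gmean(invert_about_gmean(tr))
    expect_equal(twice$freqs, tr$freqs, tolerance = 1e-12)
    expect_equal(geometric_mean(invert_about_gmean(tr)),
                 geometric_mean(tr), tolerance = 1e-12)
  }
})

test_that("block smoothing averages non-overlapping blocks, partial block over its own length", {
  expect_equal(block_smooth(rep(3, 100), 40), rep(3, 3))
  expect_equal(block_smooth(1:80, 40), c(20.5, 60.5))
  expect_equal(block_smooth(1:50, 40), c(mean(1:40), mean(41:50)))
  expect_error(block_smooth(1:10, 0), ">= 1")
  expect_error(block_smooth(numeric(0)), "empty")
})

test_that("cycle estimation counts geometric-mean crossings plus one", {
  never <- estimate_cycles(c(510, 520, 515), g = 500, duration = 1)
  expect_equal(never$half_cycles, 1L)
  expect_equal(never$cycles, 0.5)
  expect_equal(never$period_T, 2)

  two <- estimate_cycles(c(510, 490, 510), g = 500, duration = 1)
  expect_equal(two$half_cycles, 3L)
  expect_equal(two$cycles, 1.5)

  # smooth contour crossing g exactly 3 times over 1 s
  t <- seq(0, 1, by = 0.001)
  dense <- 500 * exp(0.2 * cos(2 * pi * 1.5 * t))
  est <- estimate_cycles(dense, g = 500, duration = 1)
  expect_equal(est$cycles, 2)
  expect_equal(est$period_T, 0.5)

  # a sample exactly at g counts as positive (no spurious crossing)
  expect_equal(estimate_cycles(c(510, 500, 510), 500, 1)$half_cycles, 1L)
  expect_equal(estimate_cycles(c(490, 500, 490), 500, 1)$half_cycles, 3L)
})

test_that("cycle estimator is exact on noiseless log-sinusoids after block smoothing", {
  for (k in 1:20) {
    tr <- log_sinusoid_track(g = 1500, n_cycles = k, duration = 2)
    est <- estimate_cycles(block_smooth(tr$freqs, 40), 1500,
                           track_duration(tr))
    expect_equal(est$cycles, k)
    expect_equal(est$period_T, 2 / k, tolerance = 1e-12)
  }
})

test_that("triangle contour hits its closed-form peak and trough", {
  sp <- triangle_spec(g = 1200, r = log(4 / 3), period_T = 0.5,
                      start_phase = 0, scale_x = 1)
  tc <- triangle_contour(sp, duration = 1)
  expect_equal(tc$freqs[1], 1600)            # a_hat(0) = +1
  expect_equal(tc$freqs[251], 900)           # a_hat(T/2) = -1
  half <- triangle_spec(1200, log(4 / 3), 0.5, 0, 0.5)
  expect_equal(max(triangle_contour(half, 1)$freqs),
               1200 * (4 / 3)^0.5, tolerance = 1e-12)
  zero <- triangle_spec(1200, log(4 / 3), 0.5, 0.37, 0)
  expect_equal(triangle_contour(zero, 1)$freqs, rep(1200, 1000))
  expect_error(triangle_contour(sp, duration = 1e-5), "frame period")
})

test_that("triangle log-range equals 2xr when frames sample the peak and trough", {
  set.seed(13)
  for (rep in 1:20) {
    g <- runif(1, 800, 2000)
    r <- runif(1, 0.05, 0.5)
    x <- sample(c(0.25, 0.5, 0.75, 1), 1)
    T <- sample(5:40, 1) * 2 * 0.001       # even frame multiple: T/2 on-grid
    sp <- triangle_spec(g, r, T, start_phase = 0, scale_x = x)
    tc <- triangle_contour(sp, duration = 4 * T)
    lr <- max(log(tc$freqs / g)) - min(log(tc$freqs / g))
    expect_equal(lr, 2 * x * r, tolerance = 1e-12)
  }
})

test_that("triangle geometric mean matches g over whole periods, deviates for odd half-cycles", {
  sp <- triangle_spec(g = 1500, r = 0.3, period_T = 0.25,
                      start_phase = 0.3, scale_x = 1)
  tc <- triangle_contour(sp, duration = 1)   # 4 full periods
  expect_lt(abs(geometric_mean(tc) - 1500) / 1500, 1e-6)

  # odd half-cycle count: deviation nonzero, shrinking with cycle count
  dev_for <- function(n_half) {
    T <- 0.2
    tc <- triangle_contour(triangle_spec(1500, 0.3, T, 0.1, 1),
                           duration = n_half * T / 2)
    abs(geometric_mean(tc) - 1500)
  }
  expect_gt(dev_for(3), 0)
  expect_lt(dev_for(21), dev_for(3))
})

test_that("amplitude flattening replaces the contour with its RMS power", {
  tr <- formant_track(c(500, 600), amps = c(3, 4))
  flat <- flatten_amplitude(tr)
  expect_equal(flat$amps, rep(sqrt(12.5), 2))
  expect_equal(flat$freqs, tr$freqs)
  const <- formant_track(c(500, 600), amps = c(2, 2))
  expect_equal(flatten_amplitude(const)$amps, c(2, 2))
  zero <- formant_track(c(500, 600), amps = c(0, 0))
  expect_warning(out <- flatten_amplitude(zero), "degenerate")
  expect_equal(out$amps, c(0, 0))
})

test_that("minimum-separation check flags frames closer than the limit", {
  a <- formant_track(rep(500, 5))
  expect_length(check_min_separation(a, formant_track(rep(600, 5))), 0)
  expect_equal(check_min_separation(a, formant_track(rep(560, 5))), 1:5)
  expect_error(check_min_separation(a, formant_track(rep(600, 4))),
               "frame count")
  b <- formant_track(rep(600, 5), frame_period = 0.002)
  expect_error(check_min_separation(a, b), "frame period")
})
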