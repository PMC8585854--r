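test_that("bin-aligned sinusoids are recovered exactly", {
  t <- time_axis()
  fc <- fourier_component(make_trace(2 * sin(2 * pi * 12.5 * t)), 12.5)
  expect_equal(fc$bin_index, 12L)
  expect_equal(fc$amplitude_uV, 2, tolerance = 1e-12)
  expect_equal(fc$phase_rad, 0, tolerance = 1e-10)
  # constant trace has no energy at any non-DC bin
  flat <- fourier_component(make_trace(rep(3, 480)), 12.5)
  expect_equal(flat$amplitude_uV, 0, tolerance = 1e-12)
  # distinct bins are orthogonal: a two-tone mix separates exactly,
  # matching direct projection onto each tone
  mix <- 2 * sin(2 * pi * 12.5 * t + 0.4) + 1.5 * sin(2 * pi * 18.75 * t - 1)
  tr <- make_trace(mix)
  a12 <- fourier_component(tr, 12.5)
  a18 <- fourier_component(tr, 18.75)
  expect_equal(a12$amplitude_uV, 2, tolerance = 1e-12)
  expect_equal(a18$amplitude_uV, 1.5, tolerance = 1e-12)
  expect_equal(a12$phase_rad, 0.4, tolerance = 1e-10)
  expect_equal(a18$phase_rad, -1, tolerance = 1e-10)
  # direct projection oracle for the amplitude
  proj <- sqrt(sum(mix * sin(2 * pi * 12.5 * t))^2 +
                 sum(mix * cos(2 * pi * 12.5 * t))^2) * 2 / 480
  expect_equal(a12$amplitude_uV, proj, tolerance = 1e-12)
  expect_error(fourier_component(tr, 13), "not bin-aligned")
})

test_that("adjacent-bin noise estimate averages the neighbour amplitudes", {
  t <- time_axis()
  # bins 11 and 13 at known amplitudes around the bin-12 response
  x <- 0.2 * sin(2 * pi * (11 / 0.96) * t) + 0.4 * sin(2 * pi * (13 / 0.96) * t)
  expect_equal(noise_estimate(make_trace(x), 12.5), 0.3, tolerance = 1e-12)
  # a pure bin-aligned sinusoid leaks nothing into its neighbours
  pure <- make_trace(2 * sin(2 * pi * 12.5 * t + 1))
  expect_lt(noise_estimate(pure, 12.5), 1e-10)
  # frequency whose neighbour would be DC is refused
  expect_error(noise_estimate(make_trace(x, sweep_length_s = 0.96), 1 / 0.96),
               "DC")
})

test_that("noise-bin magnitude matches the Rayleigh closed form", {
  # white noise sd sigma: bin amplitude 2|X_k|/N is Rayleigh with scale
  # sigma*sqrt(2/N), mean sigma*sqrt(pi/N)
  sigma <- 1.5; n <- 480
  set.seed(31)
  est <- replicate(300, noise_estimate(make_trace(rnorm(n, 0, sigma)), 12.5))
  expected <- sigma * sqrt(pi / n)
  # the two averaged bins are independent, so var is half the Rayleigh var
  ray_var <- (2 - pi / 2) * sigma^2 * 2 / n / 2
  mc_se <- sqrt(ray_var / 300)
  expect_lt(abs(mean(est) - expected), 3 * mc_se)
})

test_that("noise correction and SNR follow their definitions", {
  expect_equal(noise_correct(2.0, 0.3), 1.7)
  expect_equal(noise_correct(0.2, 0.3), 0)
  expect_equal(noise_correct(2.0, 0.3, "power"), sqrt(4 - 0.09))
  expect_equal(noise_correct(0.2, 0.3, "power"), 0)
  expect_equal(noise_correct(1.4, 0), 1.4)
  expect_equal(noise_correct(1.4, 0, "power"), 1.4)
  expect_error(noise_correct(1, 0.1, "median"))
  expect_equal(snr(2, 0.5), 4)
  expect_equal(snr(0, 0.5), 0)
  expect_identical(snr(1, 0), Inf)
  # corrected amplitude monotone: non-increasing in noise, non-decreasing
  # in amplitude, never exceeding the raw amplitude
  for (m in c("linear", "power")) {
    a <- seq(0, 3, by = 0.25)
    expect_true(all(diff(noise_correct(a, 0.4, m)) >= 0))
    nz <- seq(0, 2, by = 0.2)
    expect_true(all(diff(noise_correct(1.8, nz, m)) <= 0))
    expect_true(all(noise_correct(a, 0.4, m) <= a))
  }
})

test_that("spectral amplitudes satisfy Parseval on a random trace", {
  set.seed(8)
  x <- rnorm(480)
  X <- stats::fft(x)
  n <- length(x)
  amps <- 2 * Mod(X[2:(n / 2)]) / n          # peak amplitudes, bins 1..N/2-1
  dc <- Mod(X[1]) / n
  nyq <- Mod(X[n / 2 + 1]) / n
  expect_equal(mean(x^2), dc^2 + sum(amps^2) / 2 + nyq^2, tolerance = 1e-9)
})

test_that("phase converts to the unique response time in the window", {
  # half-period antiphase at 12.5 rps
  rt <- phase_to_response_time(pi, 12.5)
  expect_equal(rt$time_ms, 40, tolerance = 1e-9)
  # a delay below the window is pushed up by exactly one period
  rt2 <- phase_to_response_time(-2 * pi * 18.75 * 0.020, 18.75)
  expect_equal(rt2$time_ms, 20 + 1000 / 18.75, tolerance = 1e-9)
  expect_equal(rt2$cycles_added, 1L)
  # result invariant under adding whole turns to the phase
  for (k in -2:2) {
    rtk <- phase_to_response_time(1.1 + 2 * pi * k, 18.75)
    expect_equal(rtk$time_ms, phase_to_response_time(1.1, 18.75)$time_ms,
                 tolerance = 1e-9)
  }
  # window membership for random phases and both rates
  set.seed(13)
  for (f in c(12.5, 18.75)) {
    period <- 1000 / f
    for (phi in runif(50, -10, 10)) {
      r <- phase_to_response_time(phi, f)
      expect_gte(r$time_ms, 30)
      expect_lt(r$time_ms, 30 + period)
    }
  }
})

test_that("generated delays round-trip through spectral and timing", {
  for (f in c(12.5, 18.75)) {
    for (delay in c(33, 40, 53.2, 70)) {
      period <- 1000 / f
      b <- generate_sweep_block(2, delay, stimulus_condition(0.8, f),
                                noiseless_model(), n_sweeps = 2, seed = 1)
      tr <- preprocess_block(b, min_sweeps = 1)
      sc <- spectral_component(tr, f)
      rt <- phase_to_response_time(sc$phase_rad, f)
      expected <- delay
      while (expected >= 30 + period) expected <- expected - period
      while (expected < 30) expected <- expected + period
      expect_equal(rt$time_ms, expected, tolerance = 1e-6)
      expect_equal(sc$corrected_amplitude_uV, 2, tolerance = 1e-9)
    }
  }
})
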