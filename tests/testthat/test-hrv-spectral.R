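uniform_from <- function(values, rate = 4) {
  structure(
    list(values = values, times = (seq_along(values) - 1) / rate,
         rate = rate, detrended = TRUE),
    class = "uniform_rr"
  )
}

test_that("resampling preserves constant and monotone tachograms", {
  bt <- cumsum(c(0, rep(0.8, 50)))
  u <- resample_uniform(beat_series(bt, source = "annotated"))
  expect_equal(u$rate, 4)
  expect_true(all(abs(u$values - 800) < 1e-6))

  rr <- seq(800, 1000, length.out = 50)
  bt2 <- cumsum(c(0, rr / 1000))
  u2 <- resample_uniform(beat_series(bt2, source = "annotated"))
  interior <- u2$values[u2$times > bt2[2] & u2$times < bt2[50]]
  expect_true(all(diff(interior) > -1e-6))
  expect_error(resample_uniform(beat_series(c(0, 1, 2), source = "annotated")), "4 beats")
})

test_that("a 0.1 Hz RR modulation lands on the right periodogram bin", {
  t_beats <- cumsum(c(0, rep(0.8, 800)))
  rr <- 800 + 50 * sin(2 * pi * 0.1 * t_beats[-1])
  bt <- cumsum(c(0, rr / 1000))
  u <- resample_uniform(beat_series(bt, source = "annotated"))
  f_peak <- peak_freq(u$values, u$rate)
  expect_lt(abs(f_peak - 0.1), u$rate / length(u$values) + 1e-9)
})

test_that("quadratic detrending removes polynomial structure exactly", {
  t <- (0:999) / 4
  u <- uniform_from(3 + 0.5 * t - 0.01 * t^2)
  d <- detrend_quadratic(u)
  expect_lt(max(abs(d$values)), 1e-8)
  # residual orthogonal to the quadratic design
  set.seed(1)
  u2 <- uniform_from(rnorm(1000) + 0.2 * t + 0.001 * t^2)
  r <- detrend_quadratic(u2)$values
  tc <- t - mean(t)
  for (basis in list(rep(1, 1000), tc, tc^2)) {
    expect_lt(abs(sum(r * basis)) / sqrt(sum(basis^2)), 1e-6)
  }
})

test_that("detrending keeps an embedded oscillation intact", {
  t <- (0:2399) / 4
  tone <- 40 * sin(2 * pi * 0.1 * t)
  u <- uniform_from(tone + 900 + 0.05 * t - 1e-5 * t^2)
  d <- detrend_quadratic(u)
  frac_before <- band_power_fraction(tone, 4, 0.08, 0.12)
  frac_after <- band_power_fraction(d$values, 4, 0.08, 0.12)
  p_tone <- mean(tone^2)
  p_resid <- mean(d$values^2)
  expect_lt(abs(p_resid - p_tone) / p_tone, 0.05)
  expect_gt(frac_after, 0.95 * frac_before)
})

test_that("Welch integral recovers white-noise variance (Parseval)", {
  ratios <- vapply(1:20, function(s) {
    set.seed(s)
    u <- uniform_from(rnorm(2400, sd = 30))
    psd <- welch_psd(u)
    trapz_est <- sum(diff(psd$freq) * (psd$density[-1] + psd$density[-length(psd$density)]) / 2)
    trapz_est / (30^2)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.10)
})

test_that("a pure 0.25 Hz tone concentrates its Welch power at 0.25 Hz", {
  t <- (0:2399) / 4
  u <- uniform_from(35 * sin(2 * pi * 0.25 * t))
  psd <- welch_psd(u)
  near <- psd$freq >= 0.23 & psd$freq <= 0.27
  frac <- band_integral(psd$freq, psd$density, 0.23, 0.27) /
    band_integral(psd$freq, psd$density, 0, 2)
  expect_gt(frac, 0.90)
  expect_true(any(near))
})

test_that("zero input gives an identically zero density", {
  u <- uniform_from(rep(0, 2400))
  expect_true(all(welch_psd(u)$density == 0))
  expect_error(welch_psd(uniform_from(rep(0, 100))), "shorter")
})

test_that("welch with a full-length window equals one modified periodogram", {
  set.seed(11)
  u <- uniform_from(rnorm(1200))
  psd <- welch_psd(u, window_s = 300)
  expect_equal(psd$n_segments, 1L)
  n <- 1200
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  p <- Mod(fft(u$values * w)[1:(n / 2 + 1)])^2 / (4 * sum(w^2))
  p[2:(n / 2)] <- 2 * p[2:(n / 2)]
  expect_equal(psd$density, p, tolerance = 1e-10)
})

test_that("band powers assign tones, ratios, and logs correctly", {
  t <- (0:2399) / 4
  hf_tone <- uniform_from(30 * sin(2 * pi * 0.25 * t))
  sm <- band_powers(welch_psd(hf_tone))
  expect_gt(sm$power_hf, 50 * sm$power_lf)
  expect_gt(sm$power_hf, 50 * sm$power_vlf)

  two <- uniform_from(30 * sin(2 * pi * 0.1 * t) + 30 * sin(2 * pi * 0.3 * t))
  sm2 <- band_powers(welch_psd(two))
  expect_lt(abs(sm2$lf_hf_ratio - 1), 0.15)

  zero <- band_powers(welch_psd(uniform_from(rep(0, 2400))))
  expect_true(is.na(zero$ln_vlf) && is.na(zero$ln_hf))
})

test_that("white noise splits between bands in proportion to bandwidth", {
  ratios <- vapply(1:20, function(s) {
    set.seed(s)
    sm <- band_powers(welch_psd(uniform_from(rnorm(2400, sd = 25))))
    sm$vlf_over_lf_plus_hf
  }, numeric(1))
  expected <- (0.04 - 0.0033) / (0.5 - 0.04)
  expect_lt(abs(mean(ratios) - expected) / expected, 0.5)
})

test_that("spectral summary scales quadratically and SDNN linearly", {
  ep <- generate_rr_series(episode_spec("noPSH", duration = 660,
                                        onset_time = 600, seed = 13))
  bs <- beat_series(ep$beat_times, source = "synthetic")
  u <- detrend_quadratic(resample_uniform(bs))
  sm1 <- band_powers(welch_psd(u))
  u2 <- u
  u2$values <- u$values * 3
  sm3 <- band_powers(welch_psd(u2))
  expect_equal(sm3$power_lf / sm1$power_lf, 9, tolerance = 1e-6)
  expect_equal(sm3$power_total / sm1$power_total, 9, tolerance = 1e-6)

  td1 <- time_domain(bs)
  bs2 <- beat_series(bs$beat_times[1] + cumsum(c(0, bs$rr_ms * 2)) / 1000,
                     source = "synthetic")
  td2 <- time_domain(bs2)
  expect_equal(td2$sdnn / td1$sdnn, 2, tolerance = 1e-9)

  total <- band_integral(welch_psd(u)$freq, welch_psd(u)$density, 0, 0.5)
  expect_lte(sm1$power_vlf + sm1$power_lf + sm1$power_hf, total * (1 + 1e-9))
})

test_that("time-domain summary matches hand-computed values", {
  bt <- cumsum(c(0, rep(0.5, 40)))
  td <- time_domain(beat_series(bt, source = "annotated"))
  expect_equal(td$mean_hr, 120)
  expect_equal(td$max_hr, 120)
  expect_equal(td$sdnn, 0)

  rr <- rep(c(600, 1000), 30)
  td2 <- time_domain(beat_series(cumsum(c(0, rr / 1000)), source = "annotated"))
  expect_equal(td2$sdnn, 200)

  short <- beat_series(cumsum(c(0, rep(0.8, 5))), source = "annotated")
  expect_warning(td3 <- time_domain(short), "10")
  expect_true(is.na(td3$mean_hr))
})

test_that("synthetic PSH event window reaches the expected mean heart rate", {
  ep <- generate_rr_series(episode_spec("PSH", seed = 19))
  bs <- beat_series(ep$beat_times, source = "synthetic")
  ev <- segment_windows(bs, 1200)$Event
  td <- time_domain(ev)
  expect_gt(td$mean_hr, 118)
  expect_lt(td$mean_hr, 128)
  expect_gte(td$max_hr, td$mean_hr)
})
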