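test_that("smoothing coefficient follows the exponential design formula", {
  cfg <- lowpass_config(500, 10000)
  expect_equal(cfg$a, exp(-0.1 * pi), tolerance = 1e-12)
  # strictly decreasing in fc, bounded below by exp(-pi) on the valid range
  fcs <- seq(10, 4990, by = 10)
  as <- vapply(fcs, function(f) lowpass_config(f, 10000)$a, numeric(1))
  expect_true(all(diff(as) < 0))
  expect_true(all(as > exp(-pi) & as < 1))
  expect_error(lowpass_config(0, 10000), "Nyquist|between")
  expect_error(lowpass_config(5000, 10000), "Nyquist|between")
})

test_that("filter has unit DC gain and the stated one-sample-delay recursion", {
  cfg <- lowpass_config(100, 10000)
  a <- cfg$a
  const <- emg_recording(rep(1.5, 4000), 10000)
  out <- emg_lowpass(const, cfg)
  expect_equal(out$voltage_mv[4000], 1.5, tolerance = 1e-12)

  # unit impulse at n = 0: v_o = [init, (1-a), (1-a)a, (1-a)a^2, ...]
  imp <- emg_recording(c(1, numeric(99)), 10000)
  h <- emg_lowpass(imp, cfg)$voltage_mv
  expect_equal(h[1], 0)
  expect_equal(h[2], 1 - a, tolerance = 1e-14)
  expect_equal(h[3:100], (1 - a) * a^(1:98), tolerance = 1e-12)

  # explicit initial output honored
  h2 <- emg_lowpass(imp, cfg, initial_output = 2)$voltage_mv
  expect_equal(h2[1], 2)
  expect_equal(h2[2], a * 2 + (1 - a) * 1, tolerance = 1e-14)
})

test_that("measured sinusoidal attenuation matches the closed-form response", {
  fs <- 10000
  cfg <- lowpass_config(10, fs)
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- emg_recording(sin(2 * pi * 60 * t), fs)
  y <- emg_lowpass(x, cfg)$voltage_mv
  steady <- y[(length(y) / 2):length(y)] # past the transient
  meas <- (max(steady) - min(steady)) / 2
  expect_equal(meas, lowpass_gain(cfg, 60), tolerance = 0.01)

  # and at 10x the cutoff for a second cutoff choice
  cfg2 <- lowpass_config(50, fs)
  x2 <- emg_recording(sin(2 * pi * 500 * t), fs)
  y2 <- emg_lowpass(x2, cfg2)$voltage_mv
  steady2 <- y2[(length(y2) / 2):length(y2)]
  meas2 <- (max(steady2) - min(steady2)) / 2
  expect_equal(meas2, lowpass_gain(cfg2, 500), tolerance = 0.01)
})

test_that("spectrum satisfies Parseval and localizes integer-bin sinusoids", {
  fs <- 10000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs) # N = 10000, 60 Hz is an exact bin
  rec <- emg_recording(sin(2 * pi * 60 * t), fs)
  sp <- emg_spectrum(rec)
  expect_equal(attr(sp, "time_energy"), attr(sp, "freq_energy"),
    tolerance = 1e-9
  )
  expect_equal(sp$freq_hz[which.max(sp$energy)], 60)
  # all energy in that single bin
  expect_gte(sp$energy[sp$freq_hz == 60] / sum(sp$energy), 1 - 1e-9)

  dc <- emg_spectrum(emg_recording(rep(2, 1000), fs))
  expect_gte(dc$energy[1] / sum(dc$energy), 1 - 1e-12)

  # Parseval on odd-length noise too
  set.seed(2)
  spn <- emg_spectrum(emg_recording(rnorm(999), fs))
  expect_equal(attr(spn, "time_energy"), attr(spn, "freq_energy"),
    tolerance = 1e-9
  )
  expect_equal(attr(spn, "time_energy"), sum(spn$energy), tolerance = 1e-9)

  expect_error(emg_spectrum(emg_recording(1)), "at least 2")
  bad <- tibble::tibble(time_s = c(0, 1e-4, 5e-4), voltage_mv = c(1, 2, 3))
  expect_error(emg_spectrum(bad), "uniform")
})

test_that("dominant frequency picks the strongest non-DC component", {
  fs <- 10000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  two <- emg_recording(sin(2 * pi * 50 * t) + 2 * sin(2 * pi * 120 * t), fs)
  expect_equal(dominant_frequency(emg_spectrum(two)), 120)

  # exact tie resolves to the lower frequency
  tie <- emg_recording(sin(2 * pi * 50 * t) + sin(2 * pi * 120 * t), fs)
  expect_equal(dominant_frequency(emg_spectrum(tie)), 50)

  sp <- emg_spectrum(two)
  expect_error(dominant_frequency(sp, exclude_below_hz = 6000), "excluded")
  # DC excluded by default
  dcsig <- emg_recording(5 + 0.1 * sin(2 * pi * 30 * t), fs)
  expect_equal(dominant_frequency(emg_spectrum(dcsig)), 30)
})

test_that("cutoff tuning places fc by the geometric-mean policy", {
  fs <- 10000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  hum <- emg_recording(0.5 * sin(2 * pi * 2000 * t), fs)
  cfg <- tune_cutoff(emg_spectrum(hum))
  expect_equal(cfg$fc_hz, sqrt(450 * 2000), tolerance = 1e-9)

  # no out-of-band peak: cutoff defaults to the band edge
  inband <- emg_recording(0.5 * sin(2 * pi * 100 * t), fs)
  expect_warning(cfg2 <- tune_cutoff(emg_spectrum(inband)), "inside")
  expect_equal(cfg2$fc_hz, 450)

  flat <- emg_recording(rep(0, 100), fs)
  expect_error(tune_cutoff(emg_spectrum(flat)), "Degenerate")
})
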