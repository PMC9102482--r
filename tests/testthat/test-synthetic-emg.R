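test_that("equal seeds give bit-identical sessions", {
  a <- emg_contraction("SMP5", seed = 11, sample_rate_hz = FS_FAST)
  b <- emg_contraction("SMP5", seed = 11, sample_rate_hz = FS_FAST)
  expect_identical(a$recording$voltage_mv, b$recording$voltage_mv)
  expect_identical(a$events, b$events)
  c2 <- emg_contraction("SMP5", seed = 12, sample_rate_hz = FS_FAST)
  expect_false(identical(a$recording$voltage_mv, c2$recording$voltage_mv))
})

test_that("a contraction spans its planned duration between rest pauses", {
  s <- emg_contraction("SMP5", seed = 3, sample_rate_hz = FS_FAST)
  expect_equal(nrow(s$events), 1)
  expect_equal(s$events$start_s, 5) # 5 s leading rest
  dur <- s$events$end_s - s$events$start_s
  expect_gte(dur, 5 * 0.85) # +/- 15% duration jitter
  expect_lte(dur, 5 * 1.15)
  total <- nrow(s$recording) / FS_FAST
  expect_equal(total - s$events$end_s, 5, tolerance = 1e-6) # trailing rest
})

test_that("samples stay within the amplitude bound plus the noise margin", {
  for (amp in c(0.5, 5)) {
    s <- emg_contraction("SMP5",
      seed = 4, amplitude_mv = amp,
      sample_rate_hz = FS_FAST
    )
    expect_lte(max(abs(s$recording$voltage_mv)), amp + 0.2)
  }
  # NIM activity is bounded by 40% of the voluntary amplitude plus the
  # rest-noise and baseline-wander margin
  n <- emg_contraction("NIM", seed = 4, sample_rate_hz = FS_FAST)
  expect_lte(max(abs(n$recording$voltage_mv)), 0.4 + 0.2)
})

test_that("session concatenation yields ordered labels and total length", {
  s <- fast_session(c("SMP", "SMP3", "SMP5"), seed = 5)
  expect_equal(s$events$class, c("SMP", "SMP3", "SMP5"))
  expect_true(all(diff(s$events$start_s) > 0))
  expect_true(all(s$events$end_s > s$events$start_s))
  # balanced multi-class session: one ground-truth interval per planned burst
  s40 <- fast_session(c("SMP", "SMP3", "SMP5", "NIM"), reps = 10, seed = 42)
  expect_equal(nrow(s40$events), 40)
})

test_that("degenerate plans are rejected", {
  expect_error(emg_generate(tibble::tibble()), "non-empty")
  expect_error(
    emg_generate(
      tibble::tibble(
        class = "SMP", duration_s = -1, rest_s = 5, amplitude_mv = 1
      )
    ),
    "positive"
  )
  expect_error(emg_contraction("SMP", amplitude_mv = 0), "0, 5")
  expect_error(emg_contraction("SMP", amplitude_mv = 9), "0, 5")
  expect_error(emg_contraction("XXX"), "Unknown")
})

test_that("mixed sample rates cannot be concatenated", {
  a <- emg_contraction("SMP", seed = 1, sample_rate_hz = 2000)
  b <- emg_contraction("SMP", seed = 1, sample_rate_hz = 4000)
  expect_error(emg_bind_sessions(list(a, b)), "mixed sample rates")
  ab <- emg_bind_sessions(list(a, a))
  expect_equal(nrow(ab$recording), 2 * nrow(a$recording))
  expect_equal(nrow(ab$events), 2)
})

test_that("labeled intervals capture the above-threshold envelope energy", {
  s <- fast_session(c("SMP", "SMP3", "SMP5"), reps = 2, seed = 6)
  v <- s$recording$voltage_mv
  fs <- emg_sample_rate(s$recording)
  env <- sqrt(as.numeric(stats::filter(v^2, rep(1 / 200, 200), sides = 2)))
  env[is.na(env)] <- 0
  thr <- 3 * stats::median(env, na.rm = TRUE)
  hot <- env > thr
  e_total <- sum(env[hot]^2)
  t <- s$recording$time_s
  inside <- rep(FALSE, length(t))
  for (i in seq_len(nrow(s$events))) {
    inside <- inside | (t >= s$events$start_s[i] & t <= s$events$end_s[i])
  }
  expect_gte(sum(env[hot & inside]^2) / e_total, 0.9)
})

test_that("burst power is concentrated in the stated 20-450 Hz band", {
  s <- emg_generate(
    emg_session_plan("SMP5", reps = 2),
    seed = 7, sample_rate_hz = 10000
  )
  for (i in seq_len(nrow(s$events))) {
    idx <- round(s$events$start_s[i] * 1e4):round(s$events$end_s[i] * 1e4)
    sp <- emg_spectrum(emg_recording(s$recording$voltage_mv[idx]))
    frac <- sum(sp$energy[sp$freq_hz >= 20 & sp$freq_hz <= 450]) /
      sum(sp$energy)
    expect_gte(frac, 0.95)
  }
})

test_that("NIM windows hold erratic low-amplitude activity, not a sustained burst", {
  s <- emg_contraction("NIM", seed = 8, sample_rate_hz = FS_FAST)
  idx <- round(s$events$start_s * FS_FAST):round(s$events$end_s * FS_FAST)
  v <- s$recording$voltage_mv[idx]
  burst <- emg_contraction("SMP5", seed = 8, sample_rate_hz = FS_FAST)
  bidx <- round(burst$events$start_s * FS_FAST):round(burst$events$end_s * FS_FAST)
  # well below voluntary amplitude
  expect_lt(sqrt(mean(v^2)), 0.5 * sqrt(mean(burst$recording$voltage_mv[bidx]^2)))
})

test_that("interference injection behaves as stated", {
  s <- emg_contraction("NIM",
    seed = 9, duration_s = 1, rest_before_s = 1,
    rest_after_s = 1, sample_rate_hz = FS_FAST
  )
  rec <- s$recording
  same <- emg_inject_interference(rec, 60, 0, 0)
  expect_equal(same$voltage_mv, rec$voltage_mv)

  shifted <- emg_inject_interference(rec, 60, 0, dc_mv = 1)
  expect_equal(mean(shifted$voltage_mv) - mean(rec$voltage_mv), 1,
    tolerance = 1e-12
  )

  # rest-only recording + 60 Hz pickup: spectrum dominated by the 60 Hz bin
  rest <- emg_recording(rec$voltage_mv * 0.01, FS_FAST)
  noisy <- emg_inject_interference(rest, 60, 0.2)
  expect_equal(dominant_frequency(emg_spectrum(noisy)), 60, tolerance = 1)

  expect_error(emg_inject_interference(rec, FS_FAST / 2, 0.1), "Nyquist")
})
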