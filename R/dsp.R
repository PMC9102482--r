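#' First-order digital low-pass filter configuration
#'
#' The filter is the discretization of an RC low-pass: with cutoff `fc` and
#' sampling period `T = 1/fs`, the smoothing coefficient is
#' `a = exp(-2 * pi * fc * T)` and the difference equation is
#' `v_o[n] = a * v_o[n-1] + (1 - a) * v_in[n-1]`. One sample of input delay is
#' inherent to the recursion and is kept exactly.
#'
#' @param fc_hz Cutoff frequency in Hz, in (0, Nyquist).
#' @param sample_rate_hz Sampling rate in Hz.
#' @return A `lowpass_config` list with `fc_hz`, `sample_rate_hz`, `a`.
#' @export
#' @examples
#' lowpass_config(500, 10000)$a # exp(-0.1 * pi)
lowpass_config <- function(fc_hz, sample_rate_hz = 10000) {
  if (!is.numeric(fc_hz) || length(fc_hz) != 1 || !is.finite(fc_hz)) {
    rlang::abort("`fc_hz` must be a finite scalar.")
  }
  if (fc_hz <= 0 || fc_hz >= sample_rate_hz / 2) {
    rlang::abort("`fc_hz` must lie strictly between 0 and Nyquist.")
  }
  a <- exp(-2 * pi * fc_hz / sample_rate_hz)
  structure(
    list(fc_hz = fc_hz, sample_rate_hz = sample_rate_hz, a = a),
    class = "lowpass_config"
  )
}

#' @export
print.lowpass_config <- function(x, ...) {
  cat(sprintf(
    "<lowpass_config> fc = %g Hz, fs = %g Hz, a = %.6f\n",
    x$fc_hz, x$sample_rate_hz, x$a
  ))
  invisible(x)
}

#' Theoretical magnitude response of the first-order low-pass
#'
#' `|H(e^{j w T})| = (1 - a) / |e^{j w T} - a|` (the one-sample input delay
#' contributes only phase).
#'
#' @param cfg A [lowpass_config()].
#' @param freq_hz Frequencies at which to evaluate (Hz).
#' @return Magnitude gains.
#' @export
lowpass_gain <- function(cfg, freq_hz) {
  w <- 2 * pi * freq_hz / cfg$sample_rate_hz
  (1 - cfg$a) / Mod(exp(1i * w) - cfg$a)
}

#' Apply the first-order low-pass filter
#'
#' Causal application of `v_o[n] = a v_o[n-1] + (1-a) v_in[n-1]` over the full
#' series. The first output sample equals `initial_output`.
#'
#' @param rec A recording.
#' @param cfg A [lowpass_config()], or a cutoff frequency in Hz.
#' @param initial_output Value of the first output sample (default 0).
#' @return A filtered recording of the same length and rate.
#' @export
#' @examples
#' s <- emg_contraction("SMP", seed = 1, rest_before_s = 1, rest_after_s = 1)
#' f <- emg_lowpass(s$recording, 500)
emg_lowpass <- function(rec, cfg, initial_output = 0) {
  check_recording(rec)
  sr <- emg_sample_rate(rec)
  if (is.numeric(cfg)) {
    cfg <- lowpass_config(cfg, sr)
  }
  if (!inherits(cfg, "lowpass_config")) {
    rlang::abort("`cfg` must be a lowpass_config or a cutoff frequency.")
  }
  v <- rec$voltage_mv
  n <- length(v)
  a <- cfg$a
  if (n == 1) {
    out <- initial_output
  } else {
    drive <- (1 - a) * v[-n]
    out <- c(
      initial_output,
      as.numeric(stats::filter(drive, a, method = "recursive",
        init = initial_output
      ))
    )
  }
  res <- emg_recording(out, sample_rate_hz = sr, start_time_s = rec$time_s[1])
  res
}

#' Magnitude spectrum of a recording
#'
#' One-sided DFT magnitude spectrum over `[0, Nyquist]` with per-bin energy
#' accounting. Parseval's identity (`sum(v^2) == sum(|X|^2)/N`) holds to
#' machine precision and is carried in the attributes for verification.
#'
#' @param rec A recording (uniformly sampled; checked).
#' @param window `"rectangular"` (default, plain DFT) or `"hann"`.
#' @return A tibble of class `emg_spectrum` with columns `freq_hz`,
#'   `magnitude`, `energy`; attributes `sample_rate_hz`, `time_energy`,
#'   `freq_energy`.
#' @export
#' @examples
#' rec <- emg_recording(sin(2 * pi * 60 * seq(0, 1, by = 1e-4)))
#' sp <- emg_spectrum(rec)
#' dominant_frequency(sp)
emg_spectrum <- function(rec, window = c("rectangular", "hann")) {
  check_recording(rec)
  window <- match.arg(window)
  if (nrow(rec) < 2) {
    rlang::abort("Spectrum needs at least 2 samples.")
  }
  sr <- emg_sample_rate(rec) # errors on non-uniform sampling
  v <- rec$voltage_mv
  if (window == "hann") {
    n <- length(v)
    v <- v * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  }
  n <- length(v)
  X <- stats::fft(v)
  e_full <- Mod(X)^2 / n
  n_half <- floor(n / 2) + 1
  idx <- seq_len(n_half)
  # fold negative frequencies onto the positive axis
  energy <- e_full[idx]
  interior <- idx > 1 & idx < n_half
  if (n %% 2 == 0) {
    energy[interior] <- energy[interior] + rev(e_full[(n_half + 1):n])
  } else {
    interior <- idx > 1
    energy[interior] <- energy[interior] + rev(e_full[(n_half + 1):n])
  }
  out <- tibble::tibble(
    freq_hz = (idx - 1) * sr / n,
    magnitude = Mod(X)[idx],
    energy = energy
  )
  attr(out, "sample_rate_hz") <- sr
  attr(out, "time_energy") <- sum(v^2)
  attr(out, "freq_energy") <- sum(e_full)
  class(out) <- c("emg_spectrum", class(out))
  out
}

#' Dominant (noise) frequency of a spectrum
#'
#' Returns the bin center carrying maximal energy above an exclusion floor.
#' By default only the DC bin is excluded, so the dominant component of a
#' rest recording with injected mains pickup is the mains frequency. Ties are
#' broken toward the lower frequency.
#'
#' @param spec An [emg_spectrum()].
#' @param exclude_below_hz Ignore bins strictly below this frequency; `NULL`
#'   (default) excludes only DC.
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(spec, exclude_below_hz = NULL) {
  if (!inherits(spec, "emg_spectrum") &&
    !all(c("freq_hz", "energy") %in% names(spec))) {
    rlang::abort("`spec` must be an emg_spectrum.")
  }
  keep <- if (is.null(exclude_below_hz)) {
    spec$freq_hz > 0
  } else {
    spec$freq_hz >= exclude_below_hz
  }
  if (!any(keep)) {
    rlang::abort("All spectrum bins are excluded.")
  }
  f <- spec$freq_hz[keep]
  e <- spec$energy[keep]
  f[which.max(e)] # which.max takes the first maximum: lower frequency wins
}

#' Tune the low-pass cutoff from a measured spectrum
#'
#' Locates the dominant interference component and places the cutoff
#' frequency. If the interference lies above the signal band, the cutoff is
#' the geometric mean of the band edge and the interference frequency
#' (log-midway between passband and stopband); if no out-of-band component
#' dominates, the cutoff defaults to the band edge. Interference inside the
#' band cannot be removed by a low-pass; the cutoff stays at the band edge
#' and a warning is emitted.
#'
#' @param spec An [emg_spectrum()].
#' @param signal_band_hz Two-element signal band (default 20-450 Hz).
#' @param exclude_below_hz Passed to [dominant_frequency()].
#' @return A [lowpass_config()].
#' @export
#' @examples
#' rec <- emg_recording(0.05 * sin(2 * pi * 2000 * seq(0, 1, by = 1e-4)))
#' tune_cutoff(emg_spectrum(rec))$fc_hz # sqrt(450 * 2000)
tune_cutoff <- function(spec, signal_band_hz = c(20, 450),
                        exclude_below_hz = NULL) {
  sr <- attr(spec, "sample_rate_hz")
  if (is.null(sr)) {
    rlang::abort("`spec` must carry a sample_rate_hz attribute.")
  }
  if (all(spec$energy == 0)) {
    rlang::abort("Degenerate spectrum: no energy in any bin.")
  }
  f_noise <- dominant_frequency(spec, exclude_below_hz)
  edge <- signal_band_hz[2]
  if (f_noise > edge) {
    fc <- sqrt(edge * f_noise)
  } else {
    if (f_noise >= signal_band_hz[1]) {
      rlang::warn(sprintf(
        "Dominant component at %.1f Hz lies inside the signal band; cutoff kept at the band edge.",
        f_noise
      ))
    }
    fc <- edge
  }
  lowpass_config(min(fc, 0.499 * sr), sr)
}
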