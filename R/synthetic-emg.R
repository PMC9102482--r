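#' Contraction classes
#'
#' The four signal classes recognized by the interface: a sharp ~1 s muscle
#' pulse (SMP), smooth pulses sustained for 3 s (SMP3) and 5 s (SMP5), and a
#' noise / involuntary-movement class (NIM) covering rest and erratic
#' non-voluntary activity. Integer labels are fixed: NIM = 0, SMP = 1,
#' SMP3 = 2, SMP5 = 3.
#'
#' @return A tibble with columns `class`, `label`, `nominal_duration_s`.
#' @export
#' @examples
#' contraction_classes()
contraction_classes <- function() {
  tibble::tibble(
    class = c("NIM", "SMP", "SMP3", "SMP5"),
    label = 0:3,
    nominal_duration_s = c(NA_real_, 1, 3, 5)
  )
}

class_label <- function(class) {
  cc <- contraction_classes()
  i <- match(class, cc$class)
  if (anyNA(i)) {
    rlang::abort(paste0(
      "Unknown contraction class: ",
      paste(setdiff(class, cc$class), collapse = ", ")
    ))
  }
  cc$label[i]
}

nominal_duration <- function(class) {
  cc <- contraction_classes()
  d <- cc$nominal_duration_s[match(class, cc$class)]
  # NIM has no protocol duration; its activity window defaults to 5 s
  d[is.na(d)] <- 5
  d
}

with_local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Band-limited unit-RMS surrogate noise, hard-limited at +/- 3 so that an
# envelope of A/3 bounds samples by A. The Butterworth band-pass is applied
# twice in cascade (squared magnitude response: the -3 dB design edges become
# -6 dB, keeping >= 95% of the power inside the stated band) through
# stats::filter (C level), numerically identical to signal::filter per pass
# but much faster on session-length series.
bandlimited_noise <- function(n, sample_rate_hz, band_hz) {
  x <- stats::rnorm(n)
  ny <- sample_rate_hz / 2
  lo <- max(band_hz[1], 1e-3) / ny
  hi <- min(band_hz[2], 0.999 * ny) / ny
  bf <- signal::butter(4, c(lo, hi), type = "pass")
  nb <- length(bf$b)
  one_pass <- function(v) {
    u <- stats::filter(c(numeric(nb - 1), v), bf$b,
      method = "convolution", sides = 1
    )
    u <- u[-seq_len(nb - 1)]
    as.numeric(stats::filter(u, -bf$a[-1], method = "recursive"))
  }
  x <- one_pass(one_pass(x))
  x <- x / stats::sd(x)
  pmin(pmax(x, -3), 3)
}

trapezoid <- function(n, n_ramp) {
  if (n <= 0) {
    return(numeric(0))
  }
  n_ramp <- min(n_ramp, floor(n / 2))
  env <- rep(1, n)
  if (n_ramp > 0) {
    ramp <- seq_len(n_ramp) / n_ramp
    env[seq_len(n_ramp)] <- ramp
    env[n - n_ramp + seq_len(n_ramp)] <- rev(ramp)
  }
  env
}

# Envelope (in mV RMS units) for one plan row, plus the truth interval
# relative to the row start. Uses the current RNG stream.
row_envelope <- function(class, duration_s, rest_before_s, rest_after_s,
                         amplitude_mv, jitter, rest_noise_rms_mv,
                         sample_rate_hz, ramp_s) {
  fs <- sample_rate_hz
  if (class != "NIM" && jitter > 0) {
    duration_s <- duration_s * (1 + stats::runif(1, -jitter, jitter))
  }
  n_pre <- round(rest_before_s * fs)
  n_act <- round(duration_s * fs)
  n_post <- round(rest_after_s * fs)
  env <- rep(rest_noise_rms_mv, n_pre + n_act + n_post)
  wander <- numeric(length(env))
  if (class == "NIM") {
    # erratic sub-bursts at <= 40% of voluntary amplitude + baseline wander
    k <- sample(2:4, 1)
    for (j in seq_len(k)) {
      d <- stats::runif(1, 0.3, 1.5)
      a <- stats::runif(1, 0.10, 0.40) * amplitude_mv / 3
      s <- stats::runif(1, 0, max(duration_s - d, 0))
      i0 <- n_pre + round(s * fs)
      nn <- min(round(d * fs), n_act - round(s * fs))
      if (nn > 0) {
        idx <- i0 + seq_len(nn)
        env[idx] <- pmax(env[idx], a * trapezoid(nn, round(0.05 * fs)))
      }
    }
    f_w <- stats::runif(1, 0.1, 0.5)
    ph <- stats::runif(1, 0, 2 * pi)
    t <- (seq_along(env) - 1) / fs
    wander <- 0.05 * sin(2 * pi * f_w * t + ph)
  } else if (n_act > 0) {
    env[n_pre + seq_len(n_act)] <-
      pmax(
        rest_noise_rms_mv,
        (amplitude_mv / 3) * trapezoid(n_act, round(ramp_s * fs))
      )
  }
  list(
    envelope = env, wander = wander,
    truth_start_s = n_pre / fs, truth_end_s = (n_pre + n_act) / fs,
    n = length(env)
  )
}

new_emg_session <- function(recording, events) {
  structure(list(recording = recording, events = events),
    class = "emg_session"
  )
}

#' @export
print.emg_session <- function(x, ...) {
  sr <- emg_sample_rate(x$recording)
  cat(sprintf(
    "<emg_session> %.2f s at %g Hz, %d labeled events\n",
    nrow(x$recording) / sr, sr, nrow(x$events)
  ))
  print(x$events, ...)
  invisible(x)
}

#' Plan a synthetic recording session
#'
#' Builds the ordered table of contraction events that [emg_generate()]
#' synthesizes. Each row is one contraction (or NIM activity window) followed
#' by a rest pause; the protocol being emulated uses 5 s rest pauses between
#' contractions.
#'
#' @param classes Character vector of class names, recycled over `reps`.
#' @param reps Number of repetitions of `classes`.
#' @param rest_s Rest pause after each contraction (s).
#' @param amplitude_mv Voluntary contraction amplitude bound in mV
#'   (physiological range 0.1 to 5 mV).
#' @param duration_s Optional explicit durations; defaults to each class's
#'   nominal duration (1/3/5 s; 5 s activity window for NIM).
#' @param shuffle Shuffle event order (uses the RNG; seed it via
#'   [emg_generate()]'s `seed` if reproducibility matters at plan level,
#'   or set `shuffle = FALSE`).
#' @return A tibble with columns `class`, `duration_s`, `rest_s`,
#'   `amplitude_mv`.
#' @export
#' @examples
#' emg_session_plan(c("SMP", "SMP3", "SMP5"), reps = 2)
emg_session_plan <- function(classes = c("SMP", "SMP3", "SMP5", "NIM"),
                             reps = 1, rest_s = 5, amplitude_mv = 1,
                             duration_s = NULL, shuffle = FALSE) {
  class_label(classes) # validates
  cls <- rep(classes, reps)
  dur <- if (is.null(duration_s)) nominal_duration(cls) else rep(duration_s, reps)
  plan <- tibble::tibble(
    class = cls, duration_s = dur,
    rest_s = rest_s, amplitude_mv = amplitude_mv
  )
  if (shuffle) plan <- plan[sample(nrow(plan)), ]
  plan
}

#' Generate a synthetic EMG session
#'
#' Synthesizes a seeded single-channel sEMG-like recording following a session
#' plan. Voluntary bursts are band-limited Gaussian noise (default band
#' 20-450 Hz) shaped by a trapezoidal envelope with 100 ms ramps; rest
#' segments are low-amplitude noise (default floor 0.05 mV RMS); NIM windows
#' contain short erratic sub-bursts at reduced amplitude plus slow baseline
#' wander. Burst durations are jittered by `duration_jitter` so class
#' durations overlap slightly and classification is non-trivial.
#'
#' With amplitude bound A, every sample lies in `[-A - m, A + m]` where the
#' noise margin `m = 3 * rest_noise_rms_mv + 0.05` (rest noise is hard-limited
#' at three standard deviations; 0.05 mV allows for NIM baseline wander).
#'
#' @param plan A plan tibble from [emg_session_plan()], or a single class name.
#' @param seed Integer seed; equal seeds give bit-identical sessions.
#' @param sample_rate_hz Sampling rate (default 10000 Hz).
#' @param band_hz Two-element band of the surrogate noise (Hz).
#' @param rest_noise_rms_mv Rest-noise floor (mV RMS).
#' @param duration_jitter Fractional burst-duration jitter (default 0.15).
#' @param ramp_s Envelope rise/fall time (s).
#' @param lead_in_s Rest before the first contraction (s).
#' @return An `emg_session`: a list with `recording` (an [emg_recording()])
#'   and `events` (tibble `start_s`, `end_s`, `class`).
#' @export
#' @examples
#' s <- emg_generate(emg_session_plan("SMP3", reps = 1), seed = 7)
#' s$events
emg_generate <- function(plan, seed = NULL, sample_rate_hz = 10000,
                         band_hz = c(20, 450), rest_noise_rms_mv = 0.05,
                         duration_jitter = 0.15, ramp_s = 0.1,
                         lead_in_s = NULL) {
  if (is.character(plan)) {
    plan <- emg_session_plan(plan, reps = 1)
  }
  if (!is.data.frame(plan) || nrow(plan) == 0) {
    rlang::abort("`plan` must be a non-empty plan tibble.")
  }
  class_label(plan$class) # validates class names
  if (any(plan$duration_s <= 0)) {
    rlang::abort("Contraction durations must be positive.")
  }
  if (any(plan$amplitude_mv <= 0 | plan$amplitude_mv > 5)) {
    rlang::abort("`amplitude_mv` must lie in (0, 5] mV.")
  }
  with_local_seed(seed, {
    rows <- purrr::pmap(
      list(
        plan$class, plan$duration_s, plan$rest_s, plan$amplitude_mv,
        seq_len(nrow(plan))
      ),
      function(cls, dur, rest, amp, i) {
        row_envelope(
          class = cls, duration_s = dur,
          rest_before_s = if (i == 1) {
            if (is.null(lead_in_s)) rest else lead_in_s
          } else {
            0
          },
          rest_after_s = rest, amplitude_mv = amp,
          jitter = duration_jitter, rest_noise_rms_mv = rest_noise_rms_mv,
          sample_rate_hz = sample_rate_hz, ramp_s = ramp_s
        )
      }
    )
    env <- unlist(purrr::map(rows, "envelope"))
    wander <- unlist(purrr::map(rows, "wander"))
    noise <- bandlimited_noise(length(env), sample_rate_hz, band_hz)
    offsets <- cumsum(c(0, purrr::map_dbl(rows, "n"))) / sample_rate_hz
    events <- tibble::tibble(
      start_s = offsets[seq_len(nrow(plan))] +
        purrr::map_dbl(rows, "truth_start_s"),
      end_s = offsets[seq_len(nrow(plan))] +
        purrr::map_dbl(rows, "truth_end_s"),
      class = plan$class
    )
    rec <- emg_recording(env * noise + wander,
      sample_rate_hz = sample_rate_hz
    )
    new_emg_session(rec, events)
  })
}

#' Generate a single contraction recording
#'
#' Convenience wrapper around [emg_generate()] for one contraction preceded
#' and followed by rest.
#'
#' @inheritParams emg_generate
#' @param class Class name (`"SMP"`, `"SMP3"`, `"SMP5"`, `"NIM"`).
#' @param duration_s Contraction duration; defaults to the class nominal.
#' @param rest_before_s,rest_after_s Rest pauses around the burst (s).
#' @param amplitude_mv Amplitude bound in mV, in (0, 5].
#' @return An `emg_session` with one labeled event.
#' @export
#' @examples
#' s <- emg_contraction("SMP5", seed = 1)
emg_contraction <- function(class, duration_s = NULL, rest_before_s = 5,
                            rest_after_s = 5, amplitude_mv = 1, seed = NULL,
                            sample_rate_hz = 10000, band_hz = c(20, 450),
                            rest_noise_rms_mv = 0.05, duration_jitter = 0.15,
                            ramp_s = 0.1) {
  if (length(class) != 1) {
    rlang::abort("`class` must be a single class name.")
  }
  plan <- tibble::tibble(
    class = class,
    duration_s = if (is.null(duration_s)) nominal_duration(class) else duration_s,
    rest_s = rest_after_s,
    amplitude_mv = amplitude_mv
  )
  emg_generate(plan,
    seed = seed, sample_rate_hz = sample_rate_hz, band_hz = band_hz,
    rest_noise_rms_mv = rest_noise_rms_mv, duration_jitter = duration_jitter,
    ramp_s = ramp_s, lead_in_s = rest_before_s
  )
}

#' Concatenate sessions
#'
#' Appends sessions end to end, shifting event times. All sessions must share
#' the same sample rate.
#'
#' @param sessions List of `emg_session` objects.
#' @return A single `emg_session`.
#' @export
emg_bind_sessions <- function(sessions) {
  if (length(sessions) == 0) {
    rlang::abort("`sessions` must be non-empty.")
  }
  rates <- purrr::map_dbl(sessions, ~ emg_sample_rate(.x$recording))
  if (length(unique(rates)) != 1) {
    rlang::abort("Cannot concatenate recordings with mixed sample rates.")
  }
  ns <- purrr::map_int(sessions, ~ nrow(.x$recording))
  offsets <- cumsum(c(0, ns[-length(ns)])) / rates[1]
  events <- purrr::imap(sessions, function(s, i) {
    dplyr::mutate(s$events,
      start_s = .data$start_s + offsets[i],
      end_s = .data$end_s + offsets[i]
    )
  })
  rec <- emg_recording(
    unlist(purrr::map(sessions, ~ .x$recording$voltage_mv)),
    sample_rate_hz = rates[1]
  )
  new_emg_session(rec, dplyr::bind_rows(events))
}

#' Inject mains interference and DC offset
#'
#' Adds a sinusoidal mains component and a constant offset to a recording,
#' emulating electromagnetic pickup from lamps or other external devices and
#' the DC level produced by electrode-connection faults.
#'
#' @param rec A recording (data frame with `time_s`, `voltage_mv`).
#' @param mains_hz Interference frequency (Hz); must be below Nyquist.
#' @param mains_amp_mv Interference amplitude (mV).
#' @param dc_mv Constant offset (mV).
#' @return A recording of identical length and rate.
#' @export
#' @examples
#' s <- emg_contraction("SMP", seed = 2, rest_before_s = 1, rest_after_s = 1)
#' noisy <- emg_inject_interference(s$recording, 60, 0.2)
emg_inject_interference <- function(rec, mains_hz = 60, mains_amp_mv = 0,
                                    dc_mv = 0) {
  check_recording(rec)
  sr <- emg_sample_rate(rec)
  if (mains_hz >= sr / 2) {
    rlang::abort("`mains_hz` must be below the Nyquist frequency.")
  }
  v <- rec$voltage_mv + mains_amp_mv * sin(2 * pi * mains_hz * rec$time_s) +
    dc_mv
  out <- emg_recording(v,
    sample_rate_hz = sr,
    start_time_s = rec$time_s[1]
  )
  out
}
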