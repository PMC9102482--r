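#' Construct an EMG recording
#'
#' An EMG recording is a tibble with columns `time_s` and `voltage_mv`,
#' uniformly sampled at `sample_rate_hz`. The sample rate is carried as an
#' attribute and recovered from the time axis when the attribute has been
#' stripped by data-frame manipulation.
#'
#' @param voltage_mv Numeric vector of samples in millivolts.
#' @param sample_rate_hz Sampling rate in Hz (default 10000, the acquisition
#'   rate of the digitizing front end being emulated).
#' @param start_time_s Time of the first sample in seconds.
#' @return A tibble of class `emg_recording` with columns `time_s`,
#'   `voltage_mv`.
#' @export
#' @examples
#' rec <- emg_recording(sin(2 * pi * 60 * seq(0, 0.1, by = 1e-4)))
emg_recording <- function(voltage_mv, sample_rate_hz = 10000, start_time_s = 0) {
  if (!is.numeric(voltage_mv) || length(voltage_mv) < 1) {
    rlang::abort("`voltage_mv` must be a numeric vector of length >= 1.")
  }
  if (!all(is.finite(voltage_mv))) {
    rlang::abort("`voltage_mv` must be finite.")
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      sample_rate_hz <= 0) {
    rlang::abort("`sample_rate_hz` must be a positive scalar.")
  }
  out <- tibble::tibble(
    time_s = start_time_s + (seq_along(voltage_mv) - 1) / sample_rate_hz,
    voltage_mv = as.numeric(voltage_mv)
  )
  attr(out, "sample_rate_hz") <- sample_rate_hz
  class(out) <- c("emg_recording", class(out))
  out
}

#' Sampling rate of a recording
#'
#' Reads the `sample_rate_hz` attribute if present, otherwise infers the rate
#' from the median spacing of `time_s`. Errors on non-uniform sampling.
#'
#' @param rec A data frame with columns `time_s`, `voltage_mv`.
#' @param tol Relative tolerance on time-step uniformity.
#' @return Sampling rate in Hz.
#' @export
emg_sample_rate <- function(rec, tol = 1e-6) {
  sr <- attr(rec, "sample_rate_hz")
  if (!is.null(sr)) {
    return(sr)
  }
  check_recording(rec)
  dt <- diff(rec$time_s)
  if (length(dt) == 0) {
    rlang::abort("Cannot infer sample rate from a single sample.")
  }
  dt0 <- stats::median(dt)
  if (dt0 <= 0 || any(abs(dt - dt0) > tol * dt0)) {
    rlang::abort("Recording is not uniformly sampled.")
  }
  1 / dt0
}

check_recording <- function(rec) {
  if (!is.data.frame(rec) || !all(c("time_s", "voltage_mv") %in% names(rec))) {
    rlang::abort("Expected a recording with columns `time_s` and `voltage_mv`.")
  }
  if (nrow(rec) < 1) {
    rlang::abort("Recording is empty.")
  }
  invisible(rec)
}

#' Read / write a recording as CSV
#'
#' Plain CSV with header `time_s,voltage_mv`.
#'
#' @param rec A recording.
#' @param path File path.
#' @return `read_emg_csv()` returns an `emg_recording`; `write_emg_csv()`
#'   returns `path` invisibly.
#' @export
write_emg_csv <- function(rec, path) {
  check_recording(rec)
  utils::write.csv(rec[, c("time_s", "voltage_mv")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emg_csv
#' @export
read_emg_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "voltage_mv") %in% names(df))) {
    rlang::abort("CSV must have columns `time_s` and `voltage_mv`.")
  }
  dt <- diff(df$time_s)
  dt0 <- stats::median(dt)
  rec <- emg_recording(df$voltage_mv,
    sample_rate_hz = 1 / dt0,
    start_time_s = df$time_s[1]
  )
  rec
}
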