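#' Run the full EMG-to-robot pipeline
#'
#' Chains every stage on a recording: low-pass filtering, burst segmentation,
#' feature extraction and classification, the command state machine, inverse
#' kinematics of each emitted set-point, and PD+ regulation to it. Each
#' emitted set-point is simulated from the arm's state at the end of the
#' previous motion; a NIM event deactivates the machine and all later events
#' are ignored.
#'
#' @param rec An EMG recording (raw; filtered internally), or an
#'   `emg_session` whose recording is used.
#' @param model A trained [train_mlp()] model.
#' @param table Transition table (default [transition_table()]).
#' @param params A [robot_params()].
#' @param gains A [control_gains()].
#' @param fc_hz Low-pass cutoff used before segmentation (default 450 Hz,
#'   the upper signal-band edge).
#' @param sim_duration Simulated regulation time per set-point (s).
#' @param dt Integration step (s).
#' @param q0 Initial joint configuration.
#' @param classify_rest Classify detected rest segments too (default FALSE:
#'   only voluntary bursts and candidate involuntary events drive the
#'   machine; long rest is the protocol's pause, not a command).
#' @return A `pipeline_trace` list: `events` (classified segments), `trace`
#'   (machine states and set-points per event), `sims` (one `robot_sim` per
#'   motion command), `final_q`, and `session_time_s` (EMG timeline length,
#'   the hardware-independent response time).
#' @export
run_pipeline <- function(rec, model, table = transition_table(),
                         params = robot_params(), gains = control_gains(),
                         fc_hz = 450, sim_duration = 5, dt = 0.001,
                         q0 = NULL, classify_rest = FALSE) {
  if (inherits(rec, "emg_session")) rec <- rec$recording
  check_recording(rec)
  filtered <- emg_lowpass(rec, fc_hz)
  segs <- segment_bursts(filtered)
  if (!classify_rest) {
    segs <- segs[segs$kind == "burst" |
      (segs$end_s - segs$start_s) < 2, , drop = FALSE]
  }
  if (nrow(segs) == 0) {
    return(structure(
      list(
        events = tibble::tibble(), trace = tibble::tibble(),
        sims = list(), final_q = q0 %||% c(0, pi / 4, -pi / 4),
        session_time_s = nrow(rec) / emg_sample_rate(rec)
      ),
      class = "pipeline_trace"
    ))
  }
  feats <- extract_features(filtered, segs)
  events <- predict_class(model, feats)
  trace <- run_sequence(events$class)
  q <- q0 %||% c(0, pi / 4, -pi / 4)
  sims <- vector("list", nrow(trace))
  for (i in seq_len(nrow(trace))) {
    if (!is.na(trace$px[i]) && trace$active[i]) {
      sim <- regulate_to(
        c(trace$px[i], trace$py[i], trace$pz[i]),
        q0 = q, duration = sim_duration, dt = dt,
        gains = gains, params = params
      )
      n <- nrow(sim)
      q <- c(sim$q1[n], sim$q2[n], sim$q3[n])
      sims[[i]] <- sim
    }
  }
  structure(
    list(
      events = events, trace = trace, sims = sims, final_q = q,
      session_time_s = nrow(rec) / emg_sample_rate(rec)
    ),
    class = "pipeline_trace"
  )
}

#' @export
print.pipeline_trace <- function(x, ...) {
  cat(sprintf(
    "<pipeline_trace> %d events over %.1f s of EMG\n",
    nrow(x$events), x$session_time_s
  ))
  if (nrow(x$trace) > 0) print(x$trace, ...)
  invisible(x)
}

#' Score a trajectory-following trial
#'
#' A trial asks the user to steer the machine through an ordered list of
#' waypoint states. Every visited state that is not the next expected
#' waypoint counts as one penalty; the trial is completed when the final
#' waypoint is reached. Elapsed time is the EMG-timeline duration of the
#' session (hardware-independent), or the supplied value.
#'
#' @param waypoints Character vector of expected states, in order (the
#'   current state when the trial starts is not included).
#' @param trace A trace tibble from [run_sequence()] or the `trace` element
#'   of [run_pipeline()], or a character vector of visited states.
#' @param elapsed_s Trial duration (s); defaults to the trace attribute if
#'   present.
#' @return A one-row tibble: `penalties`, `completed`, `elapsed_s`.
#' @export
#' @examples
#' score_trial(c("S2", "DUR"), run_sequence(c("SMP3", "SMP5")))
score_trial <- function(waypoints, trace, elapsed_s = NA_real_) {
  if (is.character(trace)) {
    visited <- trace
  } else {
    visited <- trace$state
  }
  bad <- !waypoints %in% c(state_targets()$state)
  if (any(bad)) {
    rlang::abort(paste0(
      "Unknown waypoint state(s): ",
      paste(waypoints[bad], collapse = ", ")
    ))
  }
  expected_i <- 1
  penalties <- 0L
  for (s in visited) {
    if (expected_i <= length(waypoints) && s == waypoints[expected_i]) {
      expected_i <- expected_i + 1
    } else {
      penalties <- penalties + 1L
    }
  }
  tibble::tibble(
    penalties = penalties,
    completed = expected_i > length(waypoints),
    elapsed_s = elapsed_s
  )
}

#' Percent decrease in response time
#'
#' `100 (t_first - t_last) / t_first`, reported to two decimals: the
#' learning-curve summary comparing the first and last repetition of a
#' trajectory task.
#'
#' @param t_first First-trial time (s), must be positive.
#' @param t_last Last-trial time (s).
#' @return Percentage, rounded to two decimals.
#' @export
#' @examples
#' percent_decrease(118.52, 77.54) # 34.58
percent_decrease <- function(t_first, t_last) {
  if (!is.numeric(t_first) || any(t_first <= 0)) {
    rlang::abort("`t_first` must be positive.")
  }
  round(100 * (t_first - t_last) / t_first, 2)
}

#' Evaluate a series of trials
#'
#' Aggregates per-trial logs into the learning-curve report: the trial
#' table, whether times trend downward, and the percent decrease from first
#' to last trial.
#'
#' @param times Per-trial elapsed times (s), in order.
#' @param penalties Per-trial penalty counts (default all zero).
#' @return A list with `trials` (tibble `trial`, `elapsed_s`, `penalties`,
#'   `completed`), `monotone_decreasing`, and `percent_decrease`.
#' @export
#' @examples
#' evaluate_trials(c(118.52, 100, 90, 77.54))
evaluate_trials <- function(times, penalties = rep(0L, length(times))) {
  if (length(times) == 0) {
    rlang::abort("`times` must be non-empty.")
  }
  trials <- tibble::tibble(
    trial = seq_along(times),
    elapsed_s = times,
    penalties = penalties,
    completed = TRUE
  )
  list(
    trials = trials,
    monotone_decreasing = all(diff(times) <= 0),
    percent_decrease = percent_decrease(times[1], times[length(times)])
  )
}
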