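moving_rms <- function(v, n_win) {
  # centered moving RMS via a C-level rolling mean of squared samples
  n <- length(v)
  n_win <- max(1L, min(n_win, n))
  k <- rep(1 / n_win, n_win)
  m <- stats::filter(v^2, k, sides = 2)
  m <- as.numeric(m)
  # fill the half-window edges with the nearest defined value
  first <- which(!is.na(m))[1]
  last <- max(which(!is.na(m)))
  m[seq_len(first - 1)] <- m[first]
  if (last < n) m[(last + 1):n] <- m[last]
  sqrt(m)
}

#' Segment a recording into candidate contraction events
#'
#' Detects voluntary bursts with a moving-RMS envelope (default 100 ms
#' window) crossing `k` times the rest RMS. The rest RMS is estimated as the
#' median of the envelope, which is robust because the acquisition protocol
#' leaves the muscle at rest at least half of the time. Detections separated
#' by gaps shorter than `merge_gap_s` are merged; detections shorter than
#' `min_burst_s` are kept as candidate involuntary (NIM) events; rest
#' stretches of at least `min_rest_s` emit one NIM segment each.
#'
#' @param rec A recording (normally low-pass filtered first).
#' @param window_s Moving-RMS window length (s).
#' @param k Threshold multiplier on the rest RMS (default 3).
#' @param merge_gap_s Merge detections closer than this (s).
#' @param min_burst_s Minimum voluntary burst duration (s).
#' @param min_rest_s Minimum rest stretch reported as a NIM segment (s).
#' @return A tibble with columns `start_s`, `end_s`, `kind`
#'   (`"burst"` or `"rest"`), ordered by `start_s`.
#' @export
#' @examples
#' s <- emg_generate(emg_session_plan(c("SMP", "SMP3", "SMP5")), seed = 3)
#' segment_bursts(s$recording)
segment_bursts <- function(rec, window_s = 0.1, k = 3, merge_gap_s = 0.5,
                           min_burst_s = 0.3, min_rest_s = 2) {
  check_recording(rec)
  sr <- emg_sample_rate(rec)
  n_win <- round(window_s * sr)
  if (nrow(rec) < n_win) {
    rlang::abort("Recording shorter than the envelope window.")
  }
  env <- moving_rms(rec$voltage_mv, n_win)
  rest_rms <- stats::median(env)
  thr <- k * rest_rms
  active <- env > thr
  t0 <- rec$time_s[1]

  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  iv <- tibble::tibble(
    start = (starts - 1) / sr, end = ends / sr,
    on = runs$values
  )
  bursts <- iv[iv$on, c("start", "end")]
  # merge bursts separated by short gaps
  if (nrow(bursts) > 1) {
    merged <- list()
    cur_s <- bursts$start[1]
    cur_e <- bursts$end[1]
    for (i in seq_len(nrow(bursts))[-1]) {
      if (bursts$start[i] - cur_e < merge_gap_s) {
        cur_e <- bursts$end[i]
      } else {
        merged[[length(merged) + 1]] <- c(cur_s, cur_e)
        cur_s <- bursts$start[i]
        cur_e <- bursts$end[i]
      }
    }
    merged[[length(merged) + 1]] <- c(cur_s, cur_e)
    bursts <- tibble::tibble(
      start = purrr::map_dbl(merged, 1),
      end = purrr::map_dbl(merged, 2)
    )
  }
  if (nrow(bursts) > 0) {
    dur <- bursts$end - bursts$start
    voluntary <- bursts[dur >= min_burst_s, ]
    short <- bursts[dur < min_burst_s, ]
  } else {
    voluntary <- short <- bursts
  }
  # rest stretches between voluntary bursts (and at the edges)
  total <- nrow(rec) / sr
  bounds <- c(0, as.vector(t(as.matrix(voluntary))), total)
  rests <- matrix(bounds, ncol = 2, byrow = TRUE)
  rest_iv <- tibble::tibble(start = rests[, 1], end = rests[, 2])
  rest_iv <- rest_iv[rest_iv$end - rest_iv$start >= min_rest_s, ]

  out <- dplyr::bind_rows(
    dplyr::mutate(voluntary, kind = "burst"),
    dplyr::mutate(short, kind = "rest"),
    dplyr::mutate(rest_iv, kind = "rest")
  )
  out <- dplyr::arrange(out, .data$start)
  tibble::tibble(
    start_s = out$start + t0, end_s = out$end + t0,
    kind = out$kind
  )
}

#' Extract classification features for segments
#'
#' For each segment the fixed-length feature vector is
#' `[duration_s, rms_mv, mav_mv, zcr_hz]`: segment duration, root-mean-square
#' amplitude, mean absolute value, and zero-crossing rate. Duration is the
#' class-defining quantity of the contraction protocol; RMS/MAV separate
#' voluntary effort from involuntary noise; ZCR summarizes spectral content.
#'
#' @param rec The recording the segments index into.
#' @param segments A tibble with `start_s`, `end_s` (e.g. from
#'   [segment_bursts()] or a session's ground-truth `events`).
#' @return `segments` with feature columns appended.
#' @export
#' @examples
#' s <- emg_contraction("SMP3", seed = 5)
#' extract_features(s$recording, s$events)
extract_features <- function(rec, segments) {
  check_recording(rec)
  sr <- emg_sample_rate(rec)
  if (nrow(segments) == 0) {
    return(dplyr::mutate(segments,
      duration_s = numeric(0), rms_mv = numeric(0),
      mav_mv = numeric(0), zcr_hz = numeric(0)
    ))
  }
  feats <- purrr::map2(segments$start_s, segments$end_s, function(s, e) {
    i0 <- max(1L, floor((s - rec$time_s[1]) * sr) + 1L)
    i1 <- min(nrow(rec), ceiling((e - rec$time_s[1]) * sr))
    if (i1 < i0) {
      rlang::abort("Empty segment.")
    }
    v <- rec$voltage_mv[i0:i1]
    dur <- (i1 - i0 + 1) / sr
    sgn <- sign(v)
    sgn <- sgn[sgn != 0]
    zc <- sum(diff(sgn) != 0)
    c(
      duration_s = dur,
      rms_mv = sqrt(mean(v^2)),
      mav_mv = mean(abs(v)),
      zcr_hz = zc / dur
    )
  })
  fm <- do.call(rbind, feats)
  dplyr::bind_cols(segments, tibble::as_tibble(fm))
}

feature_names <- function() c("duration_s", "rms_mv", "mav_mv", "zcr_hz")

#' Label detected segments against ground-truth events
#'
#' Assigns each detected segment the class of the ground-truth interval that
#' covers at least `min_overlap` of it; segments not covered by any voluntary
#' interval (rest stretches, stray crossings from involuntary activity) are
#' labeled NIM. Training on detector output labeled this way keeps the
#' classifier's training distribution identical to what it sees in
#' deployment.
#'
#' @param segments A tibble from [segment_bursts()] (`start_s`, `end_s`).
#' @param events Ground-truth intervals (`start_s`, `end_s`, `class`), e.g. a
#'   session's `events`.
#' @param min_overlap Minimum fraction of the segment covered by a truth
#'   interval for its class to apply.
#' @return `segments` with a `class` column appended.
#' @export
#' @examples
#' s <- emg_generate(emg_session_plan(c("SMP", "SMP5")), seed = 2)
#' segs <- segment_bursts(emg_lowpass(s$recording, 450))
#' label_segments(segs, s$events)
label_segments <- function(segments, events, min_overlap = 0.5) {
  cls <- purrr::map2_chr(segments$start_s, segments$end_s, function(s, e) {
    ov <- pmin(e, events$end_s) - pmax(s, events$start_s)
    ov <- pmax(ov, 0) / (e - s)
    i <- which.max(ov)
    if (length(i) == 1 && ov[i] >= min_overlap) events$class[i] else "NIM"
  })
  dplyr::mutate(segments, class = cls)
}
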