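# Shared fixtures, built once per test run. The reduced-rate sessions keep
# the unit suite fast; the acceptance tests use the full 10 kHz protocol.

FS_FAST <- 2000

fast_session <- function(classes, reps = 1, seed = 1, rest_s = 5, ...) {
  emg_generate(
    emg_session_plan(classes, reps = reps, rest_s = rest_s, ...),
    seed = seed, sample_rate_hz = FS_FAST
  )
}

# Labeled feature table from ground-truth intervals, extracted (like the
# deployed pipeline) from the low-pass-filtered recording.
truth_features <- function(session, fc_hz = 450) {
  filt <- emg_lowpass(session$recording, fc_hz)
  f <- extract_features(filt, session$events)
  f$class <- session$events$class
  f
}

# A training session matching pipeline deployment: voluntary classes at 1 mV
# plus involuntary-movement windows at 3 mV (large arm jerks), features
# extracted from detector output labeled by ground-truth overlap.
pipeline_training_features <- function(reps = 12, seed = 42) {
  plan <- emg_session_plan(c("SMP", "SMP3", "SMP5", "NIM"), reps = reps)
  plan$amplitude_mv[plan$class == "NIM"] <- 3
  s <- emg_generate(plan, seed = seed, sample_rate_hz = FS_FAST)
  filt <- emg_lowpass(s$recording, 450)
  segs <- segment_bursts(filt)
  labeled <- label_segments(segs, s$events)
  extract_features(filt, labeled)
}

# Reduced protocol benchmark model: ground-truth (protocol) segmentation,
# uniform 1 mV amplitude, as in the supervised labeling of the acquisition
# protocol. Cached across tests.
benchmark_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      s <- fast_session(c("SMP", "SMP3", "SMP5", "NIM"), reps = 12, seed = 42)
      model <<- train_mlp(
        truth_features(s),
        train_config(epochs = 600, seed = 42)
      )
    }
    model
  }
})

# Deployment-matched model: trained on detector output via label_segments().
pipeline_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      model <<- train_mlp(
        pipeline_training_features(),
        train_config(epochs = 600, seed = 42)
      )
    }
    model
  }
})

# Random reachable targets built by sampling joint space and pushing through
# forward kinematics; configurations too close to the base axis (q1
# undefined) are rejected.
random_reachable_points <- function(n, params, seed = 99) {
  set.seed(seed)
  pts <- NULL
  while (is.null(pts) || nrow(pts) < n) {
    q <- cbind(
      stats::runif(2 * n, -pi, pi),
      stats::runif(2 * n, -pi / 2, pi / 2),
      stats::runif(2 * n, -pi + 0.1, -0.05) # elbow bent
    )
    p <- forward_kinematics(q, params)
    p <- p[p$px^2 + p$py^2 > 1e-4, , drop = FALSE]
    pts <- utils::head(rbind(pts, p), n)
  }
  pts
}
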