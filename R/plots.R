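#' Plot a synthetic session
#'
#' Voltage trace with the labeled event intervals shaded.
#'
#' @param object An `emg_session`.
#' @param max_points Downsample the trace to about this many points for
#'   drawing.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot emg_session
#' @export
autoplot.emg_session <- function(object, max_points = 20000, ...) {
  rec <- object$recording
  step <- max(1L, floor(nrow(rec) / max_points))
  dat <- rec[seq(1, nrow(rec), by = step), ]
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = object$events,
      ggplot2::aes(
        xmin = .data$start_s, xmax = .data$end_s,
        ymin = -Inf, ymax = Inf, fill = .data$class
      ),
      alpha = 0.2
    ) +
    ggplot2::geom_line(
      data = dat,
      ggplot2::aes(x = .data$time_s, y = .data$voltage_mv),
      linewidth = 0.2
    ) +
    ggplot2::labs(
      x = "time (s)", y = "voltage (mV)", fill = "class",
      title = "Synthetic sEMG session"
    )
}

#' Plot a magnitude spectrum
#'
#' @param object An `emg_spectrum`.
#' @param log_y Log-scale magnitudes.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot emg_spectrum
#' @export
autoplot.emg_spectrum <- function(object, log_y = TRUE, ...) {
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$freq_hz, y = .data$magnitude)
  ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "frequency (Hz)", y = "|X(f)|",
      title = "DFT magnitude spectrum"
    )
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot training history
#'
#' Train and validation loss (and accuracy) against epoch.
#'
#' @param object An `emg_mlp` with history.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot emg_mlp
#' @export
autoplot.emg_mlp <- function(object, ...) {
  if (is.null(object$history)) {
    rlang::abort("Model carries no training history.")
  }
  h <- tidyr::pivot_longer(
    object$history,
    cols = c("train_loss", "val_loss"),
    names_to = "series", values_to = "loss"
  )
  ggplot2::ggplot(
    h, ggplot2::aes(x = .data$epoch, y = .data$loss, color = .data$series)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "epoch", y = "cross-entropy loss",
      title = "MLP training history"
    )
}

#' Plot a regulation run
#'
#' Joint position errors against time; the PD+ objective is that every
#' error tends to zero.
#'
#' @param object A `robot_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot robot_sim
#' @export
autoplot.robot_sim <- function(object, ...) {
  h <- tidyr::pivot_longer(
    object[, c("t", "e1", "e2", "e3")],
    cols = c("e1", "e2", "e3"),
    names_to = "joint", values_to = "error_rad"
  )
  ggplot2::ggplot(
    h, ggplot2::aes(x = .data$t, y = .data$error_rad, color = .data$joint)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (s)", y = "position error (rad)",
      title = "PD+ regulation error"
    )
}
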