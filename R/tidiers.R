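#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained MLP
#'
#' One row per weight or bias, broom-style.
#'
#' @param x An `emg_mlp`.
#' @param ... Unused.
#' @return A tibble with columns `layer`, `parameter`, `row`, `col`,
#'   `estimate`.
#' @method tidy emg_mlp
#' @export
tidy.emg_mlp <- function(x, ...) {
  flat <- function(layer, parameter, m) {
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    tibble::tibble(
      layer = layer, parameter = parameter,
      row = as.vector(row(m)), col = as.vector(col(m)),
      estimate = as.vector(m)
    )
  }
  dplyr::bind_rows(
    flat(1L, "W1", x$W1), flat(1L, "b1", x$b1),
    flat(2L, "W2", x$W2), flat(2L, "b2", x$b2)
  )
}

#' Glance at a trained MLP
#'
#' @param x An `emg_mlp`.
#' @param ... Unused.
#' @return A one-row tibble: epochs, final train/validation loss and
#'   accuracy, held-out test accuracy.
#' @method glance emg_mlp
#' @export
glance.emg_mlp <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(test_accuracy = x$test_accuracy))
  }
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    epochs = nrow(x$history),
    train_loss = last$train_loss,
    val_loss = last$val_loss,
    train_accuracy = last$train_acc,
    val_accuracy = last$val_acc,
    test_accuracy = x$test_accuracy
  )
}

#' Glance at a regulation simulation
#'
#' @param x A `robot_sim` from [simulate_robot()] or [regulate_to()].
#' @param ... Unused.
#' @return A one-row tibble with final joint error norms (and Cartesian
#'   error when produced by [regulate_to()]).
#' @method glance robot_sim
#' @export
glance.robot_sim <- function(x, ...) {
  n <- nrow(x)
  tibble::tibble(
    duration_s = x$t[n],
    final_joint_error_rad = max(abs(c(x$e1[n], x$e2[n], x$e3[n]))),
    final_speed_rad_s = sqrt(x$qdot1[n]^2 + x$qdot2[n]^2 + x$qdot3[n]^2),
    final_cartesian_error_m = attr(x, "final_cartesian_error_m") %||%
      NA_real_
  )
}
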