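#' Inertia matrix M(q)
#'
#' Kinetic-energy-derived inertia matrix of the lumped 3R model (point
#' masses at the link centers of mass plus scalar link inertias). With
#' `phi = q2 + q3` and radial reach `rho = l2 cos q2 + lc3 cos phi`:
#' `M11 = I1 + I2 + I3 + m2 lc2^2 cos^2 q2 + m3 rho^2`,
#' `M22 = I2 + I3 + m2 lc2^2 + m3 (l2^2 + lc3^2 + 2 l2 lc3 cos q3)`,
#' `M23 = I3 + m3 (lc3^2 + l2 lc3 cos q3)`, `M33 = I3 + m3 lc3^2`,
#' `M12 = M13 = 0`. Symmetric positive-definite for all q.
#'
#' @param q Joint angles (3-vector, rad).
#' @param params A [robot_params()].
#' @return A symmetric 3x3 matrix.
#' @export
inertia_matrix <- function(q, params = robot_params()) {
  with(params, {
    phi <- q[2] + q[3]
    rho <- l2 * cos(q[2]) + lc3 * cos(phi)
    m11 <- I1 + I2 + I3 + m2 * lc2^2 * cos(q[2])^2 + m3 * rho^2
    m22 <- I2 + I3 + m2 * lc2^2 + m3 * (l2^2 + lc3^2 + 2 * l2 * lc3 * cos(q[3]))
    m23 <- I3 + m3 * (lc3^2 + l2 * lc3 * cos(q[3]))
    m33 <- I3 + m3 * lc3^2
    matrix(c(
      m11, 0, 0,
      0, m22, m23,
      0, m23, m33
    ), 3, 3, byrow = TRUE)
  })
}

# Analytic partial derivatives dM/dq_k, k = 1..3 (M does not depend on q1).
inertia_partials <- function(q, params) {
  with(params, {
    phi <- q[2] + q[3]
    rho <- l2 * cos(q[2]) + lc3 * cos(phi)
    drho_dq2 <- -l2 * sin(q[2]) - lc3 * sin(phi)
    drho_dq3 <- -lc3 * sin(phi)
    z <- matrix(0, 3, 3)
    d2 <- z
    d2[1, 1] <- -2 * m2 * lc2^2 * cos(q[2]) * sin(q[2]) +
      2 * m3 * rho * drho_dq2
    d3 <- z
    d3[1, 1] <- 2 * m3 * rho * drho_dq3
    d3[2, 2] <- -2 * m3 * l2 * lc3 * sin(q[3])
    d3[2, 3] <- d3[3, 2] <- -m3 * l2 * lc3 * sin(q[3])
    list(z, d2, d3)
  })
}

#' Coriolis matrix C(q, qdot)
#'
#' Built from the Christoffel symbols of the first kind of [inertia_matrix()]:
#' `C_kj = sum_i 0.5 (dM_kj/dq_i + dM_ki/dq_j - dM_ij/dq_k) qdot_i`. This
#' construction guarantees that `Mdot - 2C` is skew-symmetric, the property
#' energy-based control arguments rely on.
#'
#' @param q Joint angles (rad).
#' @param qdot Joint velocities (rad/s).
#' @param params A [robot_params()].
#' @return A 3x3 matrix (linear in `qdot`).
#' @export
coriolis_matrix <- function(q, qdot, params = robot_params()) {
  dM <- inertia_partials(q, params)
  C <- matrix(0, 3, 3)
  for (k in 1:3) {
    for (j in 1:3) {
      ckj <- 0
      for (i in 1:3) {
        ckj <- ckj + 0.5 * (dM[[i]][k, j] + dM[[j]][k, i] - dM[[k]][i, j]) *
          qdot[i]
      }
      C[k, j] <- ckj
    }
  }
  C
}

#' Gravity vector g(q)
#'
#' Gradient of the potential energy
#' `U = g (m2 lc2 sin q2 + m3 (l2 sin q2 + lc3 sin(q2+q3)))` (the base link
#' does not move vertically, so `g1 = 0` for all q).
#'
#' @inheritParams coriolis_matrix
#' @return A 3-vector of joint torques (N m).
#' @export
gravity_vector <- function(q, params = robot_params()) {
  with(params, {
    phi <- q[2] + q[3]
    c(
      0,
      g * (m2 * lc2 * cos(q[2]) + m3 * (l2 * cos(q[2]) + lc3 * cos(phi))),
      g * m3 * lc3 * cos(phi)
    )
  })
}

# Potential energy matching gravity_vector (used by the test oracle).
potential_energy <- function(q, params = robot_params()) {
  with(params, {
    g * (m2 * lc2 * sin(q[2]) + m3 * (l2 * sin(q[2]) + lc3 * sin(q[2] + q[3])))
  })
}

#' Joint accelerations from the manipulator dynamics
#'
#' Solves `tau = M(q) qddot + C(q, qdot) qdot + g(q) + B qdot` for `qddot`.
#'
#' @param q,qdot Joint state (rad, rad/s).
#' @param torque Applied joint torques (N m).
#' @param params A [robot_params()].
#' @return Joint accelerations (rad/s^2).
#' @export
dynamics_rhs <- function(q, qdot, torque, params = robot_params()) {
  M <- inertia_matrix(q, params)
  C <- coriolis_matrix(q, qdot, params)
  gv <- gravity_vector(q, params)
  B <- c(params$B1, params$B2, params$B3)
  solve(M, torque - C %*% qdot - gv - B * qdot)[, 1]
}

#' Controller gains
#'
#' Proportional and derivative gain matrices for the PD+ law. Both must be
#' symmetric positive-definite (checked by Cholesky factorization). Scalars
#' are expanded to diagonal matrices. Defaults Kp = diag(100), Kv = diag(20)
#' settle the desk-scale arm well inside 5 s.
#'
#' @param Kp Proportional gains: scalar, 3-vector, or 3x3 matrix.
#' @param Kv Derivative gains, same forms.
#' @return A `control_gains` list of two 3x3 matrices.
#' @export
#' @examples
#' control_gains()
control_gains <- function(Kp = 100, Kv = 20) {
  expand <- function(x, nm) {
    if (is.matrix(x)) {
      if (!all(dim(x) == c(3, 3)) || !isTRUE(all.equal(x, t(x)))) {
        rlang::abort(paste0("`", nm, "` must be a symmetric 3x3 matrix."))
      }
    } else {
      x <- diag(rep(x, length.out = 3))
    }
    ok <- tryCatch(
      {
        chol(x)
        TRUE
      },
      error = function(e) FALSE
    )
    if (!ok) {
      rlang::abort(paste0("`", nm, "` must be positive definite."))
    }
    x
  }
  structure(
    list(Kp = expand(Kp, "Kp"), Kv = expand(Kv, "Kv")),
    class = "control_gains"
  )
}

#' PD+ control torque
#'
#' The PD+ law with gravity compensation:
#' `tau = Kp qtilde + Kv qtilde_dot + M(q) qd_ddot + C(q, qdot) qd_dot
#'  + B qd_dot + g(q)`,
#' with position error `qtilde = qd - q` and velocity error
#' `qtilde_dot = qd_dot - qdot`. For set-point regulation
#' (`qd_dot = qd_ddot = 0`) the feedforward terms vanish and the law reduces
#' to PD feedback plus exact gravity compensation, whose closed-loop
#' equilibrium is exactly `q = qd`.
#'
#' @param q,qdot Current joint state.
#' @param qd,qd_dot,qd_ddot Desired position, velocity, acceleration.
#' @param gains A [control_gains()].
#' @param params A [robot_params()].
#' @return Joint torques (N m).
#' @export
pdplus_torque <- function(q, qdot, qd, qd_dot = c(0, 0, 0),
                          qd_ddot = c(0, 0, 0), gains = control_gains(),
                          params = robot_params()) {
  qt <- qd - q
  qt_dot <- qd_dot - qdot
  M <- inertia_matrix(q, params)
  C <- coriolis_matrix(q, qdot, params)
  B <- c(params$B1, params$B2, params$B3)
  as.numeric(
    gains$Kp %*% qt + gains$Kv %*% qt_dot +
      M %*% qd_ddot + C %*% qd_dot + B * qd_dot + gravity_vector(q, params)
  )
}
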