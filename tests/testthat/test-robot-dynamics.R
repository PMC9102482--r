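random_states <- function(n, seed = 61) {
  set.seed(seed)
  list(
    q = matrix(stats::runif(3 * n, -pi, pi), ncol = 3),
    qdot = matrix(stats::runif(3 * n, -2, 2), ncol = 3)
  )
}

test_that("inertia matrix is symmetric positive-definite with the stated entries", {
  p <- robot_params()
  st <- random_states(100)
  for (i in seq_len(100)) {
    q <- st$q[i, ]
    M <- inertia_matrix(q, p)
    expect_identical(M, t(M))
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
    # closed-form entries
    expect_equal(
      M[2, 2],
      p$I2 + p$I3 + p$lc2^2 * p$m2 +
        (p$l2^2 + p$lc3^2 + 2 * p$l2 * p$lc3 * cos(q[3])) * p$m3,
      tolerance = 1e-12
    )
    expect_equal(
      M[2, 3],
      p$I3 + p$lc3^2 * p$m3 + p$l2 * p$lc3 * p$m3 * cos(q[3]),
      tolerance = 1e-12
    )
    expect_equal(M[3, 3], p$I3 + p$lc3^2 * p$m3, tolerance = 1e-15)
  }
})

test_that("Coriolis matrix is linear in velocity and satisfies skew-symmetry", {
  p <- robot_params()
  st <- random_states(25, seed = 62)
  h <- 1e-6
  for (i in seq_len(25)) {
    q <- st$q[i, ]
    qd <- st$qdot[i, ]
    expect_equal(coriolis_matrix(q, c(0, 0, 0), p), matrix(0, 3, 3))
    expect_equal(
      coriolis_matrix(q, 3 * qd, p), 3 * coriolis_matrix(q, qd, p),
      tolerance = 1e-12
    )
    # Mdot - 2C skew-symmetric (Mdot by central differences along qdot)
    Mdot <- (inertia_matrix(q + h * qd, p) - inertia_matrix(q - h * qd, p)) /
      (2 * h)
    S <- Mdot - 2 * coriolis_matrix(q, qd, p)
    expect_lt(max(abs(S + t(S))), 1e-8)
  }
})

test_that("gravity vector is the gradient of the potential energy", {
  p <- robot_params()
  st <- random_states(25, seed = 63)
  for (i in seq_len(25)) {
    q <- st$q[i, ]
    g <- gravity_vector(q, p)
    expect_identical(g[1], 0)
    gn <- vapply(1:3, function(k) {
      e <- numeric(3)
      e[k] <- 1e-6
      (myohmi:::potential_energy(q + e, p) -
        myohmi:::potential_energy(q - e, p)) / 2e-6
    }, numeric(1))
    expect_lt(max(abs(g - gn)), 1e-8)
  }
  # horizontal-link terms vanish when both cosines are zero
  g0 <- gravity_vector(c(0.4, pi / 2, 0), p)
  expect_equal(g0[2], 0, tolerance = 1e-12)
  expect_equal(g0[3], 0, tolerance = 1e-12)
})

test_that("gravity-balanced torque holds the arm still", {
  p <- robot_params()
  q <- c(0.3, 0.4, -0.6)
  acc <- dynamics_rhs(q, c(0, 0, 0), gravity_vector(q, p), p)
  expect_equal(acc, c(0, 0, 0), tolerance = 1e-12)
})

test_that("kinetic energy is conserved without gravity, friction or torque", {
  p <- robot_params(g = 0, B1 = 0, B2 = 0, B3 = 0)
  zero_tau <- function(t, q, qdot) c(0, 0, 0)
  sim <- simulate_robot(
    q0 = c(0.2, 0.3, -0.5), qdot0 = c(0.5, -0.4, 0.6),
    desired = c(0, 0, 0), params = p, dt = 0.001, duration = 5,
    torque_fn = zero_tau
  )
  ke <- vapply(seq_len(nrow(sim)), function(i) {
    q <- c(sim$q1[i], sim$q2[i], sim$q3[i])
    qd <- c(sim$qdot1[i], sim$qdot2[i], sim$qdot3[i])
    0.5 * sum(qd * (inertia_matrix(q, p) %*% qd))
  }, numeric(1))
  expect_lt(max(abs(ke - ke[1])) / ke[1], 1e-6)
})

test_that("viscous friction dissipates kinetic energy monotonically", {
  p <- robot_params(g = 0)
  sim <- simulate_robot(
    q0 = c(0, 0.3, -0.5), qdot0 = c(1, -0.8, 0.9),
    desired = c(0, 0, 0), params = p, dt = 0.001, duration = 2,
    torque_fn = function(t, q, qdot) c(0, 0, 0)
  )
  ke <- vapply(seq_len(nrow(sim)), function(i) {
    q <- c(sim$q1[i], sim$q2[i], sim$q3[i])
    qd <- c(sim$qdot1[i], sim$qdot2[i], sim$qdot3[i])
    0.5 * sum(qd * (inertia_matrix(q, p) %*% qd))
  }, numeric(1))
  expect_true(all(diff(ke) <= 1e-12))
})

test_that("PD+ torque reduces to gravity compensation at the set-point", {
  p <- robot_params()
  gains <- control_gains()
  q <- c(0.2, 0.5, -0.4)
  tau <- pdplus_torque(q, c(0, 0, 0), qd = q, gains = gains, params = p)
  expect_equal(tau, gravity_vector(q, p), tolerance = 1e-12)

  # doubling the position error doubles only the Kp contribution
  qd1 <- q + c(0.1, 0.1, 0.1)
  qd2 <- q + c(0.2, 0.2, 0.2)
  t1 <- pdplus_torque(q, c(0, 0, 0), qd1, gains = gains, params = p)
  t2 <- pdplus_torque(q, c(0, 0, 0), qd2, gains = gains, params = p)
  expect_equal(
    t2 - t1, as.numeric(gains$Kp %*% c(0.1, 0.1, 0.1)),
    tolerance = 1e-12
  )
})

test_that("controller gains must be symmetric positive-definite", {
  expect_error(control_gains(Kp = -5), "positive definite")
  expect_error(control_gains(Kp = matrix(1:9, 3)), "symmetric")
  g <- control_gains(Kp = c(50, 100, 80), Kv = 15)
  expect_equal(diag(g$Kp), c(50, 100, 80))
  expect_equal(g$Kv, diag(rep(15, 3)))
})
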