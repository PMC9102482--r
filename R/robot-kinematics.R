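#' Manipulator parameters
#'
#' Parameters of the 3-DOF anthropomorphic arm: link lengths `l1..l3` (m),
#' center-of-mass distances `lc1..lc3` (m, measured from the proximal joint),
#' masses `m1..m3` (kg), link moments of inertia `I1..I3` (kg m^2), viscous
#' friction coefficients `B1..B3` (N m s/rad) and gravity `g` (m/s^2).
#' Defaults (desk-scale links, every command set-point reachable) ship as the
#' package's JSON config.
#'
#' @param ... Named overrides of the default parameters.
#' @param path Optional JSON file to load instead of the shipped defaults.
#' @return A `robot_params` list.
#' @export
#' @examples
#' robot_params()
#' robot_params(l2 = 0.3, l3 = 0.3)
robot_params <- function(..., path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "robot_params.json",
      package = "myohmi", mustWork = TRUE
    )
  }
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  dots <- list(...)
  if (length(dots) > 0) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad) > 0 || is.null(names(dots)) || any(names(dots) == "")) {
      rlang::abort(paste0(
        "Unknown robot parameter(s): ", paste(bad, collapse = ", ")
      ))
    }
    p[names(dots)] <- dots
  }
  with(p, {
    if (any(c(l1, l2, l3, m1, m2, m3) <= 0)) {
      rlang::abort("Link lengths and masses must be positive.")
    }
    if (lc1 <= 0 || lc1 > l1 || lc2 <= 0 || lc2 > l2 || lc3 <= 0 || lc3 > l3) {
      rlang::abort("Center-of-mass distances must satisfy 0 < lc_i <= l_i.")
    }
    if (any(c(B1, B2, B3) < 0) || any(c(I1, I2, I3) < 0)) {
      rlang::abort("Friction and inertia must be non-negative.")
    }
  })
  structure(p, class = "robot_params")
}

#' @export
print.robot_params <- function(x, ...) {
  cat(sprintf(
    "<robot_params> l = (%g, %g, %g) m, m = (%g, %g, %g) kg, g = %g m/s^2\n",
    x$l1, x$l2, x$l3, x$m1, x$m2, x$m3, x$g
  ))
  invisible(x)
}

#' Forward kinematics
#'
#' End-effector position of the 3R anthropomorphic chain: base rotation `q1`
#' about the vertical axis, shoulder `q2` and elbow `q3` in the vertical
#' plane. Uses the full link lengths `l2`, `l3` so that forward and inverse
#' kinematics are exact inverses:
#' `px = cos(q1) (l3 cos(q2+q3) + l2 cos q2)`,
#' `py = sin(q1) (l3 cos(q2+q3) + l2 cos q2)`,
#' `pz = l1 + l3 sin(q2+q3) + l2 sin q2`.
#'
#' @param q Joint angles, a numeric 3-vector (rad) or a 3-column matrix.
#' @param params A [robot_params()].
#' @return A named vector `px`, `py`, `pz` (m), or a tibble for matrix input.
#' @export
#' @examples
#' forward_kinematics(c(0, 0, 0), robot_params()) # (l2 + l3, 0, l1)
forward_kinematics <- function(q, params = robot_params()) {
  if (is.matrix(q)) {
    stopifnot(ncol(q) == 3)
    r <- params$l3 * cos(q[, 2] + q[, 3]) + params$l2 * cos(q[, 2])
    return(tibble::tibble(
      px = cos(q[, 1]) * r,
      py = sin(q[, 1]) * r,
      pz = params$l1 + params$l3 * sin(q[, 2] + q[, 3]) +
        params$l2 * sin(q[, 2])
    ))
  }
  stopifnot(length(q) == 3)
  r <- params$l3 * cos(q[2] + q[3]) + params$l2 * cos(q[2])
  c(
    px = cos(q[1]) * r,
    py = sin(q[1]) * r,
    pz = params$l1 + params$l3 * sin(q[2] + q[3]) + params$l2 * sin(q[2])
  )
}

#' Inverse kinematics
#'
#' Closed-form inverse of [forward_kinematics()]. With
#' `q1 = atan2(py, px)`, radial reach `r = px cos q1 + py sin q1` and height
#' `u = pz - l1`, the shoulder angle solves `a cos q2 + b sin q2 = c` via the
#' tangent half-angle form `q2 = 2 atan2(b + s sqrt(a^2 + b^2 - c^2), a + c)`
#' with `a = 2 l2 r`, `b = 2 l2 u`, `c = r^2 + u^2 + l2^2 - l3^2` and elbow
#' branch sign `s`; the elbow angle follows exactly from
#' `cos q3 = (r cos q2 + u sin q2 - l2)/l3`,
#' `sin q3 = (u cos q2 - r sin q2)/l3`.
#'
#' A point with `px = py = 0` leaves `q1` undefined; it is resolved to
#' `q1 = 0` with a warning. Unreachable points raise a workspace error.
#'
#' @param p Target position: named or positional 3-vector (m).
#' @param params A [robot_params()].
#' @param elbow `"up"` (`s = +1`) or `"down"` (`s = -1`) branch.
#' @return Named joint vector `q1`, `q2`, `q3` (rad).
#' @export
#' @examples
#' q <- inverse_kinematics(c(0, -0.34, 0.38))
#' forward_kinematics(q)
inverse_kinematics <- function(p, params = robot_params(),
                               elbow = c("up", "down")) {
  elbow <- match.arg(elbow)
  s <- if (elbow == "up") 1 else -1
  p <- as.numeric(p)
  stopifnot(length(p) == 3)
  px <- p[1]
  py <- p[2]
  pz <- p[3]
  if (px == 0 && py == 0) {
    rlang::warn("px = py = 0: base angle q1 is singular; using q1 = 0.")
    q1 <- 0
  } else {
    q1 <- atan2(py, px)
  }
  r <- px * cos(q1) + py * sin(q1)
  u <- pz - params$l1
  d2 <- r^2 + u^2
  l2 <- params$l2
  l3 <- params$l3
  if (d2 > (l2 + l3)^2 + 1e-12 || d2 < (l2 - l3)^2 - 1e-12) {
    rlang::abort(sprintf(
      "Point (%.3f, %.3f, %.3f) is outside the workspace.", px, py, pz
    ))
  }
  a <- 2 * l2 * r
  b <- 2 * l2 * u
  cc <- d2 + l2^2 - l3^2
  disc <- max(a^2 + b^2 - cc^2, 0) # clamp roundoff at workspace boundary
  q2 <- 2 * atan2(b + s * sqrt(disc), a + cc)
  cos_q3 <- (r * cos(q2) + u * sin(q2) - l2) / l3
  sin_q3 <- (u * cos(q2) - r * sin(q2)) / l3
  q3 <- atan2(sin_q3, cos_q3)
  c(q1 = q1, q2 = q2, q3 = q3)
}
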