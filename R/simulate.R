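#' Simulate the pulse response of a seat model
#'
#' Integrates the state-space equations from rest under a triangular
#' floor-displacement pulse with a fixed-step classical 4th-order Runge-Kutta
#' scheme. A fine step is used while the (short) pulse is active and a
#' coarser step afterwards; both are fixed so that runs are exactly
#' reproducible. The pulse response is deterministic, so `nsim` and `seed`
#' are accepted for generic compatibility only.
#'
#' The step sizes are validated against the pulse duration (at least four
#' steps across the pulse) and the fastest undamped mode (at least 20 steps
#' per period); a too-coarse step raises an error rather than silently
#' aliasing the excitation.
#'
#' @param object a [seat_model()]
#' @param nsim,seed ignored (deterministic simulation)
#' @param pulse a [pulse_input()]
#' @param t_max simulation length (s)
#' @param dt integration step during the pulse (s)
#' @param dt_after integration step after the pulse (s)
#' @param ... unused
#' @return data.frame of class `wbv_trajectory` with columns `t`, `z1`,
#'   `z1d`, `z2`, `z2d` (states, m and m/s) and `z2dd` (operator
#'   acceleration, m/s^2).
#' @examples
#' m <- seat_model(56, 84, 62800, 28723, 1600, 677.6)
#' tr <- simulate(m, pulse = pulse_input(0.03, 5.4), t_max = 1)
#' max(tr$z2) * 1000  # peak operator displacement in mm
#' @export
simulate.seat_model <- function(object, nsim = 1, seed = NULL,
                                pulse = pulse_input(), t_max = 3,
                                dt = 1e-4, dt_after = 1e-3, ...) {
  stopifnot(inherits(pulse, "pulse_input"))
  if (t_max <= 0) stop("'t_max' must be positive", call. = FALSE)
  if (dt <= 0 || dt_after <= 0) stop("step sizes must be positive", call. = FALSE)
  f_max <- max(natural_frequencies(object))
  if (dt > 1 / (20 * f_max))
    stop(sprintf(
      "resolution error: dt = %g s does not resolve the fastest mode (%.2f Hz); need dt <= %g",
      dt, f_max, 1 / (20 * f_max)), call. = FALSE)
  if (dt_after > 1 / (20 * f_max))
    stop(sprintf(
      "resolution error: dt_after = %g s does not resolve the fastest mode (%.2f Hz); need dt_after <= %g",
      dt_after, f_max, 1 / (20 * f_max)), call. = FALSE)
  if (pulse$peak > 0 && dt > pulse$duration / 4)
    stop(sprintf(
      "resolution error: dt = %g s is coarser than a quarter of the pulse (%g s)",
      dt, pulse$duration), call. = FALSE)

  # integration grid aligned with the pulse breakpoints: within each phase
  # the input is linear in t, so the scheme never steps across a slope
  # discontinuity
  breaks <- c(0, if (pulse$peak > 0) c(pulse$t_rise, pulse$duration), t_max)
  breaks <- sort(unique(breaks[breaks <= t_max]))
  if (breaks[length(breaks)] < t_max) breaks <- c(breaks, t_max)
  tgrid <- 0
  for (j in seq_len(length(breaks) - 1L)) {
    a <- breaks[j]; b <- breaks[j + 1L]
    h_target <- if (b <= pulse$duration && pulse$peak > 0) dt else dt_after
    nseg <- max(1L, ceiling((b - a) / h_target))
    tgrid <- c(tgrid, seq(a, b, length.out = nseg + 1L)[-1L])
  }

  # input over one step, evaluated from the step midpoint's phase: the grid
  # never straddles a breakpoint, so the pulse is exactly linear across the
  # step and one-sided at its ends (no O(h) error from the velocity jumps)
  u_of_step <- function(tk, h) {
    w <- triangular_pulse(pulse, tk + h / 2)
    rbind(w$z0 + w$z0d * c(-h / 2, 0, h / 2), rep(w$z0d, 3L))
  }
  A <- object$A
  B <- object$B
  n <- length(tgrid)
  X <- matrix(0, 4L, n)
  x <- numeric(4L)
  deriv <- function(x, u) A %*% x + B %*% u
  for (k in seq_len(n - 1L)) {
    h <- tgrid[k + 1L] - tgrid[k]
    u <- u_of_step(tgrid[k], h)
    k1 <- deriv(x, u[, 1L])
    k2 <- deriv(x + h / 2 * k1, u[, 2L])
    k3 <- deriv(x + h / 2 * k2, u[, 2L])
    k4 <- deriv(x + h * k3, u[, 3L])
    x <- x + h / 6 * as.numeric(k1 + 2 * k2 + 2 * k3 + k4)
    X[, k + 1L] <- x
  }
  z2dd <- as.numeric(A["z2d", ] %*% X)  # B row for z2d is zero
  structure(data.frame(t = tgrid, z1 = X[1L, ], z1d = X[2L, ],
                       z2 = X[3L, ], z2d = X[4L, ], z2dd = z2dd),
            pulse = pulse, class = c("wbv_trajectory", "data.frame"))
}

#' Total mechanical energy along a simulated trajectory
#'
#' Kinetic plus elastic energy of the two-mass system,
#' \eqn{E = \tfrac12 m_1\dot z_1^2 + \tfrac12 m_2\dot z_2^2 +
#' \tfrac12 k_1 (z_1 - z_0)^2 + \tfrac12 k_2 (z_1 - z_2)^2}.
#' After the pulse (z0 = 0) this must decay monotonically for any positive
#' damping, which the test-suite uses as an integrator diagnostic.
#'
#' @param model a [seat_model()]
#' @param trajectory a `wbv_trajectory` from [simulate.seat_model()]
#' @return numeric vector of energies (J), one per sample
#' @export
trajectory_energy <- function(model, trajectory) {
  stopifnot(inherits(model, "seat_model"), inherits(trajectory, "wbv_trajectory"))
  p <- attr(trajectory, "pulse")
  z0 <- triangular_pulse(p, trajectory$t)$z0
  0.5 * model$m1 * trajectory$z1d^2 + 0.5 * model$m2 * trajectory$z2d^2 +
    0.5 * model$k1 * (trajectory$z1 - z0)^2 +
    0.5 * model$k2 * (trajectory$z1 - trajectory$z2)^2
}
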