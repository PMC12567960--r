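# Shared fixtures and independent oracles for the suite.

case_model <- function(i) {
  cs <- seat_case_catalog()[i, ]
  seat_model(m1 = cs$m1, m2 = cs$m2, k1 = cs$k1, k2 = cs$k2,
             b1 = cs$b1, b2 = cs$b2, label = cs$label)
}

# Independent re-derivation of the system matrix from the second-order form
# M xdd + Cd xd + K x = f: A = [[0, I], [-M^-1 K, -M^-1 Cd]] in (pos, vel)
# block order, then permuted to the (z1, z1d, z2, z2d) state order.
second_order_A <- function(m1, m2, k1, k2, b1, b2) {
  M <- diag(c(m1, m2))
  K <- rbind(c(k1 + k2, -k2), c(-k2, k2))
  Cd <- rbind(c(b1 + b2, -b2), c(-b2, b2))
  blk <- rbind(cbind(matrix(0, 2, 2), diag(2)),
               cbind(-solve(M, K), -solve(M, Cd)))
  perm <- c(1, 3, 2, 4)  # (z1, z2, z1d, z2d) -> (z1, z1d, z2, z2d)
  blk[perm, perm]
}

# Direct integration of the two coupled second-order equations of motion
# with deSolve (adaptive lsoda at tight tolerance); written without
# reference to the package's state-space matrices.
ode_oracle_z2 <- function(m1, m2, k1, k2, b1, b2, pulse, times) {
  derivs <- function(t, y, parms) {
    w <- triangular_pulse(pulse, t)
    z0 <- w$z0; z0d <- w$z0d
    z1 <- y[1]; z1d <- y[2]; z2 <- y[3]; z2d <- y[4]
    z1dd <- (b1 * (z0d - z1d) + k1 * (z0 - z1) +
               b2 * (z2d - z1d) + k2 * (z2 - z1)) / m1
    z2dd <- (b2 * (z1d - z2d) + k2 * (z1 - z2)) / m2
    list(c(z1d, z1dd, z2d, z2dd))
  }
  out <- deSolve::lsoda(c(0, 0, 0, 0), times, derivs, NULL,
                        rtol = 1e-11, atol = 1e-13)
  out[, 4]
}

# Log-decrement damping estimate from successive positive peaks of a
# free-decay record.
log_decrement_zeta <- function(x) {
  pk <- which(diff(sign(diff(x))) == -2) + 1L
  pk <- pk[x[pk] > 0]
  stopifnot(length(pk) >= 3L)
  amps <- x[pk]
  delta <- mean(diff(-log(amps)))
  delta / sqrt(4 * pi^2 + delta^2)
}

make_signal <- function(ax, ay, az, fs = 256) triaxial_signal(fs, ax, ay, az)
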