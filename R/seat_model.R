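#' Two-mass suspension-seat model
#'
#' Constructs the lumped-parameter model of a seated operator on a suspension
#' seat: seat mass `m1` on a suspension spring/damper (`k1`, `b1`) to the
#' cabin floor, operator mass `m2` on the cushion spring/damper (`k2`, `b2`).
#' Vertical displacements are measured from static equilibrium; the floor
#' displacement `z0(t)` is the input.
#'
#' The equations of motion are
#' \deqn{m_1 \ddot z_1 + b_1\dot z_1 + b_2(\dot z_1-\dot z_2) + k_1 z_1 +
#'       k_2(z_1-z_2) = b_1\dot z_0 + k_1 z_0}
#' \deqn{m_2 \ddot z_2 + b_2(\dot z_2-\dot z_1) + k_2(z_2-z_1) = 0}
#' realized in state-space form with state \eqn{(z_1,\dot z_1,z_2,\dot z_2)},
#' inputs \eqn{(z_0,\dot z_0)} and outputs \eqn{(z_2,\ddot z_2)}.
#'
#' @param m1 seat mass (kg)
#' @param m2 operator (driver) mass (kg)
#' @param k1 suspension stiffness (N/m)
#' @param k2 cushion stiffness (N/m)
#' @param b1 suspension damping (N s/m)
#' @param b2 cushion damping (N s/m)
#' @param label free-text case name
#' @return An object of class `seat_model`: a list with the six parameters,
#'   `label`, and the state-space matrices `A` (4x4), `B` (4x2), `C` (2x4),
#'   `D` (2x2) with dimnames naming states, inputs and outputs.
#' @seealso [predict.seat_model()] for transmissibility,
#'   [simulate.seat_model()] for the pulse response,
#'   [natural_frequencies()], [damping_ratio()], [seat_case_catalog()].
#' @examples
#' m <- seat_model(m1 = 56, m2 = 84, k1 = 62800, k2 = 28723,
#'                 b1 = 1600, b2 = 677.6, label = "Case 1")
#' m
#' coef(m)
#' @export
seat_model <- function(m1, m2, k1, k2, b1, b2, label = "") {
  p <- c(m1 = m1, m2 = m2, k1 = k1, k2 = k2, b1 = b1, b2 = b2)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("parameter '%s' must be a single strictly positive number", nm),
           call. = FALSE)
  }
  ss <- build_state_space(m1, m2, k1, k2, b1, b2)
  structure(c(as.list(p), list(label = as.character(label)[1L]), ss),
            class = "seat_model")
}

# State-space realization. State order (z1, z1d, z2, z2d); inputs (z0, z0d);
# outputs (z2, z2dd).
build_state_space <- function(m1, m2, k1, k2, b1, b2) {
  st <- c("z1", "z1d", "z2", "z2d")
  A <- rbind(
    c(0, 1, 0, 0),
    c(-(k1 + k2) / m1, -(b1 + b2) / m1, k2 / m1, b2 / m1),
    c(0, 0, 0, 1),
    c(k2 / m2, b2 / m2, -k2 / m2, -b2 / m2))
  B <- rbind(c(0, 0), c(k1 / m1, b1 / m1), c(0, 0), c(0, 0))
  C <- rbind(c(0, 0, 1, 0), A[4L, ])
  D <- matrix(0, 2L, 2L)
  dimnames(A) <- list(st, st)
  dimnames(B) <- list(st, c("z0", "z0d"))
  dimnames(C) <- list(c("z2", "z2dd"), st)
  dimnames(D) <- list(c("z2", "z2dd"), c("z0", "z0d"))
  list(A = A, B = B, C = C, D = D)
}

#' @export
coef.seat_model <- function(object, ...) {
  unlist(object[c("m1", "m2", "k1", "k2", "b1", "b2")])
}

#' @export
print.seat_model <- function(x, ...) {
  cat("Two-mass suspension-seat model",
      if (nzchar(x$label)) paste0(" (", x$label, ")"), "\n", sep = "")
  cat(sprintf("  seat:      m1 = %g kg, k1 = %g N/m, b1 = %g N s/m\n",
              x$m1, x$k1, x$b1))
  cat(sprintf("  operator:  m2 = %g kg, k2 = %g N/m, b2 = %g N s/m\n",
              x$m2, x$k2, x$b2))
  fn <- natural_frequencies(x)
  cat(sprintf("  undamped natural frequencies: %.2f, %.2f Hz\n", fn[1L], fn[2L]))
  invisible(x)
}

#' Summarize a seat model
#'
#' Reports the parameters, the undamped natural frequencies, the single-DOF
#' damping ratios of each stage, and the displacement-transmissibility peak
#' located on a fine grid.
#'
#' @param object a [seat_model()]
#' @param fmin,fmax,df frequency grid (Hz) used to locate the
#'   transmissibility peak
#' @param ... unused
#' @return A list of class `summary.seat_model`.
#' @export
summary.seat_model <- function(object, fmin = 0.1, fmax = 10, df = 0.01, ...) {
  frf <- predict(object, frequency = seq(fmin, fmax, by = df))
  out <- list(
    label = object$label,
    coef = coef(object),
    natural_frequencies = natural_frequencies(object),
    zeta_suspension = damping_ratio(object$b1, object$m1 + object$m2, object$k1),
    zeta_cushion = damping_ratio(object$b2, object$m2, object$k2),
    peak_value = attr(frf, "peak_value"),
    peak_frequency = attr(frf, "peak_frequency"))
  class(out) <- "summary.seat_model"
  out
}

#' @export
print.summary.seat_model <- function(x, ...) {
  cat("Two-mass suspension-seat model",
      if (nzchar(x$label)) paste0(" (", x$label, ")"), "\n", sep = "")
  print(x$coef)
  cat(sprintf("Undamped natural frequencies: %.3f, %.3f Hz\n",
              x$natural_frequencies[1L], x$natural_frequencies[2L]))
  cat(sprintf("Stage damping ratios: suspension %.3f, cushion %.3f\n",
              x$zeta_suspension, x$zeta_cushion))
  cat(sprintf("Transmissibility peak |Z2/Z0| = %.3f at %.2f Hz\n",
              x$peak_value, x$peak_frequency))
  invisible(x)
}

#' Undamped natural frequencies of the two-mass system
#'
#' Eigenfrequencies of the conservative system with mass matrix
#' `diag(m1, m2)` and stiffness matrix `[[k1 + k2, -k2], [-k2, k2]]`,
#' returned in Hz sorted ascending.
#'
#' @param model a [seat_model()]
#' @return Numeric vector of length 2 (Hz).
#' @export
natural_frequencies <- function(model) {
  stopifnot(inherits(model, "seat_model"))
  M <- diag(c(model$m1, model$m2))
  K <- rbind(c(model$k1 + model$k2, -model$k2), c(-model$k2, model$k2))
  lam <- eigen(solve(M, K), only.values = TRUE)$values
  lam <- sort(Re(lam))
  lam[lam < 0 & lam > -1e-9] <- 0
  sqrt(lam) / (2 * pi)
}

#' Viscous damping ratio of a single-DOF oscillator
#'
#' \eqn{\zeta = b / (2\sqrt{m k})}, the fraction of critical damping.
#'
#' @param b viscous damping (N s/m), non-negative
#' @param m mass (kg), positive
#' @param k stiffness (N/m), positive
#' @return Dimensionless damping ratio.
#' @examples
#' damping_ratio(b = 1600, m = 110.5, k = 28723)  # ~0.45
#' @export
damping_ratio <- function(b, m, k) {
  if (!is.numeric(m) || any(m <= 0)) stop("mass 'm' must be positive", call. = FALSE)
  if (!is.numeric(k) || any(k <= 0)) stop("stiffness 'k' must be positive", call. = FALSE)
  if (!is.numeric(b) || any(b < 0)) stop("damping 'b' must be non-negative", call. = FALSE)
  b / (2 * sqrt(m * k))
}
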