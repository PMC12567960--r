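#' Triangular floor-displacement pulse
#'
#' Describes the cabin-floor input used for the time-domain simulations: a
#' triangular displacement bump `z0(t)` reaching `peak` metres at a constant
#' vertical rise rate (m/s). Two shapes are supported:
#'
#' * `"triangle"` (default): isosceles rise-and-fall, total duration
#'   `2 * peak / rise_rate`;
#' * `"sawtooth"`: rise at `rise_rate` then an immediate linear return within
#'   the same total duration `peak / rise_rate` scaled so the ramp down takes
#'   a vanishing fraction (`fall_fraction`) of the rise time. The return leg
#'   keeps `z0` continuous; a true jump would carry infinite velocity.
#'
#' @param peak displacement peak (m), positive
#' @param rise_rate constant vertical velocity of the rise (m/s), positive
#' @param shape `"triangle"` or `"sawtooth"`
#' @param fall_fraction for `"sawtooth"`, fall time as a fraction of the rise
#'   time (default 0.05)
#' @return Object of class `pulse_input` with fields `peak`, `rise_rate`,
#'   `shape`, `t_rise`, `t_fall` and `duration` (s).
#' @examples
#' p <- pulse_input(peak = 0.03, rise_rate = 5.4)  # ~11.1 ms total
#' p$duration
#' @export
pulse_input <- function(peak = 0.03, rise_rate = 5.4,
                        shape = c("triangle", "sawtooth"),
                        fall_fraction = 0.05) {
  shape <- match.arg(shape)
  if (!is.numeric(peak) || length(peak) != 1L || peak < 0)
    stop("'peak' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(rise_rate) || length(rise_rate) != 1L || rise_rate <= 0)
    stop("'rise_rate' must be a single positive number", call. = FALSE)
  t_rise <- peak / rise_rate
  t_fall <- if (shape == "triangle") t_rise else fall_fraction * t_rise
  structure(list(peak = peak, rise_rate = rise_rate, shape = shape,
                 t_rise = t_rise, t_fall = t_fall,
                 duration = t_rise + t_fall),
            class = "pulse_input")
}

#' @export
print.pulse_input <- function(x, ...) {
  cat(sprintf("Triangular floor pulse (%s): peak %g m, rise rate %g m/s, total %.4g ms\n",
              x$shape, x$peak, x$rise_rate, 1000 * x$duration))
  invisible(x)
}

#' Sample a floor pulse as displacement/velocity waveforms
#'
#' Evaluates `z0(t)` (piecewise linear, zero outside the pulse) and its
#' derivative (piecewise constant) on arbitrary times. The pair is exactly
#' consistent: the velocity is the slope of the displacement everywhere it is
#' defined.
#'
#' @param pulse a [pulse_input()]
#' @param t numeric vector of times (s)
#' @return data.frame with columns `t`, `z0` (m), `z0d` (m/s)
#' @examples
#' tp <- triangular_pulse(pulse_input(0.03, 5.4), seq(0, 0.015, by = 1e-4))
#' max(tp$z0)        # 0.03
#' max(abs(tp$z0d))  # 5.4
#' @export
triangular_pulse <- function(pulse, t) {
  stopifnot(inherits(pulse, "pulse_input"))
  tr <- pulse$t_rise; tf <- pulse$t_fall; pk <- pulse$peak
  z0 <- numeric(length(t)); z0d <- numeric(length(t))
  if (pk > 0) {
    up <- t >= 0 & t < tr
    dn <- t >= tr & t < tr + tf
    z0[up] <- pulse$rise_rate * t[up]
    z0d[up] <- pulse$rise_rate
    if (tf > 0) {
      z0[dn] <- pk * (1 - (t[dn] - tr) / tf)
      z0d[dn] <- -pk / tf
    }
  }
  data.frame(t = t, z0 = z0, z0d = z0d)
}
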