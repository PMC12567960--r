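#' ISO 2631-1 frequency weightings Wk and Wd
#'
#' Health-related whole-body-vibration weightings for a seated person:
#' `Wk` for the vertical (Z) axis and `Wd` for the horizontal (X, Y) axes.
#' Each weighting is the cascade of four analog second-order sections:
#' a band-limiting two-pole high-pass (0.4 Hz) and low-pass (100 Hz), an
#' acceleration-velocity transition, and (for Wk) an upward step. The
#' section corner frequencies and Q factors are the standard's values.
#'
#' `weighting_gain()` evaluates the exact analog magnitude response and
#' serves as the reference against which the sampled-data filter is checked.
#' `apply_weighting()` filters a time series with the digital realization:
#' each analog section is mapped to a biquad by the bilinear transform at the
#' signal's sample rate and applied in cascade.
#'
#' @param f frequency (Hz), vectorized
#' @param name `"Wk"` or `"Wd"`
#' @return `weighting_gain`: numeric vector of gains |H(f)|.
#' @examples
#' weighting_gain(5, "Wk")   # ~1.04: near-unity in the 4-8 Hz band
#' weighting_gain(1, "Wd")   # ~1.01: Wd passes 1-2 Hz
#' @export
weighting_gain <- function(f, name = c("Wk", "Wd")) {
  name <- match.arg(name)
  sec <- weighting_sections(name)
  s <- 2i * pi * f
  H <- rep(1 + 0i, length(f))
  for (sc in sec) {
    num <- sc$b[1L] * s^2 + sc$b[2L] * s + sc$b[3L]
    den <- sc$a[1L] * s^2 + sc$a[2L] * s + sc$a[3L]
    H <- H * num / den
  }
  Mod(H)
}

# Analog second-order sections (b, a are s-domain polynomial coefficients in
# decreasing powers). Corner frequencies / Q factors per the standard:
# band-limit f1 = 0.4 Hz, f2 = 100 Hz (Butterworth, Q = 1/sqrt2);
# a-v transition f3 = f4 (12.5 Hz for Wk, 2 Hz for Wd), Q4 = 0.63;
# upward step f5 = 2.37, f6 = 3.35 Hz, Q5 = Q6 = 0.91 (Wk only).
weighting_sections <- function(name) {
  q12 <- 1 / sqrt(2)
  w1 <- 2 * pi * 0.4
  w2 <- 2 * pi * 100
  sec <- list(
    list(b = c(1, 0, 0), a = c(1, w1 / q12, w1^2)),       # high-pass
    list(b = c(0, 0, w2^2), a = c(1, w2 / q12, w2^2)))    # low-pass
  if (name == "Wk") {
    w3 <- 2 * pi * 12.5; w4 <- w3; q4 <- 0.63
    w5 <- 2 * pi * 2.37; w6 <- 2 * pi * 3.35; q5 <- 0.91; q6 <- 0.91
    sec <- c(sec, list(
      list(b = c(0, w4^2 / w3, w4^2), a = c(1, w4 / q4, w4^2)),  # a-v transition
      list(b = c(1, w5 / q5, w5^2), a = c(1, w6 / q6, w6^2))))   # upward step
  } else {
    w3 <- 2 * pi * 2; w4 <- w3; q4 <- 0.63
    sec <- c(sec, list(
      list(b = c(0, w4^2 / w3, w4^2), a = c(1, w4 / q4, w4^2))))
  }
  sec
}

# Bilinear transform of one analog second-order section to a digital biquad
# at sample rate fs (no pre-warping; corner frequencies here are far below
# any practical fs so warping is negligible).
bilinear_sos <- function(sec, fs) {
  K <- 2 * fs
  b <- sec$b; a <- sec$a
  # substitute s = K (1 - z^-1) / (1 + z^-1) into (b1 s^2 + b2 s + b3)/(...)
  num <- c(b[1L] * K^2 + b[2L] * K + b[3L],
           -2 * b[1L] * K^2 + 2 * b[3L],
           b[1L] * K^2 - b[2L] * K + b[3L])
  den <- c(a[1L] * K^2 + a[2L] * K + a[3L],
           -2 * a[1L] * K^2 + 2 * a[3L],
           a[1L] * K^2 - a[2L] * K + a[3L])
  list(b = num / den[1L], a = den / den[1L])
}

#' Apply a frequency weighting to an acceleration channel
#'
#' @param x numeric acceleration samples (m/s^2)
#' @param fs sample rate (Hz)
#' @param name `"Wk"` or `"Wd"`
#' @param strict if `TRUE`, a sample rate below 200 Hz is an error; otherwise
#'   a warning (the digital sections lose fidelity near Nyquist)
#' @return `weight_channel`: the weighted samples, same length as `x`.
#' @rdname weighting_gain
#' @export
weight_channel <- function(x, fs, name = c("Wk", "Wd"), strict = FALSE) {
  name <- match.arg(name)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive sample rate", call. = FALSE)
  if (fs < 200) {
    msg <- sprintf("sample rate %g Hz is below the recommended 200 Hz for weighting fidelity", fs)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  y <- as.numeric(x)
  for (sc in weighting_sections(name)) {
    dz <- bilinear_sos(sc, fs)
    y <- as.numeric(signal::filter(dz$b, dz$a, y))
  }
  y
}

#' Frequency-weight a triaxial signal
#'
#' Applies `Wd` to the X and Y channels and `Wk` to Z, the axis map for
#' vibration entering a seated person through the supporting surface.
#'
#' @param signal a [triaxial_signal()]
#' @param strict passed to [weight_channel()]
#' @return A weighted [triaxial_signal()] with the same sample rate and length.
#' @rdname weighting_gain
#' @export
apply_weighting <- function(signal, strict = FALSE) {
  stopifnot(inherits(signal, "triaxial_signal"))
  triaxial_signal(fs = signal$fs,
                  ax = weight_channel(signal$ax, signal$fs, "Wd", strict),
                  ay = weight_channel(signal$ay, signal$fs, "Wd", strict),
                  az = weight_channel(signal$az, signal$fs, "Wk", strict),
                  t0 = signal$t0)
}
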