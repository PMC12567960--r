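#' Root-mean-square of an acceleration channel
#'
#' @param x numeric samples (m/s^2), non-empty
#' @return \eqn{\sqrt{\mathrm{mean}(x^2)}}
#' @export
weighted_rms <- function(x) {
  if (length(x) == 0L) stop("empty channel", call. = FALSE)
  sqrt(mean(x^2))
}

#' Resultant (vector-combined) weighted acceleration
#'
#' Combines per-axis weighted RMS values into the resultant
#' \eqn{a_{re} = \sqrt{(f_x a_x)^2 + (f_y a_y)^2 + (f_z a_z)^2}} with the
#' seated-health axis multipliers, 1.4 for the horizontal axes and 1.0 for
#' vertical by default.
#'
#' @param rms_x,rms_y,rms_z per-axis weighted RMS (m/s^2), non-negative
#' @param multipliers length-3 axis multipliers (x, y, z)
#' @return resultant acceleration (m/s^2)
#' @examples
#' resultant_acceleration(0.1, 0.1, 0.5)  # 0.5378
#' @export
resultant_acceleration <- function(rms_x, rms_y, rms_z,
                                   multipliers = c(1.4, 1.4, 1.0)) {
  v <- c(rms_x, rms_y, rms_z)
  if (any(v < 0)) stop("RMS values must be non-negative", call. = FALSE)
  sqrt(sum((multipliers * v)^2))
}

#' Normalize exposure to the 8-hour working day: A(8)
#'
#' \eqn{A(8) = a_{re} \sqrt{T / 8\,\mathrm{h}}}, the daily vibration
#' exposure referenced to eight hours. When a measurement is treated as
#' representative of the full shift, `exposure_duration` is 8 h and A(8)
#' equals the resultant RMS.
#'
#' @param are resultant weighted RMS (m/s^2)
#' @param exposure_duration daily exposure duration (s)
#' @return A(8) in m/s^2
#' @examples
#' a8_normalize(0.517, 8 * 3600)  # 0.517 -> prints as 0.52
#' a8_normalize(1.0, 2 * 3600)    # factor 0.5
#' @export
a8_normalize <- function(are, exposure_duration) {
  if (any(are < 0)) stop("'are' must be non-negative", call. = FALSE)
  if (!is.numeric(exposure_duration) || any(exposure_duration <= 0))
    stop("'exposure_duration' must be positive", call. = FALSE)
  are * sqrt(exposure_duration / (8 * 3600))
}

#' Vibration dose value of a weighted channel
#'
#' Fourth-power dose \eqn{VDV = (\int a_w(t)^4\,dt)^{1/4}} in m/s^1.75,
#' integrated by the trapezoidal rule on the sample grid. The fourth power
#' makes the dose far more sensitive to shock content than RMS.
#'
#' @param x weighted acceleration samples (m/s^2), non-empty
#' @param fs sample rate (Hz)
#' @return VDV (m/s^1.75)
#' @examples
#' vdv(rep(2, 1001), fs = 100)  # constant a over T: a * T^(1/4)
#' @export
vdv <- function(x, fs) {
  if (length(x) == 0L) stop("empty channel", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive sample rate", call. = FALSE)
  y <- x^4
  n <- length(y)
  integral <- (sum(y) - (y[1L] + y[n]) / 2) / fs
  integral^0.25
}

#' Normalize a measured VDV to the full working day
#'
#' \eqn{VDV_{day} = VDV_{meas} (T_{exp}/T_{meas})^{1/4}} -- the fourth-root
#' law assuming the measurement window is representative of the exposure.
#'
#' @param vdv_meas measured VDV (m/s^1.75)
#' @param t_meas measurement duration (s)
#' @param t_exposure daily exposure duration (s)
#' @return day-normalized VDV (m/s^1.75)
#' @examples
#' vdv_normalize(5.45, 30 * 60, 8 * 3600)  # 5.45 * 16^(1/4) = 10.9
#' @export
vdv_normalize <- function(vdv_meas, t_meas, t_exposure) {
  if (any(vdv_meas < 0)) stop("'vdv_meas' must be non-negative", call. = FALSE)
  if (any(t_meas <= 0) || any(t_exposure <= 0))
    stop("durations must be positive", call. = FALSE)
  vdv_meas * (t_exposure / t_meas)^0.25
}

#' Combine per-axis VDV values into the resultant dose
#'
#' \eqn{VDV_{re} = ((f_x v_x)^4 + (f_y v_y)^4 + (f_z v_z)^4)^{1/4}} with the
#' same axis multipliers as [resultant_acceleration()].
#'
#' @param vdv_x,vdv_y,vdv_z per-axis VDV (m/s^1.75), non-negative
#' @param multipliers length-3 axis multipliers (x, y, z)
#' @return resultant VDV (m/s^1.75)
#' @export
combine_vdv_axes <- function(vdv_x, vdv_y, vdv_z,
                             multipliers = c(1.4, 1.4, 1.0)) {
  v <- c(vdv_x, vdv_y, vdv_z)
  if (any(v < 0)) stop("VDV values must be non-negative", call. = FALSE)
  sum((multipliers * v)^4)^0.25
}

#' NHO-09 decision criteria for whole-body vibration
#'
#' Action levels, uncertainty band and tolerance limits for A(8) (m/s^2) and
#' VDV (m/s^1.75) with the recommended practice per band, as set by the
#' Brazilian occupational-hygiene standard NHO-09.
#'
#' @return A list of class `wbv_criteria` with elements `a8`, `vdv`
#'   (each `action`, `uncertainty_low`, `limit`) and `recommendation`.
#' @export
nho09_criteria <- function() {
  structure(list(
    a8 = c(action = 0.5, uncertainty_low = 0.9, limit = 1.1),
    vdv = c(action = 9.1, uncertainty_low = 16.4, limit = 21),
    recommendation = c(
      acceptable = "At least maintenance of the existing condition.",
      above_action = "At least the adoption of preventive measures.",
      uncertainty = "Adoption of preventive and corrective actions to reduce daily exposure.",
      above_limit = "Immediate adoption of corrective actions.")),
    class = "wbv_criteria")
}

#' Classify an exposure metric against decision criteria
#'
#' Band convention (following the standard's inequality signs): values up to
#' and including the action level are `acceptable`; strictly above the action
#' level and strictly below the uncertainty band is `above_action`; the
#' closed uncertainty band is `uncertainty`; strictly above the tolerance
#' limit is `above_limit`.
#'
#' @param value metric value, non-negative
#' @param metric `"A8"` or `"VDV"`
#' @param criteria a [nho09_criteria()] object
#' @return list with `category` (factor-ordered string) and `recommendation`.
#' @examples
#' classify_exposure(0.52, "A8")$category  # above_action
#' classify_exposure(8.2, "VDV")$category  # acceptable
#' @export
classify_exposure <- function(value, metric = c("A8", "VDV"),
                              criteria = nho09_criteria()) {
  metric <- match.arg(metric)
  if (!is.numeric(value) || length(value) != 1L || value < 0)
    stop("'value' must be a single non-negative number", call. = FALSE)
  th <- if (metric == "A8") criteria$a8 else criteria$vdv
  category <- if (value <= th[["action"]]) "acceptable"
  else if (value < th[["uncertainty_low"]]) "above_action"
  else if (value <= th[["limit"]]) "uncertainty"
  else "above_limit"
  list(category = category,
       recommendation = unname(criteria$recommendation[category]))
}

#' Full whole-body-vibration exposure assessment
#'
#' Runs the dosimetry pipeline on a raw triaxial seat signal: frequency
#' weighting (Wd on X/Y, Wk on Z), per-axis weighted RMS and VDV, resultant
#' combination with the seated-health multipliers, normalization of the
#' measurement to the daily exposure duration (square-root-of-time law for
#' A(8), fourth-root law for VDV), and classification against the decision
#' criteria.
#'
#' @param signal a raw [triaxial_signal()]
#' @param exposure_duration daily exposure the measurement represents (s);
#'   default 8 h
#' @param criteria a [nho09_criteria()] object
#' @param multipliers axis multipliers for the resultants
#' @param strict passed to [apply_weighting()]
#' @return Object of class `wbv_exposure`: per-axis RMS and VDV, `aren`,
#'   `a8`, `vdvr` (day-normalized resultant VDV), durations, categories and
#'   recommendations.
#' @examples
#' sig <- generate_signal(signal_recipe(duration = 30, seed = 1))
#' wbv_assess(sig)
#' @export
wbv_assess <- function(signal, exposure_duration = 8 * 3600,
                       criteria = nho09_criteria(),
                       multipliers = c(1.4, 1.4, 1.0), strict = FALSE) {
  stopifnot(inherits(signal, "triaxial_signal"))
  if (!is.numeric(exposure_duration) || length(exposure_duration) != 1L ||
      exposure_duration <= 0)
    stop("'exposure_duration' must be a single positive duration in seconds",
         call. = FALSE)
  w <- apply_weighting(signal, strict = strict)
  t_meas <- signal_duration(signal)
  rms <- c(x = weighted_rms(w$ax), y = weighted_rms(w$ay), z = weighted_rms(w$az))
  vdvs <- c(x = vdv(w$ax, w$fs), y = vdv(w$ay, w$fs), z = vdv(w$az, w$fs))
  aren <- resultant_acceleration(rms[["x"]], rms[["y"]], rms[["z"]], multipliers)
  a8 <- a8_normalize(aren, exposure_duration)
  vdv_meas <- combine_vdv_axes(vdvs[["x"]], vdvs[["y"]], vdvs[["z"]], multipliers)
  vdvr <- vdv_normalize(vdv_meas, t_meas, exposure_duration)
  cls_a8 <- classify_exposure(a8, "A8", criteria)
  cls_vdv <- classify_exposure(vdvr, "VDV", criteria)
  structure(list(
    rms = rms, vdv = vdvs, aren = aren, a8 = a8,
    vdv_measured = vdv_meas, vdvr = vdvr,
    measurement_duration = t_meas, exposure_duration = exposure_duration,
    category_a8 = cls_a8$category, category_vdv = cls_vdv$category,
    recommendation_a8 = cls_a8$recommendation,
    recommendation_vdv = cls_vdv$recommendation,
    multipliers = multipliers), class = "wbv_exposure")
}

#' @export
print.wbv_exposure <- function(x, ...) {
  cat("Whole-body vibration exposure assessment\n")
  cat(sprintf("  measurement: %.1f min, daily exposure: %.2f h\n",
              x$measurement_duration / 60, x$exposure_duration / 3600))
  cat(sprintf("  weighted RMS (m/s^2): x %.4f, y %.4f, z %.4f | resultant %.4f\n",
              x$rms[["x"]], x$rms[["y"]], x$rms[["z"]], x$aren))
  cat(sprintf("  A(8)  = %.3f m/s^2     [%s]\n", x$a8, x$category_a8))
  cat(sprintf("  VDV   = %.3f m/s^1.75  [%s] (measured %.3f over the window)\n",
              x$vdvr, x$category_vdv, x$vdv_measured))
  cat("  ", x$recommendation_a8, "\n", sep = "")
  invisible(x)
}

#' Serialize an exposure result to JSON
#'
#' @param x a `wbv_exposure` from [wbv_assess()]
#' @param path optional output file; if `NULL` the JSON string is returned
#' @return JSON string (invisibly if written to `path`).
#' @export
exposure_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "wbv_exposure"))
  obj <- list(rms_x = x$rms[["x"]], rms_y = x$rms[["y"]], rms_z = x$rms[["z"]],
              aren = x$aren, a8 = x$a8,
              vdv_x = x$vdv[["x"]], vdv_y = x$vdv[["y"]], vdv_z = x$vdv[["z"]],
              vdvr = x$vdvr,
              measurement_duration = x$measurement_duration,
              exposure_duration = x$exposure_duration,
              category_a8 = x$category_a8, category_vdv = x$category_vdv,
              recommendation = x$recommendation_a8)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
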