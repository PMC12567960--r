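#' Built-in catalog of suspension-seat parameter cases
#'
#' Five published stiffness/damping/mass combinations for the two-mass
#' suspension-seat model, used for the comparative transmissibility study.
#' Units: N/m (k1, k2), N s/m (b1, b2), kg (m1, m2).
#'
#' @return data.frame with columns `label`, `k1`, `k2`, `b1`, `b2`, `m1`, `m2`.
#' @examples
#' seat_case_catalog()
#' @export
seat_case_catalog <- function() {
  data.frame(
    label = paste("Case", 1:5),
    k1 = c(62800, 70000, 24854, 32300, 35776),
    k2 = c(28723, 38374, 28723, 28723, 38374),
    b1 = c(1600, 600, 514.11, 514.11, 761),
    b2 = c(677.6, 458, 677.6, 677.6, 458),
    m1 = c(56, 25, 13, 62, 62),
    m2 = c(84, 62.2, 54, 60, 84),
    stringsAsFactors = FALSE)
}

#' Read / write a case catalog as delimited text
#'
#' Catalogs are plain CSV with header `label,k1,k2,b1,b2,m1,m2` in SI units.
#'
#' @param path file path
#' @param catalog data.frame as returned by [seat_case_catalog()]
#' @return `read_case_catalog` returns the catalog data.frame;
#'   `write_case_catalog` returns `path` invisibly.
#' @export
read_case_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "k1", "k2", "b1", "b2", "m1", "m2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("case catalog is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[, need]
  for (nm in need[-1L]) df[[nm]] <- as.numeric(df[[nm]])
  df
}

#' @rdname read_case_catalog
#' @export
write_case_catalog <- function(catalog, path) {
  utils::write.csv(catalog, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the comparative case study
#'
#' For each parameter case, simulates the pulse response and evaluates the
#' transmissibility curve, returning one summary row per case: time-domain
#' displacement and acceleration peaks plus the refined transmissibility peak
#' and its frequency.
#'
#' @param cases data.frame of cases ([seat_case_catalog()] by default)
#' @param pulse a [pulse_input()]
#' @param t_max simulation length (s)
#' @param frequency frequency grid (Hz) for the transmissibility sweep
#' @param dt,dt_after integrator steps (s), see [simulate.seat_model()]
#' @return data.frame with columns `label`, `disp_peak_mm`, `accel_peak`,
#'   `T_peak`, `f_peak`.
#' @examples
#' \donttest{
#' run_case_catalog()
#' }
#' @export
run_case_catalog <- function(cases = seat_case_catalog(),
                             pulse = pulse_input(0.03, 5.4),
                             t_max = 3,
                             frequency = seq(0.1, 10, by = 0.01),
                             dt = 1e-4, dt_after = 1e-3) {
  if (!is.data.frame(cases) || nrow(cases) == 0L)
    stop("'cases' must be a non-empty data.frame of parameter cases", call. = FALSE)
  rows <- lapply(seq_len(nrow(cases)), function(i) {
    cs <- cases[i, ]
    m <- seat_model(m1 = cs$m1, m2 = cs$m2, k1 = cs$k1, k2 = cs$k2,
                    b1 = cs$b1, b2 = cs$b2, label = cs$label)
    tr <- simulate(m, pulse = pulse, t_max = t_max, dt = dt, dt_after = dt_after)
    frf <- transmissibility(m, frequency)
    data.frame(label = cs$label,
               disp_peak_mm = 1000 * max(abs(tr$z2)),
               accel_peak = max(abs(tr$z2dd)),
               T_peak = attr(frf, "peak_value"),
               f_peak = attr(frf, "peak_frequency"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
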