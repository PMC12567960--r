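#' Measurement campaign of 12 quay-crane operators
#'
#' The per-operator daily exposures measured at the port terminal: A(8) in
#' m/s^2 and day-normalized VDV in m/s^1.75 for each of the 12 container-crane
#' operators assessed.
#'
#' @return A `campaign_table` data.frame with columns `operator`, `a8`, `vdv`.
#' @examples
#' campaign_fixture()
#' @export
campaign_fixture <- function() {
  campaign_table(data.frame(
    operator = 1:12,
    a8 = c(0.52, 0.43, 0.52, 0.49, 0.36, 0.51, 0.55, 0.66, 0.57, 0.58, 0.52, 0.51),
    vdv = c(10.64, 11.43, 12.98, 12.92, 8.20, 12.67, 12.54, 14.96, 12.66, 13.01,
            10.66, 12.65)))
}

#' Construct / read / write a campaign table
#'
#' A campaign table holds one record per operator: an identifier, the daily
#' A(8) exposure (m/s^2) and the day-normalized VDV (m/s^1.75). On disk it is
#' plain CSV with header `operator,a8,vdv`.
#'
#' @param records data.frame with columns `operator`, `a8`, `vdv`
#' @param path file path
#' @return A `campaign_table` data.frame.
#' @export
campaign_table <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("operator", "a8", "vdv")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("campaign table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(records$operator))
    stop("operator ids must be unique", call. = FALSE)
  if (any(records$a8 < 0) || any(records$vdv < 0))
    stop("exposure values must be non-negative", call. = FALSE)
  structure(records[, need], class = c("campaign_table", "data.frame"))
}

#' @rdname campaign_table
#' @export
read_campaign <- function(path) {
  campaign_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname campaign_table
#' @param table a `campaign_table`
#' @export
write_campaign <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Exceedance statistics for a campaign
#'
#' Counts, per metric, how many operators fall strictly above the action
#' level, inside the uncertainty band, and above the tolerance limit, with
#' percentages rounded to the nearest integer by default. "Exceeds the
#' action level" is a strict comparison (a value exactly at the level is
#' acceptable), following the standard's inequality signs.
#'
#' @param table a [campaign_table()]
#' @param criteria a [nho09_criteria()] object
#' @param digits rounding for the percentages (0 = nearest integer)
#' @return A list of class `exceedance_summary` with element `n` and, for
#'   each metric, counts and percentages `above_action`, `uncertainty`,
#'   `above_limit` plus the per-operator categories.
#' @examples
#' exceedance_stats(campaign_fixture())  # 75% above A(8) action level
#' @export
exceedance_stats <- function(table, criteria = nho09_criteria(), digits = 0) {
  stopifnot(inherits(table, "campaign_table"))
  if (nrow(table) == 0L) stop("empty campaign table", call. = FALSE)
  n <- nrow(table)
  one_metric <- function(values, metric) {
    cats <- vapply(values, function(v)
      classify_exposure(v, metric, criteria)$category, character(1L))
    th <- if (metric == "A8") criteria$a8 else criteria$vdv
    counts <- c(above_action = sum(values > th[["action"]]),
                uncertainty = sum(cats == "uncertainty"),
                above_limit = sum(cats == "above_limit"))
    list(counts = counts, pct = round(100 * counts / n, digits),
         categories = cats)
  }
  structure(list(n = n,
                 a8 = one_metric(table$a8, "A8"),
                 vdv = one_metric(table$vdv, "VDV"),
                 operator = table$operator),
            class = "exceedance_summary")
}

#' @export
print.exceedance_summary <- function(x, ...) {
  cat(sprintf("Campaign exceedance summary (n = %d operators)\n", x$n))
  cat(sprintf("  A(8): %d/%d (%g%%) above action level, %d in uncertainty band, %d above limit\n",
              x$a8$counts[["above_action"]], x$n, x$a8$pct[["above_action"]],
              x$a8$counts[["uncertainty"]], x$a8$counts[["above_limit"]]))
  cat(sprintf("  VDV:  %d/%d (%g%%) above action level, %d in uncertainty band, %d above limit\n",
              x$vdv$counts[["above_action"]], x$n, x$vdv$pct[["above_action"]],
              x$vdv$counts[["uncertainty"]], x$vdv$counts[["above_limit"]]))
  invisible(x)
}

#' Relative error between a reference and a predicted value
#'
#' `100 * |reference - value| / |reference|`, rounded for reporting.
#' Used to compare model-predicted against measured seat accelerations.
#'
#' @param reference measured (reference) value, non-zero
#' @param value predicted value
#' @param digits decimal places for reporting (default 2)
#' @return percentage
#' @examples
#' relative_error(0.10, 0.09)  # 10
#' relative_error(0.11, 0.13)  # 18.18
#' @export
relative_error <- function(reference, value, digits = 2) {
  if (any(reference == 0)) stop("'reference' must be non-zero", call. = FALSE)
  round(100 * abs(reference - value) / abs(reference), digits)
}

#' Percentage difference between successive refinement results
#'
#' `100 * |current - previous| / previous` with a convergence flag against a
#' configurable criterion (5% by default): a quantity is taken as converged
#' when further refinement changes it by no more than the criterion.
#'
#' @param previous result on the previous (coarser) configuration, non-zero
#' @param current result on the current configuration
#' @param criterion convergence threshold in percent
#' @param digits decimal places for reporting
#' @return list with `difference` (percent) and `converged` (logical)
#' @examples
#' convergence_difference(0.34011, 0.36661)  # 7.79, not converged
#' convergence_difference(0.36661, 0.36878)  # 0.59, converged
#' @export
convergence_difference <- function(previous, current, criterion = 5, digits = 2) {
  if (any(previous == 0)) stop("'previous' must be non-zero", call. = FALSE)
  d <- round(100 * abs(current - previous) / abs(previous), digits)
  list(difference = d, converged = d <= criterion)
}

#' Render a campaign report
#'
#' Produces a deterministic report of a campaign: per-operator categories and
#' recommended practice, exceedance counts and percentages. Returned as a
#' list (serializable to JSON) plus a plain-text rendering; optionally
#' written to files.
#'
#' @param table a [campaign_table()]
#' @param criteria a [nho09_criteria()] object
#' @param json_path,text_path optional output paths
#' @return A list of class `campaign_report` with elements `summary`
#'   (n, exceedance counts/percentages), `operators` (per-operator metrics,
#'   categories, recommendations) and `text` (character vector).
#' @export
render_report <- function(table, criteria = nho09_criteria(),
                          json_path = NULL, text_path = NULL) {
  stats <- exceedance_stats(table, criteria)
  ops <- lapply(seq_len(stats$n), function(i) {
    ca <- classify_exposure(table$a8[i], "A8", criteria)
    cv <- classify_exposure(table$vdv[i], "VDV", criteria)
    list(operator = table$operator[i], a8 = table$a8[i], vdv = table$vdv[i],
         category_a8 = ca$category, category_vdv = cv$category,
         recommendation = ca$recommendation)
  })
  summary <- list(
    n = stats$n,
    a8_above_action = unname(stats$a8$counts[["above_action"]]),
    a8_above_action_pct = unname(stats$a8$pct[["above_action"]]),
    a8_above_limit = unname(stats$a8$counts[["above_limit"]]),
    vdv_above_action = unname(stats$vdv$counts[["above_action"]]),
    vdv_above_action_pct = unname(stats$vdv$pct[["above_action"]]),
    vdv_above_limit = unname(stats$vdv$counts[["above_limit"]]))
  text <- c(
    sprintf("Whole-body vibration campaign report (n = %d operators)", stats$n),
    sprintf("A(8): %d (%g%%) above the %.1f m/s^2 action level; %d above the %.1f m/s^2 tolerance limit",
            summary$a8_above_action, summary$a8_above_action_pct,
            criteria$a8[["action"]], summary$a8_above_limit,
            criteria$a8[["limit"]]),
    sprintf("VDV:  %d (%g%%) above the %.1f m/s^1.75 action level; %d above the %.1f m/s^1.75 tolerance limit",
            summary$vdv_above_action, summary$vdv_above_action_pct,
            criteria$vdv[["action"]], summary$vdv_above_limit,
            criteria$vdv[["limit"]]),
    "",
    sprintf("%-10s %-6s %-6s %-14s %-14s", "operator", "A(8)", "VDV",
            "A(8) category", "VDV category"),
    vapply(ops, function(o)
      sprintf("%-10s %-6.2f %-6.2f %-14s %-14s", o$operator, o$a8, o$vdv,
              o$category_a8, o$category_vdv), character(1L)))
  report <- structure(list(summary = summary, operators = ops, text = text),
                      class = "campaign_report")
  if (!is.null(json_path))
    writeLines(jsonlite::toJSON(list(summary = summary, operators = ops),
                                auto_unbox = TRUE, digits = NA, pretty = TRUE),
               json_path)
  if (!is.null(text_path)) writeLines(text, text_path)
  report
}

#' @export
print.campaign_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}
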