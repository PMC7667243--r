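#' Light-scatter quality control of the lymphocyte gate
#'
#' Clinical guidelines for standardized instrument set-up prescribe narrow
#' intervals for the median scatter signals of lymphocytes: median FSC-A
#' strictly between 50,000 and 60,000 and median SSC-A strictly between
#' 11,000 and 13,000 channel units. Samples violating these intervals are
#' prone to larger disagreement between gating strategies, so the check is
#' run on the lymphocyte-gated events before any comparison.
#'
#' @param events An [event_matrix] (raw or transformed scale; scatter
#'   channels are never transformed).
#' @param lymphocyte_mask Logical vector of length `n_events(events)`,
#'   `TRUE` for lymphocyte-gated events. At least 100 events must be masked.
#' @return A list of class `qc_report` with `median_fsc_a`, `median_ssc_a`,
#'   `fsc_pass`, `ssc_pass`.
#' @export
scatter_qc <- function(events, lymphocyte_mask) {
  stopifnot(inherits(events, "event_matrix"))
  if (!is.logical(lymphocyte_mask) ||
      length(lymphocyte_mask) != n_events(events))
    stop("lymphocyte_mask must be a logical vector of length n_events",
         call. = FALSE)
  n_masked <- sum(lymphocyte_mask)
  if (n_masked < 100)
    stop("scatter QC needs at least 100 lymphocyte-gated events, got ",
         n_masked, call. = FALSE)
  med_fsc <- stats::median(events$values[lymphocyte_mask, "FSC-A"])
  med_ssc <- stats::median(events$values[lymphocyte_mask, "SSC-A"])
  structure(list(
    median_fsc_a = med_fsc,
    median_ssc_a = med_ssc,
    fsc_pass = med_fsc > 50000 && med_fsc < 60000,
    ssc_pass = med_ssc > 11000 && med_ssc < 13000
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("scatter QC: median FSC-A %.0f (%s), median SSC-A %.0f (%s)\n",
              x$median_fsc_a, if (x$fsc_pass) "pass" else "FAIL",
              x$median_ssc_a, if (x$ssc_pass) "pass" else "FAIL"))
  invisible(x)
}
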