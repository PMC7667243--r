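#' Sample metadata
#'
#' Per-sample metadata needed for dual-platform absolute counting and
#' age-matched reference lookup: the sample identifier, donor age in years,
#' the white blood cell count from a hematology analyzer (cells/uL), and the
#' study group.
#'
#' @param sample_id Character scalar.
#' @param age_years Age in years, in `[0, 120]`.
#' @param wbc_per_ul White blood cell count per microliter, in `(100, 500000)`.
#' @param group One of `"HD"`, `"CVID"`, `"PID"`, `"nonPID"`.
#' @return An object of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, age_years, wbc_per_ul, group = "HD") {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (!is.numeric(age_years) || length(age_years) != 1L ||
      is.na(age_years) || age_years < 0 || age_years > 120)
    stop("age_years must be a number in [0, 120]", call. = FALSE)
  if (!is.numeric(wbc_per_ul) || length(wbc_per_ul) != 1L ||
      is.na(wbc_per_ul) || wbc_per_ul <= 100 || wbc_per_ul >= 500000)
    stop("wbc_per_ul must be in (100, 500000)", call. = FALSE)
  group <- match.arg(group, c("HD", "CVID", "PID", "nonPID"))
  structure(list(sample_id = sample_id, age_years = age_years,
                 wbc_per_ul = wbc_per_ul, group = group),
            class = "sample_meta")
}

# Upper bound of the raw intensity scale (18-bit digitizer convention).
RAW_SCALE_MAX <- 262144

#' Event-level intensity matrix
#'
#' The container every gating engine consumes: an N x C matrix of compensated
#' intensities with a panel definition, a scale flag and sample metadata.
#' Raw-scale values live on the instrument channel scale `[0, 262144]`;
#' transformed-scale values carry fluorescence channels mapped through
#' `asinh(x / cofactor)` while scatter channels always stay on the raw scale.
#'
#' @param values Numeric matrix, one row per event, columns in panel order.
#' @param panel A [panel_definition]. Column names of `values`, when present,
#'   must match the panel channel names.
#' @param meta A [sample_meta].
#' @param scale `"raw"` or `"transformed"`.
#' @param cofactor asinh cofactor used when `scale = "transformed"`.
#' @return An object of class `event_matrix` with elements `values`, `panel`,
#'   `meta`, `scale`, `cofactor`.
#' @export
event_matrix <- function(values, panel, meta, scale = "raw", cofactor = NULL) {
  stopifnot(inherits(panel, "panel_definition"), inherits(meta, "sample_meta"))
  scale <- match.arg(scale, c("raw", "transformed"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L)
    stop("an event matrix must contain at least one event", call. = FALSE)
  if (ncol(values) != nrow(panel))
    stop("event matrix has ", ncol(values), " columns but the panel defines ",
         nrow(panel), " channels", call. = FALSE)
  if (anyNA(values))
    stop("event matrix must not contain missing values", call. = FALSE)
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), panel_channels(panel)))
    stop("event matrix column names do not match the panel channel order",
         call. = FALSE)
  colnames(values) <- panel_channels(panel)
  if (scale == "raw" && !is.null(cofactor))
    stop("cofactor is only meaningful for transformed-scale matrices",
         call. = FALSE)
  structure(list(values = values, panel = panel, meta = meta,
                 scale = scale, cofactor = cofactor),
            class = "event_matrix")
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("event_matrix: %d events x %d channels (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  panel: %s; sample: %s (%s, age %.1f y, WBC %.0f/uL)\n",
              attr(x$panel, "version"), x$meta$sample_id, x$meta$group,
              x$meta$age_years, x$meta$wbc_per_ul))
  invisible(x)
}

#' @rdname event_matrix
#' @param x An `event_matrix`.
#' @export
n_events <- function(x) {
  stopifnot(inherits(x, "event_matrix"))
  nrow(x$values)
}

#' Arcsinh transform of fluorescence channels
#'
#' Maps every fluorescence channel through `asinh(x / cofactor)`, leaving the
#' scatter channels untouched, and flips the scale flag to `"transformed"`.
#' The transform is strictly monotone per channel and invertible via
#' [untransform_fluorescence()]. A single cofactor (default 150) is applied
#' to all fluorescence channels; it sets the width of the quasi-linear region
#' around zero of the standardized display scale.
#'
#' @param events A raw-scale [event_matrix].
#' @param cofactor Positive scale cofactor.
#' @return A transformed-scale `event_matrix`.
#' @export
transform_fluorescence <- function(events, cofactor = 150) {
  stopifnot(inherits(events, "event_matrix"))
  if (events$scale != "raw")
    stop("events are already on the transformed scale", call. = FALSE)
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0)
    stop("cofactor must be a positive number", call. = FALSE)
  fl <- panel_channels(events$panel, "fluorescence")
  v <- events$values
  v[, fl] <- asinh(v[, fl] / cofactor)
  event_matrix(v, events$panel, events$meta,
               scale = "transformed", cofactor = cofactor)
}

#' @rdname transform_fluorescence
#' @export
untransform_fluorescence <- function(events) {
  stopifnot(inherits(events, "event_matrix"))
  if (events$scale != "transformed")
    stop("events are already on the raw scale", call. = FALSE)
  fl <- panel_channels(events$panel, "fluorescence")
  v <- events$values
  v[, fl] <- sinh(v[, fl]) * events$cofactor
  event_matrix(v, events$panel, events$meta, scale = "raw")
}
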