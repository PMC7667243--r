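#' Threshold sets for the manual gating engine
#'
#' A threshold set holds, per marker, the three ordered cut points
#' (`neg|lo`, `lo|pos`, `pos|hi`) on the asinh-transformed scale that
#' discretize expression into the four bands used by the Boolean gating
#' hierarchy, plus the lymphocyte scatter rectangle, the FSC-A floor below
#' which events count as debris, and the singlet-ratio tolerance of the
#' doublet gate. The shipped `"pidot-v1"` set places each cut in the
#' low-density valley between the occupied bands of that marker, the way an
#' expert places gates on displayed data.
#'
#' @param cuts Named list: marker -> strictly increasing numeric vector of
#'   length 3.
#' @param scatter_gate List with `fsc_a` and `ssc_a` intervals (raw units).
#' @param debris_fsc_max FSC-A floor for debris (raw units).
#' @param doublet_ratio_tolerance Fraction in `(0, 1]` (0 allowed for
#'   degenerate boundary studies).
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(cuts, scatter_gate, debris_fsc_max,
                          doublet_ratio_tolerance = 0.25) {
  stopifnot(is.list(cuts), !is.null(names(cuts)))
  for (m in names(cuts)) {
    v <- cuts[[m]]
    if (!is.numeric(v) || length(v) != 3L || any(diff(v) <= 0))
      stop("cut points for marker '", m,
           "' must be three strictly increasing numbers", call. = FALSE)
  }
  stopifnot(is.list(scatter_gate),
            all(c("fsc_a", "ssc_a") %in% names(scatter_gate)))
  if (doublet_ratio_tolerance < 0 || doublet_ratio_tolerance >= 1)
    stop("doublet_ratio_tolerance must lie in [0, 1)", call. = FALSE)
  structure(list(cuts = lapply(cuts, as.numeric),
                 scatter_gate = lapply(scatter_gate, as.numeric),
                 debris_fsc_max = debris_fsc_max,
                 doublet_ratio_tolerance = doublet_ratio_tolerance),
            class = "threshold_set")
}

#' @rdname threshold_set
#' @param path YAML file; defaults to the shipped `"pidot-v1"` thresholds.
#' @export
pidot_thresholds <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "thresholds_pidot_v1.yaml",
                        package = "pidotgate")
  raw <- yaml::read_yaml(path)
  threshold_set(cuts = raw$cuts,
                scatter_gate = raw$scatter_gate,
                debris_fsc_max = raw$debris_fsc_max,
                doublet_ratio_tolerance = raw$doublet_ratio_tolerance)
}

# Discretize transformed marker intensities into band levels 1..4
# (neg, lo, pos, hi) using the per-marker cut points.
.band_matrix <- function(values, cuts) {
  markers <- names(cuts)
  out <- matrix(0L, nrow(values), length(markers),
                dimnames = list(NULL, markers))
  for (m in markers)
    out[, m] <- findInterval(values[, m], cuts[[m]]) + 1L
  out
}

BAND_LEVELS <- c("neg", "lo", "pos", "hi")
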