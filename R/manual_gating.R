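#' Doublet exclusion on the FSC-H / FSC-A ratio
#'
#' Singlets fall on a tight diagonal in the FSC-H vs FSC-A plane; doublets
#' carry roughly doubled area at singlet height and drop off it. The gate
#' estimates the sample's robust singlet ratio as the median FSC-H/FSC-A
#' and keeps events whose ratio lies within `tolerance` (relative) of it.
#' Events with FSC-A = 0 are excluded and tallied in the
#' `zero_fsc_excluded` attribute.
#'
#' @param events An [event_matrix] (any scale; scatter is never transformed).
#' @param tolerance Relative tolerance around the median ratio, in `[0, 1)`.
#' @return Logical vector, `TRUE` = kept singlet.
#' @export
exclude_doublets <- function(events, tolerance = 0.25) {
  stopifnot(inherits(events, "event_matrix"))
  if (tolerance < 0 || tolerance >= 1)
    stop("tolerance must lie in [0, 1)", call. = FALSE)
  fsc_a <- events$values[, "FSC-A"]
  fsc_h <- events$values[, "FSC-H"]
  ok <- fsc_a > 0
  ratio <- rep(NA_real_, length(fsc_a))
  ratio[ok] <- fsc_h[ok] / fsc_a[ok]
  med <- stats::median(ratio[ok])
  keep <- ok & abs(ratio / med - 1) <= tolerance
  keep[is.na(keep)] <- FALSE
  attr(keep, "zero_fsc_excluded") <- sum(!ok)
  keep
}

#' Lymphocyte scatter / CD45 gate
#'
#' Keeps events inside the FSC-A / SSC-A lymphocyte rectangle whose CD45
#' lies in the `hi` band; debris (FSC-A below the configured floor) and
#' other leukocytes fall outside. The doublet mask is expected to have been
#' applied upstream.
#'
#' @param events A transformed-scale [event_matrix].
#' @param thresholds A [threshold_set].
#' @return Logical vector over all events, `TRUE` = lymphocyte.
#' @export
gate_lymphocytes <- function(events, thresholds) {
  stopifnot(inherits(events, "event_matrix"),
            inherits(thresholds, "threshold_set"))
  if (events$scale != "transformed")
    stop("gate_lymphocytes needs transformed-scale events", call. = FALSE)
  v <- events$values
  sg <- thresholds$scatter_gate
  in_rect <- v[, "FSC-A"] >= sg$fsc_a[1] & v[, "FSC-A"] <= sg$fsc_a[2] &
    v[, "SSC-A"] >= sg$ssc_a[1] & v[, "SSC-A"] <= sg$ssc_a[2]
  cd45_hi <- v[, "CD45"] >= thresholds$cuts[["CD45"]][3]
  in_rect & cd45_hi
}

#' Hierarchical Boolean classification of gated events
#'
#' Runs the full manual gating strategy on one sample: doublet exclusion,
#' debris removal, the lymphocyte scatter/CD45 gate, then top-down
#' evaluation of the gate tree's band predicates until every lymphocyte
#' carries exactly one terminal label (or an explicit
#' `unclassified_<parent>` label where no sibling predicate matched).
#'
#' @param events A transformed-scale [event_matrix].
#' @param tree A [gate_tree].
#' @param thresholds A [threshold_set].
#' @return An object of class `gating_result`: list with `labels`
#'   (per-event: terminal id, `unclassified_*`, `doublet`, `debris` or
#'   `non_lymphoid`), `tree`, `thresholds` and the diagnostics tally.
#' @export
classify_events <- function(events, tree, thresholds) {
  stopifnot(inherits(events, "event_matrix"), inherits(tree, "gate_tree"),
            inherits(thresholds, "threshold_set"))
  if (events$scale != "transformed")
    stop("classify_events needs transformed-scale events", call. = FALSE)
  missing_cuts <- setdiff(
    unique(unlist(lapply(tree$nodes, function(n) names(n$bands)))),
    names(thresholds$cuts))
  if (length(missing_cuts))
    stop("thresholds lack cut points for marker(s): ",
         paste(missing_cuts, collapse = ", "), call. = FALSE)

  n <- n_events(events)
  labels <- character(n)
  singlet <- exclude_doublets(events, thresholds$doublet_ratio_tolerance)
  labels[!singlet] <- "doublet"
  fsc <- events$values[, "FSC-A"]
  debris <- singlet & fsc < thresholds$debris_fsc_max
  labels[debris] <- "debris"
  lymph <- singlet & !debris & gate_lymphocytes(events, thresholds)
  labels[singlet & !debris & !lymph] <- "non_lymphoid"

  idx <- which(lymph)
  if (length(idx)) {
    markers <- intersect(colnames(events$values), names(thresholds$cuts))
    bands <- .band_matrix(events$values[idx, markers, drop = FALSE],
                          thresholds$cuts[markers])
    lab <- .assign_tree(bands, tree, tree$root)
    labels[idx] <- lab
  }
  structure(list(labels = labels, tree = tree, thresholds = thresholds,
                 n = n,
                 zero_fsc_excluded = attr(singlet, "zero_fsc_excluded")),
            class = "gating_result")
}

# recursive top-down assignment over the band matrix rows (already gated
# into the subtree root)
.assign_tree <- function(bands, tree, node) {
  out <- rep(node, nrow(bands))
  kids <- tree_children(tree, node)
  if (!length(kids)) return(out)
  assigned <- rep(FALSE, nrow(bands))
  for (k in kids) {
    pred <- tree$nodes[[k]]$bands
    match_k <- !assigned
    for (m in names(pred)) {
      lev <- match(pred[[m]], BAND_LEVELS)
      match_k <- match_k & bands[, m] %in% lev
    }
    if (any(match_k))
      out[match_k] <- .assign_tree(bands[match_k, , drop = FALSE], tree, k)
    assigned <- assigned | match_k
  }
  out[!assigned] <- paste0("unclassified_", node)
  out
}

#' Population count table of a gating result
#'
#' Aggregates per-event labels into the reported count table: events,
#' percentage of white blood cells and the dual-platform absolute count,
#' `absolute count/uL = relative WBC (%) x WBC/uL / 100`. The
#' WBC-representing denominator is all non-doublet, non-debris events.
#' Parent populations are the events matching the parent gate, i.e. the sum
#' of their children including the explicit unclassified bucket.
#'
#' @param result A `gating_result` from [classify_events()].
#' @param meta A [sample_meta] carrying the WBC count.
#' @return Data frame with columns `population`, `events`, `pct_wbc`,
#'   `abs_per_ul`, ordered by the gating hierarchy with the nuisance
#'   buckets appended (`pct_wbc` is `NA` for doublets and debris, which do
#'   not represent white cells).
#' @export
population_counts <- function(result, meta) {
  stopifnot(inherits(result, "gating_result"), inherits(meta, "sample_meta"))
  if (is.null(meta$wbc_per_ul) || is.na(meta$wbc_per_ul))
    stop("sample metadata lacks a WBC count", call. = FALSE)
  labels <- result$labels
  tree <- result$tree
  tab <- table(labels)
  cnt <- function(ids) sum(tab[intersect(ids, names(tab))])
  n_wbc <- result$n - cnt("doublet") - cnt("debris")
  node_ids <- names(tree$nodes)
  rows <- lapply(node_ids, function(id) {
    desc <- tree_descendants(tree, id)
    ev <- cnt(c(desc, paste0("unclassified_", desc)))
    data.frame(population = id, events = ev,
               pct_wbc = 100 * ev / n_wbc,
               stringsAsFactors = FALSE)
  })
  uncl <- grep("^unclassified_", names(tab), value = TRUE)
  extra <- c(uncl, intersect(c("non_lymphoid", "doublet", "debris"),
                             names(tab)))
  rows <- c(rows, lapply(extra, function(id) {
    ev <- cnt(id)
    pct <- if (id %in% c("doublet", "debris")) NA_real_ else 100 * ev / n_wbc
    data.frame(population = id, events = ev, pct_wbc = pct,
               stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, rows)
  out$abs_per_ul <- out$pct_wbc * meta$wbc_per_ul / 100
  out
}

#' One-call manual gating of a raw sample
#'
#' Convenience wrapper: transform, classify, count.
#'
#' @param events A raw-scale [event_matrix].
#' @param meta Optional [sample_meta]; defaults to the one carried by
#'   `events`.
#' @param thresholds,tree Gating configuration; default `"pidot-v1"`.
#' @param cofactor asinh cofactor.
#' @return List with `result` (the `gating_result`) and `counts` (the
#'   count table).
#' @export
manual_gate <- function(events, meta = NULL, thresholds = pidot_thresholds(),
                        tree = pidot_gate_tree(), cofactor = 150) {
  if (is.null(meta)) meta <- events$meta
  tr <- if (events$scale == "raw")
    transform_fluorescence(events, cofactor) else events
  result <- classify_events(tr, tree, thresholds)
  list(result = result, counts = population_counts(result, meta))
}
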