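#' Percent difference between paired absolute counts
#'
#' The method-comparison metric: the manual-gating-referenced signed
#' percent difference `(count_mg - count_ag) / count_mg * 100`. When both
#' counts are zero the difference is 0; when the manual count is zero but
#' the automated count is not, the difference is undefined (`NA`) and the
#' pair is treated as non-equivalent downstream.
#'
#' @param count_mg,count_ag Non-negative absolute counts (cells/uL),
#'   vectorized.
#' @return Signed percent difference, `NA` where undefined.
#' @export
percent_difference <- function(count_mg, count_ag) {
  if (any(count_mg < 0, na.rm = TRUE) || any(count_ag < 0, na.rm = TRUE))
    stop("absolute counts must be non-negative", call. = FALSE)
  out <- (count_mg - count_ag) / count_mg * 100
  out[count_mg == 0 & count_ag == 0] <- 0
  out[count_mg == 0 & count_ag > 0] <- NA_real_
  out
}

#' Equivalence under the 20 percent criterion
#'
#' Two gating results for a population are equivalent when the percent
#' difference is defined and its magnitude is strictly below 20 (the EN ISO
#' 15189-derived acceptance criterion used in clinical method comparison).
#'
#' @param pct_diff Percent differences from [percent_difference()].
#' @return Logical vector.
#' @export
is_equivalent <- function(pct_diff) {
  !is.na(pct_diff) & abs(pct_diff) < 20
}

#' Clinical-relevance classification of a paired observation
#'
#' Compares both counts against the age-matched p5-p95 reference interval
#' (inclusive at the bounds) and flags the pair as clinically relevant when
#' the two methods lead to different interpretations, i.e. different range
#' statuses.
#'
#' @param count_mg,count_ag Absolute counts (cells/uL).
#' @param p5,p95 Reference interval bounds, `p5 < p95`.
#' @return List with `mg_status`, `ag_status`, `clinically_relevant`.
#' @export
clinical_relevance <- function(count_mg, count_ag, p5, p95) {
  mg <- range_status(count_mg, p5, p95)
  ag <- range_status(count_ag, p5, p95)
  list(mg_status = mg, ag_status = ag, clinically_relevant = mg != ag)
}

#' Paired comparison of one sample's manual and automated counts
#'
#' Builds the per-population comparison records for one sample: paired
#' counts, percent difference, equivalence flag, range statuses and
#' clinical relevance.
#'
#' @param counts_mg,counts_ag Count tables carrying `population` and
#'   `abs_per_ul` columns ([population_counts()] output and the `table` of
#'   an `autogate_report`).
#' @param meta A [sample_meta].
#' @param ranges A `reference_ranges`, or `NULL` to skip range evaluation.
#' @param populations Populations to compare; default
#'   [comparison_populations()].
#' @return Data frame of comparison records.
#' @export
compare_counts <- function(counts_mg, counts_ag, meta, ranges = NULL,
                           populations = comparison_populations()) {
  get_count <- function(tab, p) {
    i <- match(p, tab$population)
    if (is.na(i)) NA_real_ else tab$abs_per_ul[i]
  }
  rows <- lapply(populations, function(p) {
    mg <- get_count(counts_mg, p)
    ag <- get_count(counts_ag, p)
    pd <- percent_difference(mg, ag)
    eq <- is_equivalent(pd)
    mg_status <- ag_status <- NA_character_
    relevant <- NA
    if (!is.null(ranges)) {
      rg <- range_lookup(ranges, p, meta$age_years)
      if (!is.null(rg)) {
        cr <- clinical_relevance(mg, ag, rg[1], rg[2])
        mg_status <- cr$mg_status
        ag_status <- cr$ag_status
        relevant <- cr$clinically_relevant
      }
    }
    data.frame(sample_id = meta$sample_id, group = meta$group,
               population = p, count_mg = mg, count_ag = ag,
               pct_diff = pd, equivalent = eq,
               mg_status = mg_status, ag_status = ag_status,
               clinically_relevant = relevant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replicate summary statistics (SD and CV)
#'
#' The reproducibility metric: for each population, the mean, sample
#' standard deviation (n - 1 denominator) and coefficient of variation
#' `CV% = SD / mean * 100` over replicate absolute counts. A zero mean
#' leaves the CV undefined (`NA`); undefined CVs are excluded from median
#' summaries.
#'
#' @param replicates List of count tables (same populations in each), or a
#'   numeric matrix with one column per replicate and populations as row
#'   names.
#' @return Data frame with `population`, `mean`, `sd`, `cv_pct`.
#' @export
reproducibility <- function(replicates) {
  if (is.list(replicates) && !is.data.frame(replicates)) {
    pops <- replicates[[1]]$population
    for (r in replicates)
      if (!identical(r$population, pops))
        stop("replicate count tables cover different population sets",
             call. = FALSE)
    m <- vapply(replicates, function(r) r$abs_per_ul, numeric(length(pops)))
    rownames(m) <- pops
  } else {
    m <- as.matrix(replicates)
    if (is.null(rownames(m)))
      stop("a replicate matrix needs population row names", call. = FALSE)
  }
  if (ncol(m) < 2L)
    stop("at least two replicates are required", call. = FALSE)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  cv <- ifelse(mu == 0, NA_real_, sdv / mu * 100)
  data.frame(population = rownames(m), mean = unname(mu), sd = unname(sdv),
             cv_pct = unname(cv), row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks on ties; used to compare absolute
#' counts between the two gating strategies across samples.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` when either vector is
#'   constant (undefined ranks variance).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Variance ratio F-test on two CV sets
#'
#' Compares the spread of two sets of coefficients of variation: `F` is the
#' larger sample variance over the smaller, with a two-sided p-value from
#' the F distribution at `(n1 - 1, n2 - 1)` degrees of freedom (numerator =
#' the larger-variance set). Degenerate inputs are flagged: both variances
#' zero gives `p = 1` by convention; exactly one zero gives an infinite F
#' and `p = 0`.
#'
#' @param cv_a,cv_b Numeric vectors, length >= 2 each.
#' @return List with `F`, `p`, `df`, `flag`.
#' @export
variance_ratio_f_test <- function(cv_a, cv_b) {
  cv_a <- cv_a[!is.na(cv_a)]; cv_b <- cv_b[!is.na(cv_b)]
  if (length(cv_a) < 2L || length(cv_b) < 2L)
    stop("each CV set needs at least 2 defined values", call. = FALSE)
  va <- stats::var(cv_a); vb <- stats::var(cv_b)
  if (va == 0 && vb == 0)
    return(list(F = NA_real_, p = 1, df = c(NA, NA), flag = "degenerate"))
  if (va == 0 || vb == 0) {
    df <- if (vb == 0) c(length(cv_a) - 1L, length(cv_b) - 1L)
          else c(length(cv_b) - 1L, length(cv_a) - 1L)
    return(list(F = Inf, p = 0, df = df, flag = "one set constant"))
  }
  if (va >= vb) {
    f <- va / vb; df <- c(length(cv_a) - 1L, length(cv_b) - 1L)
  } else {
    f <- vb / va; df <- c(length(cv_b) - 1L, length(cv_a) - 1L)
  }
  p <- min(1, 2 * stats::pf(f, df[1], df[2], lower.tail = FALSE))
  list(F = f, p = p, df = df, flag = "ok")
}

#' Chi-squared test with Yates' continuity correction
#'
#' For a 2 x 2 contingency table: `sum((|O - E| - 0.5)^2 / E)` with the
#' p-value from the chi-squared distribution at 1 degree of freedom.
#' Expected counts come from the product of the margins. All margins must
#' be positive.
#'
#' @param tab 2 x 2 matrix of non-negative counts.
#' @return List with `chi2`, `p`, `expected`.
#' @export
chi_square_yates <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0))
    stop("tab must be a 2 x 2 matrix of non-negative counts", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins of the 2 x 2 table must be positive", call. = FALSE)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((abs(tab - e) - 0.5)^2 / e)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       expected = e)
}

#' Bonferroni correction
#'
#' Family-wise error control for `m` simultaneous tests: reject when
#' `p < alpha / m` (strict inequality); adjusted p-values are
#' `min(1, m * p)`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise significance level.
#' @return List with `adjusted` and `reject`.
#' @export
bonferroni_adjust <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  list(adjusted = stats::p.adjust(p, method = "bonferroni"),
       reject = p < alpha / m)
}

#' Delta MFI between two populations
#'
#' Difference of the per-population median raw-scale intensities of one
#' marker (median fluorescence intensity in arbitrary channel units); a
#' small delta between phenotypically adjacent populations (e.g. CD27
#' between pre-germinal center and unswitched memory B cells) marks
#' samples where single-marker discrimination is fragile.
#'
#' @param events An [event_matrix] (raw or transformed; transformed values
#'   are inverted to raw channel units first).
#' @param labels Per-event population labels.
#' @param population_a,population_b Population ids (>= 10 events each).
#' @param marker Fluorescence channel name.
#' @return `median MFI(a) - median MFI(b)` in raw channel units.
#' @export
delta_mfi <- function(events, labels, population_a, population_b, marker) {
  stopifnot(inherits(events, "event_matrix"))
  if (events$scale == "transformed") events <- untransform_fluorescence(events)
  if (!marker %in% colnames(events$values))
    stop("unknown marker '", marker, "'", call. = FALSE)
  med <- function(p) {
    i <- labels == p
    if (sum(i) < 10L)
      stop("population '", p, "' has fewer than 10 events", call. = FALSE)
    stats::median(events$values[i, marker])
  }
  med(population_a) - med(population_b)
}
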