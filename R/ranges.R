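#' Derive age-matched p5-p95 reference ranges from a simulated cohort
#'
#' Emulates the construction of age-matched reference intervals from a
#' healthy-donor cohort: for every population and age bin, the 5th and 95th
#' empirical percentiles (linear interpolation between order statistics) of
#' the ground-truth absolute counts. Automated reports compare each
#' population's count against the interval for the sample's age bin and
#' raise a "remark" (numerical alarm) outside it.
#'
#' @param cohort List of per-sample lists with elements `labels` (truth
#'   labels) and `meta` (a [sample_meta]); the output of
#'   [simulate_cohort()] works directly.
#' @param age_bins Increasing numeric vector of bin edges in years; bins are
#'   `[e_i, e_{i+1})`. The default partitions 0-120 y at clinically common
#'   break points.
#' @param registry A [population_registry].
#' @param min_per_bin Minimum samples required in every bin.
#' @return An object of class `reference_ranges`: data frame with columns
#'   `population`, `age_lo`, `age_hi`, `p5`, `p95`.
#' @export
derive_reference_ranges <- function(cohort,
                                    age_bins = c(0, 2, 5, 10, 18, 65, 120),
                                    registry = pidot_registry(),
                                    min_per_bin = 20L) {
  stopifnot(is.list(cohort), length(cohort) >= 1L, is.numeric(age_bins),
            length(age_bins) >= 2L, all(diff(age_bins) > 0))
  metas <- lapply(cohort, function(s) if (!is.null(s$meta)) s$meta
                  else s$events$meta)
  ages <- vapply(metas, `[[`, 0, "age_years")
  bin_of <- findInterval(ages, age_bins, rightmost.closed = FALSE)
  if (any(bin_of < 1 | bin_of >= length(age_bins)))
    stop("some sample ages fall outside the age bins", call. = FALSE)
  counts <- lapply(seq_along(cohort), function(i)
    truth_counts(cohort[[i]]$labels, metas[[i]], registry))
  pops <- setdiff(names(registry$populations),
                  c("other_leukocyte", "debris"))
  out <- list()
  for (b in seq_len(length(age_bins) - 1L)) {
    in_bin <- which(bin_of == b)
    if (length(in_bin) < min_per_bin)
      stop("age bin [", age_bins[b], ", ", age_bins[b + 1L], ") holds ",
           length(in_bin), " samples; at least ", min_per_bin,
           " are required", call. = FALSE)
    for (p in pops) {
      x <- vapply(in_bin, function(i) {
        ct <- counts[[i]]
        ct$abs_per_ul[ct$population == p]
      }, 0)
      q <- stats::quantile(x, c(0.05, 0.95), type = 7, names = FALSE)
      if (q[1] >= q[2])
        stop("degenerate reference range (p5 >= p95) for population '", p,
             "' in bin [", age_bins[b], ", ", age_bins[b + 1L], ")",
             call. = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        population = p, age_lo = age_bins[b], age_hi = age_bins[b + 1L],
        p5 = q[1], p95 = q[2], stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, out), class = c("reference_ranges", "data.frame"))
}

#' Look up the reference interval for one population and age
#'
#' @param ranges A `reference_ranges`.
#' @param population Population id.
#' @param age_years Age in years.
#' @return Numeric `c(p5, p95)`, or `NULL` when the population has no range.
#' @export
range_lookup <- function(ranges, population, age_years) {
  stopifnot(inherits(ranges, "reference_ranges"))
  hit <- ranges$population == population &
    ranges$age_lo <= age_years & age_years < ranges$age_hi
  if (!any(hit)) {
    if (!any(ranges$population == population)) return(NULL)
    stop("age ", age_years, " y is not covered by the reference ranges",
         call. = FALSE)
  }
  c(p5 = ranges$p5[hit][1], p95 = ranges$p95[hit][1])
}

#' Classify a count against a p5-p95 interval
#'
#' Interval inclusion is inclusive at both percentiles: a count equal to p5
#' or p95 is `in_range`.
#'
#' @param count Absolute count (cells/uL).
#' @param p5,p95 Interval bounds, `p5 < p95`.
#' @return `"below_p5"`, `"in_range"` or `"above_p95"`.
#' @export
range_status <- function(count, p5, p95) {
  stopifnot(p5 < p95)
  ifelse(count < p5, "below_p5", ifelse(count > p95, "above_p95", "in_range"))
}
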