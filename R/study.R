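#' Run the full paired-comparison study on a labeled cohort
#'
#' Mirrors the method-comparison design: every sample is analyzed in
#' parallel by manual gating (canonical thresholds) and by the automated
#' cluster-and-classify pipeline against a reference database built on a
#' disjoint training cohort; paired comparison records are produced per
#' population, equivalence is judged against the 20 percent criterion, and
#' clinical relevance (different interpretation against the age-matched
#' p5-p95 interval) is evaluated for the non-equivalent observations. A
#' reproducibility harness re-analyzes a seeded random subset of samples
#' five times per condition: intra-observer (manual: five independent
#' small-jitter re-gatings; automated: five runs with a fixed clustering
#' seed, which are bit-identical by determinism and therefore carry exactly
#' zero CV) and inter-observer (manual: five observers with independent
#' threshold jitter; automated: five runs with observer-specific clustering
#' seeds). Identical automated invocations are computed once and reused;
#' determinism of the pipeline makes the reuse exact.
#'
#' @param cohort List of samples (elements with `events`, `labels`) from
#'   [simulate_cohort()] or equivalent.
#' @param db A [reference_database] built on samples disjoint from
#'   `cohort` (checked via sample ids).
#' @param ranges A `reference_ranges` covering the cohort ages.
#' @param thresholds,tree,registry Gating configuration.
#' @param seed Master seed for all randomness in the study.
#' @param n_observers Observers in the inter-observer arm.
#' @param inter_jitter_sd,intra_jitter_sd Threshold jitter (transformed
#'   units) between observers and between re-gatings of one observer.
#' @param n_replicates Replicates per reproducibility condition.
#' @param n_repro_samples Size of the reproducibility subset.
#' @param k,cutoff_quantile,fit_sample Automated pipeline settings.
#' @param cofactor asinh cofactor.
#' @return A list of class `study_result` with `records` (comparison
#'   records), `summary` (per population x group discrepancy table),
#'   `correlations` (Spearman rho per population x group), `samples`
#'   (per-sample assignment/check statistics and scatter QC), `repro`
#'   (long CV table) and `repro_medians`.
#' @export
run_study <- function(cohort, db, ranges,
                      thresholds = pidot_thresholds(),
                      tree = pidot_gate_tree(),
                      registry = pidot_registry(),
                      seed = 1L, n_observers = 5L,
                      inter_jitter_sd = 0.1, intra_jitter_sd = 0.05,
                      n_replicates = 5L, n_repro_samples = 12L,
                      k = NULL, cutoff_quantile = 0.999,
                      cofactor = 150, fit_sample = 30000L) {
  stopifnot(inherits(db, "reference_database"))
  ids <- vapply(cohort, function(s) s$events$meta$sample_id, "")
  if (any(ids %in% db$train_ids))
    stop("reference database was trained on evaluation sample(s): ",
         paste(intersect(ids, db$train_ids), collapse = ", "), call. = FALSE)
  n <- length(cohort)
  seeds <- withr::with_seed(seed, {
    list(inter_obs = sample.int(.Machine$integer.max, n_observers),
         intra_rep = sample.int(.Machine$integer.max, n_replicates),
         repro_idx = sort(sample.int(n, min(n_repro_samples, n))))
  })
  # per-sample seeds are derived from the sample id, not the list position,
  # so the study is invariant under reordering of the cohort
  seeds$agi <- vapply(ids, function(id) .id_seed(seed, id), 0L,
                      USE.NAMES = FALSE)

  agi_cache <- new.env(parent = emptyenv())
  agi_run <- function(i, tr_events, agi_seed) {
    key <- paste(i, agi_seed, sep = "|")
    if (!is.null(agi_cache[[key]])) return(agi_cache[[key]])
    rep <- auto_gate(tr_events, db, ranges = ranges,
                     thresholds = thresholds, k = k, seed = agi_seed,
                     cutoff_quantile = cutoff_quantile,
                     registry = registry, fit_sample = fit_sample)
    agi_cache[[key]] <- rep
    rep
  }

  records <- list(); samples <- list()
  transformed <- vector("list", n)
  for (i in seq_len(n)) {
    s <- cohort[[i]]
    tr <- if (s$events$scale == "raw")
      transform_fluorescence(s$events, cofactor) else s$events
    transformed[[i]] <- tr
    mg <- classify_events(tr, tree, thresholds)
    counts_mg <- population_counts(mg, s$events$meta)
    rep_ag <- agi_run(i, tr, seeds$agi[i])
    records[[i]] <- compare_counts(counts_mg, rep_ag$table,
                                   s$events$meta, ranges)
    qc <- scatter_qc(tr, mg$labels %in%
                       tree_descendants(tree, tree$root) |
                       startsWith(mg$labels, "unclassified_"))
    samples[[i]] <- data.frame(
      sample_id = ids[i], group = s$events$meta$group,
      checks_fraction = rep_ag$checks_fraction,
      assigned_fraction = 1 - rep_ag$checks_fraction,
      n_checks = rep_ag$n_checks,
      qc_fsc_pass = qc$fsc_pass, qc_ssc_pass = qc$ssc_pass,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, records)
  samples <- do.call(rbind, samples)

  summary <- .study_summary(records)
  correlations <- .study_correlations(records)

  # ---- reproducibility harness ----
  intra_thr <- lapply(seeds$intra_rep, function(sd_seed)
    perturb_thresholds(thresholds,
                       observer_model(intra_jitter_sd, sd_seed)))
  inter_thr <- lapply(seeds$inter_obs, function(sd_seed)
    perturb_thresholds(thresholds,
                       observer_model(inter_jitter_sd, sd_seed)))
  pops <- comparison_populations()
  repro <- list()
  pull <- function(tab) {
    i <- match(pops, tab$population)
    stats::setNames(tab$abs_per_ul[i], pops)
  }
  for (i in seeds$repro_idx) {
    tr <- transformed[[i]]
    meta <- cohort[[i]]$events$meta
    mg_counts <- function(thr)
      pull(population_counts(classify_events(tr, tree, thr), meta))
    conds <- list(
      list(method = "MG", mode = "intra",
           mat = vapply(intra_thr, mg_counts, numeric(length(pops)))),
      list(method = "MG", mode = "inter",
           mat = vapply(inter_thr, mg_counts, numeric(length(pops)))),
      list(method = "AG&I", mode = "intra",
           mat = vapply(rep(seeds$agi[i], n_replicates), function(sd)
             pull(agi_run(i, tr, sd)$table), numeric(length(pops)))),
      list(method = "AG&I", mode = "inter",
           mat = vapply(seeds$inter_obs, function(sd)
             pull(agi_run(i, tr, sd)$table), numeric(length(pops))))
    )
    for (cn in conds) {
      rv <- reproducibility(cn$mat)
      rv$sample_id <- ids[i]; rv$method <- cn$method; rv$mode <- cn$mode
      repro[[length(repro) + 1L]] <- rv
    }
  }
  repro <- do.call(rbind, repro)
  repro_medians <- stats::aggregate(
    cv_pct ~ method + mode, data = repro,
    FUN = function(x) stats::median(x, na.rm = TRUE), na.action = stats::na.pass)
  names(repro_medians)[names(repro_medians) == "cv_pct"] <- "median_cv_pct"

  structure(list(records = records, summary = summary,
                 correlations = correlations, samples = samples,
                 repro = repro, repro_medians = repro_medians,
                 seed = seed),
            class = "study_result")
}

# deterministic seed from a master seed and a sample id (polynomial string
# hash folded into the positive 32-bit integer range)
.id_seed <- function(master, id) {
  h <- as.double(master %% 2147483647)
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h + 1)
}

# per population x group counts of >20% and clinically relevant differences
.study_summary <- function(records) {
  groups <- c(unique(records$group), "total")
  pops <- unique(records$population)
  rows <- list()
  for (g in groups) {
    rg <- if (g == "total") records else records[records$group == g, ]
    for (p in pops) {
      rp <- rg[rg$population == p, ]
      n <- nrow(rp)
      n_gt20 <- sum(!rp$equivalent)
      relevant <- !rp$equivalent & !is.na(rp$clinically_relevant) &
        rp$clinically_relevant
      rows[[length(rows) + 1L]] <- data.frame(
        population = p, group = g, n = n,
        n_gt20 = n_gt20, pct_gt20 = 100 * n_gt20 / n,
        n_relevant = sum(relevant), pct_relevant = 100 * sum(relevant) / n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.study_correlations <- function(records) {
  groups <- c(unique(records$group), "total")
  pops <- unique(records$population)
  rows <- list()
  for (g in groups) {
    rg <- if (g == "total") records else records[records$group == g, ]
    for (p in pops) {
      rp <- rg[rg$population == p, ]
      rho <- if (nrow(rp) >= 3L)
        spearman_rho(rp$count_mg, rp$count_ag) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        population = p, group = g, n = nrow(rp), rho = rho,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.study_result <- function(x, ...) {
  tot <- x$summary[x$summary$group == "total", ]
  cat(sprintf(
    "study_result: %d samples, %d populations; %.1f%% of observations with >20%% differences\n",
    length(unique(x$records$sample_id)), length(unique(x$records$population)),
    100 * sum(tot$n_gt20) / sum(tot$n)))
  print(x$repro_medians, row.names = FALSE)
  invisible(x)
}
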