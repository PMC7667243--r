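# Channels of the multidimensional analysis space: all fluorescence
# channels (transformed) plus the two area scatter signals. FSC-H is left
# out: it is collinear with FSC-A for singlets and the cleanup step has
# already used it.
.analysis_channels <- function(panel) {
  c(panel_channels(panel, "fluorescence"), "FSC-A", "SSC-A")
}

.analysis_matrix <- function(events) {
  events$values[, .analysis_channels(events$panel), drop = FALSE]
}

#' Build an annotated reference database from labeled samples
#'
#' Pools the labeled events of a training cohort into one multivariate
#' summary per population: mean vector and covariance matrix over the
#' analysis space (transformed fluorescence plus area scatter), with the
#' covariance shrunk toward its diagonal, `(1 - lambda) * S + lambda *
#' diag(S)`, so that sparse populations stay well conditioned. The database
#' is immutable once built and carries its panel tag and build seed.
#'
#' @param cohort List of per-sample lists with `events` (raw or transformed
#'   [event_matrix]) and `labels` (per-event population labels, e.g. truth
#'   labels of simulated samples or expert annotations).
#' @param populations Populations to include; default: all terminal lymphoid
#'   populations except the CD4+CD8+ double positives (which the automated
#'   module does not report as a separate population), plus the
#'   `other_leukocyte` background class.
#' @param lambda Diagonal shrinkage weight in `[0, 1]`.
#' @param min_events Minimum pooled training events per population.
#' @param seed Build seed recorded in the database (the build itself is
#'   deterministic).
#' @param include_dp If `TRUE`, adds `dp_t` to the default population set.
#' @param registry A [population_registry].
#' @param cofactor asinh cofactor applied to raw-scale cohort members.
#' @return An object of class `reference_database`.
#' @export
build_database <- function(cohort, populations = NULL, lambda = 0.1,
                           min_events = 50L, seed = 0L, include_dp = FALSE,
                           registry = pidot_registry(), cofactor = 150) {
  stopifnot(is.list(cohort), length(cohort) >= 1L)
  if (length(cohort) < 10L)
    stop("a reference database needs at least 10 training samples, got ",
         length(cohort), call. = FALSE)
  if (lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]", call. = FALSE)
  if (is.null(populations)) {
    populations <- setdiff(registry_terminals(registry, lymphoid = TRUE),
                           if (include_dp) character() else "dp_t")
    populations <- c(populations, "other_leukocyte")
  }
  panel <- cohort[[1]]$events$panel
  chans <- .analysis_channels(panel)
  pooled <- stats::setNames(vector("list", length(populations)), populations)
  for (s in cohort) {
    ev <- if (s$events$scale == "raw")
      transform_fluorescence(s$events, cofactor) else s$events
    m <- .analysis_matrix(ev)
    for (p in populations) {
      rows <- s$labels == p
      if (any(rows))
        pooled[[p]] <- rbind(pooled[[p]], m[rows, , drop = FALSE])
    }
  }
  deficient <- populations[vapply(pooled, function(x)
    is.null(x) || nrow(x) < min_events, TRUE)]
  if (length(deficient))
    stop("population(s) with fewer than ", min_events,
         " pooled training events: ", paste(deficient, collapse = ", "),
         call. = FALSE)
  pops <- lapply(pooled, function(x) {
    s <- stats::cov(x)
    s_shrunk <- (1 - lambda) * s + lambda * diag(diag(s))
    list(mean = colMeans(x), cov = s_shrunk, n = nrow(x))
  })
  structure(list(populations = pops, channels = chans,
                 panel_version = attr(panel, "version"),
                 lambda = lambda, seed = as.integer(seed),
                 n_samples = length(cohort),
                 train_ids = vapply(cohort, function(s)
                   s$events$meta$sample_id, "")),
            class = "reference_database")
}

#' @export
print.reference_database <- function(x, ...) {
  cat(sprintf(
    "reference_database: %d populations, %d channels, panel %s, lambda %.2f\n",
    length(x$populations), length(x$channels), x$panel_version, x$lambda))
  invisible(x)
}

#' Seeded over-clustering of a sample
#'
#' First step of the automated pipeline: partition all events into `k`
#' clusters (default `max(50, ceiling(sqrt(N)))`, deliberately many more
#' than there are populations) by k-means in the standardized analysis
#' space. For large samples the centers are fitted on a seeded subsample
#' and every event is then assigned to its nearest center in blocks, which
#' keeps memory flat without changing the deterministic seeded behavior.
#' Initialization uses a seeded k-means++ scheme for small `k` (which
#' reliably seeds sparse, well-separated populations) and a seeded simple
#' random sample of events for large `k`.
#'
#' @param events A transformed-scale [event_matrix] (cleanup is expected
#'   upstream; see [auto_gate()]).
#' @param k Number of clusters, or `NULL` for the default.
#' @param seed Integer seed.
#' @param fit_sample Maximum events used to fit the centers.
#' @param iter_max Lloyd iteration cap.
#' @return Integer vector of cluster ids (1..k) with attributes `centers`
#'   (k x channels matrix in analysis-space units) and `sizes`.
#' @export
cluster_events <- function(events, k = NULL, seed = 1L,
                           fit_sample = 50000L, iter_max = 30L) {
  stopifnot(inherits(events, "event_matrix"))
  if (events$scale != "transformed")
    stop("cluster_events needs transformed-scale events", call. = FALSE)
  n <- n_events(events)
  if (is.null(k)) k <- max(50L, ceiling(sqrt(n)))
  if (k > n) stop("k = ", k, " exceeds the number of events ", n,
                  call. = FALSE)
  x <- .analysis_matrix(events)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  cl <- withr::with_seed(seed, {
    fit_idx <- if (n > fit_sample) sample.int(n, fit_sample) else seq_len(n)
    xf <- xs[fit_idx, , drop = FALSE]
    init <- if (k == 1L) {
      matrix(colMeans(xf), 1L)
    } else if (k <= 200L) {
      .kmeanspp_centers(xf, k)
    } else {
      xf[sample.int(nrow(xf), k), , drop = FALSE]
    }
    km <- suppressWarnings(stats::kmeans(xf, centers = init,
                                         iter.max = iter_max,
                                         algorithm = "Lloyd"))
    .nearest_center(xs, km$centers)
  })
  sizes <- tabulate(cl, nbins = k)
  centers <- matrix(NA_real_, k, ncol(x), dimnames = list(NULL, colnames(x)))
  sums <- rowsum(x, cl)
  gi <- as.integer(rownames(sums))
  centers[gi, ] <- sums / sizes[gi]
  attr(cl, "centers") <- centers
  attr(cl, "sizes") <- sizes
  cl
}

# seeded k-means++ initialization
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1L, ], "-")^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- d2 / sum(d2)
    i <- sample.int(n, 1L, prob = p)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ], "-")^2))
  }
  centers
}

# blockwise nearest-center assignment (squared Euclidean)
.nearest_center <- function(x, centers, block = 20000L) {
  cn <- rowSums(centers^2)
  idx <- integer(nrow(x))
  for (s in seq(1L, nrow(x), by = block)) {
    e <- min(s + block - 1L, nrow(x))
    dd <- cn - 2 * tcrossprod(centers, x[s:e, , drop = FALSE])
    idx[s:e] <- apply(dd, 2, which.min)
  }
  idx
}

#' Classify clusters against the reference database
#'
#' Second step of the automated pipeline: each cluster centroid is compared
#' with every database population by squared Mahalanobis distance and
#' assigned to the nearest population when that distance does not exceed
#' the chi-squared quantile (`df` = number of analysis channels) at
#' `cutoff_quantile`. Clusters nearer to nothing become "checks": they stay
#' unassigned and carry the up-to-three nearest candidate populations for
#' expert review. Exact distance ties are broken toward the population with
#' more training events, then lexicographically.
#'
#' @param clusters Cluster vector from [cluster_events()].
#' @param db A [reference_database] built on the same panel.
#' @param cutoff_quantile Assignment quantile in `(0, 1)`; default 0.999.
#' @return An object of class `cluster_assignments`: data frame with one
#'   row per cluster (`cluster`, `size`, `population` (`NA` = check),
#'   `distance`, `expert_resolved`, `discarded`) and a `candidates`
#'   attribute (per-check data frames of the nearest populations).
#' @export
classify_clusters <- function(clusters, db, cutoff_quantile = 0.999) {
  stopifnot(inherits(db, "reference_database"))
  if (cutoff_quantile <= 0 || cutoff_quantile >= 1)
    stop("cutoff_quantile must lie in (0, 1)", call. = FALSE)
  centers <- attr(clusters, "centers")
  sizes <- attr(clusters, "sizes")
  if (is.null(centers))
    stop("clusters must come from cluster_events()", call. = FALSE)
  pop_ids <- names(db$populations)
  k <- nrow(centers)
  d2 <- matrix(Inf, k, length(pop_ids), dimnames = list(NULL, pop_ids))
  live <- which(sizes > 0)
  for (p in pop_ids) {
    pop <- db$populations[[p]]
    cv <- tryCatch(chol(pop$cov), error = function(e)
      stop("covariance of population '", p,
           "' is singular despite regularization", call. = FALSE))
    d2[live, p] <- stats::mahalanobis(centers[live, , drop = FALSE],
                                      pop$mean, pop$cov)
  }
  cutoff <- stats::qchisq(cutoff_quantile, df = length(db$channels))
  n_train <- vapply(db$populations, `[[`, 0, "n")
  assigned <- rep(NA_character_, k)
  distance <- rep(NA_real_, k)
  candidates <- vector("list", k)
  for (g in live) {
    d <- d2[g, ]
    # distances equal within 1e-12 are ties, broken toward the population
    # with the larger training count, then lexicographically
    ord <- order(round(d, 12), -n_train[pop_ids], pop_ids)
    best <- ord[1]
    distance[g] <- d[best]
    if (d[best] <= cutoff) {
      assigned[g] <- pop_ids[best]
    } else {
      top <- ord[seq_len(min(3L, length(ord)))]
      candidates[[g]] <- data.frame(population = pop_ids[top],
                                    distance = unname(d[top]),
                                    stringsAsFactors = FALSE)
    }
  }
  out <- data.frame(cluster = seq_len(k), size = sizes,
                    population = assigned, distance = distance,
                    expert_resolved = FALSE, discarded = FALSE,
                    stringsAsFactors = FALSE)
  structure(out, candidates = candidates,
            cutoff = cutoff, cutoff_quantile = cutoff_quantile,
            db_populations = pop_ids,
            class = c("cluster_assignments", "data.frame"))
}

#' Expert resolution of checks
#'
#' Applies an expert's decisions to the unassigned clusters: each check can
#' be mapped to a population (flagged `expert_resolved`) or discarded, in
#' which case its events are excluded from every population count while the
#' event partition is preserved through an explicit excluded bucket.
#' Automatically assigned clusters are immutable unless `override = TRUE`,
#' mirroring an extended expert revision.
#'
#' @param assignments A `cluster_assignments`.
#' @param resolution Named list: cluster id (as character) -> population id
#'   or `"discard"`.
#' @param override Allow re-assigning auto-assigned clusters.
#' @return The updated `cluster_assignments`.
#' @export
resolve_checks <- function(assignments, resolution, override = FALSE) {
  stopifnot(inherits(assignments, "cluster_assignments"))
  if (!length(resolution)) return(assignments)
  for (cid in names(resolution)) {
    g <- as.integer(cid)
    if (is.na(g) || g < 1L || g > nrow(assignments))
      stop("resolution names an unknown cluster '", cid, "'", call. = FALSE)
    if (!is.na(assignments$population[g]) && !override)
      stop("cluster ", g, " was assigned automatically; ",
           "expert resolution may only touch checks (use override = TRUE ",
           "for an extended revision)", call. = FALSE)
    target <- resolution[[cid]]
    if (identical(target, "discard")) {
      assignments$discarded[g] <- TRUE
      assignments$population[g] <- NA_character_
    } else {
      assignments$population[g] <- target
      assignments$expert_resolved[g] <- TRUE
    }
  }
  assignments
}

#' Automated gating report
#'
#' Final step of the automated pipeline: aggregates cluster assignments
#' into per-population counts (dual-platform absolute counts from the
#' sample's WBC), compares each population against its age-matched p5-p95
#' reference interval, and flags a "remark" wherever the count falls
#' outside it. Events in unresolved checks are excluded from all population
#' counts, and the fraction of lymphoid events sitting in checks is
#' reported under both denominator conventions (lymphoid events and all
#' clustered events).
#'
#' @param assignments A `cluster_assignments` (possibly after
#'   [resolve_checks()]).
#' @param meta A [sample_meta] (age and WBC count are required).
#' @param ranges A `reference_ranges`, or `NULL` to skip range evaluation.
#' @param registry A [population_registry].
#' @return An object of class `autogate_report`: list with `table`
#'   (population, events, pct_wbc, abs_per_ul, status, remark), `checks`
#'   (per-check summaries with candidates), `checks_fraction`,
#'   `checks_fraction_total`, `n_checks`, and the event bookkeeping.
#' @export
autogate_report <- function(assignments, meta, ranges = NULL,
                            registry = pidot_registry()) {
  stopifnot(inherits(assignments, "cluster_assignments"),
            inherits(meta, "sample_meta"))
  n_total <- sum(assignments$size)
  ev_by_pop <- tapply(assignments$size, assignments$population, sum)
  cnt <- function(p) if (p %in% names(ev_by_pop)) ev_by_pop[[p]] else 0
  checks <- is.na(assignments$population) & !assignments$discarded
  n_checks_events <- sum(assignments$size[checks])
  n_excluded <- sum(assignments$size[assignments$discarded])
  n_other <- cnt("other_leukocyte")
  n_lymphoid <- n_total - n_other
  # report only populations the database can represent (plus their
  # ancestors); e.g. CD4+CD8+ T cells are absent unless the database
  # includes them
  db_terminals <- setdiff(attr(assignments, "db_populations") %||%
                            names(registry$populations),
                          c("other_leukocyte", "debris"))
  report_pops <- intersect(
    names(registry$populations),
    unique(c(db_terminals,
             unlist(lapply(db_terminals, registry_ancestors,
                           reg = registry)))))
  rows <- lapply(report_pops, function(p) {
    desc <- .terminal_descendants(registry, p)
    ev <- sum(vapply(desc, cnt, 0))
    pct <- 100 * ev / n_total
    abs_ul <- pct * meta$wbc_per_ul / 100
    status <- NA_character_
    if (!is.null(ranges)) {
      rg <- range_lookup(ranges, p, meta$age_years)
      if (!is.null(rg)) status <- range_status(abs_ul, rg[1], rg[2])
    }
    data.frame(population = p, events = ev, pct_wbc = pct,
               abs_per_ul = abs_ul, status = status,
               remark = !is.na(status) & status != "in_range",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  cand <- attr(assignments, "candidates")
  check_rows <- which(checks)
  check_list <- lapply(check_rows, function(g)
    list(cluster = g, size = assignments$size[g],
         candidates = cand[[g]]))
  structure(list(
    table = tab,
    checks = check_list,
    n_checks = length(check_rows),
    checks_fraction = if (n_lymphoid > 0) n_checks_events / n_lymphoid else 0,
    checks_fraction_total = if (n_total > 0) n_checks_events / n_total else 0,
    n_events = n_total, n_lymphoid = n_lymphoid,
    n_excluded = n_excluded, n_other_leukocyte = n_other,
    meta = meta), class = "autogate_report")
}

#' @export
print.autogate_report <- function(x, ...) {
  cat(sprintf(
    "autogate_report: %d events, %d checks (%.2f%% of lymphoid events), %d remark(s)\n",
    x$n_events, x$n_checks, 100 * x$checks_fraction,
    sum(x$table$remark, na.rm = TRUE)))
  invisible(x)
}

#' One-call automated gating of a raw sample
#'
#' Runs the full automated pipeline: cleanup as in the manual pre-gating
#' (doublet exclusion on the FSC-H/FSC-A ratio and removal of events below
#' the debris FSC-A floor), asinh transformation, seeded over-clustering,
#' classification of clusters against the reference database, optional
#' expert resolution, and the final report. The WBC-representing
#' denominator (all non-doublet, non-debris events) matches the manual
#' engine's, so counts are directly comparable.
#'
#' @inheritParams cluster_events
#' @inheritParams classify_clusters
#' @inheritParams autogate_report
#' @param events A raw-scale (or transformed) [event_matrix].
#' @param db A [reference_database].
#' @param meta Optional [sample_meta]; defaults to the one in `events`.
#' @param thresholds A [threshold_set] supplying the cleanup parameters.
#' @param resolution Optional expert resolution map (see
#'   [resolve_checks()]).
#' @param cofactor asinh cofactor.
#' @return The `autogate_report`, with the `cluster_assignments` attached
#'   as attribute `assignments` and the per-event cluster labels (0 for
#'   events removed by cleanup) as attribute `event_clusters`.
#' @export
auto_gate <- function(events, db, meta = NULL, ranges = NULL,
                      thresholds = pidot_thresholds(), k = NULL, seed = 1L,
                      cutoff_quantile = 0.999, resolution = NULL,
                      registry = pidot_registry(), cofactor = 150,
                      fit_sample = 50000L) {
  stopifnot(inherits(events, "event_matrix"),
            inherits(db, "reference_database"))
  if (is.null(meta)) meta <- events$meta
  tr <- if (events$scale == "raw")
    transform_fluorescence(events, cofactor) else events
  singlet <- exclude_doublets(tr, thresholds$doublet_ratio_tolerance)
  keep <- singlet & tr$values[, "FSC-A"] >= thresholds$debris_fsc_max
  idx <- which(keep)
  if (!length(idx))
    stop("cleanup removed every event", call. = FALSE)
  sub <- event_matrix(tr$values[idx, , drop = FALSE], tr$panel, meta,
                      scale = "transformed", cofactor = tr$cofactor)
  cl <- cluster_events(sub, k = k, seed = seed, fit_sample = fit_sample)
  asg <- classify_clusters(cl, db, cutoff_quantile = cutoff_quantile)
  if (!is.null(resolution)) asg <- resolve_checks(asg, resolution)
  rep <- autogate_report(asg, meta, ranges, registry)
  ev_cl <- integer(n_events(events))
  ev_cl[idx] <- cl
  attr(rep, "assignments") <- asg
  attr(rep, "event_clusters") <- ev_cl
  rep
}
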