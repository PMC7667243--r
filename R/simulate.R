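#' Aberration specifications
#'
#' An aberration shifts the expression of one marker in one target
#' population by a fixed amount on the transformed scale (and may widen its
#' spread), emulating staining artifacts and disease-associated phenotypes:
#' a technically dim CD4 stain moves CD4+ subsets onto the CD4-CD8- TCRgd-
#' phenotype, and dim IgD on IgM-negative memory B cells blurs the boundary
#' between IgD+IgM- post-GC and switched memory B cells.
#'
#' @param population Target population id (must exist in the registry).
#' @param marker Marker whose expression is altered.
#' @param shift Amount added to the band mean, transformed units.
#' @param sd_scale Multiplier for the band sd of that marker (>= 1 smears).
#' @param label Free-text description.
#' @return An object of class `aberration_spec`.
#' @export
aberration_spec <- function(population, marker, shift = 0, sd_scale = 1,
                            label = "") {
  stopifnot(is.character(population), length(population) == 1L,
            is.character(marker), length(marker) == 1L,
            is.numeric(shift), length(shift) == 1L,
            is.numeric(sd_scale), sd_scale > 0)
  structure(list(population = population, marker = marker, shift = shift,
                 sd_scale = sd_scale, label = label),
            class = "aberration_spec")
}

#' @rdname aberration_spec
#' @param subsets CD4+ subsets affected by the dim stain.
#' @export
aberration_dim_cd4 <- function(shift = -3.0,
                               subsets = c("cd4_naive", "cd4_cm",
                                           "cd4_em", "cd4_td")) {
  lapply(subsets, aberration_spec, marker = "CD4", shift = shift,
         label = "technically dim CD4 stain")
}

#' @rdname aberration_spec
#' @export
aberration_igd_dim <- function(shift = -2.0) {
  list(aberration_spec("igd_only_post_gc", "IgD", shift = shift,
                       label = "dim IgD on IgM-negative memory B cells"))
}

#' Observer model
#'
#' Operationalizes observer-to-observer gating variability as a seeded
#' Gaussian jitter on the manual gating thresholds: each marker's cut
#' points are shifted together by one draw from `N(0, jitter_sd^2)`.
#' `jitter_sd = 0` reproduces the canonical threshold set exactly.
#'
#' @param jitter_sd Non-negative threshold jitter sd (transformed units).
#' @param seed Integer seed identifying the observer (or replicate).
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(jitter_sd = 0.1, seed = 1L) {
  stopifnot(is.numeric(jitter_sd), length(jitter_sd) == 1L, jitter_sd >= 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "observer_model")
}

#' Perturb a threshold set according to an observer model
#'
#' @param thresholds A [threshold_set].
#' @param observer An [observer_model].
#' @return A [threshold_set] with jittered marker cut points. The scatter
#'   gate and doublet tolerance are not jittered.
#' @export
perturb_thresholds <- function(thresholds, observer) {
  stopifnot(inherits(thresholds, "threshold_set"),
            inherits(observer, "observer_model"))
  if (observer$jitter_sd == 0) return(thresholds)
  markers <- names(thresholds$cuts)
  shifts <- withr::with_seed(observer$seed,
                             stats::rnorm(length(markers), 0,
                                          observer$jitter_sd))
  for (i in seq_along(markers))
    thresholds$cuts[[markers[i]]] <- thresholds$cuts[[markers[i]]] + shifts[i]
  thresholds
}

# Generate one block of events for a template population.
# Returns transformed-scale fluorescence plus raw scatter; `doublet = TRUE`
# doubles the area signals while keeping FSC-H at the singlet value.
.gen_block <- function(reg, bm, pop_id, n, aberrations, doublet = FALSE) {
  if (n == 0L) return(NULL)
  tpl <- reg$populations[[pop_id]]
  markers <- reg$markers
  mu <- bm$means[unlist(tpl$bands[markers])]
  sdv <- rep(bm$sd, length(markers))
  for (ab in aberrations) {
    if (ab$population == pop_id) {
      j <- match(ab$marker, markers)
      if (is.na(j)) stop("aberration marker '", ab$marker, "' not in panel",
                         call. = FALSE)
      mu[j] <- mu[j] + ab$shift
      sdv[j] <- sdv[j] * ab$sd_scale
    }
  }
  fl <- matrix(stats::rnorm(n * length(markers),
                            mean = rep(mu, each = n),
                            sd = rep(sdv, each = n)),
               nrow = n)
  sd_class <- if (pop_id == "debris") "debris" else
    if (pop_id == "other_leukocyte") "other_leukocyte" else "lymphoid"
  ssd <- unlist(reg$scatter_sd[[sd_class]])
  fsc <- stats::rnorm(n, tpl$scatter_mean[[1]], ssd[1])
  ssc <- stats::rnorm(n, tpl$scatter_mean[[2]], ssd[2])
  fsc_h <- fsc * stats::rnorm(n, 0.98, 0.02)
  if (doublet) {
    fsc <- fsc * 2
    ssc <- ssc * 2
  }
  list(fluor = fl, fsc_a = fsc, ssc_a = ssc, fsc_h = fsc_h)
}

#' Simulate one PIDOT-like sample with ground-truth labels
#'
#' Draws a full event-level sample: terminal lymphoid population fractions
#' are sampled uniformly within each template's `fraction_range`, the
#' remaining white-cell mass becomes the `other_leukocyte` background, and
#' event counts are one multinomial draw over doublets, debris and the
#' white-cell classes. Marker intensities follow the band model on the
#' transformed scale (mapped back to raw channel units through the inverse
#' asinh), doublets carry doubled area signals with singlet FSC-H, and
#' debris sits at low scatter. The returned matrix is raw-scale and event
#' order is randomly permuted; everything is deterministic given `seed`.
#'
#' @param registry A [population_registry].
#' @param bm A [band_model].
#' @param meta A [sample_meta].
#' @param n_events Total number of events (>= 10,000 recommended for
#'   cohort-scale use; smaller is fine in tests).
#' @param seed Integer seed; all randomness flows from it.
#' @param aberrations List of [aberration_spec] objects.
#' @param doublet_rate,debris_rate Expected fractions of doublet / debris
#'   events, each in `[0, 0.2]`.
#' @param fraction_overrides Named list fixing the drawn fraction of
#'   specific populations (fractions of WBC). A terminal id fixes that
#'   population; a parent id rescales its terminal descendants
#'   proportionally.
#' @param cofactor asinh cofactor linking transformed and raw scales.
#' @return A list with elements `events` (raw-scale [event_matrix]),
#'   `labels` (character vector of per-event ground-truth labels) and
#'   `fractions` (the drawn WBC fractions).
#' @export
simulate_sample <- function(registry, bm, meta, n_events, seed,
                            aberrations = list(),
                            doublet_rate = 0.02, debris_rate = 0.03,
                            fraction_overrides = list(),
                            cofactor = 150) {
  stopifnot(inherits(registry, "population_registry"),
            inherits(bm, "band_model"), inherits(meta, "sample_meta"))
  if (inherits(aberrations, "aberration_spec")) aberrations <- list(aberrations)
  if (n_events < 1) stop("n_events must be positive", call. = FALSE)
  if (doublet_rate < 0 || doublet_rate > 0.2 ||
      debris_rate < 0 || debris_rate > 0.2)
    stop("doublet_rate and debris_rate must lie in [0, 0.2]", call. = FALSE)
  for (ab in aberrations)
    if (!ab$population %in% names(registry$populations))
      stop("aberration targets unknown population '", ab$population, "'",
           call. = FALSE)
  term <- registry_terminals(registry, lymphoid = TRUE)
  withr::with_seed(seed, {
    fracs <- vapply(term, function(id) {
      fr <- registry$populations[[id]]$fraction_range
      stats::runif(1, fr[[1]], fr[[2]])
    }, 0)
    fracs <- .apply_fraction_overrides(registry, fracs, fraction_overrides)
    if (sum(fracs) >= 1)
      stop("lymphoid fractions sum to >= 1; inconsistent with the ",
           "whole-blood hierarchy", call. = FALSE)
    probs <- c(doublet = doublet_rate, debris = debris_rate,
               (1 - doublet_rate - debris_rate) *
                 c(fracs, other_leukocyte = 1 - sum(fracs)))
    counts <- as.vector(stats::rmultinom(1, n_events, probs))
    names(counts) <- names(probs)

    blocks <- list()
    labels <- character(0)
    # doublets: mixture of lymphoid singlet profiles with doubled area
    if (counts[["doublet"]] > 0) {
      comp <- sample(term, counts[["doublet"]], replace = TRUE,
                     prob = fracs / sum(fracs))
      for (id in unique(comp)) {
        b <- .gen_block(registry, bm, id, sum(comp == id), aberrations,
                        doublet = TRUE)
        blocks <- c(blocks, list(b))
        labels <- c(labels, rep("doublet", sum(comp == id)))
      }
    }
    for (id in c("debris", term, "other_leukocyte")) {
      n_id <- counts[[id]]
      b <- .gen_block(registry, bm, id, n_id, aberrations)
      if (!is.null(b)) {
        blocks <- c(blocks, list(b))
        labels <- c(labels, rep(id, n_id))
      }
    }
    fluor <- do.call(rbind, lapply(blocks, `[[`, "fluor"))
    t_max <- asinh(RAW_SCALE_MAX / cofactor)
    fluor[fluor < 0] <- 0
    fluor[fluor > t_max] <- t_max
    raw_fluor <- sinh(fluor) * cofactor
    scatter <- cbind(
      unlist(lapply(blocks, `[[`, "fsc_a")),
      unlist(lapply(blocks, `[[`, "fsc_h")),
      unlist(lapply(blocks, `[[`, "ssc_a"))
    )
    scatter[scatter < 0] <- 0
    scatter[scatter > RAW_SCALE_MAX] <- RAW_SCALE_MAX
    values <- cbind(scatter, raw_fluor)
    ord <- sample.int(nrow(values))
    values <- values[ord, , drop = FALSE]
    labels <- labels[ord]
  })
  panel <- pidot_panel()
  colnames(values) <- panel_channels(panel)
  list(events = event_matrix(values, panel, meta, scale = "raw"),
       labels = labels,
       fractions = fracs)
}

.apply_fraction_overrides <- function(registry, fracs, overrides) {
  for (id in names(overrides)) {
    target <- overrides[[id]]
    if (id %in% names(fracs)) {
      fracs[id] <- target
    } else if (id %in% names(registry$populations)) {
      desc <- .terminal_descendants(registry, id)
      cur <- sum(fracs[desc])
      fracs[desc] <- fracs[desc] * target / cur
    } else {
      stop("fraction override for unknown population '", id, "'",
           call. = FALSE)
    }
  }
  fracs
}

.terminal_descendants <- function(registry, id) {
  kids <- registry_children(registry, id)
  if (!length(kids)) return(id)
  unlist(lapply(kids, .terminal_descendants, registry = registry))
}

#' Simulate a cohort of healthy-donor-like samples
#'
#' Per-sample seeds are drawn (without replacement) from the master seed, so
#' samples are independent yet the whole cohort is reproducible.
#'
#' @inheritParams simulate_sample
#' @param n_samples Number of samples.
#' @param ages,wbc Numeric vectors of length `n_samples`: ages in years and
#'   WBC counts per uL.
#' @param n_events Events per sample (scalar or vector).
#' @param groups Group label(s), recycled.
#' @param sample_ids Optional ids; default `S001`, `S002`, ...
#' @return List of per-sample lists as returned by [simulate_sample()], each
#'   with its `meta` accessible as `$events$meta`.
#' @export
simulate_cohort <- function(registry, bm, n_samples, ages, wbc, seed,
                            n_events = 1e5, groups = "HD",
                            sample_ids = NULL, ...) {
  if (length(ages) != n_samples || length(wbc) != n_samples)
    stop("ages and wbc must each have length n_samples", call. = FALSE)
  groups <- rep_len(groups, n_samples)
  n_events <- rep_len(n_events, n_samples)
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
  sub_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max, n_samples))
  lapply(seq_len(n_samples), function(i) {
    meta <- sample_meta(sample_ids[i], ages[i], wbc[i], groups[i])
    simulate_sample(registry, bm, meta, n_events[i], sub_seeds[i], ...)
  })
}

#' Ground-truth population counts of a simulated sample
#'
#' Aggregates per-event ground-truth labels into the same count table shape
#' the gating engines report: events, percentage of white blood cells, and
#' the dual-platform absolute count per uL. Parent populations are sums of
#' their terminal descendants; the WBC denominator is all non-doublet,
#' non-debris events.
#'
#' @param labels Character vector of per-event truth labels.
#' @param meta A [sample_meta].
#' @param registry A [population_registry].
#' @return Data frame with columns `population`, `events`, `pct_wbc`,
#'   `abs_per_ul`.
#' @export
truth_counts <- function(labels, meta, registry = pidot_registry()) {
  n_wbc <- sum(!labels %in% c("doublet", "debris"))
  tab <- table(labels)
  pops <- names(registry$populations)
  ev <- vapply(pops, function(id) {
    desc <- .terminal_descendants(registry, id)
    sum(tab[intersect(desc, names(tab))])
  }, 0)
  pct <- 100 * ev / n_wbc
  data.frame(population = pops,
             events = unname(ev),
             pct_wbc = unname(pct),
             abs_per_ul = unname(pct * meta$wbc_per_ul / 100),
             row.names = NULL, stringsAsFactors = FALSE)
}
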