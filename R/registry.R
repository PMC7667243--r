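#' Band model for marker expression levels
#'
#' The generator realizes the four qualitative expression levels used in
#' clinical immunophenotyping (negative, low, positive, high) as Gaussian
#' bands on the asinh-transformed scale. Defaults place the band means at
#' 0 / 1.5 / 3.0 / 4.5 with a common standard deviation of 0.35, i.e.
#' adjacent bands are separated by more than 3 sd; weak-separation regimes
#' are produced by raising `sd`, not by new code paths.
#'
#' @param means Named increasing numeric vector with names
#'   `neg`, `lo`, `pos`, `hi` (transformed units).
#' @param sd Common band standard deviation (> 0, transformed units).
#' @return An object of class `band_model`.
#' @export
band_model <- function(means = c(neg = 0, lo = 1.5, pos = 3.0, hi = 4.5),
                       sd = 0.35) {
  if (!is.numeric(means) || length(means) != 4L ||
      !identical(names(means), c("neg", "lo", "pos", "hi")))
    stop("means must be a numeric vector named neg, lo, pos, hi",
         call. = FALSE)
  if (any(diff(means) <= 0))
    stop("band means must be strictly increasing", call. = FALSE)
  if (!is.numeric(sd) || length(sd) != 1L || sd <= 0)
    stop("band sd must be a positive number", call. = FALSE)
  structure(list(means = means, sd = sd), class = "band_model")
}

#' Population template registry
#'
#' The registry describes every population the pipeline knows about: the
#' gating hierarchy (parents), a per-marker band level for each terminal
#' population, light-scatter location, and a plausible healthy-donor
#' frequency window (`fraction_range`, fractions of all white blood cells)
#' from which the simulator draws. The shipped registry holds the full
#' PIDOT lymphoid hierarchy (17 terminal lymphoid populations under
#' B / T / NK parents) plus the nuisance classes `other_leukocyte` and
#' `debris`; `doublet` is synthesized by the simulator rather than
#' templated.
#'
#' @param path YAML registry file; defaults to the shipped registry.
#' @return An object of class `population_registry`: a list with elements
#'   `markers`, `populations` (named list of templates), `scatter_sd`.
#' @export
population_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "population_registry.yaml",
                        package = "pidotgate")
  raw <- yaml::read_yaml(path)
  markers <- unlist(raw$markers)
  pops <- stats::setNames(raw$populations,
                          vapply(raw$populations, `[[`, "", "id"))
  reg <- structure(list(markers = markers, populations = pops,
                        scatter_sd = raw$scatter_sd),
                   class = "population_registry")
  .validate_registry(reg)
  reg
}

.validate_registry <- function(reg) {
  ids <- names(reg$populations)
  for (p in reg$populations) {
    if (!is.null(p$parent) && !p$parent %in% ids)
      stop("registry: parent '", p$parent, "' of '", p$id, "' is unknown",
           call. = FALSE)
    if (.is_terminal(reg, p$id) && !p$id %in% c("other_leukocyte", "debris")) {
      if (is.null(p$bands) || !all(reg$markers %in% names(p$bands)))
        stop("registry: terminal population '", p$id,
             "' must define a band level for every marker", call. = FALSE)
      if (!all(unlist(p$bands) %in% c("neg", "lo", "pos", "hi")))
        stop("registry: invalid band level in '", p$id, "'", call. = FALSE)
      fr <- p$fraction_range
      if (is.null(fr) || length(fr) != 2L || fr[[1]] >= fr[[2]] || fr[[1]] <= 0)
        stop("registry: terminal population '", p$id,
             "' needs a fraction_range with 0 < low < high", call. = FALSE)
    }
  }
  lo <- sum(vapply(registry_terminals(reg, lymphoid = TRUE),
                   function(id) reg$populations[[id]]$fraction_range[[2]], 0))
  if (lo >= 1)
    stop("registry: lymphoid fraction_range maxima sum to >= 1; no room ",
         "for other leukocytes", call. = FALSE)
  invisible(reg)
}

#' Default shipped registry
#' @rdname population_registry
#' @export
pidot_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- population_registry()
    cache
  }
})

.is_terminal <- function(reg, id) {
  !id %in% vapply(reg$populations, function(p) p$parent %||% "", "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Registry accessors
#'
#' `registry_terminals()` lists terminal population ids (optionally lymphoid
#' ones only, i.e. excluding nuisance classes); `registry_children()` lists
#' the direct children of a parent; `registry_ancestors()` returns the
#' parent chain of a population from its immediate parent upward;
#' `population_label()` maps ids to display labels.
#'
#' @param reg A [population_registry].
#' @param lymphoid If `TRUE`, exclude the nuisance classes.
#' @export
registry_terminals <- function(reg, lymphoid = FALSE) {
  ids <- names(reg$populations)
  term <- ids[vapply(ids, function(id) .is_terminal(reg, id), TRUE)]
  if (lymphoid)
    term <- setdiff(term, c("other_leukocyte", "debris", "doublet"))
  term
}

#' @rdname registry_terminals
#' @param id Population id.
#' @export
registry_children <- function(reg, id) {
  ids <- names(reg$populations)
  ids[vapply(reg$populations, function(p) identical(p$parent, id), TRUE)]
}

#' @rdname registry_terminals
#' @export
registry_ancestors <- function(reg, id) {
  out <- character()
  p <- reg$populations[[id]]$parent
  while (!is.null(p)) {
    out <- c(out, p)
    p <- reg$populations[[p]]$parent
  }
  out
}

#' @rdname registry_terminals
#' @export
population_label <- function(reg, id) {
  vapply(id, function(i) reg$populations[[i]]$label %||% i, "")
}

#' Populations entering the paired MG / AG&I comparison
#'
#' The 20 lymphoid populations reported in the method comparison: the five
#' major populations (total lymphocytes, B-cells, T-cells, CD4+ and CD8+
#' T-cells) and their reported subsets. CD4+CD8+ double-positive T-cells and
#' IgD+IgM- post-GC B-cells are gated but excluded from the paired
#' comparison, because the automated module does not report the former as a
#' separate population.
#'
#' @return Character vector of population ids.
#' @export
comparison_populations <- function() {
  c("lymphocytes", "b_cells", "pre_gc_b", "unswitched_mbc_pc",
    "switched_mbc_pc", "t_cells", "cd4_t", "cd4_naive", "cd4_cm",
    "cd4_em", "cd4_td", "cd8_t", "cd8_naive", "cd8_cm", "cd8_em",
    "cd8_td27pos", "cd8_td27neg", "dn_t", "tcr_gd_t", "nk_cells")
}
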