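#' Gating hierarchy for the manual gating strategy
#'
#' A gate tree is the Boolean gating hierarchy: each node names a population
#' and constrains a subset of markers to allowed band levels; an event
#' belongs to a node when it satisfies all of the node's constraints given
#' its parent. Sibling predicates must be mutually exclusive; events under a
#' parent that match no sibling fall into an explicit
#' `unclassified_<parent>` bucket rather than being silently forced into the
#' nearest gate.
#'
#' The superscript notation of published gating tables maps onto allowed
#' band sets as: `-` = neg; `lo` = lo; `+` = pos or hi; `hi` = hi;
#' `- to lo` = neg or lo; `lo to +` = lo, pos or hi; `- to +` = neg, lo or
#' pos.
#'
#' @param nodes Named list; each element has `parent` (id or `NULL` for the
#'   single root) and `bands` (named list marker -> character vector of
#'   allowed levels from `neg, lo, pos, hi`; empty for the root whose gate
#'   is scatter plus CD45).
#' @return An object of class `gate_tree`.
#' @export
gate_tree <- function(nodes) {
  stopifnot(is.list(nodes), !is.null(names(nodes)))
  roots <- names(nodes)[vapply(nodes, function(n) is.null(n$parent), TRUE)]
  if (length(roots) != 1L)
    stop("a gate tree must have exactly one root, found ",
         length(roots), call. = FALSE)
  for (id in names(nodes)) {
    n <- nodes[[id]]
    if (!is.null(n$parent) && !n$parent %in% names(nodes))
      stop("node '", id, "' has unknown parent '", n$parent, "'",
           call. = FALSE)
    for (m in names(n$bands))
      if (!all(n$bands[[m]] %in% BAND_LEVELS))
        stop("node '", id, "' has invalid band level for marker '", m, "'",
             call. = FALSE)
  }
  # acyclicity: every node must reach the root
  for (id in names(nodes)) {
    seen <- character(); p <- nodes[[id]]$parent
    while (!is.null(p)) {
      if (p %in% seen) stop("gate tree contains a cycle at '", p, "'",
                            call. = FALSE)
      seen <- c(seen, p); p <- nodes[[p]]$parent
    }
  }
  # sibling mutual exclusivity: two conjunctive band predicates overlap iff
  # their allowed sets intersect on every marker (unconstrained = all)
  for (id in names(nodes)) {
    kids <- names(nodes)[vapply(nodes, function(n) identical(n$parent, id),
                                TRUE)]
    if (length(kids) < 2) next
    for (i in seq_along(kids)) for (j in seq_len(i - 1L)) {
      a <- nodes[[kids[i]]]$bands; b <- nodes[[kids[j]]]$bands
      overlap <- TRUE
      for (m in union(names(a), names(b))) {
        sa <- a[[m]] %||% BAND_LEVELS
        sb <- b[[m]] %||% BAND_LEVELS
        if (!length(intersect(sa, sb))) { overlap <- FALSE; break }
      }
      if (overlap)
        stop("sibling gates '", kids[i], "' and '", kids[j],
             "' are not mutually exclusive", call. = FALSE)
    }
  }
  structure(list(nodes = nodes, root = roots), class = "gate_tree")
}

#' @rdname gate_tree
#' @export
pidot_gate_tree <- function() {
  plus <- c("pos", "hi"); minus <- "neg"
  neg_lo <- c("neg", "lo"); lo_plus <- c("lo", "pos", "hi")
  gate_tree(list(
    lymphocytes = list(parent = NULL, bands = list(CD45 = "hi")),
    b_cells = list(parent = "lymphocytes",
                   bands = list(CD19 = plus, CD3 = minus, CD45RA = plus)),
    pre_gc_b = list(parent = "b_cells",
                    bands = list(CD27 = minus, IgD = plus, IgM = plus)),
    unswitched_mbc_pc = list(parent = "b_cells",
                             bands = list(IgD = plus, IgM = plus,
                                          CD27 = plus)),
    switched_mbc_pc = list(parent = "b_cells",
                           bands = list(IgD = minus, IgM = minus,
                                        CD27 = c("neg", "lo", "pos"))),
    igd_only_post_gc = list(parent = "b_cells",
                            bands = list(IgD = plus, IgM = minus,
                                         CD27 = plus)),
    t_cells = list(parent = "lymphocytes",
                   bands = list(CD3 = plus, CD19 = minus,
                                `CD16&CD56` = neg_lo)),
    tcr_gd_t = list(parent = "t_cells",
                    bands = list(TCRgd = plus, CD4 = minus, CD8 = neg_lo)),
    dn_t = list(parent = "t_cells",
                bands = list(TCRgd = minus, CD4 = minus, CD8 = neg_lo)),
    cd4_t = list(parent = "t_cells",
                 bands = list(TCRgd = minus, CD4 = plus, CD8 = minus)),
    cd4_naive = list(parent = "cd4_t",
                     bands = list(CD27 = plus, CD45RA = plus)),
    cd4_cm = list(parent = "cd4_t",
                  bands = list(CD27 = plus, CD45RA = minus)),
    cd4_em = list(parent = "cd4_t",
                  bands = list(CD27 = minus, CD45RA = minus)),
    cd4_td = list(parent = "cd4_t",
                  bands = list(CD27 = minus, CD45RA = plus)),
    cd8_t = list(parent = "t_cells",
                 bands = list(TCRgd = minus, CD4 = minus, CD8 = plus)),
    cd8_naive = list(parent = "cd8_t",
                     bands = list(CD27 = plus, CD45RA = plus)),
    cd8_cm = list(parent = "cd8_t",
                  bands = list(CD27 = plus, CD45RA = minus)),
    cd8_em = list(parent = "cd8_t",
                  bands = list(CD27 = minus, CD45RA = minus)),
    cd8_td27pos = list(parent = "cd8_t",
                       bands = list(CD27 = "lo", CD45RA = plus)),
    cd8_td27neg = list(parent = "cd8_t",
                       bands = list(CD27 = minus, CD45RA = plus)),
    dp_t = list(parent = "t_cells",
                bands = list(TCRgd = minus, CD4 = plus, CD8 = plus)),
    nk_cells = list(parent = "lymphocytes",
                    bands = list(CD19 = minus, CD3 = minus,
                                 `CD16&CD56` = "hi", CD45RA = lo_plus))
  ))
}

#' @rdname gate_tree
#' @param tree A `gate_tree`.
#' @param id Node id.
#' @export
tree_children <- function(tree, id) {
  names(tree$nodes)[vapply(tree$nodes,
                           function(n) identical(n$parent, id), TRUE)]
}

#' @rdname gate_tree
#' @export
tree_descendants <- function(tree, id) {
  kids <- tree_children(tree, id)
  c(id, unlist(lapply(kids, tree_descendants, tree = tree)))
}
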