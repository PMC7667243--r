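test_that("doublet exclusion removes labeled doublets and spares singlets", {
  s <- fix_sample()
  keep <- exclude_doublets(s$events, tolerance = 0.25)
  dbl <- s$labels == "doublet"
  expect_gte(sum(!keep & dbl) / sum(dbl), 0.99)
  expect_lte(sum(!keep & !dbl) / sum(!dbl), 0.01)
  # a sample without doublets is nearly untouched
  reg <- fix_registry(); bm <- fix_band_model()
  clean <- simulate_sample(reg, bm, fix_meta(), 5000, seed = 3,
                           doublet_rate = 0)
  expect_gte(mean(exclude_doublets(clean$events, 0.25)), 0.99)
})

test_that("tolerance 0 keeps only events exactly at the median ratio", {
  panel <- pidot_panel()
  v <- matrix(0, 5, 14, dimnames = list(NULL, panel_channels(panel)))
  v[, "FSC-A"] <- c(100, 100, 100, 100, 100)
  v[, "FSC-H"] <- c(98, 98, 98, 50, 120)
  ev <- event_matrix(v, panel, fix_meta())
  keep <- exclude_doublets(ev, tolerance = 0)
  expect_identical(as.vector(keep), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # zero FSC-A events are excluded and tallied
  v[1, "FSC-A"] <- 0
  keep2 <- exclude_doublets(event_matrix(v, panel, fix_meta()), 0.25)
  expect_false(keep2[1])
  expect_identical(attr(keep2, "zero_fsc_excluded"), 1L)
})

test_that("the lymphocyte gate keeps lymphoid templates and drops debris", {
  s <- fix_sample()
  tr <- transform_fluorescence(s$events)
  mask <- gate_lymphocytes(tr, pidot_thresholds())
  lymph <- !s$labels %in% c("doublet", "debris", "other_leukocyte")
  # doublets carry lymphoid marker profiles, so judge on singlets only
  singlet <- s$labels != "doublet"
  expect_gte(sum(mask & lymph) / sum(lymph), 0.99)
  expect_lte(sum(mask[s$labels == "debris"]) / sum(s$labels == "debris"),
             0.01)
  expect_lte(sum(mask[s$labels == "other_leukocyte"]) /
               sum(s$labels == "other_leukocyte"), 0.01)
  expect_error(gate_lymphocytes(s$events, pidot_thresholds()), "transformed")
})

test_that("band predicates reproduce the published gating table rows", {
  ev <- make_band_events(list(
    band_vec(CD45 = "hi", CD19 = "pos", CD3 = "neg", CD45RA = "pos",
             CD27 = "neg", IgD = "pos", IgM = "pos"),
    band_vec(CD45 = "hi", CD3 = "pos", TCRgd = "pos", CD4 = "neg",
             CD8 = "lo"),
    band_vec(CD45 = "hi", CD3 = "pos", CD8 = "pos", CD27 = "lo",
             CD45RA = "pos"),
    band_vec(CD45 = "hi", CD19 = "neg", CD3 = "neg", `CD16&CD56` = "hi",
             CD45RA = "lo"),
    band_vec(CD45 = "hi", CD3 = "pos", CD4 = "pos", CD8 = "pos"),
    band_vec(CD45 = "hi", CD3 = "pos", CD4 = "pos", CD27 = "pos",
             CD45RA = "neg")))
  res <- classify_events(ev, pidot_gate_tree(), pidot_thresholds())
  expect_identical(res$labels,
                   c("pre_gc_b", "tcr_gd_t", "cd8_td27pos", "nk_cells",
                     "dp_t", "cd4_cm"))
})

test_that("events matching no sibling predicate land in an explicit bucket", {
  # CD4+ with CD8 lo matches neither the CD4 nor the double-positive gate
  ev <- make_band_events(list(
    band_vec(CD45 = "hi", CD3 = "pos", CD4 = "pos", CD8 = "lo"),
    band_vec(CD45 = "hi", CD3 = "pos", CD4 = "pos", CD8 = "neg",
             CD27 = "lo", CD45RA = "pos")))
  res <- classify_events(ev, pidot_gate_tree(), pidot_thresholds())
  expect_identical(res$labels,
                   c("unclassified_t_cells", "unclassified_cd4_t"))
})

test_that("labels partition every event and counts nest exactly", {
  s <- fix_sample()
  gg <- manual_gate(s$events)
  res <- gg$result; counts <- gg$counts
  expect_equal(sum(table(res$labels)), n_events(s$events),
               ignore_attr = TRUE)
  cnt <- function(p) counts$events[counts$population == p]
  tree <- pidot_gate_tree()
  for (parent in names(tree$nodes)) {
    kids <- tree_children(tree, parent)
    if (!length(kids)) next
    uncl <- counts$events[counts$population ==
                            paste0("unclassified_", parent)]
    if (!length(uncl)) uncl <- 0
    expect_equal(cnt(parent),
                 sum(vapply(kids, cnt, 0)) + uncl, label = parent)
  }
  # absolute counts conserve through the hierarchy to 1e-9
  abs_of <- function(p) counts$abs_per_ul[counts$population == p]
  kids_t <- tree_children(tree, "t_cells")
  uncl_t <- counts$abs_per_ul[counts$population == "unclassified_t_cells"]
  if (!length(uncl_t)) uncl_t <- 0
  expect_equal(abs_of("t_cells"),
               sum(vapply(kids_t, abs_of, 0)) + uncl_t, tolerance = 1e-9)
})

test_that("the dual-platform count formula is exact", {
  # 10% of WBC at WBC = 6000/uL -> 600 cells/uL
  labels <- c(rep("nk_cells", 100), rep("other_leukocyte", 900),
              rep("debris", 50))
  res <- fake_gating_result(labels)
  counts <- population_counts(res, fix_meta(wbc = 6000))
  nk <- counts[counts$population == "nk_cells", ]
  expect_equal(nk$pct_wbc, 10)
  expect_equal(nk$abs_per_ul, 600)
  # empty populations report 0.0 cells/uL
  expect_equal(counts$abs_per_ul[counts$population == "cd4_naive"], 0)
  # doublets and debris do not represent white cells
  expect_true(is.na(counts$pct_wbc[counts$population == "debris"]))
})

test_that("gating is deterministic and invariant to event order", {
  s <- fix_sample()
  tr <- transform_fluorescence(s$events)
  r1 <- classify_events(tr, pidot_gate_tree(), pidot_thresholds())
  perm <- withr::with_seed(99, sample.int(n_events(s$events)))
  ev2 <- event_matrix(tr$values[perm, ], tr$panel, tr$meta,
                      scale = "transformed", cofactor = tr$cofactor)
  r2 <- classify_events(ev2, pidot_gate_tree(), pidot_thresholds())
  expect_identical(r1$labels[perm], r2$labels)
})

test_that("raising the CD27 lo|pos cut never grows the unswitched count", {
  s <- fix_sample()
  tr <- transform_fluorescence(s$events)
  thr <- pidot_thresholds()
  prev <- Inf
  for (cut in c(1.8, 2.0, 2.2, 2.6, 3.0)) {
    thr$cuts$CD27[2] <- cut
    cc <- population_counts(
      classify_events(tr, pidot_gate_tree(), thr), fix_meta())
    cur <- cc$events[cc$population == "unswitched_mbc_pc"]
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("gate tree validation rejects malformed hierarchies", {
  expect_error(gate_tree(list(
    a = list(parent = NULL, bands = list()),
    b = list(parent = NULL, bands = list()))), "exactly one root")
  expect_error(gate_tree(list(
    root = list(parent = NULL, bands = list()),
    x = list(parent = "root", bands = list(CD4 = c("pos", "hi"))),
    y = list(parent = "root", bands = list(CD4 = c("hi"))))),
    "not mutually exclusive")
  expect_error(gate_tree(list(
    root = list(parent = NULL, bands = list()),
    x = list(parent = "zzz", bands = list()))), "unknown parent")
})
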