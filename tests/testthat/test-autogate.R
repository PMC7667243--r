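test_that("the reference database pools labeled events correctly", {
  db <- fix_db()
  # 16 lymphoid terminals (no CD4+CD8+) plus the leukocyte background
  expect_length(db$populations, 17L)
  expect_false("dp_t" %in% names(db$populations))
  expect_true(all(c("cd8_td27pos", "igd_only_post_gc",
                    "other_leukocyte") %in% names(db$populations)))
  # population mean equals the direct average of its training events
  reg <- fix_registry(); bm <- fix_band_model()
  train <- simulate_cohort(reg, bm, 10, ages = rep(35, 10),
                           wbc = rep(6000, 10), seed = 7, n_events = 5e4,
                           sample_ids = sprintf("TR%02d", 1:10))
  pooled <- do.call(rbind, lapply(train, function(s) {
    tr <- transform_fluorescence(s$events)
    tr$values[s$labels == "nk_cells",
              c(panel_markers(pidot_panel()), "FSC-A", "SSC-A")]
  }))
  expect_equal(db$populations$nk_cells$mean, colMeans(pooled),
               tolerance = 1e-9)
  expect_identical(db$populations$nk_cells$n, nrow(pooled))
  # covariances are symmetric positive definite
  for (p in names(db$populations)) {
    ev <- eigen(db$populations[[p]]$cov, symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("full shrinkage gives a diagonal covariance and errors are caught", {
  reg <- fix_registry(); bm <- fix_band_model()
  small <- simulate_cohort(reg, bm, 10, ages = rep(35, 10),
                           wbc = rep(6000, 10), seed = 17, n_events = 2e4,
                           sample_ids = sprintf("SM%02d", 1:10))
  db1 <- build_database(small, lambda = 1)
  cv <- db1$populations$cd4_naive$cov
  expect_equal(cv, diag(diag(cv)), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(build_database(small[1:5]), "at least 10")
  # sparse populations below the event floor are listed in the error
  tiny <- simulate_cohort(reg, bm, 10, ages = rep(35, 10),
                          wbc = rep(6000, 10), seed = 18, n_events = 1500,
                          sample_ids = sprintf("TY%02d", 1:10))
  expect_error(build_database(tiny), "igd_only_post_gc")
})

test_that("clustering is deterministic, respects k, and separates blobs", {
  panel <- pidot_panel()
  withr::with_seed(12, {
    a <- matrix(rnorm(600 * 14, 0, 0.3), 600, 14)
    b <- matrix(rnorm(400 * 14, 4, 0.3), 400, 14)
  })
  v <- abs(rbind(a, b))
  colnames(v) <- panel_channels(panel)
  ev <- event_matrix(v, panel, fix_meta(), scale = "transformed",
                     cofactor = 150)
  cl1 <- cluster_events(ev, k = 10, seed = 4)
  cl2 <- cluster_events(ev, k = 10, seed = 4)
  expect_identical(as.integer(cl1), as.integer(cl2))
  truth <- rep(c("a", "b"), c(600, 400))
  for (g in unique(cl1)) {
    mix <- table(truth[cl1 == g])
    contamination <- if (length(mix) < 2L) 0 else min(mix) / sum(mix)
    expect_lt(contamination, 0.05)
  }
  expect_identical(unique(as.integer(cluster_events(ev, k = 1, seed = 1))), 1L)
  expect_error(cluster_events(ev, k = 2000, seed = 1), "exceeds")
})

test_that("cluster classification assigns by Mahalanobis distance with a chi-squared cutoff", {
  # hand-built database: two spherical populations 10 units apart
  chans <- c(panel_markers(pidot_panel()), "FSC-A", "SSC-A")
  d <- length(chans)
  mk_pop <- function(center, n) list(
    mean = stats::setNames(rep(center, d), chans),
    cov = diag(d), n = n)
  db <- structure(list(populations = list(alpha = mk_pop(0, 500),
                                          beta = mk_pop(10, 1000)),
                       channels = chans, panel_version = "pidot-v1",
                       lambda = 0, seed = 0L, n_samples = 10,
                       train_ids = sprintf("x%d", 1:10)),
                  class = "reference_database")
  mk_clusters <- function(centers, sizes) {
    cl <- rep(seq_along(sizes), sizes)
    attr(cl, "centers") <- centers
    attr(cl, "sizes") <- sizes
    cl
  }
  centers <- rbind(rep(0, d),      # exactly at alpha -> distance 0
                   rep(10, d),     # exactly at beta
                   rep(5, d))      # equidistant, far from both -> check
  colnames(centers) <- chans
  asg <- classify_clusters(mk_clusters(centers, c(50L, 60L, 10L)), db,
                           cutoff_quantile = 0.999)
  expect_identical(asg$population[1:2], c("alpha", "beta"))
  expect_equal(asg$distance[1], 0)
  # third centroid: squared distance 25 * 13 to both >> chi-squared cutoff
  expect_true(is.na(asg$population[3]))
  cand <- attr(asg, "candidates")[[3]]
  expect_lte(nrow(cand), 3L)
  expect_identical(cand$distance, sort(cand$distance))
  # equidistant tie at an assignable distance: larger training count wins
  db2 <- db
  db2$populations$beta$mean <- stats::setNames(c(6, rep(0, d - 1)), chans)
  mid <- matrix(c(3, rep(0, d - 1)), 1, dimnames = list(NULL, chans))
  asg2 <- classify_clusters(mk_clusters(mid, 20L), db2, 0.999)
  expect_equal(asg2$distance[1], 9)
  expect_identical(asg2$population[1], "beta")  # n = 1000 beats n = 500
})

test_that("expert resolution of checks is constrained and conserves events", {
  s <- fix_sample()
  rep0 <- auto_gate(s$events, fix_db(), ranges = fix_ranges(), seed = 2)
  asg <- attr(rep0, "assignments")
  expect_identical(resolve_checks(asg, list()), asg)
  auto_idx <- which(!is.na(asg$population))[1]
  expect_error(resolve_checks(asg, stats::setNames(list("nk_cells"),
                                                   auto_idx)),
               "assigned automatically")
  chk <- which(is.na(asg$population) & !asg$discarded)
  if (length(chk)) {
    res <- resolve_checks(asg, stats::setNames(list("tcr_gd_t"), chk[1]))
    expect_identical(res$population[chk[1]], "tcr_gd_t")
    expect_true(res$expert_resolved[chk[1]])
    # discarding keeps the partition through the excluded bucket
    res2 <- resolve_checks(asg, stats::setNames(list("discard"), chk[1]))
    rep2 <- autogate_report(res2, s$events$meta, fix_ranges())
    expect_identical(rep2$n_excluded, asg$size[chk[1]])
    expect_equal(rep2$n_events, sum(asg$size))
  }
})

test_that("reports flag out-of-range counts as remarks", {
  s <- fix_sample()
  rng <- fix_ranges()
  rep0 <- auto_gate(s$events, fix_db(), ranges = rng, seed = 2)
  tab <- rep0$table
  expect_identical(tab$remark, !is.na(tab$status) & tab$status != "in_range")
  # an unaberrated healthy sample leaves almost all lymphoid events assigned
  expect_lt(rep0$checks_fraction, 0.01)
  # squeezing the interval from above forces an above_p95 remark
  rng2 <- rng
  i <- rng2$population == "nk_cells"
  nk <- tab$abs_per_ul[tab$population == "nk_cells"]
  rng2$p95[i] <- nk * 0.9
  rng2$p5[i] <- nk * 0.1
  rep1 <- autogate_report(attr(rep0, "assignments"), s$events$meta, rng2)
  expect_identical(rep1$table$status[rep1$table$population == "nk_cells"],
                   "above_p95")
  expect_true(rep1$table$remark[rep1$table$population == "nk_cells"])
  # below p5
  rng2$p5[i] <- nk * 2; rng2$p95[i] <- nk * 3
  rep2 <- autogate_report(attr(rep0, "assignments"), s$events$meta, rng2)
  expect_identical(rep2$table$status[rep2$table$population == "nk_cells"],
                   "below_p5")
})

test_that("the automated pipeline is deterministic given its seed", {
  s <- fix_sample()
  r1 <- auto_gate(s$events, fix_db(), ranges = fix_ranges(), seed = 6)
  r2 <- auto_gate(s$events, fix_db(), ranges = fix_ranges(), seed = 6)
  expect_identical(r1$table, r2$table)
  expect_identical(attr(r1, "event_clusters"), attr(r2, "event_clusters"))
})
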