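# Shared fixtures, built lazily and cached for the whole test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

fix_registry <- function() fixture("registry", pidot_registry)
fix_band_model <- function() fixture("band_model", band_model)

fix_meta <- function(id = "FX1", age = 35, wbc = 6000, group = "HD") {
  sample_meta(id, age, wbc, group)
}

# one mid-size healthy-donor sample shared by several files
fix_sample <- function() {
  fixture("sample_2e4", function()
    simulate_sample(fix_registry(), fix_band_model(), fix_meta(),
                    n_events = 2e4, seed = 101))
}

# training cohort + database (shared by autogate and acceptance tests)
fix_db <- function() {
  fixture("db", function() {
    train <- simulate_cohort(fix_registry(), fix_band_model(), 10,
                             ages = rep(35, 10), wbc = rep(6000, 10),
                             seed = 7, n_events = 5e4,
                             sample_ids = sprintf("TR%02d", 1:10))
    build_database(train)
  })
}

# adult reference ranges from a 30-sample truth-only cohort (unit tests);
# the acceptance calibration test derives its own 250-sample ranges
fix_ranges <- function() {
  fixture("ranges", function() {
    rc <- simulate_cohort(fix_registry(), fix_band_model(), 30,
                          ages = withr::with_seed(3, runif(30, 20, 60)),
                          wbc = withr::with_seed(4, runif(30, 4500, 10000)),
                          seed = 11, n_events = 2e4,
                          sample_ids = sprintf("RC%03d", 1:30))
    derive_reference_ranges(rc, age_bins = c(18, 65))
  })
}

# build a transformed event_matrix directly from band levels: one row per
# entry of `level_list` (a list of named character vectors marker -> level)
make_band_events <- function(level_list, bm = fix_band_model(),
                             fsc_a = 55000, ssc_a = 12000,
                             meta = fix_meta("MB1")) {
  panel <- pidot_panel()
  markers <- panel_markers(panel)
  rows <- t(vapply(level_list, function(lv) {
    out <- bm$means[lv[markers]]
    unname(out)
  }, numeric(length(markers))))
  values <- cbind(`FSC-A` = fsc_a, `FSC-H` = 0.98 * fsc_a, `SSC-A` = ssc_a,
                  rows)
  colnames(values) <- panel_channels(panel)
  event_matrix(values, panel, meta, scale = "transformed", cofactor = 150)
}

# named band vector covering all 11 markers, defaulting to neg
band_vec <- function(...) {
  lv <- rep("neg", 11)
  names(lv) <- panel_markers(pidot_panel())
  over <- c(...)
  lv[names(over)] <- over
  lv
}

# construct a gating_result by hand from a label vector (for count-table
# formula tests)
fake_gating_result <- function(labels) {
  structure(list(labels = labels, tree = pidot_gate_tree(),
                 thresholds = pidot_thresholds(), n = length(labels),
                 zero_fsc_excluded = 0L),
            class = "gating_result")
}
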