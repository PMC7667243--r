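test_that("percent difference follows the MG-referenced formula and conventions", {
  expect_equal(percent_difference(100, 80), 20)
  expect_equal(percent_difference(100, 120), -20)
  for (x in c(1, 57.3, 4000)) expect_equal(percent_difference(x, x), 0)
  expect_equal(percent_difference(0, 0), 0)
  expect_true(is.na(percent_difference(0, 5)))
  expect_false(is_equivalent(percent_difference(0, 5)))
  expect_error(percent_difference(-1, 5), "non-negative")
  # strict 20% criterion
  expect_true(is_equivalent(19.999))
  expect_false(is_equivalent(20))
  expect_true(is_equivalent(-19.999))
})

test_that("replicate CV matches the hand-computed sample-SD oracle", {
  m <- matrix(c(1, 1, 1, 1, 1), 1, dimnames = list("p", NULL))
  expect_equal(reproducibility(m)$cv_pct, 0)
  m2 <- matrix(c(2, 4), 1, dimnames = list("p", NULL))
  expect_equal(reproducibility(m2)$cv_pct, sqrt(2) / 3 * 100)
  expect_equal(reproducibility(m2)$cv_pct, 47.14045, tolerance = 1e-6)
  # zero mean leaves the CV undefined
  m3 <- matrix(c(0, 0, 5, 7), 2, byrow = TRUE,
               dimnames = list(c("z", "p"), NULL))
  rv <- reproducibility(m3)
  expect_true(is.na(rv$cv_pct[rv$population == "z"]))
  # mismatched population sets error
  t1 <- data.frame(population = c("a", "b"), abs_per_ul = c(1, 2))
  t2 <- data.frame(population = c("a", "c"), abs_per_ul = c(1, 2))
  expect_error(reproducibility(list(t1, t2)), "different population")
})

test_that("spearman correlation matches a brute-force rank oracle with ties", {
  x <- 1:10
  expect_equal(spearman_rho(x, 2 * x + 1), 1)
  expect_equal(spearman_rho(x, rev(x)), -1)
  withr::with_seed(13, {
    a <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)   # contains ties
    b <- runif(10)
  })
  oracle <- function(x, y) {
    rx <- rank(x, ties.method = "average")
    ry <- rank(y, ties.method = "average")
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  expect_equal(spearman_rho(a, b), oracle(a, b), tolerance = 1e-12)
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
  expect_error(spearman_rho(1:2, 1:2), "length")
})

test_that("the variance-ratio F-test matches the F distribution oracle", {
  r <- variance_ratio_f_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$F, 1)
  expect_equal(r$p, 1)
  withr::with_seed(2, {
    a <- rnorm(11, sd = 2)
    b <- rnorm(11, sd = 1)
  })
  r2 <- variance_ratio_f_test(a, b)
  big <- max(var(a), var(b)); small <- min(var(a), var(b))
  expect_equal(r2$F, big / small)
  expect_equal(r2$p, min(1, 2 * pf(big / small, 10, 10, lower.tail = FALSE)))
  # var ratio exactly 4 with n = 11 each
  x <- withr::with_seed(30, scale(rnorm(11))[, 1])
  r3 <- variance_ratio_f_test(x * 2, x)
  expect_equal(r3$F, 4, tolerance = 1e-12)
  expect_equal(r3$p, 2 * pf(4, 10, 10, lower.tail = FALSE), tolerance = 1e-9)
  # degenerate cases are flagged
  r4 <- variance_ratio_f_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(r4$p, 1); expect_identical(r4$flag, "degenerate")
  r5 <- variance_ratio_f_test(c(1, 1, 1), c(1, 2, 3))
  expect_identical(r5$F, Inf); expect_equal(r5$p, 0)
})

test_that("Yates-corrected chi-squared matches hand computation", {
  r <- chi_square_yates(matrix(c(10, 20, 20, 10), 2))
  # all expected cells are 15; 4 * (5 - 0.5)^2 / 15 = 5.4
  expect_equal(r$chi2, 5.4, tolerance = 1e-12)
  expect_equal(unique(as.vector(r$expected)), 15)
  expect_equal(r$p, pchisq(5.4, 1, lower.tail = FALSE))
  # boundary O = E: only the half-count correction remains
  r2 <- chi_square_yates(matrix(c(15, 15, 15, 15), 2))
  expect_equal(r2$chi2, 4 * 0.25 / 15, tolerance = 1e-12)
  # transpose invariance for symmetric tables
  tab <- matrix(c(7, 3, 3, 7), 2)
  expect_equal(chi_square_yates(tab)$chi2, chi_square_yates(t(tab))$chi2)
  # agrees with the standard implementation away from the boundary
  tab2 <- matrix(c(12, 5, 9, 21), 2)
  expect_equal(chi_square_yates(tab2)$chi2,
               unname(suppressWarnings(
                 chisq.test(tab2, correct = TRUE)$statistic)),
               tolerance = 1e-12)
  expect_error(chi_square_yates(matrix(c(0, 0, 5, 5), 2)), "margins")
})

test_that("Bonferroni uses the strict inequality and clips adjusted p at 1", {
  r <- bonferroni_adjust(0.03, alpha = 0.05)
  expect_true(r$reject)
  expect_equal(r$adjusted, 0.03)
  # p = 0.01 with m = 5 at alpha 0.05: 0.01 < 0.01 is FALSE -> not rejected
  r2 <- bonferroni_adjust(c(0.01, 0.2, 0.001, 0.04, 0.9), alpha = 0.05)
  expect_false(r2$reject[1])
  expect_true(r2$reject[3])
  expect_equal(r2$adjusted[1], 0.05)
  withr::with_seed(6, p <- runif(12))
  r3 <- bonferroni_adjust(p)
  expect_equal(r3$adjusted, pmin(1, 12 * p))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("clinical relevance is a pure status-mismatch rule on an inclusive interval", {
  cr <- clinical_relevance(50, 150, 100, 200)
  expect_identical(cr$mg_status, "below_p5")
  expect_identical(cr$ag_status, "in_range")
  expect_true(cr$clinically_relevant)
  expect_false(clinical_relevance(150, 180, 100, 200)$clinically_relevant)
  expect_false(clinical_relevance(250, 300, 100, 200)$clinically_relevant)
  expect_true(clinical_relevance(50, 250, 100, 200)$clinically_relevant)
})

test_that("delta MFI reports raw-unit median differences antisymmetrically", {
  reg <- fix_registry(); bm <- fix_band_model()
  s <- fix_sample()
  d1 <- delta_mfi(s$events, s$labels, "unswitched_mbc_pc", "pre_gc_b", "CD27")
  d2 <- delta_mfi(s$events, s$labels, "pre_gc_b", "unswitched_mbc_pc", "CD27")
  expect_equal(d1, -d2)
  # generator bands pos (CD27 on unswitched) vs neg (pre-GC): the expected
  # gap is sinh(3)*150 - sinh(0)*150 in raw channel units
  gap <- sinh(3) * 150
  expect_lt(abs(d1 - gap) / gap, 0.05)
  expect_equal(delta_mfi(s$events, s$labels, "pre_gc_b", "pre_gc_b", "CD27"),
               0)
  expect_error(delta_mfi(s$events, s$labels, "pre_gc_b", "nope", "CD27"),
               "fewer than 10")
  # transformed input is inverted back to raw units
  tr <- transform_fluorescence(s$events)
  expect_equal(delta_mfi(tr, s$labels, "unswitched_mbc_pc", "pre_gc_b",
                         "CD27"), d1, tolerance = 1e-9)
})
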