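test_that("table rates are the direct count ratios", {
  r <- table_rates(diagnostic_table(90, 10, 5, 95))
  expect_equal(r$accuracy, 0.925)
  expect_equal(r$sensitivity, 0.90)
  expect_equal(r$fpr, 0.05)
  expect_equal(r$specificity, 0.95)
  expect_equal(r$ppv, 90 / 95)
  expect_equal(r$fnr, 0.10)
  expect_length(r$undefined, 0)
})

test_that("a diagonal partition has perfect rates", {
  r <- table_rates(diagnostic_table(37, 0, 0, 63))
  expect_equal(r$accuracy, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$ppv, 1)
})

test_that("rates with an empty margin are flagged undefined, not zero", {
  r <- table_rates(diagnostic_table(0, 0, 5, 95))
  expect_true(is.na(r$sensitivity))
  expect_true(is.na(r$fnr))
  expect_true(all(c("sensitivity", "fnr") %in% r$undefined))
  expect_equal(r$specificity, 0.95)
  expect_error(diagnostic_table(0, 0, 0, 0), "at least one")
  expect_error(diagnostic_table(-1, 0, 0, 5), "nonnegative")
})

test_that("accuracy decomposes as the margin-weighted rate average", {
  set.seed(11)
  for (i in 1:25) {
    cells <- rpois(4, lambda = c(40, 5, 5, 50)) + 1
    tab <- diagnostic_table(cells[1], cells[2], cells[3], cells[4])
    r <- table_rates(tab)
    expect_equal(r$accuracy,
                 r$sensitivity * (tab$n11 + tab$n12) / tab$n +
                   r$specificity * (tab$n21 + tab$n22) / tab$n)
  }
})

test_that("necessity/sufficiency classification tracks the off-diagonals", {
  expect_identical(classify_test(diagnostic_table(360, 0, 0, 640)),
                   "necessary_and_sufficient")
  expect_identical(classify_test(diagnostic_table(300, 0, 200, 500)),
                   "necessary_only")
  expect_identical(classify_test(diagnostic_table(100, 300, 0, 600)),
                   "sufficient_only")
  expect_identical(classify_test(diagnostic_table(100, 300, 200, 400)),
                   "neither")
  # tolerance is a fraction of the whole table
  expect_identical(classify_test(diagnostic_table(300, 5, 200, 495),
                                 tol = 0.01), "necessary_only")
  expect_error(classify_test(diagnostic_table(1, 0, 0, 1), tol = 0.5),
               "0.5")
})

test_that("iceberg correction rescales the perceived prevalence", {
  expect_equal(iceberg_true_prevalence(0.036, 0.9), 0.36)
  expect_equal(iceberg_true_prevalence(0.42, 0), 0.42)
  expect_equal(iceberg_true_prevalence(0.05, 0.5), 0.10)
  expect_error(iceberg_true_prevalence(0.3, 1), "< 1")
  expect_error(iceberg_true_prevalence(0.5, 0.9), "inconsistent")
  # round trip: hide a fraction u of cases, then correct
  for (p in seq(0, 1, by = 0.1))
    for (u in seq(0, 0.9, by = 0.1))
      expect_equal(iceberg_true_prevalence(p * (1 - u), u), p)
})

test_that("prevalence interval reproduces the worked bounds", {
  iv <- prevalence_interval(0.36, 0.3)
  expect_equal(iv[["upper"]], 0.36)
  expect_lt(abs(iv[["lower"]] - 0.086), 0.0005)  # printed precision
  expect_equal(prevalence_interval(0.36, 0), c(lower = 0.36, upper = 0.36))
  # oracle: invert P(T) = P(D) + (1 - P(D)) fpr at the worst case fpr = 0.1
  expect_equal(prevalence_interval(0.36, 0.1)[["lower"]], (0.36 - 0.1) / 0.9)
  # the two algebraic renderings of the lower bound agree
  for (pt in seq(0, 1, by = 0.25))
    for (a0 in c(0, 0.1, 0.3, 0.6))
      expect_equal(prevalence_interval(pt, a0)[["lower"]],
                   max(0, (pt - a0) / (1 - a0)))
  expect_error(prevalence_interval(0.36, 1), "\\[0, 1\\)")
})

test_that("interval lower bound is nonincreasing in alpha0 and clamps at 0", {
  a0s <- seq(0, 0.95, by = 0.05)
  lo <- vapply(a0s, function(a) prevalence_interval(0.36, a)[["lower"]],
               numeric(1))
  expect_true(all(diff(lo) <= 1e-14))
  expect_equal(lo[1], 0.36)            # width 0 at alpha0 = 0
  expect_equal(lo[length(lo)], 0)      # clamped
})

test_that("interval always contains the true prevalence under bounded fpr", {
  # generative oracle: perfect sensitivity, fpr anywhere in [0, alpha0]
  for (alpha0 in c(0.1, 0.3)) {
    for (pd in seq(0, 1, by = 0.05)) {
      for (fpr in seq(0, alpha0, length.out = 5)) {
        pt <- pd + (1 - pd) * fpr
        iv <- prevalence_interval(pt, alpha0)
        expect_gte(pd + 1e-12, iv[["lower"]])
        expect_lte(pd, iv[["upper"]])
      }
    }
  }
})

test_that("false-positive upper bound matches hand-evaluated Wald values", {
  expect_equal(fpr_upper_bound(0, 100), 0)
  expect_equal(fpr_upper_bound(3, 97), 0.0634, tolerance = 1e-3)
  expect_equal(fpr_upper_bound(3, 97, denominator = "total", n = 200),
               0.0536, tolerance = 1e-3)
  expect_error(fpr_upper_bound(0, 0), "empty")
  expect_error(fpr_upper_bound(3, 97, denominator = "total"), "'n'")
  # the bound never exceeds 1
  expect_lte(fpr_upper_bound(99, 1), 1)
})

test_that("four-step prevalence estimation composes its audited parts", {
  est <- estimate_prevalence(diagnostic_table(360, 0, 0, 640))
  expect_equal(unname(est$interval), c(0.36, 0.36))

  est <- estimate_prevalence(diagnostic_table(330, 0, 30, 640))
  expect_equal(est$p_t, 0.36)
  expect_equal(est$alpha_hat, 30 / 670)
  expect_lt(abs(est$alpha0 - 0.0605), 1e-4)
  expect_lt(abs(est$interval[["lower"]] - 0.3188), 5e-4)
  expect_equal(est$interval[["upper"]], 0.36)

  expect_error(estimate_prevalence(diagnostic_table(300, 200, 30, 470)),
               "rejected")
})

test_that("diagnostic tables round-trip through CSV", {
  tf <- withr::local_tempfile(fileext = ".csv")
  tab <- diagnostic_table(330, 0, 30, 640)
  write_diagnostic_table(tab, tf)
  back <- read_diagnostic_table(tf)
  expect_identical(unclass(back), unclass(tab))
})
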