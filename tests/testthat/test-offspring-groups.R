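test_that("offspring-group frequencies follow the mating-type expansion", {
  f <- group_frequencies(0.2)
  expect_equal(f[["F6"]], 0.4096)
  expect_equal(group_frequencies(0.5)[["F4"]], 0.25)
  for (p in seq(0, 1, by = 0.05))
    expect_equal(sum(group_frequencies(p)), 1)   # (p + q)^4 expansion
  expect_equal(unname(f),
               c(0.2^4, 4 * 0.2^3 * 0.8, 2 * 0.04 * 0.64, 4 * 0.04 * 0.64,
                 4 * 0.2 * 0.8^3, 0.8^4))
})

test_that("Mendelian offspring distributions per mating type", {
  expect_equal(unname(offspring_genotype_distribution(4)), c(0.25, 0.5, 0.25))
  expect_equal(unname(offspring_genotype_distribution(6)), c(0, 0, 1))
  expect_equal(unname(offspring_genotype_distribution(2)), c(0.5, 0.5, 0))
  m <- offspring_genotype_distribution()
  expect_equal(unname(rowSums(m)), rep(1, 6))
  expect_error(offspring_genotype_distribution(7), "1..6")
})

test_that("group risks equal penetrance expectations over Mendelian crosses", {
  expect_equal(unname(group_risks(1, 1)), c(1, 1, 1, 0.75, 0.5, 0))
  expect_equal(unname(group_risks(0.5, 1)), c(1, 0.75, 0.5, 0.5, 0.25, 0))
  # independent oracle: E[penetrance] under the offspring distribution
  m <- offspring_genotype_distribution()
  for (r in c(0.1, 0.37, 0.8, 1)) {
    for (pen in c(0.3, 1)) {
      oracle <- as.numeric(m %*% c(pen, r * pen, 0))
      expect_equal(unname(group_risks(r, pen)), oracle)
    }
  }
})

test_that("recurrence-risk ratios reproduce the three reference columns", {
  expect_equal(round(unname(recurrence_risk_ratios(0.2, 1)), 2),
               c(2.78, 2.78, 2.78, 2.08, 1.39, 0))
  expect_equal(round(unname(recurrence_risk_ratios(0.2, 0.5)), 2),
               c(5.00, 3.75, 2.50, 2.50, 1.25, 0))
  expect_equal(round(unname(recurrence_risk_ratios(0.02, 1)), 2),
               c(25.25, 25.25, 25.25, 18.94, 12.63, 0))
  expect_error(recurrence_risk_ratios(0, 1), "p = 0")
})

test_that("recurrence-risk ratios do not depend on the homozygote penetrance", {
  for (pen in c(0.37, 1)) {
    mu_via_risks <- group_risks(0.6, pen) / prevalence_dominant(0.3, 0.6, pen)
    expect_equal(unname(mu_via_risks),
                 unname(recurrence_risk_ratios(0.3, 0.6)))
  }
})

test_that("group proportions decompose the diseased population", {
  pr <- group_proportions(0.2, 1)
  expect_equal(pr[["F5"]], 0.569, tolerance = 5e-4)
  expect_equal(pr[["F6"]], 0)
  g <- param_grid()
  sums <- mapply(function(p, r) sum(group_proportions(p, r)), g$p, g$r)
  expect_lt(max(abs(sums - 1)), 1e-9)
})

test_that("sibling risk from the group sum equals the closed-form prevalence", {
  sib <- sibling_risk(dominant_model(0.2, r = 1))
  expect_equal(sib$K, 0.36)
  expect_equal(sib$Ks, 0.36)
  expect_equal(sib$lambda_s, 1)
  expect_equal(sib$phi_s, 0.25)
  g <- param_grid(20, 20, pens = seq(0.2, 1, length.out = 5))
  for (i in seq_len(nrow(g))) {
    s <- sibling_risk(dominant_model(g$p[i], r = g$r[i],
                                     pen_CC = g$pen_CC[i]))
    expect_lt(abs(s$Ks - s$K), 1e-12)
  }
})

test_that("zero-IBD sharing is 1/4 by exhaustive transmission enumeration", {
  expect_identical(phi_s_zero_share(), 0.25)
})

test_that("conditioning on both siblings affected shifts allele sharing", {
  # exact enumeration agrees with the closed form
  # 0.25 K^2 / sum P(Fi) P(D|Fi)^2: affected pairs share MORE than expected
  for (pars in list(c(0.2, 1, 1), c(0.3, 0.7, 0.9), c(0.05, 0.4, 0.6))) {
    m <- dominant_model(pars[1], r = pars[2], pen_CC = pars[3])
    cond <- phi_s_zero_share(model = m)
    expect_equal(cond, mendelian_zero_share_affected(pars[1], pars[2],
                                                     pars[3]),
                 tolerance = 1e-12)
    expect_lt(cond, 0.25)
  }
})

test_that("Monte-Carlo sharing agrees with the enumeration within 3 SE", {
  set.seed(101)
  n <- 1e5
  mc <- phi_s_zero_share("montecarlo", n_pairs = n)
  expect_lt(abs(mc - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  m <- dominant_model(0.2, r = 1)
  mc_cond <- phi_s_zero_share("montecarlo", n_pairs = n, model = m)
  exact <- phi_s_zero_share(model = m)
  # both-affected pairs are ~K^2-ish of draws; generous 4 SE on that subset
  expect_lt(abs(mc_cond - exact),
            4 * sqrt(exact * (1 - exact) / (n * 0.2384)))
})

test_that("HLA ratio handles the tabulated extremes", {
  expect_equal(lambda_s_hla(0.25), 1)
  expect_equal(lambda_s_hla(0.50), 0.50)
  expect_equal(lambda_s_hla(0.07), 3.571, tolerance = 1e-3)
  expect_identical(lambda_s_hla(0), Inf)  # tagged infinite, not an error
})

test_that("percentage HLA contribution is undefined at lambda_s = 1", {
  expect_equal(percent_lambda_s_hla(2, 2), 100)
  expect_equal(percent_lambda_s_hla(2, 4), 50)
  expect_error(percent_lambda_s_hla(1.5, 1), "undefined at lambda_s = 1")
  expect_error(percent_lambda_s_hla(-1, 2), "positive")
  expect_error(percent_lambda_s_hla(2, 0), "positive")
})

test_that("sibling prediction reproduces the clinical scenario", {
  pred <- sibling_prediction(dominant_model(0.2, r = 1))
  expect_equal(round(pred$f5_only, 2), 0.50)
  expect_equal(round(pred$weighted, 2), 0.66)
  lv <- sort(unique(round(pred$group_risks[pred$group_risks > 0], 2)))
  expect_equal(lv, c(0.50, 0.75, 1.00))
  expect_equal(sum(pred$weights), 1)   # F6 carries no diseased individuals
})

test_that("lethal-CC genotypes restrict the viable groups", {
  expect_equal(viable_groups(TRUE), 4:6)
  expect_equal(viable_groups(FALSE), 1:6)
  tab <- offspring_groups(dominant_model(0.2, r = 1), lethal_CC = TRUE)
  expect_equal(tab$group[tab$viable], c("F4", "F5", "F6"))
})

test_that("the assembled group table is internally consistent", {
  m <- dominant_model(0.2, r = 1)
  tab <- offspring_groups(m)
  expect_equal(nrow(tab), 6)
  expect_equal(sum(tab$frequency), 1)
  expect_equal(sum(tab$proportion), 1)
  expect_equal(tab$risk, tab$beta * m$pen_CC)
  expect_equal(tab$proportion, tab$frequency * tab$mu)
  expect_output(print(tab), "F5")
})
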