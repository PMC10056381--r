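test_that("a seed reproduces the cohort and its estimates exactly", {
  m <- dominant_model(0.2, r = 1)
  a <- simulate_cohort(m, 500, seed = 99)
  b <- simulate_cohort(m, 500, seed = 99)
  expect_identical(a, b)
  expect_identical(estimate_statistics(a), estimate_statistics(b))
  c2 <- simulate_cohort(m, 500, seed = 100)
  expect_false(identical(a$offspring$diseased, c2$offspring$diseased))
})

test_that("offspring-group labels are consistent with parental genotypes", {
  m <- dominant_model(0.3, r = 0.7, pen_CC = 0.9)
  cohort <- simulate_cohort(m, 2000, seed = 5)
  fam <- cohort$families
  key <- paste(pmax(fam$father, fam$mother), pmin(fam$father, fam$mother))
  map <- c("2 2" = 1, "2 1" = 2, "2 0" = 3, "1 1" = 4, "1 0" = 5, "0 0" = 6)
  expect_equal(fam$group, unname(map[key]))
})

test_that("simulated frequencies and risks recover the closed forms", {
  p <- 0.2; r <- 0.7; pen <- 0.9
  m <- dominant_model(p, r = r, pen_CC = pen)
  n <- 1e5
  cohort <- simulate_cohort(m, n, seed = 2024)
  est <- estimate_statistics(cohort)

  # group frequencies within 3 binomial standard errors
  fr <- group_frequencies(p)
  for (i in 1:6)
    expect_lt(abs(est$group_freq_hat[[i]] - fr[[i]]),
              3 * sqrt(fr[[i]] * (1 - fr[[i]]) / n))

  # prevalence within 3 nominal binomial standard errors over individuals
  K <- prevalence_dominant(p, r, pen)
  expect_lt(abs(est$K_hat - K), 3 * sqrt(K * (1 - K) / (2 * n)))

  # per-group risks within 3 standard errors for well-populated groups
  rk <- group_risks(r, pen)
  n_off <- 2 * tabulate(cohort$families$group, 6)
  for (i in which(n_off >= 200)) {
    se <- sqrt(rk[[i]] * (1 - rk[[i]]) / n_off[i])
    expect_lt(abs(est$group_risk_hat[[i]] - rk[[i]]), max(3 * se, 1e-12))
  }
  # recurrence-risk ratios follow
  for (i in which(n_off >= 200 & rk > 0))
    expect_lt(abs(est$mu_hat[[i]] - rk[[i]] / K), 0.15 * rk[[i]] / K)
})

test_that("within each group offspring genotypes follow the Mendelian cross", {
  m <- dominant_model(0.4, r = 1)
  cohort <- simulate_cohort(m, 5e4, seed = 31)
  off <- cohort$offspring
  grp <- cohort$families$group[off$family]
  dist <- offspring_genotype_distribution()
  for (g in 1:6) {
    sel <- grp == g
    if (sum(sel) < 500) next
    emp <- tabulate(3 - off$genotype[sel], 3) / sum(sel)  # CC, Cc, cc order
    for (j in 1:3)
      expect_lt(abs(emp[j] - dist[g, j]),
                3 * sqrt(max(dist[g, j] * (1 - dist[g, j]), 1e-12) /
                           sum(sel)) + 1e-12)
  }
})

test_that("a perfect test reproduces disease status exactly", {
  m <- dominant_model(0.2, r = 1)
  cohort <- simulate_cohort(m, 3000, sensitivity = 1, fpr = 0, seed = 8)
  expect_identical(cohort$offspring$test_pos, cohort$offspring$diseased)
  est <- estimate_statistics(cohort)
  expect_identical(est$P_T_hat, est$K_hat)
})

test_that("an imperfect test mixes sensitivity and false positives", {
  m <- dominant_model(0.2, r = 1)
  cohort <- simulate_cohort(m, 5e4, sensitivity = 0.9, fpr = 0.05, seed = 17)
  K <- prevalence(m)
  pt <- K * 0.9 + (1 - K) * 0.05
  est <- estimate_statistics(cohort)
  expect_lt(abs(est$P_T_hat - pt), 3 * sqrt(pt * (1 - pt) / 1e5))
})

test_that("the pair estimator converges to the Mendelian sibling risk", {
  # siblings share parents, so the realised recurrence-risk ratio sits at
  # sum P(Fi) P(D|Fi)^2 / K^2, above 1 - not at the independence value
  m <- dominant_model(0.2, r = 1)
  cohort <- simulate_cohort(m, 1e5, seed = 77)
  est <- estimate_statistics(cohort)
  lam <- mendelian_lambda_s(0.2, 1, 1)
  expect_equal(est$lambda_s_hat, lam, tolerance = 0.02)
  expect_gt(est$lambda_s_hat, 1)
})

test_that("IBD zero-sharing is 1/4 overall and drops among affected pairs", {
  m <- dominant_model(0.2, r = 1)
  cohort <- simulate_cohort(m, 1e5, seed = 13)
  z <- ibd_zero_share(cohort)
  expect_lt(abs(z - 0.25), 3 * sqrt(0.25 * 0.75 / 1e5))
  z_aff <- ibd_zero_share(cohort, affected_only = TRUE)
  exact <- mendelian_zero_share_affected(0.2, 1, 1)
  n_aff_pairs <- 0.2384 * 1e5  # expected doubly affected pair count
  expect_lt(abs(z_aff - exact),
            4 * sqrt(exact * (1 - exact) / n_aff_pairs))
  # triple route: simulation ~ enumeration ~ closed form
  expect_equal(phi_s_zero_share(model = m), exact, tolerance = 1e-12)
})

test_that("ascertainment inflates the recurrence-risk ratio estimator", {
  m <- dominant_model(0.2, r = 1)
  ex <- ascertainment_experiment(m, 3e4, seed = 4)
  lam_none <- ex$lambda_s_hat[ex$mode == "none"]
  lam_excl <- ex$lambda_s_hat[ex$mode == "exclude_F6"]
  lam_prob <- ex$lambda_s_hat[ex$mode == "proband"]
  expect_gt(lam_excl, 1)
  expect_gt(lam_excl, lam_none)
  expect_gte(lam_prob, lam_none)
  # closed-form oracles for the inflation factors
  lam <- mendelian_lambda_s(0.2, 1, 1)
  pf6 <- group_frequencies(0.2)[["F6"]]
  expect_equal(lam_excl, lam / (1 - pf6), tolerance = 0.05)
  p_any <- 2 * 0.36 - 0.2384                  # P(>= 1 affected of 2 sibs)
  expect_equal(lam_prob, lam / p_any, tolerance = 0.05)
  # F6 exclusion removes about 41% of families at p = 0.2
  expect_equal(ex$frac_families_excluded[ex$mode == "exclude_F6"], 0.4096,
               tolerance = 0.02)
})

test_that("sibling quantities are flagged undefined when uncomputable", {
  m <- dominant_model(0.2, r = 1)
  single <- simulate_cohort(m, 100, offspring_per_family = 1, seed = 1)
  est <- estimate_statistics(single)
  expect_true(is.na(est$Ks_pairs))
  expect_true(is.na(est$lambda_s_hat))
})

test_that("lambda_s responds quadratically to prevalence errors", {
  expect_equal(sensitivity_of_lambda_to_K(0.36^2, 0.36), 1)
  expect_equal(sensitivity_of_lambda_to_K(0.1296, 0.36), 1)
  expect_equal(sensitivity_of_lambda_to_K(0.1296, 0.18), 4)
  expect_error(sensitivity_of_lambda_to_K(0.1, 0), "K = 0")
})

test_that("the simulate() method draws cohorts from the model", {
  m <- dominant_model(0.2, r = 1)
  one <- simulate(m, seed = 3, n_families = 200)
  expect_s3_class(one, "simulated_cohort")
  two <- simulate(m, nsim = 2, seed = 3, n_families = 200)
  expect_length(two, 2)
  expect_identical(two[[1]]$offspring, one$offspring)
})
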