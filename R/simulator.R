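# Forward Mendelian simulation of nuclear families under the model's
# assumptions: Hardy-Weinberg random mating, uniform transmission of one
# parental allele slot per parent, disease independent across individuals
# given genotype, and an imperfect diagnostic test applied independently.

#' Simulate a cohort of nuclear families
#'
#' Each parent's two allele slots carry the dominant allele independently
#' with probability `p`; each offspring inherits one uniformly chosen slot
#' per parent, independently across offspring; disease strikes with the
#' genotype's penetrance (`pen_CC`, `r * pen_CC`, 0), independently across
#' individuals; the diagnostic test is positive with probability
#' `sensitivity` for diseased and `fpr` for disease-free individuals.
#'
#' Random draws are consumed in a fixed, documented order — parental allele
#' slots, offspring transmission slots (paternal then maternal), disease
#' uniforms, test uniforms — so a seed reproduces the cohort bit for bit.
#' Ascertainment never discards data: the full cohort is retained and a
#' logical `retained` flag marks the families forming the "clinical study"
#' (`"exclude_F6"` drops families whose parents are both `cc`; `"proband"`
#' keeps families with at least one affected offspring).
#'
#' @param model A [dominant_model()] providing `p`, `r`, `pen_CC`.
#' @param n_families Number of families to simulate.
#' @param offspring_per_family Offspring per family (>= 2 for sibling
#'   statistics; default 2, the sibling-pair setting).
#' @param sensitivity Test sensitivity `P(T|D)`; default 1.
#' @param fpr Test false-positive rate `P(T|D')`; default 0.
#' @param ascertainment One of `"none"`, `"exclude_F6"`, `"proband"`.
#' @param seed Optional integer seed (`set.seed` is called when supplied).
#' @return An object of class `"simulated_cohort"`: a list with
#'   `families` (data.frame: `family`, `father`, `mother` C-allele counts,
#'   `group`, `retained`), `offspring` (data.frame: `family`, `sib`,
#'   `pat_slot`, `mat_slot`, `genotype` as C-allele count, `diseased`,
#'   `test_pos`) and `config`.
#' @seealso [estimate_statistics()], [ascertainment_experiment()],
#'   [ibd_zero_share()]
#' @examples
#' cohort <- simulate_cohort(dominant_model(0.2, r = 1), 500, seed = 1)
#' estimate_statistics(cohort)
#' @export
simulate_cohort <- function(model, n_families, offspring_per_family = 2,
                            sensitivity = 1, fpr = 0,
                            ascertainment = c("none", "exclude_F6", "proband"),
                            seed = NULL) {
  stopifnot(inherits(model, "dominant_model"))
  n <- check_count(n_families, "n_families")
  if (n <= 0) stop("'n_families' must be positive", call. = FALSE)
  k <- check_count(offspring_per_family, "offspring_per_family")
  if (k < 1) stop("'offspring_per_family' must be at least 1", call. = FALSE)
  check_prob(sensitivity, "sensitivity")
  check_prob(fpr, "fpr")
  ascertainment <- match.arg(ascertainment)
  if (!is.null(seed)) set.seed(seed)

  # (1) parental allele slots: father slots 1-2, mother slots 3-4
  slots <- matrix(stats::runif(n * 4) < model$p, nrow = n, ncol = 4)
  father <- rowSums(slots[, 1:2, drop = FALSE])
  mother <- rowSums(slots[, 3:4, drop = FALSE])
  # unordered parental genotype pair -> offspring-group index
  lut <- matrix(0L, 3, 3)
  lut[3, 3] <- 1L; lut[3, 2] <- 2L; lut[3, 1] <- 3L
  lut[2, 2] <- 4L; lut[2, 1] <- 5L; lut[1, 1] <- 6L
  group <- lut[cbind(pmax(father, mother) + 1L, pmin(father, mother) + 1L)]

  # (2) transmissions, (3) disease, (4) test — n x k matrices, column-major
  pat_slot <- matrix(1L + (stats::runif(n * k) < 0.5), n, k)
  mat_slot <- matrix(1L + (stats::runif(n * k) < 0.5), n, k)
  u_dis <- matrix(stats::runif(n * k), n, k)
  u_tst <- matrix(stats::runif(n * k), n, k)

  fam_idx <- rep(seq_len(n), times = k)
  sib_idx <- rep(seq_len(k), each = n)
  g_off <- slots[cbind(fam_idx, as.vector(pat_slot))] +
           slots[cbind(fam_idx, 2L + as.vector(mat_slot))]
  pen <- c(model$pen_cc, model$pen_Cc, model$pen_CC)
  diseased <- as.vector(u_dis) < pen[g_off + 1]
  test_pos <- ifelse(diseased, as.vector(u_tst) < sensitivity,
                     as.vector(u_tst) < fpr)

  offspring <- data.frame(family = fam_idx, sib = sib_idx,
                          pat_slot = as.vector(pat_slot),
                          mat_slot = as.vector(mat_slot),
                          genotype = g_off, diseased = diseased,
                          test_pos = test_pos)
  offspring <- offspring[order(offspring$family, offspring$sib), ]
  rownames(offspring) <- NULL

  retained <- switch(ascertainment,
    none = rep(TRUE, n),
    exclude_F6 = group != 6L,
    proband = as.vector(rowSums(matrix(diseased, n, k)) > 0))

  structure(
    list(families = data.frame(family = seq_len(n), father = father,
                               mother = mother, group = group,
                               retained = retained),
         offspring = offspring,
         config = list(p = model$p, r = model$r, pen_CC = model$pen_CC,
                       sensitivity = sensitivity, fpr = fpr,
                       n_families = n, offspring_per_family = k,
                       ascertainment = ascertainment, seed = seed)),
    class = "simulated_cohort"
  )
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Simulated cohort: %d families x %d offspring ",
                     "(p = %s, r = %s, pen_CC = %s)\n"),
              cfg$n_families, cfg$offspring_per_family,
              format(cfg$p), format(cfg$r), format(cfg$pen_CC)))
  cat(sprintf("  ascertainment: %s (%d families retained)\n",
              cfg$ascertainment, sum(x$families$retained)))
  cat(sprintf("  affected offspring: %d / %d\n",
              sum(x$offspring$diseased), nrow(x$offspring)))
  invisible(x)
}

#' Estimators on a simulated cohort
#'
#' Computes the empirical prevalence `K_hat` and test-positive fraction
#' `P_T_hat` (always on the full, unascertained cohort — the population),
#' empirical group frequencies, group risks and recurrence-risk ratios, and
#' the sibling-risk estimators:
#' * `Ks_pairs` — the standard conditional estimator: over all ordered
#'   sibling pairs in retained families, the fraction with the second
#'   sibling affected among pairs with the first affected;
#' * `Ks_mixed` — the biased clinical construction
#'   `P_hat(D1 and D2 | study) / K_hat(population)`: the joint frequency is
#'   taken from the ascertained study families while the denominator comes
#'   from the population, which is how inflated sibling risks arise in
#'   practice.
#'
#' `lambda_s_hat` is `Ks_pairs / K_hat` under no ascertainment and
#' `Ks_mixed / K_hat` under either ascertainment mode.
#'
#' @param cohort A [simulate_cohort()] result with at least two offspring
#'   per family for the sibling quantities.
#' @return An object of class `"cohort_estimates"`: a list with `K_hat`,
#'   `P_T_hat`, `Ks_pairs`, `Ks_mixed`, `lambda_s_hat`, `group_freq_hat`,
#'   `group_risk_hat`, `mu_hat`, `n_pairs_retained`, `ascertainment`.
#'   Sibling quantities are `NA` when undefined (no affected first
#'   siblings).
#' @export
estimate_statistics <- function(cohort) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  off <- cohort$offspring
  fam <- cohort$families
  k <- cohort$config$offspring_per_family
  K_hat <- mean(off$diseased)
  P_T_hat <- mean(off$test_pos)

  freq_hat <- tabulate(fam$group, nbins = 6) / nrow(fam)
  dis_by_group <- tapply(off$diseased, fam$group[off$family],
                         mean, default = NA_real_)
  risk_hat <- rep(NA_real_, 6)
  risk_hat[as.integer(names(dis_by_group))] <- as.numeric(dis_by_group)
  mu_hat <- if (K_hat > 0) risk_hat / K_hat else rep(NA_real_, 6)

  Ks_pairs <- Ks_mixed <- lambda_s_hat <- NA_real_
  n_pairs_ret <- 0L
  if (k >= 2) {
    dmat <- matrix(off$diseased[order(off$sib, off$family)],
                   nrow = nrow(fam), ncol = k)  # families x sibs
    ret <- fam$retained
    # ordered pairs (i, j), i != j, within retained families
    n_aff <- rowSums(dmat[ret, , drop = FALSE])
    first_aff <- sum(n_aff) * (k - 1)              # pairs with sib1 affected
    both_aff <- sum(n_aff * (n_aff - 1))           # pairs with both affected
    tot_pairs <- sum(ret) * k * (k - 1)
    n_pairs_ret <- tot_pairs
    if (first_aff > 0) Ks_pairs <- both_aff / first_aff
    if (tot_pairs > 0 && K_hat > 0)
      Ks_mixed <- (both_aff / tot_pairs) / K_hat
    lambda_s_hat <- if (cohort$config$ascertainment == "none")
      Ks_pairs / K_hat else Ks_mixed / K_hat
  }

  structure(
    list(K_hat = K_hat, P_T_hat = P_T_hat,
         Ks_pairs = Ks_pairs, Ks_mixed = Ks_mixed,
         lambda_s_hat = lambda_s_hat,
         group_freq_hat = stats::setNames(freq_hat, GROUP_NAMES),
         group_risk_hat = stats::setNames(risk_hat, GROUP_NAMES),
         mu_hat = stats::setNames(mu_hat, GROUP_NAMES),
         n_pairs_retained = n_pairs_ret,
         ascertainment = cohort$config$ascertainment),
    class = "cohort_estimates"
  )
}

#' @export
print.cohort_estimates <- function(x, digits = 4, ...) {
  cat("Cohort estimates (ascertainment:", x$ascertainment, ")\n")
  cat(sprintf("  K_hat = %s, P(T)_hat = %s\n",
              format(x$K_hat, digits = digits),
              format(x$P_T_hat, digits = digits)))
  cat(sprintf("  Ks (pairs) = %s, Ks (study/population mix) = %s\n",
              format(x$Ks_pairs, digits = digits),
              format(x$Ks_mixed, digits = digits)))
  cat(sprintf("  lambda_s_hat = %s\n", format(x$lambda_s_hat,
                                              digits = digits)))
  cat("  mu_hat:", paste(format(x$mu_hat, digits = digits),
                         collapse = " "), "\n")
  invisible(x)
}

#' Ascertainment-bias experiment
#'
#' Simulates matched cohorts (same seed, hence identical families) under the
#' three ascertainment modes and reports the sibling recurrence-risk ratio
#' estimate for each. Expected behaviour: `lambda_s_hat` is close to 1 with
#' no ascertainment; excluding the all-`cc` families (F6) while keeping a
#' population-wide prevalence denominator inflates it towards
#' `1 / (1 - P(F6))`; proband ascertainment (clinic enrolment of families
#' with an affected member, i.e. participation weighted toward high-risk
#' offspring-groups) inflates it as well.
#'
#' @inheritParams simulate_cohort
#' @return A `data.frame` with one row per mode: `mode`, `K_hat`,
#'   `Ks_used` (the estimator entering `lambda_s_hat`), `lambda_s_hat`,
#'   `frac_families_excluded`.
#' @examples
#' ascertainment_experiment(dominant_model(0.2, r = 1), 2000, seed = 7)
#' @export
ascertainment_experiment <- function(model, n_families,
                                     offspring_per_family = 2,
                                     sensitivity = 1, fpr = 0, seed = NULL) {
  modes <- c("none", "exclude_F6", "proband")
  rows <- lapply(modes, function(mode) {
    cohort <- simulate_cohort(model, n_families, offspring_per_family,
                              sensitivity, fpr, ascertainment = mode,
                              seed = seed)
    est <- estimate_statistics(cohort)
    data.frame(mode = mode,
               K_hat = est$K_hat,
               Ks_used = if (mode == "none") est$Ks_pairs else est$Ks_mixed,
               lambda_s_hat = est$lambda_s_hat,
               frac_families_excluded =
                 1 - mean(cohort$families$retained),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Zero-IBD allele sharing among simulated sibling pairs
#'
#' Fraction of within-family sibling pairs that inherited different slots
#' from both parents (zero alleles identical by descent at the locus).
#' Optionally restricted to pairs with both siblings affected — the
#' conditional fraction is also 1/4 because disease status is independent of
#' transmission slots.
#'
#' @param cohort A [simulate_cohort()] result with at least 2 offspring per
#'   family.
#' @param affected_only Restrict to pairs with both siblings diseased?
#' @return The zero-share fraction, or `NA` if no qualifying pairs exist.
#' @export
ibd_zero_share <- function(cohort, affected_only = FALSE) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  k <- cohort$config$offspring_per_family
  if (k < 2) stop("cohort needs at least 2 offspring per family",
                  call. = FALSE)
  off <- cohort$offspring
  n <- cohort$config$n_families
  ord <- order(off$sib, off$family)
  pat <- matrix(off$pat_slot[ord], n, k)
  mat <- matrix(off$mat_slot[ord], n, k)
  dis <- matrix(off$diseased[ord], n, k)
  pairs <- utils::combn(k, 2)
  zero <- use <- logical(0)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    zero <- c(zero, pat[, a] != pat[, b] & mat[, a] != mat[, b])
    use <- c(use, if (affected_only) dis[, a] & dis[, b] else rep(TRUE, n))
  }
  if (!any(use)) return(NA_real_)
  mean(zero[use])
}

#' Sensitivity of the sibling recurrence-risk ratio to the prevalence
#'
#' The rearrangement `lambda_s = P(D1 and D2) / K^2` makes explicit that the
#' prevalence enters squared while the joint sibling probability enters
#' linearly: halving `K` at fixed joint probability quadruples `lambda_s`,
#' so underestimates of `K` (the common direction of error) inflate
#' `lambda_s` far more than overestimates of the joint probability do.
#'
#' @param p_joint Joint probability both siblings are affected, in `[0, 1]`.
#' @param K Population prevalence, in `(0, 1]`.
#' @return `p_joint / K^2`.
#' @examples
#' sensitivity_of_lambda_to_K(0.1296, 0.36)  # 1
#' sensitivity_of_lambda_to_K(0.1296, 0.18)  # 4
#' @export
sensitivity_of_lambda_to_K <- function(p_joint, K) {
  check_prob(p_joint, "p_joint")
  if (!is.numeric(K) || length(K) != 1L || K <= 0 || K > 1)
    stop("'K' must lie in (0, 1]; lambda_s is undefined at K = 0",
         call. = FALSE)
  p_joint / K^2
}

#' Simulate families from a dominant-disease model
#'
#' [stats::simulate()] method: draws one or more cohorts from the model via
#' [simulate_cohort()].
#'
#' @param object A [dominant_model()].
#' @param nsim Number of cohorts.
#' @param seed Optional seed for the first cohort; subsequent cohorts
#'   continue the RNG stream.
#' @param n_families,... Passed to [simulate_cohort()].
#' @return A `"simulated_cohort"` if `nsim = 1`, else a list of them.
#' @export
simulate.dominant_model <- function(object, nsim = 1, seed = NULL,
                                    n_families = 1000, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(i)
    simulate_cohort(object, n_families, ..., seed = NULL))
  if (nsim == 1) out[[1]] else out
}
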