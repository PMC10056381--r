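# Offspring-group aggregation: the six population strata F1..F6 defined by
# parental genotype pairs, their frequencies, Mendelian offspring
# distributions, group risks beta_i(r) P(D|CC), recurrence-risk ratios
# mu_i = P(D|Fi)/P(D), the proportion decomposition sum P(Fi) mu_i = 1, and
# the sibling recurrence-risk ratio identity lambda_s = 1.

GROUP_NAMES <- paste0("F", 1:6)
MATING_TYPES <- c("CC x CC", "CC x Cc", "CC x cc",
                  "Cc x Cc", "Cc x cc", "cc x cc")

#' Offspring-group frequencies
#'
#' Frequencies of the six parental mating types under Hardy-Weinberg random
#' mating: `(p^4, 4p^3q, 2p^2q^2, 4p^2q^2, 4pq^3, q^4)`, which sum to 1 (the
#' expansion of `(p + q)^4`). Ordered parents and heterozygote phase are
#' absorbed into the multipliers, equivalent to drawing each parent's two
#' alleles independently with probability `p`.
#'
#' @param p Frequency of the dominant allele, or a [dominant_model()].
#' @return Named numeric vector `F1..F6`.
#' @examples
#' group_frequencies(0.2)  # F6 = 0.4096
#' @export
group_frequencies <- function(p) {
  if (inherits(p, "dominant_model")) p <- p$p
  check_prob(p, "p")
  q <- 1 - p
  stats::setNames(
    c(p^4, 4 * p^3 * q, 2 * p^2 * q^2, 4 * p^2 * q^2, 4 * p * q^3, q^4),
    GROUP_NAMES)
}

#' Mendelian offspring-genotype distribution within a group
#'
#' The distribution of offspring genotypes (`CC`, `Cc`, `cc`) for each
#' mating type: F1 `(1,0,0)`, F2 `(1/2,1/2,0)`, F3 `(0,1,0)`,
#' F4 `(1/4,1/2,1/4)`, F5 `(0,1/2,1/2)`, F6 `(0,0,1)`.
#'
#' @param group_index Integer 1..6, or missing for the full 6x3 matrix.
#' @return A named probability vector over `c("CC","Cc","cc")`, or a 6x3
#'   matrix (rows `F1..F6`) when `group_index` is missing.
#' @examples
#' offspring_genotype_distribution(4)  # Cc x Cc: 1/4, 1/2, 1/4
#' @export
offspring_genotype_distribution <- function(group_index) {
  m <- matrix(c(1,    0,   0,
                0.5,  0.5, 0,
                0,    1,   0,
                0.25, 0.5, 0.25,
                0,    0.5, 0.5,
                0,    0,   1),
              nrow = 6, byrow = TRUE,
              dimnames = list(GROUP_NAMES, c("CC", "Cc", "cc")))
  if (missing(group_index)) return(m)
  group_index <- check_count(group_index, "group_index")
  if (group_index < 1 || group_index > 6)
    stop("'group_index' must lie in 1..6", call. = FALSE)
  m[group_index, ]
}

#' Offspring-group risk coefficients beta_i(r)
#'
#' The group risk factors out the homozygote penetrance:
#' `P(D|Fi) = beta_i(r) P(D|CC)` with `beta = (1, (1+r)/2, r, (1+2r)/4,
#' r/2, 0)` — each `beta_i(r)` is the expectation of `(1, r, 0)` under the
#' group's Mendelian offspring distribution.
#'
#' @param r Penetrance ratio, in `(0, 1]`.
#' @return Named numeric vector `F1..F6`.
#' @examples
#' group_betas(1)  # 1, 1, 1, 0.75, 0.5, 0
#' @export
group_betas <- function(r) {
  check_ratio_r(r)
  stats::setNames(c(1, (1 + r) / 2, r, (1 + 2 * r) / 4, r / 2, 0),
                  GROUP_NAMES)
}

#' Offspring-group risks P(D|Fi)
#'
#' @param r Penetrance ratio, in `(0, 1]`.
#' @param pen_CC Penetrance of `CC`, in `(0, 1]`.
#' @return Named numeric vector `F1..F6` of `beta_i(r) * pen_CC`.
#' @examples
#' group_risks(1, 1)  # 1, 1, 1, 0.75, 0.5, 0
#' @export
group_risks <- function(r, pen_CC = 1) {
  check_prob(pen_CC, "pen_CC")
  group_betas(r) * pen_CC
}

#' Offspring-group recurrence-risk ratios mu_i
#'
#' `mu_i = P(D|Fi) / P(D) = beta_i(r) / (p (2r + (1 - 2r) p))`: how much
#' more likely a member of offspring-group `Fi` is to have the disease than
#' a member of the general population. The homozygote penetrance cancels, so
#' `mu_i` depends only on `p` and `r`. `mu_6 = 0` always.
#'
#' @param p Frequency of the dominant allele, in `(0, 1)`; or a
#'   [dominant_model()] (in which case `r` is taken from it).
#' @param r Penetrance ratio, in `(0, 1]`.
#' @return Named numeric vector `F1..F6`.
#' @examples
#' round(recurrence_risk_ratios(0.2, 1), 2)  # 2.78 2.78 2.78 2.08 1.39 0
#' @export
recurrence_risk_ratios <- function(p, r) {
  if (inherits(p, "dominant_model")) { r <- p$r; p <- p$p }
  check_prob(p, "p")
  check_ratio_r(r)
  denom <- p * (2 * r + (1 - 2 * r) * p)
  if (denom <= 0)
    stop("recurrence-risk ratios are undefined at zero prevalence (p = 0)",
         call. = FALSE)
  group_betas(r) / denom
}

#' Offspring-group proportions of diseased individuals
#'
#' `P(Fi) mu_i`: the proportion of all diseased individuals who belong to
#' offspring-group `Fi`. The six proportions sum to 1 — the frequency
#' distribution of offspring-group aggregation.
#'
#' @inheritParams recurrence_risk_ratios
#' @return Named numeric vector `F1..F6` summing to 1.
#' @examples
#' round(group_proportions(0.2, 1), 3)  # F5 carries 0.569 of all cases
#' @export
group_proportions <- function(p, r) {
  if (inherits(p, "dominant_model")) { r <- p$r; p <- p$p }
  group_frequencies(p) * recurrence_risk_ratios(p, r)
}

#' Subset of offspring-groups present in the living population
#'
#' When the `CC` genotype is lethal before or shortly after birth (as in
#' Huntington's disease or Marfan syndrome), groups F1-F3 (those with a `CC`
#' parent) do not appear among the living, and `mu_4`, `mu_5` and their
#' proportions become the relevant aggregation measures.
#'
#' @param lethal_CC Logical; is the `CC` genotype lethal?
#' @return Integer vector of viable group indices.
#' @examples
#' viable_groups(TRUE)   # 4 5 6
#' @export
viable_groups <- function(lethal_CC = FALSE) {
  if (isTRUE(lethal_CC)) 4:6 else 1:6
}

#' Full offspring-group table
#'
#' Assembles, for a [dominant_model()], the per-group mating type, frequency
#' `P(Fi)`, risk `P(D|Fi)`, coefficient `beta_i(r)`, recurrence-risk ratio
#' `mu_i` and proportion `P(Fi) mu_i` of diseased individuals.
#'
#' @param model A [dominant_model()] with `0 < p < 1`.
#' @param lethal_CC Logical; if `TRUE`, rows for groups absent from the
#'   living population (F1-F3) are flagged in a `viable` column.
#' @return A `data.frame` of class `"offspring_groups"` with columns
#'   `group`, `mating_type`, `frequency`, `risk`, `beta`, `mu`,
#'   `proportion`, `viable`.
#' @examples
#' offspring_groups(dominant_model(0.2, r = 1))
#' @export
offspring_groups <- function(model, lethal_CC = FALSE) {
  stopifnot(inherits(model, "dominant_model"))
  out <- data.frame(
    group = GROUP_NAMES,
    mating_type = MATING_TYPES,
    frequency = unname(group_frequencies(model$p)),
    risk = unname(group_risks(model$r, model$pen_CC)),
    beta = unname(group_betas(model$r)),
    mu = unname(recurrence_risk_ratios(model$p, model$r)),
    proportion = unname(group_proportions(model$p, model$r)),
    viable = seq_len(6) %in% viable_groups(lethal_CC),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("offspring_groups", "data.frame"),
            lethal_CC = isTRUE(lethal_CC))
}

#' @export
print.offspring_groups <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  if (!attr(x, "lethal_CC")) df$viable <- NULL
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}

#' Sibling risk and the lambda_s = 1 identity
#'
#' Computes the population prevalence `K` from the closed form and the
#' sibling risk `Ks = P(D2|D1)` by summing the offspring-group risks over
#' the group frequencies (`Ks = sum_i P(D|Fi) P(Fi)` over F1..F5) — two
#' independently coded routes that agree identically, so the sibling
#' recurrence-risk ratio `lambda_s = Ks / K` equals 1 for every
#' dominant-disease parameterisation. The single-locus probability that two
#' siblings share zero parental alleles identical by descent, `phi_s = 1/4`,
#' is included.
#'
#' @param model A [dominant_model()].
#' @return An object of class `"sibling_statistics"`: a list with `K`,
#'   `Ks`, `lambda_s`, `phi_s`.
#' @examples
#' sibling_risk(dominant_model(0.2, r = 1))  # K = Ks = 0.36, lambda_s = 1
#' @export
sibling_risk <- function(model) {
  stopifnot(inherits(model, "dominant_model"))
  K <- prevalence(model)
  freq <- group_frequencies(model$p)
  risk <- group_risks(model$r, model$pen_CC)
  Ks <- sum(risk[1:5] * freq[1:5])  # P(D|F6) = 0 drops the last term
  structure(list(K = K, Ks = Ks,
                 lambda_s = if (K > 0) Ks / K else NA_real_,
                 phi_s = 0.25),
            class = "sibling_statistics")
}

#' @export
print.sibling_statistics <- function(x, digits = 4, ...) {
  cat("Sibling statistics\n")
  cat(sprintf("  population prevalence K        = %s\n",
              format(x$K, digits = digits)))
  cat(sprintf("  sibling risk Ks = P(D2|D1)     = %s\n",
              format(x$Ks, digits = digits)))
  cat(sprintf("  recurrence-risk ratio lambda_s = %s\n",
              format(x$lambda_s, digits = digits)))
  cat(sprintf("  zero-IBD-share prob. phi_s     = %s\n", format(x$phi_s)))
  invisible(x)
}

#' Probability two siblings share zero parental alleles IBD
#'
#' At a single autosomal locus each sibling inherits one of two allele slots
#' from each parent. `method = "enumerate"` exhaustively enumerates the 16
#' equally likely joint transmissions to two siblings: zero sharing requires
#' discordant transmission from both parents, hence `phi_s = 1/2 * 1/2 =
#' 1/4`. With a `model`, the enumeration is extended over parental allele
#' configurations and disease indicators to give the exact conditional
#' probability given both siblings affected — also 1/4, because disease
#' status is independent of transmission slots. `method = "montecarlo"`
#' samples sibling pairs instead (seed the RNG yourself for
#' reproducibility).
#'
#' @param method `"enumerate"` (exact, default) or `"montecarlo"`.
#' @param n_pairs Number of sibling pairs for the Monte-Carlo method.
#' @param model Optional [dominant_model()]; if supplied, the probability is
#'   conditioned on both siblings being affected.
#' @return The zero-share probability (0.25 exactly for the enumeration).
#' @examples
#' phi_s_zero_share()  # 0.25
#' phi_s_zero_share(model = dominant_model(0.2, r = 1))  # still 0.25
#' @export
phi_s_zero_share <- function(method = c("enumerate", "montecarlo"),
                             n_pairs = 1e6, model = NULL) {
  method <- match.arg(method)
  if (method == "enumerate") {
    # slots chosen by sib 1 and sib 2 from father (f1, f2) and mother (m1, m2)
    tr <- expand.grid(f1 = 1:2, f2 = 1:2, m1 = 1:2, m2 = 1:2)
    zero <- tr$f1 != tr$f2 & tr$m1 != tr$m2
    if (is.null(model)) return(sum(zero) / nrow(tr))
    stopifnot(inherits(model, "dominant_model"))
    pen <- c(model$pen_cc, model$pen_Cc, model$pen_CC)  # index by C-count + 1
    # parental allele configurations: father slots (a1, a2), mother (b1, b2),
    # each carrying C with probability p
    al <- expand.grid(a1 = 0:1, a2 = 0:1, b1 = 0:1, b2 = 0:1)
    w_al <- apply(al, 1, function(a) prod(ifelse(a == 1, model$p, model$q)))
    num <- den <- 0
    for (i in seq_len(nrow(al))) {
      fa <- c(al$a1[i], al$a2[i]); mo <- c(al$b1[i], al$b2[i])
      g1 <- fa[tr$f1] + mo[tr$m1]
      g2 <- fa[tr$f2] + mo[tr$m2]
      w <- w_al[i] / nrow(tr) * pen[g1 + 1] * pen[g2 + 1]
      den <- den + sum(w)
      num <- num + sum(w[zero])
    }
    if (den == 0) stop("both-affected event has probability zero",
                       call. = FALSE)
    return(num / den)
  }
  n_pairs <- check_count(n_pairs, "n_pairs")
  f_disc <- stats::runif(n_pairs) < 0.5   # sibs draw different paternal slots
  m_disc <- stats::runif(n_pairs) < 0.5
  if (is.null(model)) return(mean(f_disc & m_disc))
  stopifnot(inherits(model, "dominant_model"))
  pen <- c(model$pen_cc, model$pen_Cc, model$pen_CC)
  fa <- matrix(stats::runif(2 * n_pairs) < model$p, ncol = 2)
  mo <- matrix(stats::runif(2 * n_pairs) < model$p, ncol = 2)
  s1f <- sample(1:2, n_pairs, replace = TRUE)
  s1m <- sample(1:2, n_pairs, replace = TRUE)
  s2f <- ifelse(f_disc, 3L - s1f, s1f)
  s2m <- ifelse(m_disc, 3L - s1m, s1m)
  g1 <- fa[cbind(seq_len(n_pairs), s1f)] + mo[cbind(seq_len(n_pairs), s1m)]
  g2 <- fa[cbind(seq_len(n_pairs), s2f)] + mo[cbind(seq_len(n_pairs), s2m)]
  d1 <- stats::runif(n_pairs) < pen[g1 + 1]
  d2 <- stats::runif(n_pairs) < pen[g2 + 1]
  both <- d1 & d2
  if (!any(both)) stop("no doubly affected pairs sampled", call. = FALSE)
  mean(f_disc[both] & m_disc[both])
}

#' HLA contribution to the sibling recurrence-risk ratio
#'
#' `lambda_s_HLA = 0.25 / observed_zero_share`: the expected proportion of
#' affected sibling pairs sharing zero haplotypes IBD divided by the
#' observed proportion. An observed share of 0 yields `Inf` (a tagged
#' infinite value, not an error — clinical tabulations report this outcome
#' as "undefined").
#'
#' @param observed_zero_share Observed proportion of affected sibling pairs
#'   sharing zero haplotypes IBD, in `[0, 1]`.
#' @return The ratio, possibly `Inf`.
#' @examples
#' lambda_s_hla(0.25)  # 1
#' lambda_s_hla(0.07)  # ~3.571
#' @export
lambda_s_hla <- function(observed_zero_share) {
  check_prob(observed_zero_share, "observed_zero_share")
  if (observed_zero_share == 0) return(Inf)
  0.25 / observed_zero_share
}

#' Percentage HLA contribution (and why it is undefined)
#'
#' `100 log(lambda_s_HLA) / log(lambda_s)` under a multiplicative model.
#' Because `lambda_s = 1` in theory, the denominator vanishes and the
#' formula is undefined whenever the true sibling recurrence-risk ratio is
#' used; the function raises a dedicated error in that case rather than
#' returning a number.
#'
#' @param lambda_hla Positive HLA ratio.
#' @param lambda_s Positive sibling recurrence-risk ratio, not equal to 1.
#' @return The percentage contribution.
#' @examples
#' percent_lambda_s_hla(2, 4)  # 50
#' @export
percent_lambda_s_hla <- function(lambda_hla, lambda_s) {
  if (!is.numeric(lambda_hla) || length(lambda_hla) != 1L || lambda_hla <= 0)
    stop("'lambda_hla' must be a positive ratio", call. = FALSE)
  if (!is.numeric(lambda_s) || length(lambda_s) != 1L || lambda_s <= 0)
    stop("'lambda_s' must be a positive ratio", call. = FALSE)
  if (lambda_s == 1)
    stop("percentage contribution is undefined at lambda_s = 1 ",
         "(log(lambda_s) = 0); the theoretical sibling recurrence-risk ",
         "ratio is always 1, so this formula always produces an undefined ",
         "result when the true value is used", call. = FALSE)
  100 * log(lambda_hla) / log(lambda_s)
}

#' Disease prediction for a person with an affected sibling
#'
#' Given one affected sibling (which rules out offspring-group F6), returns:
#' the per-group conditional disease probabilities `P(D|Fi)`; the group
#' weights — the proportions `P(Fi) mu_i` of diseased individuals, restricted
#' to F1..F5; the prediction using only the largest group F5,
#' `mu_5 * K`; and the weighted-average prediction
#' `sum_i P(Fi) mu_i P(D|Fi)`.
#'
#' @param model A [dominant_model()].
#' @return An object of class `"sibling_prediction"`: a list with
#'   `group_risks`, `weights`, `f5_only`, `weighted`, `prevalence`.
#' @examples
#' pr <- sibling_prediction(dominant_model(0.2, r = 1))
#' round(pr$f5_only, 2)   # 0.50
#' round(pr$weighted, 2)  # 0.66
#' @export
sibling_prediction <- function(model) {
  stopifnot(inherits(model, "dominant_model"))
  K <- prevalence(model)
  risks <- group_risks(model$r, model$pen_CC)
  props <- group_proportions(model$p, model$r)
  mu <- recurrence_risk_ratios(model$p, model$r)
  structure(
    list(group_risks = risks,
         weights = props[1:5],
         f5_only = unname(mu[["F5"]] * K),
         weighted = sum(props[1:5] * risks[1:5]),
         prevalence = K),
    class = "sibling_prediction"
  )
}

#' @export
print.sibling_prediction <- function(x, digits = 3, ...) {
  cat("Disease prediction given one affected sibling\n")
  cat("  population prevalence:", format(x$prevalence, digits = digits), "\n")
  cat("  per-group risk P(D|Fi):",
      paste(format(x$group_risks, digits = digits), collapse = " "), "\n")
  cat("  group weights (F1..F5):",
      paste(format(x$weights, digits = digits), collapse = " "), "\n")
  cat("  F5-only prediction:     ", format(x$f5_only, digits = digits), "\n")
  cat("  weighted prediction:    ", format(x$weighted, digits = digits), "\n")
  invisible(x)
}
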