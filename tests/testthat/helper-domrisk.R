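# shared fixtures and independent oracles

# dense parameter grid used by the identity/normalisation property tests
param_grid <- function(n_p = 20, n_r = 20, pens = c(0.2, 0.5, 0.9, 1)) {
  expand.grid(p = seq(0.05, 0.95, length.out = n_p),
              r = seq(0.05, 1, length.out = n_r),
              pen_CC = pens)
}

# sibling recurrence-risk ratio implied by the Mendelian family process
# itself (siblings share parents, so genotypes are correlated):
# lambda = sum_i P(Fi) P(D|Fi)^2 / K^2. Independent of the simulator code
# path - pure closed-form arithmetic over the six groups.
mendelian_lambda_s <- function(p, r, pen_CC = 1) {
  K <- prevalence_dominant(p, r, pen_CC)
  sum(group_frequencies(p) * group_risks(r, pen_CC)^2) / K^2
}

# zero-IBD share among doubly affected sibling pairs under the same process:
# conditional on zero sharing the two genotypes are independent HWE draws,
# so P(Z | D1 & D2) = (1/4) K^2 / sum_i P(Fi) P(D|Fi)^2
mendelian_zero_share_affected <- function(p, r, pen_CC = 1) {
  K <- prevalence_dominant(p, r, pen_CC)
  0.25 * K^2 / sum(group_frequencies(p) * group_risks(r, pen_CC)^2)
}
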