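# 2x2 diagnostic-table analytics: accuracy/sensitivity/specificity, the
# necessary/sufficient classification of a test, the disease-iceberg
# correction, and interval estimation of prevalence from a necessary test
# with a bounded false-positive rate.

#' 2x2 diagnostic table
#'
#' A cohort of size `n` partitioned by disease status `D` and test result
#' `T`: `n11` = D and T (true positives), `n12` = D and T' (false
#' negatives), `n21` = D' and T (false positives), `n22` = D' and T' (true
#' negatives).
#'
#' @param n11,n12,n21,n22 Nonnegative integer cell counts; their sum must be
#'   positive.
#' @return An object of class `"diagnostic_table"`.
#' @seealso [table_rates()], [classify_test()], [estimate_prevalence()],
#'   [read_diagnostic_table()]
#' @examples
#' diagnostic_table(90, 10, 5, 95)
#' @export
diagnostic_table <- function(n11, n12, n21, n22) {
  n11 <- check_count(n11, "n11"); n12 <- check_count(n12, "n12")
  n21 <- check_count(n21, "n21"); n22 <- check_count(n22, "n22")
  n <- n11 + n12 + n21 + n22
  if (n <= 0) stop("the table must contain at least one individual",
                   call. = FALSE)
  structure(list(n11 = n11, n12 = n12, n21 = n21, n22 = n22, n = n),
            class = "diagnostic_table")
}

#' @export
print.diagnostic_table <- function(x, ...) {
  m <- matrix(c(x$n11, x$n21, x$n12, x$n22), 2, 2,
              dimnames = list(c("D", "D'"), c("T", "T'")))
  cat("Diagnostic 2x2 table (n =", x$n, ")\n")
  print(m)
  invisible(x)
}

#' Operating rates of a diagnostic test
#'
#' Computes accuracy `(n11 + n22)/n`, sensitivity `P(T|D)`, specificity
#' `P(T'|D')`, positive predictive value `P(D|T)`, false-positive rate
#' `P(T|D')` and false-negative rate `P(T'|D)`. A rate whose margin is empty
#' (e.g. sensitivity with no diseased individuals) is flagged undefined and
#' returned as `NA`, never silently as 0.
#'
#' @param table A [diagnostic_table()].
#' @return An object of class `"test_rates"`: a list with elements
#'   `accuracy`, `sensitivity`, `specificity`, `ppv`, `fpr`, `fnr`, and
#'   `undefined` (character vector naming any undefined rates).
#' @examples
#' table_rates(diagnostic_table(90, 10, 5, 95))
#' @export
table_rates <- function(table) {
  stopifnot(inherits(table, "diagnostic_table"))
  d_pos <- table$n11 + table$n12   # diseased margin
  d_neg <- table$n21 + table$n22   # disease-free margin
  t_pos <- table$n11 + table$n21   # test-positive margin
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(
    accuracy    = (table$n11 + table$n22) / table$n,
    sensitivity = rate(table$n11, d_pos),
    specificity = rate(table$n22, d_neg),
    ppv         = rate(table$n11, t_pos),
    fpr         = rate(table$n21, d_neg),
    fnr         = rate(table$n12, d_pos)
  )
  out$undefined <- names(out)[vapply(out, function(v) length(v) == 1 && is.na(v),
                                     logical(1))]
  structure(out, class = "test_rates")
}

#' @export
print.test_rates <- function(x, digits = 4, ...) {
  lbl <- c(accuracy = "accuracy", sensitivity = "sensitivity P(T|D)",
           specificity = "specificity P(T'|D')", ppv = "PPV P(D|T)",
           fpr = "false-positive rate P(T|D')",
           fnr = "false-negative rate P(T'|D)")
  for (k in names(lbl)) {
    v <- x[[k]]
    cat(sprintf("  %-28s %s\n", lbl[[k]],
                if (is.na(v)) "undefined (empty margin)"
                else format(v, digits = digits)))
  }
  invisible(x)
}

#' Classify a test as necessary and/or sufficient for the disease
#'
#' A positive result `T` is *necessary* for `D` when false negatives are
#' (approximately) absent (`n12/n <= tol`) and *sufficient* when false
#' positives are (approximately) absent (`n21/n <= tol`). A test that is both
#' induces a diagonal partition of the cohort: an accurate diagnosis.
#'
#' @param table A [diagnostic_table()].
#' @param tol Maximum off-diagonal cell fraction (of `n`) still counted as
#'   "approximately zero"; in `[0, 0.5)`. Default 0.01.
#' @return One of `"neither"`, `"necessary_only"`, `"sufficient_only"`,
#'   `"necessary_and_sufficient"`.
#' @examples
#' classify_test(diagnostic_table(360, 0, 0, 640))   # necessary_and_sufficient
#' classify_test(diagnostic_table(300, 0, 200, 500)) # necessary_only
#' @export
classify_test <- function(table, tol = 0.01) {
  stopifnot(inherits(table, "diagnostic_table"))
  if (!is.numeric(tol) || length(tol) != 1L || tol < 0 || tol >= 0.5)
    stop("'tol' must lie in [0, 0.5)", call. = FALSE)
  necessary  <- table$n12 / table$n <= tol
  sufficient <- table$n21 / table$n <= tol
  if (necessary && sufficient) "necessary_and_sufficient"
  else if (necessary) "necessary_only"
  else if (sufficient) "sufficient_only"
  else "neither"
}

#' Correct a perceived prevalence for the disease-iceberg effect
#'
#' When a fraction `u` of all cases is undiagnosed, the perceived prevalence
#' (diagnosed cases, `P(D and A)`) relates to the actual prevalence by
#' `P(D and A) = (1 - u) P(D)`; the correction is
#' `P(D) = perceived / (1 - u)`.
#'
#' @param perceived Perceived (diagnosed) prevalence, in `[0, 1]`.
#' @param undiagnosed_fraction Fraction `u` of cases that are undiagnosed,
#'   in `[0, 1)`.
#' @return The corrected prevalence `P(D)`.
#' @examples
#' iceberg_true_prevalence(0.036, 0.9)  # 0.36
#' @export
iceberg_true_prevalence <- function(perceived, undiagnosed_fraction) {
  check_prob(perceived, "perceived")
  check_prob(undiagnosed_fraction, "undiagnosed_fraction")
  if (undiagnosed_fraction >= 1)
    stop("'undiagnosed_fraction' must be < 1 (all-undiagnosed is degenerate)",
         call. = FALSE)
  out <- perceived / (1 - undiagnosed_fraction)
  if (out > 1)
    stop("inconsistent inputs: implied prevalence ", signif(out, 4),
         " exceeds 1", call. = FALSE)
  out
}

#' Prevalence interval from a necessary test with bounded false-positive rate
#'
#' When `T` is necessary for `D` and the false-positive rate `P(T|D')` is at
#' most `alpha0`, the prevalence is bracketed by
#' `P(T) - (1 - P(T)) alpha0 / (1 - alpha0) <= P(D) <= P(T)`.
#' The lower bound is clamped at 0. As `alpha0 -> 0` the interval collapses
#' onto `P(T)`: the mechanism by which refining a test makes `P(T)`
#' approach `P(D)`.
#'
#' @param p_t Probability of a positive test, `P(T)`, in `[0, 1]`.
#' @param alpha0 Upper bound for the false-positive rate, in `[0, 1)`.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' prevalence_interval(0.36, 0.3)  # lower ~ 0.086, upper 0.36
#' prevalence_interval(0.36, 0)    # zero width at 0.36
#' @export
prevalence_interval <- function(p_t, alpha0) {
  check_prob(p_t, "p_t")
  if (!is.numeric(alpha0) || length(alpha0) != 1L || alpha0 < 0 || alpha0 >= 1)
    stop("'alpha0' must lie in [0, 1)", call. = FALSE)
  lower <- max(0, p_t - (1 - p_t) * alpha0 / (1 - alpha0))
  c(lower = lower, upper = p_t)
}

#' Upper confidence bound for the false-positive rate
#'
#' Point estimate `alpha_hat = n21 / (n21 + n22)` with a Wald upper bound
#' `alpha_hat + z sqrt(alpha_hat (1 - alpha_hat) / m)`, where `z` is the
#' standard-normal quantile giving the conventional 1.96 multiplier at the
#' default 95% level. The standard-error denominator `m` is the
#' disease-negative margin `n21 + n22` (`denominator = "negatives"`, the
#' binomial sample for `alpha_hat`) or the whole cohort size
#' (`denominator = "total"`, in which case `n` must be supplied).
#'
#' @param n21 False-positive count.
#' @param n22 True-negative count; `n21 + n22 > 0`.
#' @param confidence Confidence level in `(0, 1)`; default 0.95.
#' @param denominator `"negatives"` (default) or `"total"`.
#' @param n Total cohort size, required for `denominator = "total"`.
#' @return The upper bound `alpha0`, capped at 1.
#' @examples
#' fpr_upper_bound(3, 97)                           # ~0.0634
#' fpr_upper_bound(3, 97, denominator = "total", n = 200)  # ~0.0536
#' @export
fpr_upper_bound <- function(n21, n22, confidence = 0.95,
                            denominator = c("negatives", "total"), n = NULL) {
  n21 <- check_count(n21, "n21"); n22 <- check_count(n22, "n22")
  denominator <- match.arg(denominator)
  if (n21 + n22 <= 0)
    stop("false-positive rate is undefined: empty disease-negative margin",
         call. = FALSE)
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence <= 0 || confidence >= 1)
    stop("'confidence' must lie in (0, 1)", call. = FALSE)
  m <- if (denominator == "negatives") n21 + n22 else {
    if (is.null(n)) stop("'n' must be supplied with denominator = \"total\"",
                         call. = FALSE)
    check_count(n, "n")
  }
  alpha_hat <- n21 / (n21 + n22)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  min(1, alpha_hat + z * sqrt(alpha_hat * (1 - alpha_hat) / m))
}

#' Interval estimate of prevalence from a diagnostic table
#'
#' The four-step estimation procedure for a test that is necessary for the
#' disease: (i) verify necessity (`n12/n <= tol`, otherwise the procedure is
#' rejected outright); (ii) estimate `P(T) = (n11 + n21)/n`; (iii) bound the
#' false-positive rate from above via [fpr_upper_bound()]; (iv) substitute
#' into [prevalence_interval()].
#'
#' @param table A [diagnostic_table()].
#' @param confidence Confidence level for step (iii); default 0.95.
#' @param tol Necessity tolerance for step (i); default 0.01.
#' @param denominator Standard-error denominator mode, see
#'   [fpr_upper_bound()].
#' @return An object of class `"prevalence_estimate"`: a list with
#'   `interval` (named `c(lower, upper)`), `p_t`, `alpha_hat`, `alpha0`,
#'   `confidence` and the input `table`.
#' @examples
#' est <- estimate_prevalence(diagnostic_table(330, 0, 30, 640))
#' est$interval
#' @export
estimate_prevalence <- function(table, confidence = 0.95, tol = 0.01,
                                denominator = c("negatives", "total")) {
  stopifnot(inherits(table, "diagnostic_table"))
  denominator <- match.arg(denominator)
  if (table$n12 / table$n > tol)
    stop("procedure rejected: the test is not necessary for the disease ",
         "(false-negative fraction ", signif(table$n12 / table$n, 3),
         " exceeds tol = ", tol, ")", call. = FALSE)
  p_t <- (table$n11 + table$n21) / table$n
  alpha0 <- fpr_upper_bound(table$n21, table$n22, confidence,
                            denominator, n = table$n)
  structure(
    list(interval = prevalence_interval(p_t, alpha0),
         p_t = p_t,
         alpha_hat = table$n21 / (table$n21 + table$n22),
         alpha0 = alpha0,
         confidence = confidence,
         table = table),
    class = "prevalence_estimate"
  )
}

#' @export
print.prevalence_estimate <- function(x, digits = 4, ...) {
  cat("Prevalence interval from a necessary diagnostic test\n")
  cat(sprintf("  P(T) = %s; alpha_hat = %s; alpha0 (upper %s%% bound) = %s\n",
              format(x$p_t, digits = digits),
              format(x$alpha_hat, digits = digits),
              format(100 * x$confidence), format(x$alpha0, digits = digits)))
  cat(sprintf("  P(D) in [%s, %s]\n",
              format(x$interval[["lower"]], digits = digits),
              format(x$interval[["upper"]], digits = digits)))
  invisible(x)
}
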