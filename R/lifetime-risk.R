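# Discrete age-of-detection rate curves f(i) on integer ages 1..100 and
# their cumulative lifetime-risk curves F(i). One curve type serves both the
# age-true-positive and the age-positive-predictive role. Curves are stored
# as fractions (never percentages); F(0) = 0 is implied.

MAX_AGE <- 100L

#' Age-indexed detection-rate curve
#'
#' Validates a sequence of 100 rates `f(i)` indexed by age `i = 1..100`. A
#' valid curve has `0 <= f(i) <= 1`, sums to 1 (a diagnosis that is both
#' necessary and sufficient over the lifetime), and is weakly unimodal:
#' nondecreasing up to some mode age `m`, nonincreasing after (plateaus
#' permitted). A sum within `1e-6` of 1 is renormalised exactly; anything
#' further off is rejected as an inaccurate-diagnosis flag.
#'
#' @param values Numeric vector of 100 rates for ages 1..100.
#' @return An object of class `"age_rate_curve"`: the (renormalised) rates
#'   with the mode age attached as attribute `mode_age` (first age attaining
#'   the maximum).
#' @seealso [cumulative_curve()], [make_bell_curve()], [read_age_rate_curve()]
#' @examples
#' age_rate_curve(rep(0.01, 100))
#' @export
age_rate_curve <- function(values) {
  if (!is.numeric(values) || length(values) != MAX_AGE)
    stop("'values' must be a numeric vector of ", MAX_AGE,
         " rates for ages 1..", MAX_AGE, call. = FALSE)
  if (any(!is.finite(values)))
    stop("curve contains non-finite values", call. = FALSE)
  if (any(values < 0))
    stop("curve violates 0 <= f(i): negative rate at age ",
         which(values < 0)[1], call. = FALSE)
  s <- sum(values)
  if (abs(s - 1) > 1e-6)
    stop("curve rates sum to ", signif(s, 6), ", not 1: the diagnosis does ",
         "not account for all lifetime cases", call. = FALSE)
  values <- values / s
  if (any(values > 1))
    stop("curve violates f(i) <= 1", call. = FALSE)
  # weak unimodality: once the curve strictly decreases it may never strictly
  # increase again
  d <- diff(values)
  eps <- 1e-12
  first_drop <- which(d < -eps)[1]
  if (!is.na(first_drop) && any(d[first_drop:length(d)] > eps))
    stop("curve is not unimodal: it rises again after age ",
         first_drop + which(d[first_drop:length(d)] > eps)[1] - 1,
         call. = FALSE)
  structure(as.numeric(values), names = as.character(seq_len(MAX_AGE)),
            mode_age = which.max(values), class = "age_rate_curve")
}

#' @export
print.age_rate_curve <- function(x, ...) {
  cat("Age detection-rate curve f(i), ages 1..", MAX_AGE,
      " (sum = 1, mode age m = ", attr(x, "mode_age"), ")\n", sep = "")
  print(summary(unclass(unname(x))))
  invisible(x)
}

#' Cumulative lifetime-risk curve
#'
#' Running sum `F(i) = sum_{k <= i} f(k)` of an [age_rate_curve()]. `F` is
#' nondecreasing with `F(100) = 1`: over a full lifetime an accurate
#' diagnosis accounts for every case.
#'
#' @param curve An [age_rate_curve()].
#' @return An object of class `"cumulative_curve"`: 100 cumulative
#'   probabilities.
#' @examples
#' Fu <- cumulative_curve(age_rate_curve(rep(0.01, 100)))
#' Fu[50]  # 0.5
#' @export
cumulative_curve <- function(curve) {
  stopifnot(inherits(curve, "age_rate_curve"))
  structure(cumsum(as.numeric(curve)),
            names = as.character(seq_len(MAX_AGE)),
            mode_age = attr(curve, "mode_age"), class = "cumulative_curve")
}

#' @export
print.cumulative_curve <- function(x, ...) {
  cat("Cumulative lifetime-risk curve F(i), ages 1..", MAX_AGE,
      " (F(100) = ", format(x[[MAX_AGE]]), ")\n", sep = "")
  idx <- c(10, 25, 50, 75, 90, 100)
  print(stats::setNames(round(as.numeric(x)[idx], 4), paste0("F(", idx, ")")))
  invisible(x)
}

#' Fraction of lifetime cases missed by an age-truncated study
#'
#' A study enrolling only people up to `cutoff_age` observes `F(cutoff_age)`
#' of all lifetime cases and therefore underestimates prevalence by
#' `1 - F(cutoff_age)` — substantial for diseases with later-in-life
#' detection.
#'
#' @param cum A [cumulative_curve()] (an [age_rate_curve()] is accepted and
#'   accumulated on the fly).
#' @param cutoff_age Integer age in 1..100.
#' @return The missed fraction `1 - F(cutoff_age)`.
#' @examples
#' f <- make_bell_curve(mode_age = 50, spread = 12)
#' truncation_underestimate(cumulative_curve(f), 55)
#' @export
truncation_underestimate <- function(cum, cutoff_age) {
  if (inherits(cum, "age_rate_curve")) cum <- cumulative_curve(cum)
  stopifnot(inherits(cum, "cumulative_curve"))
  cutoff_age <- check_count(cutoff_age, "cutoff_age")
  if (cutoff_age < 1 || cutoff_age > MAX_AGE)
    stop("'cutoff_age' must lie in 1..", MAX_AGE, call. = FALSE)
  1 - as.numeric(cum)[cutoff_age]
}

#' Synthetic bell-shaped detection-rate curve
#'
#' Deterministic discretisation of a unimodal, possibly skewed density on
#' ages 1..100: a two-piece Gaussian kernel with scale `spread * exp(-skew)`
#' below the mode and `spread * exp(skew)` above it, evaluated at integer
#' ages and normalised to sum 1. The mode is exactly `mode_age`; positive
#' `skew` puts more mass at older ages (later-in-life detection), so
#' `F(mode_age) < 0.5`.
#'
#' @param mode_age Integer mode age `m` in 1..100.
#' @param spread Positive width scale, approximately the standard deviation
#'   in years for the symmetric case.
#' @param skew Signed skew parameter; 0 gives a symmetric bell.
#' @return An [age_rate_curve()].
#' @examples
#' f <- make_bell_curve(50, spread = 10)
#' attr(f, "mode_age")  # 50
#' @export
make_bell_curve <- function(mode_age, spread, skew = 0) {
  mode_age <- check_count(mode_age, "mode_age")
  if (mode_age < 1 || mode_age > MAX_AGE)
    stop("'mode_age' must lie in 1..", MAX_AGE, call. = FALSE)
  if (!is.numeric(spread) || length(spread) != 1L || !is.finite(spread) ||
      spread <= 0)
    stop("'spread' must be a positive scale", call. = FALSE)
  if (!is.numeric(skew) || length(skew) != 1L || !is.finite(skew))
    stop("'skew' must be a finite number", call. = FALSE)
  ages <- seq_len(MAX_AGE)
  s <- ifelse(ages < mode_age, spread * exp(-skew), spread * exp(skew))
  f <- exp(-0.5 * ((ages - mode_age) / s)^2)
  if (!any(f > 0))
    stop("parameters produce a curve with no support on ages 1..", MAX_AGE,
         call. = FALSE)
  age_rate_curve(f / sum(f))
}

#' Plot an age-rate or cumulative curve
#'
#' @param x An [age_rate_curve()] or [cumulative_curve()].
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.age_rate_curve <- function(x, ...) {
  graphics::plot(seq_len(MAX_AGE), as.numeric(x), type = "h",
                 xlab = "age (years)", ylab = "detection rate f(i)", ...)
  graphics::abline(v = attr(x, "mode_age"), lty = 3)
  invisible(x)
}

#' @rdname plot.age_rate_curve
#' @export
plot.cumulative_curve <- function(x, ...) {
  graphics::plot(seq_len(MAX_AGE), as.numeric(x), type = "s",
                 xlab = "age (years)", ylab = "cumulative risk F(i)",
                 ylim = c(0, 1), ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
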