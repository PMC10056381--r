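# Closed-form prevalence of a disease caused by a dominant allele, in the
# autosomal two-allele model under Hardy-Weinberg equilibrium. Genotype
# frequencies are p^2 (CC), 2pq (Cc, phase ignored) and q^2 (cc) with
# q = 1 - p; no inbreeding coefficient.

#' Penetrance ratio of the heterozygote to the homozygote
#'
#' For a disease caused by a dominant allele `C`, the penetrance ratio is
#' `r = P(D|Cc) / P(D|CC)`. The dominant-disease configuration requires
#' `0 < P(D|Cc) <= P(D|CC)`, so `r` lies in `(0, 1]`.
#'
#' @param pen_CC Penetrance of the `CC` genotype, `P(D|CC)`, in `(0, 1]`.
#' @param pen_Cc Penetrance of the `Cc` genotype, `P(D|Cc)`, in `(0, pen_CC]`.
#' @return The ratio `pen_Cc / pen_CC`, a value in `(0, 1]`.
#' @examples
#' penetrance_ratio(1, 0.5)
#' penetrance_ratio(0.8, 0.4)
#' @export
penetrance_ratio <- function(pen_CC, pen_Cc) {
  check_prob(pen_CC, "pen_CC")
  check_prob(pen_Cc, "pen_Cc")
  if (pen_CC == 0)
    stop("penetrance ratio is undefined when pen_CC = 0", call. = FALSE)
  if (pen_Cc > pen_CC)
    stop("'pen_Cc' must not exceed 'pen_CC' for a dominant disease ",
         "(0 < r <= 1 requires 0 < P(D|Cc) <= P(D|CC))", call. = FALSE)
  if (pen_Cc <= 0)
    stop("'pen_Cc' must be positive for a dominant disease", call. = FALSE)
  pen_Cc / pen_CC
}

#' Dominant-allele disease model
#'
#' Bundles the three parameters that completely characterise the theoretical
#' prevalence of a disease caused by a dominant allele: the frequency `p` of
#' the dominant allele `C`, the penetrance ratio `r = P(D|Cc)/P(D|CC)`, and
#' the penetrance `P(D|CC)` of the homozygous genotype. The recessive
#' homozygote is unaffected (`P(D|cc) = 0`). Hardy-Weinberg genotype
#' frequencies are assumed.
#'
#' Either `r` or `pen_Cc` (from which `r` is derived) must be supplied. If
#' both are given they must agree to within `1e-9`.
#'
#' @param p Frequency of the dominant allele `C`, in `[0, 1]`.
#' @param r Penetrance ratio `P(D|Cc)/P(D|CC)`, in `(0, 1]`.
#' @param pen_CC Penetrance of `CC`, in `(0, 1]` (default 1, full penetrance).
#' @param pen_Cc Optional penetrance of `Cc`; an alternative way to fix `r`.
#' @return An object of class `"dominant_model"`: a list with elements
#'   `p`, `q = 1 - p`, `r`, `pen_CC`, `pen_Cc = r * pen_CC`, `pen_cc = 0`.
#' @seealso [prevalence()], [offspring_groups()], [sibling_risk()],
#'   [simulate_cohort()]
#' @examples
#' m <- dominant_model(p = 0.2, r = 1)
#' prevalence(m)      # 0.36
#' summary(m)
#' @export
dominant_model <- function(p, r = NULL, pen_CC = 1, pen_Cc = NULL) {
  check_prob(p, "p")
  check_prob(pen_CC, "pen_CC")
  if (pen_CC == 0)
    stop("'pen_CC' must be positive for a dominant disease", call. = FALSE)
  if (is.null(r) && is.null(pen_Cc))
    stop("supply the penetrance ratio 'r' or the heterozygote penetrance 'pen_Cc'",
         call. = FALSE)
  if (!is.null(pen_Cc)) {
    r_derived <- penetrance_ratio(pen_CC, pen_Cc)
    if (!is.null(r) && abs(r - r_derived) > 1e-9)
      stop("'r' (", r, ") and pen_Cc/pen_CC (", signif(r_derived, 10),
           ") disagree by more than 1e-9", call. = FALSE)
    r <- r_derived
  }
  check_ratio_r(r)
  structure(
    list(p = p, q = 1 - p, r = r,
         pen_CC = pen_CC, pen_Cc = r * pen_CC, pen_cc = 0),
    class = "dominant_model"
  )
}

#' General prevalence from genotype frequencies and penetrances
#'
#' Prevalence from the law of total probability over the genotype partition:
#' `P(D) = p^2 P(D|CC) + 2pq P(D|Cc) + q^2 P(D|cc)`. This form is fully
#' general (it does not assume dominance), so `pen_cc` may be nonzero.
#'
#' @param p Frequency of the `C` allele.
#' @param pen_CC,pen_Cc,pen_cc Genotype penetrances, each in `[0, 1]`.
#' @return Prevalence `P(D)`, in `[0, 1]`.
#' @examples
#' prevalence_general(0.2, 1, 1, 0)    # 0.36
#' prevalence_general(0.2, 1, 0.5, 0)  # 0.20
#' @export
prevalence_general <- function(p, pen_CC, pen_Cc, pen_cc = 0) {
  check_prob(p, "p")
  check_prob(pen_CC, "pen_CC")
  check_prob(pen_Cc, "pen_Cc")
  check_prob(pen_cc, "pen_cc")
  q <- 1 - p
  p^2 * pen_CC + 2 * p * q * pen_Cc + q^2 * pen_cc
}

#' Dominant-disease prevalence in the (p, r, P(D|CC)) parameterisation
#'
#' The closed form `P(D) = p (2r + (1 - 2r) p) P(D|CC)`, algebraically equal
#' to [prevalence_general()] with `pen_Cc = r * pen_CC` and `pen_cc = 0`.
#'
#' @param p Frequency of the `C` allele.
#' @param r Penetrance ratio, in `(0, 1]`.
#' @param pen_CC Penetrance of `CC`, in `(0, 1]`.
#' @return Prevalence `P(D)`, in `[0, 1]`.
#' @examples
#' prevalence_dominant(0.2, 1, 1)    # 0.36
#' prevalence_dominant(0.2, 0.5, 1)  # 0.20 (linear case)
#' @export
prevalence_dominant <- function(p, r, pen_CC = 1) {
  check_prob(p, "p")
  check_ratio_r(r)
  check_prob(pen_CC, "pen_CC")
  p * (2 * r + (1 - 2 * r) * p) * pen_CC
}

#' @rdname prevalence_dominant
#' @param x A [dominant_model()] object.
#' @param ... Unused.
#' @export
prevalence <- function(x, ...) UseMethod("prevalence")

#' @export
prevalence.dominant_model <- function(x, ...) {
  prevalence_dominant(x$p, x$r, x$pen_CC)
}

#' Envelope bounds on dominant-disease prevalence
#'
#' For any penetrance ratio `0 < r <= 1`, prevalence satisfies
#' `p^2 P(D|CC) < P(D) <= p (2 - p) P(D|CC)`. The lower bound (the `r -> 0`
#' limit) is exclusive; the upper bound (`r = 1`) is attained. A prevalence
#' estimate falling outside this envelope indicates diagnostic error.
#'
#' @param p Frequency of the `C` allele.
#' @param pen_CC Penetrance of `CC`, in `(0, 1]`.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' prevalence_envelope(0.2, 1)   # (0.04, 0.36)
#' @export
prevalence_envelope <- function(p, pen_CC = 1) {
  check_prob(p, "p")
  check_prob(pen_CC, "pen_CC")
  c(lower = p^2 * pen_CC, upper = p * (2 - p) * pen_CC)
}

#' Curvature of prevalence as a function of allele frequency
#'
#' Prevalence `P(D) = p (2r + (1 - 2r) p) P(D|CC)` is a parabola in `p` whose
#' curvature is set by the penetrance ratio: concave down for `1/2 < r <= 1`,
#' linear for `r = 1/2`, concave up for `0 < r < 1/2`.
#'
#' @param r Penetrance ratio, in `(0, 1]`.
#' @return One of `"concave_down"`, `"linear"`, `"concave_up"`.
#' @examples
#' curvature_class(1)     # "concave_down"
#' curvature_class(0.25)  # "concave_up"
#' @export
curvature_class <- function(r) {
  check_ratio_r(r)
  if (r == 0.5) "linear" else if (r > 0.5) "concave_down" else "concave_up"
}

#' Frequency of the disease-causing genotypes
#'
#' `P(G) = p^2 + 2pq`, the combined Hardy-Weinberg frequency of `CC` and
#' `Cc`. Under full penetrance of both genotypes this equals the prevalence.
#'
#' @param p Frequency of the `C` allele.
#' @return `P(G)`, in `[0, 1]`.
#' @examples
#' genotype_frequency(0.2)  # 0.36
#' @export
genotype_frequency <- function(p) {
  check_prob(p, "p")
  p^2 + 2 * p * (1 - p)
}

#' Are the disease-causing genotypes sufficient for the disease?
#'
#' The genotypes `CC` and `Cc` are always *necessary* for a dominant disease;
#' they are *sufficient* if and only if both are fully penetrant
#' (`P(D|CC) = 1` and `P(D|Cc) = 1`), in which case `P(D) = P(G)` for every
#' allele frequency.
#'
#' @param pen_CC Penetrance of `CC`, or a [dominant_model()] object.
#' @param pen_Cc Penetrance of `Cc` (ignored when a model is supplied).
#' @return `TRUE` or `FALSE`.
#' @examples
#' genotype_sufficiency_holds(1, 1)    # TRUE
#' genotype_sufficiency_holds(1, 0.5)  # FALSE
#' @export
genotype_sufficiency_holds <- function(pen_CC, pen_Cc) {
  if (inherits(pen_CC, "dominant_model")) {
    pen_Cc <- pen_CC$pen_Cc
    pen_CC <- pen_CC$pen_CC
  }
  isTRUE(pen_CC == 1 && pen_Cc == 1)
}

#' @export
print.dominant_model <- function(x, digits = 4, ...) {
  cat("Dominant-allele disease model (Hardy-Weinberg)\n")
  cat(sprintf("  allele frequencies: p = P(C) = %s, q = P(c) = %s\n",
              format(x$p, digits = digits), format(x$q, digits = digits)))
  cat(sprintf("  penetrances: P(D|CC) = %s, P(D|Cc) = %s, P(D|cc) = 0  (r = %s)\n",
              format(x$pen_CC, digits = digits),
              format(x$pen_Cc, digits = digits),
              format(x$r, digits = digits)))
  env <- prevalence_envelope(x$p, x$pen_CC)
  cat(sprintf("  prevalence P(D) = %s  [envelope (%s, %s], %s in p]\n",
              format(prevalence(x), digits = digits),
              format(env[["lower"]], digits = digits),
              format(env[["upper"]], digits = digits),
              sub("_", " ", curvature_class(x$r))))
  invisible(x)
}

#' @export
summary.dominant_model <- function(object, ...) {
  structure(
    list(model = object,
         prevalence = prevalence(object),
         envelope = prevalence_envelope(object$p, object$pen_CC),
         curvature = curvature_class(object$r),
         genotype_frequency = genotype_frequency(object$p),
         sufficiency = genotype_sufficiency_holds(object),
         groups = offspring_groups(object),
         siblings = sibling_risk(object)),
    class = "summary.dominant_model"
  )
}

#' @export
print.summary.dominant_model <- function(x, digits = 4, ...) {
  print(x$model, digits = digits)
  cat(sprintf("  P(G) = P(CC or Cc) = %s; genotypes sufficient for disease: %s\n",
              format(x$genotype_frequency, digits = digits),
              if (x$sufficiency) "yes (fully penetrant)" else "no"))
  cat("\nOffspring groups:\n")
  print(x$groups, digits = digits)
  cat("\n")
  print(x$siblings, digits = digits)
  invisible(x)
}

#' Plot prevalence against allele frequency
#'
#' Draws `P(D)` as a function of `p` for the model's penetrance ratio,
#' together with the envelope bounds (`r -> 0` and `r = 1` curves), marking
#' the model's own operating point.
#'
#' @param x A [dominant_model()] object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dominant_model <- function(x, ...) {
  pp <- seq(0, 1, length.out = 201)
  up <- pp * (2 - pp) * x$pen_CC
  lo <- pp^2 * x$pen_CC
  mid <- vapply(pp, prevalence_dominant, numeric(1), r = x$r, pen_CC = x$pen_CC)
  graphics::plot(pp, up, type = "n", xlab = "allele frequency p",
                 ylab = "prevalence P(D)", ylim = c(0, x$pen_CC), ...)
  graphics::polygon(c(pp, rev(pp)), c(up, rev(lo)),
                    col = "grey92", border = NA)
  graphics::lines(pp, up, lty = 2)
  graphics::lines(pp, lo, lty = 2)
  graphics::lines(pp, mid, lwd = 2, col = "steelblue")
  graphics::points(x$p, prevalence(x), pch = 19, col = "firebrick")
  invisible(x)
}

# input checks shared across modules -----------------------------------------

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop("'", name, "' must be a single probability in [0, 1]", call. = FALSE)
  invisible(x)
}

check_ratio_r <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0 || r > 1)
    stop("penetrance ratio 'r' must lie in (0, 1] for a dominant disease",
         call. = FALSE)
  invisible(r)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 ||
      x != round(x))
    stop("'", name, "' must be a single nonnegative integer count",
         call. = FALSE)
  invisible(as.integer(x))
}
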