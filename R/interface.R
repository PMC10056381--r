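# Text I/O for the standard inputs (2x2 tables, age-rate curves), the
# reproduction suite for the framework's canonical worked example, and the
# dispatcher behind the exec/domrisk command-line script. Probabilities are
# fractions everywhere internally; percent rendering happens only at the
# presentation layer. CSV dialect: comma-separated, UTF-8, header row,
# "." decimal.

#' Read and write a 2x2 diagnostic table
#'
#' File format: CSV with header `,T,Tprime` and rows labelled `D` and
#' `Dprime`, matching the disease-by-test orientation of
#' [diagnostic_table()].
#'
#' @param path File path.
#' @return `read_diagnostic_table()` returns a [diagnostic_table()];
#'   `write_diagnostic_table()` returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write_diagnostic_table(diagnostic_table(330, 0, 30, 640), tf)
#' read_diagnostic_table(tf)
#' @export
read_diagnostic_table <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  need_rows <- c("D", "Dprime"); need_cols <- c("T", "Tprime")
  if (!all(need_rows %in% rownames(df)) || !all(need_cols %in% colnames(df)))
    stop("diagnostic-table file must have rows D, Dprime and columns ",
         "T, Tprime", call. = FALSE)
  diagnostic_table(df["D", "T"], df["D", "Tprime"],
                   df["Dprime", "T"], df["Dprime", "Tprime"])
}

#' @rdname read_diagnostic_table
#' @param table A [diagnostic_table()].
#' @export
write_diagnostic_table <- function(table, path) {
  stopifnot(inherits(table, "diagnostic_table"))
  df <- data.frame(T = c(table$n11, table$n21),
                   Tprime = c(table$n12, table$n22),
                   row.names = c("D", "Dprime"))
  utils::write.csv(df, path)
  invisible(path)
}

#' Read and write an age-rate curve
#'
#' File format: CSV with columns `age` (integers 1..100) and `rate`. Rates
#' are fractions by default; `percent = TRUE` divides by 100 on read (and
#' multiplies on write).
#'
#' @param path File path.
#' @param percent Are/should rates (be) expressed as percentages?
#' @return `read_age_rate_curve()` returns an [age_rate_curve()];
#'   `write_age_rate_curve()` returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write_age_rate_curve(make_bell_curve(50, 10), tf)
#' read_age_rate_curve(tf)
#' @export
read_age_rate_curve <- function(path, percent = FALSE) {
  df <- utils::read.csv(path)
  if (!all(c("age", "rate") %in% colnames(df)))
    stop("curve file must have columns 'age' and 'rate'", call. = FALSE)
  df <- df[order(df$age), ]
  if (!identical(as.integer(df$age), seq_len(MAX_AGE)))
    stop("curve file must contain exactly the integer ages 1..", MAX_AGE,
         call. = FALSE)
  rate <- if (isTRUE(percent)) df$rate / 100 else df$rate
  age_rate_curve(rate)
}

#' @rdname read_age_rate_curve
#' @param curve An [age_rate_curve()].
#' @export
write_age_rate_curve <- function(curve, path, percent = FALSE) {
  stopifnot(inherits(curve, "age_rate_curve"))
  rate <- as.numeric(curve)
  if (isTRUE(percent)) rate <- 100 * rate
  utils::write.csv(data.frame(age = seq_len(MAX_AGE), rate = rate),
                   path, row.names = FALSE)
  invisible(path)
}

#' Reproduce the framework's canonical worked example
#'
#' Recomputes, from the package's own functions, every headline quantity of
#' the canonical dominant-disease example (p = 0.2, r = 1, full penetrance)
#' and its companions — the prevalence, the diagnostic interval at a
#' false-positive bound of 0.3, the iceberg correction, the recurrence-risk
#' ratio tables across three (p, r) settings, the proportion decomposition,
#' the sibling predictions, the lambda_s identity and the F6 population
#' share — and compares each against its reference value at the stated
#' tolerance.
#'
#' @return A `data.frame` of class `"reproduction_report"` with columns
#'   `check`, `computed`, `reference`, `tolerance`, `pass`; attribute
#'   `all_pass` summarises the run.
#' @examples
#' rep <- run_reproduction_suite()
#' attr(rep, "all_pass")
#' @export
run_reproduction_suite <- function() {
  m <- dominant_model(0.2, r = 1)
  pred <- sibling_prediction(m)
  sib <- sibling_risk(m)
  mu_a <- recurrence_risk_ratios(0.2, 1)
  mu_b <- recurrence_risk_ratios(0.2, 0.5)
  mu_c <- recurrence_risk_ratios(0.02, 1)
  props <- group_proportions(0.2, 1)

  rows <- list(
    list("prevalence P(D) at (0.2, 1, 1)", prevalence(m), 0.36, 1e-12),
    list("interval lower bound at P(T)=0.36, alpha0=0.3",
         prevalence_interval(0.36, 0.3)[["lower"]], 0.086, 5e-4),
    list("interval upper bound at P(T)=0.36, alpha0=0.3",
         prevalence_interval(0.36, 0.3)[["upper"]], 0.36, 1e-12),
    list("iceberg correction of 0.036 with 90% undiagnosed",
         iceberg_true_prevalence(0.036, 0.9), 0.36, 1e-12),
    list("mu1 at (0.2, 1)", mu_a[["F1"]], 2.78, 5e-3),
    list("mu4 at (0.2, 1)", mu_a[["F4"]], 2.08, 5e-3),
    list("mu5 at (0.2, 1)", mu_a[["F5"]], 1.39, 5e-3),
    list("mu1 at (0.2, 0.5)", mu_b[["F1"]], 5.00, 5e-3),
    list("mu2 at (0.2, 0.5)", mu_b[["F2"]], 3.75, 5e-3),
    list("mu1 at (0.02, 1)", mu_c[["F1"]], 25.25, 5e-3),
    list("mu5 at (0.02, 1)", mu_c[["F5"]], 12.63, 5e-3),
    list("F5 proportion at (0.2, 1)", props[["F5"]], 0.569, 5e-4),
    list("proportion sum", sum(props), 1, 1e-9),
    list("F6 frequency at p=0.2", group_frequencies(0.2)[["F6"]],
         0.4096, 1e-12),
    list("sibling risk Ks equals K", sib$Ks, sib$K, 1e-12),
    list("lambda_s", sib$lambda_s, 1, 1e-12),
    list("phi_s by enumeration", phi_s_zero_share(), 0.25, 0),
    list("F5-only sibling prediction", pred$f5_only, 0.50, 5e-3),
    list("weighted sibling prediction", pred$weighted, 0.66, 5e-3)
  )
  out <- data.frame(
    check = vapply(rows, `[[`, character(1), 1),
    computed = vapply(rows, `[[`, numeric(1), 2),
    reference = vapply(rows, `[[`, numeric(1), 3),
    tolerance = vapply(rows, `[[`, numeric(1), 4),
    stringsAsFactors = FALSE
  )
  out$pass <- abs(out$computed - out$reference) <= out$tolerance
  structure(out, class = c("reproduction_report", "data.frame"),
            all_pass = all(out$pass))
}

#' @export
print.reproduction_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$computed <- signif(df$computed, 6)
  df$status <- ifelse(df$pass, "ok", "FAIL")
  df$pass <- NULL
  print.data.frame(df, row.names = FALSE)
  cat(if (attr(x, "all_pass")) "\nAll checks passed.\n"
      else "\nSOME CHECKS FAILED.\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# command-line dispatcher (used by exec/domrisk)
#
# subcommands: prevalence, diagnose, lifetime, groups, simulate, reproduce.
# Flags are --key value (or --key=value); probabilities are fractions, ages
# integers 1..100. Output is key: value text; --out writes CSV.

cli_main <- function(args, out = stdout()) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cli_usage(out)
    return(invisible(0L))
  }
  sub <- args[1]
  opts <- cli_parse_flags(args[-1])
  emit <- function(...) writeLines(sprintf(...), con = out)
  status <- 0L
  switch(sub,
    prevalence = {
      p <- cli_num(opts, "p", required = TRUE)
      pen_CC <- cli_num(opts, "pen-CC", default = 1)
      m <- dominant_model(p, r = cli_num(opts, "r"),
                          pen_CC = pen_CC, pen_Cc = cli_num(opts, "pen-Cc"))
      env <- prevalence_envelope(p, pen_CC)
      emit("prevalence: %.10g", prevalence(m))
      emit("envelope_lower: %.10g", env[["lower"]])
      emit("envelope_upper: %.10g", env[["upper"]])
      emit("curvature: %s", curvature_class(m$r))
      if (!is.null(opts[["out"]]))
        utils::write.csv(data.frame(p = p, r = m$r, pen_CC = pen_CC,
                                    prevalence = prevalence(m),
                                    envelope_lower = env[["lower"]],
                                    envelope_upper = env[["upper"]],
                                    curvature = curvature_class(m$r)),
                         opts[["out"]], row.names = FALSE)
    },
    diagnose = {
      tab <- if (!is.null(opts[["file"]])) read_diagnostic_table(opts[["file"]])
             else diagnostic_table(cli_num(opts, "n11", required = TRUE),
                                   cli_num(opts, "n12", required = TRUE),
                                   cli_num(opts, "n21", required = TRUE),
                                   cli_num(opts, "n22", required = TRUE))
      rates <- table_rates(tab)
      for (k in c("accuracy", "sensitivity", "specificity", "ppv",
                  "fpr", "fnr"))
        emit("%s: %s", k, if (is.na(rates[[k]])) "undefined"
                          else sprintf("%.10g", rates[[k]]))
      tol <- cli_num(opts, "tol", default = 0.01)
      emit("classification: %s", classify_test(tab, tol))
      est <- tryCatch(
        estimate_prevalence(tab, cli_num(opts, "confidence", default = 0.95),
                            tol = tol),
        error = function(e) e)
      if (inherits(est, "error")) {
        emit("interval: rejected (%s)", conditionMessage(est))
      } else {
        emit("p_t: %.10g", est$p_t)
        emit("alpha0: %.10g", est$alpha0)
        emit("interval_lower: %.10g", est$interval[["lower"]])
        emit("interval_upper: %.10g", est$interval[["upper"]])
      }
    },
    lifetime = {
      curve <- read_age_rate_curve(cli_file(opts), percent =
                                     isTRUE(opts[["percent"]] == "true"))
      cum <- cumulative_curve(curve)
      emit("mode_age: %d", attr(curve, "mode_age"))
      cutoffs <- opts[["cutoff"]]
      if (!is.null(cutoffs))
        for (co in as.integer(strsplit(cutoffs, ",")[[1]]))
          emit("truncation_underestimate_%d: %.10g", co,
               truncation_underestimate(cum, co))
      if (!is.null(opts[["out"]]))
        utils::write.csv(data.frame(age = seq_len(MAX_AGE),
                                    rate = as.numeric(curve),
                                    cumulative = as.numeric(cum)),
                         opts[["out"]], row.names = FALSE)
    },
    groups = {
      m <- dominant_model(cli_num(opts, "p", required = TRUE),
                          r = cli_num(opts, "r", required = TRUE),
                          pen_CC = cli_num(opts, "pen-CC", default = 1))
      tab <- offspring_groups(m, lethal_CC =
                                isTRUE(opts[["lethal-CC"]] == "true"))
      df <- as.data.frame(tab)
      for (i in seq_len(nrow(df)))
        emit("%s: freq=%.6g risk=%.6g mu=%.6g proportion=%.6g",
             df$group[i], df$frequency[i], df$risk[i], df$mu[i],
             df$proportion[i])
      if (!is.null(opts[["out"]]))
        utils::write.csv(df, opts[["out"]], row.names = FALSE)
    },
    simulate = {
      if (is.null(opts[["seed"]]))
        stop("simulate: --seed is mandatory for a reproducible summary",
             call. = FALSE)
      cfg <- if (!is.null(opts[["config"]])) cli_read_config(opts[["config"]])
             else list()
      getp <- function(key, default = NULL) {
        v <- opts[[key]]
        if (is.null(v)) v <- cfg[[gsub("-", "_", key)]]
        if (is.null(v)) default else as.numeric(v)
      }
      m <- dominant_model(getp("p"), r = getp("r"),
                          pen_CC = getp("pen-CC", 1))
      cohort <- simulate_cohort(
        m, n_families = getp("n-families", 1000),
        offspring_per_family = getp("offspring-per-family", 2),
        sensitivity = getp("sensitivity", 1), fpr = getp("fpr", 0),
        ascertainment = {
          a <- opts[["ascertainment"]]
          if (is.null(a)) a <- cfg$ascertainment
          if (is.null(a)) "none" else a
        },
        seed = as.integer(opts[["seed"]]))
      est <- estimate_statistics(cohort)
      emit("K_hat: %.10g", est$K_hat)
      emit("P_T_hat: %.10g", est$P_T_hat)
      emit("Ks_pairs: %.10g", est$Ks_pairs)
      emit("lambda_s_hat: %.10g", est$lambda_s_hat)
      if (!is.null(opts[["out"]])) {
        off <- cohort$offspring
        fam <- cohort$families
        utils::write.csv(
          cbind(off, group = fam$group[off$family],
                father = fam$father[off$family],
                mother = fam$mother[off$family]),
          opts[["out"]], row.names = FALSE)
      }
      if (!is.null(opts[["summary-out"]]))
        utils::write.csv(
          data.frame(K_hat = est$K_hat, P_T_hat = est$P_T_hat,
                     Ks_pairs = est$Ks_pairs, Ks_mixed = est$Ks_mixed,
                     lambda_s_hat = est$lambda_s_hat,
                     seed = as.integer(opts[["seed"]])),
          opts[["summary-out"]], row.names = FALSE)
    },
    reproduce = {
      rep <- run_reproduction_suite()
      for (i in seq_len(nrow(rep)))
        emit("%s: computed=%.6g reference=%.6g %s", rep$check[i],
             rep$computed[i], rep$reference[i],
             if (rep$pass[i]) "ok" else "FAIL")
      if (!attr(rep, "all_pass")) {
        emit("failed: %s", paste(rep$check[!rep$pass], collapse = "; "))
        status <- 1L
      }
    },
    {
      cli_usage(out)
      stop("unknown subcommand: ", sub, call. = FALSE)
    }
  )
  invisible(status)
}

cli_usage <- function(out = stdout()) {
  writeLines(c(
    "usage: domrisk <subcommand> [--flag value ...]",
    "",
    "subcommands:",
    "  prevalence  --p P [--r R | --pen-Cc X] [--pen-CC Y] [--out csv]",
    "              dominant-disease prevalence, envelope and curvature",
    "  diagnose    --n11 A --n12 B --n21 C --n22 D | --file table.csv",
    "              [--confidence 0.95] [--tol 0.01]",
    "              2x2 test rates, classification, prevalence interval",
    "  lifetime    --file curve.csv [--percent true] [--cutoff 55,70]",
    "              [--out csv]   cumulative risk and truncation losses",
    "  groups      --p P --r R [--pen-CC Y] [--lethal-CC true] [--out csv]",
    "              offspring-group table (frequency, risk, mu, proportion)",
    "  simulate    --p P --r R --seed S [--n-families N] [--pen-CC Y]",
    "              [--offspring-per-family K] [--sensitivity S] [--fpr F]",
    "              [--ascertainment none|exclude_F6|proband]",
    "              [--config file] [--out csv] [--summary-out csv]",
    "  reproduce   recompute the canonical worked example (exit 1 on",
    "              failure)",
    "",
    "conventions: probabilities are fractions in [0,1]; ages are integers",
    "1..100; CSV output is comma-separated with a header row."),
    con = out)
}

cli_parse_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("expected a --flag, got: ", a, call. = FALSE)
    a <- substring(a, 3)
    if (grepl("=", a, fixed = TRUE)) {
      kv <- strsplit(a, "=", fixed = TRUE)[[1]]
      opts[[kv[1]]] <- paste(kv[-1], collapse = "=")
      i <- i + 1
    } else {
      if (i + 1 > length(args))
        stop("flag --", a, " needs a value", call. = FALSE)
      opts[[a]] <- args[i + 1]
      i <- i + 2
    }
  }
  opts
}

cli_num <- function(opts, key, default = NULL, required = FALSE) {
  v <- opts[[key]]
  if (is.null(v)) {
    if (required) stop("missing required flag --", key, call. = FALSE)
    return(default)
  }
  out <- suppressWarnings(as.numeric(v))
  if (is.na(out)) stop("flag --", key, " must be numeric, got: ", v,
                       call. = FALSE)
  out
}

cli_file <- function(opts) {
  if (is.null(opts[["file"]]))
    stop("missing required flag --file", call. = FALSE)
  opts[["file"]]
}

# key = value text config, keys matching simulate flag names with underscores
cli_read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("bad config line: ", ln, call. = FALSE)
    cfg[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
  }
  num_keys <- intersect(names(cfg),
                        c("p", "r", "pen_CC", "sensitivity", "fpr",
                          "n_families", "offspring_per_family", "seed"))
  cfg[num_keys] <- lapply(cfg[num_keys], as.numeric)
  cfg
}
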