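#' Construct a 2x2 case-control table
#'
#' Cell layout: `a` factor-positive cases (dead), `b` factor-positive
#' controls (alive), `c` factor-negative cases, `d` factor-negative
#' controls.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param stratum_label,factor_label Optional labels carried into results.
#' @return An object of class `table2x2`.
#' @export
#' @examples
#' table2x2(10, 20, 5, 40)
table2x2 <- function(a, b, c, d, stratum_label = "", factor_label = "") {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    abort_glue("table cells must be non-negative integers")
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), stratum_label = stratum_label,
                 factor_label = factor_label),
            class = "table2x2")
}

#' @export
print.table2x2 <- function(x, ...) {
  cat("<2x2>", x$factor_label, if (nzchar(x$stratum_label))
    paste0("[", x$stratum_label, "]") else "", "\n")
  m <- matrix(c(x$a, x$c, x$b, x$d), 2,
              dimnames = list(c("factor+", "factor-"), c("case", "control")))
  print(m)
  invisible(x)
}

#' Tabulate a cohort factor against outcome
#'
#' Cases are individuals with outcome `"dead"`. The factor is any locus
#' (dichotomised at `risk_level` vs the other allele) or exposure column.
#'
#' @param cohort A cohort with outcomes set.
#' @param factor Column name of a locus or exposure.
#' @param risk_level Level counted as factor-positive; defaults to the
#'   locus's first allele, or `1` for an exposure.
#' @param stratum_filter Optional character vector of stratum names, or a
#'   predicate `function(cohort) -> logical`, restricting the tabulated
#'   subcohort.
#' @return A [table2x2()].
#' @export
#' @examples
#' co <- generate_cohort(builtin_scenario("two_island_fox")) |> apply_outcomes()
#' build_table(co, "colour", "black", stratum_filter = "snow_island")
build_table <- function(cohort, factor, risk_level = NULL,
                        stratum_filter = NULL) {
  if (any(cohort$outcome == "unset"))
    abort_glue("outcomes not set; run apply_outcomes() first")
  available <- setdiff(names(cohort), c("id", "stratum", "outcome"))
  if (!factor %in% available)
    abort_glue("unknown factor '", factor, "'; available factors: ",
               paste(available, collapse = ", "))
  if (is.null(risk_level)) {
    info <- attr(cohort, "locus_info")
    risk_level <- if (!is.null(info) && factor %in% info$locus)
      info$risk_level[match(factor, info$locus)] else 1
  }
  sub <- if (is.null(stratum_filter)) cohort
         else if (is.function(stratum_filter)) cohort[stratum_filter(cohort), ]
         else dplyr::filter(cohort, .data$stratum %in% stratum_filter)
  if (nrow(sub) == 0L)
    abort_glue("empty subcohort after applying the stratum filter")
  pos <- sub[[factor]] == risk_level
  dead <- sub$outcome == "dead"
  table2x2(sum(pos & dead), sum(pos & !dead), sum(!pos & dead), sum(!pos & !dead),
           stratum_label = if (is.character(stratum_filter))
             paste(stratum_filter, collapse = "+") else "",
           factor_label = paste0(factor, "=", risk_level))
}

# --- vectorised primitives shared by odds_ratio() and stratified_scan() ----

# Pearson chi-square p (no continuity correction); degenerate margins -> p 1
chi2_p <- function(a, b, c, d) {
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  stat <- ifelse(den == 0, NA_real_, n * (a * d - b * c)^2 / den)
  ifelse(is.na(stat), 1, stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

fisher_p <- function(a, b, c, d) {
  mapply(function(a, b, c, d) {
    if (a + b + c + d == 0) return(NA_real_)
    stats::fisher.test(matrix(c(a, c, b, d), 2L))$p.value
  }, a, b, c, d)
}

# vectorised estimate + CI + p for many 2x2 tables at once
effect_from_counts <- function(a, b, c, d,
                               policy = c("haldane_anscombe", "none",
                                          "report_infinite"),
                               method = c("auto", "fisher_exact", "chi2", "wald"),
                               ci_level = 0.95) {
  policy <- match.arg(policy)
  method <- match.arg(method)
  n <- length(a)
  raw_or <- (a * d) / (b * c) # may be Inf/NaN; always recorded
  any_zero <- (a == 0) | (b == 0) | (c == 0) | (d == 0)
  degenerate <- (a + b == 0) | (c + d == 0)

  if (policy == "haldane_anscombe") {
    aa <- a + 0.5 * any_zero; bb <- b + 0.5 * any_zero
    cc <- c + 0.5 * any_zero; dd <- d + 0.5 * any_zero
  } else {
    aa <- a; bb <- b; cc <- c; dd <- d
  }
  or <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  if (policy == "report_infinite") {
    inf_mask <- (b * c == 0) & (a * d > 0)
    or[inf_mask] <- Inf
    se[inf_mask] <- NA_real_
  }
  if (policy == "none") se[any_zero] <- NA_real_
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  ci_low <- exp(log(or) - z * se)
  ci_high <- exp(log(or) + z * se)

  resolved <- if (method == "auto")
    ifelse(pmin(a, b, c, d) < 5, "fisher_exact", "chi2")
  else rep(method, n)
  p <- rep(NA_real_, n)
  fi <- resolved == "fisher_exact"
  ch <- resolved == "chi2"
  wa <- resolved == "wald"
  if (any(fi)) p[fi] <- fisher_p(a[fi], b[fi], c[fi], d[fi])
  if (any(ch)) p[ch] <- chi2_p(a[ch], b[ch], c[ch], d[ch])
  if (any(wa)) p[wa] <- 2 * stats::pnorm(-abs(log(or[wa]) / se[wa]))
  p[degenerate] <- NA_real_
  or[degenerate] <- NA_real_

  tibble::tibble(a = a, b = b, c = c, d = d,
                 odds_ratio = or, or_raw = raw_or, log_or_se = se,
                 ci_low = ci_low, ci_high = ci_high, ci_level = ci_level,
                 p_value = p, method = resolved,
                 zero_cell_policy = policy, degenerate = degenerate)
}

new_effect_estimate <- function(row, factor = "", stratum = "") {
  structure(c(list(factor = factor, stratum = stratum), as.list(row)),
            class = "effect_estimate")
}

#' Odds ratio with zero-cell policy and test
#'
#' The odds ratio is `(a d)/(b c)`. With the default
#' `haldane_anscombe` policy, 0.5 is added to every cell (before all
#' computations) if and only if any cell is zero; the uncorrected ratio is
#' always recorded as `or_raw` so an infinite raw effect stays visible.
#' `report_infinite` returns `Inf` with undefined standard error when
#' `b*c = 0` and `a*d > 0`. The Wald confidence interval is
#' `exp(log OR +/- z se)` with `se = sqrt(1/a + 1/b + 1/c + 1/d)` on
#' policy-adjusted counts. The p-value comes from Fisher's exact test when
#' any raw cell is below 5 and from the Pearson chi-square test (no
#' continuity correction) otherwise (`method = "auto"`); both act on the
#' raw counts.
#'
#' @param table A [table2x2()].
#' @param policy `"haldane_anscombe"` (default), `"none"` or
#'   `"report_infinite"`.
#' @param method `"auto"`, `"fisher_exact"`, `"chi2"` or `"wald"`.
#' @param ci_level Confidence level, default 0.95.
#' @return An `effect_estimate`; see [tidy()] for the tabular form.
#' @export
#' @examples
#' odds_ratio(table2x2(10, 20, 5, 40))
odds_ratio <- function(table, policy = c("haldane_anscombe", "none",
                                         "report_infinite"),
                       method = c("auto", "fisher_exact", "chi2", "wald"),
                       ci_level = 0.95) {
  stopifnot(inherits(table, "table2x2"))
  with(table, {
    if (a + b + c + d == 0)
      abort_glue("all four cells are zero: no information")
    if (a + b == 0 || c + d == 0)
      abort_glue("degenerate table: no contrast in ",
                 if (nzchar(table$factor_label)) table$factor_label else "the factor",
                 " (one factor level is empty)")
  })
  row <- effect_from_counts(table$a, table$b, table$c, table$d,
                            policy = policy, method = method,
                            ci_level = ci_level)
  new_effect_estimate(row[1, ], factor = table$factor_label,
                      stratum = table$stratum_label)
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat("<effect>", x$factor,
      if (nzchar(x$stratum)) paste0("[", x$stratum, "]") else "", "\n")
  cat(sprintf("  OR = %.4g (raw %.4g), %g%% CI [%.4g, %.4g], p = %.3g (%s)\n",
              x$odds_ratio, x$or_raw, 100 * x$ci_level, x$ci_low, x$ci_high,
              x$p_value, x$method))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Mantel-Haenszel pooled odds ratio across strata
#'
#' The common-odds-ratio estimator
#' `OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`, with the
#' Robins-Breslow-Greenland variance for the log estimate and the
#' Mantel-Haenszel chi-square test (no continuity correction) for the
#' p-value. If every stratum's cross-product summand is zero on either
#' side, a 0.5 continuity correction is applied to all cells of every
#' stratum before estimation (and only then).
#'
#' @param tables Non-empty list of [table2x2()] with disjoint strata.
#' @param ci_level Confidence level.
#' @return An `effect_estimate` with `method = "mantel_haenszel"`.
#' @export
#' @examples
#' snow <- table2x2(500, 0, 0, 500, "snow_island", "colour=black")
#' ash  <- table2x2(0, 500, 500, 0, "ash_island", "colour=black")
#' mantel_haenszel(list(snow, ash))
mantel_haenszel <- function(tables, ci_level = 0.95) {
  if (!length(tables)) abort_glue("mantel_haenszel needs at least one table")
  stopifnot(all(vapply(tables, inherits, logical(1), "table2x2")))
  a <- vapply(tables, `[[`, numeric(1), "a")
  b <- vapply(tables, `[[`, numeric(1), "b")
  c <- vapply(tables, `[[`, numeric(1), "c")
  d <- vapply(tables, `[[`, numeric(1), "d")
  n <- a + b + c + d
  if (any(n == 0)) abort_glue("empty stratum table")
  R <- a * d / n
  S <- b * c / n
  if (sum(R) == 0 || sum(S) == 0) { # all summands vanish on one side
    a2 <- a + 0.5; b2 <- b + 0.5; c2 <- c + 0.5; d2 <- d + 0.5
    n2 <- n + 2
  } else {
    a2 <- a; b2 <- b; c2 <- c; d2 <- d; n2 <- n
  }
  R2 <- a2 * d2 / n2; S2 <- b2 * c2 / n2
  or_mh <- sum(R2) / sum(S2)
  P <- (a2 + d2) / n2; Q <- (b2 + c2) / n2
  var_log <- sum(P * R2) / (2 * sum(R2)^2) +
    sum(P * S2 + Q * R2) / (2 * sum(R2) * sum(S2)) +
    sum(Q * S2) / (2 * sum(S2)^2)
  se <- sqrt(var_log)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  # MH chi-square on the raw counts
  E <- (a + b) * (a + c) / n
  V <- (a + b) * (c + d) * (a + c) * (b + d) / (n^2 * (n - 1))
  V[n <= 1] <- 0
  p <- if (sum(V) == 0) 1 else
    stats::pchisq((sum(a) - sum(E))^2 / sum(V), df = 1L, lower.tail = FALSE)
  row <- tibble::tibble(
    a = sum(a), b = sum(b), c = sum(c), d = sum(d),
    odds_ratio = or_mh, or_raw = if (sum(S) > 0) sum(R) / sum(S) else Inf,
    log_or_se = se, ci_low = exp(log(or_mh) - z * se),
    ci_high = exp(log(or_mh) + z * se), ci_level = ci_level,
    p_value = p, method = "mantel_haenszel",
    zero_cell_policy = if (sum(R) == 0 || sum(S) == 0)
      "haldane_anscombe" else "none",
    degenerate = FALSE)
  new_effect_estimate(row, factor = tables[[1]]$factor_label, stratum = "MH")
}

#' Woolf test for heterogeneity of odds ratios across strata
#'
#' Computes `X^2 = sum w_i (log OR_i - log OR_bar)^2` with inverse-variance
#' weights `w_i = 1 / sum(1/cell)` per stratum, on Haldane-Anscombe
#' corrected counts wherever a stratum has a zero cell, against a
#' chi-square with `strata - 1` degrees of freedom.
#'
#' @param tables List of at least two [table2x2()].
#' @return An object of class `heterogeneity_result` with fields
#'   `statistic`, `df`, `p_value`, `per_stratum_ors`.
#' @export
#' @examples
#' snow <- table2x2(500, 0, 0, 500, "snow_island")
#' ash  <- table2x2(0, 500, 500, 0, "ash_island")
#' woolf_heterogeneity(list(snow, ash))
woolf_heterogeneity <- function(tables) {
  if (length(tables) < 2L)
    abort_glue("woolf_heterogeneity needs at least 2 strata")
  stopifnot(all(vapply(tables, inherits, logical(1), "table2x2")))
  counts <- vapply(tables, function(t) c(t$a, t$b, t$c, t$d), numeric(4))
  any_zero <- apply(counts == 0, 2L, any)
  counts <- counts + rep(0.5 * any_zero, each = 4L)
  l <- log(counts[1, ] * counts[4, ] / (counts[2, ] * counts[3, ]))
  w <- 1 / colSums(1 / counts)
  lbar <- sum(w * l) / sum(w)
  stat <- sum(w * (l - lbar)^2)
  df <- length(tables) - 1L
  structure(
    list(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
         per_stratum_ors = exp(l),
         strata = vapply(tables, `[[`, character(1), "stratum_label")),
    class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Woolf heterogeneity: X^2 = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  cat("  per-stratum ORs:", paste(signif(x$per_stratum_ors, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; output is in the original input
#' order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    abort_glue("p-values must lie in [0, 1] and not be missing")
  stats::p.adjust(p_values, method = "BH")
}
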