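#' Tidy an effect estimate into a one-row tibble
#'
#' @param x An `effect_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with the counts, estimate, CI, p-value and
#'   policy record.
#' @method tidy effect_estimate
#' @export
tidy.effect_estimate <- function(x, ...) {
  tibble::tibble(
    factor = x$factor, stratum = x$stratum,
    a = x$a, b = x$b, c = x$c, d = x$d,
    odds_ratio = x$odds_ratio, or_raw = x$or_raw, log_or_se = x$log_or_se,
    ci_low = x$ci_low, ci_high = x$ci_high, ci_level = x$ci_level,
    p_value = x$p_value, method = x$method,
    zero_cell_policy = x$zero_cell_policy,
    degenerate = isTRUE(x$degenerate),
    note = x$note %||% NA_character_)
}

#' @rdname tidy.effect_estimate
#' @method glance effect_estimate
#' @export
glance.effect_estimate <- function(x, ...) {
  tibble::tibble(odds_ratio = x$odds_ratio, p_value = x$p_value,
                 method = x$method, degenerate = isTRUE(x$degenerate))
}

#' Tidy a Woolf heterogeneity result
#'
#' @param x A `heterogeneity_result`.
#' @param ... Unused.
#' @return `tidy()`: per-stratum odds ratios; `glance()`: the statistic,
#'   degrees of freedom and p-value.
#' @method tidy heterogeneity_result
#' @export
tidy.heterogeneity_result <- function(x, ...) {
  tibble::tibble(stratum = x$strata, odds_ratio = x$per_stratum_ors)
}

#' @rdname tidy.heterogeneity_result
#' @method glance heterogeneity_result
#' @export
glance.heterogeneity_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' Tidy a multi-locus scan result
#'
#' @param x A `scan_result` from [stratified_scan()].
#' @param ... Unused.
#' @return `tidy()`: the per-(locus, mode, cell) rows as a plain tibble;
#'   `glance()`: per-locus detection flags.
#' @method tidy scan_result
#' @export
tidy.scan_result <- function(x, ...) {
  tibble::as_tibble(unclass_keep(x))
}

#' @rdname tidy.scan_result
#' @method glance scan_result
#' @export
glance.scan_result <- function(x, ...) {
  attr(x, "summary")
}

#' Tidy a power comparison report
#'
#' @param x A `power_report`.
#' @param ... Unused.
#' @return `tidy()`: one row per mode; `glance()`: one row with the target
#'   locus and per-mode powers in wide form.
#' @method tidy power_report
#' @export
tidy.power_report <- function(x, ...) {
  tibble::as_tibble(unclass_keep(x))
}

#' @rdname tidy.power_report
#' @method glance power_report
#' @export
glance.power_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(unclass_keep(x))[, c("mode", "power")],
                             names_from = "mode", values_from = "power",
                             names_prefix = "power_")
  dplyr::bind_cols(tibble::tibble(target = attr(x, "target"),
                                  n_replicates = x$n_replicates[1],
                                  alpha = x$alpha[1]), wide)
}

#' Tidy a fox-rabbit demonstration report
#'
#' @param x A `fox_rabbit_report`.
#' @param ... Unused.
#' @return `tidy()`: the PASS/FAIL verdict table; `glance()`: counts of
#'   claims and passes.
#' @method tidy fox_rabbit_report
#' @export
tidy.fox_rabbit_report <- function(x, ...) {
  x$verdicts
}

#' @rdname tidy.fox_rabbit_report
#' @method glance fox_rabbit_report
#' @export
glance.fox_rabbit_report <- function(x, ...) {
  tibble::tibble(n_claims = nrow(x$verdicts),
                 n_pass = sum(x$verdicts$verdict == "PASS"),
                 alpha = x$alpha, seed = x$seed)
}

# drop the package's S3 class but keep the tibble classes
unclass_keep <- function(x) {
  class(x) <- setdiff(class(x), c("scan_result", "power_report",
                                  "propensity_profile", "pepscan_report"))
  x
}

#' Export a scan result as a tab-separated table
#'
#' One row per (locus, mode, cell) with documented column order; float
#' columns are written at round-trip precision, so identical scans export
#' byte-identically.
#'
#' @param scan A `scan_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  readr::write_tsv(as.data.frame(tidy(scan)), path, progress = FALSE)
  invisible(path)
}
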