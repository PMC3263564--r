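#' Specify how association analysis is partitioned
#'
#' @param stratify_by Character vector of cohort variables (the `stratum`
#'   column and/or exposure columns) whose level combinations define the
#'   partition cells. Empty with `include_pooled = TRUE` is the
#'   unstratified ("pooled GWAS") mode.
#' @param include_pooled Also analyse the full cohort unpartitioned.
#' @param include_mh Also report the Mantel-Haenszel common odds ratio
#'   across the partition cells.
#' @param min_cell_size Partition cells smaller than this are skipped with
#'   a warning.
#' @return An object of class `partition_spec`.
#' @export
#' @examples
#' partition_spec("stratum", include_mh = TRUE)
partition_spec <- function(stratify_by = character(), include_pooled = TRUE,
                           include_mh = FALSE, min_cell_size = 10L) {
  stopifnot(is.character(stratify_by))
  if (length(stratify_by) == 0L && !include_pooled && !include_mh)
    abort_glue("empty partition: no stratification variables and no pooled mode")
  structure(list(stratify_by = stratify_by, include_pooled = include_pooled,
                 include_mh = include_mh,
                 min_cell_size = as.integer(min_cell_size)),
            class = "partition_spec")
}

# counts of (a, b, c, d) for every locus at once on one subcohort
scan_counts <- function(sub, loci, risk_levels) {
  dead <- sub$outcome == "dead"
  counts <- vapply(seq_along(loci), function(j) {
    pos <- sub[[loci[j]]] == risk_levels[j]
    c(sum(pos & dead), sum(pos & !dead), sum(!pos & dead), sum(!pos & !dead))
  }, numeric(4))
  tibble::tibble(locus = loci, a = counts[1, ], b = counts[2, ],
                 c = counts[3, ], d = counts[4, ])
}

#' Scan all loci for association, partitioned and/or pooled
#'
#' For every locus and every partition cell (the cross-product of the
#' levels of `spec$stratify_by`), builds the 2x2 table of the locus's risk
#' allele against outcome and estimates the odds ratio; optionally adds the
#' unpartitioned (pooled) analysis and the Mantel-Haenszel common estimate
#' across cells. P-values are Benjamini-Hochberg adjusted within each
#' analysis mode (across all loci and cells of that mode), and a locus
#' counts as detected in a mode when any of its adjusted p-values falls
#' below `alpha`.
#'
#' @param cohort A cohort with outcomes set and locus metadata attached
#'   (from [generate_cohort()] or [read_cohort()] with a config).
#' @param spec A [partition_spec()].
#' @param alpha Detection level on BH-adjusted p-values.
#' @param loci Optional subset of locus names to scan (default: all).
#' @param policy,method Passed to the effect computation; see
#'   [odds_ratio()].
#' @return A tibble of class `scan_result`, one row per (locus, mode,
#'   cell), with counts, estimates, `p_value`, `p_adj` and `detected`;
#'   per-locus summary flags are available via [glance()].
#' @export
#' @examples
#' co <- generate_cohort(builtin_scenario("two_island_fox")) |> apply_outcomes()
#' stratified_scan(co, partition_spec("stratum", include_mh = TRUE))
stratified_scan <- function(cohort, spec = partition_spec("stratum"),
                            alpha = 0.05, loci = NULL,
                            policy = "haldane_anscombe", method = "auto") {
  stopifnot(inherits(spec, "partition_spec"))
  if (any(cohort$outcome == "unset"))
    abort_glue("outcomes not set; run apply_outcomes() first")
  info <- attr(cohort, "locus_info")
  if (is.null(info))
    abort_glue("cohort carries no locus metadata; regenerate it or use ",
               "read_cohort(path, config = ...)")
  if (!is.null(loci)) info <- info[info$locus %in% loci, ]
  if (!nrow(info)) abort_glue("no loci to scan")
  missing_vars <- setdiff(spec$stratify_by, names(cohort))
  if (length(missing_vars))
    abort_glue("stratification variable(s) not in cohort: ",
               paste(missing_vars, collapse = ", "))

  one_mode <- function(sub, mode, cell) {
    cnt <- scan_counts(sub, info$locus, info$risk_level)
    eff <- effect_from_counts(cnt$a, cnt$b, cnt$c, cnt$d,
                              policy = policy, method = method)
    dplyr::bind_cols(tibble::tibble(locus = cnt$locus, mode = mode,
                                    cell = cell), eff)
  }

  rows <- list()
  cell_tables <- list() # per cell, counts for the MH combination
  if (length(spec$stratify_by)) {
    cells <- dplyr::distinct(cohort[, spec$stratify_by, drop = FALSE])
    cells <- dplyr::arrange(cells, dplyr::across(dplyr::everything()))
    for (i in seq_len(nrow(cells))) {
      sel <- rep(TRUE, nrow(cohort))
      for (v in spec$stratify_by) sel <- sel & cohort[[v]] == cells[[v]][i]
      label <- paste(spec$stratify_by, unlist(cells[i, ]), sep = "=",
                     collapse = ",")
      sub <- cohort[sel, ]
      if (nrow(sub) < spec$min_cell_size) {
        warning("skipping partition cell ", label, " (n = ", nrow(sub),
                " below minimum ", spec$min_cell_size, ")", call. = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- one_mode(sub, "stratified", label)
      cell_tables[[length(cell_tables) + 1L]] <-
        scan_counts(sub, info$locus, info$risk_level)
    }
  }
  if (spec$include_pooled)
    rows[[length(rows) + 1L]] <- one_mode(cohort, "pooled", "(pooled)")
  if (spec$include_mh) {
    if (length(cell_tables) < 1L)
      abort_glue("include_mh requires at least one stratification cell")
    mh_rows <- lapply(seq_len(nrow(info)), function(j) {
      tabs <- lapply(cell_tables, function(ct)
        table2x2(ct$a[j], ct$b[j], ct$c[j], ct$d[j]))
      est <- mantel_haenszel(tabs)
      tibble::tibble(locus = info$locus[j], mode = "mh", cell = "(MH)",
                     a = est$a, b = est$b, c = est$c, d = est$d,
                     odds_ratio = est$odds_ratio, or_raw = est$or_raw,
                     log_or_se = est$log_or_se, ci_low = est$ci_low,
                     ci_high = est$ci_high, ci_level = est$ci_level,
                     p_value = est$p_value, method = est$method,
                     zero_cell_policy = est$zero_cell_policy,
                     degenerate = FALSE)
    })
    rows[[length(rows) + 1L]] <- dplyr::bind_rows(mh_rows)
  }
  res <- dplyr::bind_rows(rows)
  # BH within each analysis mode, across loci and cells
  res <- res |>
    dplyr::group_by(.data$mode) |>
    dplyr::mutate(p_adj = {
      ok <- !is.na(.data$p_value)
      out <- rep(NA_real_, dplyr::n())
      if (any(ok)) out[ok] <- bh_adjust(.data$p_value[ok])
      out
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(detected = !is.na(.data$p_adj) & .data$p_adj < alpha)
  summary <- res |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      detected_pooled = any(.data$detected[.data$mode == "pooled"]),
      detected_stratified = any(.data$detected[.data$mode == "stratified"]),
      detected_mh = any(.data$detected[.data$mode == "mh"]),
      .groups = "drop")
  structure(res, class = c("scan_result", class(res)),
            alpha = alpha, spec = spec, summary = summary)
}

#' Is an exposure a detectable cause in a cohort?
#'
#' Estimates the exposure-outcome odds ratio over the full cohort. A
#' ubiquitous exposure (present for everyone, like the fox on the two fox
#' islands) yields a degenerate table with no unexposed contrast group; the
#' result is then flagged `degenerate` with the note
#' `"undetectable - no contrast"` — which is itself the parable's point:
#' only a reference population without the agent makes the cause visible.
#'
#' @param cohort A cohort with outcomes set.
#' @param exposure Name of an exposure column.
#' @param per_stratum Also return per-stratum estimates.
#' @param ... Passed to [odds_ratio()].
#' @return An `effect_estimate` (possibly degenerate); with
#'   `per_stratum = TRUE`, a list with elements `overall` and
#'   `by_stratum`.
#' @export
#' @examples
#' co <- generate_cohort(builtin_scenario("three_island")) |> apply_outcomes()
#' cause_detectability(co, "fox")
cause_detectability <- function(cohort, exposure, per_stratum = FALSE, ...) {
  tab <- build_table(cohort, exposure, risk_level = 1)
  overall <- tryCatch(odds_ratio(tab, ...), error = function(e) {
    row <- effect_from_counts(tab$a, tab$b, tab$c, tab$d)
    est <- new_effect_estimate(row[1, ], factor = tab$factor_label,
                               stratum = "(all)")
    est$note <- "undetectable - no contrast"
    est
  })
  if (!per_stratum) return(overall)
  strata <- unique(cohort$stratum)
  by_stratum <- lapply(strata, function(s)
    tryCatch(odds_ratio(build_table(cohort, exposure, 1, stratum_filter = s), ...),
             error = function(e) NULL))
  names(by_stratum) <- strata
  list(overall = overall, by_stratum = by_stratum)
}

#' Run the full fox-rabbit demonstration on a scenario
#'
#' Generates a cohort, applies outcomes, and works through the parable's
#' claim set: per-island gene effects, the pooled and Mantel-Haenszel
#' (meta-analytic) estimates, Woolf heterogeneity, and cause detectability
#' with and without an unexposed reference stratum. Each claim is mapped to
#' PASS/FAIL in a verdict table:
#' \enumerate{
#'   \item the colour gene is detected within every exposed stratum;
#'   \item the pooled analysis is null (the gene vanishes when islands are
#'     merged);
#'   \item the Mantel-Haenszel meta-analytic estimate is null;
#'   \item the cause is undetectable when every individual is exposed;
#'   \item (only when an unexposed stratum exists) the cause becomes
#'     detectable once the unexposed stratum is included.
#' }
#'
#' @param config An `sm_scenario`, typically from [builtin_scenario()];
#'   the first locus and first exposure play the gene and cause roles.
#' @param seed Master seed (default: the config's).
#' @param alpha Significance level for the claim checks.
#' @return An object of class `fox_rabbit_report`: effects table,
#'   heterogeneity result, cause-detectability results and the verdict
#'   table ([tidy()] returns the verdicts).
#' @export
#' @examples
#' fox_rabbit_report(builtin_scenario("two_island_fox"))
fox_rabbit_report <- function(config, seed = config$seed, alpha = 0.05) {
  validate_scenario(config)
  if (!length(config$loci)) abort_glue("scenario has no locus to analyse")
  cohort <- apply_outcomes(generate_cohort(config, seed))
  gene <- config$loci[[1]]$name
  risk <- config$loci[[1]]$allele_labels[1]
  exposure <- names(config$strata[[1]]$exposures)[1]
  strata_names <- vapply(config$strata, `[[`, character(1), "name")
  exposed_strata <- strata_names[vapply(config$strata, function(s) {
    prev <- if (exposure %in% names(s$exposures)) s$exposures[[exposure]] else 0
    prev > 0
  }, logical(1))]
  unexposed_strata <- setdiff(strata_names, exposed_strata)

  island_tabs <- lapply(strata_names, function(s)
    build_table(cohort, gene, risk, stratum_filter = s))
  names(island_tabs) <- strata_names
  island_effects <- lapply(island_tabs, odds_ratio)
  pooled <- odds_ratio(build_table(cohort, gene, risk))
  mh <- mantel_haenszel(island_tabs)
  het <- woolf_heterogeneity(island_tabs)

  cause_all <- if (!is.null(exposure)) cause_detectability(cohort, exposure)
  cause_exposed_only <- if (length(exposed_strata))
    cause_detectability(dplyr::filter(cohort, .data$stratum %in% exposed_strata),
                        exposure)

  effects <- dplyr::bind_rows(
    c(lapply(island_effects, tidy_effect_row), list(tidy_effect_row(pooled),
                                                    tidy_effect_row(mh))))

  v <- list()
  exp_eff <- island_effects[exposed_strata]
  v$per_island_detection <- list(
    description = paste0("gene '", gene, "' detected within each exposed stratum"),
    pass = length(exp_eff) > 0 &&
      all(vapply(exp_eff, function(e) isTRUE(e$p_value < alpha), logical(1))))
  v$pooled_null <- list(
    description = "pooled (unstratified) gene effect is null",
    pass = isTRUE(pooled$p_value >= alpha))
  v$mh_null <- list(
    description = "Mantel-Haenszel meta-analytic gene effect is null",
    pass = isTRUE(mh$p_value >= alpha))
  v$cause_undetectable <- list(
    description = paste0("cause '", exposure,
                         "' undetectable among exposed strata (no contrast)"),
    pass = !is.null(cause_exposed_only$note))
  if (length(unexposed_strata))
    v$cause_detectable_with_reference <- list(
      description = paste0("cause '", exposure, "' detectable once the ",
                           "unexposed stratum is included"),
      pass = is.null(cause_all$note) &&
        isTRUE(cause_all$odds_ratio > 1 && cause_all$p_value < alpha))

  verdicts <- tibble::tibble(
    claim = names(v),
    description = vapply(v, `[[`, character(1), "description"),
    verdict = ifelse(unname(vapply(v, `[[`, logical(1), "pass")),
                     "PASS", "FAIL"))

  structure(list(effects = effects, heterogeneity = het,
                 cause_overall = cause_all,
                 cause_exposed_only = cause_exposed_only,
                 verdicts = verdicts, alpha = alpha, seed = seed,
                 gene = gene, exposure = exposure),
            class = "fox_rabbit_report")
}

# one-row tibble view of an effect_estimate (internal)
tidy_effect_row <- function(x) {
  tibble::tibble(factor = x$factor, stratum = x$stratum, a = x$a, b = x$b,
                 c = x$c, d = x$d, odds_ratio = x$odds_ratio,
                 or_raw = x$or_raw, ci_low = x$ci_low, ci_high = x$ci_high,
                 p_value = x$p_value, method = x$method,
                 degenerate = isTRUE(x$degenerate))
}

#' @export
print.fox_rabbit_report <- function(x, ...) {
  cat("== fox-rabbit demonstration (seed ", x$seed, ") ==\n", sep = "")
  print(as.data.frame(dplyr::mutate(
    x$effects, dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 4)))),
    row.names = FALSE)
  print(x$heterogeneity)
  cat("cause '", x$exposure, "': ", sep = "")
  if (!is.null(x$cause_overall$note)) cat(x$cause_overall$note, "\n")
  else cat(sprintf("OR = %.3g, p = %.3g\n", x$cause_overall$odds_ratio,
                   x$cause_overall$p_value))
  cat("-- verdicts --\n")
  print(as.data.frame(x$verdicts), row.names = FALSE)
  invisible(x)
}
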