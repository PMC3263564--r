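#' Generate a cohort from a scenario configuration
#'
#' Draws one individual per row, stratum-major in configuration order, with
#' 0-based contiguous ids. Genotypes follow each locus's sampling mode:
#' `exact_count` places exactly `round(freq * size)` copies of the first
#' allele in every stratum (in a seeded random order), `binomial` draws
#' per-individual. Exposures with prevalence 0 or 1 are deterministic;
#' fractional prevalences are per-individual Bernoulli draws. All outcomes
#' start `"unset"`; apply them with [apply_outcomes()].
#'
#' @param config A validated `sm_scenario`.
#' @param seed Master seed; defaults to `config$seed`. Stage seeds are
#'   derived with [derive_seed()], so identical seeds give identical
#'   cohorts.
#' @return A tibble with columns `id`, `stratum`, one column per locus
#'   (allele labels), one per exposure (0/1), and `outcome`; scenario
#'   metadata is attached as attributes `scenario`, `locus_info` and
#'   `master_seed`.
#' @export
#' @examples
#' co <- generate_cohort(builtin_scenario("two_island_fox"))
#' dplyr::count(co, stratum, colour)
generate_cohort <- function(config, seed = config$seed) {
  validate_scenario(config)
  exposure_names <- unique(unlist(lapply(config$strata,
                                         function(s) names(s$exposures))))
  parts <- lapply(config$strata, function(st) {
    n <- st$size
    row <- tibble::tibble(stratum = rep(st$name, n))
    for (lc in config$loci) {
      s <- derive_seed(seed, paste0("genotypes:", st$name, ":", lc$name))
      row[[lc$name]] <- if (n == 0L) character() else if (lc$sampling_mode == "exact_count") {
        k <- as.integer(round(lc$risk_allele_freq * n))
        with_seed(s, sample(rep(lc$allele_labels, c(k, n - k))))
      } else {
        with_seed(s, ifelse(stats::rbinom(n, 1L, lc$risk_allele_freq) == 1L,
                            lc$allele_labels[1], lc$allele_labels[2]))
      }
    }
    for (ex in exposure_names) {
      prev <- if (ex %in% names(st$exposures)) st$exposures[[ex]] else 0
      row[[ex]] <- if (prev %in% c(0, 1)) rep(as.numeric(prev), n) else {
        s <- derive_seed(seed, paste0("exposure:", st$name, ":", ex))
        with_seed(s, as.numeric(stats::rbinom(n, 1L, prev)))
      }
    }
    row
  })
  co <- dplyr::bind_rows(parts)
  co <- dplyr::mutate(co, id = dplyr::row_number() - 1L, .before = 1L)
  co$outcome <- rep("unset", nrow(co))
  locus_info <- tibble::tibble(
    locus = vapply(config$loci, `[[`, character(1), "name"),
    risk_level = vapply(config$loci, function(l) l$allele_labels[1], character(1)),
    null = FALSE
  )
  attr(co, "scenario") <- config
  attr(co, "locus_info") <- locus_info
  attr(co, "exposures") <- exposure_names %||% character()
  attr(co, "master_seed") <- as.integer(seed)
  if (config$n_null_loci > 0L)
    co <- add_null_loci(co, config$n_null_loci, config$null_locus_freq,
                        seed = derive_seed(seed, "null_loci"))
  co
}

#' Append outcome-independent null loci to a cohort
#'
#' Each null locus is an independent biallelic draw (`A1`/`A2`) unrelated to
#' outcome, stratum or any other locus — background markers for
#' multi-locus scans and type-I-error calibration.
#'
#' @param cohort A cohort tibble.
#' @param n Number of null loci (0 returns the cohort unchanged).
#' @param freq Frequency of allele `A1`.
#' @param seed Seed for the draws.
#' @return The cohort with `n` new columns `null_0001`, ... and updated
#'   locus metadata.
#' @export
add_null_loci <- function(cohort, n, freq = 0.5, seed = 1L) {
  stopifnot(n >= 0)
  if (n == 0L) return(cohort)
  info <- attr(cohort, "locus_info") %||%
    tibble::tibble(locus = character(), risk_level = character(), null = logical())
  names_new <- sprintf("null_%04d", seq_len(n) + sum(info$null))
  clash <- intersect(names_new, names(cohort))
  if (length(clash))
    abort_glue("null locus name(s) collide with existing columns: ",
               paste(clash, collapse = ", "))
  m <- nrow(cohort)
  draws <- with_seed(seed,
    matrix(stats::rbinom(m * n, 1L, freq), nrow = m, ncol = n))
  for (j in seq_len(n))
    cohort[[names_new[j]]] <- ifelse(draws[, j] == 1L, "A1", "A2")
  # keep outcome as the last column
  cohort <- dplyr::relocate(cohort, "outcome", .after = dplyr::last_col())
  attr(cohort, "locus_info") <- dplyr::bind_rows(
    info, tibble::tibble(locus = names_new, risk_level = "A1", null = TRUE))
  cohort
}

#' Apply outcomes from a penetrance table
#'
#' Draws each individual's outcome as a Bernoulli trial with probability
#' `lookup_penetrance(genotype, stratum, exposure pattern)`; combinations
#' without a table entry use the background mortality. A deterministic
#' table (all probabilities 0 or 1) fully determines the outcome. The input
#' cohort must not already carry outcomes.
#'
#' @param cohort A cohort with all outcomes `"unset"`.
#' @param penetrance An `sm_penetrance`; defaults to the generating
#'   scenario's table.
#' @param seed Seed for the Bernoulli draws; defaults to one derived from
#'   the cohort's master seed under the key `"outcomes"`.
#' @return A new cohort with `outcome` set to `"dead"` or `"alive"`.
#' @export
#' @examples
#' co <- generate_cohort(builtin_scenario("two_island_fox")) |> apply_outcomes()
#' table(co$stratum, co$outcome)
apply_outcomes <- function(cohort, penetrance = NULL, seed = NULL) {
  if (any(cohort$outcome != "unset"))
    abort_glue("outcomes already set; apply_outcomes() must not be applied twice")
  config <- attr(cohort, "scenario")
  penetrance <- penetrance %||% config$penetrance
  if (is.null(penetrance))
    abort_glue("no penetrance table: pass one or use a cohort generated ",
               "from a scenario")
  seed <- seed %||% derive_seed(attr(cohort, "master_seed") %||% 1L, "outcomes")
  p <- rep(penetrance$background_mortality, nrow(cohort))
  entries <- penetrance$entries
  if (nrow(entries)) {
    exposure_cols <- penetrance_exposures(penetrance)
    key <- dplyr::rename(entries, !!penetrance$locus := "genotype")
    missing_cols <- setdiff(c(penetrance$locus, "stratum", exposure_cols),
                            names(cohort))
    if (length(missing_cols))
      abort_glue("cohort lacks column(s) required by the penetrance table: ",
                 paste(missing_cols, collapse = ", "))
    joined <- dplyr::left_join(
      cohort[, c(penetrance$locus, "stratum", exposure_cols)], key,
      by = c(penetrance$locus, "stratum", exposure_cols))
    p <- dplyr::coalesce(joined$death_prob, p)
  }
  out <- cohort
  out$outcome <- with_seed(seed,
    ifelse(stats::rbinom(nrow(out), 1L, p) == 1L, "dead", "alive"))
  out
}

#' Write a cohort to a tab-separated file
#'
#' Column order is `id`, `stratum`, loci, exposures, `outcome`; no missing
#' values. Re-exports are byte-identical for identical cohorts, so the file
#' doubles as a determinism check.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(as.data.frame(cohort), path, progress = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path Input path.
#' @param config Optional generating `sm_scenario`; when given, scenario
#'   metadata (locus risk levels, exposure names) is re-attached so the
#'   cohort is usable by [stratified_scan()] without extra arguments.
#' @return A cohort tibble.
#' @export
read_cohort <- function(path, config = NULL) {
  co <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  co$id <- as.integer(co$id)
  if (!is.null(config)) {
    validate_scenario(config)
    attr(co, "scenario") <- config
    locus_names <- vapply(config$loci, `[[`, character(1), "name")
    null_names <- grep("^null_\\d+$", names(co), value = TRUE)
    attr(co, "locus_info") <- tibble::tibble(
      locus = c(locus_names, null_names),
      risk_level = c(vapply(config$loci, function(l) l$allele_labels[1],
                            character(1)),
                     rep("A1", length(null_names))),
      null = c(rep(FALSE, length(locus_names)), rep(TRUE, length(null_names))))
    attr(co, "exposures") <- unique(unlist(lapply(config$strata,
                                                  function(s) names(s$exposures))))
    attr(co, "master_seed") <- config$seed
  }
  co
}
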