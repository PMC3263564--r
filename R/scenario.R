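#' Define a biallelic locus
#'
#' A locus carries two allele labels and the frequency of the first
#' (risk-side) label. Sampling is either `"binomial"` (each individual draws
#' the first allele with probability `risk_allele_freq`) or `"exact_count"`
#' (each stratum receives exactly `round(freq * size)` copies of the first
#' allele, as in "an equal number of black and white rabbits").
#'
#' @param name Locus identifier.
#' @param allele_labels Character vector of length 2; the first label is the
#'   one whose frequency `risk_allele_freq` states.
#' @param risk_allele_freq Frequency of `allele_labels[1]`, in `[0, 1]`.
#' @param sampling_mode `"binomial"` or `"exact_count"`.
#' @return An object of class `sm_locus`.
#' @export
#' @examples
#' locus("colour", c("black", "white"), 0.5, "exact_count")
locus <- function(name, allele_labels, risk_allele_freq = 0.5,
                  sampling_mode = c("binomial", "exact_count")) {
  sampling_mode <- match.arg(sampling_mode)
  stopifnot(is.character(name), length(name) == 1L,
            is.character(allele_labels), length(allele_labels) == 2L,
            !anyDuplicated(allele_labels))
  if (!is.numeric(risk_allele_freq) || risk_allele_freq < 0 || risk_allele_freq > 1)
    abort_glue("risk_allele_freq must lie in [0, 1], got ", risk_allele_freq)
  structure(
    list(name = name, allele_labels = allele_labels,
         risk_allele_freq = as.numeric(risk_allele_freq),
         sampling_mode = sampling_mode),
    class = "sm_locus"
  )
}

#' Define an environment stratum ("island")
#'
#' @param name Stratum identifier.
#' @param size Non-negative integer number of individuals.
#' @param exposures Named numeric vector mapping exposure name to presence
#'   (0/1) or prevalence in `[0, 1]`; fractional values are sampled
#'   per-individual at cohort generation.
#' @return An object of class `sm_stratum`.
#' @export
#' @examples
#' stratum("snow_island", 1000, exposures = c(fox = 1))
stratum <- function(name, size, exposures = numeric()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(size) || length(size) != 1L || size < 0 || size != round(size))
    abort_glue("stratum size must be a non-negative integer, got ", size)
  if (length(exposures)) {
    if (is.null(names(exposures)) || any(names(exposures) == ""))
      abort_glue("exposures must be a named vector")
    if (any(exposures < 0 | exposures > 1))
      abort_glue("exposure prevalences must lie in [0, 1]")
  }
  structure(
    list(name = name, size = as.integer(size),
         exposures = vapply(exposures, as.numeric, numeric(1))),
    class = "sm_stratum"
  )
}

#' Define a penetrance table
#'
#' Maps (genotype at one keyed locus, stratum, exposure pattern) to a death
#' probability; combinations without an entry fall back to
#' `background_mortality`. The canonical deterministic table of the
#' fox-rabbit parable assigns probability 1 to (black, snow, fox) and
#' (white, ash, fox), 0 to the opposite colourings, and 0 to anything
#' without the fox.
#'
#' @param entries A data frame with columns `genotype`, `stratum`, one
#'   column per exposure name (0/1), and `death_prob` in `[0, 1]`.
#' @param background_mortality Fallback probability, default 0.
#' @param locus Name of the locus whose genotype keys the table.
#' @return An object of class `sm_penetrance`.
#' @export
penetrance_table <- function(entries, background_mortality = 0, locus) {
  entries <- tibble::as_tibble(entries)
  need <- c("genotype", "stratum", "death_prob")
  if (!all(need %in% names(entries)))
    abort_glue("penetrance entries need columns ",
               paste(need, collapse = ", "))
  if (any(entries$death_prob < 0 | entries$death_prob > 1))
    abort_glue("death probabilities must lie in [0, 1]")
  if (background_mortality < 0 || background_mortality > 1)
    abort_glue("background_mortality must lie in [0, 1]")
  exposure_cols <- setdiff(names(entries), need)
  entries <- entries[, c("genotype", "stratum", exposure_cols, "death_prob")]
  entries <- dplyr::mutate(entries, dplyr::across(
    dplyr::all_of(c(exposure_cols, "death_prob")), as.numeric))
  structure(
    list(entries = entries,
         background_mortality = as.numeric(background_mortality),
         locus = locus),
    class = "sm_penetrance"
  )
}

#' Names of the exposure columns keyed by a penetrance table
#' @param table An `sm_penetrance` object.
#' @return Character vector of exposure names (possibly empty).
#' @export
penetrance_exposures <- function(table) {
  setdiff(names(table$entries), c("genotype", "stratum", "death_prob"))
}

#' Assemble a full scenario configuration
#'
#' A scenario is the complete generative description of a multi-stratum
#' population experiment: loci, strata with exposures, the penetrance table,
#' optional outcome-independent null loci, and the master seed.
#'
#' @param loci List of [locus()] objects (may be empty for pure-null
#'   scenarios).
#' @param strata List of [stratum()] objects; names must be unique.
#' @param penetrance A [penetrance_table()].
#' @param n_null_loci Number of outcome-independent loci to add at cohort
#'   generation.
#' @param null_locus_freq Allele-1 frequency of the null loci.
#' @param seed Master seed; all stages derive their seeds from it via
#'   [derive_seed()].
#' @return An object of class `sm_scenario`.
#' @export
scenario_config <- function(loci, strata, penetrance, n_null_loci = 0L,
                            null_locus_freq = 0.5, seed = 1L) {
  cfg <- structure(
    list(loci = loci, strata = strata, penetrance = penetrance,
         n_null_loci = as.integer(n_null_loci),
         null_locus_freq = as.numeric(null_locus_freq),
         seed = as.integer(seed)),
    class = "sm_scenario"
  )
  validate_scenario(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Checks name uniqueness, probability ranges, exact-count feasibility and
#' penetrance-table consistency; errors name the offending component.
#'
#' @param config An `sm_scenario` object.
#' @return `config`, invisibly, if valid.
#' @export
validate_scenario <- function(config) {
  stopifnot(inherits(config, "sm_scenario"))
  locus_names <- vapply(config$loci, `[[`, character(1), "name")
  strat_names <- vapply(config$strata, `[[`, character(1), "name")
  if (anyDuplicated(locus_names))
    abort_glue("duplicate locus names: ",
               paste(unique(locus_names[duplicated(locus_names)]), collapse = ", "))
  if (anyDuplicated(strat_names))
    abort_glue("duplicate stratum names: ",
               paste(unique(strat_names[duplicated(strat_names)]), collapse = ", "))
  for (lc in config$loci) {
    if (lc$sampling_mode == "exact_count") {
      for (st in config$strata) {
        expected <- lc$risk_allele_freq * st$size
        if (abs(expected - round(expected)) > 1e-9)
          abort_glue("locus '", lc$name, "': exact_count needs an integer ",
                     "expected allele count but freq ", lc$risk_allele_freq,
                     " x size ", st$size, " = ", expected,
                     " in stratum '", st$name,
                     "'; adjust the stratum size or use binomial sampling")
      }
    }
  }
  pen <- config$penetrance
  if (length(config$loci) && !pen$locus %in% locus_names)
    abort_glue("penetrance table keys locus '", pen$locus,
               "' which is not in the scenario (available: ",
               paste(locus_names, collapse = ", "), ")")
  exposure_names <- unique(unlist(lapply(config$strata, function(s) names(s$exposures))))
  extra <- setdiff(penetrance_exposures(pen), exposure_names)
  if (length(extra))
    abort_glue("penetrance table keys unknown exposure(s): ",
               paste(extra, collapse = ", "))
  if (nrow(pen$entries) && length(config$loci)) {
    keyed <- config$loci[[match(pen$locus, locus_names)]]
    bad <- setdiff(unique(pen$entries$genotype), keyed$allele_labels)
    if (length(bad))
      abort_glue("penetrance entries use genotype value(s) not among the ",
                 "alleles of locus '", pen$locus, "': ",
                 paste(bad, collapse = ", "))
  }
  invisible(config)
}

#' Look up a death probability in a penetrance table
#'
#' Returns the entry for the exact (genotype, stratum, exposure pattern)
#' combination if present, otherwise the background mortality.
#'
#' @param table An `sm_penetrance` object.
#' @param genotype Allele value at the keyed locus.
#' @param stratum Stratum name.
#' @param exposures Named vector of 0/1 exposure indicators; names must
#'   match the table's exposure columns exactly.
#' @return A single probability in `[0, 1]`.
#' @export
#' @examples
#' cfg <- builtin_scenario("two_island_fox")
#' lookup_penetrance(cfg$penetrance, "black", "snow_island", c(fox = 1))
lookup_penetrance <- function(table, genotype, stratum, exposures = numeric()) {
  stopifnot(inherits(table, "sm_penetrance"))
  expected <- penetrance_exposures(table)
  if (!setequal(names(exposures) %||% character(), expected))
    abort_glue("malformed exposure pattern; expected exposure name(s): ",
               if (length(expected)) paste(expected, collapse = ", ") else "(none)")
  e <- table$entries
  hit <- e$genotype == genotype & e$stratum == stratum
  for (nm in expected) hit <- hit & e[[nm]] == exposures[[nm]]
  if (any(hit)) e$death_prob[which(hit)[1]] else table$background_mortality
}

#' Built-in fox-rabbit scenarios
#'
#' Three canonical configurations:
#' \describe{
#'   \item{`two_island_fox`}{Two islands (snow, volcanic ash), 1,000 rabbits
#'     each with exactly 500 black and 500 white (exact-count sampling at
#'     frequency 0.5), foxes on both, and the deterministic penetrance table:
#'     the fox takes every colour-matched rabbit (black on snow, white on
#'     ash) and no other.}
#'   \item{`three_island`}{The same plus a third island with no fox and a
#'     background "old age" mortality of 0.1 affecting both colours equally.
#'     Only this configuration provides unexposed individuals, making the
#'     fox's exposure-outcome odds ratio estimable.}
#'   \item{`interaction_demo`}{A gene-by-infection scenario: a biallelic
#'     variant whose carrier odds ratio is 0.5 in an uninfected stratum
#'     (n = 700, baseline mortality 0.30) and 8.0 in an infected stratum
#'     (n = 300, baseline 0.10), so the pooled odds ratio is near-null while
#'     each stratum carries a real effect.}
#' }
#'
#' @param name One of `"two_island_fox"`, `"three_island"`,
#'   `"interaction_demo"`.
#' @param n_per_stratum Optional override of every stratum size (scaled
#'   scenarios for replicate studies); must keep exact-count feasible.
#' @param seed Master seed stored in the config.
#' @return A validated `sm_scenario`.
#' @export
#' @examples
#' cfg <- builtin_scenario("two_island_fox")
#' vapply(cfg$strata, `[[`, integer(1), "size")
builtin_scenario <- function(name = c("two_island_fox", "three_island",
                                      "interaction_demo"),
                             n_per_stratum = NULL, seed = 1L) {
  valid <- c("two_island_fox", "three_island", "interaction_demo")
  if (!is.character(name) || length(name) != 1L || !name %in% valid)
    abort_glue("unknown scenario '", paste(name, collapse = ","),
               "'; valid names: ", paste(valid, collapse = ", "))

  # probability p from baseline odds scaled by an odds ratio
  or_to_p <- function(p0, or) { o <- p0 / (1 - p0) * or; o / (1 + o) }

  if (name %in% c("two_island_fox", "three_island")) {
    n <- n_per_stratum %||% 1000L
    colour <- locus("colour", c("black", "white"), 0.5, "exact_count")
    strata <- list(
      stratum("snow_island", n, exposures = c(fox = 1)),
      stratum("ash_island",  n, exposures = c(fox = 1))
    )
    entries <- tibble::tibble(
      genotype = c("black", "white", "white", "black"),
      stratum  = c("snow_island", "snow_island", "ash_island", "ash_island"),
      fox      = c(1, 1, 1, 1),
      death_prob = c(1, 0, 1, 0)
    )
    if (name == "three_island") {
      strata <- c(strata, list(stratum("no_fox_island", n, exposures = c(fox = 0))))
      entries <- dplyr::bind_rows(entries, tibble::tibble(
        genotype = c("black", "white"),
        stratum  = "no_fox_island",
        fox = 0,
        death_prob = 0.1
      ))
    }
    pen <- penetrance_table(entries, background_mortality = 0, locus = "colour")
    scenario_config(list(colour), strata, pen, seed = seed)
  } else {
    n_neg <- n_per_stratum %||% 700L
    n_pos <- if (is.null(n_per_stratum)) 300L else n_per_stratum
    variant <- locus("risk_variant", c("carrier", "noncarrier"), 0.5, "binomial")
    strata <- list(
      stratum("hsv_negative", n_neg, exposures = c(infection = 0)),
      stratum("hsv_positive", n_pos, exposures = c(infection = 1))
    )
    entries <- tibble::tibble(
      genotype = c("carrier", "noncarrier", "carrier", "noncarrier"),
      stratum  = c("hsv_negative", "hsv_negative", "hsv_positive", "hsv_positive"),
      infection = c(0, 0, 1, 1),
      death_prob = c(or_to_p(0.30, 0.5), 0.30, or_to_p(0.10, 8.0), 0.10)
    )
    pen <- penetrance_table(entries, background_mortality = 0, locus = "risk_variant")
    scenario_config(list(variant), strata, pen, seed = seed)
  }
}

#' @export
print.sm_scenario <- function(x, ...) {
  cat("<scenario>", length(x$loci), "locus/loci,",
      length(x$strata), "strata, seed", x$seed, "\n")
  for (st in x$strata)
    cat("  stratum", st$name, "n =", st$size,
        if (length(st$exposures))
          paste0("[", paste(names(st$exposures), st$exposures,
                            sep = "=", collapse = ", "), "]") else "", "\n")
  for (lc in x$loci)
    cat("  locus", lc$name, paste(lc$allele_labels, collapse = "/"),
        "freq", lc$risk_allele_freq, paste0("(", lc$sampling_mode, ")"), "\n")
  cat("  penetrance:", nrow(x$penetrance$entries), "entries, background",
      x$penetrance$background_mortality, "\n")
  invisible(x)
}

#' Serialise a scenario configuration to YAML
#'
#' The on-disk format is a human-editable YAML document; [read_scenario()]
#' restores an identical configuration (round-trip identity holds for all
#' built-in scenarios).
#'
#' @param config An `sm_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(config, path) {
  validate_scenario(config)
  doc <- list(
    loci = lapply(config$loci, function(l)
      list(name = l$name, allele_labels = as.list(l$allele_labels),
           risk_allele_freq = l$risk_allele_freq,
           sampling_mode = l$sampling_mode)),
    strata = lapply(config$strata, function(s)
      list(name = s$name, size = s$size,
           exposures = as.list(s$exposures))),
    penetrance = list(
      locus = config$penetrance$locus,
      background_mortality = config$penetrance$background_mortality,
      entries = lapply(seq_len(nrow(config$penetrance$entries)), function(i)
        as.list(config$penetrance$entries[i, ]))
    ),
    n_null_loci = config$n_null_loci,
    null_locus_freq = config$null_locus_freq,
    seed = config$seed
  )
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' Read a scenario configuration from YAML
#'
#' @param path Path to a file written by [write_scenario()] (or hand-edited
#'   in the same schema). Validation errors name the offending field.
#' @return A validated `sm_scenario`.
#' @export
read_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  for (field in c("strata", "penetrance", "seed"))
    if (is.null(doc[[field]]))
      abort_glue("scenario file ", path, ": missing required field '", field, "'")
  loci <- lapply(doc$loci, function(l)
    locus(l$name, unlist(l$allele_labels), l$risk_allele_freq, l$sampling_mode))
  strata <- lapply(doc$strata, function(s)
    stratum(s$name, s$size, unlist(s$exposures) %||% numeric()))
  entries <- dplyr::bind_rows(lapply(doc$penetrance$entries, tibble::as_tibble))
  pen <- penetrance_table(entries,
                          background_mortality = doc$penetrance$background_mortality,
                          locus = doc$penetrance$locus)
  scenario_config(loci, strata, pen,
                  n_null_loci = doc$n_null_loci %||% 0L,
                  null_locus_freq = doc$null_locus_freq %||% 0.5,
                  seed = doc$seed)
}
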