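#' Built-in per-residue propensity scales
#'
#' Two classical physicochemical scales, keyed by one-letter residue code:
#' `hopp_woods` (hydrophilicity; high values mark charged, surface-exposed,
#' antibody-accessible stretches) and `kyte_doolittle` (hydropathy; high
#' values mark hydrophobic stretches).
#'
#' @return Named list of named numeric vectors covering all 20 residues.
#' @export
#' @examples
#' aa_scales()$hopp_woods["K"]
aa_scales <- function() {
  list(
    hopp_woods = c(
      A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, Q = 0.2, E = 3.0,
      G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0, M = -1.3, F = -2.5,
      P = 0.0, S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5),
    kyte_doolittle = c(
      A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
      G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
      P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
  )
}

#' Sliding-window propensity profile of a peptide
#'
#' Scores position `i` as the arithmetic mean of the scale values over an
#' odd window centred at `i`, truncated at the sequence ends; `window = 1`
#' returns the raw scale values.
#'
#' @param seq A [peptide()].
#' @param scale A scale name from [aa_scales()] or a named numeric vector
#'   covering all 20 residues.
#' @param window Odd positive integer, at most the sequence length.
#' @return A tibble of class `propensity_profile` with columns `position`,
#'   `residue`, `score`; the window and scale name are attached as
#'   attributes.
#' @export
#' @examples
#' propensity_profile(abeta42(), "hopp_woods", window = 7)
propensity_profile <- function(seq, scale = "hopp_woods", window = 7L) {
  stopifnot(inherits(seq, "peptide"))
  scale_name <- "custom"
  if (is.character(scale)) {
    scales <- aa_scales()
    if (!scale %in% names(scales))
      abort_glue("unknown scale '", scale, "'; built-ins: ",
                 paste(names(scales), collapse = ", "))
    scale_name <- scale
    scale <- scales[[scale]]
  }
  missing_aa <- setdiff(AA_ALPHABET, names(scale))
  if (length(missing_aa))
    abort_glue("scale lacks residue(s): ", paste(missing_aa, collapse = ", "))
  if (window %% 2L == 0L || window < 1L)
    abort_glue("window must be an odd positive integer, got ", window)
  chars <- validate_residues(seq$residues, seq$name)
  n <- length(chars)
  if (window > n)
    abort_glue("window (", window, ") exceeds sequence length (", n, ")")
  raw <- unname(scale[chars])
  h <- (window - 1L) %/% 2L
  score <- vapply(seq_len(n), function(i)
    mean(raw[max(1L, i - h):min(n, i + h)]), numeric(1))
  structure(tibble::tibble(position = seq_len(n), residue = chars,
                           score = score),
            class = c("propensity_profile", class(tibble::tibble())),
            window = as.integer(window), scale_name = scale_name,
            peptide = seq$name)
}

#' Call contiguous above-threshold segments from per-residue scores
#'
#' Maximal runs of consecutive residues whose scores reach the threshold
#' (`>=` when `inclusive`, `>` otherwise) and whose length reaches
#' `min_len`; non-overlapping and sorted by start. The defaults mirror
#' epitope-calling practice: only segments of pentapeptide length or more
#' are regarded as antigenic regions.
#'
#' @param scores Numeric vector of per-residue scores, or a
#'   [propensity_profile()].
#' @param threshold Score threshold (e.g. 0.35 for B-cell, 0.5 for T-cell
#'   antigenicity indices).
#' @param min_len Minimum segment length, default 5.
#' @param inclusive Use `>=` (default) rather than `>`.
#' @param kind Optional label (e.g. `"b_cell"`) copied onto every segment.
#' @return A tibble with columns `start`, `end`, `length`, `mean_score`,
#'   `kind`; empty when nothing reaches the threshold.
#' @export
#' @examples
#' call_segments(abeta_table3()$t_cell, threshold = 0.5, kind = "t_cell")
call_segments <- function(scores, threshold, min_len = 5L, inclusive = TRUE,
                          kind = NA_character_) {
  if (inherits(scores, "propensity_profile")) scores <- scores$score
  if (!is.numeric(scores) || length(scores) == 0L)
    abort_glue("scores must be a non-empty numeric vector")
  above <- if (inclusive) scores >= threshold else scores > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  tibble::tibble(
    start = starts[keep], end = ends[keep],
    length = r$lengths[keep],
    mean_score = vapply(which(keep), function(i)
      mean(scores[starts[i]:ends[i]]), numeric(1)),
    kind = rep(kind, sum(keep)))
}

#' Per-residue scan report combining scores and homology runs
#'
#' One row per query residue with its B- and T-cell antigenicity scores,
#' above-threshold flags, called-segment membership, and the rendered
#' alignments of every homology run covering that residue — the layout of a
#' per-residue mimicry table.
#'
#' @param query A [peptide()].
#' @param subjects Protein set (see [find_runs()]); may be empty.
#' @param b_scores,t_scores Numeric vectors of per-residue antigenicity
#'   scores, same length as the query.
#' @param threshold_b,threshold_t Segment thresholds (defaults 0.35 / 0.5).
#' @param segment_min_len Minimum antigenic segment length (default 5).
#' @param run_min_len Minimum homology run length (default 4).
#' @param scheme A [similarity_scheme()].
#' @param max_mismatch_inside Maximum internal mismatches per run.
#' @return A tibble of class `pepscan_report` with columns `position`,
#'   `residue`, `b_score`, `t_score`, `b_above`, `t_above`, `in_b_segment`,
#'   `in_t_segment`, `alignments`; called segments and runs are attached as
#'   attributes `b_segments`, `t_segments`, `runs`.
#' @export
#' @examples
#' t3 <- abeta_table3()
#' rep <- scan_report(abeta42(), c(synthetic = "AAKLVFFAA"),
#'                    t3$b_cell, t3$t_cell)
#' rep[16:20, ]
scan_report <- function(query, subjects = character(),
                        b_scores, t_scores,
                        threshold_b = 0.35, threshold_t = 0.5,
                        segment_min_len = 5L, run_min_len = 4L,
                        scheme = similarity_scheme(),
                        max_mismatch_inside = 1L) {
  stopifnot(inherits(query, "peptide"))
  n <- nchar(query$residues)
  if (length(b_scores) != n || length(t_scores) != n)
    abort_glue("score vectors must match the query length (", n, "); got ",
               length(b_scores), " and ", length(t_scores))
  runs <- find_runs(query, subjects, scheme = scheme, min_len = run_min_len,
                    max_mismatch_inside = max_mismatch_inside)
  b_seg <- call_segments(b_scores, threshold_b, segment_min_len,
                         kind = "b_cell")
  t_seg <- call_segments(t_scores, threshold_t, segment_min_len,
                         kind = "t_cell")
  in_seg <- function(seg) {
    flag <- rep(FALSE, n)
    for (i in seq_len(nrow(seg))) flag[seg$start[i]:seg$end[i]] <- TRUE
    flag
  }
  alignments <- vapply(seq_len(n), function(pos) {
    hit <- runs$query_start <= pos & runs$query_end >= pos
    if (!any(hit)) return("")
    paste(vapply(which(hit), function(k)
      render_alignment(runs[k, ], query), character(1)), collapse = "; ")
  }, character(1))
  structure(
    tibble::tibble(
      position = seq_len(n),
      residue = strsplit(query$residues, "")[[1]],
      b_score = as.numeric(b_scores), t_score = as.numeric(t_scores),
      b_above = b_scores >= threshold_b, t_above = t_scores >= threshold_t,
      in_b_segment = in_seg(b_seg), in_t_segment = in_seg(t_seg),
      alignments = alignments),
    class = c("pepscan_report", class(tibble::tibble())),
    b_segments = b_seg, t_segments = t_seg, runs = runs,
    thresholds = c(b = threshold_b, t = threshold_t))
}
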