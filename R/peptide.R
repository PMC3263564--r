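AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

validate_residues <- function(residues, name) {
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad))
    abort_glue("sequence '", name, "': invalid residue '", chars[bad[1]],
               "' at position ", bad[1],
               " (allowed: the 20 uppercase amino-acid letters)")
  invisible(chars)
}

#' Define a peptide
#'
#' @param name Identifier.
#' @param residues Non-empty uppercase string over the 20-letter amino-acid
#'   alphabet.
#' @return An object of class `peptide`.
#' @export
#' @examples
#' peptide("KLVFF_motif", "KLVFF")
peptide <- function(name, residues) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(residues), length(residues) == 1L, nzchar(residues))
  validate_residues(residues, name)
  structure(list(name = name, residues = residues), class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide>", x$name, paste0("(", nchar(x$residues), " aa)"), "\n ",
      x$residues, "\n")
  invisible(x)
}

#' The beta-amyloid 1-42 peptide
#'
#' The 42-residue amyloid-beta peptide, the query of the bundled antigenicity
#' and homology fixtures (see [abeta_table3()]).
#'
#' @return A [peptide()] named `ABETA42`.
#' @export
#' @examples
#' abeta42()
abeta42 <- function() {
  peptide("ABETA42", "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA")
}

#' Residue similarity scheme
#'
#' Classifies an aligned residue pair as `identical`, `similar` or
#' `mismatch`. The default follows the BLAST convention behind '+' marks:
#' non-equal residues are similar when their BLOSUM62 substitution score is
#' strictly positive.
#'
#' @param name Scheme identifier; `"blosum62"` builds the default
#'   classifier.
#' @param classifier Optional `function(x, y)` returning one of
#'   `"identical"`, `"similar"`, `"mismatch"`; must be symmetric and return
#'   `"identical"` exactly for equal residues.
#' @return An object of class `similarity_scheme`.
#' @export
#' @examples
#' sch <- similarity_scheme()
#' sch$classifier("D", "E") # BLOSUM62 score 2 > 0
similarity_scheme <- function(name = "blosum62", classifier = NULL) {
  if (is.null(classifier)) {
    if (name != "blosum62")
      abort_glue("no built-in classifier named '", name,
                 "'; supply `classifier` explicitly")
    mat <- blosum62_matrix()
    classifier <- function(x, y) {
      if (x == y) "identical"
      else if (mat[x, y] > 0) "similar"
      else "mismatch"
    }
  }
  structure(list(name = name, classifier = classifier),
            class = "similarity_scheme")
}

blosum62_env <- new.env(parent = emptyenv())
blosum62_matrix <- function() {
  if (is.null(blosum62_env$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_env$mat <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  }
  blosum62_env$mat
}

# integer pair-code matrix over the alphabet: 2 identical, 1 similar, 0 mismatch
# (cached for the default BLOSUM62 scheme)
scheme_code_matrix <- function(scheme) {
  if (scheme$name == "blosum62" && !is.null(blosum62_env$codes))
    return(blosum62_env$codes)
  n <- length(AA_ALPHABET)
  codes <- matrix(0L, n, n, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cl <- scheme$classifier(AA_ALPHABET[i], AA_ALPHABET[j])
    codes[i, j] <- switch(cl, identical = 2L, similar = 1L, mismatch = 0L,
                          abort_glue("classifier returned '", cl, "'"))
  }
  if (!identical(codes, t(codes)))
    abort_glue("similarity scheme is not symmetric")
  if (any(diag(codes) != 2L))
    abort_glue("similarity scheme must classify equal residues as identical")
  if (scheme$name == "blosum62") blosum62_env$codes <- codes
  codes
}

normalize_subjects <- function(subjects) {
  if (inherits(subjects, "peptide"))
    return(stats::setNames(subjects$residues, subjects$name))
  if (is.data.frame(subjects)) {
    stopifnot(all(c("id", "seq") %in% names(subjects)))
    return(stats::setNames(subjects$seq, subjects$id))
  }
  if (methods::is(subjects, "AAStringSet"))
    return(stats::setNames(as.character(subjects), names(subjects)))
  if (is.character(subjects)) {
    if (length(subjects) == 0L)
      return(stats::setNames(character(), character()))
    if (is.null(names(subjects)))
      names(subjects) <- paste0("subject_", seq_along(subjects))
    return(subjects)
  }
  abort_glue("subjects must be a named character vector, a data frame with ",
             "columns id/seq, an AAStringSet, or a peptide")
}

#' Find identical/similar residue runs between a query and protein subjects
#'
#' Scans every ungapped offset of the query against each subject and
#' reports every maximal run whose first and last positions are identical
#' or similar residues, containing at most `max_mismatch_inside` internal
#' mismatches, of length at least `min_len`. A run is maximal when it
#' cannot be extended in either direction without breaking these
#' constraints; overlapping maximal runs on the same diagonal (sharing a
#' match block across different mismatch spans) are all reported.
#'
#' @param query A [peptide()].
#' @param subjects Protein set: named character vector, data frame with
#'   `id`/`seq`, `AAStringSet`, or a single [peptide()].
#' @param scheme A [similarity_scheme()].
#' @param min_len Minimum run length (>= 2); default 4, the shortest
#'   alignment worth reporting for short-peptide mimicry scans.
#' @param max_mismatch_inside Maximum internal mismatches per run
#'   (default 1).
#' @return A tibble with one row per run: `subject_id`, `query_start`,
#'   `query_end`, `subject_start`, `subject_end`, `length`, `mask` (query
#'   letters at identities, `'+'` at similarities, `' '` at internal
#'   mismatches), `n_identical`, `n_similar`; sorted by
#'   (`subject_id`, `subject_start`).
#' @export
#' @examples
#' find_runs(abeta42(), c(synthetic = "GGGKLVFFGGG"))
find_runs <- function(query, subjects, scheme = similarity_scheme(),
                      min_len = 4L, max_mismatch_inside = 1L) {
  stopifnot(inherits(query, "peptide"), min_len >= 2L,
            max_mismatch_inside >= 0L)
  subjects <- normalize_subjects(subjects)
  codes <- scheme_code_matrix(scheme)
  qch <- validate_residues(query$residues, query$name)
  qidx <- match(qch, AA_ALPHABET)
  lq <- length(qch)

  out <- list()
  for (sid in names(subjects)) {
    sch <- validate_residues(subjects[[sid]], sid)
    sidx <- match(sch, AA_ALPHABET)
    ls <- length(sch)
    for (off in (1L - lq):(ls - 1L)) {
      qlo <- max(1L, 1L - off); qhi <- min(lq, ls - off)
      if (qhi - qlo + 1L < min_len) next
      st <- codes[cbind(qidx[qlo:qhi], sidx[(qlo:qhi) + off])]
      runs <- maximal_runs(st, max_mismatch_inside, min_len)
      for (r in runs) {
        w <- st[r[1]:r[2]]
        qs <- qlo + r[1] - 1L; qe <- qlo + r[2] - 1L
        mask <- character(length(w))
        mask[w == 2L] <- qch[qs:qe][w == 2L]
        mask[w == 1L] <- "+"
        mask[w == 0L] <- " "
        out[[length(out) + 1L]] <- tibble::tibble(
          subject_id = sid, query_start = qs, query_end = qe,
          subject_start = qs + off, subject_end = qe + off,
          length = qe - qs + 1L, mask = paste(mask, collapse = ""),
          n_identical = sum(w == 2L), n_similar = sum(w == 1L))
      }
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(subject_id = character(), query_start = integer(),
                   query_end = integer(), subject_start = integer(),
                   subject_end = integer(), length = integer(),
                   mask = character(), n_identical = integer(),
                   n_similar = integer())
  dplyr::arrange(res, .data$subject_id, .data$subject_start, .data$query_start)
}

# maximal windows over a 0/1/2 state vector: ends non-zero, at most k zeros
# inside, length >= min_len; returns list of c(start, end) indices
maximal_runs <- function(st, k, min_len) {
  r <- rle(st == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blocks <- which(!r$values) # runs of non-mismatch states
  if (!length(blocks)) return(list())
  bs <- starts[blocks]; be <- ends[blocks]
  nb <- length(blocks)
  gaps <- if (nb > 1L) bs[-1L] - be[-nb] - 1L else integer() # zeros between blocks
  res <- list()
  j_prev <- 0L
  for (i in seq_len(nb)) {
    j <- i
    budget <- k
    while (j < nb && gaps[j] <= budget) {
      budget <- budget - gaps[j]
      j <- j + 1L
    }
    if (i == 1L || j > j_prev) { # left-maximal (else contained in previous)
      if (be[j] - bs[i] + 1L >= min_len)
        res[[length(res) + 1L]] <- c(bs[i], be[j])
    }
    j_prev <- j
  }
  res
}

#' Render a match run in alignment-mask notation
#'
#' Identical positions show the query letter, similar positions `'+'`,
#' internal mismatches `' '`; the subject identifier is appended after a
#' space (as in `"KLVFF H. pylori"`).
#'
#' @param run One row of a [find_runs()] result (data frame row or list).
#' @param query The query [peptide()] the run was found against.
#' @param include_id Append the subject identifier (default `TRUE`).
#' @return A single string.
#' @export
#' @examples
#' runs <- find_runs(abeta42(), c("H. pylori" = "AAKLVFFAA"))
#' render_alignment(runs[1, ], abeta42())
render_alignment <- function(run, query, include_id = TRUE) {
  run <- as.list(run)
  stopifnot(inherits(query, "peptide"))
  if (run$query_start < 1L || run$query_end > nchar(query$residues) ||
      run$query_start > run$query_end)
    abort_glue("run positions [", run$query_start, ", ", run$query_end,
               "] fall outside query '", query$name, "' (length ",
               nchar(query$residues), ")")
  if (nchar(run$mask) != run$query_end - run$query_start + 1L)
    abort_glue("mask length disagrees with run coordinates")
  qseg <- strsplit(substr(query$residues, run$query_start, run$query_end),
                   "")[[1]]
  mch <- strsplit(run$mask, "")[[1]]
  letters_at <- !mch %in% c("+", " ")
  if (any(mch[letters_at] != qseg[letters_at]))
    abort_glue("mask letters disagree with the query sequence over the run")
  if (include_id) paste(run$mask, run$subject_id) else run$mask
}

#' Read a protein subject set from FASTA
#'
#' Standard multi-record FASTA; the description line is split into the
#' identifier (first whitespace-delimited token) and free text.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `seq`, directly
#'   usable as the `subjects` of [find_runs()].
#' @export
read_subjects <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  full <- names(set)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  tibble::tibble(id = id, description = desc, seq = as.character(set))
}
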