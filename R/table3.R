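#' Bundled antigenicity indices for beta-amyloid 1-42
#'
#' Per-residue B-cell and T-cell antigenicity indices for the 42-residue
#' amyloid-beta peptide, as produced by a charge/hydrophobicity epitope
#' predictor. These ship as a fixed fixture so that segment calling is
#' testable exactly: at the conventional thresholds (0.35 B-cell, 0.5
#' T-cell, inclusive, pentapeptide minimum) the B-cell column yields the
#' segments 1-12 and 24-28 and the T-cell column exactly 16-20, which
#' spells KLVFF. The same values are available on disk as
#' `system.file("extdata", "abeta42_table3_scores.tsv", package =
#' "stratamask")`.
#'
#' @return A 42-row tibble with columns `position`, `residue`, `b_cell`,
#'   `t_cell`.
#' @export
#' @examples
#' call_segments(abeta_table3()$b_cell, 0.35, kind = "b_cell")
abeta_table3 <- function() {
  b <- c(0.41, 0.35, 0.62, 0.73, 0.85, 0.57, 0.69, 0.38, 0.63, 0.56,
         0.58, 0.35, -0.17, -0.66, -1.03, -1.47, -1.34, -1.20, -0.93,
         -0.98, -0.82, -0.31, 0.23, 0.81, 1.24, 1.22, 0.90, 0.36, 0.30,
         -0.24, -0.58, -1.00, -1.14, -1.19, -1.23, -1.16, -0.97, -1.02,
         -0.63, -0.45, -0.80, -1.06)
  t <- c(0.04, 0.78, 0.02, 0.93, 0.05, 0.14, 0.03, 0.02, 0.04, 0.96,
         0.02, 0.90, 0.10, 0.11, 0.03, 0.93, 0.95, 0.68, 0.69, 0.74,
         0.05, 0.05, 0.11, 0.88, 0.03, 0.03, 0.03, 0.30, 0.10, 0.05,
         0.07, 0.13, 0.03, 0.72, 0.13, 0.23, 0.03, 0.03, 0.23, 0.33,
         0.95, 0.83)
  seq <- abeta42()$residues
  tibble::tibble(position = 1:42,
                 residue = strsplit(seq, "")[[1]],
                 b_cell = b, t_cell = t)
}
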