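test_that("the bundled amyloid-beta peptide and score fixture are consistent", {
  ab <- abeta42()
  expect_equal(nchar(ab$residues), 42L)
  expect_equal(ab$residues, "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA")
  t3 <- abeta_table3()
  expect_equal(nrow(t3), 42L)
  expect_equal(paste(t3$residue, collapse = ""), ab$residues)
  disk <- readr::read_tsv(system.file("extdata", "abeta42_table3_scores.tsv",
                                      package = "stratamask"),
                          show_col_types = FALSE)
  expect_equal(tibble::as_tibble(disk), t3)
})

test_that("find_runs locates known motifs and the full self-match", {
  ab <- abeta42()
  runs <- find_runs(ab, c("H. pylori" = "AAKLVFFAA"), min_len = 5)
  klvff <- dplyr::filter(runs, query_start <= 16, query_end >= 20)
  expect_equal(nrow(klvff), 1L)
  expect_equal(substr(klvff$mask,
                      16 - klvff$query_start + 1,
                      20 - klvff$query_start + 1), "KLVFF")
  self <- find_runs(ab, stats::setNames(ab$residues, "self"),
                    min_len = 42, max_mismatch_inside = 0)
  expect_equal(nrow(self), 1L)
  expect_equal(self$query_start, 1L)
  expect_equal(self$query_end, 42L)
  expect_equal(self$n_identical, 42L)
  expect_error(find_runs(ab, c(bad = "KLXFF")), "position 3")
})

test_that("find_runs equals the exhaustive enumeration oracle", {
  sch <- similarity_scheme()
  codes <- stratamask:::scheme_code_matrix(sch)
  # biased alphabet so identities and similarities actually occur
  letters_pool <- c("A", "R", "N", "D", "K", "L", "V", "F", "E", "Q")
  set.seed(2024)
  for (i in 1:60) {
    lq <- sample(5:20, 1)
    ls <- sample(5:min(60, 2000 %/% lq), 1)
    q <- paste(sample(letters_pool, lq, replace = TRUE), collapse = "")
    s <- paste(sample(letters_pool, ls, replace = TRUE), collapse = "")
    k <- sample(0:2, 1)
    ml <- sample(3:5, 1)
    got <- find_runs(peptide("q", q), c(subj = s), sch,
                     min_len = ml, max_mismatch_inside = k)
    want <- brute_runs(q, s, codes, k, ml)
    expect_equal(nrow(got), nrow(want), info = paste("case", i))
    if (nrow(got)) {
      got_o <- got[order(got$subject_start, got$query_start), ]
      expect_equal(got_o$query_start, want$query_start)
      expect_equal(got_o$query_end, want$query_end)
      expect_equal(got_o$subject_start, want$subject_start)
    }
  }
})

test_that("alignment masks follow the letter/plus/space notation", {
  ab <- abeta42()
  runs <- find_runs(ab, c("H. pylori" = "KLVFF"), min_len = 5)
  expect_equal(render_alignment(runs[1, ], ab), "KLVFF H. pylori")
  expect_equal(render_alignment(runs[1, ], ab, include_id = FALSE), "KLVFF")
  # similar residue at the run start renders as '+' (E ~ D in BLOSUM62)
  runs2 <- find_runs(ab, c("P. gingivalis" = "EAEFR"), min_len = 5)
  expect_equal(render_alignment(runs2[1, ], ab, include_id = FALSE), "+AEFR")
  # an all-similar run renders as all '+': query DD vs subject EE
  q <- peptide("q", "GGDDGG")
  runs3 <- find_runs(q, c(s = "YYEEYY"), min_len = 2)
  all_plus <- dplyr::filter(runs3, mask == "++")
  expect_equal(nrow(all_plus), 1L)
  # internal mismatches render as spaces
  runs4 <- find_runs(ab, c(s = "DAYFRH"), min_len = 4)
  expect_equal(render_alignment(runs4[1, ], ab, include_id = FALSE), "DA FRH")
  # out-of-bounds runs are rejected
  bad <- runs[1, ]
  bad$query_end <- 99L
  expect_error(render_alignment(bad, ab), "outside")
  # masks have exactly the run length
  allr <- find_runs(ab, read_subjects(system.file(
    "extdata", "synthetic_subjects.fasta", package = "stratamask")))
  expect_true(all(nchar(allr$mask) == allr$length))
})

test_that("reversed subjects only match where the reversed text really does", {
  ab <- abeta42()
  fwd <- find_runs(ab, c(s = "AAKLVFFAA"), min_len = 5)
  rev_seq <- paste(rev(strsplit("AAKLVFFAA", "")[[1]]), collapse = "")
  bwd <- find_runs(ab, c(s = rev_seq), min_len = 5)
  expect_true(any(grepl("KLVFF", fwd$mask, fixed = TRUE)))
  expect_false(any(grepl("KLVFF", bwd$mask, fixed = TRUE)))
})

test_that("propensity profiles average the scale over truncated windows", {
  ab <- abeta42()
  hw <- aa_scales()$hopp_woods
  raw <- propensity_profile(ab, "hopp_woods", window = 1)
  expect_equal(raw$score, unname(hw[strsplit(ab$residues, "")[[1]]]))
  w7 <- propensity_profile(ab, "hopp_woods", window = 7)
  expect_equal(w7$score[4],
               mean(hw[strsplit(substr(ab$residues, 1, 7), "")[[1]]]))
  # truncation at the N-terminus: position 1 averages residues 1..4
  expect_equal(w7$score[1],
               mean(hw[strsplit(substr(ab$residues, 1, 4), "")[[1]]]))
  homo <- propensity_profile(peptide("polyK", "KKKKKKK"), "hopp_woods", 5)
  expect_true(all(homo$score == hw[["K"]]))
  expect_error(propensity_profile(ab, "hopp_woods", window = 4), "odd")
  expect_error(propensity_profile(peptide("short", "KLV"), "hopp_woods", 7),
               "exceeds")
})

test_that("segment calling reproduces the fixture's antigenic regions", {
  t3 <- abeta_table3()
  b <- call_segments(t3$b_cell, 0.35, min_len = 5, inclusive = TRUE,
                     kind = "b_cell")
  expect_equal(nrow(b), 2L)
  expect_equal(b$start, c(1L, 24L))
  expect_equal(b$end, c(12L, 28L))
  tt <- call_segments(t3$t_cell, 0.5, min_len = 5, inclusive = TRUE,
                      kind = "t_cell")
  expect_equal(nrow(tt), 1L)
  expect_equal(c(tt$start, tt$end), c(16L, 20L))
  expect_equal(substr(abeta42()$residues, tt$start, tt$end), "KLVFF")
  # strict thresholding drops the residues scored exactly 0.35 (A2, V12)
  b_strict <- call_segments(t3$b_cell, 0.35, min_len = 5, inclusive = FALSE)
  expect_equal(b_strict$start, c(3L, 24L))
  expect_equal(b_strict$end, c(11L, 28L))
  expect_equal(nrow(call_segments(t3$t_cell, 2)), 0L)
})

test_that("min_len 1 segments partition exactly the above-threshold set", {
  set.seed(1)
  for (i in 1:20) {
    sc <- runif(50, -1, 1)
    th <- runif(1, -0.5, 0.5)
    seg <- call_segments(sc, th, min_len = 1)
    covered <- rep(FALSE, 50)
    for (j in seq_len(nrow(seg))) covered[seg$start[j]:seg$end[j]] <- TRUE
    expect_equal(covered, sc >= th)
  }
})

test_that("the per-residue scan report combines scores and alignments", {
  t3 <- abeta_table3()
  subj <- read_subjects(system.file("extdata", "synthetic_subjects.fasta",
                                    package = "stratamask"))
  rep <- scan_report(abeta42(), subj, t3$b_cell, t3$t_cell)
  expect_equal(nrow(rep), 42L)
  expect_true(all(nzchar(rep$alignments[c(16, 24, 36)])))
  expect_match(rep$alignments[16], "KLVFF")
  expect_match(rep$alignments[24], "VGSNK")
  expect_match(rep$alignments[36], "VGGVV")
  expect_true(all(rep$in_t_segment[16:20]))
  expect_true(all(rep$in_b_segment[1:12]))
  expect_false(any(rep$in_b_segment[13:23]))
  # empty subject set: scores only
  rep0 <- scan_report(abeta42(), character(), t3$b_cell, t3$t_cell)
  expect_true(all(rep0$alignments == ""))
  # subject equal to query: every row covered by the self-run
  repself <- scan_report(abeta42(), stats::setNames(abeta42()$residues, "self"),
                         t3$b_cell, t3$t_cell)
  expect_true(all(nzchar(repself$alignments)))
  expect_error(scan_report(abeta42(), character(), t3$b_cell[1:10], t3$t_cell),
               "length")
})
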