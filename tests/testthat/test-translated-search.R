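test_that("six-frame translation follows the codon-table conventions", {
  fr <- six_frame_translate("ATGAAATAG")
  expect_equal(fr[["+1"]], "MK*")
  expect_equal(six_frame_translate("ATGNAA")[["+1"]], "MX")
  expect_error(six_frame_translate(""), "empty")
  # strand symmetry: frame +1 of revcomp(S) equals frame -1 of S
  set.seed(31)
  for (i in 1:5) {
    s <- random_nt(sample(30:90, 1))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(six_frame_translate(rc)[["+1"]],
                 six_frame_translate(s)[["-1"]])
  }
})

test_that("smith_waterman matches scoring conventions and edge cases", {
  mat <- aranevir:::scoring_matrix("BLOSUM62")
  s <- "MKVLAWGHEE"
  self <- smith_waterman(s, s)
  diag_sum <- sum(mat[cbind(strsplit(s, "")[[1]], strsplit(s, "")[[1]])])
  expect_equal(self$score, diag_sum)
  expect_equal(self$pct_identity, 100)

  # no positive-scoring residue pair -> empty alignment, score 0
  none <- smith_waterman("PP", "WW")
  expect_equal(none$score, 0)
  expect_length(none$query_span, 0)

  expect_error(smith_waterman("MKB!", "MK"), "unknown residue")
  expect_error(smith_waterman("", "MK"), "empty")
})

test_that("smith_waterman equals exhaustive enumeration on short pairs", {
  mat <- aranevir:::scoring_matrix("BLOSUM62")
  set.seed(17)
  for (i in 1:25) {
    a <- random_aa(sample(2:8, 1))
    b <- random_aa(sample(2:8, 1))
    expect_equal(smith_waterman(a, b)$score,
                 brute_local_score(a, b, mat),
                 info = paste(a, b))
  }
  # the textbook pair, against the same oracle
  expect_equal(smith_waterman("HEAGAWGHEE", "PAWHEAE")$score,
               brute_local_score("HEAGAWGHEE", "PAWHEAE", mat))
})

test_that("smith_waterman agrees with an independent aligner", {
  mat <- aranevir:::scoring_matrix("BLOSUM62")
  set.seed(23)
  for (i in 1:10) {
    a <- random_aa(sample(20:120, 1))
    b <- random_aa(sample(20:120, 1))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(smith_waterman(a, b)$score, max(0, ref))
  }
})

test_that("evalue implements the Karlin-Altschul formula", {
  expect_equal(evalue(100, m = 100, n = 1e5),
               0.041 * 1e7 * exp(-26.7))
  expect_equal(evalue(50, 100, 2e5), 2 * evalue(50, 100, 1e5))
  expect_lt(evalue(1e4, 100, 1e5), 1e-300)
  s <- seq(10, 100, by = 10)
  expect_true(all(diff(evalue(s, 100, 1e5)) < 0))
})

test_that("translated search finds planted proteins and honors the cutoff", {
  ds <- build_dataset(small_config(), seed = 7)
  hits <- translated_search(ds$transcripts, ds$proteins)
  expect_true("miniPV" %in% hits$transcript)
  expect_true(all(hits$evalue <= 1e-5))
  expect_false(any(grepl("^host_", hits$transcript)))
  expect_equal(nrow(translated_search(ds$transcripts, ds$proteins,
                                      max_evalue = 0)), 0L)
  expect_error(translated_search(ds$transcripts,
                                 Biostrings::AAStringSet()), "empty")
})

test_that("hit nt spans map back onto the aligned frame translation", {
  ds <- build_dataset(small_config(), seed = 7)
  # add a reverse-sense candidate so both strands are exercised
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ds$transcripts[["miniPV"]])))
  tx <- c(as.character(ds$transcripts), miniPV_rc = rc)
  hits <- translated_search(tx, ds$proteins)
  expect_true(all(c("miniPV", "miniPV_rc") %in% hits$transcript))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    sub <- substr(tx[[h$transcript]], h$t_start, h$t_end)
    if (startsWith(h$frame, "-")) {
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    }
    aa <- aranevir:::translate_nt(sub)
    sw <- smith_waterman(aa, as.character(ds$proteins[[h$ref]]))
    # re-translating the mapped span reproduces the aligned aa substring
    expect_equal(substr(aa, sw$query_span[1], sw$query_span[2]),
                 gsub("-", "", sw$aligned[["query"]]))
    expect_equal(sw$score, h$score)
  }
})

test_that("collapse_hits applies the 50%-overlap redundancy rule", {
  base <- data.frame(transcript = "t1", frame = "+1", t_start = 1,
                     t_end = 300, ref = "r1", r_start = 1, r_end = 100,
                     score = 200, evalue = 1e-10, pident = 50)
  h2 <- transform(base, t_start = 100, t_end = 400, ref = "r2",
                  evalue = 1e-8)
  h3 <- transform(base, t_start = 150, t_end = 450, ref = "r3",
                  evalue = 1e-6)
  res <- collapse_hits(rbind(base, h2, h3))
  expect_equal(nrow(res), 1L)
  expect_equal(res$ref, "r1")        # lowest E-value wins

  disjoint <- transform(base, t_start = 500, t_end = 800, ref = "r4",
                        evalue = 1e-7)
  res2 <- collapse_hits(rbind(base, disjoint))
  expect_equal(nrow(res2), 2L)
  expect_equal(unique(res2$candidate), "t1")

  # idempotence on duplicated input
  res3 <- collapse_hits(rbind(base, base))
  expect_equal(nrow(res3), 1L)
  expect_equal(res3$ref, base$ref)
})
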