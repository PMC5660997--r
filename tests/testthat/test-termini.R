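test_that("a constructed complementary terminus gives a full duplex", {
  set.seed(3)
  five <- random_nt(40)
  # exact reverse complement of the whole window: a perfect 40-nt duplex
  rc40 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(five)))
  res40 <- panhandle_duplex(five, rc40)
  expect_equal(res40$duplex_len, 40L)
  expect_equal(res40$paired_fraction, 1.0)

  # 32-nt complementary core with a guaranteed non-pairing tail
  five2 <- paste0(random_nt(32), strrep("A", 8))
  three2 <- paste0(strrep("C", 8),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(substr(five2, 1, 32)))))
  res <- panhandle_duplex(five2, three2)
  expect_equal(res$duplex_len, 32L)
  expect_equal(res$paired_fraction, 1.0)
  expect_true(all(res$pairs$type %in% c("WC", "GU")))
  # pair list is strictly monotone (no crossing)
  expect_true(all(diff(res$pairs$pos5) > 0))
  expect_true(all(diff(res$pairs$pos3) > 0))
})

test_that("G-U wobble counts as paired", {
  # 5' GGGGG... vs 3' terminus ending ...TTTTT read inward: G:T pairs
  five <- paste0(strrep("G", 12), strrep("A", 28))
  three <- paste0(strrep("C", 28), strrep("T", 12))
  res <- panhandle_duplex(five, three)
  expect_gte(res$duplex_len, 12)
  expect_true(all(res$pairs$type[1:12] == "GU"))
})

test_that("Watson-Crick duplexes survive segment reverse-complement", {
  # the duplex of the complementary strand consists of the complementary
  # pairs, so Watson-Crick panhandles are preserved exactly (G·U wobble
  # is not complement-symmetric: it becomes C·A and melts)
  set.seed(41)
  for (i in 1:5) {
    core <- random_nt(120)
    seg <- paste0(core, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(core))))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seg)))
    d1 <- panhandle_duplex(substr(seg, 1, 40), substr(seg, 201, 240))
    d2 <- panhandle_duplex(substr(rc, 1, 40), substr(rc, 201, 240))
    expect_equal(d1$duplex_len, 40L)
    expect_equal(d2$duplex_len, 40L)
    expect_equal(d1$paired_fraction, d2$paired_fraction)
  }
})

test_that("degenerate window warns; oversized window errors", {
  expect_warning(panhandle_duplex("ACGTACGTA", "ACGTACGTA", w = 8),
                 "degenerate")
  expect_error(panhandle_duplex("ACGT", "ACGTACGT", w = 20), "exceeds")
})

test_that("nussinov_fold handles the textbook hairpin and edge cases", {
  r <- nussinov_fold("GGGAAACCC")
  expect_equal(r$structure, "(((...)))")
  expect_equal(r$n_pairs, 3L)
  expect_equal(r$stem_loops, 1L)

  pa <- nussinov_fold(strrep("A", 20))
  expect_equal(pa$structure, strrep(".", 20))
  expect_equal(pa$n_pairs, 0L)

  expect_error(nussinov_fold(random_nt(301)), "300")
})

test_that("nussinov structures are well-formed and loop-constrained", {
  set.seed(6)
  for (i in 1:10) {
    s <- random_nt(sample(10:40, 1))
    r <- nussinov_fold(s)
    ch <- strsplit(r$structure, "")[[1]]
    expect_equal(sum(ch == "("), sum(ch == ")"))
    expect_equal(sum(ch == "("), r$n_pairs)
    depth <- cumsum((ch == "(") - (ch == ")"))
    expect_true(all(depth >= 0))
    if (nrow(r$pairs)) expect_true(all(r$pairs$j - r$pairs$i > 3))
  }
})

test_that("nussinov pair count equals the exhaustive maximum (<= 12 nt)", {
  set.seed(19)
  for (i in 1:20) {
    s <- random_nt(sample(6:12, 1))
    expect_equal(nussinov_fold(s)$n_pairs, brute_max_pairs(s),
                 info = s)
  }
})

test_that("the planted 3'UTR triple stem-loop folds into three hairpins", {
  ds <- cached_dataset(1)
  seg <- ds$truth$viruses$SynAV1$segments[[1]]
  s <- as.character(ds$transcripts[["SynAV1"]])
  sl <- seg$utr3_stemloop
  utr <- substr(s, sl[1], sl[2])
  r <- nussinov_fold(utr)
  expect_equal(r$n_pairs, 24L)     # three engineered 8-bp GC stems
  expect_equal(r$stem_loops, 3L)
})
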