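test_that("find_orfs reports stop-inclusive coordinates from the first ATG", {
  o <- find_orfs("AAATGAAATAA", min_aa = 1)
  expect_equal(nrow(o), 1L)
  expect_equal(c(o$start, o$end), c(3, 11))
  expect_equal(o$aa_length, 2L)
  expect_equal(o$protein, "MK")
  expect_equal(o$orientation, "forward")

  # no start codon anywhere -> empty
  expect_equal(nrow(find_orfs("CCCCCCCCCCCC", min_aa = 1)), 0L)

  # nested ATGs: the ORF starts at the FIRST ATG of the stop-bounded region
  o2 <- find_orfs("ATGAAAATGAAATAA", min_aa = 1, both_strands = FALSE)
  expect_equal(o2$start[1], 1)
  expect_equal(o2$protein[1], "MKMK")
})

test_that("reverse-strand ORFs keep ascending deposited coordinates", {
  fwd <- "AAATGAAATAA"
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  o <- find_orfs(rev, min_aa = 1)
  expect_equal(o$orientation, "reverse")
  L <- nchar(rev)
  expect_equal(c(o$start, o$end), c(L - 11 + 1, L - 3 + 1))
  expect_lt(o$start, o$end)
  expect_equal(o$protein, "MK")
})

test_that("every reported ORF satisfies the aa-length arithmetic", {
  set.seed(5)
  for (i in 1:10) {
    s <- random_nt(600)
    o <- find_orfs(s, min_aa = 5)
    if (nrow(o) == 0) next
    expect_equal(o$aa_length, (o$end - o$start + 1) %/% 3 - 1)
    expect_true(all((o$end - o$start + 1) %% 3 == 0))
    expect_equal(o$aa_length, nchar(o$protein))
  }
})

test_that("orf_aa_length handles the minimal ORF and inconsistent spans", {
  expect_equal(orf_aa_length(1, 6), 1L)
  expect_error(orf_aa_length(722, 7226), "not divisible by 3")
  expect_error(orf_aa_length(722, 7226), "722")
  expect_error(orf_aa_length(10, 5), "greater than start")
})

test_that("protein masses follow the average-mass + water convention", {
  expect_equal(protein_mass_kda("G"), 0.07507, tolerance = 1e-4)
  expect_equal(protein_mass_kda("GG"), 0.13212, tolerance = 1e-4)
  # additivity: mass(AB) = mass(A) + mass(B) - one water
  set.seed(8)
  a <- random_aa(12); b <- random_aa(9)
  expect_equal(protein_mass_kda(paste0(a, b)),
               protein_mass_kda(a) + protein_mass_kda(b) - 0.01801524,
               tolerance = 1e-9)
  expect_error(protein_mass_kda("GXZ9"), "unknown residue")
})

test_that("utr_profile counts UUUA motifs and window composition", {
  seq <- paste0("TTTATTTA", "ATG", strrep("GCA", 40), "TAA", "CCCC")
  orfs <- find_orfs(seq, min_aa = 10)
  p <- utr_profile(seq, orfs, window = 8, step = 4)
  expect_equal(p$utr5_len, 8L)
  expect_equal(p$uuua_count, 2L)
  expect_equal(p$utr3_len, 4L)
  first <- p$windows[1, ]
  expect_equal(first$au_fraction, 1)
  expect_equal(first$gc_fraction + first$au_fraction, 1)
})

test_that("the planted AU-rich leader is recovered from the profile", {
  ds <- cached_dataset(1)
  seg <- ds$truth$viruses$SynPV1$segments[[1]]
  s <- as.character(ds$transcripts[[seg$id]])
  orfs <- find_orfs(s, min_aa = 300)
  p <- utr_profile(s, orfs)
  expect_equal(p$utr5_len, 760L)
  leader <- p$windows[p$windows$position + 100 - 1 <= 760, ]
  expect_gte(mean(leader$au_fraction), 0.65)
  expect_gte(p$uuua_count, 3L)
})

test_that("pairwise identity is column-based and symmetric", {
  expect_equal(pairwise_identity("ACGT", "ACGT", "nt"), 100)
  expect_equal(pairwise_identity("ACGT", "ACGA", "nt"), 75)
  set.seed(12)
  a <- random_nt(50); b <- random_nt(50)
  expect_equal(pairwise_identity(a, b, "nt"), pairwise_identity(b, a, "nt"))
  p1 <- random_aa(40); p2 <- random_aa(40)
  expect_equal(pairwise_identity(p1, p2, "aa"),
               pairwise_identity(p2, p1, "aa"))
})

test_that("GFF3 export writes one CDS per ORF", {
  o <- find_orfs("AAATGAAATAA", min_aa = 1)
  f <- tempfile(fileext = ".gff3")
  on.exit(unlink(f))
  orfs_to_gff3(o, "toy", f)
  lines <- readLines(f)
  expect_true(any(grepl("gff-version 3", lines)))
  cds <- grep("\tCDS\t", lines, value = TRUE)
  expect_length(cds, 1L)
  expect_true(grepl("aa_length=2", cds))
})
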