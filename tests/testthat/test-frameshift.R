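test_that("slippery templates are validated against X_XXX_XXY", {
  expect_equal(aranevir:::slippery_template_to_heptamer("U_UUU_UUA"),
               "TTTTTTA")
  expect_equal(aranevir:::slippery_template_to_heptamer("A_AAA_AAC"),
               "AAAAAAC")
  # two different bases in the two triads is allowed (X_XXX_ZZY style)
  expect_equal(aranevir:::slippery_template_to_heptamer("G_GGA_AAC"),
               "GGGAAAC")
  # non-homogeneous triad or Y equal to the preceding base is not
  expect_error(aranevir:::slippery_template_to_heptamer("A_AGA_AAC"),
               "X_XXX_XXY")
  expect_error(aranevir:::slippery_template_to_heptamer("A_AAA_AAA"),
               "X_XXX_XXY")
})

test_that("detect_pseudoknot recognizes knotted but not nested topologies", {
  # anchor, gap(6), stem1a(6), loop1(2+5), stem1b(6), spacer(6), stem2b(5)
  s1 <- "GCTGCA"; s2 <- "GGCAC"
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  knot <- paste0(strrep("A", 10), "TTTTTT", "AACAAC", s1, "AT", s2,
                 rc(s1), "ACATCA", rc(s2), strrep("A", 8))
  res <- detect_pseudoknot(knot, anchor = 16)
  expect_true(res$present)
  # stem1 begins inside the 5-12 nt window after the anchor
  expect_gte(res$stem1[1], 21); expect_lte(res$stem1[1], 28)
  expect_gt(res$stem2[3], res$stem1[3])      # crossing topology

  # a plain hairpin (no loop base pairs downstream) is not a pseudoknot
  hairpin <- paste0(strrep("A", 10), "TTTTTT", "AACAAC", s1, "AAAAAAA",
                    rc(s1), strrep("A", 40))
  expect_false(detect_pseudoknot(hairpin, anchor = 16)$present)

  # single-base sequence: nothing to pair
  expect_false(detect_pseudoknot(strrep("A", 60), anchor = 5)$present)
  # anchor too close to the 3' end
  expect_false(detect_pseudoknot(knot, anchor = nchar(knot) - 3)$present)
  expect_error(detect_pseudoknot(knot, anchor = 0), "anchor")
})

test_that("find_slippery_sites requires template, register and pseudoknot", {
  # poly-G ORF: no heptamer at all
  polyg <- paste0("ATG", strrep("GGG", 60), "TAA")
  orf <- find_orfs(polyg, min_aa = 10)
  expect_equal(nrow(find_slippery_sites(polyg, orf[1, ])), 0L)

  # heptamer present at the right register but no downstream pseudoknot
  seq <- paste0("ATG", strrep("GCA", 50), "AAAAAC", strrep("GCA", 10),
                "TAA", strrep("A", 40))
  orf2 <- find_orfs(seq, min_aa = 10, both_strands = FALSE)[1, ]
  expect_equal(orf2$start, 1)
  sites <- find_slippery_sites(seq, orf2)
  expect_equal(nrow(sites), 0L)

  expect_error(find_slippery_sites(
    "ACGT", data.frame(start = 1, end = 4, orientation = "reverse")),
    "forward")
})

test_that("the fused product reuses one heptamer nucleotide", {
  # hand-built 21-nt toy: ORF1a = ATG AAT TTT TTA TGA, heptamer at 6;
  # -1 frame resumes on the heptamer's 7th base: ATG ACC TAG
  seq <- "ATGAATTTTTTATGACCTAGG"
  orf1a <- data.frame(start = 1, end = 15, orientation = "forward")
  fused <- fuse_frameshift_product(seq, orf1a, list(position = 6))
  expect_equal(fused$protein, "MNFLMT")
  expect_false(fused$truncated)

  # no shift -> plain ORF1a product
  plain <- fuse_frameshift_product(seq, orf1a, NULL)
  expect_equal(plain$protein, "MNFL")

  # no stop in the -1 frame -> truncated flag
  seq2 <- "ATGAATTTTTTATGACCTCCG"
  fused2 <- fuse_frameshift_product(seq2, orf1a, list(position = 6))
  expect_true(fused2$truncated)

  expect_error(fuse_frameshift_product(seq, orf1a, list(position = 12)),
               "outside")
})

test_that("the planted frameshift signal is recovered exactly", {
  ds <- cached_dataset(1)
  truth <- ds$truth$viruses$SynAV1$segments[[1]]$slippery
  s <- as.character(ds$transcripts[["SynAV1"]])
  orf1a <- find_orfs(s, min_aa = 300)[1, ]
  sites <- find_slippery_sites(s, orf1a)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$position, truth$position)
  expect_equal(sites$heptamer, truth$heptamer)
  expect_equal(sites$pattern_class, "U_UUU_UUA")
  expect_equal(sites$fused_aa, truth$fused_aa)
  # length consistency: the fused chain fits inside ORF1a start..-1 stop
  expect_lte(3 * sites$fused_aa, nchar(s) - orf1a$start + 1)
  # the fused product extends the ORF1a-only product
  expect_gt(sites$fused_aa, orf1a$aa_length)
})

test_that("no slippery sites are called on host transcripts", {
  ds <- cached_dataset(1)
  host <- grep("^host_", names(ds$transcripts), value = TRUE)
  n_sites <- 0L
  for (id in host) {
    s <- as.character(ds$transcripts[[id]])
    orfs <- find_orfs(s, min_aa = 30)
    fwd <- orfs[orfs$orientation == "forward", , drop = FALSE]
    if (nrow(fwd) == 0) next
    n_sites <- n_sites + nrow(find_slippery_sites(s, fwd[1, ]))
  }
  expect_equal(n_sites, 0L)
})
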