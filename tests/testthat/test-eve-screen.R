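test_that("an exact planted copy is recovered at full length and identity", {
  set.seed(14)
  cand <- random_nt(600)
  genome <- paste0(random_nt(2000), cand, random_nt(1500))
  hits <- scan_integration(cand, setNames(genome, "chr"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$length, 600L)
  expect_equal(hits$pct_identity, 100)
  expect_equal(c(hits$g_start, hits$g_end), c(2001L, 2600L))
  expect_equal(hits$strand, "+")

  # the reverse-complement integration is found on the minus strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cand)))
  genome2 <- paste0(random_nt(1000), rc, random_nt(800))
  h2 <- scan_integration(cand, setNames(genome2, "chr"))
  expect_equal(h2$strand, "-")
  expect_equal(c(h2$g_start, h2$g_end), c(1001L, 1600L))
})

test_that("a diverged planted copy is recovered near its true identity", {
  set.seed(15)
  cand <- random_nt(800)
  mut <- plant_eve(random_nt(3000), cand, divergence = 0.08, seed = 2)
  hits <- scan_integration(cand, setNames(mut$genome, "chr"))
  expect_gte(nrow(hits), 1L)
  expect_gte(hits$length[1], 100L)
  expect_equal(hits$pct_identity[1], 92, tolerance = 0.03)

  # candidate absent from the genome: no hits
  expect_equal(nrow(scan_integration(random_nt(700),
                                     setNames(random_nt(5000), "chr"))), 0L)
  expect_error(scan_integration(cand, Biostrings::DNAStringSet()), "empty")
  expect_error(scan_integration(cand, setNames(random_nt(100), "chr"),
                                k = 10), ">= 15")
})

test_that("scan_integration matches the brute-force sliding search", {
  set.seed(16)
  for (div in c(0, 0.05)) {
    cand <- random_nt(400)
    planted <- plant_eve(random_nt(1200), cand, divergence = div, seed = 3)
    hits <- scan_integration(cand, setNames(planted$genome, "chr"))
    brute <- brute_best_genome_hit(cand, planted$genome)
    expect_false(is.null(brute))
    expect_equal(hits$length[1], brute$length)
    expect_equal(hits$pct_identity[1], brute$pct_identity, tolerance = 1e-9)
  }
})

test_that("DNA-read k-mer coverage reflects the tiling of the candidate", {
  set.seed(18)
  cand <- random_nt(600)
  starts <- seq(1, 501, by = 50)
  full <- substring(cand, starts, starts + 99)
  expect_equal(dna_read_coverage(cand, setNames(full, paste0("r", starts))),
               1.0)
  half <- substring(cand, seq(1, 201, by = 50), seq(1, 201, by = 50) + 99)
  cov_half <- dna_read_coverage(cand, setNames(half, paste0("h", 1:5)))
  expect_equal(cov_half, 0.5, tolerance = 0.01)
  # reads from an unrelated genome share no k-mers
  other <- substring(random_nt(2000), seq(1, 1901, 50), seq(1, 1901, 50) + 99)
  expect_equal(dna_read_coverage(cand, setNames(other, paste0("o", 1:39))),
               0)
  expect_warning(cov0 <- dna_read_coverage(cand, character(0)), "no DNA reads")
  expect_equal(cov0, 0)
})

test_that("classification follows the genome-hit and coverage rules", {
  ev <- function(len, id, cov) {
    structure(list(
      genome_hits = if (is.null(len)) {
        data.frame(length = integer(0), pct_identity = numeric(0))
      } else data.frame(length = len, pct_identity = id),
      dna_covered_fraction = cov,
      thresholds = list(min_id = 0.90, min_len = 100, cov_min = 0.1,
                        ambiguous_margin = 0.05)),
      class = "integration_evidence")
  }
  expect_equal(classify_exogenous(ev(NULL, NULL, 0)), "bona_fide")
  expect_equal(classify_exogenous(ev(500, 98, 0)), "EVE")
  expect_equal(classify_exogenous(ev(120, 87, 0)), "ambiguous")
  expect_equal(classify_exogenous(ev(NULL, NULL, 0.4)), "EVE")
  expect_equal(classify_exogenous(ev(80, 99, 0)), "bona_fide")  # too short
})

test_that("the planted EVE is flagged while exogenous viruses are not", {
  ds <- cached_dataset(1)
  ids <- truth_segment_ids(ds)
  km <- dna_read_kmers(ds$dna_reads)
  verdicts <- vapply(ids, function(id) {
    classify_exogenous(integration_evidence(
      as.character(ds$transcripts[[id]]), ds$host_genome, km))
  }, "")
  expect_equal(unname(verdicts["SynEVE1"]), "EVE")
  expect_true(all(verdicts[setdiff(ids, "SynEVE1")] == "bona_fide"))
})
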