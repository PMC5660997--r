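test_that("dataset generation is deterministic under a fixed seed", {
  cfg <- small_config()
  d1 <- build_dataset(cfg, seed = 42)
  d2 <- build_dataset(cfg, seed = 42)
  expect_identical(as.character(d1$transcripts), as.character(d2$transcripts))
  expect_identical(as.character(d1$proteins), as.character(d2$proteins))
  expect_identical(d1$counts, d2$counts)
  d3 <- build_dataset(cfg, seed = 43)
  expect_false(identical(as.character(d1$transcripts),
                         as.character(d3$transcripts)))
})

test_that("virus_model validates its invariants", {
  expect_error(virus_model("x", "monopartite_polyprotein", c(2000, 1500)),
               "exactly one segment")
  expect_error(virus_model("x", "multipartite", c(2000, 100)), ">= 300")
  expect_error(virus_model("x", "monopartite_polyprotein", 2000,
                           au_bias = 1.2), "au_bias")
  expect_error(virus_model("x", "multipartite", c(600, 2000),
                           panhandle_len = 320), "shortest segment")
  m <- virus_model("x", "multipartite", c(2000, 1500), utr5_len = 30)
  for (o in m$orf_layout) expect_equal((o$end - o$start + 1) %% 3, 0)
})

test_that("a ten-segment model yields exactly ten truth segments", {
  ds <- cached_dataset(1)
  expect_length(ds$truth$viruses$SynRV1$segments, 10L)
  ids <- vapply(ds$truth$viruses$SynRV1$segments, `[[`, "", "id")
  expect_true(all(ids %in% names(ds$transcripts)))
})

test_that("reference proteins sit at the configured ~40% identity", {
  ds <- cached_dataset(1)
  for (v in ds$truth$viruses[c("SynPV1", "SynAV1")]) {
    seg <- v$segments[[1]]
    ref <- as.character(ds$proteins[[paste0("ref_", seg$id)]])
    ident <- pairwise_identity(seg$planted_protein, ref, level = "aa")
    expect_gte(ident, 35)
    expect_lte(ident, 45)
  }
})

test_that("planted ORFs are exactly re-discoverable on every segment", {
  ds <- cached_dataset(1)
  for (v in ds$truth$viruses) {
    for (seg in v$segments) {
      found <- find_orfs(as.character(ds$transcripts[[seg$id]]),
                         min_aa = 300)
      expect_equal(nrow(found), 1L, info = seg$id)
      expect_equal(found$start, seg$orf$start, info = seg$id)
      expect_equal(found$end, seg$orf$end, info = seg$id)
      expect_equal(found$orientation, seg$orf$orientation, info = seg$id)
      expect_equal(found$protein, seg$orf$protein, info = seg$id)
    }
  }
})

test_that("plant_eve inserts an identity-tracked copy", {
  genome <- random_nt(5000)
  seg <- random_nt(800)
  r0 <- plant_eve(genome, seg, divergence = 0, seed = 5)
  expect_equal(nchar(r0$genome), 5800)
  expect_equal(r0$record$identity, 1)
  expect_equal(substr(r0$genome, r0$record$start, r0$record$end), seg)

  r1 <- plant_eve(genome, seg, divergence = 0.1, seed = 5)
  planted <- substr(r1$genome, r1$record$start, r1$record$end)
  obs <- mean(strsplit(planted, "")[[1]] == strsplit(seg, "")[[1]])
  expect_equal(obs, r1$record$identity)
  expect_equal(r1$record$identity, 0.9, tolerance = 0.01)

  # two successive inserts at distinct loci grow the genome additively
  r2 <- plant_eve(r0$genome, random_nt(600), divergence = 0, seed = 9)
  expect_equal(nchar(r2$genome), 5800 + 600)

  expect_error(plant_eve(random_nt(100), seg, 0, 1), "longer than")
  expect_error(plant_eve(genome, seg, 0.5, 1), "divergence")
})

test_that("simulated counts follow the configured negative binomial", {
  truth <- list(viruses = list(list(
    name = "V", segments = list(list(id = "V_seg1", length = 2000L)))))
  libs <- data.frame(library_id = "L1", individual = "i1",
                     tissue = "silk", host_mapped_reads = 1e7)
  design <- list(libraries = libs,
                 infection = matrix(TRUE, 1, 1,
                                    dimnames = list("V", "L1")),
                 abundance = matrix(50, 1, 1,
                                    dimnames = list("V", "L1")))
  draws <- vapply(seq_len(200), function(i) {
    simulate_library_counts(truth, design, seed = 1000 + i)["V_seg1", "L1"]
  }, 0L)
  # mean = 50 FPKM * 2 kb * 10 M/1e6 = 1000
  expect_equal(mean(draws), 1000, tolerance = 0.1)

  design$infection[] <- FALSE
  z <- simulate_library_counts(truth, design, seed = 1)
  expect_true(all(z == 0))
})

test_that("all segments of one virus share the library infection pattern", {
  ds <- cached_dataset(1)
  exp_cnt <- ds$truth$expected_counts
  for (v in names(ds$truth$viruses)) {
    ids <- vapply(ds$truth$viruses[[v]]$segments, `[[`, "", "id")
    nz <- exp_cnt[ids, , drop = FALSE] > 0
    expect_true(all(apply(nz, 2, function(col) length(unique(col)) == 1)),
                info = v)
    expect_identical(unname(nz[1, ]), unname(ds$truth$infection[v, ]))
  }
})

test_that("expected FPKM of a planted segment equals its abundance scale", {
  ds <- cached_dataset(1)
  exp_cnt <- ds$truth$expected_counts
  M <- lib_reads(ds)
  for (v in ds$truth$viruses) {
    for (seg in v$segments) {
      expected_fpkm <- fpkm(exp_cnt[seg$id, ], seg$length, M)
      ab <- ds$truth$abundance[v$name, ]
      on <- ds$truth$infection[v$name, ]
      expect_equal(unname(expected_fpkm[on]), unname(ab[on]),
                   tolerance = 1e-9)
    }
  }
})

test_that("host transcripts carry no long ORFs resembling planted ones", {
  ds <- cached_dataset(1)
  host <- grep("^host_", names(ds$transcripts), value = TRUE)
  longest <- vapply(host[1:10], function(id) {
    o <- find_orfs(as.character(ds$transcripts[[id]]), min_aa = 1)
    if (nrow(o)) max(o$aa_length) else 0L
  }, 0L)
  expect_true(all(longest < 300))
})

test_that("write_dataset emits the declared files", {
  out <- file.path(tempdir(), "ds_out")
  on.exit(unlink(out, recursive = TRUE))
  ds <- build_dataset(small_config(eve = TRUE), seed = 2)
  paths <- write_dataset(ds, out)
  expect_true(all(file.exists(paths)))
  tx <- Biostrings::readDNAStringSet(paths["transcripts"])
  expect_equal(length(tx), length(ds$transcripts))
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(truth$seed, 2)
  expect_named(truth$viruses, c("miniPV", "SynEVE1"))
})
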