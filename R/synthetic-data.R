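# Synthetic virome dataset generator.
#
# Emulates the structure of an orb-weaver spider transcriptome survey:
# 16 rRNA-depleted RNA libraries from 4 individuals across whole-body,
# brain, silk-gland and venom-gland tissues, with planted RNA viruses of
# the architectures recovered in such surveys (a monopartite polyprotein
# virus with a long AU-rich 5'UTR, a bipartite negative-sense virus with
# complementary panhandle termini, a 10-segment dsRNA virus, and a virus
# expressing its replicase through a -1 ribosomal frameshift), plus an
# optional endogenous viral element (EVE) copy in the host genome.

#' Specify a virus model for the synthetic-data generator
#'
#' A `virus_model` describes one planted virus: its genome architecture,
#' segment lengths, UTR layout and any engineered signals (panhandle
#' termini, slippery site + pseudoknot).  ORF coordinates are derived from
#' the layout parameters and validated against the model invariants.
#'
#' @param name Virus label; used as the segment id prefix.
#' @param architecture One of `"monopartite_polyprotein"`, `"multipartite"`,
#'   `"frameshift_fusion"`.
#' @param segment_lengths Integer vector of segment lengths (nt).
#' @param utr5_len 5' untranslated region length (nt) on the reading strand.
#' @param au_bias A+U fraction used when sampling the 5'UTR (`[0, 1]`).
#' @param panhandle_len Length (nt) of engineered reverse-complementary
#'   genome termini on every segment; 0 disables.
#' @param orientation `"forward"` or `"reverse"`: strand of the main ORF on
#'   the deposited sequence (negative-sense viruses are conventionally
#'   deposited with the ORF on the minus strand).
#' @param slippery_site For `frameshift_fusion` only: a list with elements
#'   `heptamer` (slippery heptamer, e.g. `"TTTTTTA"`) and `pseudoknot`
#'   (logical; plant a downstream H-type pseudoknot).
#' @param orf1a_aa,orf1b_aa For `frameshift_fusion`: lengths (aa) of the
#'   upstream ORF and of the -1-frame extension translated after the shift.
#' @param utr3_min Minimum 3'UTR length reserved downstream of the ORF.
#' @return A validated object of class `virus_model`.
#' @examples
#' virus_model("toyPV", "monopartite_polyprotein", 2000, utr5_len = 300)
#' @export
virus_model <- function(name, architecture, segment_lengths,
                        utr5_len = 25, au_bias = 0.5, panhandle_len = 0,
                        orientation = "forward", slippery_site = NULL,
                        orf1a_aa = 437, orf1b_aa = 300, utr3_min = 25) {
  architecture <- match.arg(architecture, c("monopartite_polyprotein",
                                            "multipartite",
                                            "frameshift_fusion"))
  segment_lengths <- as.integer(segment_lengths)
  if (any(is.na(segment_lengths)) || any(segment_lengths < 300)) {
    stop("virus_model '", name, "': segment_lengths must be >= 300 nt")
  }
  if (architecture != "multipartite" && length(segment_lengths) != 1L) {
    stop("virus_model '", name, "': ", architecture,
         " must have exactly one segment")
  }
  if (au_bias < 0 || au_bias > 1) {
    stop("virus_model '", name, "': au_bias must be in [0, 1]")
  }
  if (panhandle_len >= min(segment_lengths) / 2) {
    stop("virus_model '", name,
         "': panhandle_len must be < shortest segment / 2")
  }
  if (architecture == "frameshift_fusion") {
    if (is.null(slippery_site)) {
      slippery_site <- list(heptamer = "TTTTTTA", pseudoknot = TRUE)
    }
    hept <- normalize_nt(slippery_site$heptamer, allow_n = FALSE)
    if (nchar(hept) != 7L) stop("slippery heptamer must be 7 nt")
    need <- utr5_len + 3L * (orf1a_aa + 1L) + 32L + 3L * (orf1b_aa + 1L) +
      120L
    if (segment_lengths[1] < need) {
      stop("virus_model '", name, "': segment too short for the ",
           "requested frameshift layout (need >= ", need, " nt)")
    }
    slippery_site$heptamer <- hept
  }
  # derived ORF layout (1-based inclusive, stop codon inside the span)
  layout <- lapply(segment_lengths, function(len) {
    if (architecture == "frameshift_fusion") {
      n1 <- orf1a_aa - 4L
      h <- utr5_len + 3L * n1        # heptamer start (codon position 3)
      return(data.frame(start = utr5_len + 1L, end = h + 15L,
                        orientation = "forward"))
    }
    aa <- (len - utr5_len - utr3_min) %/% 3L - 1L
    if (aa < 100L) stop("virus_model '", name, "': segment of ", len,
                        " nt leaves no room for an ORF >= 100 aa")
    span <- 3L * (aa + 1L)
    if (orientation == "forward") {
      s <- utr5_len + 1L
      data.frame(start = s, end = s + span - 1L, orientation = "forward")
    } else {
      e <- len - utr5_len
      data.frame(start = e - span + 1L, end = e, orientation = "reverse")
    }
  })
  for (i in seq_along(layout)) {
    o <- layout[[i]]
    if ((o$end - o$start + 1L) %% 3L != 0L || o$end > segment_lengths[i] ||
        o$start < 1L) {
      stop("virus_model '", name, "': derived ORF layout violates ",
           "invariants on segment ", i)
    }
    if (panhandle_len > 0 &&
        (o$start <= panhandle_len || o$end > segment_lengths[i] - panhandle_len)) {
      stop("virus_model '", name, "': ORF overlaps the engineered ",
           "panhandle termini on segment ", i)
    }
  }
  structure(list(name = name, architecture = architecture,
                 segment_lengths = segment_lengths, utr5_len = utr5_len,
                 au_bias = au_bias, panhandle_len = panhandle_len,
                 orientation = orientation, slippery_site = slippery_site,
                 orf1a_aa = as.integer(orf1a_aa),
                 orf1b_aa = as.integer(orf1b_aa),
                 utr3_min = as.integer(utr3_min), orf_layout = layout),
            class = "virus_model")
}

#' @export
print.virus_model <- function(x, ...) {
  cat("virus_model:", x$name, "(", x$architecture, ")\n")
  cat("  segments:", paste(x$segment_lengths, collapse = ", "), "nt\n")
  if (x$panhandle_len > 0) cat("  panhandle:", x$panhandle_len, "nt\n")
  if (!is.null(x$slippery_site)) {
    cat("  slippery site:", x$slippery_site$heptamer, "\n")
  }
  invisible(x)
}

# 16-library / 4-individual design: 2 whole-body + 2 brain + 10 silk +
# 2 venom glands.
default_libraries <- function() {
  data.frame(
    library_id = c("wb_ind1", "wb_ind2", "brain_ind3", "brain_ind4",
                   "venom_ind3", "venom_ind4",
                   "silk1_ind1", "silk2_ind1", "silk1_ind2", "silk2_ind2",
                   "silk1_ind3", "silk2_ind3", "silk3_ind3",
                   "silk1_ind4", "silk2_ind4", "silk3_ind4"),
    individual = c("ind1", "ind2", "ind3", "ind4", "ind3", "ind4",
                   "ind1", "ind1", "ind2", "ind2", "ind3", "ind3", "ind3",
                   "ind4", "ind4", "ind4"),
    tissue = c("whole_body", "whole_body", "brain", "brain",
               "venom", "venom", rep("silk", 10)),
    stringsAsFactors = FALSE)
}

#' Default generator configuration
#'
#' The default configuration emulates the study design the package targets:
#' 16 libraries from 4 individuals (whole body, brain, silk, venom), four
#' planted viruses — a monopartite polyprotein virus with a 760-nt AU-rich
#' 5'UTR, a bipartite virus with reverse-orientation ORFs and 32-nt
#' complementary panhandle termini, a 10-segment virus with the segment
#' lengths of a published spider reo-like virus (1,096–3,837 nt), and a
#' frameshifting virus with a U_UUU_UUA slippery site plus H-type
#' pseudoknot — and one endogenous viral element planted in the host
#' genome.  Per-library virus loads are drawn log2-uniformly inside
#' tissue-specific windows (FPKM scale); multipartite viruses span four
#' orders of magnitude so that segment co-expression dominates counting
#' noise.
#'
#' @param eve Logical; plant an endogenous viral element (default `TRUE`).
#' @return A configuration list consumed by [build_dataset()].
#' @export
default_config <- function(eve = TRUE) {
  reo_lengths <- c(3786L, 3837L, 2985L, 2628L, 2243L, 1616L, 1856L,
                   1267L, 1096L, 2339L)
  viruses <- list(
    virus_model("SynPV1", "monopartite_polyprotein", 3283L,
                utr5_len = 760L, au_bias = 0.70, utr3_min = 90L),
    virus_model("SynBV1", "multipartite", c(2400L, 1800L),
                utr5_len = 55L, utr3_min = 45L, orientation = "reverse",
                panhandle_len = 32L),
    virus_model("SynRV1", "multipartite", reo_lengths,
                utr5_len = 25L, utr3_min = 25L),
    virus_model("SynAV1", "frameshift_fusion", 2500L, utr5_len = 60L,
                orf1a_aa = 437L, orf1b_aa = 300L,
                slippery_site = list(heptamer = "TTTTTTA",
                                     pseudoknot = TRUE))
  )
  tissues <- c("whole_body", "brain", "silk", "venom")
  win <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE,
                dimnames = list(tissues, c("lo", "hi")))
    m
  }
  list(
    viruses = viruses,
    libraries = default_libraries(),
    host_mapped_reads_range = c(8e6, 1.5e7),
    infections = list(
      SynPV1 = c("ind1", "ind2", "ind3", "ind4"),
      SynBV1 = c("ind1", "ind2", "ind3", "ind4"),
      SynRV1 = c("ind1", "ind2", "ind3", "ind4"),
      SynAV1 = c("ind1", "ind3", "ind4")),
    # log2-FPKM windows per tissue (rows: whole_body, brain, silk, venom)
    abundance_log2 = list(
      SynPV1 = win(4, 8,   3, 6,   6, 11,  7, 12),
      SynBV1 = win(3, 14,  3, 14,  3, 14,  3, 14),
      SynRV1 = win(3, 14,  3, 14,  3, 14,  3, 14),
      SynAV1 = win(3, 8,   4, 9,   5, 10,  3, 8)),
    dispersion = 0.2,
    identity_target = 0.40,
    n_host_transcripts = 40L,
    host_length_range = c(600L, 1500L),
    host_abundance_meanlog = log(30),
    host_abundance_sdlog = 1,
    host_genome_length = 50000L,
    dna_read_length = 100L,
    dna_read_step = 50L,
    eve = list(enabled = eve, length = 1500L, utr5_len = 40L,
               divergence = 0.05, abundance_log2 = c(4, 6))
  )
}

# ---- segment construction -------------------------------------------------

# ATG + (n_aa - 1) sense codons + TAA; returns list(nt, protein)
make_orf_nt <- function(n_aa) {
  body <- sample(SENSE_CODONS, n_aa - 1L, replace = TRUE)
  nt <- paste0("ATG", paste(body, collapse = ""), "TAA")
  list(nt = nt, protein = translate_nt(substr(nt, 1L, 3L * n_aa)))
}

build_plain_segment <- function(model, i) {
  len <- model$segment_lengths[i]
  lay <- model$orf_layout[[i]]
  aa <- (lay$end - lay$start + 1L) %/% 3L - 1L
  orf <- make_orf_nt(aa)
  if (lay$orientation == "forward") {
    utr5 <- if (model$architecture == "monopartite_polyprotein") {
      random_dna_au(lay$start - 1L, model$au_bias)
    } else {
      random_dna(lay$start - 1L)
    }
    seq <- paste0(utr5, orf$nt, random_dna(len - lay$end))
  } else {
    # construct on the reading strand, deposit the reverse complement
    read5 <- random_dna(len - lay$end)        # reading-strand 5'UTR
    read3 <- random_dna(lay$start - 1L)       # reading-strand 3'UTR
    seq <- revcomp(paste0(read5, orf$nt, read3))
  }
  if (model$panhandle_len > 0) {
    w <- model$panhandle_len
    substr(seq, nchar(seq) - w + 1L, nchar(seq)) <-
      revcomp(substr(seq, 1L, w))
  }
  list(seq = seq, orf = cbind(lay, aa_length = aa),
       protein = orf$protein)
}

# Frameshift segment: ORF1a carries the slippery heptamer at codon position
# 3 (X|XXX|XXY) near its 3' end, a planted H-type pseudoknot begins 9 nt
# after the heptamer, and the -1 frame continues stop-free for orf1b_aa
# codons so that the fused ORF1a-b product has a known length.  A triple
# stem-loop is planted in the 3'UTR.
build_frameshift_segment <- function(model) {
  len <- model$segment_lengths[1]
  utr5_len <- model$utr5_len
  hept <- model$slippery_site$heptamer
  x <- substr(hept, 1L, 1L)
  n1 <- model$orf1a_aa - 4L
  h <- utr5_len + 3L * n1                       # heptamer start
  # part 1: ATG + (n1 - 2) sense codons + one sense codon ending in X
  endx <- SENSE_CODONS[substr(SENSE_CODONS, 3L, 3L) == x &
                         SENSE_CODONS != strrep(x, 3L)]
  part1 <- paste0("ATG",
                  paste(sample(SENSE_CODONS, n1 - 2L, replace = TRUE),
                        collapse = ""),
                  sample(endx, 1L))
  # ORF1a tail: heptamer completion + 2 filler codons + stop
  filler0 <- paste(sample(SENSE_CODONS, 2L), collapse = "")
  tail1a <- paste0(substr(hept, 2L, 7L), filler0, "TAA")
  # pseudoknot: stem1(6) loop1(7, last 5 = stem2 arm) stem1'(6) spacer(8)
  # stem2'(5); begins 9 nt after the heptamer end (inside ORF1b)
  s1 <- random_dna(6L); l1a <- random_dna(2L); s2 <- random_dna(5L)
  spacer <- random_dna(8L)
  pk <- paste0(s1, l1a, s2, revcomp(s1), spacer, revcomp(s2))
  # ORF1b continuation in the -1 frame: sense codons, no internal ATG
  body_cod <- setdiff(SENSE_CODONS, "ATG")
  orf1b <- paste(sample(body_cod, model$orf1b_aa, replace = TRUE),
                 collapse = "")
  # 3'UTR with a triple stem-loop (GC stems, A loops/linkers)
  hp <- paste0(strrep("G", 8L), "AAAA", strrep("C", 8L))
  utr3_core <- paste0("AAAAAA", hp, "AAAAAA", hp, "AAAAAA", hp, "AAAAAA")
  core <- paste0(random_dna(utr5_len), part1, tail1a, pk, orf1b, "TAA")
  fill <- len - nchar(core) - nchar(utr3_core)
  if (fill < 0) stop("frameshift segment layout exceeds segment length")
  seq <- paste0(core, utr3_core, random_dna(fill))
  stopifnot(nchar(seq) == len)
  # engineered coordinates
  orf1a <- data.frame(start = utr5_len + 1L, end = h + 15L,
                      orientation = "forward",
                      aa_length = model$orf1a_aa)
  pk_start <- h + 16L
  stem1 <- c(pk_start, pk_start + 5L, pk_start + 13L, pk_start + 18L)
  stem2 <- c(pk_start + 8L, pk_start + 12L, pk_start + 27L, pk_start + 31L)
  # fused product: ORF1a frame through the heptamer (n1 + 2 codons), then
  # the -1 frame from the reused 7th heptamer base to its stop
  part2_nt <- substr(seq, h + 6L, h + 6L + 3L * (14L + model$orf1b_aa) - 1L)
  fused_protein <- paste0(
    translate_nt(substr(seq, utr5_len + 1L, h + 6L)),
    translate_nt(part2_nt))
  utr3_sl <- c(nchar(core) + 7L, nchar(core) + nchar(utr3_core) - 6L)
  list(seq = seq,
       orf = orf1a,
       protein = translate_nt(substr(seq, utr5_len + 1L, h + 12L + 3L)) |>
         substr(1L, model$orf1a_aa),
       slippery = list(position = h, heptamer = hept,
                       pattern_class = heptamer_class(hept),
                       stem1 = stem1, stem2 = stem2,
                       fused_aa = n1 + 2L + 14L + model$orf1b_aa,
                       fused_protein = fused_protein),
       utr3_stemloop = utr3_sl)
}

heptamer_class <- function(hept) {
  u <- chartr("T", "U", hept)
  paste0(substr(u, 1, 1), "_", substr(u, 2, 4), "_", substr(u, 5, 7))
}

# Build and validate one segment; regenerate until the planted annotation
# is exactly re-discoverable (no spurious long ORFs, no uORF extension, and
# for frameshift segments a uniquely detectable slippery site).
build_segment_validated <- function(model, i, subseed, min_aa_check = 250L,
                                    max_tries = 200L) {
  for (try in seq_len(max_tries)) {
    res <- with_seed(subseed + 7919L * try, {
      if (model$architecture == "frameshift_fusion") {
        build_frameshift_segment(model)
      } else {
        build_plain_segment(model, i)
      }
    })
    found <- find_orfs(res$seq, min_aa = min_aa_check, both_strands = TRUE)
    want <- res$orf
    ok <- nrow(found) == 1L &&
      found$start == want$start && found$end == want$end &&
      found$orientation == want$orientation
    if (ok && model$architecture == "frameshift_fusion") {
      sites <- find_slippery_sites(res$seq, found[1, ])
      ok <- nrow(sites) == 1L && sites$position == res$slippery$position
      if (ok) {
        fused <- fuse_frameshift_product(res$seq, found[1, ], sites[1, ])
        ok <- nchar(fused$protein) == res$slippery$fused_aa
      }
    }
    if (ok) return(res)
  }
  stop("failed to build a clean segment for ", model$name,
       " segment ", i, " after ", max_tries, " attempts")
}

# Substitution-only mutation of a protein towards a target global identity.
mutate_protein <- function(aa, target_identity) {
  res <- strsplit(aa, "")[[1]]
  L <- length(res)
  n_sub <- round((1 - target_identity) * L)
  pos <- sample.int(L, n_sub)
  res[pos] <- vapply(res[pos],
                     function(a) sample(setdiff(AA20, a), 1L), "")
  list(protein = paste(res, collapse = ""),
       realized_identity = (L - n_sub) / L)
}

# ---- EVE ------------------------------------------------------------------

#' Insert a diverged copy of a viral segment into a host genome
#'
#' Emulates an endogenous viral element (EVE): a copy of `segment`, mutated
#' by random substitutions at rate `divergence`, is inserted at a random
#' locus of `host_genome`.  The returned record carries the insertion
#' coordinates (on the modified genome) and the realized nucleotide
#' identity between the planted copy and the original segment.
#'
#' @param host_genome Host genome sequence (character or `DNAString`).
#' @param segment Viral segment sequence to integrate.
#' @param divergence Per-base substitution rate in `[0, 0.3]`.
#' @param seed Integer seed; the operation is deterministic given
#'   `(host_genome, segment, divergence, seed)`.
#' @return A list with `genome` (modified sequence) and `record` (a
#'   one-row data frame: `start`, `end`, `identity`).
#' @export
plant_eve <- function(host_genome, segment, divergence, seed) {
  host_genome <- normalize_nt(host_genome)
  segment <- normalize_nt(segment)
  if (divergence < 0 || divergence > 0.3) {
    stop("divergence must be in [0, 0.3]")
  }
  if (nchar(segment) > nchar(host_genome)) {
    stop("segment is longer than the host genome")
  }
  with_seed(seed, {
    s <- strsplit(segment, "")[[1]]
    n_sub <- round(divergence * length(s))
    if (n_sub > 0) {
      pos <- sample.int(length(s), n_sub)
      s[pos] <- vapply(s[pos], function(b) sample(setdiff(BASES, b), 1L), "")
    }
    copy <- paste(s, collapse = "")
    at <- sample.int(nchar(host_genome) - 1L, 1L)
    genome <- paste0(substr(host_genome, 1L, at), copy,
                     substr(host_genome, at + 1L, nchar(host_genome)))
    record <- data.frame(start = at + 1L, end = at + nchar(copy),
                         identity = (length(s) - n_sub) / length(s))
    list(genome = genome, record = record)
  })
}

# ---- counts ---------------------------------------------------------------

#' Simulate per-library fragment counts for planted virus segments
#'
#' Counts are drawn from a negative binomial whose mean follows the FPKM
#' identity `mean = abundance * segment_kb * host_mapped_reads / 1e6`, so
#' that the expected FPKM of a segment equals its per-library abundance
#' scale by construction.  Libraries whose `infection` entry is `FALSE`
#' receive zero fragments for every segment of that virus.
#'
#' @param truth Truth record from [build_dataset()] (or a compatible list
#'   with `$viruses`, each with `$segments` carrying `id` and `length`).
#' @param design Library design: a list with `$libraries` (data frame with
#'   `library_id`, `individual`, `tissue`, `host_mapped_reads`),
#'   `$infection` (virus x library logical matrix) and `$abundance`
#'   (virus x library FPKM-scale matrix).
#' @param seed Integer seed.
#' @param dispersion Negative-binomial dispersion (NB `size = 1/dispersion`).
#' @return Integer matrix of fragment counts (segments x libraries) with an
#'   `"expected"` attribute holding the count means.
#' @export
simulate_library_counts <- function(truth, design, seed, dispersion = 0.2) {
  libs <- design$libraries
  stopifnot(all(c("library_id", "host_mapped_reads") %in% names(libs)))
  vnames <- vapply(truth$viruses, `[[`, "", "name")
  if (!all(rownames(design$infection) %in% vnames)) {
    stop("design refers to viruses absent from the truth record: ",
         paste(setdiff(rownames(design$infection), vnames), collapse = ", "))
  }
  seg_ids <- unlist(lapply(truth$viruses, function(v)
    vapply(v$segments, `[[`, "", "id")))
  seg_len <- unlist(lapply(truth$viruses, function(v)
    vapply(v$segments, `[[`, 0, "length")))
  seg_virus <- unlist(lapply(truth$viruses, function(v)
    rep(v$name, length(v$segments))))
  n_lib <- nrow(libs)
  mu <- matrix(0, length(seg_ids), n_lib,
               dimnames = list(seg_ids, libs$library_id))
  for (i in seq_along(seg_ids)) {
    v <- seg_virus[i]
    if (!v %in% rownames(design$infection)) next
    inf <- design$infection[v, libs$library_id]
    ab <- design$abundance[v, libs$library_id]
    mu[i, ] <- ifelse(inf, ab * (seg_len[i] / 1000) *
                        (libs$host_mapped_reads / 1e6), 0)
  }
  counts <- with_seed(seed, {
    m <- mu
    pos <- which(m > 0)
    m[pos] <- rnbinom(length(pos), mu = m[pos], size = 1 / dispersion)
    m
  })
  storage.mode(counts) <- "integer"
  attr(counts, "expected") <- mu
  counts
}

# ---- dataset assembly -----------------------------------------------------

#' Generate a complete synthetic virome dataset
#'
#' Builds host transcripts, planted virus segments, a mutated reference
#' protein set, a host genome with an optional endogenous viral element,
#' DNA "reads" tiling the genome, the 16-library count matrix and a
#' machine-readable truth record.  Deterministic for fixed
#' `(config, seed)`.
#'
#' @param config Configuration list, typically [default_config()].
#' @param seed Integer master seed.
#' @return An object of class `virome_dataset`: a list with
#'   `transcripts` (named `DNAStringSet`: host + viral), `proteins`
#'   (reference `AAStringSet`), `host_genome`, `dna_reads`, `counts`
#'   (matrix), `design` and `truth`.
#' @examples
#' ds <- build_dataset(default_config(eve = FALSE), seed = 1)
#' names(ds$truth$viruses)
#' @export
build_dataset <- function(config = default_config(), seed = 1L) {
  models <- config$viruses
  names(models) <- vapply(models, `[[`, "", "name")

  # planted viruses ---------------------------------------------------------
  vseeds <- derive_seeds(seed, length(models) * 16L, salt = 1L)
  truth_viruses <- list()
  virus_seqs <- character(0)
  ref_prot <- character(0)
  realized_ident <- numeric(0)
  si <- 0L
  for (m in models) {
    segs <- list()
    for (i in seq_along(m$segment_lengths)) {
      si <- si + 1L
      built <- build_segment_validated(m, i, vseeds[si])
      id <- if (length(m$segment_lengths) == 1L) m$name else
        paste0(m$name, "_seg", i)
      main_protein <- if (m$architecture == "frameshift_fusion") {
        built$slippery$fused_protein
      } else built$protein
      mut <- with_seed(vseeds[si] + 13L,
                       mutate_protein(main_protein, config$identity_target))
      virus_seqs[id] <- built$seq
      ref_prot[paste0("ref_", id)] <- mut$protein
      realized_ident[paste0("ref_", id)] <- mut$realized_identity
      segs[[i]] <- list(
        id = id, length = nchar(built$seq),
        orf = cbind(built$orf, protein = built$protein,
                    stringsAsFactors = FALSE),
        planted_protein = main_protein,
        panhandle_len = m$panhandle_len,
        slippery = built$slippery %||% NULL,
        utr3_stemloop = built$utr3_stemloop %||% NULL)
    }
    truth_viruses[[m$name]] <- list(name = m$name,
                                    architecture = m$architecture,
                                    segments = segs, is_eve = FALSE)
  }

  # EVE element + host genome + DNA reads -----------------------------------
  eve_cfg <- config$eve
  host_genome <- with_seed(derive_seeds(seed, 1L, salt = 2L),
                           random_dna(config$host_genome_length))
  eve_record <- NULL
  if (isTRUE(eve_cfg$enabled)) {
    eve_model <- virus_model("SynEVE1", "monopartite_polyprotein",
                             eve_cfg$length, utr5_len = eve_cfg$utr5_len,
                             utr3_min = 30L)
    eve_seed <- derive_seeds(seed, 1L, salt = 3L)
    built <- build_segment_validated(eve_model, 1L, eve_seed)
    mut <- with_seed(eve_seed + 13L,
                     mutate_protein(built$protein, config$identity_target))
    virus_seqs["SynEVE1"] <- built$seq
    ref_prot["ref_SynEVE1"] <- mut$protein
    realized_ident["ref_SynEVE1"] <- mut$realized_identity
    truth_viruses[["SynEVE1"]] <- list(
      name = "SynEVE1", architecture = "monopartite_polyprotein",
      segments = list(list(id = "SynEVE1", length = nchar(built$seq),
                           orf = cbind(built$orf, protein = built$protein,
                                       stringsAsFactors = FALSE),
                           planted_protein = built$protein,
                           panhandle_len = 0L, slippery = NULL,
                           utr3_stemloop = NULL)),
      is_eve = TRUE)
    planted <- plant_eve(host_genome, built$seq, eve_cfg$divergence,
                         seed = derive_seeds(seed, 1L, salt = 4L))
    host_genome <- planted$genome
    eve_record <- cbind(data.frame(id = "SynEVE1"), planted$record,
                        divergence = eve_cfg$divergence)
  }
  read_starts <- seq(1L, nchar(host_genome) - config$dna_read_length + 1L,
                     by = config$dna_read_step)
  dna_reads <- substring(host_genome, read_starts,
                         read_starts + config$dna_read_length - 1L)
  names(dna_reads) <- sprintf("gdna_%05d", seq_along(dna_reads))

  # host transcripts ---------------------------------------------------------
  host <- with_seed(derive_seeds(seed, 1L, salt = 5L), {
    lens <- sample(config$host_length_range[1]:config$host_length_range[2],
                   config$n_host_transcripts, replace = TRUE)
    setNames(vapply(lens, random_dna, ""),
             sprintf("host_%04d", seq_along(lens)))
  })

  # library design -----------------------------------------------------------
  libs <- config$libraries
  vnames <- names(truth_viruses)
  design <- with_seed(derive_seeds(seed, 1L, salt = 6L), {
    libs$host_mapped_reads <- round(runif(nrow(libs),
                                          config$host_mapped_reads_range[1],
                                          config$host_mapped_reads_range[2]))
    infection <- matrix(FALSE, length(vnames), nrow(libs),
                        dimnames = list(vnames, libs$library_id))
    abundance <- matrix(0, length(vnames), nrow(libs),
                        dimnames = list(vnames, libs$library_id))
    for (v in vnames) {
      if (identical(v, "SynEVE1")) {
        infection[v, ] <- TRUE   # genome-encoded, transcribed everywhere
        abundance[v, ] <- 2 ^ runif(nrow(libs), eve_cfg$abundance_log2[1],
                                    eve_cfg$abundance_log2[2])
        next
      }
      inf_ind <- config$infections[[v]]
      infection[v, ] <- libs$individual %in% inf_ind
      w <- config$abundance_log2[[v]]
      abundance[v, ] <- 2 ^ runif(nrow(libs), w[libs$tissue, "lo"],
                                  w[libs$tissue, "hi"])
      abundance[v, !infection[v, ]] <- 0
    }
    list(libraries = libs, infection = infection, abundance = abundance)
  })

  truth <- list(seed = seed, viruses = truth_viruses,
                eve = eve_record, dispersion = config$dispersion,
                identity_target = config$identity_target,
                realized_ref_identity = realized_ident)

  viral_counts <- simulate_library_counts(truth, design,
                                          seed = derive_seeds(seed, 1L,
                                                              salt = 7L),
                                          dispersion = config$dispersion)
  host_counts <- with_seed(derive_seeds(seed, 1L, salt = 8L), {
    ab <- exp(rnorm(length(host), config$host_abundance_meanlog,
                    config$host_abundance_sdlog))
    mu <- outer(ab * nchar(host) / 1000,
                design$libraries$host_mapped_reads / 1e6)
    m <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                nrow(mu), ncol(mu),
                dimnames = list(names(host), design$libraries$library_id))
    m
  })
  counts <- rbind(host_counts, viral_counts)
  truth$expected_counts <- attr(viral_counts, "expected")
  truth$abundance <- design$abundance
  truth$infection <- design$infection

  structure(list(
    transcripts = Biostrings::DNAStringSet(c(host, virus_seqs)),
    proteins = Biostrings::AAStringSet(ref_prot),
    host_genome = Biostrings::DNAStringSet(c(host_genome = host_genome)),
    dna_reads = Biostrings::DNAStringSet(dna_reads),
    counts = counts, design = design, truth = truth,
    config = config), class = "virome_dataset")
}

#' @export
print.virome_dataset <- function(x, ...) {
  nv <- sum(!vapply(x$truth$viruses, `[[`, TRUE, "is_eve"))
  cat("virome_dataset:", length(x$transcripts), "transcripts (",
      nv, "viruses", if (!is.null(x$truth$eve)) "+ 1 EVE", "),",
      ncol(x$counts), "libraries\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits the standard file formats consumed by the pipeline stages:
#' FASTA for transcripts, reference proteins, host genome and DNA reads; a
#' TSV fragment-count matrix (rows = transcripts, columns = libraries); a
#' TSV library table; and the truth record as JSON.
#'
#' @param dataset A `virome_dataset` from [build_dataset()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(transcripts = file.path(outdir, "transcripts.fasta"),
             proteins = file.path(outdir, "reference_proteins.fasta"),
             genome = file.path(outdir, "host_genome.fasta"),
             dna_reads = file.path(outdir, "dna_reads.fasta"),
             counts = file.path(outdir, "counts.tsv"),
             libraries = file.path(outdir, "libraries.tsv"),
             truth = file.path(outdir, "truth.json"))
  Biostrings::writeXStringSet(dataset$transcripts, paths["transcripts"])
  Biostrings::writeXStringSet(dataset$proteins, paths["proteins"])
  Biostrings::writeXStringSet(dataset$host_genome, paths["genome"])
  Biostrings::writeXStringSet(dataset$dna_reads, paths["dna_reads"])
  cts <- data.frame(transcript_id = rownames(dataset$counts),
                    dataset$counts, check.names = FALSE)
  write.table(cts, paths["counts"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dataset$design$libraries, paths["libraries"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(truth_to_json(dataset$truth), paths["truth"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

# JSON-friendly view of the truth record
truth_to_json <- function(truth) {
  list(seed = truth$seed,
       dispersion = truth$dispersion,
       identity_target = truth$identity_target,
       viruses = lapply(truth$viruses, function(v) {
         list(name = v$name, architecture = v$architecture,
              is_eve = v$is_eve,
              segments = lapply(v$segments, function(s) {
                list(id = s$id, length = s$length,
                     orf = s$orf[, c("start", "end", "orientation",
                                     "aa_length")],
                     panhandle_len = s$panhandle_len,
                     slippery = if (!is.null(s$slippery)) {
                       s$slippery[c("position", "heptamer",
                                    "pattern_class", "fused_aa")]
                     })
              }))
       }),
       eve = truth$eve,
       realized_ref_identity = as.list(truth$realized_ref_identity),
       abundance = as.data.frame(truth$abundance),
       infection = as.data.frame(truth$infection),
       expected_counts = as.data.frame(truth$expected_counts))
}
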