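# Endogenous viral element (EVE) screening: does a candidate virus
# sequence exist in the host genome assembly (assembled EVE) or in the
# raw host DNA reads (unassembled EVE)?

#' Scan a candidate against the host genome for integrated copies
#'
#' Exact k-mer seeds shared between the candidate and the genome are
#' extended ungapped in both directions to the maximal segment whose
#' overall identity stays at or above `min_id`; hits shorter than
#' `min_len` are discarded.  Both genome strands are scanned.
#'
#' @param candidate Candidate nucleotide sequence.
#' @param genome Host genome: `DNAStringSet`, named character vector, or
#'   FASTA path.
#' @param k Seed length (>= 15; default 31).
#' @param min_id Minimum identity of a reported hit (fraction; default
#'   0.90).
#' @param min_len Minimum hit length in nt (default 100).
#' @return Data frame of hits: `scaffold`, `strand`, `cand_start`,
#'   `cand_end`, `g_start`, `g_end`, `length`, `pct_identity`.
#' @export
scan_integration <- function(candidate, genome, k = 31, min_id = 0.90,
                             min_len = 100) {
  if (k < 15) stop("seed length k must be >= 15")
  cand <- normalize_nt(candidate)
  gen <- as_named_seqs(genome, "DNA")
  if (length(gen) == 0L || all(nchar(gen) == 0L)) stop("empty genome")
  hits <- list()
  for (sc in names(gen)) {
    for (strand in c("+", "-")) {
      g <- if (strand == "+") gen[[sc]] else revcomp(gen[[sc]])
      h <- seed_extend_hits(cand, g, k, min_id, min_len)
      if (nrow(h) == 0L) next
      if (strand == "-") {
        L <- nchar(g)
        gs <- L - h$g_end + 1L
        h$g_end <- L - h$g_start + 1L
        h$g_start <- gs
      }
      h$scaffold <- sc
      h$strand <- strand
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (!length(hits)) {
    return(data.frame(scaffold = character(0), strand = character(0),
                      cand_start = integer(0), cand_end = integer(0),
                      g_start = integer(0), g_end = integer(0),
                      length = integer(0), pct_identity = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(-out$length, out$g_start),
             c("scaffold", "strand", "cand_start", "cand_end",
               "g_start", "g_end", "length", "pct_identity")]
  rownames(out) <- NULL
  out
}

# k-mer seed + ungapped maximal >=min_id extension along each diagonal
seed_extend_hits <- function(cand, g, k, min_id, min_len) {
  if (nchar(cand) < k || nchar(g) < k) {
    return(data.frame(cand_start = integer(0), cand_end = integer(0),
                      g_start = integer(0), g_end = integer(0),
                      length = integer(0), pct_identity = numeric(0)))
  }
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(
    substring(cand, seq_len(nchar(cand) - k + 1L),
              seq_len(nchar(cand) - k + 1L) + k - 1L)))
  m <- Biostrings::matchPDict(pd, Biostrings::DNAString(g))
  starts <- IRanges::start(m)
  cpos <- rep(seq_along(starts), lengths(starts))
  gpos <- unlist(starts, use.names = FALSE)
  if (!length(gpos)) {
    return(data.frame(cand_start = integer(0), cand_end = integer(0),
                      g_start = integer(0), g_end = integer(0),
                      length = integer(0), pct_identity = numeric(0)))
  }
  diag <- gpos - cpos
  cb <- strsplit(cand, "")[[1]]
  gb <- strsplit(g, "")[[1]]
  rows <- list()
  for (d in unique(diag)) {
    # overlap region of the two sequences on this diagonal
    c_lo <- max(1L, 1L - d); c_hi <- min(length(cb), length(gb) - d)
    match_vec <- cb[c_lo:c_hi] == gb[(c_lo:c_hi) + d]
    seed_c <- min(cpos[diag == d])             # anchor at leftmost seed
    rel_seed <- seed_c - c_lo + 1L
    seg <- maximal_identity_segment(match_vec, rel_seed,
                                    rel_seed + k - 1L, min_id)
    len <- seg[2] - seg[1] + 1L
    if (len < min_len) next
    ident <- mean(match_vec[seg[1]:seg[2]])
    if (ident < min_id) next
    rows[[length(rows) + 1L]] <-
      data.frame(cand_start = c_lo + seg[1] - 1L,
                 cand_end = c_lo + seg[2] - 1L,
                 g_start = c_lo + seg[1] - 1L + d,
                 g_end = c_lo + seg[2] - 1L + d,
                 length = len, pct_identity = 100 * ident)
  }
  if (!length(rows)) {
    return(data.frame(cand_start = integer(0), cand_end = integer(0),
                      g_start = integer(0), g_end = integer(0),
                      length = integer(0), pct_identity = numeric(0)))
  }
  out <- do.call(rbind, rows)
  # collapse duplicate/contained hits from multiple seeds
  out <- unique(out)
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    contained <- out$cand_start >= out$cand_start[i] &
      out$cand_end <= out$cand_end[i] &
      out$g_start >= out$g_start[i] & out$g_end <= out$g_end[i]
    contained[i] <- FALSE
    keep[contained] <- FALSE
  }
  out[keep, , drop = FALSE]
}

# longest [lo, hi] containing [s, e] with mean(match) >= min_id, then
# trimmed to matching boundaries; exact via prefix sums of
# (match - min_id)
maximal_identity_segment <- function(match_vec, s, e, min_id) {
  n <- length(match_vec)
  P <- c(0, cumsum(match_vec - min_id))       # P[i + 1] = sum of first i
  his <- e:n
  best_len <- -1L; best <- c(s, e)
  for (lo0 in 0:(s - 1L)) {                   # lo = lo0 + 1
    ok <- his[P[his + 1L] >= P[lo0 + 1L]]
    if (length(ok)) {
      hi <- max(ok)
      if (hi - lo0 > best_len) { best_len <- hi - lo0; best <- c(lo0 + 1L, hi) }
    }
  }
  lo <- best[1]; hi <- best[2]
  while (lo < hi && !match_vec[lo]) lo <- lo + 1L
  while (hi > lo && !match_vec[hi]) hi <- hi - 1L
  c(lo, hi)
}

#' Pre-computed k-mer set of a DNA read collection
#'
#' Builds the (both-strand) k-mer set of a read collection once, for
#' reuse across many [dna_read_coverage()] calls.
#'
#' @param dna_reads `DNAStringSet`, named character vector, or FASTA path.
#' @param k k-mer length (default 31).
#' @return Character vector of class `kmer_set` with attribute `k`.
#' @export
dna_read_kmers <- function(dna_reads, k = 31) {
  reads <- tryCatch(as_named_seqs(dna_reads, "DNA"), error = function(e) {
    r <- as.character(dna_reads)
    setNames(r, paste0("read", seq_along(r)))
  })
  km <- unlist(lapply(reads, function(r) {
    r <- normalize_nt(r)
    if (nchar(r) < k) return(character(0))
    st <- seq_len(nchar(r) - k + 1L)
    c(substring(r, st, st + k - 1L),
      substring(revcomp(r), st, st + k - 1L))
  }), use.names = FALSE)
  if (is.null(km)) km <- character(0)
  structure(unique(km), k = k, n_reads = length(reads), class = "kmer_set")
}

#' Fraction of a candidate covered by k-mers shared with DNA reads
#'
#' Presence/absence evidence for unassembled integrated copies: every
#' candidate position covered by at least one exact k-mer shared with any
#' host DNA read (either strand) counts as covered.
#'
#' @param candidate Candidate nucleotide sequence.
#' @param dna_reads `DNAStringSet`, named character vector, FASTA path, or
#'   a pre-computed [dna_read_kmers()] set.
#' @param k Shared k-mer length (>= 15; default 31).
#' @return Covered fraction in `[0, 1]`.
#' @export
dna_read_coverage <- function(candidate, dna_reads, k = 31) {
  if (k < 15) stop("k must be >= 15")
  cand <- normalize_nt(candidate)
  if (inherits(dna_reads, "kmer_set")) {
    if (attr(dna_reads, "k") != k) stop("kmer_set was built with k = ",
                                        attr(dna_reads, "k"))
    if (attr(dna_reads, "n_reads") == 0L) {
      warning("no DNA reads supplied: coverage is 0")
      return(0)
    }
    read_kmers <- unclass(dna_reads)
  } else {
    ks <- dna_read_kmers(dna_reads, k)
    if (attr(ks, "n_reads") == 0L) {
      warning("no DNA reads supplied: coverage is 0")
      return(0)
    }
    read_kmers <- unclass(ks)
  }
  if (nchar(cand) < k) return(0)
  st <- seq_len(nchar(cand) - k + 1L)
  cand_kmers <- substring(cand, st, st + k - 1L)
  shared <- cand_kmers %in% read_kmers
  covered <- logical(nchar(cand))
  for (i in which(shared)) covered[i:(i + k - 1L)] <- TRUE
  mean(covered)
}

#' Assemble integration evidence for a candidate
#'
#' Runs [scan_integration()] (with the identity floor relaxed by
#' `ambiguous_margin` so that sub-threshold hits are visible to the
#' classifier) and [dna_read_coverage()], returning the evidence record
#' consumed by [classify_exogenous()].
#'
#' @param candidate Candidate nucleotide sequence.
#' @param genome Host genome (see [scan_integration()]); `NULL` to skip.
#' @param dna_reads Host DNA reads (see [dna_read_coverage()]); `NULL`
#'   to skip.
#' @param k,min_id,min_len,cov_min Screening thresholds (defaults 31,
#'   0.90, 100, 0.1).
#' @param ambiguous_margin Identity margin (default 0.05) within which a
#'   sub-threshold genome hit renders the verdict ambiguous.
#' @return List of class `integration_evidence` with `genome_hits`,
#'   `dna_covered_fraction` and the thresholds used.
#' @export
integration_evidence <- function(candidate, genome = NULL, dna_reads = NULL,
                                 k = 31, min_id = 0.90, min_len = 100,
                                 cov_min = 0.1, ambiguous_margin = 0.05) {
  hits <- if (!is.null(genome)) {
    scan_integration(candidate, genome, k = k,
                     min_id = min_id - ambiguous_margin, min_len = min_len)
  } else {
    data.frame(scaffold = character(0), strand = character(0),
               cand_start = integer(0), cand_end = integer(0),
               g_start = integer(0), g_end = integer(0),
               length = integer(0), pct_identity = numeric(0))
  }
  cov <- if (!is.null(dna_reads)) {
    suppressWarnings(dna_read_coverage(candidate, dna_reads, k = k))
  } else 0
  structure(list(genome_hits = hits, dna_covered_fraction = cov,
                 thresholds = list(min_id = min_id, min_len = min_len,
                                   cov_min = cov_min,
                                   ambiguous_margin = ambiguous_margin)),
            class = "integration_evidence")
}

#' Classify a candidate as exogenous virus, EVE, or ambiguous
#'
#' Verdict `"EVE"` when the genome carries a hit of at least `min_len` nt
#' at `min_id` identity or the DNA-read coverage reaches `cov_min`;
#' `"ambiguous"` when only sub-threshold genome hits exist (identity
#' within `ambiguous_margin` of `min_id`); `"bona_fide"` otherwise.
#'
#' @param evidence An `integration_evidence` object.
#' @param thresholds Optional overrides for the thresholds recorded in
#'   `evidence`.
#' @return Character verdict: `"bona_fide"`, `"EVE"` or `"ambiguous"`.
#' @export
classify_exogenous <- function(evidence, thresholds = list()) {
  th <- utils::modifyList(evidence$thresholds, thresholds)
  hits <- evidence$genome_hits
  strong <- nrow(hits) > 0 &&
    any(hits$pct_identity >= 100 * th$min_id & hits$length >= th$min_len)
  if (strong || evidence$dna_covered_fraction >= th$cov_min) return("EVE")
  weak <- nrow(hits) > 0 &&
    any(hits$pct_identity >= 100 * (th$min_id - th$ambiguous_margin) &
          hits$length >= th$min_len)
  if (weak) return("ambiguous")
  "bona_fide"
}
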