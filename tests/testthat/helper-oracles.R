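# Independent oracles used to cross-check the dynamic-programming
# implementations on small inputs.

# Exhaustive local-alignment score: a local alignment is a monotone
# matching of query positions to target positions; the score is the sum
# of substitution scores for matched columns plus affine gap costs
# (open + ext * len) for the index jumps between consecutive columns.
# Enumerates every matching, so it is exact for short sequences.
brute_local_score <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  best <- 0
  for (k in seq_len(min(na, nb))) {
    ia_all <- utils::combn(na, k, simplify = FALSE)
    ib_all <- utils::combn(nb, k, simplify = FALSE)
    for (ia in ia_all) {
      subs_rows <- A[ia]
      for (ib in ib_all) {
        sc <- sum(mat[cbind(subs_rows, B[ib])])
        if (k > 1) {
          di <- diff(ia) - 1L; dj <- diff(ib) - 1L
          sc <- sc - sum((gap_open + gap_extend * di)[di > 0]) -
            sum((gap_open + gap_extend * dj)[dj > 0])
        }
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# Exhaustive maximum base-pair count over all nested structures with
# hairpin loops >= min_loop.  Recursion on position subsets: pairing the
# first position with j splits the problem into inside and outside parts
# (a different decomposition from the package's interval DP).
brute_max_pairs <- function(seq, min_loop = 3) {
  b <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  ok <- c("AT", "TA", "GC", "CG", "GT", "TG")
  rec <- function(idx) {
    if (length(idx) < 2L) return(0L)
    i <- idx[1]
    best <- rec(idx[-1])
    for (j in idx[-1]) {
      if (j - i > min_loop && paste0(b[i], b[j]) %in% ok) {
        best <- max(best, 1L + rec(idx[idx > i & idx < j]) +
                      rec(idx[idx > j]))
      }
    }
    best
  }
  rec(seq_along(b))
}

# Brute-force genome scan: for every diagonal offset and strand, the
# longest segment with matching endpoints and identity >= min_id,
# enumerated over all (lo, hi) pairs.
brute_best_genome_hit <- function(cand, genome, min_id = 0.9,
                                  min_len = 100) {
  cb <- strsplit(cand, "")[[1]]
  best <- NULL
  for (strand in c("+", "-")) {
    g <- if (strand == "+") genome else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(genome)))
    gb <- strsplit(g, "")[[1]]
    for (d in (1 - length(cb)):(length(gb) - 1)) {
      lo_c <- max(1L, 1L - d); hi_c <- min(length(cb), length(gb) - d)
      if (hi_c - lo_c + 1L < min_len) next
      mv <- cb[lo_c:hi_c] == gb[(lo_c:hi_c) + d]
      n <- length(mv)
      cum <- c(0, cumsum(mv))
      for (len in seq(n, min_len)) {
        found <- FALSE
        for (lo in seq_len(n - len + 1L)) {
          hi <- lo + len - 1L
          if (mv[lo] && mv[hi] &&
              (cum[hi + 1] - cum[lo]) >= min_id * len) {
            ident <- (cum[hi + 1] - cum[lo]) / len
            if (is.null(best) || len > best$length) {
              best <- list(length = len, pct_identity = 100 * ident,
                           strand = strand)
            }
            found <- TRUE
            break
          }
        }
        if (found) break
      }
    }
  }
  best
}

random_aa <- function(n) {
  paste(sample(aranevir:::AA20, n, replace = TRUE), collapse = "")
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
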