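# Six-frame translated homology search (TBLASTN-style) of transcripts
# against a viral protein reference, with Karlin-Altschul E-value
# filtering and redundancy collapse.

#' Six-frame translation of a nucleotide sequence
#'
#' Frames `+1..+3` translate the sequence itself, `-1..-3` the reverse
#' complement.  Stop codons are rendered `*`, codons containing `N` are
#' rendered `X`, trailing 1–2 nt are dropped.  `U` is treated as `T` and
#' case is folded.
#'
#' @param nt_seq Nucleotide sequence (character, `DNAString`, or RNA
#'   with `U`).
#' @return Named character vector of six amino-acid strings, names
#'   `"+1","+2","+3","-1","-2","-3"`.
#' @examples
#' six_frame_translate("ATGAAATAG")[["+1"]]   # "MK*"
#' @export
six_frame_translate <- function(nt_seq) {
  s <- normalize_nt(nt_seq)
  if (nchar(s) == 0L) stop("cannot translate an empty sequence")
  rc <- revcomp(s)
  frames <- c(`+1` = substr(s, 1L, nchar(s)),
              `+2` = substr(s, 2L, nchar(s)),
              `+3` = substr(s, 3L, nchar(s)),
              `-1` = substr(rc, 1L, nchar(rc)),
              `-2` = substr(rc, 2L, nchar(rc)),
              `-3` = substr(rc, 3L, nchar(rc)))
  vapply(frames, translate_nt, "")
}

# BLOSUM62 with '*' made non-alignable (large negative score), so that
# local alignments never cross a stop codon in a translated frame.
scoring_matrix <- function(name = "BLOSUM62") {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  mat <- get(name, envir = env)
  if ("*" %in% rownames(mat)) {
    mat["*", ] <- -1e5
    mat[, "*"] <- -1e5
  }
  mat
}

#' Smith–Waterman local protein alignment
#'
#' Best local alignment between two amino-acid sequences under an affine
#' gap model (a gap of length \eqn{g} costs `gap_open + g * gap_extend`).
#' Stop symbols (`*`) never align.  If no alignment scores above zero the
#' result is the empty alignment with score 0.
#'
#' @param query_aa,target_aa Amino-acid sequences (character or
#'   `AAString`).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`) or a
#'   numeric matrix.
#' @param gap_open,gap_extend Positive gap penalties (BLAST defaults
#'   11 / 1).
#' @return List with `score`, `query_span`, `target_span` (1-based
#'   inclusive, `integer(0)` for the empty alignment), `pct_identity`, and
#'   the two gapped `aligned` strings.
#' @examples
#' smith_waterman("HEAGAWGHEE", "PAWHEAE")$score
#' @export
smith_waterman <- function(query_aa, target_aa, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1) {
  q <- toupper(as.character(query_aa)); t <- toupper(as.character(target_aa))
  if (nchar(q) == 0L || nchar(t) == 0L) stop("empty sequence")
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be > 0")
  mat <- if (is.character(matrix)) scoring_matrix(matrix) else matrix
  ok <- rownames(mat)
  bad <- setdiff(unique(strsplit(paste0(q, t), "")[[1]]), ok)
  if (length(bad)) stop("unknown residue symbol(s): ",
                        paste(bad, collapse = ", "))
  al <- sw_align_cpp(encode_aa(q, mat), encode_aa(t, mat), mat,
                     gap_open, gap_extend)
  if (al$score <= 0) {
    return(list(score = 0, query_span = integer(0),
                target_span = integer(0), pct_identity = NA_real_,
                aligned = c(query = "", target = "")))
  }
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  qi <- al$q_span[1]; ti <- al$s_span[1]
  colq <- colt <- character(length(al$ops))
  for (k in seq_along(al$ops)) {
    op <- al$ops[k]
    if (op == 1L) {
      colq[k] <- qc[qi]; colt[k] <- tc[ti]; qi <- qi + 1L; ti <- ti + 1L
    } else if (op == 2L) {
      colq[k] <- qc[qi]; colt[k] <- "-"; qi <- qi + 1L
    } else {
      colq[k] <- "-"; colt[k] <- tc[ti]; ti <- ti + 1L
    }
  }
  ident <- 100 * sum(colq == colt & colq != "-") / length(colq)
  list(score = al$score,
       query_span = al$q_span,
       target_span = al$s_span,
       pct_identity = ident,
       aligned = c(query = paste(colq, collapse = ""),
                   target = paste(colt, collapse = "")))
}

#' Karlin–Altschul E-value for an ungapped-statistics approximation
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of local
#' alignments of score `>= S` between a query of length `m` and a database
#' of total length `n`.  The default constants are the ungapped BLOSUM62
#' values; E-values are therefore threshold-compatible with, but not
#' bit-identical to, NCBI BLAST.
#'
#' @param raw_score Raw alignment score `S`.
#' @param m Query length (aa).
#' @param n Database length (total aa).
#' @param K,lam Karlin–Altschul parameters (`K > 0`, `lambda > 0`).
#' @return Expected hit count (numeric, vectorized over `raw_score`).
#' @export
evalue <- function(raw_score, m, n, K = 0.041, lam = 0.267) {
  stopifnot(K > 0, lam > 0, m >= 1, n >= 1)
  K * m * n * exp(-lam * raw_score)
}

#' Translated search of transcripts against a viral protein reference
#'
#' Each transcript is translated in six frames and locally aligned
#' (Smith–Waterman, BLOSUM62, gaps 11/1) against every reference protein;
#' for each (transcript, reference) pair the best-scoring frame is kept
#' and reported if its E-value passes `max_evalue`.  This mirrors a
#' TBLASTN screen of an assembly against a viral protein database.
#'
#' @param transcripts Named `DNAStringSet`, named character vector, or path
#'   to a FASTA file.
#' @param protein_db Named `AAStringSet`, named character vector, or path
#'   to a FASTA file.
#' @param max_evalue E-value cutoff (default `1e-5`).
#' @param matrix,gap_open,gap_extend Alignment scoring (see
#'   [smith_waterman()]).
#' @param K,lam Karlin–Altschul constants for [evalue()].
#' @return A data frame of hits, BLAST outfmt-6-like: `transcript`,
#'   `frame`, `t_start`, `t_end` (nt, 1-based on the deposited strand),
#'   `ref`, `r_start`, `r_end` (aa), `score`, `evalue`, `pident`.
#' @export
translated_search <- function(transcripts, protein_db, max_evalue = 1e-5,
                              matrix = "BLOSUM62", gap_open = 11,
                              gap_extend = 1, K = 0.041, lam = 0.267) {
  tx <- as_named_seqs(transcripts, "DNA")
  db <- as_named_seqs(protein_db, "AA")
  if (length(db) == 0L) stop("empty protein database")
  if (length(tx) == 0L) {
    return(empty_hits())
  }
  mat <- scoring_matrix(matrix)
  n_db <- sum(nchar(db))
  frames <- lapply(tx, six_frame_translate)
  frame_labels <- c("+1", "+2", "+3", "-1", "-2", "-3")
  all_aa <- unlist(frames, use.names = FALSE)
  frame_of <- rep(frame_labels, times = length(tx))
  tx_of <- rep(names(tx), each = 6L)
  keep <- nchar(all_aa) > 0L
  enc <- lapply(all_aa[keep], encode_aa, mat = mat)
  out <- list()
  for (r in names(db)) {
    scores <- sw_scores_cpp(enc, encode_aa(db[[r]], mat), mat,
                            gap_open, gap_extend)
    sdf <- data.frame(tx = tx_of[keep], frame = frame_of[keep],
                      idx = which(keep), score = scores)
    # best frame per transcript for this reference
    sdf <- sdf[order(sdf$tx, -sdf$score), ]
    best <- sdf[!duplicated(sdf$tx), ]
    best$evalue <- evalue(best$score, m = nchar(all_aa)[best$idx],
                          n = n_db, K = K, lam = lam)
    best <- best[best$score > 0 & best$evalue <= max_evalue, , drop = FALSE]
    if (nrow(best) == 0L) next
    rows <- lapply(seq_len(nrow(best)), function(i) {
      sw <- smith_waterman(all_aa[best$idx[i]], db[[r]], matrix = mat,
                           gap_open = gap_open, gap_extend = gap_extend)
      nt <- aa_span_to_nt(best$frame[i], sw$query_span,
                          nchar(tx[[best$tx[i]]]))
      data.frame(transcript = best$tx[i], frame = best$frame[i],
                 t_start = nt[1], t_end = nt[2], ref = r,
                 r_start = sw$target_span[1], r_end = sw$target_span[2],
                 score = sw$score, evalue = best$evalue[i],
                 pident = sw$pct_identity)
    })
    out[[r]] <- do.call(rbind, rows)
  }
  if (length(out) == 0L) return(empty_hits())
  hits <- do.call(rbind, out)
  rownames(hits) <- NULL
  hits[order(hits$transcript, hits$evalue, -hits$score, hits$ref), ]
}

# 0-based residue codes into the substitution matrix rows
encode_aa <- function(aa, mat) {
  idx <- match(strsplit(toupper(aa), "")[[1]], rownames(mat))
  if (anyNA(idx)) {
    bad <- unique(strsplit(toupper(aa), "")[[1]][is.na(idx)])
    stop("unknown residue symbol(s): ", paste(bad, collapse = ", "))
  }
  idx - 1L
}

empty_hits <- function() {
  data.frame(transcript = character(0), frame = character(0),
             t_start = integer(0), t_end = integer(0), ref = character(0),
             r_start = integer(0), r_end = integer(0), score = numeric(0),
             evalue = numeric(0), pident = numeric(0))
}

# Map an amino-acid span in a translated frame back to nucleotide
# coordinates on the deposited strand (1-based inclusive, start < end).
aa_span_to_nt <- function(frame, aa_span, nt_len) {
  f <- abs(as.integer(frame))
  s <- f + 3L * (aa_span[1] - 1L)
  e <- f + 3L * aa_span[2] - 1L
  if (startsWith(frame, "-")) c(nt_len - e + 1L, nt_len - s + 1L) else c(s, e)
}

as_named_seqs <- function(x, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      is.null(names(x))) {
    x <- if (type == "DNA") Biostrings::readDNAStringSet(x) else
      Biostrings::readAAStringSet(x)
    names(x) <- sub("\\s.*$", "", names(x))
  }
  if (methods::is(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  if (length(x) == 0L) return(setNames(character(0), character(0)))
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    stop("sequences must have unique names")
  }
  x
}

#' Collapse redundant translated-search hits into candidates
#'
#' One candidate per transcript.  Within a transcript, hits whose
#' nucleotide spans overlap by more than 50% (of the shorter span) are
#' considered redundant: the lowest E-value wins, ties broken by higher
#' score then lexicographic reference id.  Disjoint hits on the same
#' transcript are retained as separate hit records of the same candidate.
#'
#' @param hits Hit data frame from [translated_search()].
#' @return Data frame of retained hits with a `candidate` column (equal to
#'   the transcript id); the best record per candidate comes first.
#' @export
collapse_hits <- function(hits) {
  if (nrow(hits) == 0L) {
    return(cbind(empty_hits(), candidate = character(0)))
  }
  pieces <- lapply(split(hits, hits$transcript), function(h) {
    h <- h[order(h$evalue, -h$score, h$ref), , drop = FALSE]
    kept <- h[0, , drop = FALSE]
    for (i in seq_len(nrow(h))) {
      if (nrow(kept) > 0L) {
        ov <- pmin(kept$t_end, h$t_end[i]) - pmax(kept$t_start, h$t_start[i]) + 1L
        minlen <- pmin(kept$t_end - kept$t_start, h$t_end[i] - h$t_start[i]) + 1L
        if (any(ov / minlen > 0.5)) next
      }
      kept <- rbind(kept, h[i, , drop = FALSE])
    }
    kept
  })
  out <- do.call(rbind, pieces)
  out$candidate <- out$transcript
  rownames(out) <- NULL
  out[order(out$transcript, out$evalue, -out$score), ]
}
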