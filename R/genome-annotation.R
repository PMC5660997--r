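# ORF and polyprotein annotation of candidate virus genomes.
#
# Coordinate convention (used throughout the package): 1-based, inclusive,
# with the stop codon INSIDE the ORF span, so that
# aa_length = (end - start + 1) / 3 - 1.  Reverse-orientation ORFs keep
# ascending coordinates on the deposited strand plus an orientation flag.

#' Find open reading frames
#'
#' Scans all three frames (and the reverse complement when `both_strands`)
#' for ATG-initiated, stop-terminated ORFs.  Within each stop-to-stop
#' stretch the ORF starts at the first ATG (the ORFfinder convention), so
#' nested same-stop ORFs are not reported.  Only ORFs whose protein is at
#' least `min_aa` long are returned.
#'
#' @param seq Nucleotide sequence.
#' @param min_aa Minimum protein length (aa, stop excluded); default 100.
#' @param both_strands Scan the reverse complement as well (default TRUE).
#' @return Data frame sorted by decreasing `aa_length` with columns
#'   `start`, `end` (1-based inclusive on the deposited strand, stop codon
#'   included), `orientation` (`"forward"`/`"reverse"`), `frame`,
#'   `aa_length`, `protein`, `mass_kda`.
#' @examples
#' find_orfs("AAATGAAATAA", min_aa = 1)   # one ORF at (3, 11), protein "MK"
#' @export
find_orfs <- function(seq, min_aa = 100, both_strands = TRUE) {
  s <- normalize_nt(seq)
  L <- nchar(s)
  res <- list()
  scan_strand <- function(str, orientation) {
    rows <- list()
    for (f in 1:3) {
      aa <- translate_nt(substr(str, f, L))
      if (nchar(aa) == 0L) next
      chars <- strsplit(aa, "")[[1]]
      stops <- which(chars == "*")
      region_start <- 1L
      for (st in stops) {
        if (st > region_start) {
          m <- which(chars[region_start:(st - 1L)] == "M")
          if (length(m)) {
            a1 <- region_start + m[1] - 1L     # first ATG in the region
            aa_len <- st - a1                   # codons before the stop
            if (aa_len >= min_aa) {
              nt_start <- f + 3L * (a1 - 1L)
              nt_end <- f + 3L * st - 1L        # stop codon included
              prot <- paste(chars[a1:(st - 1L)], collapse = "")
              rows[[length(rows) + 1L]] <-
                data.frame(start = nt_start, end = nt_end,
                           orientation = orientation, frame = f,
                           aa_length = aa_len, protein = prot,
                           stringsAsFactors = FALSE)
            }
          }
        }
        region_start <- st + 1L
      }
    }
    rows
  }
  res <- scan_strand(s, "forward")
  if (both_strands) {
    rev_rows <- scan_strand(revcomp(s), "reverse")
    rev_rows <- lapply(rev_rows, function(r) {
      new_start <- L - r$end + 1L
      r$end <- L - r$start + 1L
      r$start <- new_start
      r
    })
    res <- c(res, rev_rows)
  }
  if (length(res) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      orientation = character(0), frame = integer(0),
                      aa_length = integer(0), protein = character(0),
                      mass_kda = numeric(0)))
  }
  out <- do.call(rbind, res)
  out$mass_kda <- vapply(out$protein, protein_mass_kda, 0, USE.NAMES = FALSE)
  out <- out[order(-out$aa_length, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Protein length implied by ORF coordinates
#'
#' Under the stop-inclusive convention, an ORF spanning `start..end`
#' encodes `(end - start + 1) / 3 - 1` amino acids (the stop codon lies
#' inside the span and is excluded from the protein).  A span that is not
#' divisible by 3 is internally inconsistent and raises an error naming
#' the offending coordinates — it is never silently rounded.
#'
#' @param start,end 1-based inclusive ORF coordinates, `end > start`.
#' @return Integer amino-acid count.
#' @examples
#' orf_aa_length(7948, 9747)  # 599
#' orf_aa_length(56, 7285)    # 2409
#' @export
orf_aa_length <- function(start, end) {
  if (any(end <= start)) stop("end must be greater than start")
  span <- end - start + 1
  if (any(span %% 3 != 0)) {
    bad <- which(span %% 3 != 0)[1]
    stop("inconsistent ORF coordinates (", start[bad], ", ", end[bad],
         "): span of ", span[bad], " nt is not divisible by 3")
  }
  as.integer(span / 3 - 1)
}

# average residue masses (Da), Expasy convention
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, Q = 128.1307, E = 129.1155, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_DA <- 18.01524

#' Average molecular mass of a protein in kDa
#'
#' Sum of average residue masses plus one water (18.015 Da), divided by
#' 1000 — the convention used when reporting polyprotein sizes such as
#' "357.963 kDa".
#'
#' @param aa_seq Amino-acid sequence over the standard 20 letters.
#' @return Mass in kDa.
#' @examples
#' protein_mass_kda("G")   # 0.07507
#' @export
protein_mass_kda <- function(aa_seq) {
  res <- strsplit(toupper(as.character(aa_seq)), "")[[1]]
  bad <- setdiff(unique(res), names(AA_MASS))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  (sum(AA_MASS[res]) + WATER_DA) / 1000
}

#' Composition profile of a candidate genome and its 5'UTR
#'
#' The 5'UTR is the region upstream of the first ORF start; its UUUA
#' motif count (overlapping occurrences) and sliding-window GC/AU
#' fractions characterize the long AU-rich, IRES-like leaders of
#' picorna-like viruses.
#'
#' @param seq Nucleotide sequence.
#' @param orfs ORF table from [find_orfs()] (at least one row).
#' @param window,step Sliding-window size and step in nt (defaults 100/10).
#' @return List with `utr5_len`, `utr3_len`, `uuua_count`, and `windows`
#'   (data frame: `position` = window start, `gc_fraction`, `au_fraction`).
#' @export
utr_profile <- function(seq, orfs, window = 100, step = 10) {
  s <- normalize_nt(seq)
  if (nrow(orfs) == 0L) stop("utr_profile requires at least one ORF")
  utr5_len <- min(orfs$start) - 1L
  utr3_len <- nchar(s) - max(orfs$end)
  uuua <- if (utr5_len >= 4L) {
    Biostrings::countPattern("TTTA",
                             Biostrings::DNAString(substr(s, 1L, utr5_len)))
  } else 0L
  L <- nchar(s)
  starts <- if (L >= window) seq(1L, L - window + 1L, by = step) else 1L
  wins <- substring(s, starts, pmin(starts + window - 1L, L))
  comp <- function(w) {
    b <- strsplit(w, "")[[1]]
    b <- b[b != "N"]
    if (!length(b)) return(c(NA_real_, NA_real_))
    c(sum(b %in% c("G", "C")), sum(b %in% c("A", "T"))) / length(b)
  }
  fr <- t(vapply(wins, comp, numeric(2), USE.NAMES = FALSE))
  list(utr5_len = utr5_len, utr3_len = utr3_len, uuua_count = uuua,
       windows = data.frame(position = starts, gc_fraction = fr[, 1],
                            au_fraction = fr[, 2]))
}

#' Global pairwise percent identity
#'
#' Needleman–Wunsch global alignment; identity is the number of identical
#' columns over all alignment columns (gaps included), times 100.
#' Nucleotide scoring: match +1, mismatch -1, gap -2 (linear).  Protein
#' scoring: BLOSUM62 with affine gaps 11/1.
#'
#' @param seq_a,seq_b Sequences to compare.
#' @param level `"nt"` or `"aa"`.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' pairwise_identity("ACGT", "ACGA")  # 75
#' @export
pairwise_identity <- function(seq_a, seq_b, level = c("nt", "aa")) {
  level <- match.arg(level)
  if (!nchar(seq_a) || !nchar(seq_b)) stop("empty sequence")
  if (level == "nt") {
    a <- Biostrings::DNAString(normalize_nt(seq_a))
    b <- Biostrings::DNAString(normalize_nt(seq_b))
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 0, gapExtension = 2)
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(toupper(seq_a)),
      Biostrings::AAString(toupper(seq_b)), type = "global",
      substitutionMatrix = scoring_matrix("BLOSUM62"),
      gapOpening = 11, gapExtension = 1)
  }
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  100 * sum(ap == as_ & ap != "-") / length(ap)
}

#' Export ORF annotations as GFF3
#'
#' Writes one `CDS` feature per ORF (phase 0) with `aa_length` and
#' `mass_kda` attributes, via `rtracklayer` when available.
#'
#' @param orfs ORF table from [find_orfs()].
#' @param seqid Sequence identifier for column 1.
#' @param file Output path.
#' @return Invisibly, the path written.
#' @export
orfs_to_gff3 <- function(orfs, seqid, file) {
  if (requireNamespace("rtracklayer", quietly = TRUE) && nrow(orfs) > 0) {
    gr <- GenomicRanges::GRanges(
      seqnames = seqid,
      ranges = IRanges::IRanges(orfs$start, orfs$end),
      strand = ifelse(orfs$orientation == "forward", "+", "-"))
    gr$type <- "CDS"
    gr$phase <- 0L
    gr$ID <- sprintf("%s.orf%d", seqid, seq_len(nrow(orfs)))
    gr$aa_length <- orfs$aa_length
    gr$mass_kda <- round(orfs$mass_kda, 3)
    rtracklayer::export(gr, file, format = "gff3")
  } else {
    lines <- c("##gff-version 3",
               if (nrow(orfs) > 0)
                 sprintf("%s\taranevir\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.orf%d;aa_length=%d;mass_kda=%.3f",
                         seqid, orfs$start, orfs$end,
                         ifelse(orfs$orientation == "forward", "+", "-"),
                         seqid, seq_len(nrow(orfs)), orfs$aa_length,
                         orfs$mass_kda))
    writeLines(lines, file)
  }
  invisible(file)
}
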