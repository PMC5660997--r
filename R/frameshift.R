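# Detection of -1 programmed ribosomal frameshift signals: a slippery
# heptamer of the X_XXX_XXY form positioned at codon boundary 3 of the
# upstream ORF, stimulated by a downstream H-type pseudoknot, and
# construction of the fused ORF1a-b product.

DEFAULT_SLIPPERY_PATTERNS <- c("A_AAA_AAC", "U_UUU_UUA")

# "U_UUU_UUA" -> "TTTTTTA"; validates the X_XXX_XXY template
# (positions 1-3 one base, 4-6 one base, 7th different from the 6th).
slippery_template_to_heptamer <- function(pattern) {
  h <- normalize_nt(gsub("_", "", pattern), allow_n = FALSE)
  if (nchar(h) != 7L) stop("slippery pattern must contain 7 bases: ", pattern)
  b <- strsplit(h, "")[[1]]
  if (length(unique(b[1:3])) != 1L || length(unique(b[4:6])) != 1L ||
      b[7] == b[6]) {
    stop("pattern ", pattern, " does not match the X_XXX_XXY template")
  }
  h
}

#' Detect an H-type pseudoknot downstream of an anchor position
#'
#' Deterministic greedy search (longest stem first) for the knotted
#' topology that stimulates -1 frameshifting: a hairpin stem 1 (>= 5 bp,
#' Watson–Crick or G·U) beginning 5–12 nt after `anchor`, enclosing loop 1
#' (3–15 nt), part of which pairs as stem 2 (>= 4 bp) with a region at
#' most 30 nt downstream of the stem 1 3' arm — the two stems cross, which
#' distinguishes a pseudoknot from a nested stem-loop.  No thermodynamic
#' model is used; this is a topological detector with exposed bounds.
#'
#' @param seq Nucleotide sequence.
#' @param anchor 1-based position the search starts from (typically the
#'   last base of the slippery heptamer).
#' @param params List of search bounds: `stem1_min` (5), `stem1_max` (12),
#'   `gap_min` (5), `gap_max` (12), `loop1_min` (3), `loop1_max` (15),
#'   `stem2_min` (4), `stem2_reach` (30).
#' @return List with `present` and, when found, `stem1` / `stem2`
#'   (each `c(arm1_start, arm1_end, arm2_start, arm2_end)`).
#' @export
detect_pseudoknot <- function(seq, anchor, params = list()) {
  p <- utils::modifyList(list(stem1_min = 5L, stem1_max = 12L,
                              gap_min = 5L, gap_max = 12L,
                              loop1_min = 3L, loop1_max = 15L,
                              stem2_min = 4L, stem2_reach = 30L), params)
  s <- strsplit(normalize_nt(seq), "")[[1]]
  L <- length(s)
  if (anchor < 1L || anchor > L) stop("anchor outside the sequence")
  pairs_ok <- function(a, b) {
    (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "G" & b == "C") | (a == "C" & b == "G") |
      (a == "G" & b == "T") | (a == "T" & b == "G")
  }
  for (l1 in seq(p$stem1_max, p$stem1_min)) {
    for (st in (anchor + p$gap_min):(anchor + p$gap_max)) {
      for (d in p$loop1_min:p$loop1_max) {
        a2 <- st + l1 + d                     # stem1 3' arm start
        if (a2 + l1 - 1L > L) next
        arm1 <- s[st:(st + l1 - 1L)]
        arm2 <- s[a2:(a2 + l1 - 1L)]
        if (!all(pairs_ok(arm1, rev(arm2)))) next
        # stem 2: bases of loop1 pairing beyond the stem1 3' arm
        loop_lo <- st + l1; loop_hi <- a2 - 1L
        if (d < p$stem2_min) next
        for (l2 in seq(d, p$stem2_min)) {
          for (b1 in loop_lo:(loop_hi - l2 + 1L)) {
            hi <- min(L - l2 + 1L, a2 + l1 + p$stem2_reach)
            lo <- a2 + l1
            if (lo > hi) next
            for (b2 in lo:hi) {
              if (all(pairs_ok(s[b1:(b1 + l2 - 1L)],
                               rev(s[b2:(b2 + l2 - 1L)])))) {
                return(list(present = TRUE,
                            stem1 = c(st, st + l1 - 1L, a2, a2 + l1 - 1L),
                            stem2 = c(b1, b1 + l2 - 1L, b2, b2 + l2 - 1L)))
              }
            }
          }
        }
      }
    }
  }
  list(present = FALSE)
}

#' Find -1 frameshift slippery sites within an ORF
#'
#' Scans the final third of `orf1a` for heptamers that (a) match one of
#' the X_XXX_XXY templates in `patterns`, (b) start at codon position 3 of
#' the ORF frame (the X|XXX|XXY register), and (c) are followed by an
#' H-type pseudoknot ([detect_pseudoknot()] anchored at the heptamer end).
#'
#' @param seq Nucleotide sequence carrying the ORF.
#' @param orf1a One row of a [find_orfs()] table (forward orientation).
#' @param patterns Character vector of slippery templates; defaults to the
#'   two classes seen in arthropod astro-like viruses and HIV-1
#'   (`A_AAA_AAC`, `U_UUU_UUA`).
#' @param pk_params Bounds passed to [detect_pseudoknot()].
#' @return Data frame of sites: `position` (heptamer start), `heptamer`,
#'   `pattern_class`, pseudoknot stem coordinates, `fused_aa`.
#' @export
find_slippery_sites <- function(seq, orf1a,
                                patterns = DEFAULT_SLIPPERY_PATTERNS,
                                pk_params = list()) {
  if (orf1a$orientation != "forward") {
    stop("find_slippery_sites expects a forward-orientation ORF")
  }
  s <- normalize_nt(seq)
  hepts <- vapply(patterns, slippery_template_to_heptamer, "")
  span <- orf1a$end - orf1a$start + 1L
  from <- orf1a$start + (2L * span) %/% 3L
  out <- list()
  for (h in seq(from, orf1a$end - 6L)) {
    if ((h - orf1a$start) %% 3L != 2L) next    # X must close a codon
    word <- substr(s, h, h + 6L)
    m <- match(word, hepts)
    if (is.na(m)) next
    pk <- detect_pseudoknot(s, anchor = h + 6L, params = pk_params)
    if (!pk$present) next
    fused <- fuse_frameshift_product(s, orf1a,
                                     list(position = h, heptamer = word))
    out[[length(out) + 1L]] <- data.frame(
      position = h, heptamer = word,
      pattern_class = heptamer_class(word),
      stem1_start = pk$stem1[1], stem1_end = pk$stem1[4],
      stem2_start = pk$stem2[1], stem2_end = pk$stem2[4],
      fused_aa = nchar(fused$protein), truncated = fused$truncated,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(position = integer(0), heptamer = character(0),
                      pattern_class = character(0),
                      stem1_start = integer(0), stem1_end = integer(0),
                      stem2_start = integer(0), stem2_end = integer(0),
                      fused_aa = integer(0), truncated = logical(0)))
  }
  do.call(rbind, out)
}

#' Construct the fused ORF1a-b product of a -1 frameshift
#'
#' Translation proceeds in the ORF1a frame through the slippery heptamer;
#' the ribosome then backtracks one nucleotide, so the 7th heptamer base
#' is reused as the first base of the next (-1 frame) codon, and
#' translation continues to the next stop in the new frame.
#'
#' @param seq Nucleotide sequence.
#' @param orf1a One row of a [find_orfs()] table (forward orientation).
#' @param site A slippery site (row of [find_slippery_sites()] output or a
#'   list with `position`), or `NULL` for the no-shift identity case.
#' @return List with `protein` (fused product, no stop) and `truncated`
#'   (TRUE when no stop occurs in the -1 frame before the sequence end).
#' @export
fuse_frameshift_product <- function(seq, orf1a, site) {
  s <- normalize_nt(seq)
  if (is.null(site)) {
    prot <- translate_nt(substr(s, orf1a$start, orf1a$end))
    return(list(protein = sub("\\*$", "", prot), truncated = FALSE))
  }
  h <- site$position
  if (h < orf1a$start || h + 6L > orf1a$end) {
    stop("slippery site lies outside the ORF")
  }
  part1 <- translate_nt(substr(s, orf1a$start, h + 6L))
  rest <- substr(s, h + 6L, nchar(s))          # 7th heptamer base reused
  aa2 <- translate_nt(rest)
  stop_at <- regexpr("*", aa2, fixed = TRUE)
  truncated <- stop_at < 0L
  part2 <- if (truncated) aa2 else substr(aa2, 1L, stop_at - 1L)
  list(protein = paste0(part1, part2), truncated = truncated)
}
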