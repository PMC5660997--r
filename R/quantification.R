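# Host-normalized FPKM quantification of virus RNA levels.
#
# The normalization deliberately uses non-rRNA HOST-genome-mapped reads
# as the "million mapped reads" denominator (not total library reads):
# this protects the values from variable rRNA-depletion success, from
# other viruses, and from the diluting effect of non-host reads.

#' Fragments per kilobase per million host-mapped reads
#'
#' `FPKM = fragments / ((length_nt / 1000) * (host_mapped_reads / 1e6))`.
#' Note the denominator is host-genome-mapped (non-rRNA) reads, not total
#' reads.  Vectorized; all inputs are recycled.
#'
#' @param fragments Mapped fragment count(s) (pairs counted once).
#' @param length_nt Segment length(s) in nt (> 0).
#' @param host_mapped_reads Host-mapped read count(s) (> 0).
#' @return FPKM value(s).
#' @examples
#' fpkm(1000, 2000, 1e7)   # 50
#' @export
fpkm <- function(fragments, length_nt, host_mapped_reads) {
  if (any(length_nt <= 0)) stop("length_nt must be > 0")
  if (any(host_mapped_reads <= 0)) stop("host_mapped_reads must be > 0")
  fragments / ((length_nt / 1000) * (host_mapped_reads / 1e6))
}

#' FPKM table for candidate segments with companion totals
#'
#' Computes the segments x libraries FPKM matrix and the per-library
#' viral totals: absolute viral fragments and percent of library
#' fragments that are viral (viral / (viral + host), valid because the
#' libraries are rRNA-depleted).
#'
#' @param counts Full fragment-count matrix (all transcripts x libraries).
#' @param lengths Named vector of transcript lengths (nt) covering at
#'   least the viral segments.
#' @param design Library design list with `$libraries` (must contain
#'   `library_id` and `host_mapped_reads`).
#' @param viral_ids Row names of `counts` that are candidate viral
#'   segments.
#' @return Object of class `fpkm_table`: list with `fpkm` (viral
#'   segments x libraries), `counts` (viral counts), `totals` (data frame
#'   per library: `viral_fragments`, `host_fragments`, `percent_viral`),
#'   `lengths`.
#' @export
fpkm_table <- function(counts, lengths, design, viral_ids) {
  libs <- design$libraries
  if (!all(colnames(counts) %in% libs$library_id)) {
    stop("unknown library in the count table: ",
         paste(setdiff(colnames(counts), libs$library_id), collapse = ", "))
  }
  if (!all(viral_ids %in% rownames(counts))) {
    stop("viral_ids missing from the count table")
  }
  M <- libs$host_mapped_reads[match(colnames(counts), libs$library_id)]
  vc <- counts[viral_ids, , drop = FALSE]
  len <- lengths[viral_ids]
  if (any(is.na(len))) stop("missing viral segment length(s)")
  f <- sweep(sweep(vc, 1, len / 1000, "/"), 2, M / 1e6, "/")
  viral_tot <- colSums(vc)
  host_tot <- colSums(counts[setdiff(rownames(counts), viral_ids), ,
                             drop = FALSE])
  totals <- data.frame(library_id = colnames(counts),
                       viral_fragments = as.numeric(viral_tot),
                       host_fragments = as.numeric(host_tot),
                       percent_viral = 100 * viral_tot /
                         pmax(viral_tot + host_tot, 1))
  structure(list(fpkm = f, counts = vc, totals = totals, lengths = len),
            class = "fpkm_table")
}

#' Summarize virus RNA levels by tissue and individual
#'
#' Per-virus mean FPKM by tissue and by individual (segments of one virus
#' averaged), per-library percent-viral fragments, and absolute fragment
#' totals per virus.
#'
#' @param tab An `fpkm_table`.
#' @param design Library design list (`$libraries` with `library_id`,
#'   `individual`, `tissue`, `host_mapped_reads`).
#' @param segment_virus Named character vector mapping segment id to virus
#'   name; segments absent from the map are treated as their own virus.
#' @return List with `tissue_means` (virus x tissue), `individual_means`
#'   (virus x individual), `library_fpkm` (virus x library, segment
#'   means), `percent_viral` (per library), `virus_totals` (fragments per
#'   virus).
#' @export
summarize_profiles <- function(tab, design, segment_virus = NULL) {
  stopifnot(inherits(tab, "fpkm_table"))
  libs <- design$libraries
  if (!all(colnames(tab$fpkm) %in% libs$library_id)) {
    stop("unknown library in the FPKM table")
  }
  segs <- rownames(tab$fpkm)
  virus <- if (is.null(segment_virus)) segs else {
    v <- segment_virus[segs]
    v[is.na(v)] <- segs[is.na(v)]
    v
  }
  lib_meta <- libs[match(colnames(tab$fpkm), libs$library_id), ]
  # virus x library: mean FPKM over the segments of each virus
  vf <- rowsum(tab$fpkm, virus) / as.vector(table(virus)[sort(unique(virus))])
  agg <- function(fac) {
    groups <- split(seq_len(ncol(vf)), fac)
    out <- vapply(groups, function(ix) rowMeans(vf[, ix, drop = FALSE]),
                  numeric(nrow(vf)))
    if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                         dimnames = list(rownames(vf),
                                                         names(groups)))
    out
  }
  totals_v <- rowsum(rowSums(tab$counts), virus)
  list(tissue_means = agg(lib_meta$tissue),
       individual_means = agg(lib_meta$individual),
       library_fpkm = vf,
       percent_viral = tab$totals,
       virus_totals = data.frame(virus = rownames(totals_v),
                                 fragments = as.numeric(totals_v)))
}
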