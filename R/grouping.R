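# Grouping of candidate viral segments into putative multipartite viruses
# by shared presence/absence across libraries and co-expression.

#' Presence/absence matrix from FPKM and fragment counts
#'
#' A segment is called present in a library iff `FPKM >= fpkm_min` AND
#' `fragments >= frag_min` — the fragment floor protects against
#' length-inflated FPKM of near-zero counts.
#'
#' @param fpkm,counts Numeric matrices (segments x libraries) with
#'   matching dimensions and dimnames.
#' @param fpkm_min,frag_min Presence thresholds (defaults 1 and 10).
#' @return Logical matrix of the same shape.
#' @export
presence_matrix <- function(fpkm, counts, fpkm_min = 1, frag_min = 10) {
  if (!identical(dim(fpkm), dim(counts)) ||
      !identical(dimnames(fpkm), dimnames(counts))) {
    stop("fpkm and counts matrices must share dimensions and labels")
  }
  fpkm >= fpkm_min & counts >= frag_min
}

#' Build per-segment expression profiles
#'
#' Bundles fragment counts, FPKM and presence calls for the candidate
#' segments, the unit consumed by [group_segments()].
#'
#' @param counts Fragment-count matrix (segments x libraries).
#' @param lengths Named vector of segment lengths (nt).
#' @param host_mapped_reads Named vector of per-library host-mapped read
#'   counts (the FPKM denominator).
#' @param fpkm_min,frag_min Presence thresholds (see [presence_matrix()]).
#' @return Object of class `expression_profiles`: list with `counts`,
#'   `fpkm`, `presence`.
#' @export
expression_profiles <- function(counts, lengths, host_mapped_reads,
                                fpkm_min = 1, frag_min = 10) {
  counts <- as.matrix(counts)
  lengths <- lengths[rownames(counts)]
  host_mapped_reads <- host_mapped_reads[colnames(counts)]
  if (any(is.na(lengths))) stop("missing segment length(s)")
  if (any(is.na(host_mapped_reads))) stop("missing library read total(s)")
  f <- fpkm(counts, matrix(lengths, nrow(counts), ncol(counts)),
            matrix(host_mapped_reads, nrow(counts), ncol(counts),
                   byrow = TRUE))
  dimnames(f) <- dimnames(counts)
  structure(list(counts = counts, fpkm = f,
                 presence = presence_matrix(f, counts, fpkm_min, frag_min)),
            class = "expression_profiles")
}

#' Group segments into putative multipartite viruses
#'
#' Segments are grouped iff (a) their presence patterns across libraries
#' are identical with at least one present library, and (b) the Pearson
#' correlation of `log2(FPKM + 1)` — computed over libraries where at
#' least one of the pair is present — is at least `r_min` for EVERY pair
#' in the group (complete linkage, so one promiscuous segment cannot
#' chain unrelated viruses).  Ungrouped segments are singletons.  With a
#' single library, grouping is refused and flagged singletons returned.
#'
#' @param profiles An `expression_profiles` object.
#' @param r_min Pairwise correlation threshold (default 0.8).
#' @return Data frame: `group_id`, `segment_id`, `pattern` (presence
#'   string), `mean_r` (mean pairwise correlation inside the group, `NA`
#'   for singletons), `flag`.  Deterministic: segments are processed in
#'   lexicographic order.
#' @export
group_segments <- function(profiles, r_min = 0.8) {
  stopifnot(inherits(profiles, "expression_profiles"))
  pres <- profiles$presence
  lf <- log2(profiles$fpkm + 1)
  segs <- sort(rownames(pres))
  if (ncol(pres) < 2L) {
    return(data.frame(group_id = paste0("G", seq_along(segs)),
                      segment_id = segs,
                      pattern = apply(pres[segs, , drop = FALSE], 1,
                                      function(p) paste(as.integer(p),
                                                        collapse = "")),
                      mean_r = NA_real_,
                      flag = "insufficient_libraries"))
  }
  patt <- apply(pres[segs, , drop = FALSE], 1,
                function(p) paste(as.integer(p), collapse = ""))
  out <- list()
  gid <- 0L
  for (pt in sort(unique(patt))) {
    members <- segs[patt == pt]
    if (length(members) == 1L || !grepl("1", pt)) {
      for (m in members) {
        gid <- gid + 1L
        out[[length(out) + 1L]] <- data.frame(
          group_id = paste0("G", gid), segment_id = m, pattern = pt,
          mean_r = NA_real_, flag = "")
      }
      next
    }
    rmat <- pair_correlations(lf[members, , drop = FALSE],
                              pres[members, , drop = FALSE])
    cl <- cutree(hclust(as.dist(1 - rmat), method = "complete"),
                 h = 1 - r_min)
    for (g in sort(unique(cl))) {
      gm <- members[cl == g]
      gid <- gid + 1L
      mr <- if (length(gm) > 1L) {
        sub <- rmat[gm, gm]
        mean(sub[upper.tri(sub)])
      } else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        group_id = paste0("G", gid), segment_id = gm,
        pattern = pt, mean_r = mr, flag = "")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# pairwise Pearson correlations of log2 FPKM, each pair restricted to
# libraries where at least one of the two segments is present
pair_correlations <- function(lf, pres) {
  n <- nrow(lf)
  r <- matrix(1, n, n, dimnames = list(rownames(lf), rownames(lf)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- pres[i, ] | pres[j, ]
      x <- lf[i, use]; y <- lf[j, use]
      val <- if (sum(use) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
        if (isTRUE(all.equal(x, y))) 1 else 0
      } else stats::cor(x, y)
      r[i, j] <- r[j, i] <- val
    }
  }
  r
}
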