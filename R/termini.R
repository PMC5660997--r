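# Genome-termini analysis: panhandle complementarity scoring for
# negative-sense segments, and simplified (pair-maximizing) RNA folding
# for stem-loop counting in short UTRs.

#' Score panhandle complementarity between genome termini
#'
#' Anneals the 5' terminus against the 3' terminus read inward from the
#' genome ends (the register in which bunya-like panhandle promoters
#' form), counting Watson–Crick and G·U pairs.  The duplex extends from
#' the termini and is terminated when either a mismatch run longer than
#' `max_mismatch_run` or more than `max_mismatches` total interior
#' mismatches accumulate; it is trimmed back to the last paired position.
#' Small register shifts (up to `max_shift`) may be explored; the best
#' duplex wins (ties: more pairs, then smaller shift).
#'
#' @param five_term 5'-terminal sequence (first `w` nt used).
#' @param three_term 3'-terminal sequence (last `w` nt used).
#' @param w Terminal window (default 40).
#' @param max_mismatch_run Longest tolerated run of consecutive unpaired
#'   positions inside the duplex (default 2).
#' @param max_mismatches Total interior mismatch budget (default 2).
#' @param max_shift Register shifts to explore (default 0: the terminal
#'   register only).
#' @return List of class `panhandle_result`: `duplex_len`,
#'   `paired_fraction`, `pairs` (data frame `pos5`, `pos3`, `type`;
#'   `pos3` counted from the 3' end, 1 = last base), `shift`.
#' @export
panhandle_duplex <- function(five_term, three_term, w = 40,
                             max_mismatch_run = 2, max_mismatches = 2,
                             max_shift = 0) {
  a_full <- normalize_nt(five_term)
  b_full <- normalize_nt(three_term)
  if (w > nchar(a_full) || w > nchar(b_full)) {
    stop("w exceeds a terminus length")
  }
  if (w < 10) warning("terminal window < 10 nt: degenerate panhandle scan")
  a <- strsplit(substr(a_full, 1L, w), "")[[1]]
  b3 <- strsplit(substr(b_full, nchar(b_full) - w + 1L, nchar(b_full)),
                 "")[[1]]
  b <- rev(b3)                                # read 3' terminus inward
  pair_type <- function(x, y) {
    wc <- (x == "A" & y == "T") | (x == "T" & y == "A") |
      (x == "G" & y == "C") | (x == "C" & y == "G")
    gu <- (x == "G" & y == "T") | (x == "T" & y == "G")
    ifelse(wc, "WC", ifelse(gu, "GU", "none"))
  }
  best <- NULL
  for (sh in seq(-max_shift, max_shift)) {
    ia <- seq_len(w) + max(0L, sh)            # index into a
    ib <- seq_len(w) - min(0L, sh)            # index into b
    keep <- ia <= w & ib <= w
    ia <- ia[keep]; ib <- ib[keep]
    tp <- pair_type(a[ia], b[ib])
    paired <- tp != "none"
    run <- 0L; mm <- 0L; last <- 0L
    for (j in seq_along(paired)) {
      if (paired[j]) {
        run <- 0L; last <- j
      } else {
        run <- run + 1L; mm <- mm + 1L
        if (run > max_mismatch_run || mm > max_mismatches) break
      }
    }
    if (last == 0L) {
      cand <- list(duplex_len = 0L, n_paired = 0L, shift = sh,
                   pairs = data.frame(pos5 = integer(0), pos3 = integer(0),
                                      type = character(0)))
    } else {
      idx <- seq_len(last)
      sel <- idx[paired[idx]]
      cand <- list(duplex_len = last, n_paired = length(sel), shift = sh,
                   pairs = data.frame(pos5 = ia[sel], pos3 = ib[sel],
                                      type = tp[sel]))
    }
    if (is.null(best) || cand$duplex_len > best$duplex_len ||
        (cand$duplex_len == best$duplex_len &&
         (cand$n_paired > best$n_paired ||
          (cand$n_paired == best$n_paired &&
           abs(cand$shift) < abs(best$shift))))) {
      best <- cand
    }
  }
  structure(list(duplex_len = best$duplex_len,
                 paired_fraction = if (best$duplex_len > 0)
                   best$n_paired / best$duplex_len else 0,
                 pairs = best$pairs, shift = best$shift),
            class = "panhandle_result")
}

#' @export
print.panhandle_result <- function(x, ...) {
  cat("panhandle duplex:", x$duplex_len, "nt,",
      sprintf("%.0f%% paired", 100 * x$paired_fraction),
      if (x$shift != 0) paste0("(shift ", x$shift, ")"), "\n")
  invisible(x)
}

#' Pair-maximizing RNA secondary structure (Nussinov algorithm)
#'
#' Exact dynamic program maximizing the number of nested base pairs
#' (Watson–Crick plus G·U) with hairpin loops of at least `min_loop`
#' unpaired bases.  Traceback is deterministic: pairing is preferred over
#' leaving a base unpaired, and ties between co-optimal partners are
#' resolved in favor of the innermost (shortest-range) stem, which keeps
#' tandem stem-loops separate instead of nesting them.  This is a
#' declared simplification of
#' thermodynamic folding — pair counting, not free energy — adequate for
#' counting stem-loops in short UTR elements.
#'
#' @param seq RNA/DNA sequence of at most 300 nt.
#' @param min_loop Minimum hairpin loop length (default 3).
#' @return List with `structure` (dot-bracket), `n_pairs`, `pairs`
#'   (data frame `i`, `j`), and `stem_loops` (number of hairpin loops).
#' @examples
#' nussinov_fold("GGGAAACCC")$structure   # "(((...)))"
#' @export
nussinov_fold <- function(seq, min_loop = 3) {
  s <- chartr("U", "T", toupper(as.character(seq)))
  s <- normalize_nt(s)
  n <- nchar(s)
  if (n > 300) {
    stop("sequence longer than 300 nt: use a dedicated RNA-folding tool ",
         "(e.g. RNAfold/mfold) for full-length structures")
  }
  b <- strsplit(s, "")[[1]]
  can_pair <- function(x, y) {
    (x == "A" & y == "T") | (x == "T" & y == "A") |
      (x == "G" & y == "C") | (x == "C" & y == "G") |
      (x == "G" & y == "T") | (x == "T" & y == "G")
  }
  if (n == 0L) return(list(structure = "", n_pairs = 0L,
                           pairs = data.frame(i = integer(0),
                                              j = integer(0)),
                           stem_loops = 0L))
  N <- matrix(0L, n, n)
  if (n - 1L >= min_loop + 1L) {
    for (span in seq(min_loop + 1L, n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- N[i, j - 1L]                      # j unpaired
        ks <- i:(j - min_loop - 1L)
        ks <- ks[can_pair(b[ks], b[j])]
        if (length(ks)) {
          left <- ifelse(ks > i, N[cbind(pmax(i, 1L), pmax(ks - 1L, 1L))], 0L)
          left[ks == i] <- 0L
          inner <- N[cbind(pmin(ks + 1L, n), rep(j - 1L, length(ks)))]
          inner[ks + 1L > j - 1L] <- 0L
          best <- max(best, max(left + 1L + inner))
        }
        N[i, j] <- best
      }
    }
  }
  # deterministic traceback: prefer pairing, leftmost partner first
  struct <- rep(".", n)
  pr <- list()
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j || j - i <= min_loop) next
    target <- N[i, j]
    if (target == 0L) next
    ks <- i:(j - min_loop - 1L)
    ks <- ks[can_pair(b[ks], b[j])]
    done <- FALSE
    for (k in rev(ks)) {
      left <- if (k > i) N[i, k - 1L] else 0L
      inner <- if (k + 1L <= j - 1L) N[k + 1L, j - 1L] else 0L
      if (left + 1L + inner == target) {
        struct[k] <- "("; struct[j] <- ")"
        pr[[length(pr) + 1L]] <- c(k, j)
        if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
        stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
        done <- TRUE
        break
      }
    }
    if (!done) stack[[length(stack) + 1L]] <- c(i, j - 1L)
  }
  dot <- paste(struct, collapse = "")
  pairs <- if (length(pr)) {
    d <- do.call(rbind, pr)
    data.frame(i = d[, 1], j = d[, 2])
  } else data.frame(i = integer(0), j = integer(0))
  list(structure = dot, n_pairs = length(pr), pairs = pairs,
       stem_loops = count_hairpins(dot))
}

# hairpin loops = innermost '(' ... ')' groups
count_hairpins <- function(dot) {
  length(gregexpr("\\(\\.*\\)", dot)[[1]][
    gregexpr("\\(\\.*\\)", dot)[[1]] > 0])
}
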