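# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")

# the 61 sense codons
SENSE_CODONS <- local({
  all <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  setdiff(all, STOP_CODONS)
})

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible stream of sub-seeds from a master seed (kept
# < 2^31).  `salt` separates independent streams: since
# gcd(104729, 1000003) = 1, streams with different salts never collide
# for any realistic (salt, index) range.
derive_seeds <- function(seed, n, salt = 0L) {
  (as.numeric(seed) + 104729 * salt + 1000003 * seq_len(n)) %% 2147483647
}

# Uppercase, U -> T; optionally validate the alphabet.
normalize_nt <- function(x, allow_n = TRUE) {
  x <- chartr("u", "T", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  ok <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!all(grepl(ok, x))) {
    bad <- unique(unlist(strsplit(gsub(if (allow_n) "[ACGTN]" else "[ACGT]",
                                       "", x), "")))
    stop("invalid nucleotide symbol(s): ", paste(bad, collapse = ", "))
  }
  x
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(BASES, n, replace = TRUE, prob = prob), collapse = "")
}

# AU-biased random sequence: `au` is the total A+U fraction.
random_dna_au <- function(n, au = 0.5) {
  p <- c(au / 2, (1 - au) / 2, (1 - au) / 2, au / 2) # A C G T
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# standard genetic code as a fast lookup vector
GENCODE <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

# Translate an in-frame nucleotide string; N-containing codons become X,
# stops become *.
translate_nt <- function(nt) {
  nt <- normalize_nt(nt)
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  aa <- GENCODE[codons_of(nt)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# split a string into codons
codons_of <- function(nt) {
  n <- nchar(nt) %/% 3L
  substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
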