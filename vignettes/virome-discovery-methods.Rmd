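---
title: "Methods: RNA virome discovery from transcriptome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RNA virome discovery from transcriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aranevir)
```

## The problem

Large de novo transcriptome assemblies of arthropods routinely contain
complete RNA virus genomes assembled alongside host transcripts.
`aranevir` re-implements, as a tested and reusable pipeline, the analysis
used to mine such assemblies — the concrete template being the virome
survey of the golden orb-weaver spider, whose RNA resource comprises 16
rRNA-depleted libraries from four individuals across whole-body, brain,
silk-gland and venom-gland tissues.  The stages are:

1. **Discovery** — six-frame translated local alignment of every
   transcript against a viral protein reference, filtered at
   E &le; 10^-5^ (the TBLASTN screen).
2. **Annotation** — ORF prediction, protein lengths and masses, 5'UTR
   composition (AU richness, UUUA motifs) of picorna-like leaders.
3. **Signals** — -1 programmed ribosomal frameshift sites (slippery
   heptamer + H-type pseudoknot) and complementary panhandle genome
   termini of negative-sense segments.
4. **Segment grouping** — assigning candidate segments to multipartite
   viruses by shared presence/absence and co-expression.
5. **EVE screening** — distinguishing exogenous viruses from endogenous
   viral elements using the host genome assembly and raw DNA reads.
6. **Quantification** — host-normalized FPKM per library, summarized by
   tissue and individual.

Because the original 1.5-million-transcript assembly is not a tractable
test substrate, every stage is validated against a fully specified
synthetic dataset with machine-readable ground truth; this vignette
records the models, parameters and design decisions involved.

## Coordinate convention

All ORF coordinates are 1-based and inclusive **with the stop codon
inside the span**, so a span of $n$ nt encodes $n/3 - 1$ amino acids.
This is the only convention consistent with all nine checkable
coordinate/length pairs in the published annotations the package ships
(`inst/extdata/nephila_virus_orfs.tsv`); for example:

```{r}
orf_aa_length(761, 10147)   # a 3,128-aa polyprotein
orf_aa_length(56, 7285)     # a 2,409-aa bunya-like L protein
```

One published pair (722–7,226, reported as 2,412 aa) spans 6,505 nt —
not divisible by three.  `orf_aa_length()` raises an explicit
inconsistency error on such spans rather than silently rounding; the
row is retained in the shipped table flagged `consistent = FALSE`.

Reverse-orientation ORFs (negative-sense segments deposited 3'–5')
keep ascending deposited-strand coordinates plus an orientation flag.
ORFs start at ATG only and at the *first* ATG of a stop-bounded region
(the ORFfinder convention); the default discovery threshold is
`min_aa = 100`.  Protein masses use average residue masses plus one
water (18.015 Da), matching the kDa scale of reported polyproteins.

## Translated search

Each transcript is translated in six frames (stops rendered `*`,
N-containing codons `X`) and aligned against every reference protein by
Smith–Waterman with BLOSUM62 and affine gaps 11/1 — BLAST's protein
defaults, since the source analysis names only the tool.  The `*`
symbol is non-alignable (score $-10^5$), so local alignments never
cross a stop codon, mimicking TBLASTN HSP behavior.  The alignment
kernel is compiled (Rcpp); its scores are checked in the test suite
against both exhaustive enumeration over all monotone matchings (short
pairs) and an independent aligner (`Biostrings::pairwiseAlignment`).

Significance uses the Karlin–Altschul formula
$E = K m n e^{-\lambda S}$ with the ungapped BLOSUM62 constants
($K = 0.041$, $\lambda = 0.267$) and database length $n$ equal to the
total reference residues, with no edge-effect correction.  These
E-values are monotone-correct and threshold-compatible with, but not
bit-identical to, NCBI BLAST; the cutoff (default $10^{-5}$) is
configurable to compensate.  Redundant hits on one transcript (>50%
nucleotide-span overlap) collapse to the lowest E-value, ties broken by
score then reference id.

## Frameshift detection

A -1 programmed ribosomal frameshift signal is called when a heptamer of
the form X_XXX_XXY sits at codon position 3 of the upstream ORF's final
third *and* an H-type pseudoknot follows.  The default template set is
exactly the two classes relevant to the modelled viruses — A_AAA_AAC
(astrovirus-like) and U_UUU_UUA (HIV-1/Sindbis-like) — extensible with
any heptamer satisfying the template.  The pseudoknot detector is a
deterministic topological search, longest stem first: stem 1 (&ge;5 bp,
Watson–Crick or G·U) starting 5–12 nt past the heptamer, loop 1 of
3–15 nt, and a crossing stem 2 (&ge;4 bp) pairing loop-1 bases with a
region at most 30 nt further downstream.  No thermodynamic model is
used — free-energy ranking is explicitly out of scope — so the detector
reports topology, not stability, and all bounds are exposed as
parameters.

The fused ORF1a-b product is built by translating through the heptamer
and then resuming in the -1 frame *on* the heptamer's 7th base (the
single-nucleotide ribosome backtrack), continuing to the next stop.  A
missing -1-frame stop sets a truncation flag.

## Panhandle termini

Negative-sense segments circularize by base pairing between their
complementary genome ends.  `panhandle_duplex()` anneals the 5'
terminus against the 3' terminus read inward from the ends (the
register in which the duplex forms), counting Watson–Crick and G·U
pairs.  The duplex extends from the termini and terminates when either
a mismatch run longer than `max_mismatch_run` (default 2) or more than
`max_mismatches` (default 2) total interior mismatches accumulate, and
is trimmed to the last paired base.  This terminal-anchored,
mismatch-budgeted definition was chosen over a free sliding-window
"longest complementary region" score because the latter saturates on
random sequence: with pairing probability 6/16 per position, random
40-mer termini produce a &ge;10-nt run-tolerant region in more than half
of draws, destroying the contrast with genuine panhandles.  Under the
implemented definition random termini score below 10 nt in &gt;99% of
draws while the engineered 32-nt termini of the synthetic bunya-like
virus score &ge;32 — preserving "extending over 30 nt" as a meaningful
reporting level.  The terminal window is `w = 40` (the published
statement does not fix a window; 40 nt covers the reported >30-nt
duplex with margin).

Short-UTR folding uses the Nussinov pair-maximization DP (Watson–Crick
+ G·U, hairpin loops &ge; 3 nt, inputs &le; 300 nt) as a declared
simplification of thermodynamic folding: it supports stem-loop
*counting*, not stability claims.  Traceback is deterministic — pairing
is preferred over leaving a base unpaired, and ties between co-optimal
partners resolve to the innermost stem.  The innermost rule matters:
three tandem hairpins (the triple stem-loop architecture of astro-like
3'UTRs) admit co-optimal fully-nested pairings with the same pair
count, and an outermost-first tie-break would report them as a single
nested hairpin.  Pair counts are oracle-checked against exhaustive
enumeration of all nested structures for sequences up to 12 nt.

## Segment grouping

Candidate segments are grouped into putative multipartite viruses iff
(a) their presence patterns across libraries are identical, with at
least one present library, and (b) Pearson correlation of
log2(FPKM + 1), computed per pair over libraries where at least one of
the two is present, is &ge; `r_min` for *every* pair in the group
(complete linkage, so a promiscuous segment cannot chain unrelated
viruses).  Presence requires both FPKM &ge; 1 and &ge; 10 fragments; the
fragment floor stops length-inflated FPKM of near-zero counts.  The
published analysis states only "significant co-expression", so the
thresholds (`fpkm_min = 1`, `frag_min = 10`, `r_min = 0.8`) are declared
substitutes, all exposed in the configuration.  Grouping is refused
with a single library (insufficient evidence) and is invariant to input
order; raising `r_min` can only refine groups.

## EVE screening

A candidate is an endogenous viral element (EVE) if it can be found in
the host genome assembly or in the raw DNA reads.  The genome scan uses
exact 31-mer seeds extended ungapped in both directions to the longest
segment maintaining &ge;90% identity, keeping hits &ge;100 nt (the
published screen gives only a BLASTN E-value, so identity/length
thresholds are declared substitutes); both strands are scanned, and the
seed-and-extend result is oracle-checked against brute-force
sliding-window search.  DNA-read evidence is the fraction of candidate
positions covered by 31-mers shared with any read — alignment-free, but
sufficient for a presence/absence verdict.  Verdicts: `EVE` when a
strong genome hit or read coverage &ge; 0.1 exists; `ambiguous` when
only sub-threshold genome hits (identity within 5 points of the cutoff)
exist; `bona_fide` otherwise.

## Quantification

Virus RNA levels are FPKM with the "million mapped reads" denominator
restricted to non-rRNA host-genome-mapped reads:

$$\mathrm{FPKM} = \frac{\text{fragments}}
{(\text{length}/1000)\,(\text{host-mapped reads}/10^6)}$$

This insulates the values from variable rRNA-depletion success, from
other viruses in the library, and from non-host read dilution.
Fragments are mapped-fragment counts as provided (pairs counted once),
with no effective-length correction.  Percent-viral uses
viral/(viral + host) fragments, valid because the modelled libraries
are rRNA-depleted by construction.

## The synthetic benchmark

`default_config()` emulates the study design: 16 libraries (2 whole
body, 2 brain, 10 silk, 2 venom) from 4 individuals, host-mapped depths
drawn uniformly between 8 and 15 million reads, and four planted
viruses plus one EVE:

* **SynPV1** — monopartite polyprotein virus, 3,283 nt, with a 760-nt
  AU-rich (70% A+U) 5'UTR carrying UUUA motifs, the picorna-like leader
  architecture.
* **SynBV1** — bipartite virus, 2,400 + 1,800 nt, ORFs in reverse
  orientation and 32-nt reverse-complementary panhandle termini.
* **SynRV1** — 10-segment virus whose segment lengths are exactly the
  published reo-like segment lengths (1,096–3,837 nt, 23.6 kb total;
  `inst/extdata/ncrv2_segments.tsv`).
* **SynAV1** — 2,500-nt frameshift virus: ORF1a (437 aa) with a
  U_UUU_UUA heptamer at codon register 3 near its 3' end, an engineered
  H-type pseudoknot 9 nt downstream, a 300-codon stop-free -1 frame
  (the fused product is 749 aa by construction), and a triple
  stem-loop in the 3'UTR.
* **SynEVE1** — a 1,500-nt virus-like element expressed in all
  libraries and integrated into the 50-kb host genome at 5%
  divergence; 100-nt DNA "reads" tile the genome at 50-nt steps.

Reference proteins are the planted ORF products mutated by random
substitutions to 40% amino-acid identity — the center of the best-hit
identity range in surveys of highly divergent invertebrate viruses — so
the search must work at realistic divergence.  Counts are negative
binomial (dispersion 0.2; the source gives no noise model) with mean
`abundance x kb x host-mapped reads / 10^6`, making the expected FPKM
of a segment equal its abundance scale by construction.

Per-library abundances are drawn log2-uniformly inside per-tissue
windows.  Monopartite viruses carry the tissue structure seen in such
surveys (silk/venom-enriched picorna-like levels; the astro-like virus
absent from one individual).  The two multipartite viruses instead
draw from a wide window (log2 FPKM in [3, 14], i.e. 8–16,000 FPKM)
across all 16 libraries.  That width is a power decision made before
any grouping test was run: with negative-binomial dispersion 0.2 the
per-observation noise SD of log2(FPKM+1) is ~0.66, and requiring every
pairwise correlation of a 10-segment virus (45 pairs, &le;16 libraries)
to clear 0.8 needs the shared per-library load variance to dominate by
a factor of ~20 — i.e. loads spanning several orders of magnitude,
which is also what published per-sample virus loads do.  The floor of
8 FPKM keeps every infected library solidly above the presence
thresholds so segments of one virus share their pattern.

Each planted segment is rejection-sampled until its annotation is
exactly re-discoverable: exactly one ORF &ge; 250 aa (the planted one,
from its first ATG), and for the frameshift virus a uniquely detectable
slippery site with the constructed fused length.  This makes
"truth recovery" tests sharp: any later regression in the annotation or
detection code, not generator luck, fails them.

### What the generator does not emulate

Read-level artifacts (sequencing error, strand bleed-through, coverage
ramps), assembly fragmentation and chimerism, rRNA carry-over,
polymorphism among individuals, and codon bias in host ORFs.  Passing
tests therefore demonstrate the correctness of the statistical and
algorithmic machinery under the declared generative model — not
robustness to assembler pathology, which belongs to the upstream
assembly/curation steps that are out of scope (transcripts and counts
are inputs here).

## Problem sizes and determinism

The default benchmark (55 transcripts, ~78 kb of sequence, 15 reference
proteins, 16 libraries) is sized so a full pipeline run completes in
under a minute and the multi-seed validation suite in a few minutes,
while keeping every planted signal at the published scale that matters
(segment lengths, UTR lengths, panhandle extent, heptamer register).
All stochastic stages consume seeds derived from a single master seed
through salted coprime streams, so datasets, counts and reports are
byte-reproducible; `run_pipeline()` records the seed and a
configuration hash in its report.

## Known limitations

* E-values are approximate (ungapped constants, no length correction);
  use them as a filter, not as cross-tool evidence.
* The pseudoknot caller is topological; it will accept
  thermodynamically implausible knots that satisfy the bounds, and its
  false-positive rate on arbitrary windows is non-trivial — it is
  gated on a matching slippery heptamer for exactly that reason.
* Panhandle scoring is gap-free; bulged panhandles score as truncated
  duplexes.
* Grouping assumes segments of one virus share infection status per
  library; co-infection patterns that violate this merge or split
  groups accordingly.
* The EVE genome scan is ungapped; integrations older than ~30%
  divergence or heavily indel-eroded copies fall below its seeds.
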