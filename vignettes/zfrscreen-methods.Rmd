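---
title: "Methods: design and quantification of zinc-finger recombinase fusion screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design and quantification of zinc-finger recombinase fusion screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfrscreen)
```

## The problem

Tyrosine site-specific recombinases of the Cre family cut and rejoin DNA at
~34-bp lox sites (two 13-bp half sites around an 8-bp asymmetric spacer)
without double-strand-break repair. Fusing a zinc-finger DNA-binding domain
(ZFD) to such an enzyme — at a terminus, or inserted into the coding
sequence with flexible Gly-Gly-Ser (GGS) linkers — can raise activity on
composite *lox-zif* sites (lox flanked by the ZFD's binding motif) and, for
insertional fusions, make recombination *conditional* on ZFD binding. Which
fusion geometry works is an empirical question answered by combinatorial
screens: libraries of fusion architectures (linker lengths, fusion mode)
crossed with libraries of target sites (motif spacing, motif orientation),
read out by long-read sequencing of plasmid pools in which excision between
two direct-repeat sites converts a two-site ("unrecombined") molecule into
a one-site ("recombined") one.

`zfrscreen` implements the computational side of that programme as five
cooperating module groups:

1. **Library design** — the combinatorial grammar: target sites, fusion
   coding sequences, and paired recombined/unrecombined reference
   amplicons.
2. **Screen quantification** — read quality filtering, classification of
   each long read to a (variant, state) pair, coverage filtering, per-combination
   recombination rates and heat maps, and two-phase demultiplexing for
   insertion-variant libraries.
3. **Insertion scanning** — profiling of pentapeptide (15-bp in-frame)
   insertions along an ORF from long reads via exact affine-gap alignment.
4. **Motif scanning** — position probability/weight matrices with exact
   p-values, composite lox-site search, and the flank-constrained ZF-motif
   off-target scan.
5. **Synthetic data** — generators for every input with recorded ground
   truth, so each stage is testable end to end.

## Design grammar

A target-site design is `motif + pad + lox + pad + motif` with a spacing of
0–10 bp of neutral pad on each flanked side. Two conventions deserve
explicit statement because they are otherwise ambiguous:

* **Orientation.** Orientation `A` places the motif's given sequence on the
  top strand on the left flank and its reverse complement on the right
  flank (mirror symmetry, one motif per recombinase monomer); orientation
  `B` is the reverse-complement arrangement. The labels are an internal
  convention; both orientations are screened, so relabeling cannot change
  any result.
* **Flanking.** Motifs sit on both outer flanks by default (each monomer of
  the tetramer carries one ZFD); single-sided designs are supported via
  `flanked_sides` for left-only/right-only controls.

The pad is a deterministic non-homopolymer cycle (`TGCA…`), so target-site
construction is reproducible and annotation round-trips recover the design.
`bound_bp` accounts for protein-contacted bases only: a 34-bp lox plus two
three-finger 9-bp motifs gives 52 bp, pads excluded.

Fusion coding sequences are joined in frame with fixed GGS codons
(`GGT GGT AGC` per repeat). Terminal linkers take 2–12 repeats in steps of
two; insertional fusions place the ZFD after codon 278 (1-based; "junction
278/279") with independent 1–8-repeat linkers on each side. With 23 target
sites (11 spacings × 2 orientations + unflanked control), the terminal
screen spans 12 × 23 = 276 combinations and the insertional screen
64 × 23 = 1,472.

Reference amplicon pairs model excision resolving within the lox 8-nt
spacer: the recombined molecule keeps one complete composite site whose
flanking motifs are the outermost copies, and equals the unrecombined
molecule with one contiguous internal deletion (intersite segment + one
full site). Anchors in the backbone template make the assembly explicit
and testable. All intervals are 0-based half-open; no real lox or zif
sequence is hard-coded — sequences are configuration inputs, and all
shipped fixtures are synthetic placeholders with the published geometry.

## Read classification and rates

Reads are filtered by mean Phred quality ≥ 10 (inclusive), where "mean" is
the mean of per-base error probabilities converted back to Phred — the
standard convention, configurable to the median. Classification then
proceeds in two stages:

1. **k-mer prefilter** (k = 12). Candidate references are the ones sharing
   the most k-mers with the read on its better-matching strand. Two
   subtleties matter. GGS-linker variants of different repeat counts have
   *identical k-mer sets* (the linker is 9-periodic), and low-complexity
   spacer segments can leave the true reference a few k-mers behind an
   impostor, so the candidate pool keeps all references within 90% of the
   top count and then ranks by closeness of reference length to read
   length, always keeping a complete length-distance class together. This
   assumes full-length amplicon reads, which is what plasmid-pool nanopore
   screens produce; partial reads are handled by the alignment's free
   reference end gaps and the downstream coverage filter.
2. **Banded affine-gap alignment** of the read against each candidate
   (free end gaps on the reference, read fully aligned). The single best
   reference wins if its score beats the runner-up by at least
   `min_margin = 8` — twice the mismatch penalty, enough to separate
   single-GGS-repeat (9-nt) neighbours under moderate error. Exact ties
   are never broken randomly; they yield an `ambiguous` flag and the read
   is dropped from both numerator and denominator.

The coverage filter requires the aligned reference span to *contain* the
target-site interval(s) and the fusion-diagnostic (CDS) interval
(overlap-fraction mode available). Rates are
`n_rec / (n_rec + n_unrec)` over state-determined, unflagged reads; an
odds output (`rec/unrec`) is provided separately so the two published
phrasings ("fraction" vs "ratio") cannot be confused. Heat maps organise
rates as linker × spacing per orientation; for insertional screens the
summed-left-plus-right view pools *counts* of all (L, R) pairs with equal
total before recomputing the rate, which conserves totals exactly.

Two-phase demultiplexing mirrors the published procedure for
insertion-variant pools: phase 1 assigns each read to one backbone
(recombinase × recombination state — e.g. three recombinases give six
references); only reads unambiguously mapping proceed to phase 2, where
each backbone's subset is classified against that backbone's library of
insertion variants. The margin rule doubles as the "unambiguous" criterion,
which the source material leaves unstated.

## Affine alignment and insertion profiling

The aligner is a three-state Gotoh DP (match/mismatch, insertion,
deletion) with affine gaps costing `gap_open + L × gap_extend`
(match +2, mismatch −4, open −4, extend −2 by default — long-read-ish
values; the original pipeline's alignment parameters are not published).
Gap-to-gap transitions are allowed and each opens a new gap, so the
optimum ranges over all alignments. Traceback ties break
match/mismatch > deletion > insertion, giving deterministic CIGARs. The
implementation is exact when unbanded; a band (default 100, automatically
widened by the query/reference length difference) is used only where
speed matters. Its optimality is tested against both an independent
op-conditioned recursion and `Biostrings::pairwiseAlignment` on exhaustive
small-pair suites.

Insertion profiling globally aligns each orientation-normalized read to
the wild-type ORF, extracts insertion runs of exactly 15 nt (tolerance
configurable), left-normalizes them (placement in repeats is
alignment-ambiguous; left alignment is the standard canonicalization and
never changes event count or length), and maps positions to residue
junctions by rounding to the nearest codon boundary — sequencing errors
shift apparent positions off frame by a base or two, and nearest-boundary
rounding absorbs that; a strict in-frame mode is available. All accepted
events of a read are counted by default (one-per-read available), since
the published counting is not specified either way. Profiles normalize to
frequencies, merge across libraries for cumulative views, and rank top-N
junctions with ties toward the lower index.

The simulator can emulate Mu-transposition chemistry (a 15-bp insert
ending in a 5-bp duplication of the preceding target bases). Such inserts
are *inherently* placement-ambiguous — the duplication lets the event
slide up to 5 nt — so left-normalized calls sit up to two codons left of
the nominal junction; tests assert exactly that window. Without the
duplication flag the simulator pins boundary bases so planted and
recovered junctions coincide exactly on error-free reads.

## Motif matrices, exact p-values, and the off-target scan

PPMs use per-base pseudocounts (default 0.1, suited to matrices built from
half a dozen aligned sites); PWMs are `log2(p / background)` with a uniform
default background (configurable to sequence composition). The p-value of
a score is `P(S ≥ s)` under the background model, computed exactly by
convolving per-position score distributions on a discretized grid
(bin width 0.001 score units; the error bound, width × bin, is attached to
every result). Scanning scores words *on the same integer grid*, which
makes thresholds, reported p-values, and false-positive counts exactly
self-consistent — mixing continuous scores with binned p-values produces
visible distortions at the atom-rich score distributions short motifs
have. DP p-values are verified against exhaustive enumeration of all
4^w words for widths up to 8.

The composite lox search scans both strands for
`left half + fixed-length unscored spacer + right half`, requiring each
half to pass the p-threshold independently (a conservative AND — how the
published scan combined two half matrices is not stated; a full-width
single-matrix mode is available via `scan_sequence`). The
flank-constrained off-target scan then looks upstream of each lox hit for
the upstream ZF motif on the reverse strand and downstream for the
downstream motif on the forward strand — the strand convention of designed
flanking ZFDs — with the gap between the outer lox edge and the near motif
edge within 4–6 bp inclusive (the designed ZFDs sit 5 bp upstream and 4 bp
downstream, so the window brackets them). Distances are defined
edge-to-edge in bp. For minus-strand lox hits the roles mirror. Hits
report which sides matched (`both`/`left`/`right`, in site-local
orientation); gaps of 7 bp are outside the window and never reported.

Clone mutation tallies compare equal-length (indel-free) evolved protein
sequences against the designed reference, reporting per-position mutated
counts, frequencies, and the number of distinct substituting residues;
length-mismatched clones are rejected with a warning.

## Synthetic data: what it does and does not emulate

The generators provide: per-base i.i.d. substitutions and single-base
indels (defaults 3% substitution, 0.5% each indel — nanopore-like overall
error without homopolymer structure); constant per-read Phred drawn from
N(12, 3) truncated to [2, 40] so the Q ≥ 10 filter exercises both
branches; state draws per read at the variant's true rate; 15-nt in-frame
inserts at sampled junctions; and random genomes with planted composite
sites at recorded coordinates. Determinism is a contract: one run seed,
with each read's randomness drawn from a counter-derived substream, so
read order never changes results and every output is reproducible from
`(inputs, seed)`.

What passing tests on these data do *not* show: robustness to homopolymer
error bursts, chimeric or adapter-bearing reads, barcode cross-talk,
non-uniform pool composition, or real genomic sequence composition. The
generators emulate the statistical structure the pipeline's decisions
depend on (error rate, length differences, state mixtures, planted
geometry), not pore physics.

## Problem sizes and numerical choices

The validation experiments use sizes chosen to give tight statistical
checks at desk scale: rate recovery runs 10 insertional variants × 1,000
reads at 3% error against a 3-binomial-SE criterion (boundary rates 0 and
1 must be recovered exactly — state misclassification would need the
~200-nt state difference to be bridged by noise); insertion-profile
recovery uses a 343-codon ORF with a 70/20/10 planted distribution, exact
on error-free reads and within 3 multinomial SE at 3% error; the
off-target scan plants all six 4–6-bp gap combinations in a 60-kb genome
and requires 100% recovery with correct gap and strand calls. Alignment
and p-value components are checked against independent oracles rather
than statistical bounds.

## Known limitations

* Classification cost is one banded alignment per candidate per read
  (~tens of ms per read on one core at 1.7-kb amplicons); very large
  screens would want a vectorized or multi-core driver.
* The length-proximity candidate rule assumes read length reflects
  template length; heavily truncated reads fall back on alignment scores
  alone and may be flagged rather than assigned.
* The composite-site AND rule is conservative; sites with one weak half
  compensated by a strong half are found only in full-width single-matrix
  mode.
* Gel band intensities are taken as numbers (`band_intensity_rate`);
  image densitometry is out of scope.
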