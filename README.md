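# zfrscreen

Design and long-read analysis of zinc-finger (ZF) recombinase fusion
screens, for protein engineers and sequencing bioinformaticians working on
Cre-type site-specific recombinases.

Cre-family recombinases recombine ~34-bp lox sites (13-bp half sites
around an 8-bp spacer). Fusing a zinc-finger DNA-binding domain to such an
enzyme — at a terminus with a Gly-Gly-Ser (GGS) linker, or inserted into
the coding sequence between two linkers — changes its activity on
composite *lox-zif* target sites (lox flanked by the ZF motif at a defined
spacing and orientation). Finding working architectures means screening a
combinatorial grid of fusion designs against a grid of target-site
designs and reading the outcome from long-read sequencing of plasmid
pools, where excision between two direct-repeat sites converts the
two-site (unrecombined) molecule into a one-site (recombined) one.

The package implements that pipeline end to end:

* **Library design** — enumerate fusion × target-site grids (2 termini ×
  6 linkers × 23 sites = 276 terminal combinations; 8 × 8 insertional
  linker pairs × 23 sites = 1,472), assemble in-frame fusion coding
  sequences, and synthesize paired recombined/unrecombined reference
  amplicons with interval annotations.
* **Screen quantification** — Phred ≥ 10 read filtering, classification of
  each read to a (variant, state) pair by k-mer prefilter plus banded
  affine-gap alignment with an explicit ambiguity margin, coverage
  filtering against annotated intervals, per-combination recombination
  rates `n_rec / (n_rec + n_unrec)`, linker × spacing heat maps, and
  two-phase demultiplexing for insertion-variant pools.
* **Pentapeptide insertion profiling** — exact Gotoh affine-gap alignment
  of reads to a wild-type ORF, extraction of 15-nt in-frame insertions
  from the CIGAR, left normalization, mapping to residue junctions, and
  per-junction frequency profiles with top-N reporting.
* **Motif scanning** — position probability/weight matrices, exact
  p-values by dynamic programming over the discretized score
  distribution, FIMO-style scanning (p ≤ 0.001), composite
  half-site + spacer + half-site lox search, and the flank-constrained
  off-target scan (ZF motif 4–6 bp from the lox edge, upstream on the
  reverse strand / downstream on the forward strand).
* **Synthetic data** — seeded generators for noisy long reads at known
  recombination rates, insertion libraries with planted junction
  distributions, and genomes with planted lox+flank composites, each with
  a ground-truth table.

## Worked example

The `analysis/` directory holds the narrative workflow. Running it from
the repository root:

```sh
Rscript analysis/01_design_library.R
Rscript analysis/02_screen_quantification.R
Rscript analysis/03_insertion_scan.R
Rscript analysis/04_offtarget_scan.R
```

prints, among other things:

```
terminal screen design space:    276 combinations
insertional screen design space: 1472 combinations
flanked composite site: 62 nt total, 52 bound bp
...
simulated 3200 reads over 16 variants
                    stage reads
1                   input  3200
2     removed_low_quality   671
3 unassigned_or_ambiguous     0
4     flagged_no_coverage     0
5        state_determined  2529
max |estimated - true| rate over 16 variants: 0.059
...
merged top-5 junctions: 278, 60, 200, 150, 300
...
recovered 4 of 4 planted sites
```

Reading those numbers: the two design spaces match the closed-form grid
products; a 5-bp-spaced flanked site is 62 nt long of which 52 bp are
protein-bound (34-bp lox + two 9-bp three-finger motifs, pads excluded);
of 3,200 simulated nanopore-like reads, 671 fall below Q10 and every
surviving read is classified with state determined, giving per-variant
rate estimates within 0.059 of the planted truth at 200 reads/variant;
the merged insertion profile ranks junction 278 — the insertion point
used for insertional fusions — first; and the flank-constrained scan
recovers all planted lox+flank composites, including an upstream-only
site. Outputs land under `results/` as TSV/FASTA/BED/MEME files.

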