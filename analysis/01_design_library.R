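#!/usr/bin/env Rscript
# Step 1 — combinatorial library design.
#
# Validates the two screen configurations, enumerates their design spaces
# (276 terminal combinations, 1,472 insertional), and synthesizes the
# reference amplicons for a small worked subset of the terminal screen:
# multi-FASTA (one record per variant x state), BED annotations, and the
# TSV design manifest.

suppressPackageStartupMessages({
  library(zfrscreen)
  library(dplyr)
})

dir.create("results", showWarnings = FALSE)

terminal_cfg <- parse_and_validate_config(
  system.file("extdata", "terminal_screen.yaml", package = "zfrscreen"))
insertional_cfg <- parse_and_validate_config(
  system.file("extdata", "insertional_screen.yaml", package = "zfrscreen"))
cat(sprintf("terminal screen design space:    %d combinations\n",
            attr(terminal_cfg, "design_space")))
cat(sprintf("insertional screen design space: %d combinations\n",
            attr(insertional_cfg, "design_space")))

# a flanked site binds lox (34 bp) plus two three-finger motifs (9 bp each)
site <- build_target_site(
  target_site_design(terminal_cfg$lox, terminal_cfg$motif, 5L, "A"))
cat(sprintf("flanked composite site: %d nt total, %d bound bp\n",
            nchar(site$sequence), site$bound_bp))

# worked subset: both termini x linkers {2, 12} x spacings {0, 5, 10} (A)
# plus the unflanked control
sites <- enumerate_target_library(terminal_cfg$lox, terminal_cfg$motif,
                                  spacings = c(0L, 5L, 10L),
                                  orientations = "A")
fusions <- enumerate_fusion_library("Brec1", c("N_TERMINAL", "C_TERMINAL"),
                                    linker_grid = c(2L, 12L))

set.seed(terminal_cfg$seed)
codon_pool <- c("GCA", "TGC", "GAT", "GAA", "TTC", "GGA", "CAT", "ATC",
                "AAA", "CTG", "ATG", "AAC", "CCG", "CAG", "CGT", "AGC",
                "ACC", "GTT", "TGG", "TAT")
rec_cds <- paste0(c("ATG", sample(codon_pool, 341, TRUE), "GCA"),
                  collapse = "")
zf_cds <- paste0(c("ATG", sample(codon_pool, 88, TRUE), "GCA"),
                 collapse = "")
backbone <- paste0(strrep("TGCA", 15), "[SITE1][INTERSITE][SITE2]",
                   strrep("GTCA", 10), "[CDS]", strrep("CAGT", 8))
intersite <- strrep("GATC", 38)

refs <- build_screen_references(fusions, sites, backbone, rec_cds, zf_cds,
                                intersite)
cat(sprintf("built %d reference amplicons (%d variants x 2 states)\n",
            length(refs), length(refs) / 2))

write_fasta(refs, "results/references.fasta")
write_reference_bed(refs, "results/references.bed")
write_design_manifest(fusions, sites, "results/design_manifest.tsv")
saveRDS(list(refs = refs, rec_cds = rec_cds, zf_cds = zf_cds,
             backbone = backbone, intersite = intersite,
             cfg = terminal_cfg),
        "results/design_objects.rds")
cat("wrote results/references.fasta, references.bed, design_manifest.tsv\n")
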