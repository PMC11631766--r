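# Shared fixtures and independent oracles. All sequences are synthetic
# placeholders with the published geometry (13+8+13 lox, 9-nt three-finger
# motif); no real lox/zif sequence is printed in the source material.

fixture_lox <- function() {
  lox_site("loxSYN", "ATAACTTCGTATA", "GCATACAT", "TATACGAAGTTAT")
}

fixture_motif <- function() zf_motif("zifSYN", "GCGTGGGCG")

# deterministic codon soup without stop codons
fixture_cds <- function(n_codons, seed = 42L) {
  pool <- c("GCA", "TGC", "GAT", "GAA", "TTC", "GGA", "CAT", "ATC", "AAA",
            "CTG", "ATG", "AAC", "CCG", "CAG", "CGT", "AGC", "ACC", "GTT",
            "TGG", "TAT")
  withr::with_seed(seed, paste0(
    c("ATG", sample(pool, n_codons - 2L, replace = TRUE), "GCA"),
    collapse = ""))
}

fixture_backbone <- function() {
  paste0(zfrscreen:::pad_seq(60), "[SITE1][INTERSITE][SITE2]",
         zfrscreen:::pad_seq(40, "GTCA"), "[CDS]",
         zfrscreen:::pad_seq(30, "CAGT"))
}

fixture_intersite <- function(n = 150L) zfrscreen:::pad_seq(n, "GATC")

# small screen reference set: a few fusions x a few sites
fixture_refs <- function(fusions = NULL, sites = NULL, n_codons = 80L) {
  lox <- fixture_lox()
  zm <- fixture_motif()
  if (is.null(sites)) {
    all_sites <- enumerate_target_library(lox, zm, spacings = 0:10)
    sites <- all_sites[c(1, 6, 23)]
  }
  if (is.null(fusions)) {
    fusions <- enumerate_fusion_library("Brec1")[1:2]
  }
  build_screen_references(fusions, sites, fixture_backbone(),
                          fixture_cds(n_codons), fixture_cds(30L, 7L),
                          fixture_intersite())
}

random_dna <- function(n, seed) {
  withr::with_seed(seed, paste0(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = ""))
}

# Independent affine-gap alignment oracle: op-conditioned recursion with
# memoisation, written query-major and charging gap_open + gap_extend on
# every gap opening (including gaps adjacent to a differently typed gap).
oracle_affine_score <- function(q, r, match = 2, mismatch = -4,
                                gap_open = -4, gap_extend = -2) {
  n <- nchar(q); m <- nchar(r)
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, last) {
    key <- paste(i, j, last)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i == 0 && j == 0) return(if (last == "S") 0 else -Inf)
    best <- -Inf
    if (i > 0 && j > 0 && last == "M") {
      s <- if (qs[i] == rs[j]) match else mismatch
      best <- max(best, s + max(rec(i - 1, j - 1, "M"),
                                rec(i - 1, j - 1, "I"),
                                rec(i - 1, j - 1, "D"),
                                rec(i - 1, j - 1, "S")))
    }
    if (i > 0 && last == "I") {
      best <- max(best,
                  gap_extend + rec(i - 1, j, "I"),
                  gap_open + gap_extend + max(rec(i - 1, j, "M"),
                                              rec(i - 1, j, "D"),
                                              rec(i - 1, j, "S")))
    }
    if (j > 0 && last == "D") {
      best <- max(best,
                  gap_extend + rec(i, j - 1, "D"),
                  gap_open + gap_extend + max(rec(i, j - 1, "M"),
                                              rec(i, j - 1, "I"),
                                              rec(i, j - 1, "S")))
    }
    memo[[key]] <- best
    best
  }
  max(rec(n, m, "M"), rec(n, m, "I"), rec(n, m, "D"))
}

# Exhaustive PWM p-value oracle: enumerate all 4^w words on the same score
# grid the DP uses.
oracle_pwm_pvalue <- function(pwm, score, bin_width = 0.001) {
  m <- unclass(pwm)
  bg <- attr(pwm, "background")
  w <- ncol(m)
  mi <- matrix(as.integer(floor(m / bin_width + 0.5)), nrow = 4)
  scores <- 0L
  probs <- 1
  for (j in seq_len(w)) {
    scores <- as.vector(outer(scores, mi[, j], "+"))
    probs <- as.vector(outer(probs, bg, "*"))
  }
  q <- as.integer(floor(score / bin_width + 0.5))
  cont_min <- attr(pwm, "min_score")
  vapply(seq_along(q), function(k) {
    if (score[k] <= cont_min + 1e-12) return(1.0)
    sum(probs[scores >= q[k]])
  }, numeric(1))
}

# quality helper: constant-Q reads
qreads <- function(seqs, q) {
  tibble::tibble(id = sprintf("r%03d", seq_along(seqs)), sequence = seqs,
                 qualities = lapply(nchar(seqs), function(n) rep.int(q, n)))
}
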