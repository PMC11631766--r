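test_that("PPM construction normalizes columns with pseudocounts", {
  one <- build_ppm("ACGT", pseudocount = 0)
  expect_equal(unname(one["A", 1]), 1)
  expect_equal(unname(one["C", 2]), 1)
  expect_equal(unname(diag(unclass(one)[c("A", "C", "G", "T"), ])),
               rep(1, 4))

  w1 <- build_ppm("A", pseudocount = 1)
  expect_equal(unname(w1[, 1]), c(2, 1, 1, 1) / 5)

  set.seed(4)
  seqs <- replicate(6, paste0(sample(c("A", "C", "G", "T"), 13, TRUE),
                              collapse = ""))
  p <- build_ppm(seqs)
  expect_equal(colSums(unclass(p)), rep(1, 13), tolerance = 1e-12)
  expect_true(all(unclass(p) > 0))
  expect_equal(attr(p, "n_sequences"), 6L)
  expect_error(build_ppm(c("ACGT", "ACG")), "ragged")
})

test_that("log-odds transform and score bounds behave as defined", {
  uniform <- build_ppm(c("AAAA", "CCCC", "GGGG", "TTTT"), pseudocount = 0)
  pw0 <- ppm_to_pwm(uniform)
  expect_equal(matrix(as.numeric(pw0), 4, 4), matrix(0, 4, 4))

  p <- build_ppm(rep("ACGT", 6), pseudocount = 0.1)
  pw <- ppm_to_pwm(p)
  # max_score equals the consensus score
  expect_equal(pwm_score(pw, "ACGT"), attr(pw, "max_score"))
  expect_equal(attr(pw, "min_score"), sum(apply(unclass(pw), 2, min)))
  # strong column: p ~ 1 gives ~ log2(4) = 2 bits against uniform
  expect_equal(unname(unclass(pw)["A", 1]),
               log2((6 + 0.1) / (6 + 0.4) / 0.25), tolerance = 1e-12)

  expect_error(ppm_to_pwm(build_ppm("ACGT", pseudocount = 0)), "zero|pseudo")
})

test_that("DP p-values equal exhaustive enumeration up to width 8", {
  set.seed(7)
  for (w in c(1L, 3L, 5L, 8L)) {
    seqs <- replicate(6, paste0(sample(c("A", "C", "G", "T"), w, TRUE),
                                collapse = ""))
    ppm <- build_ppm(seqs, 0.1)
    bg <- c(0.3, 0.2, 0.2, 0.3)
    pwm <- ppm_to_pwm(ppm, bg)
    probe <- seq(attr(pwm, "min_score"), attr(pwm, "max_score"),
                 length.out = 9)
    dp <- pwm_pvalue(pwm, probe)
    oracle <- oracle_pwm_pvalue(pwm, probe)
    expect_equal(as.numeric(dp), oracle, tolerance = 1e-9,
                 info = paste("width", w))
    # structural properties
    expect_equal(as.numeric(pwm_pvalue(pwm, attr(pwm, "min_score"))), 1.0)
    expect_true(all(diff(as.numeric(dp)) <= 1e-12))  # monotone
  }
  # width-1 uniform: unique maximum attained by 1 of 4 bases
  w1 <- ppm_to_pwm(build_ppm(rep("A", 5), 0.1))
  expect_equal(as.numeric(pwm_pvalue(w1, attr(w1, "max_score"))), 0.25)
  expect_error(pwm_pvalue(w1, 0, bin_width = -1), "bin")
})

test_that("scanning finds planted motifs on both strands", {
  set.seed(12)
  seqs <- replicate(6, paste0(sample(c("A", "C", "G", "T"), 9, TRUE),
                              collapse = ""))
  ppm <- build_ppm(seqs, 0.1)
  pwm <- ppm_to_pwm(ppm)
  cons <- paste0(c("A", "C", "G", "T")[apply(unclass(ppm), 2, which.max)],
                 collapse = "")
  g <- random_genome(3000, seed = 21)
  g <- paste0(substr(g, 1, 500), cons, substr(g, 510, 3000))
  hits <- scan_sequence(pwm, g, p_threshold = 0.001)
  expect_true(any(hits$start == 500 & hits$strand == "+"))

  # reverse complement of the consensus: minus-strand hit at the same
  # forward coordinate
  g2 <- paste0(substr(g, 1, 1000), revcomp(cons), substr(g, 1010, 3000))
  hits2 <- scan_sequence(pwm, g2, p_threshold = 0.001)
  expect_true(any(hits2$start == 1000 & hits2$strand == "-"))

  # monotonicity: a looser threshold never removes hits
  loose <- scan_sequence(pwm, g2, p_threshold = 0.01)
  key <- function(h) paste(h$start, h$strand)
  expect_true(all(key(hits2) %in% key(loose)))

  # strand consistency: scanning the reverse complement mirrors hits
  rc_hits <- scan_sequence(pwm, revcomp(g2), p_threshold = 0.001)
  mirrored <- nchar(g2) - rc_hits$start - 9L
  expect_setequal(paste(mirrored, ifelse(rc_hits$strand == "+", "-", "+")),
                  key(hits2))

  # windows with non-ACGT bases are skipped
  gn <- paste0(substr(g, 1, 500), "NNNNNNNNN", substr(g, 510, 3000))
  expect_false(any(scan_sequence(pwm, gn, 0.001)$start == 500))
})

test_that("composite lox scan enforces the fixed spacer geometry", {
  lhalf <- "ATAACTTCGTATA"
  rhalf <- "TATACGAAGTTAT"
  lppm <- build_ppm(rep(lhalf, 6), 0.1)
  rppm <- build_ppm(rep(rhalf, 6), 0.1)
  lox34 <- paste0(lhalf, "GCATACAT", rhalf)
  expect_equal(nchar(lox34), 34)

  g <- random_genome(10000, seed = 31)
  g_ok <- paste0(substr(g, 1, 4000), lox34, substr(g, 4035, 10000))
  hits <- scan_lox_candidates(lppm, rppm, 8L, g_ok, 0.001)
  expect_true(any(hits$start == 4000 & hits$strand == "+"))
  expect_equal(hits$width[1], 34L)

  # spacer off by one at plant time: not reported as a composite
  lox35 <- paste0(lhalf, "GCATACATT", rhalf)
  g_bad <- paste0(substr(g, 1, 4000), lox35, substr(g, 4036, 10000))
  expect_false(any(scan_lox_candidates(lppm, rppm, 8L, g_bad,
                                       0.001)$start == 4000))

  # minus-strand composite is found at the mirrored coordinate
  g_rc <- paste0(substr(g, 1, 2000), revcomp(lox34), substr(g, 2035, 10000))
  hits_rc <- scan_lox_candidates(lppm, rppm, 8L, g_rc, 0.001)
  expect_true(any(hits_rc$start == 2000 & hits_rc$strand == "-"))
})

test_that("flank-constrained scan respects distances and strands", {
  lhalf <- "ATAACTTCGTATA"
  rhalf <- "TATACGAAGTTAT"
  lppm <- build_ppm(rep(lhalf, 6), 0.1)
  rppm <- build_ppm(rep(rhalf, 6), 0.1)
  lox34 <- paste0(lhalf, "GCATACAT", rhalf)
  up <- "GCAATGAAT"        # read on the reverse strand upstream
  dn <- "CAAGATTGGCAG"     # read on the forward strand downstream
  up_pwm <- ppm_to_pwm(build_ppm(rep(up, 6), 0.1))
  dn_pwm <- ppm_to_pwm(build_ppm(rep(dn, 6), 0.1))

  run_case <- function(up_gap, dn_gap) {
    plants <- tibble::tibble(
      lox_seq = lox34,
      up_motif = if (is.na(up_gap)) NA_character_ else up,
      up_gap = up_gap, down_motif = if (is.na(dn_gap)) NA_character_
                                    else dn,
      down_gap = dn_gap)
    pg <- plant_genome(8000, plants, seed = 17)
    loxh <- scan_lox_candidates(lppm, rppm, 8L, pg$sequence, 0.001)
    list(hits = flank_constrained_scan(loxh, up_pwm, dn_pwm, pg$sequence),
         truth = pg$truth)
  }

  # both flanks at the designed 5 bp / 4 bp: sides = both
  both <- run_case(5L, 4L)
  expect_equal(nrow(both$hits), 1L)
  expect_equal(both$hits$sides, "both")
  expect_equal(both$hits$left_distance, 5L)
  expect_equal(both$hits$right_distance, 4L)
  expect_equal(both$hits$left_motif_strand, "-")
  expect_equal(both$hits$right_motif_strand, "+")
  expect_equal(both$hits$left_motif_start, both$truth$up_motif_start)
  expect_equal(both$hits$right_motif_start, both$truth$down_motif_start)

  # upstream only: sides = left
  left_only <- run_case(5L, NA)
  expect_equal(left_only$hits$sides, "left")

  # a 7-bp gap is outside the 4-6 window and never reported
  out_of_range <- run_case(7L, NA)
  expect_equal(nrow(out_of_range$hits), 0L)

  expect_error(flank_constrained_scan(tibble::tibble(), up_pwm, dn_pwm,
                                      "ACGT", distance_range = c(6, 4)),
               "inverted")
})

test_that("clone mutation tallies count differing residues per position", {
  ref <- "MKRHGLDNYRGYSL"
  clones <- rep(ref, 10)
  t0 <- tally_clone_mutations(clones, ref)
  expect_equal(sum(t0$n_mutated), 0L)

  clones[1] <- sub("G", "R", clones[1])  # G5 -> R in one clone
  t1 <- tally_clone_mutations(clones, ref)
  expect_equal(t1$frequency[t1$position == 5], 0.1)
  expect_equal(t1$distinct_residues[t1$position == 5], 1L)

  clones[2] <- paste0(substr(ref, 1, 4), "K", substr(ref, 6, 14))
  t2 <- tally_clone_mutations(clones, ref)
  expect_equal(t2$n_mutated[t2$position == 5], 2L)
  expect_equal(t2$distinct_residues[t2$position == 5], 2L)
  expect_equal(t2$residues[t2$position == 5], "K,R")

  expect_warning(t3 <- tally_clone_mutations(c(clones, "MKR"), ref),
                 "rejected")
  expect_equal(sum(t3$n_mutated), sum(t2$n_mutated))
})
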