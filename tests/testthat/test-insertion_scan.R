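test_that("affine aligner matches independent oracles on small pairs", {
  # randomized suite of short pairs vs (a) an op-conditioned memoised
  # recursion and (b) Biostrings pairwiseAlignment
  suppressPackageStartupMessages(library(Biostrings))
  submat <- nucleotideSubstitutionMatrix(match = 2, mismatch = -4)
  set.seed(101)
  for (i in 1:40) {
    n <- sample(1:12, 1)
    m <- sample(1:12, 1)
    q <- paste0(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    r <- paste0(sample(c("A", "C", "G", "T"), m, TRUE), collapse = "")
    al <- global_align_affine(q, r)
    expect_equal(al$score, oracle_affine_score(q, r),
                 info = paste(q, r))
    pa <- pairwiseAlignment(q, r, type = "global",
                            substitutionMatrix = submat,
                            gapOpening = 4, gapExtension = 2)
    expect_equal(al$score, score(pa), info = paste(q, r))
  }
})

test_that("alignment CIGARs are deterministic and reconstruct lengths", {
  ref <- random_dna(200, 5)
  al <- global_align_affine(ref, ref)
  expect_equal(al$cigar$op, "M")
  expect_equal(al$cigar$len, 200L)
  expect_equal(al$score, 400)

  # single 15-nt insert produces exactly one 15I run
  q <- paste0(substr(ref, 1, 120), "GATTACAGATTACAG", substr(ref, 121, 200))
  al2 <- global_align_affine(q, ref)
  expect_equal(sum(al2$cigar$op == "I"), 1L)
  expect_equal(al2$cigar$len[al2$cigar$op == "I"], 15L)

  # the same call twice gives identical CIGARs (fixed tie-break)
  expect_identical(global_align_affine(q, ref), al2)

  expect_error(global_align_affine("", ref), "empty")
  expect_error(global_align_affine("ACNGT", ref), "non-ACGT")
})

test_that("insertion events are extracted, filtered and left-normalized", {
  ref <- random_dna(300, 9)
  # pin the boundary context so the planted placement is unambiguous
  # (insert starts and ends with G; flanking reference bases must differ)
  substr(ref, 100, 101) <- "CT"
  substr(ref, 80, 81) <- "CT"
  substr(ref, 200, 201) <- "TA"
  q <- paste0(substr(ref, 1, 100), "GATTACAGATTACAG",
              substr(ref, 101, 300))
  al <- global_align_affine(q, ref)
  ev <- extract_insertions(al, q)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$ref_pos, 100L)
  expect_equal(ev$length, 15L)
  expect_equal(ev$inserted_seq, "GATTACAGATTACAG")

  # off-length insertions are ignored at zero tolerance
  q3 <- paste0(substr(ref, 1, 100), "GAT", substr(ref, 101, 300))
  expect_equal(nrow(extract_insertions(global_align_affine(q3, ref), q3)),
               0L)
  # ... but accepted with tolerance
  expect_equal(nrow(extract_insertions(global_align_affine(q3, ref), q3,
                                       target_length = 3L)), 1L)

  # two separated inserts give two events
  q2 <- paste0(substr(ref, 1, 80), "GATTACAGATTACAG",
               substr(ref, 81, 200), "CCCGGGTTTAAACCC",
               substr(ref, 201, 300))
  ev2 <- extract_insertions(global_align_affine(q2, ref), q2)
  expect_equal(nrow(ev2), 2L)
  expect_equal(ev2$ref_pos, c(80L, 200L))

  # left normalization in a repeat context: enumerate equivalent
  # placements and require the minimum
  repref <- paste0("ACGT", strrep("TAG", 6), "CCGGA")
  ins <- strrep("TAG", 5)
  ev_right <- tibble::tibble(ref_pos = 4L + 18L, length = 15L,
                             inserted_seq = ins)
  shifted <- left_align_insertion(ev_right, repref)
  equivalent <- function(pos, insert) {
    paste0(substr(repref, 1, pos), insert,
           substr(repref, pos + 1, nchar(repref)))
  }
  target <- equivalent(ev_right$ref_pos, ins)
  min_equiv <- min(Filter(function(p) {
    any(vapply(0:14, function(k) {
      rot <- paste0(substr(ins, 15 - k + 1, 15), substr(ins, 1, 15 - k))
      equivalent(p, rot) == target
    }, logical(1)))
  }, 0:22))
  expect_equal(shifted$ref_pos, min_equiv)
  # idempotence, length preserved
  expect_identical(left_align_insertion(shifted, repref), shifted)
  expect_equal(shifted$length, 15L)

  # non-repetitive context: unchanged
  ev_plain <- tibble::tibble(ref_pos = 100L, length = 15L,
                             inserted_seq = "GATTACAGATTACAG")
  expect_equal(left_align_insertion(ev_plain, ref)$ref_pos, 100L)
})

test_that("positions map to residue junctions with codon rounding", {
  expect_equal(position_to_junction(834L, 0L), 278L)  # 278 x 3
  expect_equal(position_to_junction(835L, 0L), 278L)  # nearest boundary
  expect_equal(position_to_junction(836L, 0L), 279L)
  expect_equal(position_to_junction(0L, 0L), 0L)
  expect_equal(position_to_junction(850L, 16L), 278L)  # offset ORF
  expect_true(is.na(position_to_junction(835L, 0L, strict = TRUE)))
  expect_equal(position_to_junction(834L, 0L, strict = TRUE), 278L)
  expect_error(position_to_junction(5L, 10L), "before ORF")
  expect_error(position_to_junction(900L, 0L, orf_length_codons = 100L),
               "beyond ORF")
})

test_that("insertion profiles count, normalize, merge and rank junctions", {
  ev <- tibble::tibble(read_id = sprintf("r%d", 1:100),
                       junction = rep(40L, 100))
  prof <- build_insertion_profile(ev, 100L)
  expect_equal(prof$frequency[prof$junction == 40L], 1.0)
  expect_equal(sum(prof$count), 100L)
  expect_equal(sum(prof$frequency), 1.0)

  none <- build_insertion_profile(ev[0, ], 100L)
  expect_equal(sum(none$count), 0L)
  expect_true(all(is.na(none$frequency)))

  multi <- tibble::tibble(read_id = c("a", "a", "b"),
                          junction = c(10L, 20L, 10L))
  expect_equal(sum(build_insertion_profile(multi, 50L)$count), 3L)
  expect_equal(sum(build_insertion_profile(multi, 50L, "first")$count), 2L)
  expect_error(build_insertion_profile(
    tibble::tibble(read_id = "a", junction = 200L), 100L), "range")

  # ranking with ties toward the lower junction
  cnt <- tibble::tibble(read_id = sprintf("r%d", 1:15),
                        junction = c(rep(10L, 5), rep(20L, 9), 30L))
  p <- build_insertion_profile(cnt, 50L)
  expect_equal(top_positions(p, 2L), c(20L, 10L))
  tie <- build_insertion_profile(
    tibble::tibble(read_id = sprintf("r%d", 1:4),
                   junction = c(7L, 7L, 3L, 3L)), 50L)
  expect_equal(top_positions(tie, 2L), c(3L, 7L))
  expect_equal(top_positions(tie, 10L), c(3L, 7L))  # only populated

  merged <- merge_insertion_profiles(p, tie)
  expect_equal(sum(merged$count), 19L)
  expect_equal(sum(merged$frequency), 1.0)
})

test_that("planted junction distributions are recovered from reads", {
  orf_codons <- 200L
  ref <- fixture_cds(orf_codons, seed = 33L)
  jd <- tibble::tibble(junction = c(60L, 120L, 170L),
                       prob = c(0.7, 0.2, 0.1))

  # error-free reads: exact recovery
  sim0 <- simulate_insertion_reads(ref, 0L, jd, n_reads = 60L,
                                   model = error_model(0, 0, 0), seed = 2L)
  out0 <- profile_insertions(sim0$reads, ref, 0L, orf_codons)
  truth_tab <- table(factor(sim0$truth$junction, levels = 0:orf_codons))
  expect_equal(out0$profile$count, as.integer(truth_tab))

  # 3% substitutions plus indels: within 3 multinomial SE
  n <- 150L
  sim <- simulate_insertion_reads(ref, 0L, jd, n_reads = n,
                                  model = error_model(0.03, 0.005, 0.005),
                                  seed = 8L)
  out <- profile_insertions(sim$reads, ref, 0L, orf_codons)
  # collapse codon-rounding jitter of +-1 junction around each planted site
  est <- vapply(jd$junction, function(j) {
    sum(out$profile$frequency[abs(out$profile$junction - j) <= 1])
  }, numeric(1))
  se <- sqrt(jd$prob * (1 - jd$prob) / n)
  expect_true(all(abs(est - jd$prob) <= 3 * se))

  # orientation normalization: reverse-complemented reads profile the same
  rc_reads <- sim0$reads
  rc_reads$sequence <- revcomp(rc_reads$sequence)
  out_rc <- profile_insertions(rc_reads, ref, 0L, orf_codons)
  expect_equal(out_rc$profile$count, out0$profile$count)
})

test_that("duplication-mode inserts land within the ambiguity window", {
  orf_codons <- 120L
  ref <- fixture_cds(orf_codons, seed = 12L)
  jd <- tibble::tibble(junction = 60L, prob = 1)
  sim <- simulate_insertion_reads(ref, 0L, jd, n_reads = 10L,
                                  model = error_model(0, 0, 0),
                                  duplication = TRUE, seed = 3L)
  out <- profile_insertions(sim$reads, ref, 0L, orf_codons)
  hit <- out$profile$junction[out$profile$count > 0]
  # the 5-bp duplication makes placement ambiguous by up to 5 nt (2 codons)
  expect_true(all(abs(hit - 60L) <= 2L))
  expect_equal(sum(out$profile$count), 10L)
})
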