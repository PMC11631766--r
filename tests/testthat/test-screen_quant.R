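test_that("quality filter applies the inclusive Phred threshold", {
  reads <- qreads(c(strrep("ACGT", 25), strrep("ACGT", 25),
                    strrep("ACGT", 25)), 10L)
  reads$qualities[[1]] <- rep.int(9L, 100)   # below
  reads$qualities[[2]] <- rep.int(10L, 100)  # boundary: retained
  reads$qualities[[3]] <- rep.int(30L, 100)
  kept <- filter_reads_by_quality(reads, 10)
  expect_equal(kept$id, c("r002", "r003"))

  # empty input passes through
  expect_equal(nrow(filter_reads_by_quality(reads[0, ], 10)), 0L)

  # mixed per-base qualities use the mean-error convention
  q <- c(rep.int(30L, 50), rep.int(3L, 50))
  expect_lt(read_quality(q), mean(q))  # low-Q bases dominate
  expect_equal(read_quality(q, "median"), 16.5)

  # reads without qualities pass with a warning
  noq <- tibble::tibble(id = "x", sequence = "ACGT",
                        qualities = list(NULL))
  expect_warning(out <- filter_reads_by_quality(noq, 10), "retained")
  expect_equal(nrow(out), 1L)

  expect_error(filter_reads_by_quality(reads, -1), "non-negative")
})

test_that("classification assigns exact copies and flags ties", {
  refs <- fixture_refs()
  idx <- build_reference_index(refs)

  # error-free copy of each reference classifies to it with positive margin
  for (nm in names(refs)[c(1, 4, 9)]) {
    r <- refs[[nm]]
    a <- classify_read(tibble::tibble(id = "t", sequence = r$sequence),
                       idx)
    expect_equal(a$variant_id, r$variant_id)
    expect_equal(a$state, r$state)
    expect_gt(a$margin, 0)
    expect_equal(a$flags, "")
  }

  # reverse-complement invariance
  r <- refs[[3]]
  a_fwd <- classify_read(tibble::tibble(id = "t", sequence = r$sequence),
                         idx)
  a_rev <- classify_read(tibble::tibble(id = "t",
                                        sequence = revcomp(r$sequence)),
                         idx)
  expect_equal(a_rev$variant_id, a_fwd$variant_id)
  expect_equal(a_rev$state, a_fwd$state)
  expect_equal(a_rev$score, a_fwd$score)

  # synthetic tie: two references with identical sequence -> ambiguous
  dup <- refs[1:2]
  dup[["copyA"]] <- dup[[1]]
  tie_idx <- build_reference_index(dup)
  a <- classify_read(tibble::tibble(id = "t",
                                    sequence = dup[[1]]$sequence), tie_idx)
  expect_true(is.na(a$variant_id))
  expect_match(a$flags, "ambiguous")

  expect_error(classify_read(tibble::tibble(id = "t", sequence = ""), idx),
               "empty")
  expect_error(build_reference_index(list()), "empty")
})

test_that("coverage filter requires interval containment", {
  refs <- fixture_refs()
  r <- refs[[1]]
  full <- tibble::tibble(read_id = "t", variant_id = r$variant_id,
                         state = r$state, score = 1, margin = 10,
                         ref_start = 0L,
                         ref_end = nchar(r$sequence), flags = "")
  expect_true(coverage_filter(full, r))

  cds <- r$annotations[r$annotations$name == "fusion_diagnostic", ]
  missing_cds <- dplyr::mutate(full, ref_end = cds$start + 5L)
  expect_false(coverage_filter(missing_cds, r))

  # overlapping but not containing the first target site
  site1 <- r$annotations[r$annotations$name == "target_site", ][1, ]
  partial <- dplyr::mutate(full, ref_start = site1$start + 3L)
  expect_false(coverage_filter(partial, r))
  expect_true(coverage_filter(partial, r, mode = "overlap"))

  flagged <- apply_coverage_filter(dplyr::bind_rows(full, missing_cds),
                                   build_reference_index(refs))
  expect_equal(flagged$flags, c("", "no_coverage"))
})

test_that("rates, odds and band intensities follow the count definitions", {
  asg <- tibble::tibble(
    read_id = sprintf("r%02d", 1:45),
    variant_id = c(rep("Brec1-N-L2|loxSYN-5-zifSYN(A)", 40),
                   rep("Brec1-N-L4|loxSYN", 5)),
    state = c(rep("REC", 10), rep("UNREC", 30), rep("REC", 2),
              rep("UNREC", 3)),
    score = 1, margin = 10, ref_start = 0L, ref_end = 100L,
    flags = c(rep("", 40), rep("no_coverage", 5)))
  rates <- compute_rates(asg)
  expect_equal(nrow(rates), 1L)  # flagged variant contributes no record
  expect_equal(rates$n_rec, 10L)
  expect_equal(rates$n_unrec, 30L)
  expect_equal(rates$rate, 0.25)
  expect_equal(rates$mode, "N_TERMINAL")
  expect_equal(rates$linker_left, 2L)
  expect_equal(rates$spacing, 5L)
  expect_equal(rates$orientation, "A")

  empty <- compute_rates(asg[asg$flags != "", ])
  expect_equal(nrow(empty), 0L)

  expect_equal(band_intensity_rate(1, 3), 0.25)
  expect_equal(band_intensity_rate(0, 5), 0)
  expect_equal(band_intensity_rate(5, 0), 1)
  expect_true(is.na(band_intensity_rate(0, 0)))
  expect_equal(recombination_odds(1, 4), 0.25)
  expect_error(band_intensity_rate(-1, 1), "non-negative")
})

test_that("heat maps pool summed-linker counts and conserve totals", {
  mk <- function(l, r, sp, ori, nrec, nunrec) tibble::tibble(
    variant_id = sprintf("Brec1-ins278-L%dR%d|loxSYN-%d-zifSYN(%s)",
                         l, r, sp, ori),
    fusion_id = sprintf("Brec1-ins278-L%dR%d", l, r),
    site_id = sprintf("loxSYN-%d-zifSYN(%s)", sp, ori),
    mode = "INSERTIONAL", linker_left = l, linker_right = r,
    spacing = sp, orientation = ori, n_rec = nrec, n_unrec = nunrec,
    rate = nrec / (nrec + nunrec))
  rr <- dplyr::bind_rows(mk(3, 5, 5, "A", 10, 10), mk(4, 4, 5, "A", 30, 10),
                         mk(1, 1, 0, "A", 0, 20), mk(2, 6, 5, "B", 5, 15))
  hm <- build_heatmap(rr, "summed_left_right")
  row8 <- hm[hm$linker == 8 & hm$spacing == 5 & hm$orientation == "A", ]
  expect_equal(row8$n_rec, 40L)   # pooled counts
  expect_equal(row8$n_unrec, 20L)
  expect_equal(row8$rate, 40 / 60)  # rate recomputed from pooled counts
  expect_equal(sum(hm$n_rec) + sum(hm$n_unrec),
               sum(rr$n_rec) + sum(rr$n_unrec))  # conservation

  m <- heatmap_matrix(hm, "A")
  expect_equal(m["8", "5"], 40 / 60)
  expect_true(is.na(m["2", "5"]))

  # terminal grid keeps the per-linker axis
  tr <- tibble::tibble(
    variant_id = "x", fusion_id = "x", site_id = "y", mode = "N_TERMINAL",
    linker_left = 12L, linker_right = NA_integer_, spacing = 5L,
    orientation = "B", n_rec = 3L, n_unrec = 1L, rate = 0.75)
  hmt <- build_heatmap(tr, "per_linker")
  expect_equal(hmt$linker, 12L)
  expect_error(build_heatmap(tr, "summed_left_right"), "insertional")
})

test_that("simulated screens recover true rates within binomial error", {
  # one orientation x several variants, moderate depth; nanopore-like noise
  lox <- fixture_lox()
  zm <- fixture_motif()
  sites <- enumerate_target_library(lox, zm, spacings = c(0L, 5L))[
    c("loxSYN-0-zifSYN(A)", "loxSYN-5-zifSYN(A)")]
  fus <- enumerate_fusion_library("Brec1")[c(1, 4)]
  refs <- build_screen_references(fus, sites, fixture_backbone(),
                                  fixture_cds(80L), fixture_cds(30L, 7L),
                                  fixture_intersite())
  truth <- tibble::tibble(
    variant_id = unique(vapply(refs, function(r) r$variant_id,
                               character(1))),
    rate = c(0, 1, 0.3, 0.7), n_reads = 120L)
  sim <- simulate_screen_reads(refs, truth,
                               error_model(0.03, 0.005, 0.005), seed = 11L)
  idx <- build_reference_index(refs)
  reads <- filter_reads_by_quality(sim$reads, 10)
  asg <- apply_coverage_filter(classify_reads(reads, idx), idx)
  rates <- compute_rates(asg)
  log <- run_log(nrow(sim$reads), reads, asg)
  expect_true(attr(log, "conserved"))

  joined <- dplyr::left_join(rates, truth, by = "variant_id",
                             suffix = c("", "_true"))
  n <- joined$n_rec + joined$n_unrec
  se <- sqrt(joined$rate_true * (1 - joined$rate_true) / pmax(n, 1))
  expect_true(all(abs(joined$rate - joined$rate_true) <= 3 * se + 1e-12))
  # boundary rates are recovered exactly
  expect_equal(joined$rate[joined$rate_true == 0], 0)
  expect_equal(joined$rate[joined$rate_true == 1], 1)
})

test_that("two-phase demultiplexing recovers per-variant rates", {
  # two recombinase backbones x two states = 4 phase-1 references here;
  # each backbone's library holds insertion variants at 3 positions
  lox <- fixture_lox()
  site <- build_target_site(target_site_design(lox, NULL))
  inter <- fixture_intersite(120L)
  backbone <- fixture_backbone()
  recs <- c(VikaA = 42L, VikaB = 99L)
  positions <- c(30L, 60L, 90L)

  backbone_refs <- list()
  variant_libraries <- list()
  all_refs <- list()
  for (rn in names(recs)) {
    cds <- fixture_cds(120L, seed = recs[[rn]])
    pair <- build_reference_pair(backbone, site, cds, inter, rn)
    backbone_refs[[paste0(rn, "|UNREC")]] <- pair$UNREC
    backbone_refs[[paste0(rn, "|REC")]] <- pair$REC
    for (st in c("REC", "UNREC")) {
      lib <- list()
      for (pos in positions) {
        ins_cds <- paste0(substr(cds, 1, 3 * pos), "GATCCTGAACCTGAA",
                          substr(cds, 3 * pos + 1, nchar(cds)))
        vp <- build_reference_pair(backbone, site, ins_cds, inter,
                                   sprintf("%s-ins%d", rn, pos))
        lib[[sprintf("%s-ins%d|%s", rn, pos, st)]] <- vp[[st]]
        all_refs[[sprintf("%s-ins%d|%s", rn, pos, st)]] <- vp[[st]]
      }
      variant_libraries[[paste0(rn, "|", st)]] <- lib
    }
  }
  truth <- tibble::tibble(
    variant_id = c("VikaA-ins30", "VikaA-ins60", "VikaA-ins90",
                   "VikaB-ins30", "VikaB-ins60", "VikaB-ins90"),
    rate = c(0, 0.5, 1, 1, 0.5, 0), n_reads = 60L)
  sim <- simulate_screen_reads(all_refs, truth,
                               error_model(0.02, 0.003, 0.003), seed = 5L)
  out <- two_phase_demultiplex(sim$reads, backbone_refs, variant_libraries)

  expect_equal(nrow(out$rates), 6L)
  joined <- dplyr::left_join(out$rates, truth, by = "variant_id",
                             suffix = c("", "_true"))
  n <- joined$n_rec + joined$n_unrec
  se <- sqrt(joined$rate_true * (1 - joined$rate_true) / pmax(n, 1))
  expect_true(all(abs(joined$rate - joined$rate_true) <= 3 * se + 1e-12))
  expect_equal(joined$rate[joined$rate_true == 0], c(0, 0))
  expect_equal(joined$rate[joined$rate_true == 1], c(1, 1))

  # backbone set missing a state is rejected
  expect_error(two_phase_demultiplex(sim$reads, backbone_refs[c(1, 3)],
                                     variant_libraries), "both")
})
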