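# Long-read classification against the combinatorial reference set and
# recombination-rate estimation.
#
# Reads are held as a tibble with columns:
#   id        character
#   sequence  character (A/C/G/T)
#   qualities list-column of integer Phred scores (may be NULL per read)

# Quality filter ---------------------------------------------------------

#' Mean Phred quality of a read
#'
#' Per-base Phred scores are converted to error probabilities, averaged, and
#' converted back (the standard mean-quality convention). `statistic =
#' "median"` uses the plain median Phred instead.
#'
#' @param qualities integer vector of Phred scores.
#' @param statistic `"mean_error"` (default) or `"median"`.
#' @return scalar quality.
#' @export
read_quality <- function(qualities, statistic = c("mean_error", "median")) {
  statistic <- match.arg(statistic)
  if (statistic == "median") return(stats::median(qualities))
  -10 * log10(mean(10^(-qualities / 10)))
}

#' Filter reads by Phred quality
#'
#' Retains reads whose summary Phred quality is at least `min_phred`
#' (boundary inclusive). Reads without quality strings pass with a warning.
#' Input order is preserved.
#'
#' @param reads read tibble (id, sequence, qualities list-column).
#' @param min_phred minimum quality, default 10.
#' @param statistic passed to [read_quality()].
#' @return filtered read tibble.
#' @export
filter_reads_by_quality <- function(reads, min_phred = 10,
                                    statistic = "mean_error") {
  if (min_phred < 0) stop("min_phred must be non-negative")
  if (nrow(reads) == 0L) return(reads)
  if (!"qualities" %in% names(reads) || is.null(reads$qualities)) {
    warning("reads carry no qualities; all retained")
    return(reads)
  }
  keep <- vapply(reads$qualities, function(q) {
    if (is.null(q)) return(NA)
    read_quality(q, statistic) >= min_phred
  }, logical(1))
  if (anyNA(keep)) {
    warning("some reads carry no qualities; those are retained")
    keep[is.na(keep)] <- TRUE
  }
  reads[keep, , drop = FALSE]
}

# Reference index and classification -------------------------------------

#' Build a k-mer index over a reference set
#'
#' Used as a prefilter so each read is aligned only against the references
#' sharing the most k-mers with it.
#'
#' @param refs named list of [reference_amplicon()]s (names
#'   `variant_id|state`).
#' @param k k-mer size (default 12).
#' @return object of class `reference_index`.
#' @export
build_reference_index <- function(refs, k = 12L) {
  if (length(refs) == 0L) stop("empty reference set")
  seqs <- vapply(refs, function(r) r$sequence, character(1))
  ids <- names(refs)
  if (is.null(ids)) ids <- vapply(refs, function(r)
    paste(r$variant_id, r$state, sep = "|"), character(1))
  kmers <- lapply(seqs, function(s) {
    if (nchar(s) < k) character(0)
    else unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  })
  tab <- tibble(kmer = unlist(kmers, use.names = FALSE),
                ref = rep.int(seq_along(refs), lengths(kmers)))
  structure(list(refs = refs, ids = ids, k = as.integer(k),
                 kmer_ref = tab),
            class = "reference_index")
}

read_kmers <- function(s, k) {
  if (nchar(s) < k) return(character(0))
  unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
}

# Default alignment scoring shared by the classifier and the insertion
# profiler (match, mismatch, gap_open, gap_extend); a length-L gap costs
# gap_open + L * gap_extend.
default_align_params <- function() {
  list(match = 2, mismatch = -4, gap_open = -4, gap_extend = -2)
}

#' Classify one read against the reference index
#'
#' A k-mer prefilter nominates candidate references on the better-matching
#' strand; candidates are then scored with a banded affine-gap alignment
#' (free end gaps on the reference so partial amplicons still align). The
#' single best reference is assigned when its score exceeds the runner-up by
#' at least `min_margin`; exact ties are never broken at random and yield an
#' `ambiguous` flag.
#'
#' @param read one-row read tibble (or list with id/sequence).
#' @param index a [build_reference_index()].
#' @param min_margin minimum score gap to the second-best reference (default
#'   8, twice the per-base mismatch penalty, which separates
#'   single-GGS-repeat neighbors under moderate error).
#' @param n_candidates number of k-mer candidates to align (default 5).
#' @param band alignment band half-width (default 100); the band window
#'   additionally widens by the read/reference length difference, so this
#'   only needs to absorb indel drift.
#' @param params alignment scoring parameters.
#' @return one-row assignment tibble: read_id, variant_id, state, score,
#'   margin, ref_start, ref_end, flags (comma-joined).
#' @export
classify_read <- function(read, index, min_margin = 8,
                          n_candidates = 5L, band = 100L,
                          params = default_align_params()) {
  stopifnot(inherits(index, "reference_index"))
  seq_fwd <- read$sequence[[1]]
  if (is.null(seq_fwd) || nchar(seq_fwd) == 0L) stop("empty read")
  id <- read$id[[1]]
  unassigned <- function(flags) {
    tibble(read_id = id, variant_id = NA_character_, state = NA_character_,
           score = NA_real_, margin = NA_real_, ref_start = NA_integer_,
           ref_end = NA_integer_, flags = paste(flags, collapse = ","))
  }
  k <- index$k
  tally <- function(s) {
    km <- read_kmers(s, k)
    hit <- index$kmer_ref[index$kmer_ref$kmer %in% km, ]
    if (nrow(hit) == 0L) return(integer(0))
    tab <- table(hit$ref)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    sort(counts, decreasing = TRUE)
  }
  t_fwd <- tally(seq_fwd)
  seq_rev <- revcomp(seq_fwd)
  t_rev <- tally(seq_rev)
  best_fwd <- if (length(t_fwd)) t_fwd[[1]] else 0L
  best_rev <- if (length(t_rev)) t_rev[[1]] else 0L
  if (best_fwd == 0L && best_rev == 0L) {
    return(unassigned("no_kmer_match"))
  }
  # Candidate set: top references by shared k-mers from the better strand
  # (both strands when tied). Repeat-length variants (GGS linker grids)
  # have identical k-mer SETS, so tallies tie exactly; ties are broken by
  # closeness of reference length to read length, and a whole
  # length-distance class is always kept together so the true reference
  # can never be dropped by an arbitrary tie split.
  ref_lens <- vapply(index$refs, function(r) nchar(r$sequence), numeric(1))
  select_candidates <- function(tal, read_len) {
    if (length(tal) == 0L) return(integer(0))
    # near-tied counts stay in the pool: low-complexity regions (periodic
    # linkers, repetitive spacers) can leave the true reference a few
    # k-mers behind an impostor
    pool <- as.integer(names(tal)[tal >= 0.9 * tal[[1]]])
    if (length(pool) < min(n_candidates, length(tal))) {
      pool <- as.integer(names(tal)[seq_len(min(n_candidates,
                                                length(tal)))])
    }
    dist <- abs(ref_lens[pool] - read_len)
    ord <- order(dist, pool)
    pool <- pool[ord]
    dist <- dist[ord]
    k <- min(n_candidates, length(pool))
    pool[seq_along(pool) <= k | dist == dist[k]]
  }
  cands <- list()
  add_cands <- function(tal, s, strand) {
    for (i in select_candidates(tal, nchar(s))) {
      cands[[length(cands) + 1L]] <<- list(ref = i, query = s,
                                           strand = strand)
    }
  }
  if (best_fwd >= best_rev) add_cands(t_fwd, seq_fwd, "+")
  if (best_rev >= best_fwd) add_cands(t_rev, seq_rev, "-")

  scores <- numeric(length(cands))
  spans <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    r <- index$refs[[cands[[i]]$ref]]
    al <- .affine_align_cpp(cands[[i]]$query, r$sequence,
                            params$match, params$mismatch,
                            params$gap_open, params$gap_extend,
                            as.integer(band), TRUE)
    scores[i] <- al$score
    spans[[i]] <- c(al$ref_start, al$ref_end)
  }
  # collapse duplicate (ref, strand) candidates to the max score per ref
  ref_ids <- vapply(cands, function(c) c$ref, numeric(1))
  per_ref <- tapply(scores, ref_ids, max)
  ord <- order(per_ref, decreasing = TRUE)
  best_ref <- as.integer(names(per_ref)[ord[1]])
  best_score <- per_ref[[ord[1]]]
  margin <- if (length(per_ref) > 1L) best_score - per_ref[[ord[2]]] else Inf
  if (margin == 0) {
    return(unassigned("ambiguous"))
  }
  if (margin < min_margin) {
    return(unassigned("ambiguous"))
  }
  win <- which(ref_ids == best_ref & scores == best_score)[1]
  ref <- index$refs[[best_ref]]
  tibble(read_id = id, variant_id = ref$variant_id, state = ref$state,
         score = best_score, margin = margin,
         ref_start = as.integer(spans[[win]][1]),
         ref_end = as.integer(spans[[win]][2]), flags = "")
}

#' Classify many reads
#'
#' @param reads read tibble.
#' @param index a [build_reference_index()].
#' @param ... passed to [classify_read()].
#' @return assignment tibble, one row per read, input order preserved.
#' @export
classify_reads <- function(reads, index, ...) {
  if (nrow(reads) == 0L) {
    return(tibble(read_id = character(), variant_id = character(),
                  state = character(), score = numeric(), margin = numeric(),
                  ref_start = integer(), ref_end = integer(),
                  flags = character()))
  }
  bind_rows(lapply(seq_len(nrow(reads)), function(i) {
    classify_read(reads[i, ], index, ...)
  }))
}

# Coverage filter --------------------------------------------------------

#' Coverage filter on an assignment
#'
#' Checks that the aligned reference span covers the assigned reference's
#' required intervals (all `target_site` intervals and the
#' `fusion_diagnostic` interval by default). `mode = "contain"` requires full
#' containment; `mode = "overlap"` accepts any overlap with each interval.
#'
#' @param assignment one assignment row (needs variant_id, ref_start,
#'   ref_end).
#' @param ref the assigned [reference_amplicon()].
#' @param required_names annotation names that must be covered.
#' @param mode `"contain"` (default) or `"overlap"`.
#' @return logical scalar.
#' @export
coverage_filter <- function(assignment, ref,
                            required_names = c("target_site",
                                               "fusion_diagnostic"),
                            mode = c("contain", "overlap")) {
  mode <- match.arg(mode)
  if (is.na(assignment$variant_id)) stop("assignment is UNASSIGNED")
  req <- ref$annotations[ref$annotations$name %in% required_names, ]
  if (any(req$start < 0L) || any(req$end > nchar(ref$sequence))) {
    stop("required interval outside reference bounds")
  }
  s <- assignment$ref_start
  e <- assignment$ref_end
  if (mode == "contain") {
    all(s <= req$start & e >= req$end)
  } else {
    all(s < req$end & e > req$start)
  }
}

#' Apply the coverage filter to an assignment table
#'
#' Rows failing the filter keep their variant call but gain a `no_coverage`
#' flag; downstream rate computation drops flagged rows.
#'
#' @param assignments assignment tibble.
#' @param index the [build_reference_index()] used for classification.
#' @inheritParams coverage_filter
#' @return assignment tibble with updated flags.
#' @export
apply_coverage_filter <- function(assignments, index,
                                  required_names = c("target_site",
                                                     "fusion_diagnostic"),
                                  mode = "contain") {
  if (nrow(assignments) == 0L) return(assignments)
  key <- paste(assignments$variant_id, assignments$state, sep = "|")
  idx_by_name <- setNames(seq_along(index$ids), index$ids)
  for (i in seq_len(nrow(assignments))) {
    if (is.na(assignments$variant_id[i])) next
    ref <- index$refs[[idx_by_name[[key[i]]]]]
    ok <- coverage_filter(assignments[i, ], ref, required_names, mode)
    if (!ok) {
      assignments$flags[i] <- paste(
        c(strsplit(assignments$flags[i], ",")[[1]], "no_coverage"),
        collapse = ",")
    }
  }
  assignments
}

# Rates ------------------------------------------------------------------

variant_key_fields <- function(variant_id) {
  # decompose "fusion_id|site_id" into the screen axes; fields that do not
  # apply come back NA
  parts <- strsplit(variant_id, "|", fixed = TRUE)
  fusion <- vapply(parts, `[`, character(1), 1)
  site <- vapply(parts, `[`, character(1), 2)
  mode <- dplyr::case_when(
    grepl("-ins\\d+-", fusion) ~ "INSERTIONAL",
    grepl("-N-L\\d+$", fusion) ~ "N_TERMINAL",
    grepl("-C-L\\d+$", fusion) ~ "C_TERMINAL",
    TRUE ~ NA_character_)
  lnum <- function(re) {
    m <- regmatches(fusion, regexpr(re, fusion, perl = TRUE))
    out <- rep(NA_integer_, length(fusion))
    out[regexpr(re, fusion, perl = TRUE) > 0] <-
      as.integer(gsub("\\D", "", m))
    out
  }
  linker_left <- ifelse(mode == "INSERTIONAL",
                        lnum("(?<=-L)\\d+(?=R)"), lnum("(?<=-L)\\d+$"))
  linker_right <- ifelse(mode == "INSERTIONAL", lnum("(?<=R)\\d+$"),
                         NA_integer_)
  spacing <- suppressWarnings(as.integer(
    sub("^[^-]+-(\\d+)-.*$", "\\1", site)))
  orientation <- ifelse(grepl("\\((A|B)\\)", site),
                        sub(".*\\((A|B)\\).*", "\\1", site), NA_character_)
  tibble(variant_id = variant_id, fusion_id = fusion, site_id = site,
         mode = mode, linker_left = as.integer(linker_left),
         linker_right = as.integer(linker_right),
         spacing = spacing, orientation = orientation)
}

#' Per-variant recombination rates from an assignment table
#'
#' Counts recombined and unrecombined reads per variant among assigned,
#' unflagged reads and computes rate = n_rec / (n_rec + n_unrec). Flagged
#' (ambiguous, no_coverage, low_quality) and unassigned reads contribute to
#' neither numerator nor denominator.
#'
#' @param assignments assignment tibble.
#' @return rate tibble with the decomposed variant key fields, n_rec,
#'   n_unrec, rate (NA when no state-determined reads).
#' @export
compute_rates <- function(assignments) {
  ok <- !is.na(assignments$variant_id) & assignments$flags == ""
  a <- assignments[ok, , drop = FALSE]
  if (nrow(a) == 0L) {
    return(mutate(variant_key_fields(character(0)),
                  n_rec = integer(0), n_unrec = integer(0),
                  rate = numeric(0)))
  }
  counts <- a %>%
    group_by(.data$variant_id) %>%
    summarise(n_rec = sum(.data$state == "REC"),
              n_unrec = sum(.data$state == "UNREC"), .groups = "drop")
  variant_key_fields(counts$variant_id) %>%
    mutate(n_rec = counts$n_rec, n_unrec = counts$n_unrec,
           rate = ifelse(.data$n_rec + .data$n_unrec > 0,
                         .data$n_rec / (.data$n_rec + .data$n_unrec),
                         NA_real_)) %>%
    arrange(.data$variant_id)
}

#' Recombination efficiency from band intensities
#'
#' The gel-based efficiency: recombined band intensity over the sum of
#' recombined and non-recombined intensities.
#'
#' @param rec_intensity,unrec_intensity non-negative numbers.
#' @return fraction in `[0,1]`, or `NA` when both intensities are zero.
#' @export
band_intensity_rate <- function(rec_intensity, unrec_intensity) {
  if (any(c(rec_intensity, unrec_intensity) < 0)) {
    stop("band intensities must be non-negative")
  }
  tot <- rec_intensity + unrec_intensity
  ifelse(tot > 0, rec_intensity / tot, NA_real_)
}

#' Raw recombined/non-recombined odds
#'
#' Companion output to [band_intensity_rate()]: the plain ratio rec/unrec.
#'
#' @inheritParams band_intensity_rate
#' @return non-negative number (Inf when unrec is zero and rec positive).
#' @export
recombination_odds <- function(rec_intensity, unrec_intensity) {
  if (any(c(rec_intensity, unrec_intensity) < 0)) {
    stop("band intensities must be non-negative")
  }
  ifelse(rec_intensity + unrec_intensity > 0,
         rec_intensity / unrec_intensity, NA_real_)
}

# Heat maps --------------------------------------------------------------

#' Screen heat map from rate records
#'
#' One heat map per orientation, rows = linker axis, columns = spacing.
#' `aggregation = "per_linker"` keeps the terminal-screen linker length as
#' the row axis; `"summed_left_right"` pools counts of all (L, R) insertional
#' linker pairs with equal L + R into one row and recomputes the rate from
#' the pooled counts. Count pooling conserves totals.
#'
#' @param rate_records output of [compute_rates()].
#' @param aggregation `"per_linker"` or `"summed_left_right"`.
#' @return tibble (orientation, linker, spacing, n_rec, n_unrec, rate) of
#'   class `screen_heatmap`; unobserved cells are absent (NA when pivoted
#'   with [heatmap_matrix()]).
#' @export
build_heatmap <- function(rate_records,
                          aggregation = c("per_linker",
                                          "summed_left_right")) {
  aggregation <- match.arg(aggregation)
  modes <- unique(rate_records$mode[!is.na(rate_records$mode)])
  if (aggregation == "summed_left_right") {
    if (!all(modes == "INSERTIONAL")) {
      stop("summed_left_right aggregation applies to insertional records")
    }
    rr <- mutate(rate_records, linker = .data$linker_left +
                   .data$linker_right)
  } else {
    if ("INSERTIONAL" %in% modes && length(modes) > 1L) {
      stop("mixed screen modes in rate records")
    }
    rr <- mutate(rate_records, linker = .data$linker_left)
  }
  out <- rr %>%
    filter(!is.na(.data$orientation)) %>%
    group_by(.data$orientation, .data$linker, .data$spacing) %>%
    summarise(n_rec = sum(.data$n_rec), n_unrec = sum(.data$n_unrec),
              .groups = "drop") %>%
    mutate(rate = ifelse(.data$n_rec + .data$n_unrec > 0,
                         .data$n_rec / (.data$n_rec + .data$n_unrec),
                         NA_real_)) %>%
    arrange(.data$orientation, .data$linker, .data$spacing)
  class(out) <- c("screen_heatmap", class(out))
  out
}

#' Pivot one orientation of a heat map to a rate matrix
#'
#' @param heatmap a [build_heatmap()] result.
#' @param orientation which orientation to pivot.
#' @param value `"rate"`, `"n_rec"` or `"n_unrec"`.
#' @return numeric matrix, rows = linker axis, columns = spacing; missing
#'   cells NA.
#' @export
heatmap_matrix <- function(heatmap, orientation, value = "rate") {
  h <- heatmap[heatmap$orientation == orientation, ]
  wide <- tidyr::pivot_wider(
    h[, c("linker", "spacing", value)],
    names_from = "spacing", values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$linker
  m[, order(as.integer(colnames(m))), drop = FALSE]
}

# Two-phase demultiplexing -----------------------------------------------

#' Two-phase demultiplexing of insertion-library screens
#'
#' Phase 1 assigns each read to one backbone reference (recombinase x
#' recombination state); ambiguous reads are dropped. Phase 2 re-classifies
#' each backbone's read subset against that backbone's insertion-variant
#' library to call the insertion position. Per-variant rates are the
#' fraction of recombined reads among state-determined reads of that
#' variant.
#'
#' @param reads read tibble.
#' @param backbone_refs named list of [reference_amplicon()]s covering every
#'   recombinase in both states (`variant_id` = recombinase id).
#' @param variant_libraries named list keyed by `recombinase|state`, each a
#'   named list of `reference_amplicon`s whose `variant_id` identifies the
#'   insertion variant.
#' @param min_margin,band passed to the classifier in both phases.
#' @return list with `phase1` (assignment tibble), `phase2` (assignment
#'   tibble with backbone columns), and `rates` (per insertion-variant rate
#'   tibble: recombinase, variant_id, n_rec, n_unrec, rate).
#' @export
two_phase_demultiplex <- function(reads, backbone_refs, variant_libraries,
                                  min_margin = 8, band = 100L) {
  states <- vapply(backbone_refs, function(r) r$state, character(1))
  recs <- vapply(backbone_refs, function(r) r$variant_id, character(1))
  if (!all(c("REC", "UNREC") %in% states)) {
    stop("backbone set must cover both recombination states")
  }
  for (r in unique(recs)) {
    if (!setequal(states[recs == r], c("REC", "UNREC"))) {
      stop(sprintf("backbone set for %s must cover both states", r))
    }
  }
  idx1 <- build_reference_index(backbone_refs)
  phase1 <- classify_reads(reads, idx1, min_margin = min_margin, band = band)
  assigned <- phase1[!is.na(phase1$variant_id) & phase1$flags == "", ]
  phase2 <- list()
  for (key in unique(paste(assigned$variant_id, assigned$state, sep = "|"))) {
    if (!key %in% names(variant_libraries)) {
      stop(sprintf("no variant library for backbone %s", key))
    }
    sub_ids <- assigned$read_id[paste(assigned$variant_id, assigned$state,
                                      sep = "|") == key]
    sub_reads <- reads[reads$id %in% sub_ids, , drop = FALSE]
    idx2 <- build_reference_index(variant_libraries[[key]])
    a2 <- classify_reads(sub_reads, idx2, min_margin = min_margin,
                         band = band)
    a2$backbone <- sub(paste0("\\|", "(REC|UNREC)$"), "", key)
    a2$backbone_state <- sub("^.*\\|", "", key)
    phase2[[key]] <- a2
  }
  phase2 <- bind_rows(phase2)
  ok <- phase2[!is.na(phase2$variant_id) & phase2$flags == "", ,
               drop = FALSE]
  rates <- ok %>%
    group_by(recombinase = .data$backbone, variant_id = .data$variant_id) %>%
    summarise(n_rec = sum(.data$backbone_state == "REC"),
              n_unrec = sum(.data$backbone_state == "UNREC"),
              .groups = "drop") %>%
    mutate(rate = ifelse(.data$n_rec + .data$n_unrec > 0,
                         .data$n_rec / (.data$n_rec + .data$n_unrec),
                         NA_real_)) %>%
    arrange(.data$recombinase, .data$variant_id)
  list(phase1 = phase1, phase2 = phase2, rates = rates)
}

# Run accounting ---------------------------------------------------------

#' Stage-count log for a screen quantification run
#'
#' Reconciles read counts across stages: total in, removed by quality,
#' unassigned/ambiguous, flagged by coverage, and state-determined. The
#' conservation identity `total = removed_quality + unassigned + flagged +
#' counted` always holds.
#'
#' @param n_total reads in.
#' @param reads_after_quality read tibble after [filter_reads_by_quality()].
#' @param assignments final assignment tibble (post coverage filter).
#' @return tibble of stage counts with attribute `conserved` (logical).
#' @export
run_log <- function(n_total, reads_after_quality, assignments) {
  n_q <- nrow(reads_after_quality)
  unassigned <- sum(is.na(assignments$variant_id))
  flagged <- sum(!is.na(assignments$variant_id) & assignments$flags != "")
  counted <- sum(!is.na(assignments$variant_id) & assignments$flags == "")
  out <- tibble(
    stage = c("input", "removed_low_quality", "unassigned_or_ambiguous",
              "flagged_no_coverage", "state_determined"),
    reads = c(n_total, n_total - n_q, unassigned, flagged, counted),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  attr(out, "conserved") <-
    (n_total - n_q) + unassigned + flagged + counted == n_total
  out
}
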