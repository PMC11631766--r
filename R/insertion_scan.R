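# Pentapeptide-insertion profiling: global affine-gap alignment of long
# reads to a wild-type ORF, extraction of fixed-length (15-nt) insertion
# events, left normalization, mapping to residue junctions, and per-junction
# frequency profiles.

#' Global affine-gap alignment (Gotoh)
#'
#' Optimal global alignment of `query` against `reference` under affine gap
#' scoring (a gap of length L costs `gap_open + L * gap_extend`). The
#' traceback uses a fixed tie-break (match/mismatch > deletion > insertion),
#' so CIGARs are deterministic. Defaults are long-read-ish: match +2,
#' mismatch -4, gap open -4, gap extend -2.
#'
#' @param query,reference nucleotide sequences (non-empty).
#' @param params list with match, mismatch, gap_open, gap_extend.
#' @param band optional band half-width around the length-difference
#'   diagonal; `NULL` (default) computes the full, exact DP.
#' @return object of class `affine_alignment`: `cigar` tibble (op in
#'   M/I/D, len), `score`, `params`, and query/reference lengths.
#' @export
global_align_affine <- function(query, reference,
                                params = default_align_params(),
                                band = NULL) {
  if (nchar(query) == 0L || nchar(reference) == 0L) {
    stop("empty sequence")
  }
  assert_dna(query, "query")
  assert_dna(reference, "reference")
  res <- .affine_align_cpp(toupper(query), toupper(reference),
                           params$match, params$mismatch,
                           params$gap_open, params$gap_extend,
                           if (is.null(band)) 0L else as.integer(band),
                           FALSE)
  cigar <- tibble(op = res$op, len = res$len)
  # internal consistency: the CIGAR must reconstruct both lengths
  stopifnot(sum(cigar$len[cigar$op != "D"]) == nchar(query),
            sum(cigar$len[cigar$op != "I"]) == nchar(reference))
  structure(list(cigar = cigar, score = res$score, params = params,
                 query_length = nchar(query),
                 reference_length = nchar(reference)),
            class = "affine_alignment")
}

#' @export
print.affine_alignment <- function(x, ...) {
  cat(sprintf("<affine_alignment score %.1f, cigar %s>\n", x$score,
              paste0(x$cigar$len, x$cigar$op, collapse = "")))
  invisible(x)
}

#' Extract fixed-length insertion events from an alignment
#'
#' Walks the CIGAR and reports insertion runs whose length is within
#' `length_tolerance` of `target_length` (default: exactly 15 nt, the
#' pentapeptide footprint). `ref_pos` is the 0-based reference coordinate
#' before which the insertion sits.
#'
#' @param alignment an [global_align_affine()] result.
#' @param query the query sequence the alignment was computed from (used to
#'   recover inserted sequences).
#' @param target_length expected insertion length (nt), default 15.
#' @param length_tolerance accepted deviation from `target_length`,
#'   default 0.
#' @return tibble of events: ref_pos, length, inserted_seq.
#' @export
extract_insertions <- function(alignment, query, target_length = 15L,
                               length_tolerance = 0L) {
  stopifnot(inherits(alignment, "affine_alignment"))
  cig <- alignment$cigar
  ref_pos <- 0L
  q_pos <- 0L
  out <- list()
  for (i in seq_len(nrow(cig))) {
    op <- cig$op[i]
    len <- cig$len[i]
    if (op == "I") {
      if (abs(len - target_length) <= length_tolerance) {
        out[[length(out) + 1L]] <- tibble(
          ref_pos = ref_pos, length = len,
          inserted_seq = substr(query, q_pos + 1L, q_pos + len))
      }
      q_pos <- q_pos + len
    } else if (op == "D") {
      ref_pos <- ref_pos + len
    } else {
      ref_pos <- ref_pos + len
      q_pos <- q_pos + len
    }
  }
  if (length(out) == 0L) {
    return(tibble(ref_pos = integer(), length = integer(),
                  inserted_seq = character()))
  }
  bind_rows(out)
}

#' Left-normalize an insertion event
#'
#' Insertions adjacent to repeats have alignment-ambiguous placement; this
#' shifts an event to its leftmost equivalent position (standard left
#' alignment: while the reference base before `ref_pos` equals the last base
#' of the insert, rotate the insert right and move one base left).
#' Idempotent; never changes event length.
#'
#' @param event one event row (ref_pos, length, inserted_seq).
#' @param reference the reference sequence.
#' @return the event with normalized ref_pos and rotated inserted_seq.
#' @export
left_align_insertion <- function(event, reference) {
  pos <- event$ref_pos[[1]]
  ins <- event$inserted_seq[[1]]
  if (pos < 0L || pos > nchar(reference)) stop("event outside reference")
  while (pos > 0L &&
         substr(reference, pos, pos) == substr(ins, nchar(ins), nchar(ins))) {
    ins <- paste0(substr(ins, nchar(ins), nchar(ins)),
                  substr(ins, 1L, nchar(ins) - 1L))
    pos <- pos - 1L
  }
  event$ref_pos <- pos
  event$inserted_seq <- ins
  event
}

#' Map a reference position to a residue junction
#'
#' Junction k means "between residues k and k+1" (after codon k); the 0-based
#' nucleotide position is rounded to the nearest codon boundary by default,
#' since sequencing errors can shift apparent insertion positions off frame.
#' `strict = TRUE` instead rejects off-frame positions with NA.
#'
#' @param ref_pos 0-based reference coordinate(s).
#' @param orf_start 0-based position of the first ORF base.
#' @param orf_length_codons ORF length in codons (for bounds checking),
#'   optional.
#' @param strict reject off-frame positions instead of rounding.
#' @return integer junction index (0 = before the first residue).
#' @export
position_to_junction <- function(ref_pos, orf_start = 0L,
                                 orf_length_codons = NULL, strict = FALSE) {
  if (any(ref_pos < orf_start)) stop("ref_pos before ORF start")
  off <- ref_pos - orf_start
  j <- ifelse(strict & off %% 3L != 0L, NA_integer_,
              as.integer(round(off / 3)))
  if (!is.null(orf_length_codons) &&
      any(j > orf_length_codons, na.rm = TRUE)) {
    stop("ref_pos beyond ORF end")
  }
  j
}

#' Per-junction insertion profile
#'
#' Counts accepted insertion events per residue junction and normalizes to
#' frequencies. By default all accepted events of a read are counted
#' (`events_per_read = "all"`); `"first"` keeps one event per read.
#'
#' @param events event tibble with columns read_id and junction.
#' @param orf_length_codons ORF length in codons; junctions run 0 ..
#'   `orf_length_codons`.
#' @param events_per_read `"all"` or `"first"`.
#' @return object of class `insertion_profile`: tibble (junction, count,
#'   frequency) over all junctions, plus totals as attributes. Frequencies
#'   are NA when no event was accepted.
#' @export
build_insertion_profile <- function(events, orf_length_codons,
                                    events_per_read = c("all", "first")) {
  events_per_read <- match.arg(events_per_read)
  if (nrow(events) > 0 &&
      (any(events$junction < 0L) ||
       any(events$junction > orf_length_codons))) {
    stop("junction out of range")
  }
  if (events_per_read == "first" && nrow(events) > 0) {
    events <- events %>%
      group_by(.data$read_id) %>%
      dplyr::slice(1L) %>%
      ungroup()
  }
  counts <- integer(orf_length_codons + 1L)
  if (nrow(events) > 0) {
    tab <- table(factor(events$junction, levels = 0:orf_length_codons))
    counts <- as.integer(tab)
  }
  total <- sum(counts)
  out <- tibble(junction = 0:orf_length_codons, count = counts,
                frequency = if (total > 0) counts / total
                            else rep(NA_real_, length(counts)))
  structure(out, class = c("insertion_profile", class(out)),
            n_events = total,
            n_reads = if (nrow(events)) length(unique(events$read_id))
                      else 0L)
}

#' Merge insertion profiles across libraries
#'
#' Pools per-junction counts (cumulative-frequency view across screens of
#' several recombinases) and renormalizes.
#'
#' @param ... `insertion_profile`s over the same junction range.
#' @return merged `insertion_profile`.
#' @export
merge_insertion_profiles <- function(...) {
  profs <- list(...)
  stopifnot(length(profs) >= 1L)
  junctions <- profs[[1]]$junction
  for (p in profs) stopifnot(identical(p$junction, junctions))
  counts <- Reduce(`+`, lapply(profs, function(p) p$count))
  total <- sum(counts)
  out <- tibble(junction = junctions, count = counts,
                frequency = if (total > 0) counts / total
                            else rep(NA_real_, length(counts)))
  structure(out, class = c("insertion_profile", class(out)),
            n_events = total,
            n_reads = sum(vapply(profs, function(p)
              attr(p, "n_reads"), integer(1))))
}

#' Top insertion-tolerant junctions
#'
#' @param profile an [build_insertion_profile()] result.
#' @param n how many junctions to report (default 5).
#' @return integer vector of junctions ordered by descending count, ties
#'   broken toward the lower junction index; only populated junctions are
#'   returned.
#' @export
top_positions <- function(profile, n = 5L) {
  pop <- profile[profile$count > 0L, ]
  ord <- order(-pop$count, pop$junction)
  head(pop$junction[ord], n)
}

#' Profile pentapeptide insertions from reads
#'
#' End-to-end profiling: orientation-normalize each read (best of forward
#' and reverse complement by alignment score), globally align to the
#' wild-type ORF reference, extract 15-nt insertion events, left-normalize,
#' map to residue junctions, and build the per-junction profile.
#'
#' @param reads read tibble (id, sequence).
#' @param reference wild-type reference sequence containing the ORF.
#' @param orf_start 0-based position of the first ORF base in `reference`.
#' @param orf_length_codons ORF length in codons.
#' @param target_length,length_tolerance insertion acceptance window
#'   (default exactly 15 nt).
#' @param params,band alignment options (see [global_align_affine()]).
#' @param events_per_read see [build_insertion_profile()].
#' @return list with `profile` (an `insertion_profile`) and `events`
#'   (per-read accepted event tibble).
#' @export
profile_insertions <- function(reads, reference, orf_start = 0L,
                               orf_length_codons =
                                 (nchar(reference) - orf_start) %/% 3L,
                               target_length = 15L, length_tolerance = 0L,
                               params = default_align_params(), band = NULL,
                               events_per_read = "all") {
  events <- list()
  for (i in seq_len(nrow(reads))) {
    s_fwd <- reads$sequence[i]
    s_rev <- revcomp(s_fwd)
    al_fwd <- global_align_affine(s_fwd, reference, params, band)
    al_rev <- global_align_affine(s_rev, reference, params, band)
    if (al_fwd$score >= al_rev$score) {
      al <- al_fwd; s <- s_fwd
    } else {
      al <- al_rev; s <- s_rev
    }
    ev <- extract_insertions(al, s, target_length, length_tolerance)
    if (nrow(ev) == 0L) next
    ev <- bind_rows(lapply(seq_len(nrow(ev)), function(k) {
      left_align_insertion(ev[k, ], reference)
    }))
    ev$read_id <- reads$id[i]
    events[[length(events) + 1L]] <- ev
  }
  events <- if (length(events)) bind_rows(events) else
    tibble(ref_pos = integer(), length = integer(),
           inserted_seq = character(), read_id = character())
  if (nrow(events) > 0) {
    events$junction <- position_to_junction(
      pmin(events$ref_pos, orf_start + 3L * orf_length_codons),
      orf_start, orf_length_codons)
  } else {
    events$junction <- integer(0)
  }
  profile <- build_insertion_profile(events, orf_length_codons,
                                     events_per_read)
  list(profile = profile, events = events)
}
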