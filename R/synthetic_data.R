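# Synthetic inputs with known ground truth: noisy long reads from reference
# mixtures at set recombination rates, pentapeptide-insertion read
# libraries, and genomes with planted lox-like sites plus flanking ZF
# motifs.
#
# Determinism contract: every generator takes a single integer seed; each
# read's randomness comes from a counter-derived substream so read order
# never changes results.

#' Sequencing error model
#'
#' Per-base i.i.d. substitution/insertion/deletion rates emulating long-read
#' (nanopore-like) noise. Indels are single-base events.
#'
#' @param substitution_rate,insertion_rate,deletion_rate probabilities in
#'   `[0, 1)`.
#' @return object of class `error_model`.
#' @export
error_model <- function(substitution_rate = 0.03, insertion_rate = 0.005,
                        deletion_rate = 0.005) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  if (any(rates < 0) || any(rates >= 1)) stop("rates must be in [0, 1)")
  structure(list(substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate),
            class = "error_model")
}

# counter-mode substream: a per-read seed derived from run seed + counter,
# kept below 2^31
substream_seed <- function(seed, counter) {
  (as.double(seed) * 48271 + as.double(counter) * 16807) %% 2147483587 + 1
}

with_substream <- function(seed, counter, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(substream_seed(seed, counter))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

#' Apply sequencing errors to a sequence
#'
#' Per-base: deletion with the model's deletion rate, substitution (to a
#' uniformly drawn different base) with the substitution rate, and an
#' insertion of one uniform base after the position with the insertion
#' rate. Deterministic given `seed` and `counter`.
#'
#' @param sequence template sequence.
#' @param model an [error_model()].
#' @param seed run seed.
#' @param counter per-read counter (substream selector), default 0.
#' @return mutated sequence (character scalar).
#' @export
mutate_sequence <- function(sequence, model, seed = 1L, counter = 0L) {
  stopifnot(inherits(model, "error_model"))
  n <- nchar(sequence)
  if (n == 0L) return(sequence)
  if (model$substitution_rate == 0 && model$insertion_rate == 0 &&
      model$deletion_rate == 0) {
    return(sequence)
  }
  with_substream(seed, counter, {
    bases <- strsplit(sequence, "")[[1]]
    del <- runif(n) < model$deletion_rate
    sub <- runif(n) < model$substitution_rate
    ins <- runif(n) < model$insertion_rate
    if (any(sub)) {
      k <- sum(sub)
      cur <- match(bases[sub], DNA_BASES)
      # uniform over the three other bases
      shift <- sample.int(3L, k, replace = TRUE)
      bases[sub] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
    ins_base <- character(n)
    if (any(ins)) {
      ins_base[ins] <- DNA_BASES[sample.int(4L, sum(ins), replace = TRUE)]
    }
    out <- paste0(ifelse(del, "", bases), ins_base, collapse = "")
    out
  })
}

# constant per-read Phred drawn from a truncated normal so that the Q>=10
# filter has both outcomes
draw_read_quality <- function(n_bases, mean_q = 12, sd_q = 3) {
  q <- round(rnorm(1, mean_q, sd_q))
  q <- max(2L, min(40L, as.integer(q)))
  rep.int(q, n_bases)
}

#' Simulate screen reads at known recombination rates
#'
#' For each variant in `truth`, draws each read from the recombined
#' reference with probability equal to the variant's true rate (otherwise
#' the unrecombined reference), applies the error model, and attaches a
#' constant per-read Phred quality drawn from N(`mean_q`, `sd_q`) so the
#' quality filter is exercisable.
#'
#' @param refs named list of [reference_amplicon()]s (names
#'   `variant_id|state`) covering both states of every truth variant.
#' @param truth tibble with columns variant_id, rate, n_reads.
#' @param model an [error_model()].
#' @param seed run seed.
#' @param mean_q,sd_q per-read quality distribution (defaults 12 and 3).
#' @return list with `reads` (read tibble) and `truth` (per-read truth
#'   tibble: read_id, variant_id, state).
#' @export
simulate_screen_reads <- function(refs, truth, model = error_model(),
                                  seed = 1L, mean_q = 12, sd_q = 3) {
  stopifnot(all(c("variant_id", "rate", "n_reads") %in% names(truth)))
  stopifnot(all(truth$rate >= 0 & truth$rate <= 1), all(truth$n_reads > 0))
  for (v in truth$variant_id) {
    if (!all(paste(v, c("REC", "UNREC"), sep = "|") %in% names(refs))) {
      stop(sprintf("truth variant %s lacks REC/UNREC references", v))
    }
  }
  reads <- list()
  tt <- list()
  counter <- 0L
  for (i in seq_len(nrow(truth))) {
    v <- truth$variant_id[i]
    for (r in seq_len(truth$n_reads[i])) {
      counter <- counter + 1L
      st <- with_substream(seed, counter,
                           if (runif(1) < truth$rate[i]) "REC" else "UNREC")
      template <- refs[[paste(v, st, sep = "|")]]$sequence
      s <- mutate_sequence(template, model, seed, counter + 500000L)
      q <- with_substream(seed, counter + 1000000L,
                          draw_read_quality(nchar(s), mean_q, sd_q))
      id <- sprintf("read_%06d", counter)
      reads[[counter]] <- tibble(id = id, sequence = s,
                                 qualities = list(q))
      tt[[counter]] <- tibble(read_id = id, variant_id = v, state = st)
    }
  }
  list(reads = bind_rows(reads), truth = bind_rows(tt))
}

#' Simulate pentapeptide-insertion reads
#'
#' Each read is the wild-type ORF (with optional flanks) carrying one 15-nt
#' in-frame insertion at a junction sampled from `junction_distribution`,
#' then run through the error model. With `duplication = TRUE` the insert
#' emulates Mu-transposition chemistry: a 10-nt core plus a duplication of
#' the 5 reference bases preceding the junction; such inserts are inherently
#' placement-ambiguous (the duplication lets the event slide), so
#' left-normalized positions sit up to 5 nt left of the nominal junction.
#' Without duplication the drawn insert's boundary bases are adjusted so
#' they differ from the flanking reference bases, which pins the alignment
#' placement to the planted junction.
#'
#' @param reference wild-type sequence containing the ORF.
#' @param orf_start 0-based ORF start within `reference`.
#' @param junction_distribution tibble with columns junction, prob (summing
#'   to 1).
#' @param n_reads number of reads.
#' @param model an [error_model()].
#' @param duplication emulate the 5-bp target-site duplication.
#' @param seed run seed.
#' @return list with `reads` (read tibble, constant Q20 qualities) and
#'   `truth` (read_id, junction).
#' @export
simulate_insertion_reads <- function(reference, orf_start = 0L,
                                     junction_distribution, n_reads,
                                     model = error_model(),
                                     duplication = FALSE, seed = 1L) {
  jd <- junction_distribution
  stopifnot(all(c("junction", "prob") %in% names(jd)),
            abs(sum(jd$prob) - 1) < 1e-9)
  max_j <- (nchar(reference) - orf_start) %/% 3L
  if (any(jd$junction < 0L | jd$junction > max_j)) {
    stop("junction out of range")
  }
  ins_core <- "GGTTCAGGAT"  # fixed 10-nt transposon-derived core
  reads <- list()
  tt <- list()
  for (i in seq_len(n_reads)) {
    j <- with_substream(seed, i,
                        jd$junction[sample.int(nrow(jd), 1L,
                                               prob = jd$prob)])
    cut <- orf_start + 3L * j
    insert <- if (duplication) {
      dup <- substr(reference, cut - 4L, cut)
      if (nchar(dup) < 5L) dup <- pad_seq(5L)  # junction too close to start
      paste0(ins_core, dup)
    } else {
      with_substream(seed, i + 2000000L, {
        ins <- DNA_BASES[sample.int(4L, 15L, replace = TRUE)]
        # pin placement: boundary bases must differ from the flanking
        # reference bases or the insertion could slide
        left_ref <- substr(reference, cut, cut)
        right_ref <- substr(reference, cut + 1L, cut + 1L)
        if (nchar(left_ref) && ins[15] == left_ref) {
          ins[15] <- sample(setdiff(DNA_BASES, left_ref), 1L)
        }
        if (nchar(right_ref) && ins[1] == right_ref) {
          ins[1] <- sample(setdiff(DNA_BASES, right_ref), 1L)
        }
        paste0(ins, collapse = "")
      })
    }
    s0 <- paste0(substr(reference, 1L, cut), insert,
                 substr(reference, cut + 1L, nchar(reference)))
    s <- mutate_sequence(s0, model, seed, i + 4000000L)
    id <- sprintf("insread_%06d", i)
    reads[[i]] <- tibble(id = id, sequence = s,
                         qualities = list(rep.int(20L, nchar(s))))
    tt[[i]] <- tibble(read_id = id, junction = j)
  }
  list(reads = bind_rows(reads), truth = bind_rows(tt))
}

#' Random background sequence
#'
#' @param length sequence length.
#' @param composition base probabilities (A,C,G,T), default uniform.
#' @param seed,counter substream selectors.
#' @return character scalar.
#' @export
random_genome <- function(length, composition = rep(0.25, 4), seed = 1L,
                          counter = 0L) {
  stopifnot(abs(sum(composition) - 1) < 1e-9)
  with_substream(seed, counter, paste0(
    sample(DNA_BASES, length, replace = TRUE, prob = composition),
    collapse = ""))
}

#' Plant lox+flank composite sites in a random genome
#'
#' Generates a random background and overwrites it at recorded, non
#' overlapping coordinates with planted composites: reverse-strand upstream
#' ZF motif, gap, lox site, gap, forward-strand downstream ZF motif (per
#' plant, each flank optional). Gaps and coordinates come from the plant
#' table; the truth is returned as a 0-based half-open BED-style tibble.
#'
#' @param length genome length.
#' @param plants tibble with columns: lox_seq, up_motif (or NA), up_gap,
#'   down_motif (or NA), down_gap, and optionally start (0-based position of
#'   the full planted block; sampled non-overlapping when absent).
#' @param composition background base probabilities.
#' @param seed run seed.
#' @return list with `sequence` and `truth` (tibble: name, block_start,
#'   block_end, lox_start, lox_end, up_motif_start, down_motif_start, ...).
#' @export
plant_genome <- function(length, plants, composition = rep(0.25, 4),
                         seed = 1L) {
  g <- strsplit(random_genome(length, composition, seed, 0L), "")[[1]]
  block_len <- function(p) {
    up <- if (is.na(p$up_motif)) 0L else nchar(p$up_motif) + p$up_gap
    dn <- if (is.na(p$down_motif)) 0L else nchar(p$down_motif) + p$down_gap
    up + nchar(p$lox_seq) + dn
  }
  lens <- vapply(seq_len(nrow(plants)), function(i)
    as.integer(block_len(plants[i, ])), integer(1))
  if (!"start" %in% names(plants)) {
    # deterministic spread: equal slots with a jitter-free left placement
    slot <- length %/% (nrow(plants) + 1L)
    if (any(lens >= slot)) stop("plants do not fit without overlap")
    plants$start <- as.integer(slot * seq_len(nrow(plants)) - lens %/% 2L)
  }
  ends <- plants$start + lens
  ord <- order(plants$start)
  if (any(plants$start[ord][-1] < ends[ord][-nrow(plants)]) ||
      any(plants$start < 0L) || any(ends > length)) {
    stop("plants overlap or fall outside the genome")
  }
  truth <- list()
  for (i in seq_len(nrow(plants))) {
    p <- plants[i, ]
    pos <- p$start
    up_start <- NA_integer_
    if (!is.na(p$up_motif)) {
      up <- revcomp(p$up_motif)  # motif is read on the reverse strand
      substr_replace <- strsplit(up, "")[[1]]
      g[(pos + 1):(pos + nchar(up))] <- substr_replace
      up_start <- pos
      pos <- pos + nchar(up) + p$up_gap
    }
    lox_start <- pos
    g[(pos + 1):(pos + nchar(p$lox_seq))] <- strsplit(p$lox_seq, "")[[1]]
    pos <- pos + nchar(p$lox_seq)
    down_start <- NA_integer_
    if (!is.na(p$down_motif)) {
      pos <- pos + p$down_gap
      g[(pos + 1):(pos + nchar(p$down_motif))] <-
        strsplit(p$down_motif, "")[[1]]
      down_start <- pos
      pos <- pos + nchar(p$down_motif)
    }
    truth[[i]] <- tibble(
      name = sprintf("plant_%02d", i),
      block_start = as.integer(p$start), block_end = as.integer(ends[i]),
      lox_start = as.integer(lox_start),
      lox_end = as.integer(lox_start + nchar(p$lox_seq)),
      up_motif_start = up_start,
      up_gap = if (is.na(p$up_motif)) NA_integer_
               else as.integer(p$up_gap),
      down_motif_start = down_start,
      down_gap = if (is.na(p$down_motif)) NA_integer_
                 else as.integer(p$down_gap))
  }
  list(sequence = paste0(g, collapse = ""), truth = bind_rows(truth))
}
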