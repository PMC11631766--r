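# Position probability / weight matrices, exact p-values, FIMO-style
# scanning, composite lox-site search, flank-constrained ZF off-target
# search, and per-position mutation tallies of evolved clones.

# PPM / PWM --------------------------------------------------------------

#' Position probability matrix from aligned sites
#'
#' Column j, base b: (count + pseudocount) / (n + 4 * pseudocount).
#'
#' @param aligned_sequences character vector of equal-length ACGT sequences.
#' @param pseudocount per-base pseudocount (default 0.1, suited to matrices
#'   built from a handful of sites).
#' @return object of class `ppm`: 4 x width probability matrix (rows
#'   A/C/G/T) with `pseudocount` and `n_sequences` attributes.
#' @export
build_ppm <- function(aligned_sequences, pseudocount = 0.1) {
  widths <- nchar(aligned_sequences)
  if (length(unique(widths)) != 1L) stop("ragged input: unequal widths")
  assert_dna(aligned_sequences, "aligned site")
  w <- widths[1]
  n <- length(aligned_sequences)
  mat <- matrix(0, nrow = 4, ncol = w, dimnames = list(DNA_BASES, NULL))
  chars <- do.call(rbind, strsplit(toupper(aligned_sequences), ""))
  for (j in seq_len(w)) {
    tab <- table(factor(chars[, j], levels = DNA_BASES))
    mat[, j] <- (as.numeric(tab) + pseudocount) / (n + 4 * pseudocount)
  }
  stopifnot(all(abs(colSums(mat) - 1) < 1e-9))
  structure(mat, class = "ppm", pseudocount = pseudocount, n_sequences = n)
}

#' Log-odds position weight matrix from a PPM
#'
#' value = log2(p / background); `min_score`/`max_score` are the column-wise
#' minima/maxima sums.
#'
#' @param ppm a [build_ppm()] result (or plain 4 x w probability matrix with
#'   rows A/C/G/T).
#' @param background base probabilities (A,C,G,T), strictly positive,
#'   summing to 1; default uniform.
#' @return object of class `pwm`: 4 x width log-odds matrix with
#'   `background`, `min_score`, `max_score` attributes.
#' @export
ppm_to_pwm <- function(ppm, background = rep(0.25, 4)) {
  stopifnot(length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-9)
  p <- unclass(ppm)
  if (any(p == 0)) {
    stop("zero probabilities in PPM; rebuild with a positive pseudocount")
  }
  lo <- log2(p / background)
  structure(lo, class = "pwm", background = background,
            min_score = sum(apply(lo, 2, min)),
            max_score = sum(apply(lo, 2, max)))
}

#' Score one word with a PWM
#'
#' @param pwm a [ppm_to_pwm()] result.
#' @param word ACGT string of the PWM's width.
#' @return log-odds score.
#' @export
pwm_score <- function(pwm, word) {
  w <- ncol(pwm)
  stopifnot(nchar(word) == w)
  idx <- match(strsplit(toupper(word), "")[[1]], DNA_BASES)
  if (anyNA(idx)) stop("non-ACGT characters in word")
  sum(unclass(pwm)[cbind(idx, seq_len(w))])
}

# Exact p-values ---------------------------------------------------------

# Discretized distribution of PWM scores under the background model:
# convolution over positions of the per-position score distributions on an
# integer grid of width `bin_width`. Returns the support (score bins) and
# the survival function P(S >= bin).
pwm_score_distribution <- function(pwm, bin_width = 0.001) {
  if (bin_width <= 0) stop("invalid bin width")
  bg <- attr(pwm, "background")
  m <- unclass(pwm)
  w <- ncol(m)
  # integer offsets per cell, floored so that DP p-values upper-bound exact
  # ones by at most w * bin_width in score
  mi <- matrix(as.integer(floor(m / bin_width + 0.5)), nrow = 4)
  lo <- sum(apply(mi, 2, min))
  hi <- sum(apply(mi, 2, max))
  probs <- numeric(hi - lo + 1L)
  # DP over positions
  cur_lo <- 0L
  probs[1] <- 1
  cur <- 1
  dist <- c(1)
  for (j in seq_len(w)) {
    col <- mi[, j]
    new_lo <- cur_lo + min(col)
    new_hi <- cur_lo + length(dist) - 1L + max(col)
    newdist <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      off <- cur_lo + col[b] - new_lo
      idx <- seq_along(dist) + off
      newdist[idx] <- newdist[idx] + dist * bg[b]
    }
    dist <- newdist
    cur_lo <- new_lo
  }
  sf <- rev(cumsum(rev(dist)))
  list(bins = (cur_lo:(cur_lo + length(dist) - 1L)), sf = sf,
       bin_width = bin_width,
       error_bound = w * bin_width)
}

#' Exact PWM p-value by dynamic programming
#'
#' P(score >= s) for a random word drawn from the PWM's background model,
#' computed by convolving the discretized per-position score distributions.
#' Monotone non-increasing in `s`; p(min_score) = 1. The discretization
#' error bound (width x bin_width in score units) is attached as an
#' attribute.
#'
#' @param pwm a [ppm_to_pwm()] result.
#' @param score score(s) at which to evaluate the survival function.
#' @param bin_width score discretization (default 0.001 score units).
#' @return p-value(s) in (0, 1].
#' @export
pwm_pvalue <- function(pwm, score, bin_width = 0.001) {
  d <- pwm_score_distribution(pwm, bin_width)
  q <- as.integer(floor(score / bin_width + 0.5))
  cont_min <- attr(pwm, "min_score")
  p <- vapply(seq_along(q), function(k) {
    # every word scores at least the continuous minimum, whatever the
    # per-cell rounding did
    if (!is.null(cont_min) && score[k] <= cont_min + 1e-12) return(1.0)
    qi <- q[k]
    if (qi <= d$bins[1]) return(1.0)
    if (qi > d$bins[length(d$bins)]) return(0.0)
    d$sf[qi - d$bins[1] + 1L]
  }, numeric(1))
  attr(p, "error_bound") <- d$error_bound
  p
}

# score threshold achieving p <= p_threshold (smallest such score bin)
pwm_score_threshold <- function(pwm, p_threshold, bin_width = 0.001) {
  d <- pwm_score_distribution(pwm, bin_width)
  ok <- which(d$sf <= p_threshold)
  if (length(ok) == 0L) return(Inf)  # no word passes
  d$bins[ok[1]] * bin_width
}

# Scanning ---------------------------------------------------------------
#
# Scanning scores words on the same integer grid the p-value DP uses (the
# PWM cells snapped to bin_width), so reported p-values, thresholds and hit
# counts are exactly self-consistent.

pwm_int_matrix <- function(pwm, bin_width) {
  matrix(as.integer(floor(unclass(pwm) / bin_width + 0.5)), nrow = 4,
         dimnames = dimnames(unclass(pwm)))
}

# integer windowed scores along the forward strand; windows containing
# non-ACGT bases come back NA
pwm_window_scores_int <- function(mi, sequence) {
  w <- ncol(mi)
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < w) return(numeric(0))
  code <- match(strsplit(s, "")[[1]], DNA_BASES)
  scores <- numeric(n - w + 1L)
  for (j in seq_len(w)) {
    cj <- code[j:(j + n - w)]
    scores <- scores + mi[cbind(cj, j)]
  }
  scores  # NA propagates from non-ACGT positions
}

# continuous windowed scores (same loop over the raw log-odds cells)
pwm_window_scores <- function(pwm, sequence) {
  pwm_window_scores_int(unclass(pwm), sequence)
}

# survival-function lookup on the integer grid
sf_lookup <- function(d, S) {
  ifelse(S <= d$bins[1], 1,
         ifelse(S > d$bins[length(d$bins)], 0,
                d$sf[pmax(pmin(S - d$bins[1] + 1L, length(d$sf)), 1L)]))
}

# smallest integer grid score with p <= threshold (Inf if none)
threshold_bin <- function(d, p_threshold) {
  ok <- which(d$sf <= p_threshold)
  if (length(ok) == 0L) Inf else d$bins[ok[1]]
}

#' Scan a sequence for PWM occurrences
#'
#' FIMO-style scan: windows on the requested strands whose exact p-value is
#' at or below `p_threshold` are reported. Coordinates are 0-based on the
#' forward strand regardless of hit strand; windows containing non-ACGT
#' bases are skipped.
#'
#' @param pwm a [ppm_to_pwm()] result.
#' @param sequence subject sequence (length >= PWM width).
#' @param p_threshold report hits with p-value <= this (default 0.001).
#' @param strand_mode `"both"` (default), `"forward"`, or `"reverse"`.
#' @param bin_width p-value discretization.
#' @param seq_id identifier recorded on hits.
#' @return tibble of hits: seq_id, start, strand, score, p_value.
#' @export
scan_sequence <- function(pwm, sequence, p_threshold = 0.001,
                          strand_mode = c("both", "forward", "reverse"),
                          bin_width = 0.001, seq_id = "seq") {
  strand_mode <- match.arg(strand_mode)
  w <- ncol(pwm)
  if (nchar(sequence) < w) stop("sequence shorter than PWM width")
  d <- pwm_score_distribution(pwm, bin_width)
  mi <- pwm_int_matrix(pwm, bin_width)
  thr <- threshold_bin(d, p_threshold)
  hits <- list()
  emit <- function(scores, strand) {
    pass <- which(!is.na(scores) & scores >= thr)
    if (length(pass) == 0L) return(NULL)
    starts <- if (strand == "+") pass - 1L
              else nchar(sequence) - (pass - 1L) - w
    tibble(seq_id = seq_id, start = as.integer(starts), strand = strand,
           score = scores[pass] * bin_width,
           p_value = sf_lookup(d, scores[pass]))
  }
  if (strand_mode %in% c("both", "forward")) {
    hits[["+"]] <- emit(pwm_window_scores_int(mi, sequence), "+")
  }
  if (strand_mode %in% c("both", "reverse")) {
    hits[["-"]] <- emit(pwm_window_scores_int(mi, revcomp(sequence)), "-")
  }
  out <- bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble(seq_id = character(), start = integer(),
                  strand = character(), score = numeric(),
                  p_value = numeric()))
  }
  arrange(out, .data$start, .data$strand)
}

#' Composite lox-site scan with half-site matrices
#'
#' A composite match is a left-half window, a fixed-length unscored spacer,
#' and a right-half window; the composite score is the sum of the half
#' scores and each half must independently pass `p_threshold` (conservative
#' AND combination). Both strands are scanned; a minus-strand composite is
#' the reverse complement arrangement. For a full-width single-matrix search
#' use [scan_sequence()] directly.
#'
#' @param left_ppm,right_ppm half-site PPMs ([build_ppm()]).
#' @param spacer_length unscored gap between the halves (default 8).
#' @param sequence subject sequence.
#' @param p_threshold per-half p-value threshold (default 0.001).
#' @param background,bin_width passed to the PWM transform / p-values.
#' @param seq_id identifier recorded on hits.
#' @return tibble of composite hits: seq_id, start, strand, score,
#'   left_p, right_p, width, plus half boundary columns (left_start,
#'   left_end, right_start, right_end; forward-strand coordinates).
#' @export
scan_lox_candidates <- function(left_ppm, right_ppm, spacer_length = 8L,
                                sequence, p_threshold = 0.001,
                                background = rep(0.25, 4),
                                bin_width = 0.001, seq_id = "seq") {
  if (spacer_length < 0L) stop("spacer_length must be >= 0")
  lpwm <- ppm_to_pwm(left_ppm, background)
  rpwm <- ppm_to_pwm(right_ppm, background)
  lw <- ncol(lpwm); rw <- ncol(rpwm)
  width <- lw + spacer_length + rw
  n <- nchar(sequence)
  if (n < width) stop("sequence shorter than composite width")
  ld <- pwm_score_distribution(lpwm, bin_width)
  rd <- pwm_score_distribution(rpwm, bin_width)
  lmi <- pwm_int_matrix(lpwm, bin_width)
  rmi <- pwm_int_matrix(rpwm, bin_width)
  lthr <- threshold_bin(ld, p_threshold)
  rthr <- threshold_bin(rd, p_threshold)

  scan_one_strand <- function(s, strand) {
    ls <- pwm_window_scores_int(lmi, s)
    rs <- pwm_window_scores_int(rmi, s)
    # left half at i (0-based), right half at i + lw + spacer
    starts <- 0:(n - width)
    li <- starts + 1L
    ri <- starts + lw + spacer_length + 1L
    pass <- which(!is.na(ls[li]) & !is.na(rs[ri]) &
                    ls[li] >= lthr & rs[ri] >= rthr)
    if (length(pass) == 0L) return(NULL)
    st <- starts[pass]
    on_plus <- strand == "+"
    fwd_start <- if (on_plus) st else n - st - width
    tibble(seq_id = seq_id, start = as.integer(fwd_start), strand = strand,
           score = (ls[li[pass]] + rs[ri[pass]]) * bin_width,
           left_p = sf_lookup(ld, ls[li[pass]]),
           right_p = sf_lookup(rd, rs[ri[pass]]),
           width = width,
           left_start = as.integer(if (on_plus) st else n - (st + lw)),
           left_end = as.integer(if (on_plus) st + lw else n - st),
           right_start = as.integer(if (on_plus) st + lw + spacer_length
                                    else n - (st + width)),
           right_end = as.integer(if (on_plus) st + width
                                  else n - (st + lw + spacer_length)))
  }
  out <- bind_rows(scan_one_strand(sequence, "+"),
                   scan_one_strand(revcomp(sequence), "-"))
  if (nrow(out) == 0L) {
    return(tibble(seq_id = character(), start = integer(),
                  strand = character(), score = numeric(),
                  left_p = numeric(), right_p = numeric(),
                  width = integer(), left_start = integer(),
                  left_end = integer(), right_start = integer(),
                  right_end = integer()))
  }
  arrange(out, .data$start, .data$strand)
}

#' Flank-constrained ZF-motif scan around lox hits
#'
#' For each lox hit, searches the upstream flank for `zf_pwm_upstream` on
#' the reverse strand and the downstream flank for `zf_pwm_downstream` on
#' the forward strand (the strand convention of designed flanking ZFDs),
#' with the gap between the outer edge of the lox site and the near edge of
#' the motif within `distance_range` (inclusive; default 4-6 bp). For
#' minus-strand lox hits the flank roles and strands are mirrored.
#'
#' @param lox_hits tibble from [scan_lox_candidates()] (needs start, strand,
#'   width columns), or any tibble with those columns.
#' @param zf_pwm_upstream,zf_pwm_downstream ZF motif PWMs
#'   ([ppm_to_pwm()]).
#' @param sequence subject sequence the hits refer to.
#' @param distance_range inclusive bp gap range, default `c(4, 6)`.
#' @param p_threshold motif p-value threshold (default 0.001).
#' @param bin_width p-value discretization.
#' @return tibble of composite hits: one row per lox hit with at least one
#'   passing flank; columns lox_start, lox_strand, sides (both/left/right
#'   in site-local orientation: left = upstream flank present, right =
#'   downstream), left/right motif start, strand, score, p, distance.
#' @export
flank_constrained_scan <- function(lox_hits, zf_pwm_upstream,
                                   zf_pwm_downstream, sequence,
                                   distance_range = c(4L, 6L),
                                   p_threshold = 0.001, bin_width = 0.001) {
  if (distance_range[1] > distance_range[2]) {
    stop("distance_range inverted")
  }
  n <- nchar(sequence)
  out <- list()
  for (i in seq_len(nrow(lox_hits))) {
    h <- lox_hits[i, ]
    # forward-strand extent of the lox composite
    s0 <- h$start
    e0 <- h$start + h$width
    # search one genomic flank; want_strand is the genomic strand the motif
    # must lie on ("-" for the genomic-left flank, "+" for the right)
    find_flank <- function(pwm, want_strand, genomic_side) {
      w <- ncol(pwm)
      d <- pwm_score_distribution(pwm, bin_width)
      mi <- pwm_int_matrix(pwm, bin_width)
      best <- NULL
      for (gap in distance_range[1]:distance_range[2]) {
        st <- if (genomic_side == "left") s0 - gap - w else e0 + gap
        if (st < 0L || st + w > n) next
        word <- substr(sequence, st + 1L, st + w)
        if (grepl("[^ACGT]", word)) next
        word_eff <- if (want_strand == "-") revcomp(word) else word
        idx <- match(strsplit(word_eff, "")[[1]], DNA_BASES)
        si <- sum(mi[cbind(idx, seq_len(w))])
        p <- sf_lookup(d, si)
        sc <- si * bin_width
        if (p <= p_threshold && (is.null(best) || sc > best$score)) {
          best <- tibble(start = as.integer(st), strand = want_strand,
                         score = sc, p = p, distance = as.integer(gap))
        }
      }
      best
    }
    # in site-local orientation the upstream motif sits on the site-reverse
    # strand off the left half, the downstream motif on the site-forward
    # strand off the right half; for a minus-strand lox hit both roles
    # mirror onto the forward-strand coordinates
    if (h$strand == "+") {
      left <- find_flank(zf_pwm_upstream, "-", "left")      # upstream
      right <- find_flank(zf_pwm_downstream, "+", "right")  # downstream
    } else {
      left <- find_flank(zf_pwm_upstream, "+", "right")     # upstream
      right <- find_flank(zf_pwm_downstream, "-", "left")   # downstream
    }
    if (is.null(left) && is.null(right)) next
    sides <- if (!is.null(left) && !is.null(right)) "both"
             else if (!is.null(left)) "left" else "right"
    out[[length(out) + 1L]] <- tibble(
      seq_id = if ("seq_id" %in% names(h)) h$seq_id else "seq",
      lox_start = as.integer(s0), lox_strand = h$strand, sides = sides,
      left_motif_start = if (is.null(left)) NA_integer_ else left$start,
      left_motif_strand = if (is.null(left)) NA_character_ else left$strand,
      left_motif_score = if (is.null(left)) NA_real_ else left$score,
      left_motif_p = if (is.null(left)) NA_real_ else left$p,
      left_distance = if (is.null(left)) NA_integer_ else left$distance,
      right_motif_start = if (is.null(right)) NA_integer_ else right$start,
      right_motif_strand = if (is.null(right)) NA_character_
                           else right$strand,
      right_motif_score = if (is.null(right)) NA_real_ else right$score,
      right_motif_p = if (is.null(right)) NA_real_ else right$p,
      right_distance = if (is.null(right)) NA_integer_ else right$distance)
  }
  if (length(out) == 0L) {
    return(tibble(seq_id = character(), lox_start = integer(),
                  lox_strand = character(), sides = character(),
                  left_motif_start = integer(),
                  left_motif_strand = character(),
                  left_motif_score = numeric(), left_motif_p = numeric(),
                  left_distance = integer(),
                  right_motif_start = integer(),
                  right_motif_strand = character(),
                  right_motif_score = numeric(), right_motif_p = numeric(),
                  right_distance = integer()))
  }
  bind_rows(out)
}

# Clone mutation tallies -------------------------------------------------

#' Per-position mutation tally of evolved clones
#'
#' Compares equal-length (indel-free) clone protein sequences to the
#' designed reference and reports, per position, how many clones differ and
#' how many distinct non-reference residues were observed. Clones whose
#' length differs from the reference are rejected with a warning.
#'
#' @param clone_sequences character vector of clone protein sequences.
#' @param reference_sequence the designed reference protein sequence.
#' @return tibble: position (1-based), reference residue, n_mutated,
#'   frequency, distinct_residues, residues (comma-joined set).
#' @export
tally_clone_mutations <- function(clone_sequences, reference_sequence) {
  len <- nchar(reference_sequence)
  ok <- nchar(clone_sequences) == len
  if (!all(ok)) {
    warning(sprintf("%d clone(s) rejected: length differs from reference",
                    sum(!ok)))
    clone_sequences <- clone_sequences[ok]
  }
  if (length(clone_sequences) == 0L) stop("no length-matched clones")
  refc <- strsplit(reference_sequence, "")[[1]]
  mat <- do.call(rbind, strsplit(clone_sequences, ""))
  n <- nrow(mat)
  res <- lapply(seq_len(len), function(j) {
    diffs <- mat[, j][mat[, j] != refc[j]]
    tibble(position = j, reference = refc[j],
           n_mutated = length(diffs),
           frequency = length(diffs) / n,
           distinct_residues = length(unique(diffs)),
           residues = paste(sort(unique(diffs)), collapse = ","))
  })
  bind_rows(res)
}
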