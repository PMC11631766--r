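# File formats and configuration: FASTA/FASTQ via Biostrings, BED and TSV
# writers, MEME minimal motif text, YAML screen configuration with
# aggregated validation.
#
# Conventions: BED intervals are 0-based half-open; FASTA record IDs use
# "|"-delimited composite keys (fusion_id|site_id|STATE); rate tables use
# fixed 6-decimal formatting and serialize NA as "NA".

# FASTA / FASTQ ----------------------------------------------------------

#' Write sequences to FASTA
#'
#' @param seqs named character vector, or list of [reference_amplicon()]s
#'   (IDs become `variant_id|state`).
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.list(seqs) && inherits(seqs[[1]], "reference_amplicon")) {
    ids <- vapply(seqs, function(r) paste(r$variant_id, r$state, sep = "|"),
                  character(1))
    seqs <- setNames(vapply(seqs, function(r) r$sequence, character(1)),
                     ids)
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path input file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write reads to FASTQ
#'
#' @param reads read tibble (id, sequence, qualities list-column of integer
#'   Phred scores; reads without qualities get Q20).
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  quals <- vapply(seq_len(nrow(reads)), function(i) {
    q <- reads$qualities[[i]]
    if (is.null(q)) q <- rep.int(20L, nchar(reads$sequence[i]))
    rawToChar(as.raw(q + 33L))
  }, character(1))
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  qs <- Biostrings::BStringSet(quals)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qs)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path input file.
#' @return read tibble (id, sequence, qualities list-column).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  quals <- lapply(as.character(S4Vectors::mcols(x)$qualities), function(q) {
    as.integer(charToRaw(q)) - 33L
  })
  tibble(id = names(x), sequence = unname(as.character(x)),
         qualities = unname(quals))
}

# BED / TSV --------------------------------------------------------------

#' Write annotation intervals as BED
#'
#' 0-based half-open intervals; columns chrom, start, end, name, score,
#' strand (BED6).
#'
#' @param intervals tibble with chrom, start, end, name and optionally
#'   score, strand.
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(
    chrom = intervals$chrom, start = intervals$start, end = intervals$end,
    name = intervals$name,
    score = if ("score" %in% names(intervals)) intervals$score else 0,
    strand = if ("strand" %in% names(intervals)) intervals$strand else ".")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' @param path input file.
#' @return tibble with chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score",
                 "strand")[seq_len(ncol(df))]
  as_tibble(df)
}

#' Write annotations of a reference set as BED
#'
#' One BED row per annotated interval, chrom = the reference's composite ID.
#'
#' @param refs named list of [reference_amplicon()]s.
#' @param path output file.
#' @export
write_reference_bed <- function(refs, path) {
  rows <- lapply(refs, function(r) {
    tibble(chrom = paste(r$variant_id, r$state, sep = "|"),
           start = r$annotations$start, end = r$annotations$end,
           name = r$annotations$name)
  })
  write_bed(bind_rows(rows), path)
}

#' Write a rate table as TSV
#'
#' Stable column order, fixed 6-decimal rate formatting, NA serialized as
#' "NA"; round-trips losslessly through [read_rate_table()].
#'
#' @param rate_records output of [compute_rates()].
#' @param path output file.
#' @export
write_rate_table <- function(rate_records, path) {
  df <- as.data.frame(rate_records)
  if ("rate" %in% names(df)) {
    df$rate <- ifelse(is.na(df$rate), NA, sprintf("%.6f", df$rate))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a rate table written by [write_rate_table()]
#'
#' @param path input file.
#' @return rate tibble.
#' @export
read_rate_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, na.strings = "NA")
  as_tibble(df)
}

#' Write the design manifest of a screen as TSV
#'
#' @param fusions,sites design lists from the enumerate functions.
#' @param path output file.
#' @export
write_design_manifest <- function(fusions, sites, path) {
  rows <- list()
  for (f in fusions) {
    for (s in sites) {
      rows[[length(rows) + 1L]] <- tibble(
        variant_id = paste(f$fusion_id, s$site_id, sep = "|"),
        fusion_id = f$fusion_id, site_id = s$site_id, mode = f$mode,
        linker_left = f$linker_left_repeats,
        linker_right = ifelse(is.null(f$linker_right_repeats), NA_integer_,
                              f$linker_right_repeats),
        spacing = ifelse(s$flanked_sides == "none", NA_integer_,
                         s$spacing_bp),
        orientation = ifelse(s$flanked_sides == "none", NA_character_,
                             s$orientation))
    }
  }
  write.table(as.data.frame(bind_rows(rows)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

# MEME minimal motif format ----------------------------------------------

#' Write PPMs in MEME minimal text format
#'
#' @param ppms named list of [build_ppm()] matrices.
#' @param path output file.
#' @param background base probabilities recorded in the header.
#' @export
write_meme <- function(ppms, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_BASES, background),
                     collapse = " "), ""), con)
  for (nm in names(ppms)) {
    p <- unclass(ppms[[nm]])
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(p), attr(ppms[[nm]], "n_sequences") %||% 20L), con)
    for (j in seq_len(ncol(p))) {
      writeLines(paste(sprintf("%.6f", p[, j]), collapse = "  "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a MEME minimal motif file
#'
#' @param path input file.
#' @return named list of `ppm` matrices.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF ", lines[i])) {
      nm <- sub("^MOTIF +", "", lines[i])
      nm <- strsplit(nm, " ")[[1]][1]
      hdr <- lines[i + 1L]
      w <- as.integer(sub(".*w= *(\\d+).*", "\\1", hdr))
      nsites <- as.integer(sub(".*nsites= *(\\d+).*", "\\1", hdr))
      rows <- lines[(i + 2L):(i + 1L + w)]
      vals <- do.call(rbind, lapply(strsplit(trimws(rows), " +"),
                                    as.numeric))
      m <- t(vals)
      rownames(m) <- DNA_BASES
      out[[nm]] <- structure(m, class = "ppm", pseudocount = NA_real_,
                             n_sequences = nsites)
      i <- i + 1L + w
    }
    i <- i + 1L
  }
  out
}

# Screen configuration ---------------------------------------------------

#' Parse and validate a screen configuration
#'
#' Reads a YAML configuration describing the design grammar (lox parts,
#' motif, spacings, orientations, screen mode, linker grids) and the
#' pipeline thresholds, collecting ALL validation errors before failing.
#'
#' @param path YAML file.
#' @return object of class `screen_config` (a validated list) with a
#'   `design_space` attribute ([count_design_space()]).
#' @export
parse_and_validate_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  errors <- character()
  err <- function(msg) errors <<- c(errors, msg)
  known <- c("lox", "motif", "spacings", "orientations",
             "include_unflanked", "mode", "modes", "linker_grid",
             "linker_left_grid", "linker_right_grid", "insertion_junction",
             "max_spacing", "thresholds", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    err(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  for (part in c("name", "left_half", "spacer", "right_half")) {
    if (is.null(cfg$lox[[part]])) err(sprintf("lox$%s missing", part))
  }
  if (!is.null(cfg$lox) &&
      any(grepl("[^ACGT]", toupper(unlist(cfg$lox[c("left_half", "spacer",
                                                    "right_half")]))))) {
    err("lox parts contain non-ACGT characters")
  }
  if (is.null(cfg$motif$sequence)) {
    err("motif$sequence missing")
  } else if (nchar(cfg$motif$sequence) %% 3 != 0) {
    err("motif$sequence length not divisible by 3")
  }
  max_spacing <- cfg$max_spacing %||% 10L
  if (is.null(cfg$spacings) || length(cfg$spacings) == 0L) {
    err("spacings missing or empty")
  } else {
    if (anyDuplicated(cfg$spacings)) err("duplicate spacing values")
    bad <- cfg$spacings[cfg$spacings < 0 | cfg$spacings > max_spacing]
    if (length(bad)) {
      err(sprintf("spacings out of range [0, %d]: %s", max_spacing,
                  paste(bad, collapse = ", ")))
    }
  }
  if (is.null(cfg$orientations) ||
      !all(cfg$orientations %in% c("A", "B"))) {
    err("orientations must be a subset of {A, B}")
  }
  mode <- cfg$mode %||% "TERMINAL"
  if (mode == "INSERTIONAL") {
    if (is.null(cfg$linker_left_grid) || length(cfg$linker_left_grid) == 0L)
      err("linker_left_grid missing or empty")
    if (is.null(cfg$linker_right_grid) ||
        length(cfg$linker_right_grid) == 0L)
      err("linker_right_grid missing or empty")
    if (!is.null(cfg$linker_left_grid) &&
        !all(cfg$linker_left_grid %in% 1:8))
      err("linker_left_grid values must be in 1..8")
    if (!is.null(cfg$linker_right_grid) &&
        !all(cfg$linker_right_grid %in% 1:8))
      err("linker_right_grid values must be in 1..8")
  } else {
    if (is.null(cfg$linker_grid) || length(cfg$linker_grid) == 0L) {
      err("linker_grid missing or empty")
    } else if (!all(cfg$linker_grid %in% c(2, 4, 6, 8, 10, 12))) {
      err("linker_grid values must be in {2,4,6,8,10,12}")
    }
    if (is.null(cfg$modes) ||
        !all(cfg$modes %in% c("N_TERMINAL", "C_TERMINAL"))) {
      err("modes must be a subset of {N_TERMINAL, C_TERMINAL}")
    }
  }
  thr <- cfg$thresholds %||% list()
  if (!is.null(thr$min_phred) && thr$min_phred < 0) {
    err("thresholds$min_phred must be non-negative")
  }
  if (!is.null(thr$p_threshold) &&
      (thr$p_threshold <= 0 || thr$p_threshold > 1)) {
    err("thresholds$p_threshold must be in (0, 1]")
  }
  if (!is.null(thr$distance_range) &&
      (length(thr$distance_range) != 2 ||
       thr$distance_range[1] > thr$distance_range[2])) {
    err("thresholds$distance_range must be an ordered pair")
  }
  if (length(errors)) {
    stop(paste(c("invalid screen config:", paste(" -", errors)),
               collapse = "\n"), call. = FALSE)
  }
  out <- list(
    lox = lox_site(cfg$lox$name, toupper(cfg$lox$left_half),
                   toupper(cfg$lox$spacer), toupper(cfg$lox$right_half)),
    motif = zf_motif(cfg$motif$name %||% "motif",
                     toupper(cfg$motif$sequence)),
    spacings = as.integer(cfg$spacings),
    orientations = cfg$orientations,
    include_unflanked = isTRUE(cfg$include_unflanked %||% TRUE),
    mode = mode,
    modes = cfg$modes,
    linker_grid = cfg$linker_grid,
    linker_left_grid = cfg$linker_left_grid,
    linker_right_grid = cfg$linker_right_grid,
    insertion_junction = cfg$insertion_junction %||% 278L,
    max_spacing = as.integer(max_spacing),
    thresholds = list(
      min_phred = thr$min_phred %||% 10,
      min_margin = thr$min_margin %||% 8,
      p_threshold = thr$p_threshold %||% 0.001,
      distance_range = thr$distance_range %||% c(4L, 6L)),
    seed = cfg$seed %||% 1L)
  class(out) <- "screen_config"
  attr(out, "design_space") <- count_design_space(out)
  out
}

#' @export
print.screen_config <- function(x, ...) {
  cat(sprintf("<screen_config %s: %s mode, design space %d>\n",
              x$lox$name, x$mode, attr(x, "design_space")))
  invisible(x)
}
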