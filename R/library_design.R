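# Combinatorial design of lox-zif target sites, ZF-recombinase fusion coding
# sequences, and paired recombined/unrecombined reference amplicons.
#
# Geometry conventions:
#  * a lox site is left_half + spacer + right_half (default 13 + 8 + 13 = 34 nt)
#  * zif motifs sit on the outer flanks of the lox site, separated from it by
#    spacing_bp of neutral pad
#  * all intervals are 0-based, half-open
#  * residue numbering is 1-based; insertion junction 278/279 means the
#    insert goes after codon 278

# Constructors -----------------------------------------------------------

#' Lox site description
#'
#' A Cre-type recombinase target site: two half sites around an asymmetric
#' spacer. The default geometry is 13 + 8 + 13 = 34 nt.
#'
#' @param name identifier, e.g. `"loxBTR"`.
#' @param left_half,spacer,right_half nucleotide sequences (A/C/G/T).
#' @return an object of class `lox_site`.
#' @export
lox_site <- function(name, left_half, spacer, right_half) {
  assert_dna(c(left_half, spacer, right_half), "lox site part")
  structure(
    list(name = name, left_half = toupper(left_half),
         spacer = toupper(spacer), right_half = toupper(right_half)),
    class = "lox_site")
}

#' @export
print.lox_site <- function(x, ...) {
  cat(sprintf("<lox_site %s: %d+%d+%d = %d nt>\n", x$name,
              nchar(x$left_half), nchar(x$spacer), nchar(x$right_half),
              lox_width(x)))
  invisible(x)
}

lox_width <- function(lox) {
  nchar(lox$left_half) + nchar(lox$spacer) + nchar(lox$right_half)
}

lox_sequence <- function(lox) {
  paste0(lox$left_half, lox$spacer, lox$right_half)
}

#' Zinc-finger binding motif
#'
#' The DNA sequence bound by a zinc-finger domain. Each finger reads 3 bp, so
#' the length must be divisible by 3 (9 nt for three fingers, 12 for four).
#'
#' @param name identifier, e.g. `"zif268"`.
#' @param sequence nucleotide sequence (A/C/G/T), length divisible by 3.
#' @return an object of class `zf_motif`.
#' @export
zf_motif <- function(name, sequence) {
  assert_dna(sequence, "zf motif")
  if (nchar(sequence) %% 3L != 0L) {
    stop("zf motif length must be divisible by 3 (one finger per 3 nt)")
  }
  structure(list(name = name, sequence = toupper(sequence)),
            class = "zf_motif")
}

#' Target-site design point
#'
#' One point of the target-site library: a lox site optionally flanked by a
#' ZF binding motif at a given spacing and orientation.
#'
#' Orientation semantics: orientation `"A"` places the motif's given sequence
#' on the top strand on the left flank (and its reverse complement on the
#' right flank, mirror-symmetrically); orientation `"B"` is the reverse
#' complement arrangement.
#'
#' @param lox a [lox_site()].
#' @param motif a [zf_motif()], or `NULL` for the unflanked site.
#' @param spacing_bp integer gap (bp) between motif and lox site, 0-10 by
#'   default range; ignored when `motif` is `NULL`.
#' @param orientation `"A"` or `"B"`.
#' @param flanked_sides which flanks carry the motif: `"both"` (default),
#'   `"left"`, `"right"`, or `"none"` (forced when `motif` is `NULL`).
#' @param max_spacing upper bound of the allowed spacing range.
#' @return an object of class `target_site_design` with a unique `site_id`.
#' @export
target_site_design <- function(lox, motif = NULL, spacing_bp = 0L,
                               orientation = c("A", "B"),
                               flanked_sides = c("both", "left", "right", "none"),
                               max_spacing = 10L) {
  stopifnot(inherits(lox, "lox_site"))
  orientation <- match.arg(orientation)
  flanked_sides <- match.arg(flanked_sides)
  if (is.null(motif)) {
    flanked_sides <- "none"
  } else {
    stopifnot(inherits(motif, "zf_motif"))
    if (flanked_sides == "none") {
      stop("flanked_sides = 'none' requires motif = NULL")
    }
    if (spacing_bp < 0L || spacing_bp > max_spacing) {
      stop(sprintf("spacing_bp %d outside allowed range [0, %d]",
                   spacing_bp, max_spacing))
    }
  }
  site_id <- if (flanked_sides == "none") {
    lox$name
  } else {
    sprintf("%s-%d-%s(%s)%s", lox$name, spacing_bp, motif$name, orientation,
            ifelse(flanked_sides == "both", "",
                   paste0("-", toupper(substr(flanked_sides, 1, 1)))))
  }
  structure(
    list(lox = lox, motif = motif, spacing_bp = as.integer(spacing_bp),
         orientation = orientation, flanked_sides = flanked_sides,
         site_id = site_id),
    class = "target_site_design")
}

#' Fusion design point
#'
#' One point of the fusion library: where the ZF domain joins the recombinase
#' and how long the Gly-Gly-Ser linkers are.
#'
#' @param recombinase_id identifier, e.g. `"Brec1"`.
#' @param mode `"N_TERMINAL"`, `"C_TERMINAL"` or `"INSERTIONAL"`.
#' @param linker_left_repeats GGS repeat count; for terminal modes this is
#'   THE linker (allowed 2,4,...,12), for insertional mode the left linker
#'   (allowed 1..8).
#' @param linker_right_repeats right linker GGS count, insertional mode only.
#' @param insertion_junction 1-based residue after which the insert goes
#'   (278 means between residues 278 and 279); required for insertional mode.
#' @return an object of class `fusion_design` with a unique `fusion_id`.
#' @export
fusion_design <- function(recombinase_id, mode = c("N_TERMINAL", "C_TERMINAL",
                                                   "INSERTIONAL"),
                          linker_left_repeats,
                          linker_right_repeats = NULL,
                          insertion_junction = NULL) {
  mode <- match.arg(mode)
  if (mode == "INSERTIONAL") {
    if (is.null(insertion_junction)) {
      stop("insertional fusions need an insertion_junction")
    }
    if (is.null(linker_right_repeats)) {
      stop("insertional fusions need linker_right_repeats")
    }
    if (!all(c(linker_left_repeats, linker_right_repeats) %in% 1:8)) {
      stop("insertional linker repeats must each be in 1..8")
    }
    fusion_id <- sprintf("%s-ins%d-L%dR%d", recombinase_id,
                         insertion_junction, linker_left_repeats,
                         linker_right_repeats)
  } else {
    if (!linker_left_repeats %in% c(2L, 4L, 6L, 8L, 10L, 12L)) {
      stop("terminal linker repeats must be in {2,4,6,8,10,12}")
    }
    linker_right_repeats <- NULL
    fusion_id <- sprintf("%s-%s-L%d", recombinase_id,
                         ifelse(mode == "N_TERMINAL", "N", "C"),
                         linker_left_repeats)
  }
  structure(
    list(recombinase_id = recombinase_id, mode = mode,
         insertion_junction = if (is.null(insertion_junction)) NULL
                              else as.integer(insertion_junction),
         linker_left_repeats = as.integer(linker_left_repeats),
         linker_right_repeats = if (is.null(linker_right_repeats)) NULL
                                else as.integer(linker_right_repeats),
         fusion_id = fusion_id),
    class = "fusion_design")
}

# Target-site assembly ---------------------------------------------------

#' Assemble a target-site sequence from a design
#'
#' Builds motif + pad + lox + pad + motif per the design's `flanked_sides`,
#' with deterministic neutral pad of `spacing_bp` nt on each flanked side.
#' Orientation `"A"` puts the motif's given sequence on the left flank and
#' its reverse complement on the right (mirror symmetry); `"B"` swaps the
#' two. The returned object carries 0-based half-open interval annotations
#' and a `bound_bp` accounting of recombinase + ZF-contacted bases (lox width
#' plus the widths of the motifs present, pads excluded).
#'
#' @param design a [target_site_design()].
#' @return an object of class `target_site` with elements `sequence`,
#'   `annotations` (tibble: name, start, end), `bound_bp`, `design`.
#' @export
build_target_site <- function(design) {
  stopifnot(inherits(design, "target_site_design"))
  lox <- design$lox
  loxseq <- lox_sequence(lox)
  parts <- character()
  ann <- tibble(name = character(), start = integer(), end = integer())
  pos <- 0L
  add <- function(nm, s) {
    if (nchar(s) == 0L) return(invisible(NULL))
    parts[[length(parts) + 1L]] <<- s
    ann <<- bind_rows(ann, tibble(name = nm, start = pos,
                                  end = pos + nchar(s)))
    pos <<- pos + nchar(s)
    invisible(NULL)
  }
  has_left <- design$flanked_sides %in% c("both", "left")
  has_right <- design$flanked_sides %in% c("both", "right")
  motif_fwd <- if (!is.null(design$motif)) design$motif$sequence else ""
  motif_rev <- if (!is.null(design$motif)) revcomp(motif_fwd) else ""
  left_motif <- if (design$orientation == "A") motif_fwd else motif_rev
  right_motif <- if (design$orientation == "A") motif_rev else motif_fwd
  if (has_left) {
    add("motif_left", left_motif)
    add("pad_left", pad_seq(design$spacing_bp))
  }
  add("lox", loxseq)
  # mark the lox spacer (excision resolves within it)
  ann <- bind_rows(ann, tibble(
    name = "lox_spacer",
    start = ann$start[ann$name == "lox"] + nchar(lox$left_half),
    end = ann$start[ann$name == "lox"] + nchar(lox$left_half) +
      nchar(lox$spacer)))
  if (has_right) {
    add("pad_right", pad_seq(design$spacing_bp))
    add("motif_right", right_motif)
  }
  bound_bp <- lox_width(lox) +
    (has_left + has_right) * nchar(motif_fwd)
  structure(
    list(sequence = paste0(parts, collapse = ""),
         annotations = arrange(ann, .data$start, .data$name),
         bound_bp = as.integer(bound_bp),
         design = design),
    class = "target_site")
}

#' @export
print.target_site <- function(x, ...) {
  cat(sprintf("<target_site %s: %d nt, %d bound bp>\n",
              x$design$site_id, nchar(x$sequence), x$bound_bp))
  invisible(x)
}

#' Enumerate the target-site library
#'
#' Cartesian product of spacings and orientations, plus optionally the
#' unflanked lox-only design.
#'
#' @param lox a [lox_site()].
#' @param motif a [zf_motif()].
#' @param spacings integer vector of spacings (bp), no duplicates.
#' @param orientations subset of `c("A", "B")`.
#' @param include_unflanked add the bare lox site as one extra design.
#' @param max_spacing upper bound passed through to [target_site_design()].
#' @return list of `target_site_design` objects with unique `site_id`s.
#' @export
enumerate_target_library <- function(lox, motif, spacings = 0:10,
                                     orientations = c("A", "B"),
                                     include_unflanked = TRUE,
                                     max_spacing = max(10L, max(spacings))) {
  if (length(spacings) == 0L) stop("spacings must be non-empty")
  if (anyDuplicated(spacings)) stop("duplicate spacing values")
  designs <- list()
  for (ori in orientations) {
    for (sp in spacings) {
      designs[[length(designs) + 1L]] <-
        target_site_design(lox, motif, spacing_bp = sp, orientation = ori,
                           max_spacing = max_spacing)
    }
  }
  if (include_unflanked) {
    designs[[length(designs) + 1L]] <- target_site_design(lox, motif = NULL)
  }
  ids <- vapply(designs, function(d) d$site_id, character(1))
  if (anyDuplicated(ids)) stop("non-unique site ids in enumeration")
  names(designs) <- ids
  designs
}

# Fusion CDS assembly ----------------------------------------------------

# fixed codon choice for one Gly-Gly-Ser repeat (recorded for
# reproducibility; any consistent choice works)
GGS_CODONS <- "GGTGGTAGC"

ggs_linker <- function(repeats) strrep(GGS_CODONS, repeats)

has_internal_stop <- function(cds) {
  if (nchar(cds) < 3L) return(FALSE)
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  any(codons %in% c("TAA", "TAG", "TGA"))
}

strip_stop <- function(cds) {
  if (nchar(cds) >= 3L &&
      substr(cds, nchar(cds) - 2, nchar(cds)) %in% c("TAA", "TAG", "TGA")) {
    substr(cds, 1L, nchar(cds) - 3L)
  } else {
    cds
  }
}

#' Assemble a fusion coding sequence
#'
#' Joins recombinase and ZF coding sequences per the fusion design:
#' N-terminal = ZF (stop removed) + linker + recombinase; C-terminal =
#' recombinase (stop removed) + linker + ZF; insertional = recombinase codons
#' 1..junction + left linker + ZF (start/stop removed) + right linker +
#' remaining recombinase codons. GGS linker codons are fixed (`GGT GGT AGC`).
#'
#' @param recombinase_cds,zf_cds in-frame coding sequences (length divisible
#'   by 3, no internal stop codons). `zf_cds` may be `""` for the degenerate
#'   linker-only insertion.
#' @param design a [fusion_design()].
#' @return the fused coding sequence (character scalar), in frame.
#' @export
build_fusion_cds <- function(recombinase_cds, zf_cds, design) {
  stopifnot(inherits(design, "fusion_design"))
  recombinase_cds <- toupper(recombinase_cds)
  zf_cds <- toupper(zf_cds)
  assert_dna(recombinase_cds, "recombinase CDS")
  if (nchar(zf_cds) > 0) assert_dna(zf_cds, "ZF CDS")
  if (nchar(recombinase_cds) %% 3L != 0L || nchar(zf_cds) %% 3L != 0L) {
    stop("coding sequences must be in frame (length divisible by 3)")
  }
  rec_body <- strip_stop(recombinase_cds)
  zf_body <- strip_stop(zf_cds)
  if (has_internal_stop(rec_body) || has_internal_stop(zf_body)) {
    stop("internal stop codon in input CDS")
  }
  out <- switch(
    design$mode,
    N_TERMINAL = paste0(zf_body, ggs_linker(design$linker_left_repeats),
                        recombinase_cds),
    C_TERMINAL = paste0(rec_body, ggs_linker(design$linker_left_repeats),
                        zf_cds),
    INSERTIONAL = {
      j <- design$insertion_junction
      if (3L * j > nchar(rec_body)) {
        stop("insertion junction beyond recombinase CDS")
      }
      paste0(substr(recombinase_cds, 1L, 3L * j),
             ggs_linker(design$linker_left_repeats),
             zf_body,
             ggs_linker(design$linker_right_repeats),
             substr(recombinase_cds, 3L * j + 1L, nchar(recombinase_cds)))
    })
  stopifnot(nchar(out) %% 3L == 0L)
  out
}

#' Enumerate the fusion library
#'
#' Terminal screens: modes x linker grid. Insertional screens: left x right
#' linker grid at a fixed junction.
#'
#' @param recombinase_id identifier.
#' @param modes subset of `c("N_TERMINAL", "C_TERMINAL")`, or
#'   `"INSERTIONAL"`.
#' @param linker_grid GGS repeat counts for terminal modes.
#' @param linker_left_grid,linker_right_grid repeat grids for insertional
#'   mode.
#' @param insertion_junction 1-based junction residue (default 278).
#' @return list of `fusion_design` objects with unique `fusion_id`s.
#' @export
enumerate_fusion_library <- function(recombinase_id,
                                     modes = c("N_TERMINAL", "C_TERMINAL"),
                                     linker_grid = c(2L, 4L, 6L, 8L, 10L, 12L),
                                     linker_left_grid = 1:8,
                                     linker_right_grid = 1:8,
                                     insertion_junction = 278L) {
  designs <- list()
  if ("INSERTIONAL" %in% modes) {
    if (length(modes) > 1L) stop("insertional screens are enumerated alone")
    if (length(linker_left_grid) == 0L || length(linker_right_grid) == 0L) {
      stop("empty linker grid")
    }
    for (l in linker_left_grid) {
      for (r in linker_right_grid) {
        designs[[length(designs) + 1L]] <-
          fusion_design(recombinase_id, "INSERTIONAL",
                        linker_left_repeats = l, linker_right_repeats = r,
                        insertion_junction = insertion_junction)
      }
    }
  } else {
    if (length(modes) == 0L || length(linker_grid) == 0L) {
      stop("empty mode set or linker grid")
    }
    for (mode in modes) {
      for (l in linker_grid) {
        designs[[length(designs) + 1L]] <-
          fusion_design(recombinase_id, mode, linker_left_repeats = l)
      }
    }
  }
  ids <- vapply(designs, function(d) d$fusion_id, character(1))
  if (anyDuplicated(ids)) stop("non-unique fusion ids in enumeration")
  names(designs) <- ids
  designs
}

# Reference amplicons -----------------------------------------------------

#' Reference amplicon constructor (internal shape)
#'
#' @param variant_id composite key `fusion_id|site_id`.
#' @param state `"REC"` or `"UNREC"`.
#' @param sequence nucleotide sequence.
#' @param annotations tibble with columns name, start, end (0-based
#'   half-open).
#' @return object of class `reference_amplicon`.
#' @export
reference_amplicon <- function(variant_id, state, sequence, annotations) {
  stopifnot(state %in% c("REC", "UNREC"))
  stopifnot(all(annotations$start >= 0L),
            all(annotations$end <= nchar(sequence)))
  n_sites <- sum(annotations$name == "target_site")
  if (state == "UNREC" && n_sites != 2L) {
    stop("UNREC amplicon must carry exactly 2 target_site intervals")
  }
  if (state == "REC" && n_sites != 1L) {
    stop("REC amplicon must carry exactly 1 target_site interval")
  }
  structure(list(variant_id = variant_id, state = state,
                 sequence = sequence, annotations = annotations),
            class = "reference_amplicon")
}

#' @export
print.reference_amplicon <- function(x, ...) {
  cat(sprintf("<reference_amplicon %s|%s: %d nt, %d annotations>\n",
              x$variant_id, x$state, nchar(x$sequence),
              nrow(x$annotations)))
  invisible(x)
}

#' Build the recombined/unrecombined reference pair for one variant
#'
#' The backbone is a template string containing the literal anchor tokens
#' `[SITE1]`, `[INTERSITE]`, `[SITE2]` and `[CDS]` exactly once each (in that
#' order along the molecule for the two sites). The unrecombined reference
#' substitutes the full target site at both anchors plus the inter-site
#' segment and the fusion CDS. The recombined reference models excision
#' resolving within the lox 8-nt spacer: everything from the end of the first
#' site's lox spacer through the end of the second site's lox spacer is
#' removed, leaving exactly one complete composite site whose flanking motifs
#' are the outermost copies.
#'
#' @param backbone template with anchor tokens.
#' @param site a `target_site` from [build_target_site()].
#' @param fusion_cds fusion coding sequence (diagnostic region).
#' @param intersite_segment excisable segment between the two sites
#'   (non-empty).
#' @param variant_id composite key recorded on both amplicons.
#' @return list with elements `UNREC` and `REC`, both `reference_amplicon`s.
#' @export
build_reference_pair <- function(backbone, site, fusion_cds,
                                 intersite_segment, variant_id) {
  stopifnot(inherits(site, "target_site"))
  if (nchar(intersite_segment) == 0L) stop("intersite_segment is empty")
  for (tok in c("[SITE1]", "[INTERSITE]", "[SITE2]", "[CDS]")) {
    if (length(gregexpr(tok, backbone, fixed = TRUE)[[1]]) != 1L ||
        gregexpr(tok, backbone, fixed = TRUE)[[1]][1] == -1L) {
      stop(sprintf("backbone must contain anchor %s exactly once", tok))
    }
  }
  site_seq <- site$sequence
  spacer_end <- site$annotations$end[site$annotations$name == "lox_spacer"]

  assemble <- function(site1_part, with_intersite, site2_part) {
    pieces <- strsplit(backbone, "\\[(SITE1|INTERSITE|SITE2|CDS)\\]")[[1]]
    toks <- regmatches(backbone,
                       gregexpr("\\[(SITE1|INTERSITE|SITE2|CDS)\\]",
                                backbone))[[1]]
    out <- ""
    ann <- tibble(name = character(), start = integer(), end = integer())
    for (i in seq_along(toks)) {
      out <- paste0(out, pieces[i])
      ins <- switch(toks[i],
                    "[SITE1]" = site1_part,
                    "[INTERSITE]" = if (with_intersite) intersite_segment else "",
                    "[SITE2]" = site2_part,
                    "[CDS]" = fusion_cds)
      nm <- switch(toks[i],
                   "[SITE1]" = "target_site",
                   "[INTERSITE]" = "intersite",
                   "[SITE2]" = "target_site",
                   "[CDS]" = "fusion_diagnostic")
      if (nchar(ins) > 0L) {
        ann <- bind_rows(ann, tibble(name = nm, start = nchar(out),
                                     end = nchar(out) + nchar(ins)))
        out <- paste0(out, ins)
      }
    }
    if (length(pieces) > length(toks)) {
      out <- paste0(out, pieces[length(pieces)])
    }
    list(sequence = out, annotations = ann)
  }

  un <- assemble(site_seq, TRUE, site_seq)
  # excision product: site1 up to (and including) its lox spacer, then
  # site2 from just after its lox spacer; the intersite segment is gone
  rec_site1 <- substr(site_seq, 1L, spacer_end)
  rec_site2 <- substr(site_seq, spacer_end + 1L, nchar(site_seq))
  rec <- assemble(rec_site1, FALSE, rec_site2)
  # the two adjacent fragments reconstitute one full site: merge annotations
  ts <- rec$annotations$name == "target_site"
  stopifnot(sum(ts) == 2L)
  merged_start <- min(rec$annotations$start[ts])
  merged_end <- max(rec$annotations$end[ts])
  if (merged_end - merged_start != nchar(site_seq)) {
    stop("excision did not leave one contiguous composite site ",
         "(anchors [SITE1] and [SITE2] must be adjacent to [INTERSITE])")
  }
  rec$annotations <- bind_rows(
    rec$annotations[!ts, ],
    tibble(name = "target_site", start = merged_start, end = merged_end)) %>%
    arrange(.data$start)
  # assembly guard: the full site must be present in both products
  if (!grepl(site_seq, un$sequence, fixed = TRUE) ||
      !grepl(site_seq, rec$sequence, fixed = TRUE)) {
    stop("assembled reference does not contain the target site")
  }
  list(
    UNREC = reference_amplicon(variant_id, "UNREC", un$sequence,
                               un$annotations),
    REC = reference_amplicon(variant_id, "REC", rec$sequence,
                             rec$annotations))
}

#' Build the full reference set for a screen
#'
#' Crosses a fusion library with a target-site library and builds the
#' REC/UNREC amplicon pair for every combination.
#'
#' @param fusions list of `fusion_design`s.
#' @param sites list of `target_site_design`s.
#' @param backbone anchor-token template (see [build_reference_pair()]).
#' @param recombinase_cds,zf_cds coding sequences fed to
#'   [build_fusion_cds()].
#' @param intersite_segment excisable segment.
#' @return named list of `reference_amplicon`s, names `variant_id|state`.
#' @export
build_screen_references <- function(fusions, sites, backbone,
                                    recombinase_cds, zf_cds,
                                    intersite_segment) {
  refs <- list()
  for (f in fusions) {
    cds <- build_fusion_cds(recombinase_cds, zf_cds, f)
    for (s in sites) {
      ts <- build_target_site(s)
      vid <- paste(f$fusion_id, s$site_id, sep = "|")
      pair <- build_reference_pair(backbone, ts, cds, intersite_segment, vid)
      refs[[paste(vid, "UNREC", sep = "|")]] <- pair$UNREC
      refs[[paste(vid, "REC", sep = "|")]] <- pair$REC
    }
  }
  refs
}

#' Size of the combinatorial design space
#'
#' @param screen_config a validated screen configuration (see
#'   [parse_and_validate_config()]) or a list with the same fields.
#' @return integer: number of fusion designs times number of target-site
#'   designs.
#' @export
count_design_space <- function(screen_config) {
  cfg <- screen_config
  n_sites <- length(cfg$spacings) * length(cfg$orientations) +
    as.integer(isTRUE(cfg$include_unflanked))
  n_fusions <- if (identical(cfg$mode, "INSERTIONAL")) {
    length(cfg$linker_left_grid) * length(cfg$linker_right_grid)
  } else {
    length(cfg$modes) * length(cfg$linker_grid)
  }
  as.integer(n_fusions * n_sites)
}
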