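#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

NULL

SEGMENT_NAMES <- c(
  "signal_peptide", "pro", "VPS10p", "10CC", "YWTD", "EGF",
  "CR_cluster", "3Fn_cassette", "TM_tail"
)

REPEAT_CLASSES <- c("CR", "3Fn", "YWTD_blade", "L1_loop", "L2_loop")

#' Load a domain architecture from a structured configuration
#'
#' Reads the architecture block of a JSON configuration (segments, repeat
#' units, residue anchors) and validates it: segments must be sorted,
#' non-overlapping and tile residues `1..protein_length` without gaps; repeat
#' units of one class must be index-ordered and non-overlapping and lie within
#' their parent segment, except for a small configurable overhang which is
#' accepted with a warning. Every anchor pair (global residue, within-repeat
#' position) is checked against the repeat boundaries at load time, so a
#' configuration that contradicts its own anchors refuses to load.
#'
#' @param config_source Path to a JSON configuration file, or an equivalent
#'   named list (as returned by [jsonlite::read_json()]).
#' @return An object of class `sorl_architecture`: a list with
#'   `protein_length`, `segments` and `repeats` tibbles, an `anchors` tibble,
#'   and the `reference_sequence` (filled in by [sorl1_refseq()] for the
#'   packaged default).
#' @seealso [sorl1_architecture()] for the packaged SORL1 default,
#'   [locate_residue()] to map residues into it.
#' @export
load_architecture <- function(config_source) {
  cfg <- read_config(config_source)
  if (is.null(cfg$protein_length) || is.null(cfg$segments)) {
    stop("architecture config must contain 'protein_length' and 'segments'", call. = FALSE)
  }
  protein_length <- as.integer(cfg$protein_length)
  segments <- dplyr::bind_rows(lapply(cfg$segments, tibble::as_tibble))
  segments <- dplyr::mutate(segments,
    start = as.integer(.data$start), end = as.integer(.data$end)
  )
  validate_segments(segments, protein_length)

  repeats <- if (length(cfg$repeats)) {
    dplyr::bind_rows(lapply(cfg$repeats, tibble::as_tibble))
  } else {
    tibble::tibble(
      repeat_class = character(), index = integer(),
      start = integer(), end = integer(), parent = character()
    )
  }
  if (nrow(repeats)) {
    repeats <- dplyr::mutate(repeats,
      index = as.integer(.data$index),
      start = as.integer(.data$start), end = as.integer(.data$end)
    )
  }
  max_overhang <- if (is.null(cfg$max_repeat_overhang)) 0L else as.integer(cfg$max_repeat_overhang)
  validate_repeats(repeats, segments, max_overhang)

  anchors <- if (length(cfg$anchors)) {
    dplyr::bind_rows(lapply(cfg$anchors, tibble::as_tibble))
  } else {
    tibble::tibble(residue = integer(), repeat_class = character(),
                   index = integer(), position = integer())
  }

  arch <- structure(
    list(
      name = cfg$name %||% "unnamed",
      protein_length = protein_length,
      segments = segments,
      repeats = repeats,
      anchors = anchors,
      reference_sequence = NULL
    ),
    class = "sorl_architecture"
  )
  validate_anchors(arch)
  arch
}

#' The packaged default SORL1 architecture and rule configuration
#'
#' Loads the `sorl1_default` configuration shipped with the package: the
#' nine-segment architecture of the 2,214-residue receptor (signal peptide,
#' pro-peptide, VPS10p beta-propeller with its L1/L2 loops, 10CC, YWTD
#' beta-propeller, EGF, the 11-repeat CR cluster, the six-repeat 3Fn cassette
#' and the transmembrane/cytoplasmic tail), the residue-rule set used for
#' prioritization, and a synthetic reference sequence consistent with every
#' rule position (see [sorl1_refseq()]). Repeat boundaries not pinned by a
#' published residue/repeat-position anchor are interpolations and are marked
#' as user-editable in the configuration file itself.
#'
#' @return A `sorl_architecture` object with `reference_sequence` set.
#' @export
sorl1_architecture <- function() {
  arch <- get0(".sorl1_arch_cache", envir = .sorldmdm_cache)
  if (!is.null(arch)) return(arch)
  path <- system.file("extdata", "sorl1_default.json", package = "sorldmdm")
  arch <- suppressWarnings(load_architecture(path))
  arch$reference_sequence <- sorl1_refseq(arch)
  assign(".sorl1_arch_cache", arch, envir = .sorldmdm_cache)
  arch
}

.sorldmdm_cache <- new.env(parent = emptyenv())

`%||%` <- function(x, y) if (is.null(x)) y else x

read_config <- function(config_source) {
  if (is.character(config_source) && length(config_source) == 1L) {
    if (!file.exists(config_source)) {
      stop("config file not found: ", config_source, call. = FALSE)
    }
    jsonlite::read_json(config_source)
  } else if (is.list(config_source)) {
    config_source
  } else {
    stop("config_source must be a file path or a list", call. = FALSE)
  }
}

validate_segments <- function(segments, protein_length) {
  stopifnot(all(c("name", "start", "end") %in% names(segments)))
  bad <- segments$name[!segments$name %in% SEGMENT_NAMES]
  if (length(bad)) stop("unknown segment name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(segments$start > segments$end)) {
    i <- which(segments$start > segments$end)[1]
    stop("segment ", segments$name[i], " has start > end", call. = FALSE)
  }
  segments <- segments[order(segments$start), ]
  if (segments$start[1] != 1L) stop("segments must start at residue 1", call. = FALSE)
  if (segments$end[nrow(segments)] != protein_length) {
    stop("segments must end at residue ", protein_length, call. = FALSE)
  }
  if (nrow(segments) > 1L) {
    gap <- segments$start[-1] - segments$end[-nrow(segments)]
    if (any(gap > 1L)) {
      i <- which(gap > 1L)[1]
      stop("gap between segments ", segments$name[i], " and ", segments$name[i + 1],
           call. = FALSE)
    }
    if (any(gap < 1L)) {
      i <- which(gap < 1L)[1]
      stop("overlap between segments ", segments$name[i], " and ", segments$name[i + 1],
           call. = FALSE)
    }
  }
  invisible(segments)
}

validate_repeats <- function(repeats, segments, max_overhang) {
  if (!nrow(repeats)) return(invisible(repeats))
  stopifnot(all(c("repeat_class", "index", "start", "end", "parent") %in% names(repeats)))
  bad <- repeats$repeat_class[!repeats$repeat_class %in% REPEAT_CLASSES]
  if (length(bad)) stop("unknown repeat class(es): ", paste(unique(bad), collapse = ", "), call. = FALSE)
  if (any(repeats$start > repeats$end)) stop("repeat with start > end", call. = FALSE)
  for (cls in unique(repeats$repeat_class)) {
    r <- repeats[repeats$repeat_class == cls, ]
    r <- r[order(r$index), ]
    if (any(diff(r$start) <= 0) || any(r$start[-1] <= r$end[-nrow(r)])) {
      stop("repeats of class ", cls, " overlap or are not index-ordered", call. = FALSE)
    }
  }
  # repeats of different classes must not overlap either, so that every
  # residue has at most one repeat context
  all_sorted <- repeats[order(repeats$start), ]
  if (nrow(all_sorted) > 1L &&
      any(all_sorted$start[-1] <= all_sorted$end[-nrow(all_sorted)])) {
    i <- which(all_sorted$start[-1] <= all_sorted$end[-nrow(all_sorted)])[1]
    stop("repeats ", all_sorted$repeat_class[i], all_sorted$index[i], " and ",
         all_sorted$repeat_class[i + 1], all_sorted$index[i + 1], " overlap",
         call. = FALSE)
  }
  for (i in seq_len(nrow(repeats))) {
    seg <- segments[segments$name == repeats$parent[i], ]
    if (!nrow(seg)) stop("repeat parent segment not found: ", repeats$parent[i], call. = FALSE)
    over_lo <- seg$start - repeats$start[i]
    over_hi <- repeats$end[i] - seg$end
    over <- max(over_lo, over_hi, 0L)
    if (over > max_overhang) {
      stop("repeat ", repeats$repeat_class[i], repeats$index[i],
           " (", repeats$start[i], "-", repeats$end[i], ") exceeds parent segment ",
           repeats$parent[i], " by ", over, " residues", call. = FALSE)
    }
    if (over > 0L) {
      warning("repeat ", repeats$repeat_class[i], repeats$index[i],
              " overhangs parent segment ", repeats$parent[i], " by ", over,
              " residue(s); accepted (<= max_repeat_overhang)", call. = FALSE)
    }
  }
  invisible(repeats)
}

validate_anchors <- function(arch) {
  anchors <- arch$anchors
  if (!nrow(anchors)) return(invisible(arch))
  for (i in seq_len(nrow(anchors))) {
    ctx <- locate_residue(arch, anchors$residue[i])
    ok <- identical(ctx$repeat_class, anchors$repeat_class[i]) &&
      identical(as.integer(ctx$repeat_index), as.integer(anchors$index[i])) &&
      identical(as.integer(ctx$repeat_position), as.integer(anchors$position[i]))
    if (!ok) {
      stop("anchor violated: residue ", anchors$residue[i], " expected ",
           anchors$repeat_class[i], anchors$index[i], " position ",
           anchors$position[i], call. = FALSE)
    }
  }
  invisible(arch)
}

#' Map a protein residue to its domain context
#'
#' Every residue of the protein maps to exactly one segment; if it also falls
#' inside a configured repeat unit, the within-repeat position is
#' `position - repeat_start + 1` (1-based). When a residue lies in the
#' overhang of a repeat that extends past its parent segment (the default
#' configuration allows small anchored overhangs), the containing segment is
#' still the tiling segment, and the repeat fields refer to the overhanging
#' repeat.
#'
#' @param arch A `sorl_architecture`.
#' @param position Integer vector of 1-based residue indices.
#' @return A tibble with one row per input position: `position`, `segment`,
#'   `repeat_class`, `repeat_index`, `repeat_position` (repeat columns are
#'   `NA` outside any repeat unit).
#' @export
locate_residue <- function(arch, position) {
  stopifnot(inherits(arch, "sorl_architecture"))
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L) || any(position > arch$protein_length)) {
    stop("position out of range 1..", arch$protein_length, call. = FALSE)
  }
  seg_idx <- findInterval(position, arch$segments$start)
  segment <- arch$segments$name[seg_idx]

  repeat_class <- rep(NA_character_, length(position))
  repeat_index <- rep(NA_integer_, length(position))
  repeat_position <- rep(NA_integer_, length(position))
  reps <- arch$repeats
  if (nrow(reps)) {
    for (j in seq_len(nrow(reps))) {
      inside <- position >= reps$start[j] & position <= reps$end[j]
      if (any(inside)) {
        repeat_class[inside] <- reps$repeat_class[j]
        repeat_index[inside] <- reps$index[j]
        repeat_position[inside] <- position[inside] - reps$start[j] + 1L
      }
    }
  }
  tibble::tibble(
    position = position, segment = segment,
    repeat_class = repeat_class, repeat_index = repeat_index,
    repeat_position = repeat_position
  )
}

#' Synthetic SORL1 reference amino-acid sequence
#'
#' Builds a 2,214-residue amino-acid string that is consistent with every
#' residue-identity constraint used by the rule set and with the residues of
#' the variants discussed in the package documentation: aspartates/glutamate
#' at the CR calcium-cage positions, the six-cysteine CR framework, the ten
#' 10CC and eight EGF cysteines, the Y/W/T/D tetrad on each YWTD blade, the
#' 3Fn tyrosine corner (L/P/Y at repeat positions 77/79/83), conserved 3Fn
#' glycines, tryptophan/tyrosine core residues and N-terminal prolines. All
#' remaining positions are filled with a fixed cysteine-free background cycle.
#' This is a synthetic stand-in, not the biological sequence: it exists so
#' that cysteine gain/loss logic and reference-identity checks are exactly
#' testable.
#'
#' @param arch A `sorl_architecture` (defaults to the packaged one, without
#'   recursion into the cached copy).
#' @return A single character string of length `protein_length`.
#' @export
sorl1_refseq <- function(arch) {
  n <- arch$protein_length
  background <- c("G", "A", "S", "T", "V", "L", "I", "P", "N", "Q")
  seq <- background[((seq_len(n) - 1L) %% length(background)) + 1L]

  set_at <- function(pos, aa) {
    pos <- pos[pos >= 1L & pos <= n]
    seq[pos] <<- aa
  }
  reps <- arch$repeats
  rep_rows <- function(cls) reps[reps$repeat_class == cls, , drop = FALSE]
  set_rep <- function(cls, rel_pos, aa) {
    r <- rep_rows(cls)
    for (j in seq_len(nrow(r))) {
      p <- r$start[j] + rel_pos - 1L
      p <- p[p <= r$end[j]]
      set_at(p, aa)
    }
  }

  # CR repeats: calcium cage D/D/D/E at 37/41/47/48, Asx-turn D at 44,
  # framework cysteines at 5/12/19/27/34/45.
  set_rep("CR", c(37L, 41L), "D")
  set_rep("CR", 47L, "D")
  set_rep("CR", 48L, "E")
  set_rep("CR", 44L, "D")
  for (p in c(5L, 12L, 19L, 27L, 34L, 45L)) set_rep("CR", p, "C")

  # YWTD blades: Y/W/T/D tetrad, conserved L29/G35, partly conserved S9/R38.
  set_rep("YWTD_blade", 17L, "Y"); set_rep("YWTD_blade", 18L, "W")
  set_rep("YWTD_blade", 19L, "T"); set_rep("YWTD_blade", 20L, "D")
  set_rep("YWTD_blade", 29L, "L"); set_rep("YWTD_blade", 35L, "G")
  set_rep("YWTD_blade", 9L, "S");  set_rep("YWTD_blade", 38L, "R")

  # 3Fn repeats: W25/Y41 hydrophobic core, G36/G96, tyrosine corner L77/P79/Y83,
  # N-terminal prolines P6/P7.
  set_rep("3Fn", 25L, "W"); set_rep("3Fn", 41L, "Y")
  set_rep("3Fn", 36L, "G"); set_rep("3Fn", 96L, "G")
  set_rep("3Fn", 77L, "L"); set_rep("3Fn", 79L, "P"); set_rep("3Fn", 83L, "Y")
  set_rep("3Fn", 6L, "P");  set_rep("3Fn", 7L, "P")

  # 10CC: ten cysteines; EGF: eight cysteines.
  set_at(c(625L, 638L, 651L, 664L, 677L, 690L, 703L, 716L, 729L, 742L), "C")
  set_at(c(1018L, 1026L, 1033L, 1040L, 1047L, 1054L, 1061L, 1068L), "C")

  # Loop and single-residue identities referenced in documentation and tests.
  set_at(391L, "Y"); set_at(398L, "G")                      # L1 loop
  set_at(467L, "C"); set_at(473L, "C"); set_at(474L, "S"); set_at(480L, "R") # L2 loop
  set_at(722L, "Y")                                         # 10CC
  set_at(1064L, "Y")                                        # EGF
  set_at(c(138L, 236L, 564L), "S"); set_at(570L, "I")       # VPS10p Asp-box area
  set_at(270L, "E"); set_at(528L, "A"); set_at(511L, "G")   # common VPS10p variants
  set_at(c(744L, 866L), "R")                                # recurrent nonsense sites
  set_at(c(1080L, 1124L, 1303L, 1490L), "R")                # CR arginines (cysteine gains)
  set_at(1681L, "G"); set_at(2065L, "D")                    # 3Fn singletons

  paste(seq, collapse = "")
}

#' Approximate residue-to-exon map for the 48-exon gene
#'
#' Returns the exon number plausibly encoding each residue. The map is exact
#' where the exon structure is pinned by the architecture (exon 1 encodes
#' residues 1-95, exon 22 the EGF domain, exons 23-33 the eleven CR repeats,
#' exon 48 the residues from the transmembrane segment onward) and linear
#' interpolation elsewhere. Intended for simulation and display; real data
#' should carry its own exon annotation.
#'
#' @param position Integer vector of residue indices.
#' @param arch A `sorl_architecture`.
#' @return Integer vector of exon numbers in 1..48.
#' @export
residue_exon <- function(position, arch = sorl1_architecture()) {
  position <- as.integer(position)
  exon <- rep(NA_integer_, length(position))
  exon[position <= 95L] <- 1L
  cr <- arch$repeats[arch$repeats$repeat_class == "CR", ]
  # region between exon 1 and the EGF domain: exons 2..21 spread linearly
  mid <- position > 95L & position < 1014L
  exon[mid] <- 2L + as.integer(floor((position[mid] - 96L) / ((1014L - 96L) / 20)))
  exon[position >= 1014L & position <= 1074L] <- 22L
  in_cr_gap <- position > 1074L & position < 1551L
  exon[in_cr_gap] <- 23L + pmin(10L, as.integer(floor((position[in_cr_gap] - 1075L) / 43.3)))
  for (j in seq_len(nrow(cr))) {
    sel <- position >= cr$start[j] & position <= cr$end[j]
    exon[sel] <- 22L + cr$index[j]
  }
  late <- position > 1550L & position < 2122L
  exon[late] <- 34L + as.integer(floor((position[late] - 1551L) / ((2122L - 1551L) / 14)))
  exon[position >= 2122L] <- 48L
  pmin(pmax(exon, 1L), 48L)
}

#' @export
print.sorl_architecture <- function(x, ...) {
  cat("<sorl_architecture>", x$name, "-", x$protein_length, "residues\n")
  cat("  segments:", nrow(x$segments), " repeats:", nrow(x$repeats),
      " anchors:", nrow(x$anchors), "\n")
  cat("  reference sequence:", if (is.null(x$reference_sequence)) "absent" else "present", "\n")
  invisible(x)
}
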