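AA3_TO_1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q", Glu = "E",
  Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K", Met = "M", Phe = "F",
  Pro = "P", Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
  Ter = "*", Sec = "U"
)
AA1 <- unname(AA3_TO_1[1:20])

#' Parse an HGVS protein-change string
#'
#' Accepts the short one-letter form used throughout the package
#' (`"p.Y391C"`, `"Y391C"`, `"p.R866X"`, `"p.S577fs"`) as well as the
#' three-letter HGVS form (`"p.Arg866Ter"`, `"p.(Tyr391Cys)"`). Terminator
#' tokens `X`, `*` and `Ter` map to a nonsense change; an `fs` suffix maps to
#' frameshift. Two adjacent substitutions written `"p.D100G;E101K"` parse into
#' a primary change plus `second_change` fields (used for merged in-cis
#' pairs).
#'
#' @param text A single HGVS-p string.
#' @param protein_length Optional protein length; positions outside
#'   `1..protein_length` raise a bounds error.
#' @return A list of class `protein_change` with fields `ref_aa`, `position`,
#'   `alt_aa`, `change_kind` (`"missense"`, `"nonsense"`, `"frameshift"`) and
#'   optionally `ref_aa2`, `alt_aa2` for a merged adjacent substitution.
#' @export
parse_hgvs_p <- function(text, protein_length = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- text
  s <- gsub("^p\\.", "", trimws(text))
  s <- gsub("^\\((.*)\\)$", "\\1", s)

  if (grepl(";", s, fixed = TRUE)) {
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("cannot parse HGVS-p token: ", raw, call. = FALSE)
    first <- parse_hgvs_p(parts[1], protein_length)
    second <- parse_hgvs_p(parts[2], protein_length)
    if (first$change_kind != "missense" || second$change_kind != "missense" ||
        second$position != first$position + 1L) {
      stop("second change must be an adjacent missense substitution: ", raw, call. = FALSE)
    }
    first$ref_aa2 <- second$ref_aa
    first$alt_aa2 <- second$alt_aa
    return(first)
  }

  s1 <- convert_aa3(s)
  m <- regmatches(s1,
    regexec("^([A-Z\\*])([0-9]+)([A-Z\\*\\?]?fs.*|fs.*|[A-Z\\*\\?]|Ter)?$", s1))[[1]]
  if (!length(m)) stop("cannot parse HGVS-p token: ", raw, call. = FALSE)
  ref_aa <- m[2]
  position <- as.integer(m[3])
  tail <- m[4]
  if (position < 1L) stop("residue position must be >= 1: ", raw, call. = FALSE)
  if (!is.null(protein_length) && position > protein_length) {
    stop("residue position ", position, " exceeds protein length ", protein_length,
         call. = FALSE)
  }
  if (!ref_aa %in% AA1) stop("unknown reference amino acid in: ", raw, call. = FALSE)

  if (is.na(tail) || tail == "" ) stop("cannot parse HGVS-p token: ", raw, call. = FALSE)
  if (grepl("fs", tail, fixed = TRUE)) {
    out <- list(ref_aa = ref_aa, position = position, alt_aa = NA_character_,
                change_kind = "frameshift")
  } else if (tail %in% c("X", "*", "Ter")) {
    out <- list(ref_aa = ref_aa, position = position, alt_aa = "*",
                change_kind = "nonsense")
  } else if (tail %in% AA1) {
    if (tail == ref_aa) stop("reference and alternate amino acid identical: ", raw, call. = FALSE)
    out <- list(ref_aa = ref_aa, position = position, alt_aa = tail,
                change_kind = "missense")
  } else {
    stop("cannot parse HGVS-p token: ", raw, call. = FALSE)
  }
  structure(out, class = "protein_change")
}

convert_aa3 <- function(s) {
  # replace three-letter codes (incl. Ter) greedily; one-letter strings pass through
  if (!grepl("[a-z]", s) || grepl("^..?[0-9]", s)) {
    # allow 'fs' suffix lowercase on one-letter form
    return(s)
  }
  for (code in names(AA3_TO_1)) {
    s <- gsub(code, AA3_TO_1[[code]], s, fixed = TRUE)
  }
  s
}

#' Format a protein change back to canonical HGVS-p
#'
#' Inverse of [parse_hgvs_p()]: produces the short one-letter canonical form
#' (`"p.Y391C"`, `"p.R866X"`, `"p.S577fs"`, `"p.D100G;E101K"`), which
#' re-parses to an equal value.
#'
#' @param change A `protein_change`.
#' @return A single character string.
#' @export
format_hgvs_p <- function(change) {
  stopifnot(inherits(change, "protein_change"))
  core <- switch(change$change_kind,
    missense = paste0(change$ref_aa, change$position, change$alt_aa),
    nonsense = paste0(change$ref_aa, change$position, "X"),
    frameshift = paste0(change$ref_aa, change$position, "fs"),
    stop("unsupported change kind: ", change$change_kind)
  )
  if (!is.null(change$ref_aa2) && !is.na(change$ref_aa2)) {
    core <- paste0(core, ";", change$ref_aa2, change$position + 1L, change$alt_aa2)
  }
  paste0("p.", core)
}

#' @export
print.protein_change <- function(x, ...) {
  cat("<protein_change>", format_hgvs_p(x), "-", x$change_kind, "\n")
  invisible(x)
}
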