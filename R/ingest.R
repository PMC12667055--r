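VARIANT_COLUMNS <- c(
  "variant_id", "hgvs_p", "consequence", "exon", "revel", "loftee",
  "splice_score", "gnomad_maf"
)

#' Assemble a case/control cohort object
#'
#' Bundles the three tables every analysis stage operates on: per-individual
#' phenotypes, the normalized variant table, and the long carrier table
#' (posterior dosages). Carrier identifiers must exist in the individual
#' table; ages must be positive (ages recorded as "> 89" are stored as 90 at
#' read time).
#'
#' @param individuals Tibble with columns `id`, `status` ("case"/"control"),
#'   `aao_or_age` (age at onset for cases, age at last screening for
#'   controls), `apoe_e4`, `apoe_e2` (allele counts 0/1/2 or NA),
#'   `pc1`..`pc6`, `cohort_label`.
#' @param variants Tibble as produced by [normalize_variants()].
#' @param carriers Tibble with columns `variant_id`, `id`, `dosage` in
#'   `[0, 2]`.
#' @param exclusions List with elements `exons` (integer vector) and
#'   `residue_ranges` (list of `start`/`end` pairs); defaults to the packaged
#'   exclusion of exon 1 / residues 1-95.
#' @return An object of class `sorl_cohort`.
#' @export
sorl_cohort <- function(individuals, variants, carriers,
                        exclusions = default_exclusions()) {
  individuals <- tibble::as_tibble(individuals)
  variants <- tibble::as_tibble(variants)
  carriers <- tibble::as_tibble(carriers)
  stopifnot(all(c("id", "status", "aao_or_age") %in% names(individuals)))
  if (!all(individuals$status %in% c("case", "control"))) {
    stop("status must be 'case' or 'control'", call. = FALSE)
  }
  if (any(!is.na(individuals$aao_or_age) & individuals$aao_or_age <= 0)) {
    stop("ages must be positive", call. = FALSE)
  }
  if (nrow(carriers)) {
    stopifnot(all(c("variant_id", "id", "dosage") %in% names(carriers)))
    missing_ids <- setdiff(carriers$id, individuals$id)
    if (length(missing_ids)) {
      stop("carrier ids not present in individual table: ",
           paste(utils::head(missing_ids, 3), collapse = ", "), call. = FALSE)
    }
    if (any(carriers$dosage < 0 | carriers$dosage > 2)) {
      stop("dosages must lie in [0, 2]", call. = FALSE)
    }
  }
  structure(
    list(individuals = individuals, variants = variants, carriers = carriers,
         exclusions = exclusions),
    class = "sorl_cohort"
  )
}

default_exclusions <- function() {
  list(exons = 1L, residue_ranges = list(list(start = 1L, end = 95L)))
}

#' @export
print.sorl_cohort <- function(x, ...) {
  n_case <- sum(x$individuals$status == "case")
  cat("<sorl_cohort>", nrow(x$individuals), "individuals (", n_case, "cases /",
      nrow(x$individuals) - n_case, "controls ),", nrow(x$variants), "variants,",
      nrow(x$carriers), "carrier records\n")
  invisible(x)
}

#' Normalize a raw variant table
#'
#' Parses the `hgvs_p` column with [parse_hgvs_p()] into `ref_aa`, `position`,
#' `alt_aa` and `change_kind`, taking `consequence` as authoritative for
#' non-substitution classes (splice and other non-coding consequences carry no
#' protein change). Missing REVEL on a missense variant is retained and later
#' classified conservatively.
#'
#' @param variants Tibble with at least `variant_id` and either `hgvs_p` or
#'   `consequence`; recognised columns are
#'   `r paste(VARIANT_COLUMNS, collapse = ", ")`.
#' @param protein_length Bound for positional sanity checks.
#' @return The input tibble with parsed columns appended.
#' @export
normalize_variants <- function(variants, protein_length = 2214L) {
  variants <- tibble::as_tibble(variants)
  for (col in setdiff(VARIANT_COLUMNS, names(variants))) {
    variants[[col]] <- switch(col,
      exon = NA_integer_, loftee = 0L,
      hgvs_p = NA_character_, consequence = NA_character_,
      NA_real_
    )
  }
  parsed <- lapply(seq_len(nrow(variants)), function(i) {
    h <- variants$hgvs_p[i]
    if (is.na(h) || h == "") {
      return(list(ref_aa = NA_character_, position = NA_integer_,
                  alt_aa = NA_character_, change_kind = NA_character_,
                  ref_aa2 = NA_character_, alt_aa2 = NA_character_))
    }
    pc <- parse_hgvs_p(h, protein_length)
    list(ref_aa = pc$ref_aa, position = pc$position, alt_aa = pc$alt_aa,
         change_kind = pc$change_kind,
         ref_aa2 = pc$ref_aa2 %||% NA_character_,
         alt_aa2 = pc$alt_aa2 %||% NA_character_)
  })
  for (col in c("ref_aa", "alt_aa", "change_kind", "ref_aa2", "alt_aa2")) {
    variants[[col]] <- vapply(parsed, function(p) p[[col]], character(1))
  }
  variants$position <- vapply(parsed, function(p) as.integer(p$position), integer(1))
  # consequence column wins for non-substitution classes
  override <- !is.na(variants$consequence) &
    variants$consequence %in% c("splice", "other", "synonymous", "non_coding")
  variants$change_kind[override] <- ifelse(
    variants$consequence[override] == "splice", "splice", "other"
  )
  fill <- is.na(variants$change_kind) & !is.na(variants$consequence)
  variants$change_kind[fill] <- variants$consequence[fill]
  variants$loftee <- as.integer(variants$loftee)
  variants
}

#' Merge juxtaposed in-cis substitutions into single records
#'
#' Two records whose protein changes are adjacent missense substitutions,
#' whose phase is confirmed cis, and which share exactly the same carriers are
#' replaced by one record carrying both substitutions; the merged REVEL score
#' is the minimum of the pair (the conservative convention for consecutive
#' substitutions that ensemble scores cannot annotate jointly). Adjacent pairs
#' of unknown phase are left unmerged and flagged `phase_unknown`.
#'
#' @param variants Normalized variant tibble sorted by residue position.
#' @param carriers Carrier tibble.
#' @param phase_info Tibble with columns `variant_id1`, `variant_id2`,
#'   `phase` in `c("cis", "trans", "unknown")`. Pairs not listed are treated
#'   as unknown.
#' @return A list with elements `variants` (with a `flags` column) and
#'   `carriers`.
#' @export
merge_cis_adjacent <- function(variants, carriers,
                               phase_info = tibble::tibble(
                                 variant_id1 = character(),
                                 variant_id2 = character(),
                                 phase = character())) {
  variants <- tibble::as_tibble(variants)
  if (!"flags" %in% names(variants)) variants$flags <- ""
  if (nrow(variants) < 2L) return(list(variants = variants, carriers = carriers))

  ord <- order(variants$position)
  variants <- variants[ord, ]
  drop <- rep(FALSE, nrow(variants))

  for (i in seq_len(nrow(variants) - 1L)) {
    j <- i + 1L
    if (drop[i] || drop[j]) next
    a <- variants[i, ]; b <- variants[j, ]
    adjacent <- !is.na(a$position) && !is.na(b$position) &&
      b$position == a$position + 1L &&
      identical(a$change_kind, "missense") && identical(b$change_kind, "missense")
    if (!adjacent) next
    ph <- lookup_phase(phase_info, a$variant_id, b$variant_id)
    same_carriers <- setequal(
      carrier_set(carriers, a$variant_id),
      carrier_set(carriers, b$variant_id)
    )
    if (identical(ph, "cis") && same_carriers) {
      merged <- a
      merged$variant_id <- paste(a$variant_id, b$variant_id, sep = "+")
      merged$hgvs_p <- paste0(
        "p.", a$ref_aa, a$position, a$alt_aa, ";", b$ref_aa, b$position, b$alt_aa
      )
      merged$ref_aa2 <- b$ref_aa
      merged$alt_aa2 <- b$alt_aa
      merged$revel <- suppressWarnings(min(c(a$revel, b$revel), na.rm = TRUE))
      if (!is.finite(merged$revel)) merged$revel <- NA_real_
      merged$gnomad_maf <- suppressWarnings(max(c(a$gnomad_maf, b$gnomad_maf), na.rm = TRUE))
      if (!is.finite(merged$gnomad_maf)) merged$gnomad_maf <- NA_real_
      merged$flags <- add_flag(a$flags, "merged_cis")
      variants[i, ] <- merged
      drop[j] <- TRUE
      carriers$variant_id[carriers$variant_id == b$variant_id] <- NA_character_
      carriers$variant_id[carriers$variant_id == a$variant_id] <- merged$variant_id
    } else if (!identical(ph, "trans")) {
      variants$flags[i] <- add_flag(variants$flags[i], "phase_unknown")
      variants$flags[j] <- add_flag(variants$flags[j], "phase_unknown")
    }
  }
  carriers <- carriers[!is.na(carriers$variant_id), , drop = FALSE]
  list(variants = variants[!drop, , drop = FALSE], carriers = carriers)
}

lookup_phase <- function(phase_info, id1, id2) {
  if (!nrow(phase_info)) return("unknown")
  hit <- (phase_info$variant_id1 == id1 & phase_info$variant_id2 == id2) |
    (phase_info$variant_id1 == id2 & phase_info$variant_id2 == id1)
  if (!any(hit)) "unknown" else phase_info$phase[which(hit)[1]]
}

add_flag <- function(flags, new) {
  flags[is.na(flags)] <- ""
  ifelse(flags == "", new,
         ifelse(grepl(new, flags, fixed = TRUE), flags, paste(flags, new, sep = ";")))
}

#' Carriers of a variant above the posterior-dosage threshold
#'
#' @param carriers Carrier tibble (`variant_id`, `id`, `dosage`) or a
#'   `sorl_cohort`.
#' @param variant_id Variant identifier.
#' @param dosage_threshold Strict lower bound on posterior dosage; an
#'   individual is a carrier only when `dosage > dosage_threshold`
#'   (default 0.5).
#' @return Character vector of individual ids.
#' @export
carrier_set <- function(carriers, variant_id, dosage_threshold = 0.5) {
  if (inherits(carriers, "sorl_cohort")) carriers <- carriers$carriers
  stopifnot(dosage_threshold > 0, dosage_threshold < 2)
  sel <- carriers$variant_id == variant_id & carriers$dosage > dosage_threshold
  unique(carriers$id[sel])
}

#' Effective minor allele frequency with fallback to the sample
#'
#' Returns the reference-database (non-neuro popmax) MAF when annotated, and
#' otherwise the in-sample carrier frequency, `carriers / individuals`. The
#' carrier-based denominator is the definition under which 21 carriers in a
#' 40,852-individual cohort sit just above the 0.05% rare-variant threshold;
#' an allele-based frequency (`carriers / 2N`) is available via
#' `denominator = "alleles"`.
#'
#' @param variants Normalized variant tibble (or a single-row subset).
#' @param cohort A `sorl_cohort`.
#' @param dosage_threshold Carrier dosage threshold.
#' @param denominator `"individuals"` (default) or `"alleles"`.
#' @return Tibble with `variant_id`, `maf`, `maf_source`
#'   (`"gnomad"`/`"sample"`).
#' @export
effective_maf <- function(variants, cohort, dosage_threshold = 0.5,
                          denominator = c("individuals", "alleles")) {
  denominator <- match.arg(denominator)
  n_ind <- nrow(cohort$individuals)
  stopifnot(n_ind > 0)
  denom <- if (denominator == "individuals") n_ind else 2L * n_ind
  counts <- cohort$carriers[cohort$carriers$dosage > dosage_threshold, , drop = FALSE]
  tab <- table(counts$variant_id)
  n_carriers <- as.integer(tab[variants$variant_id])
  n_carriers[is.na(n_carriers)] <- 0L
  has_gnomad <- !is.na(variants$gnomad_maf)
  tibble::tibble(
    variant_id = variants$variant_id,
    maf = ifelse(has_gnomad, variants$gnomad_maf, n_carriers / denom),
    maf_source = ifelse(has_gnomad, "gnomad", "sample")
  )
}

#' Read a variant table from TSV
#'
#' Expected columns: `variant_id`, `hgvs_p`, `consequence`, `exon`, `revel`,
#' `loftee`, `splice_score`, `gnomad_maf` (missing optional columns are
#' filled). Returns a normalized variant tibble.
#'
#' @param path TSV file.
#' @param protein_length Positional bound for HGVS parsing.
#' @export
read_variant_table <- function(path, protein_length = 2214L) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  normalize_variants(raw, protein_length)
}

#' Write a normalized variant table to TSV
#' @param variants Variant tibble.
#' @param path Output file.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(variants, path, progress = FALSE)
  invisible(path)
}

#' Read a cohort (phenotype) table from TSV
#'
#' Columns: `id`, `status`, `aao_or_age`, `apoe_e4`, `apoe_e2`, `pc1`..`pc6`,
#' `cohort`. Ages recorded as the censored label `"> 89"` (or `">89"`) are
#' stored as 90 before any analysis.
#'
#' @param path TSV file.
#' @return Tibble of individuals.
#' @export
read_cohort_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(aao_or_age = readr::col_character()))
  age <- trimws(raw$aao_or_age)
  age[age %in% c("> 89", ">89")] <- "90"
  raw$aao_or_age <- as.numeric(age)
  if ("cohort" %in% names(raw) && !"cohort_label" %in% names(raw)) {
    raw <- dplyr::rename(raw, cohort_label = "cohort")
  }
  tibble::as_tibble(raw)
}

#' Read annotated variants and carriers from a VCF file
#'
#' Reads a (GRCh37-convention) VCF with per-variant annotations in INFO keys
#' `HGVSP`, `CSQ_CLASS` (consequence), `EXON`, `REVEL`, `LOFTEE`, `SPLICEAI`
#' and `GNOMAD_NN_POPMAX`, and derives carrier dosages from the genotype
#' matrix (the `DS` FORMAT field when present, otherwise the alternate-allele
#' count of `GT`). The result normalizes to the same variant/carrier tables
#' as the TSV path.
#'
#' @param path VCF file (plain or bgzipped).
#' @param protein_length Positional bound for HGVS parsing.
#' @return List with `variants` (normalized tibble) and `carriers` (long
#'   dosage tibble).
#' @export
read_variant_vcf <- function(path, protein_length = 2214L) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(v))
  info_field <- function(key) {
    vals <- vcfR::extract.info(v, element = key)
    if (is.null(vals)) rep(NA_character_, nrow(fix)) else vals
  }
  variants <- tibble::tibble(
    variant_id = paste0(fix$CHROM, ":", fix$POS, ":", fix$REF, ">", fix$ALT),
    hgvs_p = info_field("HGVSP"),
    consequence = info_field("CSQ_CLASS"),
    exon = suppressWarnings(as.integer(info_field("EXON"))),
    revel = suppressWarnings(as.numeric(info_field("REVEL"))),
    loftee = {
      lf <- suppressWarnings(as.integer(info_field("LOFTEE")))
      ifelse(is.na(lf), 0L, lf)
    },
    splice_score = suppressWarnings(as.numeric(info_field("SPLICEAI"))),
    gnomad_maf = suppressWarnings(as.numeric(info_field("GNOMAD_NN_POPMAX")))
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    ds <- apply(gt, 2, function(col) {
      vapply(col, function(g) {
        if (is.na(g)) return(0)
        sum(as.integer(strsplit(gsub("\\|", "/", g), "/")[[1]]) > 0)
      }, numeric(1))
    })
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(variants),
                                       dimnames = list(NULL, colnames(gt)))
  }
  if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(variants),
                                     dimnames = list(NULL, colnames(gt)))
  hit <- which(!is.na(ds) & ds > 0, arr.ind = TRUE)
  carriers <- tibble::tibble(
    variant_id = variants$variant_id[hit[, 1]],
    id = colnames(ds)[hit[, 2]],
    dosage = ds[hit]
  )
  list(variants = normalize_variants(variants, protein_length),
       carriers = tibble::as_tibble(carriers))
}
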