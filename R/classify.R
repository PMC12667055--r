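#' Priority categories, highest first
#'
#' The total order used when one individual carries several rare variants:
#' protein-truncating first, then high-, moderate-, low- and no-priority
#' missense, then less-rare variants; non-carriers are `WT`.
#' @export
CATEGORY_LEVELS <- c("PTV", "HPV", "MPV", "LPV", "NPV", "LESS_RARE", "WT")

#' Load a priority rule set from a structured configuration
#'
#' The rule block of the configuration holds the score thresholds (REVEL,
#' MAF, carrier dosage, splice-review), the exon list for the
#' truncating-variant rescue, the analysis exclusion regions, and the residue
#' rules. Each residue rule names a scope (a segment or a repeat class), a
#' trigger (`fixed_position` on within-repeat positions,
#' `cysteine_gain_or_loss`, or `revel_at_least`) and a priority (`high` or
#' `moderate`). Every rule scope is checked against the architecture.
#'
#' @param config_source Path to a JSON configuration or an equivalent list
#'   (the packaged default holds architecture and rules in one file).
#' @param arch Architecture used to validate rule scopes.
#' @return An object of class `sorl_rules`.
#' @export
load_rules <- function(config_source, arch = sorl1_architecture()) {
  cfg <- read_config(config_source)
  th <- cfg$thresholds %||% list()
  rules <- dplyr::bind_rows(lapply(cfg$rules, function(r) {
    tibble::tibble(
      label = r$label, scope_type = r$scope_type, scope = r$scope,
      trigger = r$trigger,
      positions = list(as.integer(unlist(r$positions))),
      priority = r$priority
    )
  }))
  stopifnot(all(rules$priority %in% c("high", "moderate")),
            all(rules$trigger %in% c("fixed_position", "cysteine_gain_or_loss",
                                     "revel_at_least")))
  bad_seg <- rules$scope[rules$scope_type == "segment" &
                           !rules$scope %in% arch$segments$name]
  bad_rep <- rules$scope[rules$scope_type == "repeat" &
                           !rules$scope %in% arch$repeats$repeat_class]
  if (length(bad_seg) || length(bad_rep)) {
    stop("rule scope not present in architecture: ",
         paste(unique(c(bad_seg, bad_rep)), collapse = ", "), call. = FALSE)
  }
  if (any(rules$trigger == "fixed_position" &
          vapply(rules$positions, length, integer(1)) == 0L)) {
    stop("fixed_position rules need a non-empty position list", call. = FALSE)
  }
  excl <- cfg$exclusions %||% list()
  structure(
    list(
      revel_threshold = th$revel_threshold %||% 0.5,
      maf_threshold = th$maf_threshold %||% 5e-4,
      dosage_threshold = th$dosage_threshold %||% 0.5,
      splice_review_threshold = th$splice_review_threshold %||% 0.2,
      ptv_exon_rescue = as.integer(unlist(cfg$ptv_exon_rescue %||% 48L)),
      exclusions = list(
        exons = as.integer(unlist(excl$exons %||% 1L)),
        residue_ranges = lapply(excl$residue_ranges %||%
                                  list(list(start = 1, end = 95)),
                                function(r) list(start = as.integer(r$start),
                                                 end = as.integer(r$end)))
      ),
      rules = rules
    ),
    class = "sorl_rules"
  )
}

#' The packaged default rule set
#' @return A `sorl_rules` object matching [sorl1_architecture()].
#' @export
sorl1_rules <- function() {
  rs <- get0(".sorl1_rules_cache", envir = .sorldmdm_cache)
  if (!is.null(rs)) return(rs)
  path <- system.file("extdata", "sorl1_default.json", package = "sorldmdm")
  rs <- load_rules(path)
  assign(".sorl1_rules_cache", rs, envir = .sorldmdm_cache)
  rs
}

#' Is a record a protein-truncating variant?
#'
#' A record is a PTV when the loss-of-function annotation flag is set, or
#' when it is a nonsense/frameshift change in one of the rescue exons (the
#' last exon encodes trafficking motifs the upstream annotation tool does not
#' cover). Splice variants without the flag but with a splice-prediction
#' score at or above the review threshold are *not* promoted automatically:
#' they return `ptv = FALSE` with `review = TRUE`, since promotion is an
#' explicit curation decision.
#'
#' @param record One-row variant tibble (normalized).
#' @param rules A `sorl_rules`.
#' @return List with logical fields `ptv` and `review`.
#' @export
is_ptv <- function(record, rules = sorl1_rules()) {
  loftee <- record$loftee %||% 0L
  if (!is.na(loftee) && loftee == 1L) return(list(ptv = TRUE, review = FALSE))
  kind <- record$change_kind
  if (!is.na(kind) && kind %in% c("nonsense", "frameshift") &&
      !is.na(record$exon) && record$exon %in% rules$ptv_exon_rescue) {
    return(list(ptv = TRUE, review = FALSE))
  }
  if (!is.na(kind) && kind == "splice" &&
      !is.na(record$splice_score) &&
      record$splice_score >= rules$splice_review_threshold) {
    return(list(ptv = FALSE, review = TRUE))
  }
  list(ptv = FALSE, review = FALSE)
}

#' Does a substitution gain or lose a cysteine?
#'
#' Checks the reference sequence at the stated position (a mismatch between
#' the record and the reference is a data-integrity error, not a
#' classification outcome) and reports `"gain"` when a non-cysteine becomes
#' cysteine, `"loss"` when a cysteine is substituted away, else `"none"`.
#'
#' @param refseq Reference amino-acid string.
#' @param ref_aa,position,alt_aa The substitution.
#' @return `"gain"`, `"loss"` or `"none"`.
#' @export
cysteine_change <- function(refseq, ref_aa, position, alt_aa) {
  actual <- substr(refseq, position, position)
  if (!identical(actual, ref_aa)) {
    stop("reference mismatch at residue ", position, ": sequence has '", actual,
         "', record states '", ref_aa, "'", call. = FALSE)
  }
  if (is.na(alt_aa)) return("none")
  if (ref_aa != "C" && alt_aa == "C") return("gain")
  if (ref_aa == "C" && alt_aa != "C") return("loss")
  "none"
}

in_exclusion <- function(record, rules) {
  if (!is.na(record$exon) && record$exon %in% rules$exclusions$exons) return(TRUE)
  if (!is.na(record$position)) {
    for (rg in rules$exclusions$residue_ranges) {
      if (record$position >= rg$start && record$position <= rg$end) return(TRUE)
    }
  }
  FALSE
}

match_rules <- function(record, ctx, arch, rules, priority) {
  sub <- rules$rules[rules$rules$priority == priority, , drop = FALSE]
  refseq <- arch$reference_sequence
  for (k in seq_len(nrow(sub))) {
    rule <- sub[k, ]
    in_scope <- if (rule$scope_type == "segment") {
      identical(ctx$segment, rule$scope)
    } else {
      identical(ctx$repeat_class, rule$scope)
    }
    if (!in_scope) next
    if (rule$trigger == "fixed_position") {
      if (rule$scope_type == "repeat" &&
          !is.na(ctx$repeat_position) &&
          ctx$repeat_position %in% rule$positions[[1]]) {
        return(list(label = rule$label, subcategory = rule$label))
      }
    } else if (rule$trigger == "cysteine_gain_or_loss") {
      if (is.null(refseq)) {
        stop("cysteine rules require a reference sequence in the architecture",
             call. = FALSE)
      }
      cys <- cysteine_change(refseq, record$ref_aa, record$position, record$alt_aa)
      if (cys == "none" && !is.na(record$ref_aa2 %||% NA_character_)) {
        cys <- cysteine_change(refseq, record$ref_aa2, record$position + 1L,
                               record$alt_aa2)
      }
      if (cys != "none") {
        return(list(label = rule$label,
                    subcategory = paste0(rule$label, "_", cys)))
      }
    } else if (rule$trigger == "revel_at_least") {
      if (!is.na(record$revel) && record$revel >= rules$revel_threshold) {
        return(list(label = rule$label, subcategory = rule$label))
      }
    }
  }
  NULL
}

classify_one <- function(record, maf, arch, rules) {
  flags <- character(0)
  result <- function(category, subcategory = NA_character_,
                     rule = NA_character_) {
    tibble::tibble(
      category = category, subcategory = subcategory, triggering_rule = rule,
      needs_manual_review = "needs_review" %in% flags,
      flags = paste(flags, collapse = ";")
    )
  }
  if (in_exclusion(record, rules)) return(result("EXCLUDED"))
  if (!is.na(maf) && maf >= rules$maf_threshold) return(result("LESS_RARE"))

  ptv <- is_ptv(record, rules)
  if (ptv$review) flags <- c(flags, "needs_review")
  if (ptv$ptv) return(result("PTV"))

  kind <- record$change_kind
  if (is.na(kind) || kind != "missense") {
    if (!is.na(kind) && kind == "splice") flags <- union(flags, "needs_review")
    return(result("NPV"))
  }

  ctx <- locate_one(arch, record$position)
  hi <- match_rules(record, ctx, arch, rules, "high")
  if (!is.null(hi)) return(result("HPV", hi$subcategory, hi$label))

  mod <- match_rules(record, ctx, arch, rules, "moderate")
  if (!is.null(mod)) return(result("MPV", mod$subcategory, mod$label))

  if (is.na(record$revel)) {
    flags <- c(flags, "revel_missing")
    return(result("NPV"))
  }
  if (record$revel >= rules$revel_threshold && !identical(ctx$segment, "VPS10p")) {
    return(result("LPV", "revel", "revel_threshold"))
  }
  result("NPV")
}

locate_one <- function(arch, position) {
  ctx <- locate_residue(arch, position)
  list(position = ctx$position[1], segment = ctx$segment[1],
       repeat_class = ctx$repeat_class[1], repeat_index = ctx$repeat_index[1],
       repeat_position = ctx$repeat_position[1])
}

#' Classify variants into priority categories
#'
#' Applies the full decision order to each variant: (1) analysis-exclusion
#' regions; (2) the rare/less-rare MAF gate using [effective_maf()]; (3) the
#' protein-truncating test [is_ptv()]; (4) non-missense residuals to NPV
#' (splice changes flagged for review); (5) high-priority residue rules
#' (calcium cages, Asx-turn, conserved-cysteine gains/losses, YWTD motif and
#' conserved blade positions, 3Fn tyrosine corner, glycines and core
#' residues, and the REVEL gate inside the VPS10p/10CC domains); (6)
#' moderate-priority rules (3Fn N-terminal prolines); (7) the LPV REVEL gate
#' outside the VPS10p domain; (8) NPV. A missense record whose REVEL score is
#' missing where a REVEL rule would apply is classified conservatively as NPV
#' and flagged `revel_missing`.
#'
#' @param variants Normalized variant tibble.
#' @param cohort A `sorl_cohort` (supplies in-sample frequencies).
#' @param arch A `sorl_architecture` with a reference sequence.
#' @param rules A `sorl_rules`.
#' @return The variant tibble with `maf`, `maf_source`, `category`,
#'   `subcategory`, `triggering_rule`, `needs_manual_review` and `flags`
#'   columns appended.
#' @export
classify_variants <- function(variants, cohort, arch = sorl1_architecture(),
                              rules = sorl1_rules()) {
  mafs <- effective_maf(variants, cohort, rules$dosage_threshold)
  out <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    out[[i]] <- classify_one(variants[i, ], mafs$maf[i], arch, rules)
  }
  dplyr::bind_cols(variants,
                   tibble::tibble(maf = mafs$maf, maf_source = mafs$maf_source),
                   dplyr::bind_rows(out))
}

#' Highest-priority category among carried variants
#'
#' An individual carrying several rare variants is grouped by the variant
#' with the highest priority under the order
#' `PTV > HPV > MPV > LPV > NPV > LESS_RARE`; carrying nothing is `WT`.
#'
#' @param categories Character vector of carried categories (possibly empty).
#' @return A single category string.
#' @export
assign_carrier_category <- function(categories) {
  categories <- categories[!is.na(categories) & categories != "EXCLUDED"]
  if (!length(categories)) return("WT")
  CATEGORY_LEVELS[min(match(categories, CATEGORY_LEVELS))]
}

#' Assign every individual a carrier category and subcategory
#'
#' Joins carriers (posterior dosage above threshold) to classified variants
#' and reduces each individual to the highest-priority carried variant;
#' analysis-excluded variants do not contribute. The subcategory is the one
#' of the top-priority variant (ties broken by variant-table order).
#'
#' @param cohort A `sorl_cohort`.
#' @param classified Output of [classify_variants()].
#' @param dosage_threshold Carrier dosage threshold.
#' @return The individual tibble with `carrier_category` and
#'   `carrier_subcategory` columns.
#' @export
assign_carriers <- function(cohort, classified,
                            dosage_threshold = sorl1_rules()$dosage_threshold) {
  carried <- cohort$carriers[cohort$carriers$dosage > dosage_threshold, , drop = FALSE]
  joined <- dplyr::inner_join(
    carried,
    classified[, c("variant_id", "category", "subcategory")],
    by = "variant_id"
  )
  joined <- joined[!joined$category %in% "EXCLUDED", , drop = FALSE]
  joined$rank <- match(joined$category, CATEGORY_LEVELS)
  top <- joined |>
    dplyr::group_by(.data$id) |>
    dplyr::slice_min(.data$rank, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  out <- dplyr::left_join(
    cohort$individuals,
    top[, c("id", "category", "subcategory")],
    by = "id"
  )
  out$carrier_category <- ifelse(is.na(out$category), "WT", out$category)
  out$carrier_subcategory <- out$subcategory
  out$category <- NULL
  out$subcategory <- NULL
  out
}
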