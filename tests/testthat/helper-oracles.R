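# Independent oracles used to cross-check the implementation.

# Exact two-sided Fisher p via explicit combinatorial enumeration (lchoose),
# written independently of the dhyper-based implementation.
oracle_fisher <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  if (n == 0) return(1)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  xs <- lo:hi
  logp <- lchoose(c1, xs) + lchoose(n - c1, r1 - xs) - lchoose(n, r1)
  p <- exp(logp)
  pobs <- p[a - lo + 1]
  sum(p[p <= pobs * (1 + 1e-7)])
}

# Per-margin variant returning the two-sided p for every feasible a at once.
oracle_fisher_margin <- function(r1, c1, n) {
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  xs <- lo:hi
  logp <- lchoose(c1, xs) + lchoose(n - c1, r1 - xs) - lchoose(n, r1)
  p <- exp(logp)
  vapply(seq_along(xs), function(i) sum(p[p <= p[i] * (1 + 1e-7)]), numeric(1))
}

# Flat re-encoding of the written prioritization rules, independent of the
# rule-engine implementation. Takes normalized variants plus their effective
# MAFs and returns a category per variant.
oracle_classify <- function(variants, mafs, arch) {
  refseq <- arch$reference_sequence
  reps <- arch$repeats
  segs <- arch$segments
  out <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if ((!is.na(v$exon) && v$exon == 1L) ||
        (!is.na(v$position) && v$position <= 95L)) {
      out[i] <- "EXCLUDED"; next
    }
    if (!is.na(mafs[i]) && mafs[i] >= 5e-4) { out[i] <- "LESS_RARE"; next }
    is_trunc <- (!is.na(v$loftee) && v$loftee == 1L) ||
      (!is.na(v$change_kind) && v$change_kind %in% c("nonsense", "frameshift") &&
         !is.na(v$exon) && v$exon == 48L)
    if (is_trunc) { out[i] <- "PTV"; next }
    if (is.na(v$change_kind) || v$change_kind != "missense") { out[i] <- "NPV"; next }

    pos <- v$position
    seg <- segs$name[segs$start <= pos & segs$end >= pos]
    rcls <- NA_character_; rpos <- NA_integer_
    hit <- which(reps$start <= pos & reps$end >= pos)
    if (length(hit)) {
      rcls <- reps$repeat_class[hit[1]]
      rpos <- pos - reps$start[hit[1]] + 1L
    }
    cys <- FALSE
    if (!is.na(v$alt_aa)) {
      ref <- substr(refseq, pos, pos)
      cys <- (ref == "C") != (v$alt_aa == "C")
      if (!is.na(v$ref_aa2) && !cys) {
        ref2 <- substr(refseq, pos + 1L, pos + 1L)
        cys <- (ref2 == "C") != (v$alt_aa2 == "C")
      }
    }
    revel_hi <- !is.na(v$revel) && v$revel >= 0.5

    hpv <- (identical(rcls, "CR") && rpos %in% c(37L, 41L, 44L, 47L, 48L)) ||
      (cys && (identical(rcls, "CR") || identical(rcls, "L1_loop") ||
                 identical(rcls, "L2_loop") ||
                 identical(seg, "10CC") || identical(seg, "EGF"))) ||
      (identical(rcls, "YWTD_blade") && rpos %in% c(17:20, 29L, 35L, 9L, 38L)) ||
      (identical(rcls, "3Fn") && rpos %in% c(36L, 96L, 25L, 41L, 77L, 79L, 83L)) ||
      (seg %in% c("VPS10p", "10CC") && revel_hi)
    if (hpv) { out[i] <- "HPV"; next }
    if (identical(rcls, "3Fn") && rpos %in% c(6L, 7L)) { out[i] <- "MPV"; next }
    if (revel_hi && !identical(seg, "VPS10p")) { out[i] <- "LPV"; next }
    out[i] <- "NPV"
  }
  out
}

# Small cohort builder: n_case cases / n_control controls with no carriers.
make_empty_cohort <- function(n_case = 50L, n_control = 50L, variants = NULL) {
  n <- n_case + n_control
  ind <- tibble::tibble(
    id = sprintf("p%05d", seq_len(n)),
    status = rep(c("case", "control"), c(n_case, n_control)),
    aao_or_age = c(stats::runif(n_case, 50, 90), stats::runif(n_control, 50, 95)),
    apoe_e4 = 0L, apoe_e2 = 0L,
    pc1 = 0, pc2 = 0, pc3 = 0, pc4 = 0, pc5 = 0, pc6 = 0,
    cohort_label = "test"
  )
  if (is.null(variants)) {
    variants <- normalize_variants(tibble::tibble(variant_id = character(),
                                                  hgvs_p = character()))
  }
  sorl_cohort(ind, variants,
              tibble::tibble(variant_id = character(), id = character(),
                             dosage = numeric()))
}

# Assigned-carrier table builder for burden tests: counts -> individuals.
make_assigned <- function(case_carriers, case_noncarriers, control_carriers,
                          control_noncarriers, category = "PTV",
                          case_aao = 60) {
  n <- case_carriers + case_noncarriers + control_carriers + control_noncarriers
  tibble::tibble(
    id = sprintf("q%06d", seq_len(n)),
    status = rep(c("case", "control"),
                 c(case_carriers + case_noncarriers,
                   control_carriers + control_noncarriers)),
    aao_or_age = case_aao,
    carrier_category = c(rep(category, case_carriers),
                         rep("WT", case_noncarriers),
                         rep(category, control_carriers),
                         rep("WT", control_noncarriers))
  )
}
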