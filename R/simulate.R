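#' Simulation parameters for synthetic case/control cohorts
#'
#' Defaults describe the full-scale assembled sample the analysis targets:
#' 18,959 cases (about a third with onset before 65) and 21,893 controls;
#' per-category carrier prevalences among controls matching the observed
#' carrier counts; category odds ratios of 17.2 (PTV), 6.1 (HPV), 1.5 (MPV),
#' 1.2 (LPV) and 1.1 (NPV); a wild-type median onset of 72 years with
#' category shifts of -10 (PTV) and -8 (HPV) years; onset dispersion chosen
#' so the 10-90% inter-percentile range spans about 30 years; a 3-fold
#' per-allele APOE-e4 odds ratio with a -5 year per-allele onset shift.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param eoad_fraction Expected fraction of cases with onset below 65; with
#'   the default onset model this emerges at roughly this value and the
#'   parameter is recorded for bookkeeping rather than enforced.
#' @param category_control_prevalence Named carrier frequencies among
#'   controls.
#' @param category_or Named target odds ratios per category.
#' @param wt_aao_median Median onset of wild-type cases (years).
#' @param aao_shift Named onset shifts per category (years).
#' @param aao_dispersion Onset standard deviation (years).
#' @param aao_truncation Onset support (years); a truncated normal.
#' @param apoe_e4_freq,apoe_e2_freq APOE allele frequencies.
#' @param apoe_per_allele_or Disease odds ratio per e4 allele.
#' @param apoe_aao_shift Onset shift per e4 allele (years).
#' @param control_age_mean,control_age_sd Age at last screening of controls.
#' @param pc_noise_scale Scale of the standardized ancestry PCs.
#' @param control_apoe_missing Fraction of controls with APOE set missing.
#' @param seed Integer seed.
#' @return A list of class `sorl_sim_params`.
#' @export
simulation_params <- function(
    n_cases = 18959L, n_controls = 21893L,
    eoad_fraction = 0.32,
    category_control_prevalence = c(PTV = 6 / 21893, HPV = 29 / 21893,
                                    MPV = 61 / 21893, LPV = 85 / 21893,
                                    NPV = 312 / 21893),
    category_or = c(PTV = 17.2, HPV = 6.1, MPV = 1.5, LPV = 1.2, NPV = 1.1),
    wt_aao_median = 72,
    aao_shift = c(PTV = -10, HPV = -8, MPV = 0, LPV = 0, NPV = 0),
    aao_dispersion = 11.7,
    aao_truncation = c(30, 105),
    apoe_e4_freq = 0.14, apoe_e2_freq = 0.08,
    apoe_per_allele_or = 3.0, apoe_aao_shift = -5,
    control_age_mean = 71, control_age_sd = 17,
    pc_noise_scale = 1, control_apoe_missing = 0,
    seed = 1L) {
  stopifnot(n_cases > 0, n_controls > 0,
            all(category_control_prevalence > 0),
            all(category_control_prevalence < 1),
            all(category_or > 0), aao_dispersion > 0,
            apoe_e4_freq + apoe_e2_freq < 1)
  structure(as.list(environment()), class = "sorl_sim_params")
}

SIM_CLASS_PLAN <- list(
  list(class = "ptv_loftee",      kind = "nonsense",  truth = "PTV", rule = NA),
  list(class = "ptv_frameshift",  kind = "frameshift", truth = "PTV", rule = NA),
  list(class = "ptv_exon48",      kind = "nonsense",  truth = "PTV", rule = NA),
  list(class = "splice_review",   kind = "splice",    truth = "NPV", rule = NA),
  list(class = "calcium_cage",    kind = "missense",  truth = "HPV", rule = "calcium_cage"),
  list(class = "asx_turn",        kind = "missense",  truth = "HPV", rule = "asx_turn"),
  list(class = "onc_gain",        kind = "missense",  truth = "HPV", rule = "ONC_cysteine"),
  list(class = "onc_loss",        kind = "missense",  truth = "HPV", rule = "ONC_cysteine"),
  list(class = "tencc_cys",       kind = "missense",  truth = "HPV", rule = "tencc_cysteine"),
  list(class = "egf_cys",         kind = "missense",  truth = "HPV", rule = "egf_cysteine"),
  list(class = "l1_cys",          kind = "missense",  truth = "HPV", rule = "l1_cysteine"),
  list(class = "l2_cys",          kind = "missense",  truth = "HPV", rule = "l2_cysteine"),
  list(class = "ywtd_motif",      kind = "missense",  truth = "HPV", rule = "ywtd_motif"),
  list(class = "ywtd_conserved",  kind = "missense",  truth = "HPV", rule = "ywtd_conserved"),
  list(class = "ywtd_partly",     kind = "missense",  truth = "HPV", rule = "ywtd_partly_conserved"),
  list(class = "fn3_glycine",     kind = "missense",  truth = "HPV", rule = "fn3_glycines"),
  list(class = "fn3_core",        kind = "missense",  truth = "HPV", rule = "fn3_hydrophobic_core"),
  list(class = "tyrosine_corner", kind = "missense",  truth = "HPV", rule = "tyrosine_corner"),
  list(class = "vps10p_revel",    kind = "missense",  truth = "HPV", rule = "vps10p_revel"),
  list(class = "tencc_revel",     kind = "missense",  truth = "HPV", rule = "tencc_revel"),
  list(class = "fn3_proline",     kind = "missense",  truth = "MPV", rule = "fn3_prolines"),
  list(class = "lpv",             kind = "missense",  truth = "LPV", rule = NA),
  list(class = "npv_low_revel",   kind = "missense",  truth = "NPV", rule = NA),
  list(class = "npv_no_revel",    kind = "missense",  truth = "NPV", rule = NA),
  list(class = "less_rare",       kind = "missense",  truth = "LESS_RARE", rule = NA),
  list(class = "excluded_exon1",  kind = "missense",  truth = "EXCLUDED", rule = NA),
  list(class = "synonymous",      kind = "other",     truth = "NPV", rule = NA)
)

#' Simulate a variant table with known truth labels
#'
#' Emits at least one variant for every rule class of the prioritization
#' scheme (truncating variants through the annotation flag, the last-exon
#' rescue and a splice-review case; every fixed-position and cysteine rule;
#' the REVEL gates; moderate-priority prolines; low/no-priority and
#' less-rare fillers; an analysis-excluded first-exon variant) plus
#' randomized fillers up to `n_variants`. Residue identities are read from
#' the architecture's reference sequence so every planted variant is
#' consistent with it, and the intended category and rule are recorded as
#' truth labels, assigned by construction, independently of the classifier.
#'
#' @param arch Architecture with reference sequence.
#' @param rules Rule set (thresholds used to draw scores on the correct side).
#' @param n_variants Total variants to emit (at least the number of planted
#'   classes, else an error lists the uncovered classes).
#' @param seed Integer seed.
#' @return List with `variants` (normalized tibble) and `truth` (tibble with
#'   `variant_id`, `sim_class`, `truth_category`, `truth_rule`).
#' @export
simulate_variant_table <- function(arch = sorl1_architecture(),
                                   rules = sorl1_rules(),
                                   n_variants = 250L, seed = 1L) {
  n_classes <- length(SIM_CLASS_PLAN)
  if (n_variants < n_classes) {
    stop("n_variants = ", n_variants, " cannot cover ", n_classes,
         " required classes: ",
         paste(vapply(SIM_CLASS_PLAN, `[[`, "", "class")[(n_variants + 1):n_classes],
               collapse = ", "), call. = FALSE)
  }
  refseq <- arch$reference_sequence
  stopifnot(!is.null(refseq))
  reps <- arch$repeats
  ref_at <- function(p) substr(refseq, p, p)

  variants <- withr::with_seed(as.integer(seed), {
    plan <- c(SIM_CLASS_PLAN,
              sample(SIM_CLASS_PLAN, n_variants - n_classes, replace = TRUE))
    rows <- lapply(seq_along(plan), function(i) {
      sim_one_variant(plan[[i]], i, arch, rules, reps, ref_at)
    })
    out <- dplyr::bind_rows(rows)
    out$variant_id <- paste0(
      "11:", 121340000L + seq_len(nrow(out)) * 7L,
      ":", sample(c("A", "C", "G", "T"), nrow(out), TRUE),
      ">", sample(c("A", "C", "G", "T"), nrow(out), TRUE)
    )
    out
  })
  truth <- variants[, c("variant_id", "sim_class", "truth_category", "truth_rule")]
  list(
    variants = normalize_variants(
      variants[, intersect(VARIANT_COLUMNS, names(variants))],
      arch$protein_length
    ),
    truth = truth
  )
}

# picks a residue position for a simulated class and builds the raw record
sim_one_variant <- function(cls, i, arch, rules, reps, ref_at) {
  pick_repeat_pos <- function(class_name, rel_positions) {
    r <- reps[reps$repeat_class == class_name, , drop = FALSE]
    fits <- vapply(seq_len(nrow(r)), function(j) {
      any(r$start[j] + rel_positions - 1L <= r$end[j])
    }, logical(1))
    r <- r[fits, , drop = FALSE]
    j <- sample.int(nrow(r), 1L)
    valid <- rel_positions[r$start[j] + rel_positions - 1L <= r$end[j]]
    rel <- valid[sample.int(length(valid), 1L)]
    r$start[j] + rel - 1L
  }
  # neutral repeat positions that trigger no rule and hold no framework cysteine
  neutral_cr <- c(2L, 8L, 15L, 22L, 30L)
  neutral_fn3 <- c(12L, 50L, 55L, 60L, 70L)
  alt_not <- function(ref, forbid = "C") {
    pool <- setdiff(c("A", "G", "S", "T", "V", "L", "N", "Q", "R", "H", "K",
                      "E", "D", "F", "Y", "W", "P", "M", "I"), c(ref, forbid))
    pool[sample.int(length(pool), 1L)]
  }
  rare_maf <- function() stats::runif(1, 1e-5, rules$maf_threshold * 0.9)
  pos <- NA_integer_; hgvs <- NA_character_; consequence <- NA_character_
  revel <- NA_real_; loftee <- 0L; splice <- NA_real_
  maf <- rare_maf(); exon <- NA_integer_

  switch(cls$class,
    ptv_loftee = {
      pos <- sample(200:2100, 1L); loftee <- 1L
      hgvs <- paste0("p.", ref_at(pos), pos, "X"); consequence <- "nonsense"
    },
    ptv_frameshift = {
      pos <- sample(200:2100, 1L); loftee <- 1L
      hgvs <- paste0("p.", ref_at(pos), pos, "fs"); consequence <- "frameshift"
    },
    ptv_exon48 = {
      pos <- sample(2122:2205, 1L); loftee <- 0L
      hgvs <- paste0("p.", ref_at(pos), pos, "X"); consequence <- "nonsense"
    },
    splice_review = {
      consequence <- "splice"; loftee <- 0L
      splice <- stats::runif(1, rules$splice_review_threshold, 1)
    },
    calcium_cage = {
      pos <- pick_repeat_pos("CR", c(37L, 41L, 47L, 48L))
      hgvs <- paste0("p.", ref_at(pos), pos, alt_not(ref_at(pos)))
      revel <- stats::runif(1)
    },
    asx_turn = {
      pos <- pick_repeat_pos("CR", 44L)
      hgvs <- paste0("p.", ref_at(pos), pos, alt_not(ref_at(pos)))
      revel <- stats::runif(1)
    },
    onc_gain = {
      pos <- pick_repeat_pos("CR", neutral_cr)
      hgvs <- paste0("p.", ref_at(pos), pos, "C"); revel <- stats::runif(1)
    },
    onc_loss = {
      pos <- pick_repeat_pos("CR", c(5L, 12L, 19L, 27L, 34L, 45L))
      hgvs <- paste0("p.C", pos, alt_not("C")); revel <- stats::runif(1)
    },
    tencc_cys = {
      pos <- sample(c(625L, 651L, 677L, 703L, 729L), 1L)
      hgvs <- paste0("p.C", pos, alt_not("C"))
      revel <- stats::runif(1, 0, rules$revel_threshold * 0.9)
    },
    egf_cys = {
      pos <- sample(c(1018L, 1033L, 1047L, 1061L), 1L)
      hgvs <- paste0("p.C", pos, alt_not("C")); revel <- stats::runif(1)
    },
    l1_cys = {
      pos <- 391L
      hgvs <- paste0("p.", ref_at(pos), pos, "C")
      revel <- stats::runif(1, 0, rules$revel_threshold * 0.9)
    },
    l2_cys = {
      pos <- sample(c(467L, 473L), 1L)
      hgvs <- paste0("p.C", pos, alt_not("C"))
      revel <- stats::runif(1, 0, rules$revel_threshold * 0.9)
    },
    ywtd_motif = {
      pos <- pick_repeat_pos("YWTD_blade", c(17L, 18L, 19L, 20L))
      hgvs <- paste0("p.", ref_at(pos), pos, alt_not(ref_at(pos)))
      revel <- stats::runif(1)
    },
    ywtd_conserved = {
      pos <- pick_repeat_pos("YWTD_blade", c(29L, 35L))
      hgvs <- paste0("p.", ref_at(pos), pos, alt_not(ref_at(pos)))
      revel <- stats::runif(1)
    },
    ywtd_partly = {
      pos <- pick_repeat_pos("YWTD_blade", c(9L, 38L))
      hgvs <- paste0("p.", ref_at(pos), pos, alt_not(ref_at(pos)))
      revel <- stats::runif(1)
    },
    fn3_glycine = {
      pos <- pick_repeat_pos("3Fn", c(36L, 96L))
      hgvs <- paste0("p.G", pos, alt_not("G")); revel <- stats::runif(1)
    },
    fn3_core = {
      pos <- pick_repeat_pos("3Fn", c(25L, 41L))
      hgvs <- paste0("p.", ref_at(pos), pos, alt_not(ref_at(pos)))
      revel <- stats::runif(1)
    },
    tyrosine_corner = {
      pos <- pick_repeat_pos("3Fn", c(77L, 79L, 83L))
      hgvs <- paste0("p.", ref_at(pos), pos, alt_not(ref_at(pos)))
      revel <- stats::runif(1)
    },
    vps10p_revel = {
      pos <- sample(c(150L, 200L, 250L, 300L, 550L), 1L)
      hgvs <- paste0("p.", ref_at(pos), pos, alt_not(ref_at(pos)))
      revel <- stats::runif(1, rules$revel_threshold, 1)
    },
    tencc_revel = {
      pos <- sample(c(640L, 668L, 695L, 745L), 1L)
      hgvs <- paste0("p.", ref_at(pos), pos, alt_not(ref_at(pos)))
      revel <- stats::runif(1, rules$revel_threshold, 1)
    },
    fn3_proline = {
      pos <- pick_repeat_pos("3Fn", c(6L, 7L))
      hgvs <- paste0("p.P", pos, alt_not("P"))
      revel <- stats::runif(1, 0, rules$revel_threshold * 0.9)
    },
    lpv = {
      pos <- pick_repeat_pos("3Fn", neutral_fn3)
      hgvs <- paste0("p.", ref_at(pos), pos, alt_not(ref_at(pos)))
      revel <- stats::runif(1, rules$revel_threshold, 1)
    },
    npv_low_revel = {
      pos <- pick_repeat_pos("3Fn", neutral_fn3)
      hgvs <- paste0("p.", ref_at(pos), pos, alt_not(ref_at(pos)))
      revel <- stats::runif(1, 0, rules$revel_threshold * 0.9)
    },
    npv_no_revel = {
      pos <- sample(c(150L, 200L, 300L), 1L)
      hgvs <- paste0("p.", ref_at(pos), pos, alt_not(ref_at(pos)))
      revel <- NA_real_
    },
    less_rare = {
      pos <- pick_repeat_pos("3Fn", neutral_fn3)
      hgvs <- paste0("p.", ref_at(pos), pos, alt_not(ref_at(pos)))
      revel <- stats::runif(1); maf <- stats::runif(1, rules$maf_threshold, 0.05)
    },
    excluded_exon1 = {
      pos <- sample(2:95, 1L)
      hgvs <- paste0("p.", ref_at(pos), pos, alt_not(ref_at(pos)))
      revel <- stats::runif(1); exon <- 1L
    },
    synonymous = {
      consequence <- "other"; revel <- NA_real_
    },
    stop("unknown simulated class: ", cls$class)
  )
  if (is.na(exon) && !is.na(pos)) exon <- residue_exon(pos, arch)
  tibble::tibble(
    variant_id = paste0("tmp", i), hgvs_p = hgvs, consequence = consequence,
    exon = exon, revel = revel, loftee = loftee, splice_score = splice,
    gnomad_maf = maf, sim_class = cls$class, truth_category = cls$truth,
    truth_rule = if (is.na(cls$rule)) NA_character_ else cls$rule
  )
}

#' Simulate a case/control cohort with known generating parameters
#'
#' Draws carrier categories at the configured prevalences, APOE genotypes,
#' and standardized ancestry PCs; case/control status follows a logistic
#' disease model whose linear predictor adds the log category odds ratio and
#' the per-allele APOE-e4 log odds ratio, with the intercept solved so the
#' expected case fraction matches `n_cases / (n_cases + n_controls)`. Case
#' onset ages follow a truncated normal centred at the wild-type median plus
#' category and APOE shifts; controls receive an age at last screening.
#' Each carrier is linked to one variant of their true category (dosage 1).
#'
#' @param params A `sorl_sim_params`.
#' @param variants,truth Output of [simulate_variant_table()].
#' @param seed Overrides `params$seed` when given.
#' @return List with `cohort` (a `sorl_cohort`) and `truth_individuals`
#'   (tibble `id`, `truth_category`).
#' @export
simulate_cohort <- function(params, variants, truth, seed = params$seed) {
  stopifnot(inherits(params, "sorl_sim_params"))
  cats <- names(params$category_control_prevalence)
  n <- params$n_cases + params$n_controls
  f_case <- params$n_cases / n

  withr::with_seed(as.integer(seed), {
    a1 <- sample(c("e4", "e2", "e3"), n, replace = TRUE,
                 prob = c(params$apoe_e4_freq, params$apoe_e2_freq,
                          1 - params$apoe_e4_freq - params$apoe_e2_freq))
    a2 <- sample(c("e4", "e2", "e3"), n, replace = TRUE,
                 prob = c(params$apoe_e4_freq, params$apoe_e2_freq,
                          1 - params$apoe_e4_freq - params$apoe_e2_freq))
    e4 <- (a1 == "e4") + (a2 == "e4")
    e2 <- (a1 == "e2") + (a2 == "e2")

    # the configured prevalences are frequencies *among controls*; invert the
    # disease model (carriers are case-enriched, hence control-depleted) so
    # the expected control-stratum frequency matches the parameter
    apoe_lp <- log(params$apoe_per_allele_or) * e4
    # the APOE linear predictor takes three values; work on its empirical
    # distribution rather than the full individual vector
    w_e4 <- tabulate(e4 + 1L, 3L) / n
    lp_lev <- log(params$apoe_per_allele_or) * (0:2)
    mean_p <- function(b) sum(w_e4 * stats::plogis(b + lp_lev))
    b0_wt <- stats::uniroot(function(b) mean_p(b) - f_case,
                            interval = stats::qlogis(f_case) + c(-6, 6))$root
    p0 <- mean_p(b0_wt)
    odds <- function(p) p / (1 - p)
    # the configured ORs are marginal (unadjusted, cohort-scale) odds ratios,
    # as in a Fisher carrier table; calibrate each category's logit
    # coefficient so that collapsing over APOE reproduces them exactly
    beta <- vapply(params$category_or, function(orr) {
      stats::uniroot(function(b) {
        odds(mean_p(b0_wt + b)) / odds(p0) - orr
      }, interval = c(log(orr) - 3, log(orr) + 3), extendInt = "upX")$root
    }, numeric(1))
    p1 <- vapply(beta, function(b) mean_p(b0_wt + b), numeric(1))
    prev <- params$category_control_prevalence * (1 - p0) / (1 - p1)
    cat_draw <- sample(c(cats, "WT"), n, replace = TRUE,
                       prob = c(prev, 1 - sum(prev)))

    log_or <- beta[cat_draw]
    log_or[is.na(log_or)] <- 0
    lp_partial <- log_or + log(params$apoe_per_allele_or) * e4
    lev <- unique(lp_partial)
    w_lev <- tabulate(match(lp_partial, lev), length(lev)) / n
    b0 <- stats::uniroot(
      function(b) sum(w_lev * stats::plogis(b + lev)) - f_case,
      interval = stats::qlogis(f_case) + c(-6, 6)
    )$root
    status <- ifelse(stats::rbinom(n, 1L, stats::plogis(b0 + lp_partial)) == 1L,
                     "case", "control")

    shift <- params$aao_shift[cat_draw]
    shift[is.na(shift)] <- 0
    mu <- params$wt_aao_median + shift + params$apoe_aao_shift * e4
    lo <- params$aao_truncation[1]; hi <- params$aao_truncation[2]
    u <- stats::runif(n,
                      stats::pnorm(lo, mu, params$aao_dispersion),
                      stats::pnorm(hi, mu, params$aao_dispersion))
    aao <- stats::qnorm(u, mu, params$aao_dispersion)
    ctrl_age <- pmin(pmax(stats::rnorm(n, params$control_age_mean,
                                       params$control_age_sd), 40), 104)
    age <- ifelse(status == "case", aao, ctrl_age)

    pcs <- matrix(stats::rnorm(n * 6L, sd = params$pc_noise_scale), ncol = 6L)
    colnames(pcs) <- paste0("pc", 1:6)

    if (params$control_apoe_missing > 0) {
      drop <- status == "control" &
        stats::runif(n) < params$control_apoe_missing
      e4[drop] <- NA_integer_; e2[drop] <- NA_integer_
    }

    individuals <- dplyr::bind_cols(
      tibble::tibble(
        id = sprintf("ind%06d", seq_len(n)),
        status = status, aao_or_age = age,
        apoe_e4 = as.integer(e4), apoe_e2 = as.integer(e2)
      ),
      tibble::as_tibble(pcs)
    )
    individuals$cohort_label <- "synthetic"

    # link carriers to one variant of their true category; only variants with
    # a database MAF are used so in-sample frequency fallbacks stay rare
    carrier_rows <- which(cat_draw != "WT")
    annotated <- !is.na(variants$gnomad_maf[match(truth$variant_id,
                                                  variants$variant_id)])
    pool <- split(truth$variant_id[annotated], truth$truth_category[annotated])
    vid <- vapply(carrier_rows, function(i) {
      choices <- pool[[cat_draw[i]]]
      choices[sample.int(length(choices), 1L)]
    }, character(1))
    carriers <- tibble::tibble(
      variant_id = vid, id = individuals$id[carrier_rows], dosage = 1
    )
  })

  cohort <- sorl_cohort(individuals, variants, carriers)
  list(
    cohort = cohort,
    truth_individuals = tibble::tibble(id = individuals$id,
                                       truth_category = cat_draw)
  )
}
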