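arch <- sorl1_architecture()
rules <- sorl1_rules()

mkvar <- function(hgvs, revel = NA_real_, maf = 1e-5, loftee = 0L,
                  exon = NA_integer_, consequence = NA_character_,
                  splice = NA_real_) {
  v <- normalize_variants(tibble::tibble(
    variant_id = paste0("t:", hgvs), hgvs_p = hgvs, consequence = consequence,
    revel = revel, loftee = loftee, splice_score = splice,
    gnomad_maf = maf, exon = exon
  ))
  if (!is.na(v$position[1]) && is.na(v$exon[1])) {
    v$exon <- residue_exon(v$position, arch)
  }
  v
}

classify1 <- function(v, cohort = make_empty_cohort(variants = v)) {
  classify_variants(v, cohort, arch, rules)
}

test_that("protein-truncating logic covers the flag, the last-exon rescue and splice review", {
  expect_true(is_ptv(mkvar("p.R744X", loftee = 1L), rules)$ptv)
  # nonsense in exon 48 rescued despite flag 0
  r <- is_ptv(mkvar("p.Q2150X", loftee = 0L, exon = 48L), rules)
  expect_true(r$ptv)
  expect_false(r$review)
  # splice variant with high predicted splice effect: review, no auto-promotion
  r <- is_ptv(mkvar(NA_character_, consequence = "splice", splice = 0.9), rules)
  expect_false(r$ptv)
  expect_true(r$review)
  expect_false(is_ptv(mkvar("p.Y391C"), rules)$ptv)
})

test_that("cysteine gain/loss detection checks the reference sequence", {
  refseq <- arch$reference_sequence
  expect_equal(cysteine_change(refseq, "Y", 391L, "C"), "gain")
  expect_equal(cysteine_change(refseq, "C", 467L, "Y"), "loss")
  expect_equal(cysteine_change(refseq, "D", 1108L, "N"), "none")
  expect_error(cysteine_change(refseq, "W", 391L, "C"), "reference mismatch")
})

test_that("documented variants classify into their expected categories", {
  cases <- list(
    list(v = mkvar("p.Y391C", revel = 0.3), cat = "HPV", rule = "l1_cysteine"),
    list(v = mkvar("p.D1108N", revel = 0.3), cat = "HPV", rule = "calcium_cage"),
    list(v = mkvar("p.Y1816C", revel = 0.3), cat = "HPV", rule = "tyrosine_corner"),
    list(v = mkvar("p.C716W", revel = 0.3), cat = "HPV", rule = "tencc_cysteine"),
    list(v = mkvar("p.R953H", revel = 0.9), cat = "HPV", rule = "ywtd_partly_conserved"),
    list(v = mkvar("p.G1732A", revel = 0.6), cat = "HPV", rule = "fn3_glycines"),
    list(v = mkvar("p.A528T", maf = 0.036), cat = "LESS_RARE", rule = NA),
    list(v = mkvar("p.P1546L", revel = 0.2), cat = "MPV", rule = "fn3_prolines")
  )
  for (cs in cases) {
    cl <- classify1(cs$v)
    expect_equal(cl$category, cs$cat, info = cs$v$hgvs_p)
    if (!is.na(cs$rule)) expect_equal(cl$triggering_rule, cs$rule, info = cs$v$hgvs_p)
  }
  # cysteine subcategories carry the gain/loss direction
  expect_equal(classify1(mkvar("p.Y391C", revel = 0.3))$subcategory,
               "l1_cysteine_gain")
  expect_equal(classify1(mkvar("p.C473S", revel = 0.3))$subcategory,
               "l2_cysteine_loss")
})

test_that("the residual decision order yields LPV/NPV/EXCLUDED as specified", {
  # rare missense off every rule with high REVEL outside VPS10p -> LPV
  lin <- mkvar("p.V1595L", revel = 0.8)  # neutral 3Fn position, no rule
  expect_equal(classify1(lin)$category, "LPV")
  # same position with low REVEL -> NPV
  expect_equal(classify1(mkvar("p.V1595A", revel = 0.1))$category, "NPV")
  # VPS10p missense with REVEL above threshold -> HPV via the REVEL gate
  expect_equal(classify1(mkvar("p.E270K", revel = 0.7))$triggering_rule,
               "vps10p_revel")
  # VPS10p missense with missing REVEL -> conservative NPV, flagged
  cl <- classify1(mkvar("p.E270K"))
  expect_equal(cl$category, "NPV")
  expect_match(cl$flags, "revel_missing")
  # first-exon variants are retained but excluded from analysis
  expect_equal(classify1(mkvar("p.A50T", revel = 0.9, exon = 1L))$category,
               "EXCLUDED")
})

test_that("classification partitions the input and is deterministic", {
  vt <- simulate_variant_table(n_variants = 120, seed = 21)
  coh <- make_empty_cohort(variants = vt$variants)
  cl1 <- classify_variants(vt$variants, coh, arch, rules)
  cl2 <- classify_variants(vt$variants, coh, arch, rules)
  expect_identical(cl1, cl2)
  expect_false(any(is.na(cl1$category)))
  expect_equal(sum(table(cl1$category)), nrow(vt$variants))
  expect_true(all(cl1$category %in% c(CATEGORY_LEVELS, "EXCLUDED")))
  # every high/moderate call names its triggering rule
  hm <- cl1$category %in% c("HPV", "MPV")
  expect_true(all(!is.na(cl1$triggering_rule[hm])))
})

test_that("removing a triggering rule demotes the variants it classified", {
  drop_rule <- function(label) {
    r <- rules
    r$rules <- r$rules[r$rules$label != label, ]
    r
  }
  coh <- function(v) make_empty_cohort(variants = v)
  v <- mkvar("p.D1108N", revel = 0.3)
  expect_equal(classify_variants(v, coh(v), arch, drop_rule("calcium_cage"))$category,
               "NPV")
  v <- mkvar("p.Y1816C", revel = 0.3)
  expect_equal(classify_variants(v, coh(v), arch, drop_rule("tyrosine_corner"))$category,
               "NPV")
  v <- mkvar("p.P1546L", revel = 0.2)
  expect_equal(classify_variants(v, coh(v), arch, drop_rule("fn3_prolines"))$category,
               "NPV")
})

test_that("rule-engine output equals an independent flat evaluation of the rules", {
  vt <- simulate_variant_table(n_variants = 250, seed = 42)
  coh <- make_empty_cohort(variants = vt$variants)
  cl <- classify_variants(vt$variants, coh, arch, rules)
  oracle <- oracle_classify(cl, cl$maf, arch)
  expect_equal(cl$category, oracle)
})

test_that("multi-variant carriers group by the highest-priority variant", {
  expect_equal(assign_carrier_category(c("HPV", "PTV")), "PTV")
  expect_equal(assign_carrier_category(c("NPV", "LPV")), "LPV")
  expect_equal(assign_carrier_category(c("LESS_RARE", "NPV")), "NPV")
  expect_equal(assign_carrier_category(character(0)), "WT")
  expect_equal(assign_carrier_category(c("EXCLUDED")), "WT")

  # through the cohort path: one individual carries an ONC variant and a PTV
  v <- normalize_variants(tibble::tibble(
    variant_id = c("onc", "ptv"),
    hgvs_p = c("p.C1453F", "p.R744X"),
    revel = c(0.4, NA), loftee = c(0L, 1L),
    gnomad_maf = c(1e-5, 1e-5),
    exon = c(32L, 21L)
  ))
  ind <- tibble::tibble(id = c("A", "B"), status = "case", aao_or_age = c(46, 70))
  carriers <- tibble::tibble(variant_id = c("onc", "ptv", "onc"),
                             id = c("A", "A", "B"), dosage = 1)
  coh <- sorl_cohort(ind, v, carriers)
  cl <- classify_variants(v, coh, arch, rules)
  expect_equal(cl$category, c("HPV", "PTV"))
  asg <- assign_carriers(coh, cl)
  expect_equal(asg$carrier_category[asg$id == "A"], "PTV")
  expect_equal(asg$carrier_category[asg$id == "B"], "HPV")
})
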