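test_that("carrier_set applies the strict posterior-dosage threshold", {
  carriers <- tibble::tibble(
    variant_id = c("v1", "v1", "v1", "v2"),
    id = c("A", "B", "C", "A"),
    dosage = c(0.9, 0.4, 0.5, 1.0)
  )
  expect_setequal(carrier_set(carriers, "v1"), "A")        # 0.5 is excluded
  expect_equal(carrier_set(carriers, "v3"), character(0))  # absent variant
  expect_setequal(carrier_set(carriers, "v1", dosage_threshold = 0.3),
                  c("A", "B", "C"))
})

test_that("effective_maf falls back to the per-individual sample frequency", {
  n <- 40852L
  ind <- tibble::tibble(id = sprintf("s%05d", seq_len(n)),
                        status = rep(c("case", "control"), length.out = n),
                        aao_or_age = 70)
  variants <- normalize_variants(tibble::tibble(
    variant_id = c("va", "vb", "vc"),
    hgvs_p = c("p.Y391C", "p.D1108N", "p.Y1816C"),
    gnomad_maf = c(0.002, NA, NA)
  ))
  carriers <- tibble::tibble(
    variant_id = c(rep("vb", 21L), "vc"),
    id = ind$id[1:22],
    dosage = 1
  )
  coh <- sorl_cohort(ind, variants, carriers)
  m <- effective_maf(variants, coh)
  expect_equal(m$maf[1], 0.002)
  expect_equal(m$maf_source[1], "gnomad")
  # 21 carriers of 40,852 individuals sits just above the 0.05% threshold
  expect_equal(m$maf[2], 21 / 40852)
  expect_gt(m$maf[2], 5e-4)
  expect_equal(m$maf_source[2], "sample")
  expect_equal(m$maf[3], 1 / 40852, tolerance = 1e-12)
  expect_lt(m$maf[3], 5e-4)
  # allele-based denominator available behind a flag
  m2 <- effective_maf(variants, coh, denominator = "alleles")
  expect_equal(m2$maf[2], 21 / (2 * 40852))
  # monotone in carrier count when source is the sample
  expect_gt(m$maf[2], m$maf[3])
})

test_that("juxtaposed in-cis substitutions merge conservatively", {
  variants <- normalize_variants(tibble::tibble(
    variant_id = c("m1", "m2", "m3"),
    hgvs_p = c("p.D1200G", "p.E1201K", "p.Y1816C"),
    revel = c(0.8, 0.3, 0.9),
    gnomad_maf = c(1e-5, 1e-5, 1e-5)
  ))
  carriers <- tibble::tibble(
    variant_id = c("m1", "m2", "m3"),
    id = c("A", "A", "B"),
    dosage = 1
  )
  phase <- tibble::tibble(variant_id1 = "m1", variant_id2 = "m2", phase = "cis")
  res <- merge_cis_adjacent(variants, carriers, phase)
  expect_equal(nrow(res$variants), 2L)
  merged <- res$variants[grepl("m1", res$variants$variant_id), ]
  expect_equal(merged$revel, 0.3)   # lowest of the pair
  expect_equal(merged$hgvs_p, "p.D1200G;E1201K")
  expect_equal(merged$ref_aa2, "E")
  expect_match(merged$flags, "merged_cis")
  # total carrier count at the merged locus is unchanged
  expect_setequal(carrier_set(res$carriers, merged$variant_id), "A")
  expect_setequal(carrier_set(res$carriers, "m3"), "B")

  # unknown phase: left unmerged, both flagged
  res2 <- merge_cis_adjacent(variants, carriers)
  expect_equal(nrow(res2$variants), 3L)
  expect_match(res2$variants$flags[res2$variants$variant_id == "m1"], "phase_unknown")
  expect_match(res2$variants$flags[res2$variants$variant_id == "m2"], "phase_unknown")
  expect_equal(res2$variants$flags[res2$variants$variant_id == "m3"], "")

  # a single record is returned unchanged
  res3 <- merge_cis_adjacent(variants[3, ], carriers[3, ])
  expect_equal(nrow(res3$variants), 1L)
})

test_that("cohort tables read with censored-age coercion and validation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    id = c("a", "b", "c"), status = c("case", "control", "control"),
    aao_or_age = c("64", "> 89", ">89"),
    apoe_e4 = c(1L, 0L, NA), apoe_e2 = c(0L, 0L, NA),
    pc1 = 0, pc2 = 0, pc3 = 0, pc4 = 0, pc5 = 0, pc6 = 0,
    cohort = "unit"
  ), path)
  ind <- read_cohort_table(path)
  expect_equal(ind$aao_or_age, c(64, 90, 90))
  expect_true("cohort_label" %in% names(ind))

  expect_error(
    sorl_cohort(dplyr::mutate(ind, aao_or_age = c(-1, 90, 90)),
                normalize_variants(tibble::tibble(variant_id = character(),
                                                  hgvs_p = character())),
                tibble::tibble(variant_id = character(), id = character(),
                               dosage = numeric())),
    "positive"
  )
  expect_error(
    sorl_cohort(ind,
                normalize_variants(tibble::tibble(variant_id = "v",
                                                  hgvs_p = "p.Y391C")),
                tibble::tibble(variant_id = "v", id = "nobody", dosage = 1)),
    "carrier ids"
  )
})

test_that("variant TSV writing and reading round-trips the parsed columns", {
  vt <- simulate_variant_table(n_variants = 40, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(vt$variants, path)
  back <- read_variant_table(path)
  expect_equal(back$variant_id, vt$variants$variant_id)
  expect_equal(back$position, vt$variants$position)
  expect_equal(back$change_kind, vt$variants$change_kind)
  expect_equal(back$revel, vt$variants$revel, tolerance = 1e-12)
})

test_that("annotated VCF input normalizes to the same variant/carrier tables", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=HGVSP,Number=1,Type=String,Description=\"protein change\">",
    "##INFO=<ID=EXON,Number=1,Type=Integer,Description=\"exon\">",
    "##INFO=<ID=REVEL,Number=1,Type=Float,Description=\"REVEL\">",
    "##INFO=<ID=LOFTEE,Number=1,Type=Integer,Description=\"LoF flag\">",
    "##INFO=<ID=GNOMAD_NN_POPMAX,Number=1,Type=Float,Description=\"MAF\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    paste0("11\t121421313\t.\tA\tG\t.\tPASS\t",
           "HGVSP=p.Y391C;EXON=9;REVEL=0.41;LOFTEE=0;GNOMAD_NN_POPMAX=1e-05",
           "\tGT\t0/1\t0/0\t0/0"),
    paste0("11\t121458007\t.\tC\tT\t.\tPASS\t",
           "HGVSP=p.R866X;EXON=20;LOFTEE=1",
           "\tGT\t0/0\t0/1\t1/1")
  ), vcf)
  res <- read_variant_vcf(vcf)
  expect_equal(nrow(res$variants), 2L)
  expect_equal(res$variants$change_kind, c("missense", "nonsense"))
  expect_equal(res$variants$position, c(391L, 866L))
  expect_equal(res$variants$revel[1], 0.41)
  expect_equal(res$variants$loftee, c(0L, 1L))
  expect_true(is.na(res$variants$gnomad_maf[2]))
  expect_setequal(carrier_set(res$carriers, res$variants$variant_id[1]), "S1")
  expect_setequal(carrier_set(res$carriers, res$variants$variant_id[2]),
                  c("S2", "S3"))
  expect_equal(res$carriers$dosage[res$carriers$id == "S3"], 2)
})
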