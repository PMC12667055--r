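# sorldmdm

Domain-aware prioritization and burden analysis of rare coding variants in
**SORL1**, the multidomain endosomal sorting receptor implicated in
Alzheimer's disease (AD).

Protein-truncating *SORL1* variants occur almost exclusively in AD cases,
but most coding variants seen in patients are rare missense changes of
unknown significance. This package implements a domain-mapping
prioritization for them — scoring each affected residue by its position
within SORL1's repeated domain units (complement-type repeats with their
calcium cages and six-cysteine framework, fibronectin-III domains with
their tyrosine corner, YWTD propeller blades, the VPS10p loops) — and the
downstream statistics: rare-variant burden association and case-only
age-at-onset analysis. It is aimed at statistical geneticists and
neurogenetics groups who want the classification scheme, its association
machinery, and a fully synthetic test bed in one reproducible place.

## What it computes

**Classification** (per rare variant, MAF < 0.05%):

* `PTV` — truncating variants (LoF flag, last-exon rescue, curated splice),
* `HPV` — missense at high-priority residues: CR calcium cage
  (repeat positions 37/41/47/48) and Asx-turn (44); cysteine gains/losses in
  CR, 10CC, EGF and the VPS10p L1/L2 loops; the YWTD motif (blade 17–20) and
  conserved blade positions; 3Fn glycines, core residues and the tyrosine
  corner (77/79/83); and REVEL ≥ 0.5 inside VPS10p/10CC,
* `MPV` / `LPV` / `NPV` — moderate rules, the REVEL ≥ 0.5 residual gate
  outside VPS10p, and everything else.

Individuals carrying several variants are grouped by the highest-priority
one (`PTV > HPV > MPV > LPV > NPV > LESS_RARE`, non-carriers `WT`).

**Burden association** per category and onset stratum: the cross-product
odds ratio with a log-scale Wald interval,

    OR = (a d)/(b c),   CI = exp(ln OR ± 1.96 √(1/a + 1/b + 1/c + 1/d)),

two-sided Fisher exact p-values, explicit-family Bonferroni adjustment,
covariate-adjusted logistic regression (APOE-e4 + PC1..PC6) and an APOE
interaction likelihood-ratio test.

**Age at onset**, case-only: Kaplan–Meier medians with 10–90%
inter-percentile ranges, bootstrap deltas vs `WT` carriers, log-rank tests,
APOE-e4-stratified summaries.

**Synthetic cohorts**: a generator that plants variants across every rule
class with truth labels and simulates full-scale case/control cohorts
(18,959 cases / 21,893 controls by default) with configured carrier
prevalences, marginal odds ratios, onset shifts and APOE structure, so the
whole pipeline is testable end-to-end with no protected data.

## Worked example

```r
library(sorldmdm)

# association table rebuilt from the shipped reference carrier counts
ref <- burden_from_counts(sorl1_reference_counts())
subset(as.data.frame(ref), stratum == "ALL" & label %in% c("PTV", "HPV"),
       select = c(label, case_carriers, control_carriers, or, ci_low, ci_high, p_fisher))
#>   label case_carriers control_carriers    or   ci_low  ci_high     p_fisher
#> 1   PTV            89                6 17.20 7.525398 39.33478 4.351893e-23
#> 4   HPV           151               29  6.05 4.066065  9.010582 1.904306e-25
```

PTV carriers show a 17.2-fold (95% CI 7.5–39.3) increased odds of AD; HPV
carriers 6.1-fold (4.1–9.0). The same functions drive the synthetic
pipeline:

```r
vt  <- simulate_variant_table(seed = 1)                  # 250 variants, truth-labelled
sim <- simulate_cohort(simulation_params(seed = 1), vt$variants, vt$truth)
cl  <- classify_variants(sim$cohort$variants, sim$cohort)
mean(cl$category == vt$truth$truth_category)             # 1  (exact agreement)
asg <- assign_carriers(sim$cohort, cl)
burden_scan(asg, labels = c("PTV", "HPV"), strata = "ALL")[, c("label", "or", "p_fisher")]
aao_summary(asg, categories = c("PTV", "HPV"), n_boot = 500)
```

The numbered drivers under `analysis/` run these stages at full scale and
write their tables under `results/analysis/`:

```sh
Rscript analysis/01_simulate.R   # variant table + synthetic cohort
Rscript analysis/02_classify.R   # classification + carrier grouping
Rscript analysis/03_burden.R     # reference + synthetic burden, adjusted models
Rscript analysis/04_aao.R        # onset summaries, APOE stratification
```

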