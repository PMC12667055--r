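---
title: "Domain-aware prioritization and burden analysis of rare SORL1 variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-aware prioritization and burden analysis of rare SORL1 variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorldmdm)
```

## The scientific problem

SORL1 (SORLA) is a 2,214-residue multidomain endosomal sorting receptor
encoded by 48 exons. Protein-truncating variants (PTVs) in *SORL1* occur
almost exclusively in Alzheimer's disease (AD) cases, but most coding
variants observed in patients are rare missense changes, each typically
private to one family, and most of them benign. The question this package
operationalises is: *which rare missense variants behave like damaging
alleles?*

The approach is domain mapping of disease mutations: because SORL1 is built
from repeated domain units — eleven complement-type repeats (CR), six
fibronectin-type-III (3Fn) domains, six YWTD beta-propeller blades — a
residue position *within a repeat* can be scored by what is known about the
homologous position in related disease proteins (LDLR-family receptors for
CR repeats and the YWTD propeller, fibronectin-like proteins for 3Fn).
Variants hitting positions with established pathogenic homologues are
high-priority; everything else falls through a small decision cascade.

## The domain model

The architecture ships as a JSON configuration (`sorl1_default.json`) with
three blocks:

* **segments** — the nine-segment tiling of residues 1–2214: signal peptide
  (1–28), pro-peptide (29–81), VPS10p beta-propeller (82–617) with its L1
  (380–405) and L2 (460–490) loops, 10CC (618–753), YWTD propeller
  (754–1013), EGF (1014–1074), CR cluster (1075–1550), 3Fn cassette
  (1551–2121), transmembrane/tail (2122–2214). Segments must tile the
  protein exactly; violations refuse to load.
* **repeats** — CR, 3Fn, YWTD-blade, L1/L2 units. Per-repeat boundaries are
  *not* published anywhere authoritative. Where a residue/repeat-position
  pair is known (e.g. residue 1816 is position 83 of the third 3Fn domain;
  1732 is position 96 of the second; 1619 is position 79 of the first;
  2065 is position 47 of the sixth; 953 is position 38 of the fifth YWTD
  blade; 1108, 1261, 1345 are calcium-cage aspartates of CR repeats 1, 5
  and 7) the repeat start is derived exactly as `start = residue − position
  + 1`. All other boundaries are interpolations and explicitly
  user-editable.
* **anchors** — the pairs above, re-checked at load time: a configuration
  that contradicts its own anchors refuses to load.

Two derived starts overhang their parent segment: the first 3Fn repeat
starts at 1541 although the cassette is stated to start at 1551 (the
position-77/79 anchors force this), and the first CR repeat starts at 1068,
seven residues before the cluster. Overhangs up to 10 residues load with a
warning rather than an error, preserving both printed facts. One published
pair could not be reconciled: a glycine at residue 1681 described as repeat
position 36 implies a second-3Fn start of 1646, which contradicts the start
of 1637 implied by residue 1732 at position 96. The shipped configuration
anchors 1732 and leaves 1681 unanchored; editing the boundaries is a
one-line configuration change. The eleventh CR repeat is ended at 1540 so
that no residue belongs to two repeats (a validated invariant).

The architecture carries a **synthetic reference sequence**: a 2,214-letter
string with the correct residue identity at every rule position (D/D/D/E
calcium cages, the CR cysteine framework, the Y/W/T/D tetrad, the L/P/Y
tyrosine corner, conserved glycines and prolines, and the residues of all
variants used in the documentation) over a cysteine-free background cycle.
It is *not* the biological sequence; it exists so that cysteine gain/loss
logic and reference-identity checks are exactly testable without shipping
proprietary annotation.

## The prioritization cascade

Classification applies, in order:

1. **Exclusion** — exon 1 / residues 1–95 (differential coverage between
   cases and controls in the source data) are retained in tables but marked
   `EXCLUDED` and dropped from association analyses.
2. **Frequency gate** — the effective minor allele frequency is the
   reference-database (non-neuro popmax) MAF when annotated, otherwise the
   in-sample *carrier* frequency (carriers / individuals — the definition
   under which 21 carriers among 40,852 individuals sits just above the
   threshold; an allele-based denominator is available behind a flag).
   Variants at or above 0.05% are `LESS_RARE` and analysed separately.
3. **PTV** — the loss-of-function annotation flag, plus a rescue for
   nonsense/frameshift changes in exon 48 (which encodes the trafficking
   motifs of the cytoplasmic tail that the annotation tool does not cover).
   Splice variants without the flag but with a splice-prediction score of
   0.2 or more are flagged for manual review, never auto-promoted.
4. **High-priority rules (HPV)** — CR calcium cage (repeat positions
   37/41/47/48) and Asx-turn (44); cysteine gain or loss in CR repeats
   (odd-number-of-cysteines), the 10CC and EGF domains and the VPS10p L1/L2
   loops; the YWTD motif (blade positions 17–20) plus conserved (29/35) and
   partly conserved (9/38) blade positions; 3Fn conserved glycines (36/96),
   hydrophobic-core residues (25/41) and the tyrosine corner (77/79/83);
   and a REVEL ≥ 0.5 gate inside the VPS10p and 10CC domains (the
   VPS10p-family holds too few known disease variants for homology mapping,
   so Asp-box and similar positions are covered by the score gate rather
   than fixed positions).
5. **Moderate (MPV)** — 3Fn N-terminal prolines (positions 6/7). These are
   kept moderate (they appear under high-priority groupings in some
   summaries, but the analysis text treats them as moderate); position 79,
   the tyrosine-corner proline, is high. Both are configuration entries.
6. **LPV** — REVEL ≥ 0.5 outside the VPS10p domain, off every rule.
7. **NPV** — everything else. A missense record with missing REVEL where a
   REVEL rule would decide is classified conservatively as NPV and flagged.

The REVEL cutoff is ≥ 0.5 (the formal scheme prints the inclusive
inequality; configurable). Individuals carrying several rare variants are
grouped by the *highest-priority* carried variant under the total order
PTV > HPV > MPV > LPV > NPV > LESS_RARE; non-carriers are WT. Juxtaposed
substitutions confirmed in cis with identical carriers are merged into one
record annotated with the *lower* REVEL score of the pair (ensemble scores
cannot score double substitutions); unknown-phase pairs stay unmerged and
flagged.

Tunable thresholds, with defaults: REVEL 0.5 (unitless score in [0,1]), MAF
5e-4, carrier posterior dosage strictly > 0.5 (dosage in [0,2]), splice
review 0.2, early-onset boundary: age at onset < 65 years (one source table
legend reads ≤ 65; the boundary is a parameter).

## Association statistics

Carrier burden per category is tested on 2×2 tables (case/control ×
carrier/non-carrier), with cases optionally restricted to early (< 65) or
late onset while controls always remain the full control set, so stratified
effects share one reference. The point estimate is the sample cross-product
odds ratio with a log-scale Wald interval,

$$\widehat{OR} = \frac{ad}{bc}, \qquad
  CI_{95} = \exp\!\Big(\ln\widehat{OR} \pm 1.96\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\Big),$$

which is the only pairing that reproduces both the published point
estimates and intervals from the published counts (a conditional-MLE OR is
what `fisher.test` would print and does not). Zero cells give `NA` (the
Haldane–Anscombe 0.5 correction is available behind a flag, off by
default). Significance uses the two-sided Fisher exact test — the sum of
hypergeometric probabilities of tables no more probable than the observed
one — checked in the test suite against brute-force enumeration for every
table with N ≤ 60. Multiplicity uses Bonferroni with an *explicit* family
size (default: the number of tests in the scan; the family used for any
published table is not stated, so it is a parameter rather than a hidden
constant).

Covariate-adjusted association fits `status ~ carrier + APOE-e4 + PC1..PC6`
by maximum-likelihood logistic regression (convergence tolerance 1e-8, at
most 100 iterations); complete separation — for instance a category whose
carriers are all cases — is detected and reported as a flagged result with
`NA` standard error. The APOE interaction test compares the additive model
against one with a `carrier × e4-count` term by likelihood ratio against
chi-squared.

## Age-at-onset analysis

Because controls are younger than cases, onset is analysed case-only: every
case is an event (no censoring; censoring support exists for synthetic
experiments). Curves are Kaplan–Meier product-limit estimates with
log-transformed pointwise 95% bands. Quantiles use the smallest event time
at which survival reaches 1 − q or below (so the median of an uncensored
sample is the ⌈n/2⌉-th order statistic); quantiles never reached under
censoring are `NA`. Ages recorded as "> 89" are coerced to 90 at ingest,
before any survival computation.

The onset delta of a category is the difference of Kaplan–Meier medians
against wild-type carriers. No interval method for such deltas is standard,
so the package uses a percentile bootstrap over individuals (default 2,000
resamples) with an explicit seed; exact reproduction of any published
interval is therefore not claimed. Group comparisons use the unweighted
log-rank test. Summaries can be stratified by APOE-e4 genotype (e4/e4,
heterozygous, negative), with deltas computed against wild type *within*
the stratum.

## The synthetic cohort generator

`simulate_variant_table()` plants at least one variant for each of 27
scenario classes — every fixed-position and cysteine rule, both REVEL
gates, the exon-48 rescue, a splice-review case, less-rare and low/no
priority fillers and an excluded first-exon variant — drawing residue
identities from the reference sequence and recording the intended category
and rule as truth labels assigned by construction. The classifier is
required (and tested) to reproduce these labels exactly.

`simulate_cohort()` emulates the full-scale study conditions by default:
18,959 cases and 21,893 controls; carrier prevalences among controls
matching the observed counts (for example 6 / 21,893 for PTV); category
odds ratios 17.2 / 6.1 / 1.5 / 1.2 / 1.1 for PTV / HPV / MPV / LPV / NPV; a
wild-type onset centre of 72 years with shifts of −10 (PTV) and −8 (HPV);
onset dispersion 11.7 years, chosen so the 10–90% inter-percentile range
spans about 30 years, truncated to [30, 105]; APOE-e4 allele frequency 0.14
with a 3-fold per-allele disease odds ratio and a −5 year per-allele onset
shift; controls screened at 71 ± 17 years; standardized ancestry PCs. With
this onset model roughly a third of cases onset before 65, matching the
cohort's early-onset share without a separate enrichment mechanism, so the
`eoad_fraction` parameter is bookkeeping rather than a constraint.

Three calibrations deserve note:

* **Control-stratum prevalence.** The prevalence parameters are frequencies
  *among controls*. Drawing carriers at those frequencies in the population
  would deplete control carriers (carriers are case-enriched), so the
  generator inverts the disease model and draws at
  `q (1 − p0) / (1 − p1)`.
* **Marginal odds ratios.** The published ORs are unadjusted carrier-table
  ratios, i.e. marginal over APOE. Odds ratios are non-collapsible: a logit
  coefficient of ln 17.2 would yield a smaller marginal OR. The generator
  therefore solves for the conditional coefficient whose *collapsed* OR
  equals the configured value.
* **Onset-shift identification.** Among cases, carriers of high-OR
  categories are less APOE-e4-enriched than wild type (the carrier effect
  explains away APOE), so the marginal carrier-vs-WT onset delta sits
  closer to zero than the generating shift. The shift is exactly identified
  within an APOE stratum, and parameter-recovery checks compare within
  e4-negative cases (the largest stratum); the marginal delta remains the
  reported descriptive quantity, mirroring how unmatched and APOE-matched
  deltas differ in real cohorts.

What the generator does **not** emulate: genotype uncertainty (dosages are
exactly 1), relatedness and founder structure, ancestry covariance between
PCs and carrier status (PCs are pure noise, so adjusted and unadjusted
estimates coincide in expectation), per-variant frequency spectra within a
category, and age-dependent control selection. Passing recovery tests
therefore demonstrate the correctness of the estimators under the stated
model, not robustness to confounding or cryptic relatedness in real data.

## Problem sizes and numerical choices

The test suite runs the recovery study at the full simulated scale (40,852
individuals) with 100 replicates for interval coverage of the odds ratios
and onset shifts and 200 replicates for null calibration of the exact-test
p-values (Kolmogorov–Smirnov against uniform, on the densest category where
discreteness is negligible); bootstrap deltas in tests use 200–400
resamples against the 2,000-resample default. The Fisher oracle check
enumerates all ~635,000 tables with N ≤ 60 and requires agreement to 1e-12.
Ties in the exact test use the standard `1 + 1e-7` relative tolerance.
Uniroot calibrations in the generator operate on the three-point APOE
distribution, making them exact and fast. All randomness flows through
explicit integer seeds; identical seeds give byte-identical outputs.

## Known limitations

* The shipped rule set covers the residue classes documented in the main
  analysis; the complete alignment-derived black/grey residue sets of the
  source compendium are not enumerable from public text, so the default
  configuration is deliberately not presented as complete — it is a
  configuration, and extending it is data entry, not code.
* Repeat boundaries other than the anchored ones are interpolations; the
  1646-vs-1637 second-3Fn discrepancy above is unresolved by construction.
* Published onset medians, their deltas' intervals, APOE-stratified medians
  and adjusted regression estimates require individual-level data and are
  validated structurally on synthetic cohorts, not reproduced numerically.
* The case-only design cannot estimate penetrance; simulated onset and risk
  parameters describe an assembled, early-onset-enriched sample, not the
  population.
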