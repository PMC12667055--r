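#!/usr/bin/env Rscript

# Stage 2: prioritize variants and group carriers.
#
# Applies the domain-mapping classification (PTV / HPV / MPV / LPV / NPV,
# with less-rare and excluded variants routed aside) to the stage-1 variant
# table, then reduces every individual to their highest-priority carried
# variant. Reports agreement with the generator's truth labels.

suppressMessages(library(sorldmdm))

out_dir <- "results/analysis"
variants <- read_variant_table(file.path(out_dir, "variants.tsv"))
individuals <- read_cohort_table(file.path(out_dir, "cohort.tsv"))
carriers <- readr::read_tsv(file.path(out_dir, "carriers.tsv"),
                            show_col_types = FALSE)
truth <- readr::read_tsv(file.path(out_dir, "variant_truth.tsv"),
                         show_col_types = FALSE)
cohort <- sorl_cohort(individuals, variants, carriers)

message("Classifying ", nrow(variants), " variants ...")
classified <- classify_variants(variants, cohort)
print(table(classified$category))
agreement <- mean(classified$category == truth$truth_category)
message("Agreement with generator truth labels: ",
        sprintf("%.1f%%", 100 * agreement))

assigned <- assign_carriers(cohort, classified)
message("Carrier groups (individuals by highest-priority variant):")
print(table(assigned$carrier_category))

readr::write_tsv(
  classified[, c("variant_id", "hgvs_p", "category", "subcategory",
                 "triggering_rule", "maf", "maf_source", "flags")],
  file.path(out_dir, "classified.tsv")
)
readr::write_tsv(assigned, file.path(out_dir, "carrier_categories.tsv"))
message("Stage 2 outputs written to ", out_dir)
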