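#' Run the full analysis pipeline
#'
#' Orchestrates the stages `simulate` (or loading of user tables),
#' `classify`, `burden` and `aao` with one configuration, writing each
#' stage's table and a run manifest (parameters, seed, output files with MD5
#' hashes) into the output directory. Reruns with the same configuration
#' produce hash-identical outputs. Fails before any stage runs if a
#' referenced input path does not exist.
#'
#' @param config Named list (or path to a JSON file) with any of:
#'   `out_dir` (required), `seed` (default 1), `stages` (subset of
#'   `c("simulate", "classify", "burden", "aao")`, default all),
#'   `variant_table`/`cohort_table`/`carrier_table` (TSV paths; used instead
#'   of simulation when given), `n_variants`, `sim` (named overrides passed
#'   to [simulation_params()]), `bootstrap_n`, `bonferroni_m`,
#'   `eoad_boundary`.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  if (is.null(cfg$out_dir)) stop("config must name an out_dir", call. = FALSE)
  stages <- cfg$stages %||% c("simulate", "classify", "burden", "aao")
  seed <- as.integer(cfg$seed %||% 1L)
  eoad_boundary <- cfg$eoad_boundary %||% 65
  n_boot <- cfg$bootstrap_n %||% 2000L

  for (p in c(cfg$variant_table, cfg$cohort_table, cfg$carrier_table)) {
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  arch <- sorl1_architecture()
  rules <- sorl1_rules()
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    readr::write_tsv(df, path, progress = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  if ("simulate" %in% stages && is.null(cfg$variant_table)) {
    sim_args <- cfg$sim %||% list()
    sim_args$seed <- seed
    params <- do.call(simulation_params, sim_args)
    vt <- simulate_variant_table(arch, rules,
                                 n_variants = cfg$n_variants %||% 250L,
                                 seed = seed)
    sim <- simulate_cohort(params, vt$variants, vt$truth)
    cohort <- sim$cohort
    emit(vt$variants, "variants.tsv")
    emit(vt$truth, "variant_truth.tsv")
    emit(sim$truth_individuals, "individual_truth.tsv")
    emit(cohort$individuals, "cohort.tsv")
    emit(cohort$carriers, "carriers.tsv")
  } else {
    variants <- read_variant_table(cfg$variant_table, arch$protein_length)
    individuals <- read_cohort_table(cfg$cohort_table)
    carriers <- readr::read_tsv(cfg$carrier_table, show_col_types = FALSE,
                                progress = FALSE)
    cohort <- sorl_cohort(individuals, variants, carriers)
  }

  classified <- assigned <- NULL
  if ("classify" %in% stages) {
    classified <- classify_variants(cohort$variants, cohort, arch, rules)
    assigned <- assign_carriers(cohort, classified, rules$dosage_threshold)
    emit(classified[, c("variant_id", "hgvs_p", "category", "subcategory",
                        "triggering_rule", "maf", "maf_source", "flags")],
         "classified.tsv")
    emit(assigned[, c("id", "status", "carrier_category", "carrier_subcategory")],
         "carrier_categories.tsv")
  }
  if ("burden" %in% stages) {
    if (is.null(assigned)) stop("burden stage requires classify", call. = FALSE)
    burden <- burden_scan(assigned, eoad_boundary = eoad_boundary,
                          family_size = cfg$bonferroni_m %||% NULL)
    emit(burden, "burden.tsv")
  }
  if ("aao" %in% stages) {
    if (is.null(assigned)) stop("aao stage requires classify", call. = FALSE)
    aao <- aao_summary(assigned, n_boot = n_boot, seed = seed)
    emit(aao, "aao.tsv")
  }

  manifest <- list(
    package = "sorldmdm",
    version = as.character(utils::packageVersion("sorldmdm")),
    seed = seed,
    stages = stages,
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    outputs = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
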