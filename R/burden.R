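#' Build a 2x2 case/control carrier table for a category
#'
#' Cases are restricted to the requested onset stratum (`ALL`, `EOAD`:
#' age at onset below the boundary, `LOAD`: at or above it); controls are
#' always the full control set, so stratified effect sizes are comparable
#' against one reference group.
#'
#' @param assigned Individual tibble with `carrier_category` (see
#'   [assign_carriers()]).
#' @param category Carrier category (or a logical column name) defining
#'   carriership.
#' @param stratum `"ALL"`, `"EOAD"` or `"LOAD"`.
#' @param eoad_boundary Age-at-onset boundary separating early from late
#'   onset (default 65; onset strictly below is early).
#' @return Named list with counts `case_carriers`, `case_noncarriers`,
#'   `control_carriers`, `control_noncarriers`.
#' @export
build_table <- function(assigned, category, stratum = c("ALL", "EOAD", "LOAD"),
                        eoad_boundary = 65) {
  stratum <- match.arg(stratum)
  is_case <- assigned$status == "case"
  cases <- assigned[is_case, , drop = FALSE]
  if (stratum == "EOAD") cases <- cases[!is.na(cases$aao_or_age) & cases$aao_or_age < eoad_boundary, , drop = FALSE]
  if (stratum == "LOAD") cases <- cases[!is.na(cases$aao_or_age) & cases$aao_or_age >= eoad_boundary, , drop = FALSE]
  if (!nrow(cases)) stop("empty case stratum: ", stratum, call. = FALSE)
  controls <- assigned[!is_case, , drop = FALSE]
  list(
    case_carriers = sum(cases$carrier_category == category),
    case_noncarriers = sum(cases$carrier_category != category),
    control_carriers = sum(controls$carrier_category == category),
    control_noncarriers = sum(controls$carrier_category != category)
  )
}

#' Cross-product odds ratio with a log-scale Wald interval
#'
#' `OR = (a d) / (b c)` with the 95% interval
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell yields
#' `NA` (no continuity correction by default; set `haldane = TRUE` for the
#' 0.5-correction variant).
#'
#' @param table 2x2 count list (as from [build_table()]) or a numeric vector
#'   `c(a, b, c, d)` = (case carriers, case non-carriers, control carriers,
#'   control non-carriers).
#' @param conf_level Confidence level (default 0.95).
#' @param haldane Apply the Haldane-Anscombe 0.5 correction to zero-cell
#'   tables instead of returning `NA`.
#' @return List with `or`, `ci_low`, `ci_high`.
#' @export
odds_ratio_wald <- function(table, conf_level = 0.95, haldane = FALSE) {
  x <- as_counts(table)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(x == 0)) {
    if (!haldane) return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
    x <- x + 0.5
  }
  or <- (x[1] * x[4]) / (x[2] * x[3])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / x))
  list(or = or, ci_low = or * exp(-z * se), ci_high = or * exp(z * se))
}

as_counts <- function(table) {
  if (is.list(table) && !is.null(table$case_carriers)) {
    as.numeric(c(table$case_carriers, table$case_noncarriers,
                 table$control_carriers, table$control_noncarriers))
  } else {
    stopifnot(length(table) == 4L)
    as.numeric(table)
  }
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Conditions on both margins and sums the hypergeometric probabilities of
#' every table no more probable than the observed one (with the standard
#' `1 + 1e-7` relative tolerance against ties lost to floating point). This
#' is the exact two-sided test used for all sparse carrier tables.
#'
#' @inheritParams odds_ratio_wald
#' @return A p-value in `(0, 1]`.
#' @export
fisher_p <- function(table) {
  x <- as_counts(table)
  a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  if (n == 0) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  dens <- stats::dhyper(support, c1, n - c1, r1)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

#' Bonferroni adjustment with an explicit family size
#'
#' `p_adj = min(1, p * family_size)`. The family size defaults to the length
#' of the vector, but the family actually tested is an analysis decision and
#' can be set explicitly.
#'
#' @param p_values Numeric vector of raw p-values.
#' @param family_size Number of tests in the family (`>= length(p_values)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, family_size = length(p_values)) {
  stopifnot(family_size >= length(p_values))
  pmin(1, p_values * family_size)
}

#' Burden scan over carrier categories and onset strata
#'
#' One association per category x stratum: the 2x2 table, cross-product OR
#' with Wald interval, Fisher exact p and the Bonferroni-adjusted p over the
#' whole scan (overridable family size).
#'
#' @param assigned Individual tibble with `carrier_category`.
#' @param labels Categories to scan (default: all present except `WT`).
#' @param strata Onset strata (default all three).
#' @param eoad_boundary Early/late onset boundary.
#' @param family_size Bonferroni family; defaults to the number of tests in
#'   this scan.
#' @return Tibble with one row per label x stratum: counts, `or`, `ci_low`,
#'   `ci_high`, `p_fisher`, `p_adjusted`.
#' @export
burden_scan <- function(assigned,
                        labels = setdiff(intersect(CATEGORY_LEVELS,
                                                   unique(assigned$carrier_category)),
                                         "WT"),
                        strata = c("ALL", "EOAD", "LOAD"),
                        eoad_boundary = 65, family_size = NULL) {
  grid <- expand.grid(label = labels, stratum = strata,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tab <- build_table(assigned, grid$label[i], grid$stratum[i], eoad_boundary)
    orw <- odds_ratio_wald(tab)
    tibble::tibble(
      label = grid$label[i], stratum = grid$stratum[i],
      case_carriers = tab$case_carriers, case_noncarriers = tab$case_noncarriers,
      control_carriers = tab$control_carriers,
      control_noncarriers = tab$control_noncarriers,
      or = orw$or, ci_low = orw$ci_low, ci_high = orw$ci_high,
      p_fisher = fisher_p(tab)
    )
  })
  out <- dplyr::bind_rows(rows)
  m <- family_size %||% nrow(out)
  out$p_adjusted <- bonferroni(out$p_fisher, m)
  out
}

#' Covariate-adjusted burden association (logistic regression)
#'
#' Fits `case status ~ carrier + APOE-e4 count + PC1..PC6` by maximum
#' likelihood and returns the carrier coefficient. Individuals missing any
#' covariate are dropped (count reported). Complete separation (all carriers
#' on one side) is detected and reported as a flagged result with `NA`
#' standard error rather than a spurious estimate.
#'
#' @param assigned Individual tibble with `carrier_category` and covariates
#'   `apoe_e4`, `pc1`..`pc6`.
#' @param category Carrier category defining the exposure indicator.
#' @param covariates Covariate column names.
#' @return Tibble with `beta`, `se`, `p`, `or`, `n_used`, `n_dropped`,
#'   `separation`.
#' @export
adjusted_burden <- function(assigned, category,
                            covariates = c("apoe_e4", paste0("pc", 1:6))) {
  dat <- assigned
  dat$carrier <- as.integer(dat$carrier_category == category)
  dat$y <- as.integer(dat$status == "case")
  keep <- stats::complete.cases(dat[, c("y", "carrier", covariates)])
  n_dropped <- sum(!keep)
  dat <- dat[keep, , drop = FALSE]
  sep <- with(dat, min(tapply(y, carrier, function(v) min(mean(v), 1 - mean(v)))))
  if (length(unique(dat$carrier)) < 2L) {
    stop("no carriers of category ", category, " among complete cases", call. = FALSE)
  }
  fml <- stats::as.formula(paste("y ~ carrier +", paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(
    stats::glm(fml, data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  co <- summary(fit)$coefficients["carrier", ]
  separation <- is.na(sep) || sep == 0 || !fit$converged || abs(co[1]) > 15
  tibble::tibble(
    beta = if (separation) NA_real_ else unname(co[1]),
    se = if (separation) NA_real_ else unname(co[2]),
    p = if (separation) NA_real_ else unname(co[4]),
    or = if (separation) NA_real_ else exp(unname(co[1])),
    n_used = nrow(dat), n_dropped = n_dropped, separation = separation
  )
}

#' Likelihood-ratio test for a carrier x APOE-e4 interaction
#'
#' Compares the additive logistic model
#' `status ~ carrier + e4 + PC1..PC6` against the model with the
#' `carrier:e4` interaction; the statistic `2 (loglik_full - loglik_additive)`
#' is referred to a chi-squared distribution with the parameter-count
#' difference as degrees of freedom.
#'
#' @param assigned Individual tibble with `carrier_category`, `apoe_e4`
#'   (0/1/2) and `pc1`..`pc6`.
#' @param category Carrier category.
#' @return Tibble with `p_interaction`, `lrt_stat`, `df`.
#' @export
apoe_interaction_lrt <- function(assigned, category) {
  dat <- assigned
  dat$carrier <- as.integer(dat$carrier_category == category)
  dat$y <- as.integer(dat$status == "case")
  covars <- c("apoe_e4", paste0("pc", 1:6))
  keep <- stats::complete.cases(dat[, c("y", "carrier", covars)])
  dat <- dat[keep, , drop = FALSE]
  if (sum(dat$carrier) == 0L) {
    stop("no carriers of category ", category, " with complete covariates", call. = FALSE)
  }
  base <- paste("y ~ carrier + apoe_e4 +", paste(paste0("pc", 1:6), collapse = " + "))
  fit_add <- stats::glm(stats::as.formula(base), data = dat,
                        family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  fit_full <- stats::glm(stats::as.formula(paste(base, "+ carrier:apoe_e4")),
                         data = dat, family = stats::binomial(),
                         control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit_add$converged || !fit_full$converged) {
    stop("logistic fits did not converge for interaction test", call. = FALSE)
  }
  stat <- as.numeric(2 * (stats::logLik(fit_full) - stats::logLik(fit_add)))
  df <- attr(stats::logLik(fit_full), "df") - attr(stats::logLik(fit_add), "df")
  tibble::tibble(
    p_interaction = stats::pchisq(stat, df = df, lower.tail = FALSE),
    lrt_stat = stat, df = df
  )
}

#' Reference carrier counts for the published case/control sample
#'
#' Carrier counts per variant group as reported for the 18,959-case /
#' 21,893-control sequencing sample (6,155 early-onset cases). The `all`
#' column counts carriers among cases and controls combined; case carriers
#' are `all - controls`. These counts are the input from which the published
#' odds ratios are recomputed (see [burden_from_counts()]).
#'
#' @return Tibble with `label`, `carriers_all`, `carriers_eoad`,
#'   `carriers_load`, `carriers_controls`; cohort totals are attached as
#'   attributes `n_cases`, `n_eoad`, `n_controls`.
#' @export
sorl1_reference_counts <- function() {
  counts <- tibble::tribble(
    ~label,            ~carriers_all, ~carriers_eoad, ~carriers_load, ~carriers_controls,
    "PTV",             95L,  59L, 30L, 6L,
    "HPV",             180L, 80L, 71L, 29L,
    "MPV",             141L, 20L, 60L, 61L,
    "LPV",             170L, 33L, 52L, 85L,
    "NPV",             612L, 101L, 199L, 312L,
    "HPV_VPS10p",      43L,  22L, 16L, 5L,
    "HPV_L1L2_cys",    18L,  8L,  8L,  2L,
    "HPV_10CC",        30L,  11L, 13L, 6L,
    "HPV_YWTD",        25L,  13L, 7L,  5L,
    "HPV_CR",          57L,  23L, 26L, 8L,
    "HPV_CR_ONC",      42L,  12L, 22L, 8L,
    "HPV_3Fn",         15L,  8L,  5L,  2L
  )
  attr(counts, "n_cases") <- 18959L
  attr(counts, "n_eoad") <- 6155L
  attr(counts, "n_controls") <- 21893L
  counts
}

#' Burden statistics from aggregate carrier counts
#'
#' Rebuilds the per-stratum 2x2 tables from aggregate carrier counts (such as
#' [sorl1_reference_counts()]) and cohort totals, then computes the
#' cross-product OR, Wald interval and Fisher exact p for each group x
#' stratum. Used to reproduce published association tables without
#' individual-level data.
#'
#' @param counts Tibble like [sorl1_reference_counts()].
#' @param n_cases,n_eoad,n_controls Cohort totals (default: attributes of
#'   `counts`).
#' @return Tibble with one row per label x stratum.
#' @export
burden_from_counts <- function(counts,
                               n_cases = attr(counts, "n_cases"),
                               n_eoad = attr(counts, "n_eoad"),
                               n_controls = attr(counts, "n_controls")) {
  n_load <- n_cases - n_eoad
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    ctrl <- counts$carriers_controls[i]
    case_all <- counts$carriers_all[i] - ctrl
    cells <- list(
      ALL = c(case_all, n_cases - case_all, ctrl, n_controls - ctrl),
      EOAD = c(counts$carriers_eoad[i], n_eoad - counts$carriers_eoad[i],
               ctrl, n_controls - ctrl),
      LOAD = c(counts$carriers_load[i], n_load - counts$carriers_load[i],
               ctrl, n_controls - ctrl)
    )
    dplyr::bind_rows(lapply(names(cells), function(s) {
      x <- cells[[s]]
      orw <- odds_ratio_wald(x)
      tibble::tibble(
        label = counts$label[i], stratum = s,
        case_carriers = x[1], case_noncarriers = x[2],
        control_carriers = x[3], control_noncarriers = x[4],
        or = orw$or, ci_low = orw$ci_low, ci_high = orw$ci_high,
        p_fisher = fisher_p(x)
      )
    }))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- bonferroni(out$p_fisher, nrow(out))
  out
}
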