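#' Kaplan-Meier age-at-onset curve
#'
#' Product-limit estimate of the onset-age distribution with log-transformed
#' pointwise 95% bands. The case-only analysis treats every case as an event
#' (no censoring); censoring is supported for synthetic experiments and for
#' mixed inputs.
#'
#' @param ages Positive onset ages (or censoring ages).
#' @param events Logical/0-1 event indicators (default: all events).
#' @param conf_level Confidence level of the pointwise bands.
#' @return Object of class `sorl_km`: list with `time`, `surv`, `ci_low`,
#'   `ci_high`, `n_risk`, `n_event`, `n`.
#' @export
km_curve <- function(ages, events = rep(1L, length(ages)), conf_level = 0.95) {
  if (!length(ages)) stop("empty input to km_curve", call. = FALSE)
  stopifnot(all(ages > 0), length(events) == length(ages))
  fit <- survival::survfit(
    survival::Surv(ages, as.integer(events)) ~ 1,
    conf.type = "log", conf.int = conf_level
  )
  structure(
    list(time = fit$time, surv = fit$surv,
         ci_low = fit$lower, ci_high = fit$upper,
         n_risk = fit$n.risk, n_event = fit$n.event, n = length(ages)),
    class = "sorl_km"
  )
}

#' @export
print.sorl_km <- function(x, ...) {
  cat("<sorl_km> n =", x$n, ", ", sum(x$n_event), "events,",
      length(x$time), "time points\n")
  invisible(x)
}

#' Median and 10-90% inter-percentile range of a survival curve
#'
#' Quantile convention: the q-quantile is the smallest event time at which
#' the survival estimate drops to `1 - q` or below. A quantile the curve
#' never reaches (heavy censoring) is `NA`.
#'
#' @param curve A `sorl_km`.
#' @return List with `median`, `p10`, `p90`.
#' @export
median_and_ipr <- function(curve) {
  stopifnot(inherits(curve, "sorl_km"))
  q <- function(target) {
    hit <- which(curve$surv <= 1 - target & curve$n_event > 0)
    if (!length(hit)) return(NA_real_)
    curve$time[min(hit)]
  }
  list(median = q(0.5), p10 = q(0.1), p90 = q(0.9))
}

km_median <- function(ages, events = rep(1L, length(ages))) {
  median_and_ipr(km_curve(ages, events))$median
}

#' Median onset delta against a reference group, with bootstrap CI
#'
#' `delta = median(group) - median(reference)` under the Kaplan-Meier median
#' convention, with a percentile bootstrap interval over individuals
#' (resampling both groups independently). The resample count and seed are
#' explicit so intervals are reproducible.
#'
#' @param group_ages,ref_ages Onset ages of the two groups.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf_level Interval level.
#' @param seed Integer seed for the bootstrap.
#' @return List with `delta`, `ci_low`, `ci_high`, `n_boot`.
#' @export
delta_aao <- function(group_ages, ref_ages, n_boot = 2000, conf_level = 0.95,
                      seed = 20260101) {
  if (!length(group_ages) || !length(ref_ages)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  m_g <- km_median(group_ages)
  m_r <- km_median(ref_ages)
  if (is.na(m_g) || is.na(m_r)) {
    return(list(delta = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n_boot = n_boot))
  }
  delta <- m_g - m_r
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      g <- sample(group_ages, replace = TRUE)
      r <- sample(ref_ages, replace = TRUE)
      sorted_km_median(g) - sorted_km_median(r)
    }, numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(delta = delta, ci_low = ci[1], ci_high = ci[2], n_boot = n_boot)
}

# Uncensored KM median without the survfit overhead: the smallest order
# statistic x_(k) with k >= n/2, i.e. survival (n-k)/n <= 0.5.
sorted_km_median <- function(x) {
  s <- sort(x)
  s[ceiling(length(s) / 2)]
}

#' Log-rank test between two onset-age samples
#'
#' Standard (unweighted) log-rank chi-squared test, two-sided; symmetric in
#' group order.
#'
#' @param ages_a,ages_b Onset ages.
#' @param events_a,events_b Event indicators (default all events).
#' @return List with `p`, `chisq`, `df`.
#' @export
logrank <- function(ages_a, ages_b,
                    events_a = rep(1L, length(ages_a)),
                    events_b = rep(1L, length(ages_b))) {
  if (!length(ages_a) || !length(ages_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  time <- c(ages_a, ages_b)
  event <- c(as.integer(events_a), as.integer(events_b))
  grp <- rep(c("a", "b"), c(length(ages_a), length(ages_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       chisq = sd$chisq, df = 1L)
}

#' Case-only onset-age summary per carrier category
#'
#' For each requested category among cases: the Kaplan-Meier median with
#' 10-90% inter-percentile range, the median delta against wild-type
#' carriers with a bootstrap interval, and the log-rank p against wild-type.
#'
#' @param assigned Individual tibble with `carrier_category` (cases are
#'   selected internally).
#' @param categories Categories to summarize (default: all present except
#'   `WT`).
#' @param n_boot Bootstrap resamples for the delta interval.
#' @param seed Bootstrap seed.
#' @return Tibble with `label`, `n`, `median_aao`, `p10`, `p90`,
#'   `delta_vs_wt`, `delta_ci_low`, `delta_ci_high`, `logrank_p_vs_wt`.
#' @export
aao_summary <- function(assigned,
                        categories = setdiff(intersect(CATEGORY_LEVELS,
                                                       unique(assigned$carrier_category)),
                                             "WT"),
                        n_boot = 2000, seed = 20260101) {
  cases <- assigned[assigned$status == "case" & !is.na(assigned$aao_or_age), ,
                    drop = FALSE]
  wt_ages <- cases$aao_or_age[cases$carrier_category == "WT"]
  wt_row <- summarize_group("WT", wt_ages, wt_ages, n_boot, seed, is_wt = TRUE)
  rows <- lapply(categories, function(cat) {
    ages <- cases$aao_or_age[cases$carrier_category == cat]
    summarize_group(cat, ages, wt_ages, n_boot, seed)
  })
  dplyr::bind_rows(c(list(wt_row), rows))
}

summarize_group <- function(label, ages, wt_ages, n_boot, seed, is_wt = FALSE) {
  if (!length(ages)) {
    return(tibble::tibble(
      label = label, n = 0L, median_aao = NA_real_, p10 = NA_real_,
      p90 = NA_real_, delta_vs_wt = NA_real_, delta_ci_low = NA_real_,
      delta_ci_high = NA_real_, logrank_p_vs_wt = NA_real_
    ))
  }
  mq <- median_and_ipr(km_curve(ages))
  if (is_wt || !length(wt_ages)) {
    d <- list(delta = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    lr <- NA_real_
  } else {
    d <- delta_aao(ages, wt_ages, n_boot = n_boot, seed = seed)
    lr <- logrank(ages, wt_ages)$p
  }
  tibble::tibble(
    label = label, n = length(ages), median_aao = mq$median, p10 = mq$p10,
    p90 = mq$p90, delta_vs_wt = d$delta, delta_ci_low = d$ci_low,
    delta_ci_high = d$ci_high, logrank_p_vs_wt = lr
  )
}

#' Onset-age summaries stratified by APOE-e4 genotype
#'
#' Splits cases into e4/e4 homozygotes, e4 heterozygotes and e4-negative
#' individuals (missing APOE excluded, with a message giving the count), and
#' summarizes each category within each stratum; deltas are computed against
#' wild-type carriers of the *same* APOE stratum.
#'
#' @inheritParams aao_summary
#' @return Tibble with an `apoe_stratum` column prepended to the
#'   [aao_summary()] columns; strata with no individuals yield NA rows.
#' @export
apoe_stratified_summary <- function(assigned,
                                    categories = setdiff(intersect(CATEGORY_LEVELS,
                                                                   unique(assigned$carrier_category)),
                                                         "WT"),
                                    n_boot = 2000, seed = 20260101) {
  cases <- assigned[assigned$status == "case", , drop = FALSE]
  n_missing <- sum(is.na(cases$apoe_e4))
  if (n_missing) {
    message(n_missing, " case(s) with missing APOE genotype excluded from stratified summary")
  }
  if (all(is.na(cases$apoe_e4))) {
    warning("no APOE genotypes available; stratified summary is empty", call. = FALSE)
    return(tibble::tibble(apoe_stratum = character(0)))
  }
  strata <- list("e4/e4" = 2L, "e4 het" = 1L, "e4-negative" = 0L)
  out <- lapply(names(strata), function(s) {
    sub <- cases[!is.na(cases$apoe_e4) & cases$apoe_e4 == strata[[s]], , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    res <- aao_summary(sub, categories = categories, n_boot = n_boot, seed = seed)
    dplyr::bind_cols(tibble::tibble(apoe_stratum = rep(s, nrow(res))), res)
  })
  dplyr::bind_rows(out)
}
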