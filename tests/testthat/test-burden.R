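test_that("cross-product OR and Wald interval reproduce hand-checked values", {
  r <- odds_ratio_wald(c(89, 18870, 6, 21887))
  expect_equal(r$or, (89 * 21887) / (18870 * 6), tolerance = 1e-12)
  expect_equal(round(r$or, 1), 17.2)
  expect_equal(round(c(r$ci_low, r$ci_high), 1), c(7.5, 39.3))

  expect_equal(odds_ratio_wald(c(10, 10, 10, 10))$or, 1)
  z <- odds_ratio_wald(c(0, 100, 5, 95))
  expect_true(is.na(z$or) && is.na(z$ci_low))
  h <- odds_ratio_wald(c(0, 100, 5, 95), haldane = TRUE)
  expect_false(is.na(h$or))
})

test_that("OR is transposition-symmetric and reciprocal under label flips", {
  withr::with_seed(4, {
    for (i in 1:25) {
      x <- sample(1:50, 4, replace = TRUE)
      a <- odds_ratio_wald(x)$or
      transposed <- odds_ratio_wald(x[c(1, 3, 2, 4)])$or
      flipped <- odds_ratio_wald(x[c(3, 4, 1, 2)])$or
      expect_equal(a, transposed, tolerance = 1e-12)
      expect_equal(a, 1 / flipped, tolerance = 1e-12)
    }
  })
})

test_that("fisher_p matches its closed-form examples and reference routes", {
  expect_equal(fisher_p(c(5, 0, 0, 5)), 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(round(fisher_p(c(5, 0, 0, 5)), 5), 0.00794)
  expect_equal(fisher_p(c(1, 1, 1, 1)), 1)
  expect_lt(fisher_p(c(89, 18870, 6, 21887)), 1e-20)
  withr::with_seed(11, {
    for (i in 1:40) {
      x <- sample(0:30, 4, replace = TRUE)
      p_impl <- fisher_p(x)
      p_ora <- oracle_fisher(x[1], x[2], x[3], x[4])
      p_ref <- stats::fisher.test(matrix(x, 2, byrow = TRUE))$p.value
      expect_equal(p_impl, p_ora, tolerance = 1e-12)
      expect_equal(p_impl, p_ref, tolerance = 1e-9)
    }
  })
})

test_that("bonferroni caps at one and honours the family size", {
  expect_equal(bonferroni(0.01, family_size = 5), 0.05)
  expect_equal(bonferroni(0.5, family_size = 3), 1)
  expect_equal(bonferroni(0.2), 0.2)
  expect_equal(bonferroni(c(0.01, 0.04), family_size = 10), c(0.1, 0.4))
  expect_error(bonferroni(c(0.1, 0.2), family_size = 1), "family_size")
})

test_that("2x2 construction stratifies cases but keeps the full control set", {
  asg <- dplyr::bind_rows(
    make_assigned(8, 42, 2, 48, case_aao = 60),   # early-onset cases
    make_assigned(4, 46, 0, 0, case_aao = 70)     # late-onset cases
  )
  all_tab <- build_table(asg, "PTV", "ALL")
  eoad <- build_table(asg, "PTV", "EOAD")
  load <- build_table(asg, "PTV", "LOAD")
  expect_equal(all_tab$case_carriers, 12)
  expect_equal(eoad$case_carriers + load$case_carriers, all_tab$case_carriers)
  expect_equal(eoad$case_noncarriers + load$case_noncarriers,
               all_tab$case_noncarriers)
  expect_equal(eoad$control_carriers, all_tab$control_carriers)
  expect_equal(load$control_noncarriers, all_tab$control_noncarriers)
  # configurable boundary moves cases across strata
  eoad66 <- build_table(asg, "PTV", "EOAD", eoad_boundary = 66)
  expect_equal(eoad66$case_carriers, 8)
  expect_error(build_table(asg[asg$status == "control", ], "PTV", "ALL"), "empty")
})

test_that("burden_scan emits one consistent result per label and stratum", {
  vt <- simulate_variant_table(seed = 31)
  sim <- simulate_cohort(simulation_params(seed = 31), vt$variants, vt$truth)
  cl <- classify_variants(sim$cohort$variants, sim$cohort)
  asg <- assign_carriers(sim$cohort, cl)
  b <- burden_scan(asg)
  expect_equal(nrow(b), length(unique(b$label)) * 3L)
  for (lab in unique(b$label)) {
    sub <- b[b$label == lab, ]
    expect_equal(sub$case_carriers[sub$stratum == "ALL"],
                 sub$case_carriers[sub$stratum == "EOAD"] +
                   sub$case_carriers[sub$stratum == "LOAD"])
    ok <- !is.na(sub$or)
    expect_true(all(sub$ci_low[ok] <= sub$or[ok] & sub$or[ok] <= sub$ci_high[ok]))
  }
  expect_true(all(b$p_adjusted >= b$p_fisher - 1e-15))
  expect_true(all(b$p_adjusted <= 1))
})

test_that("adjusted logistic burden recovers a simulated carrier effect", {
  withr::with_seed(77, {
    n <- 20000
    carrier <- stats::rbinom(n, 1, 0.02)
    e4 <- stats::rbinom(n, 2, 0.14)
    pcs <- matrix(stats::rnorm(n * 6), ncol = 6)
    lp <- -0.5 + log(5) * carrier + log(2) * e4 + 0.2 * pcs[, 1]
    y <- stats::rbinom(n, 1, stats::plogis(lp))
    asg <- tibble::tibble(
      id = as.character(seq_len(n)),
      status = ifelse(y == 1, "case", "control"),
      aao_or_age = 70,
      carrier_category = ifelse(carrier == 1, "PTV", "WT"),
      apoe_e4 = e4,
      pc1 = pcs[, 1], pc2 = pcs[, 2], pc3 = pcs[, 3],
      pc4 = pcs[, 4], pc5 = pcs[, 5], pc6 = pcs[, 6]
    )
    fit <- adjusted_burden(asg, "PTV")
    expect_false(fit$separation)
    # true conditional OR 5 within the fit's 95% interval
    expect_gt(exp(fit$beta + 1.96 * fit$se), 5)
    expect_lt(exp(fit$beta - 1.96 * fit$se), 5)
    expect_lt(fit$p, 1e-10)

    # null carrier: beta near zero
    asg$carrier_category <- ifelse(stats::rbinom(n, 1, 0.02) == 1, "PTV", "WT")
    null_fit <- adjusted_burden(asg, "PTV")
    expect_lt(abs(null_fit$beta), 3 * null_fit$se + 0.5)

    # complete separation: all carriers are cases
    asg$carrier_category <- "WT"
    asg$carrier_category[which(asg$status == "case")[1:20]] <- "PTV"
    sep_fit <- adjusted_burden(asg, "PTV")
    expect_true(sep_fit$separation)
    expect_true(is.na(sep_fit$se))
  })
})

test_that("missing covariates are dropped with an accounting", {
  asg <- make_assigned(20, 180, 10, 190)
  asg$apoe_e4 <- rep(c(0L, 1L, NA), length.out = nrow(asg))
  for (k in 1:6) asg[[paste0("pc", k)]] <- 0
  fit <- adjusted_burden(asg, "PTV")
  expect_equal(fit$n_dropped, sum(is.na(asg$apoe_e4)))
  expect_equal(fit$n_used + fit$n_dropped, nrow(asg))
})

test_that("APOE interaction LRT is calibrated under additivity and detects interaction", {
  n <- 2500
  one_rep <- function(seed, gamma) {
    withr::with_seed(seed, {
      carrier <- stats::rbinom(n, 1, 0.05)
      e4 <- stats::rbinom(n, 2, 0.2)
      pcs <- matrix(stats::rnorm(n * 6), ncol = 6)
      lp <- -0.3 + log(3) * carrier + log(2) * e4 + gamma * carrier * e4
      y <- stats::rbinom(n, 1, stats::plogis(lp))
      asg <- tibble::tibble(
        id = as.character(seq_len(n)),
        status = ifelse(y == 1, "case", "control"), aao_or_age = 70,
        carrier_category = ifelse(carrier == 1, "PTV", "WT"), apoe_e4 = e4,
        pc1 = pcs[, 1], pc2 = pcs[, 2], pc3 = pcs[, 3], pc4 = pcs[, 4],
        pc5 = pcs[, 5], pc6 = pcs[, 6]
      )
      apoe_interaction_lrt(asg, "PTV")$p_interaction
    })
  }
  p_null <- vapply(1:300, one_rep, numeric(1), gamma = 0)
  p_alt <- vapply(1:60, one_rep, numeric(1), gamma = log(2.5))
  rej_null <- mean(p_null < 0.05)
  rej_alt <- mean(p_alt < 0.05)
  expect_gt(suppressWarnings(stats::ks.test(p_null, "punif")$p.value), 0.01)
  expect_lt(rej_null, 0.12)
  expect_gt(rej_alt, rej_null)

  asg <- make_assigned(0, 50, 0, 50)
  asg$apoe_e4 <- 0L
  for (k in 1:6) asg[[paste0("pc", k)]] <- 0
  expect_error(apoe_interaction_lrt(asg, "PTV"), "no carriers")
})

test_that("published-style aggregate counts rebuild into per-stratum tables", {
  counts <- sorl1_reference_counts()
  b <- burden_from_counts(counts)
  expect_equal(nrow(b), nrow(counts) * 3L)
  ptv <- b[b$label == "PTV", ]
  expect_equal(ptv$case_carriers[ptv$stratum == "ALL"], 89)
  expect_equal(ptv$case_carriers[ptv$stratum == "EOAD"] +
                 ptv$case_carriers[ptv$stratum == "LOAD"], 89)
  expect_equal(unique(ptv$control_carriers), 6)
  # zero-control-carrier groups give NA ORs, matching how such rows are reported
  ywtd_na <- burden_from_counts(tibble::tibble(
    label = "motif", carriers_all = 8L, carriers_eoad = 6L,
    carriers_load = 2L, carriers_controls = 0L
  ), n_cases = 18959L, n_eoad = 6155L, n_controls = 21893L)
  expect_true(all(is.na(ywtd_na$or)))
  expect_true(all(ywtd_na$p_fisher <= 1))
})
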