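fit_pair <- function(seed = 61, rr = 1.5, n = 600) {
  sim <- simulate_families(sim_config(n_case = n, n_strata = 1, rr = rr,
                                      var_freq = 0.3), seed = seed)
  fit_families(sim$families, "gene_dose")
}

test_that("the Wald interaction statistic is zero for identical strata", {
  fit <- fit_pair()
  w <- wald_interaction_test(list(fit, fit, fit))
  expect_equal(w$statistic, 0, tolerance = 1e-10)
  expect_equal(w$p_value, 1)
  expect_equal(w$df, 2)
})

test_that("with two strata the Wald test is the squared z difference", {
  f1 <- fit_pair(seed = 62, rr = 1.2)
  f2 <- fit_pair(seed = 63, rr = 2)
  w <- wald_interaction_test(list(f1, f2))
  t1 <- f1$estimates[["log_rr"]]; v1 <- f1$vcov[1, 1]
  t2 <- f2$estimates[["log_rr"]]; v2 <- f2$vcov[1, 1]
  expect_equal(w$statistic, (t1 - t2)^2 / (v1 + v2))
  expect_equal(w$df, 1)
  # trend test coincides with the Wald test for S = 2
  tr <- trend_test(list(f1, f2))
  expect_equal(tr$statistic^2, w$statistic)
  expect_equal(tr$p_value, w$p_value)
})

test_that("the Wald statistic ignores stratum ordering and baseline", {
  f1 <- fit_pair(seed = 64, rr = 1)
  f2 <- fit_pair(seed = 65, rr = 1.5)
  f3 <- fit_pair(seed = 66, rr = 2.2)
  w_fwd <- wald_interaction_test(list(f1, f2, f3))
  w_rev <- wald_interaction_test(list(f3, f2, f1))
  expect_equal(w_fwd$statistic, w_rev$statistic, tolerance = 1e-8)
  # trend flips sign but keeps the p-value under order reversal
  t_fwd <- trend_test(list(f1, f2, f3))
  t_rev <- trend_test(list(f3, f2, f1))
  expect_equal(t_fwd$statistic, -t_rev$statistic, tolerance = 1e-8)
  expect_equal(t_fwd$p_value, t_rev$p_value, tolerance = 1e-8)
})

test_that("trend on equal estimates is flat", {
  fit <- fit_pair(seed = 67)
  tr <- trend_test(list(fit, fit, fit))
  expect_equal(tr$slope, 0, tolerance = 1e-10)
  expect_equal(tr$p_value, 1)
})

test_that("tests degrade gracefully with unusable fits", {
  fit <- fit_pair(seed = 68)
  expect_equal(wald_interaction_test(list(fit))$status, "not_assessable")
  broken <- fit
  broken$converged <- FALSE
  expect_equal(wald_interaction_test(list(fit, broken))$status,
               "not_assessable")
})

test_that("stratified fits keep strata independent and pool correctly", {
  sim <- simulate_families(sim_config(n_case = c(400, 400, 400),
                                      rr = c(1, 1.5, 2.2), var_freq = 0.3),
                           seed = 69)
  sf <- stratified_fit(sim$families)
  expect_length(sf$stratum_fits, 3L)
  # identical data in each stratum gives identical estimates
  fam1 <- dplyr::filter(sim$families, stratum == 1)
  copies <- dplyr::bind_rows(fam1,
                             dplyr::mutate(fam1, stratum = 2L),
                             dplyr::mutate(fam1, stratum = 3L))
  sf_same <- stratified_fit(copies)
  ests <- vapply(sf_same$stratum_fits, function(f) f$estimates[["log_rr"]],
                 numeric(1))
  expect_equal(unname(diff(ests)), c(0, 0), tolerance = 1e-8)
  # pooled fit equals the single-stratum fit when S = 1
  sf1 <- stratified_fit(fam1)
  expect_equal(sf1$pooled$estimates, sf1$stratum_fits[["1"]]$estimates,
               tolerance = 1e-8)
})

test_that("run_gxme assembles estimates, tests and flags", {
  sim <- simulate_families(sim_config(n_case = c(500, 500, 500),
                                      rr = c(1, 1.5, 2.2), var_freq = 0.3),
                           seed = 70)
  res <- run_gxme(sim$families, snp_id = "rs1", category = "promoter")
  gl <- glance(res)
  expect_equal(gl$analysis, "gxme")
  expect_lt(gl$wald_p, 0.05)
  expect_lt(gl$trend_p, gl$wald_p) # monotone alternative favours the trend
  td <- tidy(res)
  expect_setequal(td$stratum, c("1", "2", "3", "all"))
  expect_true(all(td$conf.low <= td$rr & td$rr <= td$conf.high))
  expect_error(run_gxme(dplyr::filter(sim$families, stratum == 1)),
               "single methylation stratum")
})

test_that("run_pooxme tests the log RRR across strata", {
  sim <- simulate_families(
    sim_config(n_case = c(1000, 1000, 1000), model = "poo",
               rr_maternal = c(1, 1.8, 3), rr_paternal = c(1, 1, 1),
               var_freq = 0.3),
    seed = 71
  )
  res <- run_pooxme(sim$families, snp_id = "rs2")
  expect_lt(res$wald_p, 0.05)
  td <- tidy(res)
  expect_equal(unique(td$term), "log_rrr")
  # equal maternal and paternal risks: RRR about 1 everywhere
  sim0 <- simulate_families(
    sim_config(n_case = c(500, 500, 500), model = "poo",
               rr_maternal = c(1.5, 1.5, 1.5),
               rr_paternal = c(1.5, 1.5, 1.5), var_freq = 0.3),
    seed = 72
  )
  res0 <- run_pooxme(sim0$families)
  td0 <- tidy(res0)
  rrr_all <- td0$estimate[td0$stratum == "all"]
  expect_lt(abs(rrr_all), 0.15)
})

test_that("control comparison reproduces the false-positive screening logic", {
  sim <- simulate_families(sim_config(n_case = c(800, 800, 800),
                                      rr = c(1, 1.5, 2.2), var_freq = 0.3),
                           seed = 73)
  res_case <- run_gxme(sim$families)
  res_ctrl_sig <- res_case # same interaction pattern in controls
  out <- control_comparison(res_case, res_ctrl_sig)
  expect_equal(out$flag, "suspected_false_positive")
  expect_equal(out$control_wald_p, res_ctrl_sig$wald_p)
  res_ctrl_null <- res_case
  res_ctrl_null$wald_p <- 0.6
  expect_equal(control_comparison(res_case, res_ctrl_null)$flag, "ok")
  expect_equal(control_comparison(res_case, NULL)$flag, "not_assessable")
})

test_that("poo_scan ranks a true parent-of-origin SNP first", {
  set.seed(74)
  sims <- lapply(1:4, function(i) {
    rrm <- if (i == 1) 2 else 1
    simulate_families(sim_config(n_case = 700, n_strata = 1, model = "poo",
                                 rr_maternal = rrm, rr_paternal = 1,
                                 var_freq = 0.3),
                      seed = 740 + i)$families |>
      dplyr::mutate(snp_id = paste0("rs", i))
  })
  genotypes <- dplyr::bind_rows(sims)
  mono <- dplyr::mutate(sims[[2]], snp_id = "rs_mono", m = 0L, f = 0L,
                        c = 0L, ci = 1L, cj = 1L)
  expect_message(scan <- poo_scan(dplyr::bind_rows(genotypes, mono)),
                 "monomorphic")
  expect_equal(scan$snp_id[1], "rs1")
  expect_false("rs_mono" %in% scan$snp_id)
  expect_equal(nrow(scan), 4L)
})

test_that("BH adjustment matches the closed form", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_pvalues(0.37), 0.37)
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("qq data pairs sorted p-values with beta order-statistic bands", {
  one <- qq_data(0.3)
  expect_equal(one$p_expected, 0.5)
  set.seed(75)
  qq <- qq_data(runif(200))
  expect_equal(qq$p_observed, sort(qq$p_observed))
  expect_true(all(qq$band_lower <= qq$p_expected &
                    qq$p_expected <= qq$band_upper))
  expect_true(all(diff(qq$neglog10_expected) <= 0 |
                    diff(qq$neglog10_expected) >= 0)) # monotone axis
  p <- autoplot(qq)
  expect_s3_class(p, "ggplot")
})
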