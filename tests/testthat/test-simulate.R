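test_that("simulation is reproducible from the seed", {
  cfg <- sim_config(n_case = c(50, 50, 50), n_control = 30, rr = c(1, 1.5, 2))
  a <- simulate_families(cfg, seed = 81)
  b <- simulate_families(cfg, seed = 81)
  expect_identical(a$families, b$families)
  c <- simulate_families(cfg, seed = 82)
  expect_false(identical(a$families, c$families))
})

test_that("per-stratum case quotas and control counts are honoured", {
  cfg <- sim_config(n_case = c(40, 50, 60), n_control = 35,
                    rr = c(1, 1.3, 1.6))
  sim <- simulate_families(cfg, seed = 83)
  cases <- dplyr::filter(sim$families, status == "case")
  expect_equal(as.vector(table(cases$stratum)), c(40L, 50L, 60L))
  expect_equal(sum(sim$families$status == "control"), 35L)
})

test_that("the null keeps the case children at the population allele frequency", {
  cfg <- sim_config(n_case = 2500, n_strata = 1, rr = 1, var_freq = 0.3)
  sim <- simulate_families(cfg, seed = 84)
  expect_lt(abs(mean(sim$families$c) / 2 - 0.3), 0.02)
  # families are internally Mendelian-consistent
  expect_equal(sim$families$c,
               (sim$families$ci == 2L) + (sim$families$cj == 2L))
})

test_that("control genotypes follow HWE and Mendelian expectations", {
  cfg <- sim_config(n_case = 1, n_control = 3000, rr = 3, var_freq = 0.4,
                    baseline_risk = 0.001)
  sim <- simulate_families(cfg, seed = 85)
  mothers <- dplyr::filter(sim$families, status == "control")$m
  expected <- stats::dbinom(0:2, 2, 0.4)
  gof <- suppressWarnings(
    stats::chisq.test(tabulate(mothers + 1L, 3L), p = expected)
  )
  expect_gt(gof$p.value, 1e-4)
})

test_that("impossible penetrance is rejected before sampling", {
  expect_error(sim_config(rr = 12, baseline_risk = 0.05),
               "penetrance exceeds 1")
  expect_error(sim_config(model = "poo", rr_maternal = 8, rr_paternal = 8,
                          baseline_risk = 0.05),
               "penetrance exceeds 1")
})

test_that("methylation dependence tilts strata by the configured covariate", {
  cfg <- sim_config(n_case = 3000, n_strata = 3, rr = 1, var_freq = 0.4,
                    me_dependence = "child_symmetric", me_effect = 0.8)
  sim <- simulate_families(cfg, seed = 86)
  fam <- sim$families
  # higher child dose pushes samples into higher strata
  mean_dose <- tapply(fam$c, fam$stratum, mean)
  expect_true(mean_dose[[1]] < mean_dose[[3]])
  # symmetric by construction: orientation carries no extra information
  het <- dplyr::filter(fam, c == 1)
  tab <- table(het$ci, het$stratum)
  gof <- suppressWarnings(stats::chisq.test(tab))
  expect_gt(gof$p.value, 0.001)
})

test_that("beta blocks honour correlation and rank-agree with the strata", {
  cfg <- sim_config(n_case = c(60, 60, 60),
                    cpg_block = list(n_cpgs = 2, rho = 1, noise_sd = 0.04))
  sim <- simulate_families(cfg, seed = 87)
  expect_equal(sim$beta[[2]], sim$beta[[3]]) # rho = 1: identical columns
  cfg2 <- sim_config(n_case = c(60, 60, 60),
                     cpg_block = list(n_cpgs = 4, rho = 0.4, noise_sd = 0))
  sim2 <- simulate_families(cfg2, seed = 88)
  smry <- summarize_region(sim2$beta, sim2$manifest$cpg_id)
  joined <- dplyr::inner_join(sim2$families, smry,
                              by = c(child_sample_id = "sample_id"))
  rho <- stats::cor(joined$stratum, joined$mean_beta, method = "spearman")
  # region means sort samples consistently with the assigned strata
  expect_true(all(tapply(joined$mean_beta, joined$stratum, max)[-3] <
                    tapply(joined$mean_beta, joined$stratum, min)[-1]))
  expect_gt(rho, 0.8)
  # CpGs land within the 50 kb window of the synthetic SNP
  expect_true(all(abs(sim2$manifest$position - sim2$snp$position) <= 50000))
})

test_that("the region pipeline reproduces generator strata exactly at zero noise", {
  cfg <- sim_config(n_case = c(80, 80, 80),
                    cpg_block = list(n_cpgs = 5, rho = 0.5, noise_sd = 0))
  sim <- simulate_families(cfg, seed = 89)
  plan <- plan_analyses(as.list(sim$snp[1, ]), sim$manifest, sim$regions)
  expect_equal(nrow(plan), 1L)
  strata <- region_strata(sim$beta, plan$cpg_ids[[1]])
  joined <- dplyr::inner_join(sim$families, strata,
                              by = c(child_sample_id = "sample_id"))
  expect_equal(joined$stratum.x, joined$stratum.y)
})
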