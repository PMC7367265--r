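test_that("cell probabilities reduce to Mendelian transmission under the null", {
  p <- cell_probability(c(log_rr = 0), ordered = TRUE)
  dhet <- p[p$m == 1 & p$f == 1, ]
  expect_equal(dhet$prob, rep(0.25, 4))
  # every mating type matches raw transmission when RR = 1
  expect_equal(p$prob, transmission_prob(p$m, p$f, p$ci, p$cj))
  # conditional probabilities sum to 1 within each mating type
  sums <- tapply(p$prob, paste(p$m, p$f), sum)
  expect_equal(as.vector(sums), rep(1, 9))
})

test_that("double-het child distribution follows the RR weights", {
  # RR_single = 2, multiplicative double dose = 4:
  # ordered probs proportional to (1, 2, 2, 4)/4 -> (1, 2, 2, 4)/9
  p <- cell_probability(c(log_rr = log(2)), ordered = TRUE)
  dhet <- p[p$m == 1 & p$f == 1, ]
  expect_equal(sort(dhet$prob), c(1, 2, 2, 4) / 9)
  # unordered: het cell merges the two ordered states
  pu <- cell_probability(c(log_rr = log(2)))
  dhet_u <- pu[pu$m == 1 & pu$f == 1, ]
  expect_equal(dhet_u$prob[dhet_u$c_copies == 1], 4 / 9)
  # cross-check all mating types against the brute-force oracle
  for (mt in list(c(1, 1), c(0, 1), c(1, 2))) {
    got <- pu[pu$m == mt[1] & pu$f == mt[2], ]
    want <- oracle_child_probs(mt[1], mt[2], log(2))
    expect_equal(got$prob, unname(want[want > 0]), tolerance = 1e-12)
  }
})

test_that("poo model with equal parental RRs equals the gene-dose model", {
  p_poo <- cell_probability(c(log_rr_m = log(1.7), log_rr_f = log(1.7)),
                            model = "poo", ordered = TRUE)
  p_gd <- cell_probability(c(log_rr = log(1.7)), ordered = TRUE)
  expect_equal(p_poo$prob, p_gd$prob)
})

test_that("marginal cell probabilities normalise over all cells", {
  p <- cell_probability(c(log_rr = log(1.5)), condition = "marginal",
                        var_freq = 0.3)
  expect_equal(sum(p$prob), 1)
  expect_error(cell_probability(c(log_rr = 0), condition = "marginal"),
               "var_freq")
})

test_that("the fitted log-likelihood beats a brute-force grid search", {
  set.seed(21)
  for (i in 1:8) {
    tab <- random_cell_table(60)
    fit <- fit_stratum(tab, "gene_dose")
    expect_gte(fit$loglik, oracle_grid_max(tab) - 1e-6)
    # the package loglik agrees with the oracle at the MLE
    expect_equal(fit$loglik,
                 oracle_loglik(fit$estimates[["log_rr"]], tab),
                 tolerance = 1e-8)
  }
})

test_that("relative risks are recovered from simulated triads", {
  cfg_null <- sim_config(n_case = 2000, n_strata = 1, rr = 1,
                         var_freq = 0.3)
  sim <- simulate_families(cfg_null, seed = 31)
  fit <- fit_families(sim$families, "gene_dose")
  se <- sqrt(fit$vcov[1, 1])
  expect_lt(abs(fit$estimates[["log_rr"]]), 3 * se)

  cfg_alt <- sim_config(n_case = 2000, n_strata = 1, rr = 2,
                        var_freq = 0.3, baseline_risk = 0.005)
  sim2 <- simulate_families(cfg_alt, seed = 32)
  fit2 <- fit_families(sim2$families, "gene_dose")
  se2 <- sqrt(fit2$vcov[1, 1])
  expect_lt(abs(fit2$estimates[["log_rr"]] - log(2)), 3 * se2)
  expect_true(fit2$converged)
  expect_equal(sum(fit2$expected_cells$expected), fit2$n_families)
})

test_that("a free double dose recovers a non-multiplicative penetrance", {
  cfg <- sim_config(n_case = 3000, n_strata = 1, rr = 1.5, rr_double = 1.5,
                    var_freq = 0.4, baseline_risk = 0.005)
  sim <- simulate_families(cfg, seed = 33)
  fit <- fit_families(sim$families, "gene_dose", dose = "free")
  se_dd <- sqrt(fit$vcov["log_rr_dd", "log_rr_dd"])
  expect_lt(abs(fit$estimates[["log_rr_dd"]] - log(1.5)), 3 * se_dd)
  se_s <- sqrt(fit$vcov["log_rr", "log_rr"])
  expect_lt(abs(fit$estimates[["log_rr"]] - log(1.5)), 3 * se_s)
})

test_that("conditional fits are robust to a non-HWE mating distribution", {
  # hand-rolled generator with skewed, correlated parental genotypes:
  # the conditional likelihood only uses transmissions within mating type,
  # so the RR estimate must remain consistent
  set.seed(35)
  n_pool <- 200000
  m <- sample(0:2, n_pool, replace = TRUE, prob = c(0.6, 0.1, 0.3))
  f <- ifelse(runif(n_pool) < 0.5, m, sample(0:2, n_pool, replace = TRUE,
                                             prob = c(0.2, 0.5, 0.3)))
  ci <- 1L + rbinom(n_pool, 1, m / 2)
  cj <- 1L + rbinom(n_pool, 1, f / 2)
  dose <- (ci == 2L) + (cj == 2L)
  rr <- 1.6
  case <- rbinom(n_pool, 1, 0.01 * rr^dose) == 1L
  fam <- make_families(m[case], f[case], dose[case])
  fit <- fit_families(fam, "gene_dose")
  se <- sqrt(fit$vcov[1, 1])
  expect_lt(abs(fit$estimates[["log_rr"]] - log(rr)), 3 * se)
})

test_that("degenerate tables are rejected or flagged", {
  uninformative <- tibble::tibble(m = c(0, 2), f = c(0, 2),
                                  c_copies = c(0, 2), count = c(5, 5))
  expect_error(fit_stratum(uninformative, "gene_dose"),
               "Non-identifiable")
  inconsistent <- tibble::tibble(m = 0, f = 0, c_copies = 2, count = 3)
  expect_error(fit_stratum(inconsistent, "gene_dose"), "inconsistent")
  sparse <- tibble::tibble(m = c(1, 1), f = c(1, 1), c_copies = c(0, 2),
                           count = c(2, 1))
  fit <- fit_stratum(sparse, "gene_dose")
  expect_true("unstable" %in% fit$flags)
})

test_that("tidy and glance summarise stratum fits", {
  set.seed(36)
  tab <- random_cell_table(200)
  fit <- fit_stratum(tab, "gene_dose", stratum = 2)
  td <- tidy(fit)
  expect_equal(td$term, "log_rr")
  expect_true(td$conf.low <= td$rr && td$rr <= td$conf.high)
  gl <- glance(fit)
  expect_equal(gl$stratum, "2")
  expect_equal(gl$n_families, sum(tab$count))
  # poo fit reports the derived log RRR with a delta-method SE
  sim <- simulate_families(sim_config(n_case = 800, n_strata = 1,
                                      model = "poo", rr_maternal = 2,
                                      rr_paternal = 1, var_freq = 0.3),
                           seed = 37)
  fit_p <- fit_families(sim$families, "poo")
  td_p <- tidy(fit_p)
  expect_setequal(td_p$term, c("log_rr_m", "log_rr_f", "log_rrr"))
  rrr <- td_p[td_p$term == "log_rrr", ]
  expect_equal(rrr$estimate,
               td_p$estimate[td_p$term == "log_rr_m"] -
                 td_p$estimate[td_p$term == "log_rr_f"])
  expect_lt(abs(rrr$estimate - log(2)), 3 * rrr$std.error)
})
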