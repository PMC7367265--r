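test_that("beta values follow the intensity formula and stay in [0, 1)", {
  expect_equal(beta_from_intensities(900, 0), 0.9)
  expect_equal(beta_from_intensities(0, 0), 0)
  expect_equal(beta_from_intensities(100, 800), 0.1)
  expect_error(beta_from_intensities(-1, 5), "non-negative")
  set.seed(4)
  b <- beta_from_intensities(runif(100, 0, 1e4), runif(100, 0, 1e4))
  expect_true(all(b >= 0 & b < 1))
})

test_that("the 50 kb window boundary is inclusive and chromosome-aware", {
  snp <- list(snp_id = "rs1", chromosome = "2", position = 100000L)
  manifest <- tibble::tibble(
    cpg_id = c("at_edge", "past_edge", "other_chrom", "close"),
    chromosome = c("2", "2", "3", "2"),
    position = c(150000L, 150001L, 100000L, 99000L)
  )
  got <- select_cpgs_near_snp(manifest, snp)
  expect_setequal(got$cpg_id, c("at_edge", "close"))
  # monotone in max_distance: enlarging the window never removes a CpG
  smaller <- select_cpgs_near_snp(manifest, snp, max_distance = 10000)
  expect_true(all(smaller$cpg_id %in% got$cpg_id))
  # mismatched genome builds are refused when both sides are tagged
  attr(manifest, "build") <- "GRCh38"
  expect_error(
    select_cpgs_near_snp(manifest, c(snp, build = "GRCh37")),
    "build mismatch"
  )
})

test_that("CpGs are classified into every overlapping category", {
  cpgs <- tibble::tibble(
    cpg_id = c("cg1", "cg2", "cg3"),
    chromosome = "1",
    position = c(500L, 100L, 5000L)
  )
  regions <- tibble::tibble(
    region_id = c("prom1", "gene1"),
    chromosome = "1",
    start = c(100L, 400L),
    end = c(600L, 900L),
    category = c("promoter", "gene_body")
  )
  got <- classify_cpgs(cpgs, regions)
  # cg1 is inside both the promoter and the gene body
  expect_setequal(got$category[got$cpg_id == "cg1"],
                  c("promoter", "gene_body"))
  # position == region start is included (closed intervals)
  expect_true("cg2" %in% got$cpg_id[got$category == "promoter"])
  # cg3 overlaps nothing and is dropped
  expect_false("cg3" %in% got$cpg_id)
  expect_equal(nrow(classify_cpgs(cpgs, regions[0, ])), 0L)
  expect_error(
    classify_cpgs(cpgs, dplyr::mutate(regions, category = "exon")),
    "Unknown region category"
  )
})

test_that("region summaries average non-missing betas per sample", {
  beta <- tibble::tibble(
    sample_id = c("A", "B", "C"),
    cg1 = c(0.75, 0.25, 0.2),
    cg2 = c(0.25, 0.75, NA),
    cg3 = c(NA, NA, 0.4)
  )
  # two individuals with opposite per-CpG values share the same mean
  s12 <- summarize_region(beta, c("cg1", "cg2"))
  expect_equal(s12$mean_beta[s12$sample_id == "A"], 0.5)
  expect_equal(s12$mean_beta[s12$sample_id == "B"], 0.5)
  # missing values are skipped in the mean
  s_all <- summarize_region(beta, c("cg1", "cg2", "cg3"))
  expect_equal(s_all$mean_beta[s_all$sample_id == "C"], mean(c(0.2, 0.4)))
  # single CpG is the identity
  expect_equal(summarize_region(beta, "cg1")$mean_beta, beta$cg1)
  # permutation invariance in CpG order
  expect_equal(summarize_region(beta, c("cg2", "cg1"))$mean_beta,
               s12$mean_beta)
  expect_error(summarize_region(beta, character()), "empty")
  expect_error(summarize_region(beta, "cg9"), "cg9")
  # sample missing everywhere gets NA
  beta$cg3[1:2] <- NA
  expect_true(is.na(summarize_region(beta, "cg3")$mean_beta[1]))
})

test_that("strata are equally sized with larger groups at lower strata", {
  smry <- tibble::tibble(sample_id = sprintf("s%02d", 1:9),
                         mean_beta = (1:9) / 10)
  got <- assign_strata(smry)
  expect_equal(as.vector(table(got$stratum)), c(3L, 3L, 3L))
  # lowest values land in stratum 1
  expect_equal(got$stratum[got$mean_beta <= 0.3], rep(1L, 3))
  expect_length(attr(got, "boundaries"), 2L)

  smry10 <- tibble::tibble(sample_id = sprintf("s%02d", 1:10),
                           mean_beta = (1:10) / 11)
  got10 <- assign_strata(smry10)
  expect_equal(as.vector(table(got10$stratum)), c(4L, 3L, 3L))

  expect_error(assign_strata(smry[1:2, ]), "at least 3")
  # degenerate distribution: deterministic split by sample id with warning
  tied <- tibble::tibble(sample_id = sprintf("s%02d", 1:6),
                         mean_beta = rep(0.5, 6))
  expect_warning(got_t <- assign_strata(tied), "Degenerate")
  expect_equal(got_t$stratum, rep(1:3, each = 2))
  # samples with missing summaries belong to no stratum
  with_na <- dplyr::add_row(smry, sample_id = "s99", mean_beta = NA)
  expect_false("s99" %in% assign_strata(with_na)$sample_id)
})

test_that("analysis planning yields one unit per populated category", {
  snp <- list(snp_id = "rs1", chromosome = "1", position = 10000L)
  manifest <- tibble::tibble(
    cpg_id = c("cg1", "cg2", "cg3"),
    chromosome = "1",
    position = c(9000L, 11000L, 40000L)
  )
  regions <- tibble::tibble(
    region_id = c("p1", "g1", "e1"),
    chromosome = "1",
    start = c(8500L, 10500L, 39000L),
    end = c(9500L, 12000L, 41000L),
    category = c("promoter", "gene_body", "enhancer")
  )
  plan <- plan_analyses(snp, manifest, regions)
  expect_equal(nrow(plan), 3L) # -> six analyses (GxMe + PoOxMe each)
  plan2 <- plan_analyses(snp, manifest, regions[1:2, ])
  expect_equal(nrow(plan2), 2L)
  expect_message(
    plan0 <- plan_analyses(list(snp_id = "rs2", chromosome = "9",
                                position = 1L), manifest, regions),
    "no CpGs"
  )
  expect_equal(nrow(plan0), 0L)
})
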