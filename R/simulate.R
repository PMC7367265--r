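# ---- synthetic triad/dyad data with methylation ----------------------------

#' Simulation configuration for family-methylation data
#'
#' Defines the generative model for case-parent triads with methylation
#' strata: Hardy-Weinberg parents at variant frequency `var_freq`,
#' Mendelian transmission with recorded parental origin, a methylation
#' stratum drawn with configurable dependence on the genotypes, and
#' disease risk following the stratum-specific penetrance
#' B * RR_M * RR_F. Families are ascertained by their disease outcome
#' (rejection sampling), so with a small `baseline_risk` the control
#' families approximate the population distribution (rare-disease
#' approximation).
#'
#' @param var_freq Variant allele frequency in (0, 1).
#' @param n_case Number of case families: a scalar total, or a vector of
#'   length `n_strata` of per-stratum quotas (the natural emulation of an
#'   analysis whose strata are tertiles, hence exactly balanced).
#' @param n_control Number of control families (ascertained without
#'   stratum quotas).
#' @param design `"triad"`, `"mother_dyad"` (father genotype masked) or
#'   `"father_dyad"`.
#' @param model `"gene_dose"` or `"poo"`.
#' @param rr For `model = "gene_dose"`: single-dose relative risk per
#'   stratum (length `n_strata`, recycled).
#' @param rr_maternal,rr_paternal For `model = "poo"`: per-stratum
#'   relative risks of a maternally / paternally inherited variant allele.
#' @param rr_double Optional per-stratum double-dose relative risk;
#'   defaults to the multiplicative dose-response (product of single-dose
#'   RRs).
#' @param baseline_risk Baseline disease risk B (scalar or per stratum);
#'   keep small (default 0.01) so the rare-disease approximation holds in
#'   simulated controls.
#' @param me_dependence How the methylation stratum depends on genotype:
#'   `"independent"`; `"parental"` (depends on the parental allele-dose
#'   sum, symmetric in mother/father, so the origin-symmetry condition
#'   holds); `"child_symmetric"` (depends on the unordered child dose:
#'   genotype-methylation independence violated but origin symmetry
#'   preserved); `"child_asymmetric"` (depends on the maternal-origin
#'   variant indicator: origin symmetry violated, an asymmetric meQTL).
#' @param me_effect Strength of the dependence (log-scale tilt per unit of
#'   the genotype covariate per unit of the centred stratum score).
#' @param n_strata Number of methylation strata; default 3.
#' @param cpg_block Optional list configuring raw beta generation, see
#'   [simulate_beta_block()]: `n_cpgs`, `rho` (within-region
#'   correlation), `noise_sd` (logit-scale noise), `category`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(var_freq = 0.3, n_case = 500, n_control = 0,
                       design = c("triad", "mother_dyad", "father_dyad"),
                       model = c("gene_dose", "poo"), rr = 1,
                       rr_maternal = 1, rr_paternal = 1, rr_double = NULL,
                       baseline_risk = 0.01,
                       me_dependence = c("independent", "parental",
                                         "child_symmetric",
                                         "child_asymmetric"),
                       me_effect = 0, n_strata = 3, cpg_block = NULL) {
  design <- match.arg(design)
  model <- match.arg(model)
  me_dependence <- match.arg(me_dependence)
  n_strata <- as.integer(n_strata)
  stopifnot(var_freq > 0, var_freq < 1, n_strata >= 1L,
            all(baseline_risk > 0), all(baseline_risk < 1),
            all(rr > 0), all(rr_maternal > 0), all(rr_paternal > 0),
            is.null(rr_double) || all(rr_double > 0),
            all(n_case >= 0), n_control >= 0,
            length(n_case) %in% c(1L, n_strata))
  cfg <- list(
    var_freq = var_freq, n_case = n_case, n_control = n_control,
    design = design, model = model,
    rr = rep_len(rr, n_strata),
    rr_maternal = rep_len(rr_maternal, n_strata),
    rr_paternal = rep_len(rr_paternal, n_strata),
    rr_double = if (is.null(rr_double)) NULL else
      rep_len(rr_double, n_strata),
    baseline_risk = rep_len(baseline_risk, n_strata),
    me_dependence = me_dependence, me_effect = me_effect,
    n_strata = n_strata, cpg_block = cpg_block
  )
  # penetrance must be a probability in every cell, checked before sampling
  max_pen <- max(cfg$baseline_risk * max_risk_factor(cfg))
  if (max_pen > 1) {
    stop("Invalid configuration: penetrance exceeds 1 (max ",
         format(max_pen), ") for some genotype/stratum cell.",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# largest per-stratum penetrance risk factor over genotype cells
max_risk_factor <- function(cfg) {
  double <- if (!is.null(cfg$rr_double)) {
    cfg$rr_double
  } else if (cfg$model == "gene_dose") {
    cfg$rr^2
  } else {
    cfg$rr_maternal * cfg$rr_paternal
  }
  single <- if (cfg$model == "gene_dose") {
    cfg$rr
  } else {
    pmax(cfg$rr_maternal, cfg$rr_paternal)
  }
  pmax(1, single, double)
}

# per-family penetrance risk factor given stratum and ordered genotype
sim_risk_factor <- function(cfg, stratum, ci, cj) {
  d <- (ci == 2L) + (cj == 2L)
  fac <- if (cfg$model == "gene_dose") {
    cfg$rr[stratum]^d
  } else {
    cfg$rr_maternal[stratum]^(ci == 2L) * cfg$rr_paternal[stratum]^(cj == 2L)
  }
  if (!is.null(cfg$rr_double)) {
    fac[d == 2L] <- cfg$rr_double[stratum[d == 2L]]
  }
  fac
}

# genotype covariate driving the methylation-genotype dependence
me_covariate <- function(cfg, m, f, ci, cj) {
  switch(cfg$me_dependence,
    independent = rep(0, length(m)),
    parental = (m + f) / 2,
    child_symmetric = (ci == 2L) + (cj == 2L),
    child_asymmetric = as.numeric(ci == 2L)
  )
}

# draw methylation strata given the covariate g: P(Me = s) proportional to
# exp(me_effect * g * centred score of s)
draw_strata <- function(cfg, g) {
  S <- cfg$n_strata
  if (cfg$me_effect == 0 || all(g == 0)) {
    return(sample.int(S, length(g), replace = TRUE))
  }
  scores <- seq_len(S) - (S + 1) / 2
  W <- exp(cfg$me_effect * outer(g, scores))
  tot <- rowSums(W)
  cm <- W
  if (S > 1L) {
    for (s in 2:S) cm[, s] <- cm[, s - 1L] + W[, s]
  }
  u <- stats::runif(length(g)) * tot
  1L + rowSums(cm[, -S, drop = FALSE] < u)
}

#' Simulate case-parent families with methylation strata
#'
#' Draws families from the generative model in [sim_config()] and
#' ascertains cases and controls by rejection sampling on the disease
#' outcome. The true parental origin of the child's alleles (`ci`, `cj`)
#' and the methylation stratum are recorded; for dyad designs the masked
#' parent's genotype is `NA` in `m`/`f` (the truth is not retained, as in
#' real data). Reproducible given the seed.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A list of class `triadme_sim` with `families` (tibble:
#'   `family_id`, `design`, `status`, `m`, `f`, `c`, `ci`, `cj`,
#'   `stratum`, `child_sample_id`) and `config`; when
#'   `config$cpg_block` is set, also `beta`, `manifest`, `regions` and
#'   `snp` from [simulate_beta_block()].
#' @export
simulate_families <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  S <- cfg$n_strata
  case_quota <- if (length(cfg$n_case) == 1L) cfg$n_case else cfg$n_case
  per_stratum <- length(cfg$n_case) == S && S > 1L
  got_case <- if (per_stratum) integer(S) else 0L
  got_control <- 0L
  keep <- list()
  # expected yield governs the batch size
  p_case <- mean(cfg$baseline_risk)
  need_cases <- sum(cfg$n_case)
  batch <- as.integer(min(5e5, max(2e4, ceiling(need_cases / p_case / 4))))
  for (round in 1:400) {
    m <- stats::rbinom(batch, 2, cfg$var_freq)
    f <- stats::rbinom(batch, 2, cfg$var_freq)
    ci <- 1L + stats::rbinom(batch, 1, m / 2)
    cj <- 1L + stats::rbinom(batch, 1, f / 2)
    g <- me_covariate(cfg, m, f, ci, cj)
    stratum <- draw_strata(cfg, g)
    pen <- cfg$baseline_risk[stratum] * sim_risk_factor(cfg, stratum, ci, cj)
    d <- stats::rbinom(batch, 1, pen)
    df <- data.frame(m = m, f = f, ci = ci, cj = cj,
                     stratum = stratum, d = d)
    # take cases up to quota
    cases <- df[df$d == 1L, , drop = FALSE]
    if (per_stratum) {
      picked <- lapply(seq_len(S), function(s) {
        pool <- cases[cases$stratum == s, , drop = FALSE]
        utils::head(pool, max(0L, cfg$n_case[s] - got_case[s]))
      })
      picked <- do.call(rbind, picked)
      got_case <- got_case + tabulate(picked$stratum, nbins = S)
    } else {
      picked <- utils::head(cases, max(0L, cfg$n_case - got_case))
      got_case <- got_case + nrow(picked)
    }
    controls <- utils::head(df[df$d == 0L, , drop = FALSE],
                            max(0L, cfg$n_control - got_control))
    got_control <- got_control + nrow(controls)
    keep[[length(keep) + 1L]] <- rbind(picked, controls)
    done_cases <- if (per_stratum) all(got_case >= cfg$n_case) else
      got_case >= cfg$n_case
    if (done_cases && got_control >= cfg$n_control) break
  }
  if (!done_cases || got_control < cfg$n_control) {
    stop("Ascertainment did not reach the requested sample sizes; ",
         "increase baseline_risk or lower the target n.", call. = FALSE)
  }
  fam <- dplyr::bind_rows(keep) |>
    tibble::as_tibble() |>
    dplyr::mutate(
      family_id = sprintf("fam%05d", dplyr::row_number()),
      child_sample_id = sprintf("child%05d", dplyr::row_number()),
      status = ifelse(.data$d == 1L, "case", "control"),
      c = (.data$ci == 2L) + (.data$cj == 2L),
      design = cfg$design
    )
  if (cfg$design == "mother_dyad") fam$f <- NA_integer_
  if (cfg$design == "father_dyad") fam$m <- NA_integer_
  fam <- fam |>
    dplyr::select("family_id", "design", "status", "m", "f", "c",
                  "ci", "cj", "stratum", "child_sample_id")
  out <- list(families = fam, config = cfg)
  class(out) <- "triadme_sim"
  if (!is.null(cfg$cpg_block)) {
    blk <- do.call(simulate_beta_block, c(
      list(strata = fam$stratum, sample_ids = fam$child_sample_id,
           n_strata = S),
      cfg$cpg_block
    ))
    out <- c(out, blk)
    class(out) <- "triadme_sim"
  }
  out
}

#' Simulate raw CpG beta values consistent with assigned strata
#'
#' Generates a block of correlated logit-normal beta values for one
#' synthetic region near one synthetic SNP. Each sample receives a latent
#' region-mean level drawn from disjoint intervals ordered by its assigned
#' stratum, so region means rank-agree with the strata by construction;
#' per-CpG offsets (scaled by `sqrt(1 - rho)`, hence vanishing at full
#' correlation) and correlated logit-scale noise are added on top. With
#' `noise_sd = 0` the region-average pipeline reproduces the assigned
#' strata exactly (when the stratum sizes match the equal-split pattern);
#' with `rho = 1` all CpG columns are identical.
#'
#' @param strata Integer stratum label per sample.
#' @param sample_ids Sample identifiers.
#' @param n_strata Number of strata.
#' @param n_cpgs CpGs in the region; default 5.
#' @param rho Within-region correlation in (0, 1]; default 0.5.
#' @param noise_sd Logit-scale noise standard deviation; default 0.05.
#' @param category Region category for the synthetic annotation; default
#'   `"promoter"`.
#' @param chromosome,snp_position Coordinates of the synthetic SNP; the
#'   CpGs are placed within 50 kb.
#' @return A list with `beta` (tibble: `sample_id` + one column per CpG),
#'   `manifest`, `regions` and `snp`.
#' @export
simulate_beta_block <- function(strata, sample_ids, n_strata = 3,
                                n_cpgs = 5, rho = 0.5, noise_sd = 0.05,
                                category = "promoter", chromosome = "1",
                                snp_position = 1000000L) {
  stopifnot(length(strata) == length(sample_ids), n_cpgs >= 1,
            rho >= 0, rho <= 1, noise_sd >= 0)
  n <- length(strata)
  S <- as.integer(n_strata)
  breaks <- seq(0.3, 0.7, length.out = S + 1L)
  u <- stats::runif(n, breaks[strata], breaks[strata + 1L])
  offsets <- if (n_cpgs == 1L) 0 else {
    sqrt(1 - rho) * 0.15 * scale(seq_len(n_cpgs), scale = FALSE)[, 1L]
  }
  z_shared <- stats::rnorm(n, 0, noise_sd)
  beta_mat <- vapply(seq_len(n_cpgs), function(k) {
    eps <- sqrt(rho) * z_shared +
      sqrt(1 - rho) * stats::rnorm(n, 0, noise_sd)
    stats::plogis(stats::qlogis(u) + offsets[k] + eps)
  }, numeric(n))
  cpg_ids <- sprintf("cg%07d", seq_len(n_cpgs))
  colnames(beta_mat) <- cpg_ids
  positions <- as.integer(snp_position + 1000L * seq_len(n_cpgs))
  list(
    beta = dplyr::bind_cols(tibble::tibble(sample_id = sample_ids),
                            tibble::as_tibble(beta_mat)),
    manifest = tibble::tibble(cpg_id = cpg_ids, chromosome = chromosome,
                              position = positions),
    regions = tibble::tibble(
      region_id = "region1", chromosome = chromosome,
      start = min(positions) - 100L, end = max(positions) + 100L,
      category = category
    ),
    snp = tibble::tibble(snp_id = "snp1", chromosome = chromosome,
                         position = as.integer(snp_position))
  )
}
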