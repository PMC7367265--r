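# ---- stratified fits and interaction tests ---------------------------------

#' Fit the relative-risk model within each methylation stratum
#'
#' Partitions case families by their methylation stratum, fits the model
#' independently in each stratum, and additionally fits the whole dataset
#' ignoring strata (the pooled "all" column). A stratum whose fit fails is
#' kept as `NULL` with a warning and the remaining strata are still
#' fitted.
#'
#' @param families Data frame of case families with `m`, `f`, `c` and
#'   `stratum`.
#' @param model,dose,method As in [fit_families()].
#' @param ... Passed to [fit_families()].
#' @return An object of class `stratified_fit`: a list with
#'   `stratum_fits` (one `stratum_fit` per stratum, in stratum order),
#'   `pooled` and `model`/`dose`.
#' @export
stratified_fit <- function(families, model = c("gene_dose", "poo"),
                           dose = c("multiplicative", "free"),
                           method = c("auto", "conditional", "em"), ...) {
  model <- match.arg(model)
  dose <- match.arg(dose)
  method <- match.arg(method)
  stopifnot("stratum" %in% names(families))
  strata <- sort(unique(families$stratum))
  fits <- lapply(strata, function(s) {
    fam_s <- families[families$stratum == s, , drop = FALSE]
    tryCatch(
      fit_families(fam_s, model = model, dose = dose, method = method,
                   stratum = s, ...),
      error = function(e) {
        warning("Stratum ", s, " could not be fitted: ",
                conditionMessage(e), call. = FALSE)
        NULL
      }
    )
  })
  names(fits) <- as.character(strata)
  pooled <- tryCatch(
    fit_families(families, model = model, dose = dose, method = method,
                 stratum = "all", ...),
    error = function(e) {
      warning("Pooled fit failed: ", conditionMessage(e), call. = FALSE)
      NULL
    }
  )
  structure(
    list(stratum_fits = fits, pooled = pooled, model = model, dose = dose),
    class = "stratified_fit"
  )
}

#' Wald test for interaction across methylation strata
#'
#' Tests equality of the selected log-scale parameters across strata with
#' the Wald statistic W = (C theta)' (C V C')^{-1} (C theta), where theta
#' stacks the per-stratum parameter vectors, C takes successive
#' differences between adjacent strata, and V is block-diagonal because
#' the strata partition the families into independent samples. W is
#' chi-square with df = rank(C) under the null of no interaction. The
#' statistic does not depend on which stratum is taken as baseline.
#'
#' @param fits List of `stratum_fit` objects (one per stratum), or a
#'   `stratified_fit`.
#' @param parameter Names of the tested log-scale parameters, or `"rrr"`
#'   to test the log relative-risk ratio of a parent-of-origin model.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `status`
#'   (`"ok"` or `"not_assessable"` when fewer than two usable fits or a
#'   singular contrast covariance).
#' @export
wald_interaction_test <- function(fits, parameter = "log_rr") {
  fits <- as_fit_list(fits)
  fits <- fits[!vapply(fits, is.null, logical(1))]
  fits <- fits[vapply(fits, function(f) isTRUE(f$converged), logical(1))]
  if (length(fits) < 2L) {
    return(test_row(NA, NA, NA, "not_assessable"))
  }
  parts <- lapply(fits, fit_theta, parameter = parameter)
  k <- length(parts[[1L]]$theta)
  S <- length(parts)
  theta <- unlist(lapply(parts, `[[`, "theta"), use.names = FALSE)
  V <- matrix(0, S * k, S * k)
  for (s in seq_len(S)) {
    ix <- (s - 1L) * k + seq_len(k)
    V[ix, ix] <- parts[[s]]$vcov
  }
  # successive-difference contrasts between adjacent strata
  C <- matrix(0, (S - 1L) * k, S * k)
  for (s in seq_len(S - 1L)) {
    rows <- (s - 1L) * k + seq_len(k)
    C[rows, (s - 1L) * k + seq_len(k)] <- diag(k)
    C[rows, s * k + seq_len(k)] <- -diag(k)
  }
  d <- C %*% theta
  M <- C %*% V %*% t(C)
  W <- tryCatch(drop(t(d) %*% solve(M, d)), error = function(e) NA_real_)
  if (!is.finite(W)) {
    return(test_row(NA, NA, NA, "not_assessable"))
  }
  df <- qr(C)$rank
  test_row(W, df, stats::pchisq(W, df, lower.tail = FALSE), "ok")
}

test_row <- function(statistic, df, p, status) {
  tibble::tibble(statistic = as.numeric(statistic), df = as.numeric(df),
                 p_value = as.numeric(p), status = status)
}

as_fit_list <- function(fits) {
  if (inherits(fits, "stratified_fit")) fits$stratum_fits else fits
}

#' Trend test of a log parameter across ordered methylation strata
#'
#' Inverse-variance weighted least-squares slope of the tested log-scale
#' parameter on centred stratum scores, testing for a dose-response
#' relationship across strata; z = slope / SE, two-sided p-value. More
#' powerful than the omnibus Wald test when the parameter changes
#' monotonically with the methylation level. For two strata the squared
#' trend z equals the Wald statistic.
#'
#' @param fits As in [wald_interaction_test()].
#' @param parameter A single log-scale parameter name, or `"rrr"`.
#' @param scores Numeric stratum scores; default `1, 2, ..., S` (equally
#'   spaced ordinal strata).
#' @return One-row tibble: `statistic` (z), `slope`, `se`, `p_value`,
#'   `status`.
#' @export
trend_test <- function(fits, parameter = "log_rr", scores = NULL) {
  fits <- as_fit_list(fits)
  fits <- fits[!vapply(fits, is.null, logical(1))]
  fits <- fits[vapply(fits, function(f) isTRUE(f$converged), logical(1))]
  if (length(fits) < 2L) {
    return(tibble::tibble(statistic = NA_real_, slope = NA_real_,
                          se = NA_real_, p_value = NA_real_,
                          status = "not_assessable"))
  }
  parts <- lapply(fits, fit_theta, parameter = parameter)
  if (length(parts[[1L]]$theta) != 1L) {
    stop("`trend_test()` requires a single (scalar) tested parameter.",
         call. = FALSE)
  }
  y <- vapply(parts, function(p) unname(p$theta), numeric(1))
  v <- vapply(parts, function(p) p$vcov[1L, 1L], numeric(1))
  if (is.null(scores)) scores <- seq_along(y)
  stopifnot(length(scores) == length(y))
  w <- 1 / v
  xbar <- sum(w * scores) / sum(w)
  sxx <- sum(w * (scores - xbar)^2)
  if (sxx <= 0 || any(!is.finite(w))) {
    return(tibble::tibble(statistic = NA_real_, slope = NA_real_,
                          se = NA_real_, p_value = NA_real_,
                          status = "not_assessable"))
  }
  slope <- sum(w * (scores - xbar) * y) / sxx
  se <- sqrt(1 / sxx)
  z <- slope / se
  tibble::tibble(statistic = z, slope = slope, se = se,
                 p_value = 2 * stats::pnorm(-abs(z)), status = "ok")
}

# per-stratum summary table for an interaction result
stratum_summary <- function(families, fits, pooled, model) {
  term <- if (model == "poo") "log_rrr" else "log_rr"
  one <- function(fit, fam, label) {
    if (is.null(fit)) {
      return(tibble::tibble(stratum = label, n_families = nrow(fam),
                            var_freq_child = NA_real_, estimate = NA_real_,
                            rr = NA_real_, conf.low = NA_real_,
                            conf.high = NA_real_))
    }
    th <- fit_theta(fit, if (model == "poo") "rrr" else "log_rr")
    se <- sqrt(th$vcov[1L, 1L])
    est <- unname(th$theta)
    tibble::tibble(
      stratum = label, n_families = nrow(fam),
      var_freq_child = mean(fam$c) / 2,
      estimate = est, rr = exp(est),
      conf.low = exp(est - 1.96 * se), conf.high = exp(est + 1.96 * se)
    )
  }
  strata <- sort(unique(families$stratum))
  rows <- lapply(strata, function(s) {
    one(fits[[as.character(s)]], families[families$stratum == s, ],
        as.character(s))
  })
  dplyr::bind_rows(c(rows, list(one(pooled, families, "all")))) |>
    dplyr::mutate(term = term, .after = "stratum")
}

#' Gene-methylation (GxMe) interaction analysis
#'
#' Runs the full GxMe analysis for one analysis unit: fits the gene-dose
#' relative-risk model within each methylation stratum, tests for a change
#' of the log relative risk across strata with the Wald interaction test
#' and the trend test, and reports the pooled ("all") fit alongside the
#' per-stratum estimates.
#'
#' @param families Case families with `m`, `f`, `c`, `stratum` (at least
#'   two strata).
#' @param dose `"multiplicative"` or `"free"` double dose.
#' @param tested Parameters entering the Wald interaction test; defaults
#'   to all dose parameters of the model.
#' @param scores Stratum scores for the trend test (default 1..S); the
#'   trend is always computed on the single-dose log RR.
#' @param snp_id,category Optional labels carried into the result.
#' @param method Likelihood method, see [fit_families()].
#' @return An object of class `interaction_result`. Use
#'   [glance()][generics::glance] for the test summary and
#'   [tidy()][generics::tidy] for per-stratum estimates.
#' @export
run_gxme <- function(families, dose = c("multiplicative", "free"),
                     tested = NULL, scores = NULL, snp_id = NA_character_,
                     category = NA_character_,
                     method = c("auto", "conditional", "em")) {
  dose <- match.arg(dose)
  run_interaction(families, model = "gene_dose", dose = dose,
                  analysis = "gxme", tested = tested, scores = scores,
                  snp_id = snp_id, category = category,
                  method = match.arg(method))
}

#' Parent-of-origin-methylation (PoOxMe) interaction analysis
#'
#' As [run_gxme()], but fits the parent-of-origin model (free maternal and
#' paternal relative risks) in each stratum and tests for a change of the
#' log relative-risk ratio, log RRR = log(RR_M / RR_F), across strata.
#'
#' @inheritParams run_gxme
#' @return An `interaction_result` with `analysis = "pooxme"`.
#' @export
run_pooxme <- function(families, dose = c("multiplicative", "free"),
                       scores = NULL, snp_id = NA_character_,
                       category = NA_character_,
                       method = c("auto", "conditional", "em")) {
  dose <- match.arg(dose)
  run_interaction(families, model = "poo", dose = dose,
                  analysis = "pooxme", tested = "rrr", scores = scores,
                  snp_id = snp_id, category = category,
                  method = match.arg(method))
}

run_interaction <- function(families, model, dose, analysis, tested,
                            scores, snp_id, category, method) {
  stopifnot("stratum" %in% names(families))
  strata <- sort(unique(families$stratum))
  if (length(strata) < 2L) {
    stop("Interaction is undefined with a single methylation stratum.",
         call. = FALSE)
  }
  if (is.null(tested)) {
    tested <- if (model == "poo") "rrr" else param_names(model, dose)
  }
  sf <- stratified_fit(families, model = model, dose = dose,
                       method = method)
  wald <- wald_interaction_test(sf, parameter = tested)
  trend_par <- if (model == "poo") "rrr" else "log_rr"
  trend <- trend_test(sf, parameter = trend_par, scores = scores)
  flags <- unlist(lapply(sf$stratum_fits, function(f) {
    if (is.null(f)) "unfitted" else f$flags
  }))
  flag <- if (wald$status == "not_assessable") {
    "not_assessable"
  } else if ("unstable" %in% flags || "unfitted" %in% flags) {
    "unstable"
  } else {
    "ok"
  }
  structure(
    list(snp_id = snp_id, category = category, analysis = analysis,
         model = model, dose = dose,
         estimates = stratum_summary(families, sf$stratum_fits, sf$pooled,
                                     model),
         fits = sf,
         wald_chi2 = wald$statistic, wald_df = wald$df,
         wald_p = wald$p_value,
         trend_z = trend$statistic, trend_p = trend$p_value,
         control_wald_p = NA_real_, flag = flag),
    class = "interaction_result"
  )
}

#' @export
print.interaction_result <- function(x, ...) {
  cat("<interaction_result>", x$analysis,
      if (!is.na(x$snp_id)) paste0("SNP ", x$snp_id) else "",
      if (!is.na(x$category)) paste0("[", x$category, "]") else "", "\n")
  print(x$estimates)
  cat(sprintf("Wald interaction: chi2 = %.4g, df = %g, p = %.4g\n",
              x$wald_chi2, x$wald_df, x$wald_p))
  cat(sprintf("Trend: z = %.4g, p = %.4g\n", x$trend_z, x$trend_p))
  cat("flag:", x$flag, "\n")
  invisible(x)
}

#' Compare a case interaction result against controls
#'
#' A significant interaction found in both the case and the control
#' dataset indicates a background SNP-methylation correlation (e.g. an
#' meQTL) rather than a disease interaction, and is flagged as a suspected
#' false positive.
#'
#' @param case_result,control_result `interaction_result` objects for the
#'   same (SNP, category, analysis); `control_result` may be `NULL`.
#' @param alpha Significance level; default 0.05.
#' @return The case result with `control_wald_p` recorded and `flag` set
#'   to `"suspected_false_positive"`, `"ok"` or `"not_assessable"`.
#' @export
control_comparison <- function(case_result, control_result, alpha = 0.05) {
  stopifnot(inherits(case_result, "interaction_result"))
  if (is.null(control_result) || !is.finite(control_result$wald_p)) {
    case_result$flag <- "not_assessable"
    return(case_result)
  }
  stopifnot(inherits(control_result, "interaction_result"))
  case_result$control_wald_p <- control_result$wald_p
  if (is.finite(case_result$wald_p) &&
      case_result$wald_p < alpha && control_result$wald_p < alpha) {
    case_result$flag <- "suspected_false_positive"
  } else if (case_result$flag == "not_assessable") {
    # leave as is
  } else if (!"unstable" %in% case_result$flag) {
    case_result$flag <- "ok"
  }
  case_result
}

#' Genome scan for parent-of-origin effects
#'
#' Fits the unstratified parent-of-origin model SNP by SNP (window size 1)
#' and reports the Wald p-value for log RRR = 0, sorted ascending. SNPs
#' that are monomorphic or otherwise unfittable are skipped with a
#' message.
#'
#' @param genotypes Long-format genotype data with columns `snp_id`, `m`,
#'   `f`, `c` (one row per family per SNP).
#' @param dose,method As in [fit_families()].
#' @return A tibble: `snp_id`, `log_rrr`, `rrr`, `se`, `p_value`,
#'   `converged`, sorted by `p_value`.
#' @export
poo_scan <- function(genotypes, dose = c("multiplicative", "free"),
                     method = c("auto", "conditional", "em")) {
  dose <- match.arg(dose)
  method <- match.arg(method)
  stopifnot("snp_id" %in% names(genotypes))
  snps <- unique(genotypes$snp_id)
  rows <- lapply(snps, function(s) {
    fam <- genotypes[genotypes$snp_id == s, , drop = FALSE]
    gt <- c(fam$m, fam$f, fam$c)
    if (length(unique(stats::na.omit(gt))) < 2L) {
      message("SNP ", s, ": monomorphic, skipped.")
      return(NULL)
    }
    fit <- tryCatch(
      fit_families(fam, model = "poo", dose = dose, method = method),
      error = function(e) {
        message("SNP ", s, ": fit failed (", conditionMessage(e),
                "), skipped.")
        NULL
      }
    )
    if (is.null(fit)) return(NULL)
    th <- fit_theta(fit, "rrr")
    se <- sqrt(th$vcov[1L, 1L])
    z <- unname(th$theta) / se
    tibble::tibble(snp_id = s, log_rrr = unname(th$theta),
                   rrr = exp(unname(th$theta)), se = se,
                   p_value = 2 * stats::pnorm(-abs(z)),
                   converged = fit$converged)
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$p_value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over [stats::p.adjust()] with input validation, for
#' controlling the false-discovery rate over a scan's p-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method Adjustment method; default `"BH"`.
#' @return Adjusted p-values (q-values for `"BH"`).
#' @export
adjust_pvalues <- function(p, method = "BH") {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("All p-values must lie in [0, 1].", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}

#' Quantile-quantile data with point-wise confidence band
#'
#' Sorts observed p-values against uniform expected quantiles
#' (i - 0.5) / n and attaches a point-wise 95% band from the
#' Beta(i, n - i + 1) distribution of uniform order statistics, on both
#' the raw and the -log10 scale.
#'
#' @param p Non-empty numeric vector of p-values.
#' @param level Band coverage; default 0.95.
#' @return A tibble of class `qq_data`: `p_observed`, `p_expected`,
#'   `band_lower`, `band_upper` and their `-log10` counterparts
#'   (`neglog10_*`).
#' @export
qq_data <- function(p, level = 0.95) {
  stopifnot(length(p) > 0L, all(is.finite(p)), all(p >= 0 & p <= 1))
  n <- length(p)
  i <- seq_len(n)
  a <- (1 - level) / 2
  out <- tibble::tibble(
    rank = i,
    p_observed = sort(p),
    p_expected = (i - 0.5) / n,
    band_lower = stats::qbeta(a, i, n - i + 1),
    band_upper = stats::qbeta(1 - a, i, n - i + 1)
  ) |>
    dplyr::mutate(
      neglog10_observed = -log10(.data$p_observed),
      neglog10_expected = -log10(.data$p_expected),
      neglog10_lower = -log10(.data$band_upper),
      neglog10_upper = -log10(.data$band_lower)
    )
  class(out) <- c("qq_data", class(out))
  out
}
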