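#' @importFrom rlang .data
NULL

# ---- penetrance risk factors -----------------------------------------------
#
# The penetrance model is P(D | C_ij, Me = m) = B * RR_M,i * RR_F,j with the
# reference allele's RR fixed to 1. Under the gene-dose model the maternal and
# paternal RRs are equal, so the factor depends only on the variant-allele
# dose; under the parent-of-origin (poo) model they are free. The double dose
# is multiplicative by default (RR_double = product of single-dose RRs) or a
# free parameter (`dose = "free"`).
#
# Parameters are always carried on the log scale as a named vector:
#   gene_dose, multiplicative: log_rr
#   gene_dose, free:           log_rr, log_rr_dd
#   poo, multiplicative:       log_rr_m, log_rr_f
#   poo, free:                 log_rr_m, log_rr_f, log_rr_dd

param_names <- function(model, dose) {
  base <- switch(model,
    gene_dose = "log_rr",
    poo = c("log_rr_m", "log_rr_f"),
    stop("Unknown model: ", model, call. = FALSE)
  )
  if (dose == "free") c(base, "log_rr_dd") else base
}

# log risk factor for each ordered cell (vectors ci, cj)
log_risk_factor <- function(ci, cj, params, model, dose) {
  d <- (ci == 2L) + (cj == 2L)
  lf <- if (model == "gene_dose") {
    params[["log_rr"]] * d
  } else {
    params[["log_rr_m"]] * (ci == 2L) + params[["log_rr_f"]] * (cj == 2L)
  }
  if (dose == "free") {
    lf[d == 2L] <- params[["log_rr_dd"]]
  }
  lf
}

#' Case-triad cell probabilities under the penetrance model
#'
#' Computes the probability of each Mendelian-consistent (mother, father,
#' child) genotype cell among case families, either conditional on the
#' parental mating type (the population mating-type distribution and the
#' baseline risk cancel) or marginally over mating types under
#' Hardy-Weinberg parental genotypes at frequency `var_freq`. The
#' ambiguous double-heterozygote child cell is the sum of its two ordered
#' constituents.
#'
#' @param params Named log-scale parameter vector (see Details of
#'   [fit_stratum()]); e.g. `c(log_rr = log(2))` for the gene-dose model.
#' @param model `"gene_dose"` (maternal and paternal RR equal) or `"poo"`.
#' @param dose `"multiplicative"` (double-dose RR is the product of the
#'   single-dose RRs) or `"free"`.
#' @param condition `"mating_type"` for probabilities conditional on
#'   (mother, father) genotypes, or `"marginal"` for the joint cell
#'   distribution (requires `var_freq`).
#' @param var_freq Variant allele frequency; required when
#'   `condition = "marginal"`.
#' @param ordered Logical; return ordered child genotypes (maternal allele
#'   `ci`, paternal `cj`) instead of unordered cells.
#' @return A tibble of cells with a `prob` column. Conditional
#'   probabilities sum to 1 within each mating type; marginal
#'   probabilities sum to 1 overall.
#' @examples
#' # Null model: reduces to Mendelian transmission within mating type
#' cell_probability(c(log_rr = 0), ordered = TRUE)
#' @export
cell_probability <- function(params, model = c("gene_dose", "poo"),
                             dose = c("multiplicative", "free"),
                             condition = c("mating_type", "marginal"),
                             var_freq = NULL, ordered = FALSE) {
  model <- match.arg(model)
  dose <- match.arg(dose)
  condition <- match.arg(condition)
  check_params(params, model, dose)
  cells <- ordered_cell_template()
  w <- cells$transmission *
    exp(log_risk_factor(cells$ci, cells$cj, params, model, dose))
  if (condition == "marginal") {
    if (is.null(var_freq)) {
      stop("`var_freq` is required for marginal cell probabilities.",
           call. = FALSE)
    }
    w <- w * mating_type_prob(cells$m, cells$f, var_freq)
    cells$prob <- w / sum(w)
  } else {
    cells <- cells |>
      dplyr::mutate(w = w) |>
      dplyr::group_by(.data$m, .data$f) |>
      dplyr::mutate(prob = .data$w / sum(.data$w)) |>
      dplyr::ungroup() |>
      dplyr::select(-"w")
  }
  if (ordered) {
    return(cells |> dplyr::select(-"transmission"))
  }
  cells |>
    dplyr::group_by(.data$m, .data$f, .data$c_copies) |>
    dplyr::summarise(prob = sum(.data$prob), .groups = "drop")
}

check_params <- function(params, model, dose) {
  need <- param_names(model, dose)
  if (!all(need %in% names(params))) {
    stop("`params` must contain: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(unlist(params[need])))) {
    stop("All log-RR parameters must be finite.", call. = FALSE)
  }
  invisible(TRUE)
}

# ---- conditional (mating-type) likelihood for complete triads --------------

# Negative log-likelihood of unordered cell counts, conditional on mating
# type. `counts` is a data frame with m, f, c_copies, count (complete triads
# only). Implemented on the 16-row ordered template for speed.
neg_loglik_conditional <- function(theta, counts, model, dose) {
  tpl <- .cell_tpl
  params <- stats::setNames(as.list(theta), .fit_par_names(model, dose))
  lw <- log(tpl$transmission) +
    log_risk_factor(tpl$ci, tpl$cj, params, model, dose)
  w <- exp(lw)
  denom <- rowsum(w, tpl$mf_key, reorder = TRUE) # per mating type
  num <- rowsum(w, tpl$cell_key, reorder = TRUE) # per unordered cell
  key <- paste(counts$m, counts$f, counts$c_copies, sep = ":")
  mfk <- paste(counts$m, counts$f, sep = ":")
  ll <- sum(counts$count * (log(num[key, 1L]) - log(denom[mfk, 1L])))
  -ll
}

.fit_par_names <- function(model, dose) param_names(model, dose)

# cached ordered template with grouping keys (built at load time)
.cell_tpl <- NULL

.build_cell_tpl <- function() {
  tpl <- as.data.frame(ordered_cell_template())
  tpl$mf_key <- paste(tpl$m, tpl$f, sep = ":")
  tpl$cell_key <- paste(tpl$m, tpl$f, tpl$c_copies, sep = ":")
  tpl
}

.onLoad <- function(libname, pkgname) {
  assign(".cell_tpl", .build_cell_tpl(), envir = parent.env(environment()))
}

# numerical central-difference gradient
num_grad <- function(fn, x, h = 1e-6, ...) {
  vapply(seq_along(x), function(k) {
    e <- rep(0, length(x)); e[k] <- h
    (fn(x + e, ...) - fn(x - e, ...)) / (2 * h)
  }, numeric(1))
}

# quasi-Newton fit with Newton polishing; returns list(par, value, hessian,
# gradient, converged)
optimize_loglik <- function(nll, n_par, ..., start = NULL) {
  start <- if (is.null(start)) rep(0, n_par) else start
  opt <- stats::optim(start, nll, ..., method = "BFGS",
                      control = list(reltol = 1e-12, maxit = 500))
  par <- opt$par
  # Newton polish to drive the gradient infinity-norm down
  for (it in 1:10) {
    g <- num_grad(nll, par, ...)
    if (max(abs(g)) < 1e-6) break
    H <- stats::optimHess(par, nll, ...)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    cand <- par - step
    if (nll(cand, ...) <= opt$value + 1e-9) {
      par <- cand
      opt$value <- nll(par, ...)
    } else break
  }
  g <- num_grad(nll, par, ...)
  H <- stats::optimHess(par, nll, ...)
  list(
    par = par, value = nll(par, ...), gradient = g, hessian = H,
    converged = opt$convergence == 0L &&
      max(abs(g)) < 1e-4 * max(1, abs(opt$value)) &&
      all(abs(par) < 10)
  )
}

#' Fit the per-stratum relative-risk model to a triad cell table
#'
#' Maximises the multinomial likelihood of unordered child genotypes
#' conditional on the parental mating type (the population mating-type
#' distribution and baseline risk cancel, so only relative risks remain).
#' The covariance matrix is the inverse observed information at the MLE.
#' For the parent-of-origin model, the log relative-risk ratio
#' `log RRR = log RR_M - log RR_F` is reported with a delta-method
#' standard error.
#'
#' @param cells A cell-count table for complete triads: columns `m`, `f`,
#'   `c_copies`, `count` (see [build_cell_tables()]), typically one
#'   methylation stratum.
#' @param model `"gene_dose"` or `"poo"`.
#' @param dose `"multiplicative"` or `"free"` double dose.
#' @param stratum Optional stratum label stored in the result.
#' @return An object of class `stratum_fit`: log-scale `estimates`,
#'   `vcov`, `loglik`, `n_families`, `expected_cells`, `converged` and
#'   `flags` (may include `"unstable"` when an informative expected cell
#'   count is below 5, or `"boundary"`). Use [tidy()][generics::tidy] for
#'   a tabular summary on the RR scale.
#' @export
fit_stratum <- function(cells, model = c("gene_dose", "poo"),
                        dose = c("multiplicative", "free"), stratum = NA) {
  model <- match.arg(model)
  dose <- match.arg(dose)
  stopifnot(is.data.frame(cells),
            all(c("m", "f", "c_copies", "count") %in% names(cells)))
  if (any(is.na(cells$m) | is.na(cells$f))) {
    stop("`fit_stratum()` requires complete triads; use `fit_dyads_em()` ",
         "for families with a missing parent.", call. = FALSE)
  }
  counts <- cells |>
    dplyr::group_by(.data$m, .data$f, .data$c_copies) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  n_fam <- sum(counts$count)
  bad <- !paste(counts$m, counts$f, counts$c_copies, sep = ":") %in%
    .cell_tpl$cell_key
  if (any(bad)) {
    stop("Cell table contains Mendelian-inconsistent cells; run the input ",
         "through `build_cell_tables()` first.", call. = FALSE)
  }
  informative <- counts$count > 0 & (counts$m == 1L | counts$f == 1L)
  if (!any(informative)) {
    stop("Non-identifiable: no families in informative cells (at least one ",
         "heterozygous parent is required).", call. = FALSE)
  }
  pn <- param_names(model, dose)
  fit <- optimize_loglik(neg_loglik_conditional, length(pn),
                         counts = counts, model = model, dose = dose)
  est <- stats::setNames(fit$par, pn)
  vcov <- tryCatch(solve(fit$hessian), error = function(e) {
    matrix(NA_real_, length(pn), length(pn))
  })
  dimnames(vcov) <- list(pn, pn)
  if (any(!is.finite(vcov))) fit$converged <- FALSE
  # expected counts: conditional probs times per-mating-type totals
  # (base-R on the cached template: this sits in simulation hot loops)
  tpl <- .cell_tpl
  w <- tpl$transmission *
    exp(log_risk_factor(tpl$ci, tpl$cj, as.list(est), model, dose))
  denom <- rowsum(w, tpl$mf_key, reorder = TRUE)
  num <- rowsum(w, tpl$cell_key, reorder = TRUE)
  mt_tot <- rowsum(counts$count, paste(counts$m, counts$f, sep = ":"),
                   reorder = TRUE)
  ucell <- tpl[!duplicated(tpl$cell_key),
               c("m", "f", "c_copies", "cell_key", "mf_key")]
  tot_of <- stats::setNames(rep(0, nrow(ucell)), ucell$cell_key)
  present <- ucell$mf_key %in% rownames(mt_tot)
  tot_of[present] <- mt_tot[ucell$mf_key[present], 1L]
  expected <- tibble::tibble(
    m = ucell$m, f = ucell$f, c_copies = ucell$c_copies,
    expected = num[ucell$cell_key, 1L] / denom[ucell$mf_key, 1L] *
      unname(tot_of)
  )
  flags <- character()
  informative_exp <- expected[expected$m == 1L | expected$f == 1L, ]
  if (any(informative_exp$expected < 5)) flags <- c(flags, "unstable")
  if (any(abs(fit$par) >= 10)) flags <- c(flags, "boundary")
  new_stratum_fit(
    stratum = stratum, model = model, dose = dose, method = "conditional",
    estimates = est, vcov = vcov, loglik = -fit$value, n_families = n_fam,
    expected_cells = expected, converged = fit$converged, flags = flags
  )
}

new_stratum_fit <- function(stratum, model, dose, method, estimates, vcov,
                            loglik, n_families, expected_cells, converged,
                            flags, var_freq = NA_real_, em_trace = NULL,
                            n_iter = NA_integer_) {
  structure(
    list(stratum = stratum, model = model, dose = dose, method = method,
         estimates = estimates, vcov = vcov, loglik = loglik,
         n_families = n_families, expected_cells = expected_cells,
         converged = converged, flags = flags, var_freq = var_freq,
         em_trace = em_trace, n_iter = n_iter),
    class = "stratum_fit"
  )
}

#' @export
print.stratum_fit <- function(x, ...) {
  cat("<stratum_fit> model:", x$model, "(", x$dose, "dose ), method:",
      x$method, "\n")
  cat("  families:", x$n_families, " loglik:", format(x$loglik), "\n")
  print(tidy(x))
  invisible(x)
}

# log RRR contrast for a poo fit: estimate and variance
rrr_contrast <- function(fit) {
  stopifnot(fit$model == "poo")
  a <- stats::setNames(numeric(length(fit$estimates)), names(fit$estimates))
  a[c("log_rr_m", "log_rr_f")] <- c(1, -1)
  est <- sum(a * fit$estimates)
  var <- drop(t(a) %*% fit$vcov %*% a)
  c(estimate = est, var = var)
}

# extract the tested parameter vector and its covariance from a fit;
# `parameter` is a character vector of estimate names or "rrr"
fit_theta <- function(fit, parameter) {
  if (identical(parameter, "rrr")) {
    ct <- rrr_contrast(fit)
    return(list(theta = ct[["estimate"]],
                vcov = matrix(ct[["var"]], 1, 1)))
  }
  stopifnot(all(parameter %in% names(fit$estimates)))
  list(theta = fit$estimates[parameter],
       vcov = fit$vcov[parameter, parameter, drop = FALSE])
}
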