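# ---- marginal (HWE) likelihood with missing parents via EM -----------------

# Joint case-cell probabilities over the 16 ordered cells under HWE parents
# at variant frequency q and the penetrance risk factors. Returns the
# normalized probability vector aligned with .cell_tpl rows.
marginal_cell_probs <- function(theta, eta, model, dose) {
  tpl <- .cell_tpl
  q <- stats::plogis(eta)
  params <- stats::setNames(as.list(theta), param_names(model, dose))
  w <- stats::dbinom(tpl$m, 2, q) * stats::dbinom(tpl$f, 2, q) *
    tpl$transmission *
    exp(log_risk_factor(tpl$ci, tpl$cj, params, model, dose))
  w / sum(w)
}

# Map each observed family pattern (m possibly NA, f possibly NA, c) to the
# indices of compatible ordered cells in .cell_tpl.
pattern_cells <- function(m, f, c_copies) {
  tpl <- .cell_tpl
  which(
    (is.na(m) | tpl$m == m) &
      (is.na(f) | tpl$f == f) &
      tpl$c_copies == c_copies
  )
}

# observed-data negative log-likelihood for aggregated patterns
neg_loglik_observed <- function(par, patterns, model, dose) {
  k <- length(par) - 1L
  p <- marginal_cell_probs(par[seq_len(k)], par[k + 1L], model, dose)
  ll <- sum(patterns$count *
              log(vapply(patterns$cells, function(ix) sum(p[ix]),
                         numeric(1))))
  -ll
}

#' Fit the relative-risk model to dyads (or mixed designs) by EM
#'
#' Maximises the observed-data likelihood of case families where one
#' parent's genotype may be missing (mother-child or father-child dyads,
#' possibly mixed with complete triads), marginalising the missing parent
#' under Hardy-Weinberg equilibrium and random mating. The variant allele
#' frequency is estimated jointly with the relative risks. The E-step
#' computes the posterior distribution over the compatible ordered
#' (mother, father, child) cells for each family; the M-step maximises the
#' expected complete-data log-likelihood. The observed-data log-likelihood
#' is non-decreasing across iterations; a decrease beyond tolerance is
#' flagged (`"em_failure"`), never silently ignored. The covariance matrix
#' comes from the numerical Hessian of the observed-data log-likelihood at
#' the MLE.
#'
#' @param families Data frame with columns `m`, `f` (parental copies,
#'   `NA` when that parent is missing) and `c` (child copies).
#' @param model,dose As in [fit_stratum()].
#' @param var_freq_init Starting value for the variant allele frequency;
#'   defaults to the empirical allele frequency over observed genotypes.
#' @param max_iter,tol EM iteration cap (default 500) and absolute
#'   convergence tolerance on the observed log-likelihood (default 1e-8).
#' @param stratum Optional stratum label stored in the result.
#' @return A `stratum_fit` (method `"em"`) with the fitted `var_freq`, the
#'   per-iteration log-likelihood trace in `em_trace` and `n_iter`.
#' @export
fit_dyads_em <- function(families, model = c("gene_dose", "poo"),
                         dose = c("multiplicative", "free"),
                         var_freq_init = NULL, max_iter = 500, tol = 1e-8,
                         stratum = NA) {
  model <- match.arg(model)
  dose <- match.arg(dose)
  stopifnot(is.data.frame(families),
            all(c("m", "f", "c") %in% names(families)))
  ok <- mendelian_consistent(families$m, families$f, families$c)
  if (any(!ok)) {
    warning(sprintf("Excluded %d Mendelian-inconsistent famil%s.",
                    sum(!ok), if (sum(!ok) == 1L) "y" else "ies"),
            call. = FALSE)
    families <- families[ok, , drop = FALSE]
  }
  if (nrow(families) == 0L) {
    stop("No consistent families to fit.", call. = FALSE)
  }
  patterns <- families |>
    dplyr::count(.data$m, .data$f, c_copies = .data$c, name = "count")
  patterns$cells <- purrr::pmap(
    list(patterns$m, patterns$f, patterns$c_copies), pattern_cells
  )
  if (is.null(var_freq_init)) {
    gt <- c(families$m, families$f, families$c)
    var_freq_init <- mean(gt, na.rm = TRUE) / 2
    var_freq_init <- min(max(var_freq_init, 0.02), 0.98)
  }
  pn <- param_names(model, dose)
  theta <- rep(0, length(pn))
  eta <- stats::qlogis(var_freq_init)

  obs_ll <- function(th, et) {
    -neg_loglik_observed(c(th, et), patterns, model, dose)
  }
  trace <- obs_ll(theta, eta)
  flags <- character()
  converged <- FALSE
  n_cells <- nrow(.cell_tpl)
  for (iter in seq_len(max_iter)) {
    # E-step: expected cell counts given current parameters
    p <- marginal_cell_probs(theta, eta, model, dose)
    w_cells <- numeric(n_cells)
    for (r in seq_len(nrow(patterns))) {
      ix <- patterns$cells[[r]]
      w_cells[ix] <- w_cells[ix] + patterns$count[r] * p[ix] / sum(p[ix])
    }
    # M-step: weighted complete-data multinomial fit
    m_nll <- function(par) {
      k <- length(par) - 1L
      pc <- marginal_cell_probs(par[seq_len(k)], par[k + 1L], model, dose)
      -sum(w_cells * log(pc))
    }
    m_opt <- stats::optim(c(theta, eta), m_nll, method = "BFGS",
                          control = list(reltol = 1e-12, maxit = 200))
    theta <- m_opt$par[seq_along(pn)]
    eta <- m_opt$par[length(pn) + 1L]
    ll_new <- obs_ll(theta, eta)
    if (ll_new < utils::tail(trace, 1L) - 1e-8) {
      flags <- c(flags, "em_failure")
      trace <- c(trace, ll_new)
      break
    }
    delta <- ll_new - utils::tail(trace, 1L)
    trace <- c(trace, ll_new)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  par_hat <- c(theta, eta)
  H <- stats::optimHess(par_hat, function(p) {
    neg_loglik_observed(p, patterns, model, dose)
  })
  vcov_full <- tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, length(par_hat), length(par_hat))
  })
  vcov <- vcov_full[seq_along(pn), seq_along(pn), drop = FALSE]
  dimnames(vcov) <- list(pn, pn)
  if (any(!is.finite(vcov))) converged <- FALSE
  if (any(abs(theta) >= 10)) flags <- c(flags, "boundary")
  new_stratum_fit(
    stratum = stratum, model = model, dose = dose, method = "em",
    estimates = stats::setNames(theta, pn), vcov = vcov,
    loglik = utils::tail(trace, 1L), n_families = sum(patterns$count),
    expected_cells = NULL,
    converged = converged && !"em_failure" %in% flags,
    flags = flags, var_freq = stats::plogis(eta), em_trace = trace,
    n_iter = length(trace) - 1L
  )
}

#' Fit families with automatic choice of likelihood
#'
#' Dispatches to the mating-type-conditional triad likelihood
#' ([fit_stratum()]) when all families are complete triads, and to the
#' marginal EM likelihood ([fit_dyads_em()]) when any parent is missing.
#'
#' @param families Data frame with `m`, `f`, `c` (and `family_id` for
#'   exclusion messages).
#' @param model,dose As in [fit_stratum()].
#' @param method `"auto"` (default), `"conditional"` or `"em"`.
#' @param stratum Optional stratum label.
#' @param ... Passed on to [fit_dyads_em()].
#' @return A `stratum_fit`.
#' @export
fit_families <- function(families, model = c("gene_dose", "poo"),
                         dose = c("multiplicative", "free"),
                         method = c("auto", "conditional", "em"),
                         stratum = NA, ...) {
  model <- match.arg(model)
  dose <- match.arg(dose)
  method <- match.arg(method)
  has_missing <- any(is.na(families$m) | is.na(families$f))
  if (method == "auto") {
    method <- if (has_missing) "em" else "conditional"
  }
  if (method == "conditional") {
    if (has_missing) {
      stop("Conditional likelihood requires complete triads.", call. = FALSE)
    }
    fam <- families
    if (!"family_id" %in% names(fam)) fam$family_id <- seq_len(nrow(fam))
    cells <- build_cell_tables(fam, strata = rep(1L, nrow(fam)))
    fit_stratum(cells, model = model, dose = dose, stratum = stratum)
  } else {
    fit_dyads_em(families, model = model, dose = dose, stratum = stratum,
                 ...)
  }
}
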