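# ---- broom-style tidiers ---------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a per-stratum relative-risk fit
#'
#' @param x A `stratum_fit`.
#' @param conf.level Confidence level for the Wald interval; default 0.95.
#' @param ... Unused.
#' @return A tibble with one row per parameter (plus the derived
#'   `log_rrr` contrast for parent-of-origin fits): `term`, `estimate`
#'   (log scale), `std.error`, `rr` (exponentiated), `conf.low`,
#'   `conf.high` (RR scale).
#' @export
tidy.stratum_fit <- function(x, conf.level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  est <- x$estimates
  se <- sqrt(diag(x$vcov))
  rows <- tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se)
  )
  if (x$model == "poo") {
    ct <- rrr_contrast(x)
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      term = "log_rrr", estimate = ct[["estimate"]],
      std.error = sqrt(ct[["var"]])
    ))
  }
  rows |>
    dplyr::mutate(
      rr = exp(.data$estimate),
      conf.low = exp(.data$estimate - z * .data$std.error),
      conf.high = exp(.data$estimate + z * .data$std.error)
    )
}

#' Glance at a per-stratum fit
#'
#' @param x A `stratum_fit`.
#' @param ... Unused.
#' @return One-row tibble: `stratum`, `model`, `dose`, `method`,
#'   `logLik`, `n_families`, `converged`, `flags`, `var_freq`, `n_iter`.
#' @export
glance.stratum_fit <- function(x, ...) {
  tibble::tibble(
    stratum = as.character(x$stratum), model = x$model, dose = x$dose,
    method = x$method, logLik = x$loglik, n_families = x$n_families,
    converged = x$converged,
    flags = paste(x$flags, collapse = ","),
    var_freq = x$var_freq, n_iter = x$n_iter
  )
}

#' Tidy an interaction result
#'
#' @param x An `interaction_result`.
#' @param ... Unused.
#' @return The per-stratum estimate table (one row per stratum plus the
#'   pooled `"all"` row): `stratum`, `term`, `n_families`,
#'   `var_freq_child`, `estimate`, `rr`, `conf.low`, `conf.high`.
#' @export
tidy.interaction_result <- function(x, ...) {
  x$estimates |>
    dplyr::mutate(snp_id = x$snp_id, category = x$category,
                  analysis = x$analysis, .before = 1L)
}

#' Glance at an interaction result
#'
#' @param x An `interaction_result`.
#' @param ... Unused.
#' @return One-row tibble: labels, `wald_chi2`, `wald_df`, `wald_p`,
#'   `trend_z`, `trend_p`, `control_wald_p`, `flag`.
#' @export
glance.interaction_result <- function(x, ...) {
  tibble::tibble(
    snp_id = x$snp_id, category = x$category, analysis = x$analysis,
    model = x$model, dose = x$dose,
    wald_chi2 = x$wald_chi2, wald_df = x$wald_df, wald_p = x$wald_p,
    trend_z = x$trend_z, trend_p = x$trend_p,
    control_wald_p = x$control_wald_p, flag = x$flag
  )
}

#' Tidy a stratified fit
#'
#' @param x A `stratified_fit`.
#' @param ... Passed to [tidy.stratum_fit()].
#' @return Row-bound tidy tables of the per-stratum fits and the pooled
#'   fit, with a `stratum` column (`"all"` for pooled).
#' @export
tidy.stratified_fit <- function(x, ...) {
  fits <- c(x$stratum_fits, list(all = x$pooled))
  rows <- purrr::imap(fits, function(f, nm) {
    if (is.null(f)) return(NULL)
    tidy(f, ...) |> dplyr::mutate(stratum = nm, .before = 1L)
  })
  dplyr::bind_rows(rows)
}
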