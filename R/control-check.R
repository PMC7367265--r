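# ---- control-triad diagnostics of the methylation assumptions --------------

#' Control-triad check of methylation symmetry by parental origin
#'
#' Uses control triads, under the rare-disease approximation, to estimate
#' the population distribution of methylation strata within genetic
#' categories, P(Me | M, F, C), and to test the symmetry condition that
#' methylation does not depend on which parent a heterozygous child's
#' variant allele came from (P(Me | C_ij) = P(Me | C_ji)). The test
#' contrasts the stratum distribution between heterozygous control
#' children whose variant allele is maternally vs paternally derived,
#' restricted to families where the origin is determined by the parental
#' genotypes (all het-child triads except the double heterozygote), with a
#' chi-square test over strata. A violation signals an asymmetric meQTL
#' that can bias parent-of-origin estimates.
#'
#' @param control_families Data frame of control families with `m`, `f`,
#'   `c` and `stratum`.
#' @param alpha Significance level for flagging; default 0.05.
#' @return An object of class `control_me_check`: `proportions`
#'   (empirical P(stratum | m, f, c)), `symmetry_table` (origin x stratum
#'   counts), `statistic`, `df`, `p_value`, `flagged`, `status`
#'   (`"ok"` or `"not_assessable"`), `n_oriented`.
#' @export
estimate_control_methylation <- function(control_families, alpha = 0.05) {
  stopifnot(is.data.frame(control_families))
  need <- c("m", "f", "c", "stratum")
  stopifnot(all(need %in% names(control_families)))
  fam <- control_families |>
    dplyr::filter(!is.na(.data$m), !is.na(.data$f), !is.na(.data$stratum))
  proportions <- fam |>
    dplyr::count(.data$m, .data$f, .data$c, .data$stratum) |>
    dplyr::group_by(.data$m, .data$f, .data$c) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  oriented <- fam |>
    dplyr::filter(.data$c == 1L, !(.data$m == 1L & .data$f == 1L)) |>
    dplyr::mutate(origin = dplyr::case_when(
      .data$m == 2L | .data$f == 0L ~ "maternal",
      .data$m == 0L | .data$f == 2L ~ "paternal"
    ))
  not_assessable <- function(reason) {
    structure(
      list(proportions = proportions, symmetry_table = NULL,
           statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
           alpha = alpha, flagged = NA, status = "not_assessable",
           reason = reason, n_oriented = nrow(oriented)),
      class = "control_me_check"
    )
  }
  if (nrow(oriented) == 0L) {
    return(not_assessable("no oriented control families"))
  }
  tab <- table(origin = oriented$origin, stratum = oriented$stratum)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(not_assessable(
      "need both maternal and paternal origins and at least two strata"))
  }
  test <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(
    list(proportions = proportions, symmetry_table = tab,
         statistic = unname(test$statistic), df = unname(test$parameter),
         p_value = unname(test$p.value), alpha = alpha,
         flagged = unname(test$p.value) < alpha, status = "ok",
         reason = NULL, n_oriented = nrow(oriented)),
    class = "control_me_check"
  )
}

#' @export
print.control_me_check <- function(x, ...) {
  cat("<control_me_check> status:", x$status, "\n")
  if (x$status == "ok") {
    cat("  symmetry chi-square:", format(x$statistic), " df:", x$df,
        " p:", format(x$p_value), "\n")
    cat("  flagged (p <", x$alpha, "):", x$flagged, "\n")
    print(x$symmetry_table)
  } else {
    cat("  reason:", x$reason, "\n")
  }
  invisible(x)
}
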