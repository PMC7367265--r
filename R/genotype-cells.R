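#' Enumerate Mendelian-consistent triad genotype cells
#'
#' A "cell" is a combination of mother genotype, father genotype and child
#' genotype that is possible under Mendelian inheritance of a biallelic SNP.
#' Genotypes are coded as copies of the variant allele (0, 1, 2). In the
#' ordered enumeration the child genotype distinguishes which allele came
#' from the mother (`ci`) and which from the father (`cj`), with allele
#' index 1 = reference, 2 = variant. The only mating type where the two
#' ordered heterozygous child states are both possible is the double
#' heterozygote (m = 1, f = 1); in the unordered enumeration these collapse
#' into a single ambiguous cell, giving 15 unordered vs 16 ordered cells.
#'
#' @param ordered Logical; if `TRUE`, distinguish maternal/paternal origin
#'   of the child's alleles.
#' @return A tibble, deterministically sorted. For `ordered = TRUE`:
#'   columns `m`, `f`, `ci`, `cj`, `c_copies`, `transmission`. For
#'   `ordered = FALSE`: columns `m`, `f`, `c_copies`, `ambiguous`
#'   (`TRUE` only for the double-heterozygote child cell).
#' @examples
#' nrow(enumerate_cells(ordered = FALSE)) # 15
#' nrow(enumerate_cells(ordered = TRUE))  # 16
#' @export
enumerate_cells <- function(ordered = FALSE) {
  cells <- ordered_cell_template()
  if (ordered) {
    return(cells)
  }
  cells |>
    dplyr::group_by(.data$m, .data$f, .data$c_copies) |>
    dplyr::summarise(ambiguous = dplyr::n() > 1L, .groups = "drop") |>
    dplyr::arrange(.data$m, .data$f, .data$c_copies)
}

# Ordered cell template with Mendelian transmission probabilities.
# ci/cj are allele indices (1 = reference A1, 2 = variant A2) inherited from
# the mother and father respectively.
ordered_cell_template <- function() {
  grid <- tidyr::expand_grid(m = 0:2, f = 0:2, ci = 1:2, cj = 1:2)
  grid <- grid |>
    dplyr::mutate(
      transmission = transmit_prob(.data$m, .data$ci) *
        transmit_prob(.data$f, .data$cj),
      c_copies = (.data$ci == 2L) + (.data$cj == 2L)
    ) |>
    dplyr::filter(.data$transmission > 0) |>
    dplyr::arrange(.data$m, .data$f, .data$ci, .data$cj)
  grid
}

# P(parent with `copies` variant alleles transmits allele index `allele`)
transmit_prob <- function(copies, allele) {
  p_var <- copies / 2
  ifelse(allele == 2L, p_var, 1 - p_var)
}

#' Mendelian transmission probability of an ordered child genotype
#'
#' @param m,f Parental genotypes as copies of the variant allele (0, 1, 2).
#' @param ci,cj Allele index (1 = reference, 2 = variant) inherited from the
#'   mother and the father. Vectorised.
#' @return Probability of the ordered child genotype given the parents;
#'   0 when Mendelian-inconsistent.
#' @examples
#' transmission_prob(1, 1, ci = 1, cj = 2) # 0.25
#' transmission_prob(0, 1, ci = 1, cj = 2) # 0.5
#' transmission_prob(0, 0, ci = 2, cj = 1) # 0
#' @export
transmission_prob <- function(m, f, ci, cj) {
  stopifnot(all(m %in% 0:2), all(f %in% 0:2),
            all(ci %in% 1:2), all(cj %in% 1:2))
  transmit_prob(m, ci) * transmit_prob(f, cj)
}

#' Mating-type probability under Hardy-Weinberg and random mating
#'
#' P(M = m) * P(F = f) with each parent's genotype Hardy-Weinberg
#' distributed at variant-allele frequency `var_freq`.
#'
#' @param m,f Parental variant-allele copies (0, 1, 2). Vectorised.
#' @param var_freq Variant allele frequency, strictly inside (0, 1).
#' @return Probability of the (mother, father) genotype pair.
#' @examples
#' mating_type_prob(1, 1, 0.5) # 0.25
#' @export
mating_type_prob <- function(m, f, var_freq) {
  if (!is.numeric(var_freq) || length(var_freq) != 1L ||
      is.na(var_freq) || var_freq <= 0 || var_freq >= 1) {
    stop("`var_freq` must be a single number strictly between 0 and 1.",
         call. = FALSE)
  }
  stats::dbinom(m, 2, var_freq) * stats::dbinom(f, 2, var_freq)
}

#' Resolve the parental origin of a child's alleles
#'
#' Given parental genotypes and the unordered child genotype, return the
#' ordered child genotypes consistent with the observation together with
#' their conditional probabilities (proportional to Mendelian transmission,
#' restricted to the compatible set). Origin is fully determined except for
#' a heterozygous child of two heterozygous parents.
#'
#' @param m,f Parental variant-allele copies (0, 1, 2).
#' @param child_copies Child variant-allele copies (0, 1, 2).
#' @param family_id Optional label used in the error message when the
#'   genotypes are Mendelian-inconsistent.
#' @return A tibble with columns `ci`, `cj` (allele index from mother and
#'   father) and `prob`, summing to 1.
#' @examples
#' orient_child(0, 1, 1) # variant allele must be paternal
#' orient_child(1, 1, 1) # 50/50 ambiguous
#' @export
orient_child <- function(m, f, child_copies, family_id = NULL) {
  stopifnot(m %in% 0:2, f %in% 0:2, child_copies %in% 0:2)
  cells <- ordered_cell_template() |>
    dplyr::filter(.data$m == !!m, .data$f == !!f,
                  .data$c_copies == !!child_copies)
  if (nrow(cells) == 0L) {
    lab <- if (is.null(family_id)) "" else paste0(" (family ", family_id, ")")
    stop("Mendelian-inconsistent genotypes", lab, ": mother=", m,
         ", father=", f, ", child=", child_copies, ".", call. = FALSE)
  }
  cells |>
    dplyr::transmute(ci = .data$ci, cj = .data$cj,
                     prob = .data$transmission / sum(.data$transmission))
}

# TRUE when (m, f, child) is Mendelian-consistent; parents may be NA
# (missing parent in a dyad), in which case only the observed parent
# constrains the child.
mendelian_consistent <- function(m, f, c_copies) {
  ok_mother <- is.na(m) | (c_copies == 2L & m >= 1L) |
    (c_copies == 0L & m <= 1L) | c_copies == 1L
  # a het child needs each parent to be able to donate one of the alleles
  het_ok <- function(p, q) {
    # child het: one variant, one reference; origin unknown here, so the
    # pair is consistent unless both parents are the same homozygote
    !(!is.na(p) & !is.na(q) & ((p == 0L & q == 0L) | (p == 2L & q == 2L)))
  }
  hom_ref <- c_copies == 0L &
    (is.na(m) | m <= 1L) & (is.na(f) | f <= 1L)
  hom_var <- c_copies == 2L &
    (is.na(m) | m >= 1L) & (is.na(f) | f >= 1L)
  het <- c_copies == 1L & het_ok(m, f) &
    (is.na(m) | is.na(f) |
       (m >= 1L | f >= 1L)) # at least one parent carries the variant
  hom_ref | hom_var | het
}

#' Tabulate families into per-stratum genotype cell tables
#'
#' Cross-classifies families by methylation stratum, parental mating type
#' and unordered child genotype. A heterozygous child of two heterozygous
#' parents is counted in the single ambiguous cell, never split between the
#' two ordered states. Families with a missing parent (dyads) are tabulated
#' with `NA` for that parent. Mendelian-inconsistent families are excluded
#' with a warning; the number excluded is attached as attribute
#' `n_excluded`.
#'
#' @param families A data frame with columns `family_id`, `m` (mother
#'   copies, `NA` if missing), `f` (father copies), `c` (child copies) and,
#'   unless `strata` is given, `stratum`.
#' @param strata Optional per-family stratum labels (vector recycled
#'   against rows of `families`); defaults to `families$stratum`.
#' @return A tibble with columns `stratum`, `m`, `f`, `c_copies`, `count`.
#'   Strata with no families are absent.
#' @export
build_cell_tables <- function(families, strata = NULL) {
  stopifnot(is.data.frame(families))
  if (is.null(strata)) {
    if (!"stratum" %in% names(families)) {
      stop("`families` must contain a `stratum` column or `strata` must be given.",
           call. = FALSE)
    }
    strata <- families$stratum
  }
  fam <- families |>
    dplyr::mutate(stratum = !!strata) |>
    dplyr::mutate(.consistent = mendelian_consistent(.data$m, .data$f, .data$c))
  n_bad <- sum(!fam$.consistent)
  if (n_bad > 0L) {
    bad_ids <- fam$family_id[!fam$.consistent]
    warning(sprintf(
      "Excluded %d Mendelian-inconsistent famil%s: %s",
      n_bad, if (n_bad == 1L) "y" else "ies",
      paste(utils::head(bad_ids, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  out <- fam |>
    dplyr::filter(.data$.consistent) |>
    dplyr::count(.data$stratum, .data$m, .data$f,
                 c_copies = .data$c, name = "count") |>
    dplyr::arrange(.data$stratum, .data$m, .data$f, .data$c_copies)
  attr(out, "n_excluded") <- n_bad
  out
}
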