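#' Methylation beta value from signal intensities
#'
#' beta = I_M / (I_M + I_U + 100), where the constant 100 in the
#' denominator guards against division by zero for probes with no signal.
#'
#' @param i_meth,i_unmeth Non-negative methylated / unmethylated signal
#'   intensities. Vectorised.
#' @return Beta values in `[0, 1)`.
#' @examples
#' beta_from_intensities(900, 0)   # 0.9
#' beta_from_intensities(100, 800) # 0.1
#' @export
beta_from_intensities <- function(i_meth, i_unmeth) {
  if (any(i_meth < 0, na.rm = TRUE) || any(i_unmeth < 0, na.rm = TRUE)) {
    stop("Signal intensities must be non-negative.", call. = FALSE)
  }
  i_meth / (i_meth + i_unmeth + 100)
}

#' Select CpGs within a window around a SNP
#'
#' Keeps manifest CpGs on the SNP's chromosome whose position is within
#' `max_distance` base pairs of the SNP position (inclusive boundary).
#'
#' @param manifest A data frame of CpG sites with columns `cpg_id`,
#'   `chromosome`, `position` (1-based).
#' @param snp A one-row data frame or list with `snp_id`, `chromosome`,
#'   `position`.
#' @param max_distance Window half-width in base pairs; default 50 kb.
#' @return The matching manifest rows, sorted by position. May be empty.
#' @export
select_cpgs_near_snp <- function(manifest, snp, max_distance = 50000) {
  stopifnot(is.data.frame(manifest),
            all(c("cpg_id", "chromosome", "position") %in% names(manifest)))
  # genome builds are the caller's responsibility, but when both sides
  # carry a build tag a mismatch is an error, not a silent wrong answer
  b_snp <- if ("build" %in% names(snp)) snp[["build"]] else NULL
  b_man <- attr(manifest, "build")
  if (!is.null(b_snp) && !is.null(b_man) && !identical(b_snp, b_man)) {
    stop("Genome build mismatch: SNP is ", b_snp, ", manifest is ",
         b_man, ".", call. = FALSE)
  }
  manifest |>
    dplyr::filter(
      .data$chromosome == snp$chromosome,
      abs(.data$position - snp$position) <= max_distance
    ) |>
    dplyr::arrange(.data$position)
}

#' Classify CpGs into genomic region categories
#'
#' Assigns each CpG to every region whose interval contains its position
#' (1-based, closed intervals). A CpG inside both a promoter and a gene
#' body is listed under both categories; CpGs overlapping no region are
#' dropped.
#'
#' @param cpgs A data frame with `cpg_id`, `chromosome`, `position`.
#' @param regions A data frame with `region_id`, `chromosome`, `start`,
#'   `end` (1-based inclusive) and `category` (one of `"promoter"`,
#'   `"enhancer"`, `"gene_body"`).
#' @return A tibble with one row per (CpG, category): columns `category`,
#'   `cpg_id`, `chromosome`, `position`, `region_ids` (comma-separated
#'   contributing regions).
#' @export
classify_cpgs <- function(cpgs, regions) {
  stopifnot(is.data.frame(cpgs), is.data.frame(regions))
  check_region_categories(regions$category)
  if (nrow(cpgs) == 0L || nrow(regions) == 0L) {
    return(tibble::tibble(category = character(), cpg_id = character(),
                          chromosome = character(), position = integer(),
                          region_ids = character()))
  }
  gr_cpg <- GenomicRanges::GRanges(
    cpgs$chromosome,
    IRanges::IRanges(start = cpgs$position, width = 1L)
  )
  gr_reg <- GenomicRanges::GRanges(
    regions$chromosome,
    IRanges::IRanges(start = regions$start, end = regions$end)
  )
  hits <- GenomicRanges::findOverlaps(gr_cpg, gr_reg, ignore.strand = TRUE)
  if (length(hits) == 0L) {
    return(tibble::tibble(category = character(), cpg_id = character(),
                          chromosome = character(), position = integer(),
                          region_ids = character()))
  }
  tibble::tibble(
    cpg_id = cpgs$cpg_id[S4Vectors::queryHits(hits)],
    chromosome = cpgs$chromosome[S4Vectors::queryHits(hits)],
    position = cpgs$position[S4Vectors::queryHits(hits)],
    category = regions$category[S4Vectors::subjectHits(hits)],
    region_id = regions$region_id[S4Vectors::subjectHits(hits)]
  ) |>
    dplyr::group_by(.data$category, .data$cpg_id, .data$chromosome,
                    .data$position) |>
    dplyr::summarise(
      region_ids = paste(sort(unique(.data$region_id)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$category, .data$position)
}

region_categories <- c("promoter", "enhancer", "gene_body")

check_region_categories <- function(x) {
  bad <- setdiff(unique(x), region_categories)
  if (length(bad) > 0L) {
    stop("Unknown region category: ", paste(bad, collapse = ", "),
         ". Expected one of: ", paste(region_categories, collapse = ", "),
         ".", call. = FALSE)
  }
  invisible(TRUE)
}

#' Region-average methylation per sample
#'
#' Arithmetic mean of beta values over the given CpGs, per sample, ignoring
#' missing values. A sample missing at every CpG gets `NA`.
#'
#' @param beta A methylation data frame: column `sample_id` plus one
#'   numeric beta column per CpG.
#' @param cpg_ids CpG column names to average over; must be non-empty and
#'   present in `beta`.
#' @return A tibble with columns `sample_id`, `mean_beta`.
#' @export
summarize_region <- function(beta, cpg_ids) {
  stopifnot(is.data.frame(beta), "sample_id" %in% names(beta))
  if (length(cpg_ids) == 0L) {
    stop("No CpGs to summarise: the region is empty.", call. = FALSE)
  }
  missing_cols <- setdiff(cpg_ids, names(beta))
  if (length(missing_cols) > 0L) {
    stop("CpGs absent from the methylation matrix: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(beta[, cpg_ids, drop = FALSE])
  tibble::tibble(
    sample_id = beta$sample_id,
    mean_beta = rowMeans(vals, na.rm = TRUE)
  ) |>
    dplyr::mutate(mean_beta = ifelse(is.nan(.data$mean_beta), NA_real_,
                                     .data$mean_beta))
}

#' Split samples into equally sized methylation strata
#'
#' Ranks samples by their summary methylation value (ties broken by stable
#' ascending `sample_id`) and cuts them into `n_strata` groups whose sizes
#' differ by at most one, with the larger groups at the lower strata.
#' Stratum 1 is lowest methylation. The beta values at the cut ranks are
#' attached as attribute `boundaries`.
#'
#' @param summary A data frame with `sample_id` and `mean_beta`; samples
#'   with missing `mean_beta` are dropped (they belong to no stratum).
#' @param n_strata Number of strata; default 3 (tertiles).
#' @return The input rows with non-missing values, plus an integer
#'   `stratum` column; attribute `boundaries` holds the `n_strata - 1`
#'   cut values.
#' @export
assign_strata <- function(summary, n_strata = 3) {
  stopifnot(is.data.frame(summary),
            all(c("sample_id", "mean_beta") %in% names(summary)))
  n_strata <- as.integer(n_strata)
  stopifnot(n_strata >= 1L)
  keep <- summary |> dplyr::filter(!is.na(.data$mean_beta))
  n <- nrow(keep)
  if (n < n_strata) {
    stop("Need at least ", n_strata, " samples with non-missing values to ",
         "form ", n_strata, " strata; got ", n, ".", call. = FALSE)
  }
  if (dplyr::n_distinct(keep$mean_beta) == 1L && n_strata > 1L) {
    warning("Degenerate methylation distribution: all summary values are ",
            "identical; strata assigned by sample-id order.", call. = FALSE)
  }
  # larger groups at lower strata: first (n mod S) groups get the extra one
  sizes <- rep(n %/% n_strata, n_strata)
  extra <- n %% n_strata
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  out <- keep |>
    dplyr::arrange(.data$mean_beta, .data$sample_id) |>
    dplyr::mutate(stratum = rep(seq_len(n_strata), times = sizes))
  cut_ranks <- cumsum(sizes)[-n_strata]
  attr(out, "boundaries") <- out$mean_beta[cut_ranks]
  out
}

#' Plan the per-SNP analysis units
#'
#' For one SNP, finds the nearby CpGs (within `max_distance`), classifies
#' them into region categories, and returns one analysis unit per category
#' that has at least one CpG — at most three units per SNP, each of which
#' drives one GxMe and one PoOxMe analysis downstream (hence "six analyses
#' at most" per SNP).
#'
#' @param snp One-row data frame or list with `snp_id`, `chromosome`,
#'   `position`.
#' @param manifest CpG manifest (`cpg_id`, `chromosome`, `position`).
#' @param regions Region annotation (`region_id`, `chromosome`, `start`,
#'   `end`, `category`).
#' @param max_distance Window half-width in base pairs; default 50 kb.
#' @return A tibble with columns `snp_id`, `category`, `cpg_ids`
#'   (list-column of CpG ids), `region_ids`, `n_cpgs`. Zero rows when no
#'   nearby CpG falls in any annotated region (reported with a message).
#' @export
plan_analyses <- function(snp, manifest, regions, max_distance = 50000) {
  near <- select_cpgs_near_snp(manifest, snp, max_distance = max_distance)
  if (nrow(near) == 0L) {
    message("SNP ", snp$snp_id, ": no CpGs within ", max_distance,
            " bp; no analysis units.")
    return(empty_plan())
  }
  classified <- classify_cpgs(near, regions)
  if (nrow(classified) == 0L) {
    message("SNP ", snp$snp_id, ": nearby CpGs overlap no annotated region;",
            " no analysis units.")
    return(empty_plan())
  }
  classified |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      cpg_ids = list(.data$cpg_id),
      region_ids = paste(sort(unique(unlist(
        strsplit(.data$region_ids, ",", fixed = TRUE)
      ))), collapse = ","),
      n_cpgs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(snp_id = snp$snp_id, .before = 1L)
}

empty_plan <- function() {
  tibble::tibble(snp_id = character(), category = character(),
                 cpg_ids = list(), region_ids = character(),
                 n_cpgs = integer())
}

#' Region-average methylation strata for one analysis unit
#'
#' Convenience composition of [summarize_region()] and [assign_strata()]
#' for a single (SNP, region category) analysis unit.
#'
#' @param beta Methylation data frame (`sample_id` + CpG columns).
#' @param cpg_ids CpG ids contributing to the unit.
#' @param n_strata Number of methylation strata; default 3.
#' @param boundaries Optional externally supplied cut values (e.g. imported
#'   from another dataset); when given, samples are cut at these values
#'   instead of at within-dataset ranks.
#' @return As [assign_strata()]: `sample_id`, `mean_beta`, `stratum`, with
#'   attribute `boundaries`.
#' @export
region_strata <- function(beta, cpg_ids, n_strata = 3, boundaries = NULL) {
  smry <- summarize_region(beta, cpg_ids)
  if (is.null(boundaries)) {
    return(assign_strata(smry, n_strata = n_strata))
  }
  out <- smry |>
    dplyr::filter(!is.na(.data$mean_beta)) |>
    dplyr::mutate(stratum = findInterval(.data$mean_beta, sort(boundaries),
                                         left.open = TRUE) + 1L)
  attr(out, "boundaries") <- sort(boundaries)
  out
}
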