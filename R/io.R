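# ---- readers and writers for the external formats --------------------------

#' Read family genotypes
#'
#' Two dialects are supported. The TSV dialect has a header
#' `family_id`, `role` (mother/father/child), `status` (case/control),
#' optionally `sample_id`, plus one column per SNP holding unordered
#' allele pairs like `"A/C"` (`"0/0"` or `"./."` = missing). PLINK
#' PED+MAP files are whitespace-delimited with the usual six leading
#' columns and two allele columns per SNP (`0` = missing allele);
#' phenotype 2 = case, 1 = control.
#'
#' Genotypes are converted to copies of the variant allele; by default the
#' minor (less frequent) allele in the data is the variant, overridable
#' per SNP via `ref_alleles`.
#'
#' @param path Path to the TSV file, or to the `.ped` file (with a `.map`
#'   next to it or given via `map_path`).
#' @param format `"tsv"` or `"ped"`.
#' @param map_path Optional explicit path to the MAP file.
#' @param ref_alleles Optional named character vector `snp_id -> reference
#'   allele`.
#' @return A long tibble: `family_id`, `design`, `status`, `snp_id`, `m`,
#'   `f`, `c`, `child_sample_id`; attribute `loci` holds per-SNP allele
#'   metadata (`snp_id`, `allele_ref`, `allele_var`, `var_freq`), and
#'   attribute `parse_report` the counts of families read/excluded.
#' @export
read_genotypes <- function(path, format = c("tsv", "ped"), map_path = NULL,
                           ref_alleles = NULL) {
  format <- match.arg(format)
  raw <- if (format == "tsv") {
    read_genotype_tsv(path)
  } else {
    read_genotype_ped(path, map_path)
  }
  genotypes_to_copies(raw, ref_alleles = ref_alleles)
}

read_genotype_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("family_id", "role", "status")
  if (!all(need %in% names(df))) {
    stop("Genotype TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(df$role), c("mother", "father", "child"))
  if (length(bad_role) > 0L) {
    stop("Unknown role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  bad_status <- setdiff(unique(df$status), c("case", "control"))
  if (length(bad_status) > 0L) {
    stop("Unknown status value(s): ", paste(bad_status, collapse = ", "),
         call. = FALSE)
  }
  dup <- df |> dplyr::count(.data$family_id, .data$role) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("Duplicated family_id + role: ",
         paste(paste(dup$family_id, dup$role), collapse = ", "),
         call. = FALSE)
  }
  snp_cols <- setdiff(names(df), c("family_id", "role", "status",
                                   "sample_id"))
  if (length(snp_cols) == 0L) {
    stop("Genotype TSV contains no SNP columns.", call. = FALSE)
  }
  if (!"sample_id" %in% names(df)) df$sample_id <- NA_character_
  df |>
    tidyr::pivot_longer(dplyr::all_of(snp_cols), names_to = "snp_id",
                        values_to = "alleles")
}

read_genotype_ped <- function(path, map_path = NULL) {
  if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", path)
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chromosome", "snp_id", "cm",
                                         "position"),
                           colClasses = c("character", "character",
                                          "character", "integer"))
  ped <- utils::read.table(path, header = FALSE, colClasses = "character")
  n_snps <- nrow(map)
  if (ncol(ped) != 6L + 2L * n_snps) {
    stop("PED file has ", ncol(ped), " columns; expected ",
         6L + 2L * n_snps, " for ", n_snps, " SNPs in the MAP file.",
         call. = FALSE)
  }
  names(ped)[1:6] <- c("family_id", "individual_id", "father_id",
                       "mother_id", "sex", "phenotype")
  rows <- lapply(seq_len(nrow(ped)), function(r) {
    p <- ped[r, ]
    role <- if (p$father_id != "0" || p$mother_id != "0") "child"
            else NA_character_
    a1 <- as.character(p[6L + 2L * seq_len(n_snps) - 1L])
    a2 <- as.character(p[6L + 2L * seq_len(n_snps)])
    alleles <- ifelse(a1 == "0" | a2 == "0", NA_character_,
                      paste(a1, a2, sep = "/"))
    tibble::tibble(family_id = p$family_id,
                   individual_id = p$individual_id, role = role,
                   phenotype = p$phenotype, snp_id = map$snp_id,
                   alleles = alleles)
  })
  long <- dplyr::bind_rows(rows)
  # assign parental roles: an individual is the mother/father named by the
  # child row of its family
  children <- long |> dplyr::filter(.data$role == "child") |>
    dplyr::distinct(.data$family_id, .data$individual_id)
  ped_roles <- ped |>
    dplyr::select("family_id", "individual_id", "father_id", "mother_id")
  child_rows <- ped_roles[ped_roles$individual_id %in%
                            children$individual_id, ]
  long |>
    dplyr::left_join(
      dplyr::bind_rows(
        child_rows |> dplyr::transmute(.data$family_id,
                                       individual_id = .data$mother_id,
                                       role2 = "mother"),
        child_rows |> dplyr::transmute(.data$family_id,
                                       individual_id = .data$father_id,
                                       role2 = "father")
      ),
      by = c("family_id", "individual_id")
    ) |>
    dplyr::mutate(
      role = dplyr::coalesce(.data$role, .data$role2),
      status = ifelse(.data$phenotype == "2", "case", "control"),
      sample_id = .data$individual_id
    ) |>
    dplyr::filter(!is.na(.data$role)) |>
    dplyr::select("family_id", "role", "status", "sample_id", "snp_id",
                  "alleles")
}

# long (family, role, snp, "A/C") -> wide family records in variant-copy
# coding
genotypes_to_copies <- function(long, ref_alleles = NULL) {
  split_alleles <- function(x) {
    x[x %in% c("0/0", "./.", "", "NA")] <- NA_character_
    strsplit(x, "/", fixed = TRUE)
  }
  parsed <- long |>
    dplyr::mutate(pair = split_alleles(.data$alleles))
  # family status is the child's status (parents in PED pedigrees carry
  # their own phenotype codes)
  child_status <- parsed |>
    dplyr::filter(.data$role == "child") |>
    dplyr::distinct(.data$family_id, child_status = .data$status)
  parsed <- parsed |>
    dplyr::left_join(child_status, by = "family_id") |>
    dplyr::mutate(status = dplyr::coalesce(.data$child_status,
                                           .data$status)) |>
    dplyr::select(-"child_status")
  alleles_long <- parsed |>
    tidyr::unnest_longer("pair") |>
    dplyr::filter(!is.na(.data$pair))
  loci <- alleles_long |>
    dplyr::count(.data$snp_id, .data$pair, name = "n_allele")
  loci_meta <- loci |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(
      alleles = list(stats::setNames(.data$n_allele, .data$pair)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      allele_ref = purrr::map2_chr(.data$alleles, .data$snp_id,
        function(a, s) {
          if (!is.null(ref_alleles) && s %in% names(ref_alleles)) {
            return(ref_alleles[[s]])
          }
          names(a)[which.max(a)] # major allele is the reference default
        }),
      allele_var = purrr::map2_chr(.data$alleles, .data$allele_ref,
        function(a, ref) {
          others <- setdiff(names(a), ref)
          if (length(others) == 0L) NA_character_ else
            others[which.max(unlist(a[others]))]
        }),
      var_freq = purrr::map2_dbl(.data$alleles, .data$allele_ref,
        function(a, ref) {
          tot <- sum(a)
          (tot - sum(a[names(a) == ref])) / tot
        })
    ) |>
    dplyr::select("snp_id", "allele_ref", "allele_var", "var_freq")
  multi <- alleles_long |>
    dplyr::distinct(.data$snp_id, .data$pair) |>
    dplyr::count(.data$snp_id) |>
    dplyr::filter(.data$n > 2L)
  if (nrow(multi) > 0L) {
    stop("Multi-allelic SNP(s) not supported: ",
         paste(multi$snp_id, collapse = ", "), call. = FALSE)
  }
  copies <- parsed |>
    dplyr::left_join(loci_meta, by = "snp_id") |>
    dplyr::mutate(copies = purrr::map2_int(.data$pair, .data$allele_ref,
      function(p, ref) {
        if (is.null(p) || anyNA(p)) return(NA_integer_)
        sum(p != ref)
      })) |>
    dplyr::select("family_id", "role", "status", "sample_id", "snp_id",
                  "copies")
  wide <- copies |>
    tidyr::pivot_wider(id_cols = c("family_id", "status", "snp_id"),
                       names_from = "role",
                       values_from = c("copies", "sample_id")) |>
    dplyr::rename(m = "copies_mother", f = "copies_father",
                  c = "copies_child",
                  child_sample_id = "sample_id_child")
  for (col in c("m", "f", "c", "child_sample_id")) {
    if (!col %in% names(wide)) {
      wide[[col]] <- if (col == "child_sample_id") NA_character_ else
        NA_integer_
    }
  }
  missing_child <- is.na(wide$c)
  if (any(missing_child)) {
    stop("Child genotype missing for family/SNP: ",
         paste(utils::head(
           paste(wide$family_id[missing_child], wide$snp_id[missing_child]),
           5L), collapse = ", "), call. = FALSE)
  }
  out <- wide |>
    dplyr::mutate(
      design = dplyr::case_when(
        !is.na(.data$m) & !is.na(.data$f) ~ "triad",
        !is.na(.data$m) ~ "mother_dyad",
        !is.na(.data$f) ~ "father_dyad",
        TRUE ~ "child_only"
      )
    ) |>
    dplyr::select("family_id", "design", "status", "snp_id", "m", "f",
                  "c", "child_sample_id") |>
    dplyr::arrange(.data$snp_id, .data$family_id)
  attr(out, "loci") <- loci_meta
  attr(out, "parse_report") <- list(
    n_families = dplyr::n_distinct(out$family_id),
    n_snps = dplyr::n_distinct(out$snp_id)
  )
  out
}

#' Read a per-sample CpG beta matrix
#'
#' TSV with samples in rows: column `sample_id` plus one numeric column
#' per CpG. Values must lie in `[0, 1]`; the first offending cell is
#' named in the error.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_methylation <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", .default = "d"
  ), progress = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("Methylation matrix must have a `sample_id` column.",
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("Duplicate sample_id in methylation matrix.", call. = FALSE)
  }
  cpg_cols <- setdiff(names(df), "sample_id")
  for (cc in cpg_cols) {
    bad <- which(!is.na(df[[cc]]) & (df[[cc]] < 0 | df[[cc]] > 1))
    if (length(bad) > 0L) {
      stop("Beta value outside [0, 1] at sample ",
           df$sample_id[bad[1L]], ", CpG ", cc, ": ", df[[cc]][bad[1L]],
           call. = FALSE)
    }
  }
  df
}

#' Read a CpG manifest
#'
#' TSV with columns `cpg_id`, `chromosome`, `position` (1-based).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    cpg_id = "c", chromosome = "c", position = "i"
  ), progress = FALSE)
  need <- c("cpg_id", "chromosome", "position")
  if (!all(need %in% names(df))) {
    stop("Manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$cpg_id)) {
    stop("Duplicate cpg_id in manifest: ",
         df$cpg_id[duplicated(df$cpg_id)][1L], call. = FALSE)
  }
  if (any(df$position < 1L, na.rm = TRUE)) {
    stop("Manifest positions must be >= 1 (1-based).", call. = FALSE)
  }
  df
}

#' Read genomic region annotation
#'
#' Dialect `"tsv"`: 1-based closed intervals with header `region_id`,
#' `chromosome`, `start`, `end`, `category`. Dialect `"bed"`: strict BED
#' (0-based half-open, no header, columns chrom/start/end/region_id/
#' category), converted internally to 1-based closed coordinates
#' (BED start 99 becomes position 100).
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"bed"`.
#' @return A tibble with 1-based closed `start`/`end`.
#' @export
read_regions <- function(path, dialect = c("tsv", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- readr::read_tsv(path, col_types = readr::cols(
      region_id = "c", chromosome = "c", start = "i", end = "i",
      category = "c"
    ), progress = FALSE)
  } else {
    df <- readr::read_tsv(path,
      col_names = c("chromosome", "start", "end", "region_id", "category"),
      col_types = "ciicc", progress = FALSE) |>
      dplyr::mutate(start = .data$start + 1L) # 0-based half-open -> 1-based closed
  }
  need <- c("region_id", "chromosome", "start", "end", "category")
  if (!all(need %in% names(df))) {
    stop("Region annotation must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  check_region_categories(df$category)
  if (any(df$start > df$end)) {
    stop("Region start must be <= end.", call. = FALSE)
  }
  df[need]
}

#' Write interaction results to TSV
#'
#' One row per (SNP, category, analysis); see
#' [glance()][generics::glance].
#'
#' @param results A single `interaction_result` or a list of them.
#' @param path Output file.
#' @return The written tibble, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "interaction_result")) results <- list(results)
  tab <- dplyr::bind_rows(lapply(results, glance))
  readr::write_tsv(tab, path)
  invisible(tab)
}

#' Write a run-metadata sidecar
#'
#' Records options, seed and input-file checksums as JSON next to the
#' results, so a run can be reproduced from its sidecar.
#'
#' @param path Output JSON file.
#' @param options Named list of analysis options.
#' @param seed Seed used.
#' @param inputs Character vector of input file paths (hashed with their
#'   sizes and modification-free md5-like content sum).
#' @return The metadata list, invisibly.
#' @export
write_run_metadata <- function(path, options = list(), seed = NA,
                               inputs = character()) {
  hash_file <- function(p) {
    if (!file.exists(p)) return(NA_character_)
    unname(tools::md5sum(p))
  }
  meta <- list(
    package = "triadme",
    version = as.character(utils::packageVersion("triadme")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    options = options,
    inputs = lapply(stats::setNames(inputs, inputs), hash_file)
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(meta)
}
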