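# Shared fixture builders (all programmatic; no files on disk).

# Minimal triad family tibble from parallel genotype vectors.
make_families <- function(m, f, c, stratum = 1L, status = "case") {
  tibble::tibble(
    family_id = sprintf("fam%03d", seq_along(c)),
    design = "triad", status = status,
    m = as.integer(m), f = as.integer(f), c = as.integer(c),
    stratum = rep_len(as.integer(stratum), length(c)),
    child_sample_id = sprintf("child%03d", seq_along(c))
  )
}

# Random small triad cell table: multinomial counts over the consistent
# cells of one or more informative mating types, at a random gene-dose RR.
random_cell_table <- function(n_families = 50) {
  log_rr <- stats::runif(1, -1.2, 1.2)
  mts <- list(c(1, 1), c(1, 0), c(0, 1), c(1, 2), c(2, 1))
  picked <- mts[sample.int(length(mts), sample(2:4, 1))]
  rows <- lapply(picked, function(mt) {
    p <- oracle_child_probs(mt[1], mt[2], log_rr)
    ok <- p > 0
    n_mt <- max(2L, stats::rpois(1, n_families / length(picked)))
    cnt <- as.vector(stats::rmultinom(1, n_mt, p[ok]))
    tibble::tibble(m = mt[1], f = mt[2],
                   c_copies = as.integer(names(p)[ok]), count = cnt)
  })
  dplyr::bind_rows(rows)
}
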