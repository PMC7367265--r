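# Independent brute-force oracle for the mating-type-conditional triad
# likelihood. Written from first principles with explicit loops over
# parental allele transmissions; deliberately shares no code with the
# package's vectorised likelihood.

# P(unordered child genotype | mother m, father f, log RR params) for the
# gene-dose model: enumerate the four maternal x paternal transmission
# combinations, weight each by RR^dose, normalise within the mating type.
oracle_child_probs <- function(m, f, log_rr, log_rr_dd = NULL) {
  w <- c(`0` = 0, `1` = 0, `2` = 0)
  for (a_m in c(1, 2)) {
    p_m <- if (a_m == 2) m / 2 else 1 - m / 2
    for (a_f in c(1, 2)) {
      p_f <- if (a_f == 2) f / 2 else 1 - f / 2
      dose <- (a_m == 2) + (a_f == 2)
      risk <- if (dose == 2 && !is.null(log_rr_dd)) {
        exp(log_rr_dd)
      } else {
        exp(log_rr * dose)
      }
      w[as.character(dose)] <- w[as.character(dose)] + p_m * p_f * risk
    }
  }
  w / sum(w)
}

# Poo-model variant: separate maternal/paternal log RRs.
oracle_child_probs_poo <- function(m, f, log_rr_m, log_rr_f) {
  w <- list()
  for (a_m in c(1, 2)) {
    p_m <- if (a_m == 2) m / 2 else 1 - m / 2
    for (a_f in c(1, 2)) {
      p_f <- if (a_f == 2) f / 2 else 1 - f / 2
      risk <- exp(log_rr_m * (a_m == 2) + log_rr_f * (a_f == 2))
      key <- as.character((a_m == 2) + (a_f == 2))
      w[[key]] <- (if (is.null(w[[key]])) 0 else w[[key]]) +
        p_m * p_f * risk
    }
  }
  tot <- sum(unlist(w))
  vapply(c("0", "1", "2"), function(k) {
    if (is.null(w[[k]])) 0 else w[[k]] / tot
  }, numeric(1))
}

# Conditional log-likelihood of a cell-count table (columns m, f, c_copies,
# count) at a given gene-dose log RR.
oracle_loglik <- function(log_rr, counts, log_rr_dd = NULL) {
  ll <- 0
  for (r in seq_len(nrow(counts))) {
    if (counts$count[r] == 0) next
    p <- oracle_child_probs(counts$m[r], counts$f[r], log_rr, log_rr_dd)
    ll <- ll + counts$count[r] * log(p[[as.character(counts$c_copies[r])]])
  }
  ll
}

# Grid maximum of the oracle log-likelihood over log RR in [-2, 2].
oracle_grid_max <- function(counts, step = 0.01) {
  grid <- seq(-2, 2, by = step)
  max(vapply(grid, oracle_loglik, numeric(1), counts = counts))
}
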