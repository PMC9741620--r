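# Small fixtures and independent oracles used across test files.

# Random biallelic panel at HWE with given frequencies.
hwe_panel <- function(n, p, ids = sprintf("s%02d", seq_len(n))) {
  L <- length(p)
  calls <- matrix(stats::rbinom(n * L, 2, rep(p, each = n)), n, L)
  geno_matrix(calls, samples = ids)
}

# Draw one individual with inbreeding f at frequencies p.
inbred_calls <- function(p, f) {
  pr2 <- f * p + (1 - f) * p^2
  pr1 <- (1 - f) * 2 * p * (1 - p)
  u <- stats::runif(length(p))
  ifelse(u < pr2, 2L, ifelse(u < pr2 + pr1, 1L, 0L))
}

# Independent oracle for the nine-state genotype-pair probabilities:
# enumerate the 16 ordered assignments of minor/major to the four alleles
# (i1, i2, j1, j2), keep those consistent with the state's IBD classes
# (all alleles of a class equal), and weight by one frequency factor per
# class. Class structure is written down independently of the package's
# partition encoding, following the condensed-state definitions.
oracle_state_probs <- function(p) {
  classes <- list(                  # class index per allele i1,i2,j1,j2
    S1 = c(1, 1, 1, 1),
    S2 = c(1, 1, 2, 2),
    S3 = c(1, 1, 1, 2),
    S4 = c(1, 1, 2, 3),
    S5 = c(1, 2, 1, 1),
    S6 = c(1, 2, 3, 3),
    S7 = c(1, 2, 1, 2),
    S8 = c(1, 2, 1, 3),
    S9 = c(1, 2, 3, 4)
  )
  out <- matrix(0, 9, 9,
                dimnames = list(names(classes),
                                paste0("g", rep(0:2, each = 3), rep(0:2, 3))))
  combos <- as.matrix(expand.grid(rep(list(0:1), 4)))  # minor = 1
  for (k in seq_along(classes)) {
    cls <- classes[[k]]
    for (row in seq_len(nrow(combos))) {
      al <- combos[row, ]
      consistent <- all(tapply(al, cls, function(v) length(unique(v)) == 1))
      if (!consistent) next
      pr <- 1
      for (cl in unique(cls)) {
        a <- al[match(cl, cls)]
        pr <- pr * if (a == 1) p else (1 - p)
      }
      gi <- al[1] + al[2]; gj <- al[3] + al[4]
      out[k, 3 * gi + gj + 1] <- out[k, 3 * gi + gj + 1] + pr
    }
  }
  out
}

# Random valid pedigree: n_founders founders then n_extra members whose
# parents are drawn from earlier members.
random_pedigree <- function(n_founders, n_extra, founder_f = 0) {
  ids <- sprintf("m%02d", seq_len(n_founders + n_extra))
  sire <- dam <- rep(NA_character_, n_founders + n_extra)
  for (k in seq_len(n_extra)) {
    x <- n_founders + k
    par <- sample(ids[seq_len(x - 1L)], 2)
    sire[x] <- par[1]; dam[x] <- par[2]
  }
  pedigree(ids, sire, dam,
           founder_f = rep_len(founder_f, n_founders + n_extra))
}

# Random point on the 8-simplex.
random_delta <- function() {
  d <- -log(stats::runif(9))
  d / sum(d)
}
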