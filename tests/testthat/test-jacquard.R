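test_that("state table matches closed-form anchor values", {
  S <- state_genotype_probs(0.5)
  expect_equal(S["S9", "g11"], 0.25)       # independent HWE het x het
  expect_equal(S["S7", "g11"], 0.5)        # shared pair of IBD alleles
  expect_equal(state_genotype_probs(0.3)["S1", "g22"], 0.3)  # all four IBD
  # S7 forces identical genotypes with HWE marginals
  expect_equal(sum(S["S7", c("g01", "g02", "g10", "g12", "g20", "g21")]), 0)
  expect_error(state_genotype_probs(0), "degenerate")
})

test_that("state table equals exhaustive allele-identity enumeration", {
  for (p in c(0.1, 0.3, 0.5)) {
    S <- state_genotype_probs(p)
    expect_equal(S, oracle_state_probs(p), tolerance = 1e-12)
    expect_equal(unname(rowSums(S)), rep(1, 9), tolerance = 1e-12)
  }
})

test_that("dyad log-likelihood is the mixture over states", {
  e7 <- replace(rep(0, 9), 7, 1)
  e9 <- replace(rep(0, 9), 9, 1)
  expect_equal(dyad_loglik(1L, 1L, 0.5, e9), log(0.25))
  # pure S7 on identical genotypes: product of HWE genotype probabilities
  set.seed(7)
  p <- runif(50, 0.1, 0.5)
  g <- rbinom(50, 2, p)
  hwe <- ifelse(g == 2, p^2, ifelse(g == 1, 2 * p * (1 - p), (1 - p)^2))
  expect_equal(dyad_loglik(g, g, p, e7), sum(log(hwe)))
  # mixture bound: no mixture beats the best pure state at a single locus
  for (rep in 1:20) {
    pp <- runif(1, 0.1, 0.9)
    gi <- sample(0:2, 1); gj <- sample(0:2, 1)
    pure <- vapply(1:9, function(k)
      dyad_loglik(gi, gj, pp, replace(rep(0, 9), k, 1)), numeric(1))
    expect_lte(dyad_loglik(gi, gj, pp, random_delta()), max(pure) + 1e-12)
  }
})

test_that("EM keeps the estimate on the simplex with non-decreasing likelihood", {
  set.seed(8)
  for (rep in 1:25) {
    p <- runif(150, 0.05, 0.5)
    f <- runif(1, 0, 0.5)
    fit <- dyad_ml(inbred_calls(p, f), inbred_calls(p, f), p)
    expect_true(all(fit$delta >= 0))
    expect_equal(sum(fit$delta), 1, tolerance = 1e-9)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("duplicated individuals and unrelated pairs sit at the expected boundaries", {
  set.seed(9)
  p <- runif(1400, 0.05, 0.5)
  g <- rbinom(1400, 2, p)
  expect_lt(abs(dyad_ml(g, g, p)$r - 1), 0.05)
  fit0 <- dyad_ml(rbinom(1400, 2, p), rbinom(1400, 2, p), p)
  expect_lt(fit0$r, 0.05)
  expect_gt(fit0$delta[9], 0.9)
})

test_that("full-sibling relatedness is recovered over replicates", {
  set.seed(10)
  ped <- pedigree(c("p1", "p2", "c1", "c2"), sire = c(NA, NA, "p1", "p1"),
                  dam = c(NA, NA, "p2", "p2"))
  r <- replicate(100, {
    p <- runif(1400, 0.05, 0.5)
    gm <- cross_genotypes(ped, hwe_panel(2, p, ids = c("p1", "p2")))
    dyad_ml(gm["c1", ], gm["c2", ], p)$r
  })
  expect_lt(abs(mean(r) - 0.5), 0.05)
})

test_that("panel-wide frequencies inflate within-subpopulation dyads", {
  # the estimator's structural failure mode: dyads from one subpopulation
  # evaluated with panel-wide frequencies look more related than with their
  # own subpopulation's true frequencies
  set.seed(11)
  infl <- replicate(100, {
    p_anc <- runif(400, 0.1, 0.5)
    fst <- 0.2
    p1 <- pmin(pmax(rbeta(400, p_anc * (1 - fst) / fst,
                          (1 - p_anc) * (1 - fst) / fst), 1e-4), 1 - 1e-4)
    p2 <- pmin(pmax(rbeta(400, p_anc * (1 - fst) / fst,
                          (1 - p_anc) * (1 - fst) / fst), 1e-4), 1 - 1e-4)
    gi <- rbinom(400, 2, p1); gj <- rbinom(400, 2, p1)
    panel_freq <- (2 * p1 + 2 * p2) / 4   # two equal-size subpopulations
    dyad_ml(gi, gj, panel_freq)$r - dyad_ml(gi, gj, p1)$r
  })
  expect_gt(mean(infl), 0)
})

test_that("locus bootstrap is deterministic, degenerate for constant panels, and covers 0", {
  # identically-informative loci: every resample is the same dataset
  g <- rep(1L, 100); p <- rep(0.5, 100)
  bs <- bootstrap_ci(g, g, p, n_boot = 20, seed = 1)
  expect_equal(diff(bs$ci), 0)

  set.seed(12)
  p <- runif(200, 0.1, 0.5)
  g1 <- rbinom(200, 2, p); g2 <- rbinom(200, 2, p)
  b1 <- bootstrap_ci(g1, g2, p, n_boot = 25, seed = 99)
  b2 <- bootstrap_ci(g1, g2, p, n_boot = 25, seed = 99)
  expect_identical(b1$ci, b2$ci)

  # unrelated pairs: the 95% interval overlaps 0 in at least 90% of sims
  overlap <- vapply(1:10, function(s) {
    set.seed(100 + s)
    p <- runif(200, 0.1, 0.5)
    bs <- bootstrap_ci(rbinom(200, 2, p), rbinom(200, 2, p), p,
                       n_boot = 100, seed = s)
    bs$ci[1] <= 0
  }, logical(1))
  expect_gte(mean(overlap), 0.9)
})

test_that("significance filtering keeps only intervals strictly above zero", {
  est <- data.frame(sample_i = c("a", "a", "b"), sample_j = c("b", "c", "c"),
                    relatedness = c(0.25, 0.15, 0.1),
                    ci_low = c(0.1, -0.02, 0), ci_high = c(0.4, 0.3, 0.3))
  attr(est, "samples") <- c("a", "b", "c")
  class(est) <- c("kin_estimates", class(est))
  kept <- filter_significant(est)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$ci_low, 0.1)
})
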