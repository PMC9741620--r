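test_that("individualization panel carries the advertised truth structure", {
  panel <- simulate_individualization_panel(seed = 2)
  expect_equal(nrow(panel$replicate_pairs), 23)
  expect_equal(nrow(panel$inbred_pairs), 5)
  expect_true(all(panel$replicate_pairs %in% rownames(panel$geno)))
  expect_true(all(panel$inbred_pairs %in% rownames(panel$geno)))
  # the trio's panel-referenced inbreeding matches the emulated locality
  f <- inbreeding_ml(panel$geno[grep("^inbred", rownames(panel$geno))[1:3], ],
                     allele_freqs(panel$geno))
  expect_gt(mean(f), 0.6)
})

test_that("counting estimator individualizes; likelihood estimator conflates inbred kin", {
  panel <- simulate_individualization_panel(seed = 3)
  rep <- run_individualization(panel, maf_grid = 0.025)
  res <- rep$results
  king <- res[res$estimator == "king", ]
  dyad <- res[res$estimator == "dyadml", ]
  expect_equal(king$replicates_detected, 23L)
  expect_equal(dyad$replicates_detected, 23L)
  expect_equal(king$inbred_separated, 5L)
  vals <- rep$values
  expect_true(all(vals$relatedness[vals$estimator == "king" &
                                   vals$category == "different_individual"] < 0.8))
  # the likelihood estimator reports near-clonal relatedness for the trio
  expect_true(any(vals$relatedness[vals$estimator == "dyadml" &
                                   vals$category == "different_individual"] > 0.9))
  expect_error(run_individualization(list(replicate_pairs = NULL)),
               "no replicate pairs")
})

test_that("the counting estimator wins the individualization comparison across seeds", {
  accuracy <- function(res)
    (res$replicates_detected + res$inbred_separated) /
      (res$replicates_total + res$inbred_total)
  wins <- ties <- 0L
  n_rep <- 20L
  for (s in seq_len(n_rep)) {
    panel <- simulate_individualization_panel(seed = 100 + s)
    res <- run_individualization(panel, maf_grid = 0.025)$results
    a_king <- accuracy(res[res$estimator == "king", ])
    a_dyad <- accuracy(res[res$estimator == "dyadml", ])
    expect_gte(a_king, a_dyad)
    if (a_king > a_dyad) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.8)
})

test_that("recovery reports aggregate per category with the right shape", {
  rep <- run_relatedness_recovery(n_sims = 3, n_loci = 300, seed = 5)
  expect_setequal(rep$table$category, names(relationship_pedigrees()))
  expect_true(all(c("king_mean", "king_sd", "dyadml_mean", "dyadml_sd")
                  %in% names(rep$table)))
  expect_equal(nrow(rep$raw), 3 * 7 * 2)

  irep <- run_inbreeding_recovery(n_sims = 3, n_loci = 300, seed = 6)
  expect_setequal(irep$table$category, names(inbreeding_pedigrees()))
  expect_true(all(irep$table$ml_sd >= 0, na.rm = TRUE))
})

test_that("inbreeding recovery matches theory for the canonical matings", {
  rep <- run_inbreeding_recovery(n_sims = 30, seed = 7)
  tab <- rep$table
  get <- function(cat, col) tab[tab$category == cat, col]
  expect_lt(abs(get("full_siblings", "ml_mean") - 0.25), 0.05)
  expect_lt(abs(get("half_siblings", "ml_mean") - 0.125), 0.05)
  expect_lt(get("none", "ml_mean"), 0.05)
  expect_lt(abs(get("half_first_cousins", "ml_mean") - 0.03125), 0.05)
})

test_that("inbreeding is recovered more accurately than relatedness under structure", {
  rrel <- run_relatedness_recovery(founders = "structured", n_sims = 10,
                                   seed = 8)
  rinb <- run_inbreeding_recovery(founders = "structured", n_sims = 10,
                                  seed = 8)
  err_rel <- mean(abs(rrel$table$dyadml_mean - rrel$table$theoretical))
  err_inb <- mean(abs(rinb$table$ml_mean - rinb$table$theoretical))
  expect_lt(err_inb, err_rel)
})

test_that("network edges obey significance and close/distant classification", {
  est <- data.frame(sample_i = c("a", "a", "b", "c"),
                    sample_j = c("b", "c", "c", "d"),
                    relatedness = c(0.25, 0.15, 0.3, -0.05),
                    ci_low = c(0.1, 0.02, -0.01, NA),
                    ci_high = c(0.4, 0.28, 0.6, NA))
  attr(est, "samples") <- c("a", "b", "c", "d")
  class(est) <- c("kin_estimates", class(est))
  net <- build_network(est)
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$edges$class, c("close", "distant"))

  # counting-estimator path: sign filter only
  est2 <- est; est2$ci_low <- NULL; est2$ci_high <- NULL
  net2 <- build_network(est2)
  expect_equal(nrow(net2$edges), 3)
  expect_false(any(net2$edges$relatedness < 0))
  g <- as_igraph(net2)
  expect_equal(igraph::vcount(g), 4)
})

test_that("seeded experiment runs are reproducible end to end", {
  a <- run_relatedness_recovery(n_sims = 2, n_loci = 200, seed = 9)
  b <- run_relatedness_recovery(n_sims = 2, n_loci = 200, seed = 9)
  expect_identical(a$table, b$table)
  p1 <- simulate_individualization_panel(seed = 10)
  p2 <- simulate_individualization_panel(seed = 10)
  expect_identical(unclass(p1$geno), unclass(p2$geno))
})
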