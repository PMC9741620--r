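test_that("pedigree construction validates structure", {
  expect_error(pedigree(c("a", "b"), sire = c(NA, "a"), dam = c(NA, NA)),
               "two recorded parents or none")
  expect_error(pedigree(c("a", "b"), sire = c("b", "a"), dam = c("b", "a")),
               "cycle")
  expect_error(pedigree("a", sire = "x", dam = "y"), "unknown parent")
  # "0" and "" mean founder
  ped <- pedigree(c("a", "b", "c"), sire = c("0", "", "a"),
                  dam = c("0", "", "b"))
  expect_equal(sum(is.na(ped$sire)), 2L)
})

test_that("recursive kinship reproduces the canonical relationship values", {
  for (nm in names(relationship_pedigrees())) {
    ped <- relationship_pedigrees()[[nm]]
    d <- attr(ped, "dyad")
    expect_identical(2 * theoretical_kinship(ped, d[1], d[2]),
                     attr(ped, "theoretical_r"))
  }
  # self-kinship of a fully inbred founder
  ped <- pedigree("x", founder_f = 1)
  expect_identical(theoretical_kinship(ped, "x", "x"), 1)
})

test_that("theoretical inbreeding equals the parents' kinship", {
  for (nm in names(inbreeding_pedigrees())) {
    ped <- inbreeding_pedigrees()[[nm]]
    expect_identical(theoretical_inbreeding(ped, attr(ped, "target")),
                     attr(ped, "theoretical_f"))
  }
  ped <- pedigree("x", founder_f = 0.78)
  expect_equal(theoretical_inbreeding(ped, "x"), 0.78)
})

test_that("gene-drop Monte Carlo agrees with the recursion", {
  ped <- relationship_pedigrees()$parent_offspring
  gd <- gene_drop_ibd(ped, "p1", "c1", n_reps = 100000, seed = 1)
  expect_lt(abs(gd$kinship - 0.25), 3 * gd$se + 1e-9)
  # founders are unrelated
  expect_equal(gene_drop_ibd(ped, "p1", "p2", n_reps = 1000, seed = 2)$kinship, 0)
  # every pair of a random 10-member pedigree
  set.seed(3)
  rped <- random_pedigree(4, 6)
  phi <- outer(rped$id, rped$id, Vectorize(function(a, b)
    theoretical_kinship(rped, a, b)))
  for (k in 1:8) {
    ab <- sample(rped$id, 2)
    gd <- gene_drop_ibd(rped, ab[1], ab[2], n_reps = 20000, seed = 30 + k)
    expect_lt(abs(gd$kinship - phi[match(ab[1], rped$id), match(ab[2], rped$id)]),
              3 * gd$se + 1e-9)
  }
  # founder inbreeding propagates through the drop
  pedf <- pedigree(c("p1", "p2", "c1"), sire = c(NA, NA, "p1"),
                   dam = c(NA, NA, "p2"), founder_f = c(1, 1, 0))
  gdf <- gene_drop_ibd(pedf, "c1", "c1", n_reps = 50000, seed = 4)
  # phi(c1, c1) = (1 + F_c1)/2 = 0.5 since parents are unrelated
  expect_lt(abs(gdf$kinship - theoretical_kinship(pedf, "c1", "c1")),
            3 * gdf$se + 1e-9)
})

test_that("genotype crossing follows Mendelian transmission", {
  loci <- paste0("L", 1:3)
  fnd <- geno_matrix(rbind(p1 = c(2L, 1L, 2L), p2 = c(0L, 1L, NA)),
                     loci = loci)
  ped <- pedigree(c("p1", "p2", "c1"), sire = c(NA, NA, "p1"),
                  dam = c(NA, NA, "p2"))
  gm <- cross_genotypes(ped, fnd, seed = 5)
  expect_equal(as.integer(gm["c1", "L1"]), 1L)   # hom x hom is certain
  expect_true(is.na(gm["c1", "L3"]))             # missing parent call

  # het x het segregates 1:2:1
  L <- 10000
  fnd2 <- geno_matrix(rbind(p1 = rep(1L, L), p2 = rep(1L, L)))
  gm2 <- cross_genotypes(ped, fnd2, seed = 6)
  tab <- table(factor(gm2["c1", ], levels = 0:2))
  expect_gt(chisq.test(tab, p = c(.25, .5, .25))$p.value, 0.001)
})

test_that("crossing a full-sib mating realizes the theoretical inbreeding", {
  set.seed(7)
  L <- 10000
  ped <- inbreeding_pedigrees()$full_siblings
  fnd <- hwe_panel(2, rep(0.5, L), ids = c("p1", "p2"))
  gm <- cross_genotypes(ped, fnd, seed = 8)
  # excess homozygosity of the inbred offspring relative to p = 0.5
  f_hat <- unname(inbreeding_moment(gm["x1", , drop = FALSE], rep(0.5, L)))
  se <- sqrt(0.25 * (1 - 0.25) / (L * 0.5))  # rough binomial-scale error
  expect_lt(abs(f_hat - 0.25), 5 * se)
})

test_that("simulate() yields reproducible crossing realizations", {
  set.seed(9)
  ped <- relationship_pedigrees()$full_siblings
  fnd <- hwe_panel(2, runif(100, .1, .5), ids = c("p1", "p2"))
  a <- simulate(ped, nsim = 2, seed = 11, founder_gm = fnd)
  b <- simulate(ped, nsim = 2, seed = 11, founder_gm = fnd)
  expect_identical(lapply(a, unclass), lapply(b, unclass))
})

test_that("pedigree TSV reader round-trips the canonical format", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsire\tdam\tfounder_f",
               "p1\t0\t0\t0.5", "p2\t0\t0\t0", "kid\tp1\tp2\t0"), path)
  ped <- read_pedigree(path)
  expect_equal(nrow(ped), 3)
  expect_equal(ped$founder_f[ped$id == "p1"], 0.5)
  # phi(p1, kid) = phi(p1, p1)/2 = (1 + 0.5)/4 with an inbred founder
  expect_equal(theoretical_kinship(ped, "p1", "kid"), 0.375)
})
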