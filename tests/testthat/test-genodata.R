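test_that("geno_matrix validates codes and identifiers", {
  expect_s3_class(geno_matrix(rbind(a = c(0, 1, 2), b = c(NA, 2, 0))),
                  "geno_matrix")
  expect_error(geno_matrix(rbind(a = c(0, 3))), "genotype codes")
  expect_error(geno_matrix(rbind(a = 0:1, a = 0:1)), "unique")
})

test_that("allele frequencies come from non-missing calls only", {
  gm <- geno_matrix(rbind(a = c(0, 0, NA), b = c(1, 0, NA), c = c(2, 1, NA)))
  f <- allele_freqs(gm)
  expect_equal(unname(f), c(0.5, 1 / 6, NA))
})

test_that("VCF round trip preserves genotype codes, polarization and missingness", {
  # ALT dosages (1, 2) give ALT frequency 0.75: re-polarized to (1, 0), MAF 0.25
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "sampA", "sampB", sep = "\t"),
           paste("chr1", "100", "snp1", "A", "G", ".", "PASS", ".", "GT",
                 "0/1", "1/1", sep = "\t"),
           paste("chr1", "200", "snp2", "C", "T", ".", "PASS", ".", "GT",
                 "./.", "0/1", sep = "\t"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  res <- read_vcf(path)
  expect_equal(unname(unclass(res$geno)[, "snp1"]), c(1L, 0L))
  expect_equal(res$catalog$maf[1], 0.25)
  expect_true(is.na(res$geno["sampA", "snp2"]))

  set.seed(4)
  gm <- hwe_panel(5, runif(30, 0.05, 0.45))
  gm[2, 3] <- NA
  # polarize so codes count the minor allele, the writer's contract
  flip <- allele_freqs(gm) > 0.5
  gm[, flip] <- 2L - gm[, flip, drop = FALSE]
  out <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path = out)
  back <- read_vcf(out)
  expect_identical(unclass(back$geno), unclass(gm))

  empty <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(geno_matrix(matrix(integer(0), 0, 0)), path = empty)
  expect_true(all(grepl("^#", readLines(empty))))
})

test_that("genotype codes map to the expected GT strings", {
  gm <- geno_matrix(matrix(c(0L, 1L, 2L, NA), 1,
                           dimnames = list("s1", paste0("L", 1:4))))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path = path)
  body <- grep("^[^#]", readLines(path), value = TRUE)
  gt <- vapply(strsplit(body, "\t"), `[`, character(1), 10)
  expect_equal(gt, c("0/0", "0/1", "1/1", "./."))
})

test_that("call-rate filter keeps exactly the loci at or above the threshold", {
  set.seed(1)
  # 10 samples; locus j has j-1 called genotypes, j = 1..11
  calls <- sapply(0:10, function(k) c(rep(0L, k), rep(NA, 10 - k)))
  gm <- geno_matrix(calls, samples = paste0("s", 1:10),
                    loci = paste0("L", 0:10))
  expect_equal(colnames(filter_call_rate(gm, 0.9)), c("L9", "L10"))
  # enumeration oracle over call counts and thresholds
  for (thr in c(0.05, 0.1, 0.3, 0.5, 0.75, 1)) {
    kept <- colnames(filter_call_rate(gm, thr))
    expect_equal(kept, paste0("L", (0:10)[(0:10) / 10 >= thr]))
  }
})

test_that("MAF filter recomputes folded frequencies at filter time", {
  # 10 samples, 20 alleles; minor count 1 -> MAF 0.05
  gm <- geno_matrix(cbind(c(1L, rep(0L, 9)), rep(1L, 10), rep(0L, 10)),
                    samples = paste0("s", 1:10), loci = c("rare", "het", "mono"))
  expect_equal(colnames(filter_maf(gm, 0.025)), c("rare", "het"))
  expect_equal(colnames(filter_maf(gm, 0.1)), "het")
  expect_identical(colnames(filter_maf(gm, 0)), colnames(gm))
})

test_that("LD pruning is greedy and leaves no violating retained pair", {
  g1 <- c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L)
  gm <- geno_matrix(cbind(g1, g1, c(0L, 0L, 1L, 1L, 2L, 2L, 0L, 0L)),
                    samples = paste0("s", 1:8), loci = c("a", "b", "c"))
  pruned <- ld_prune(gm, 0.8)
  expect_equal(colnames(pruned), c("a", "c"))

  set.seed(7)
  for (rep in 1:5) {
    gm <- hwe_panel(12, runif(5, 0.2, 0.5))
    # make some columns correlated
    gm[, 3] <- gm[, 1]
    out <- ld_prune(gm, 0.8)
    r2 <- suppressWarnings(cor(unclass(out), use = "pairwise.complete.obs"))^2
    r2[is.na(r2)] <- 0
    diag(r2) <- 0
    expect_lte(max(r2), 0.8)  # brute-force pairwise oracle
    # every dropped locus violated the bound with some retained earlier locus
    dropped <- setdiff(colnames(gm), colnames(out))
    for (d in dropped) {
      r2d <- suppressWarnings(
        cor(unclass(gm)[, d], unclass(out), use = "pairwise.complete.obs"))^2
      expect_gt(max(r2d, na.rm = TRUE), 0.8)
    }
  }
})

test_that("first-SNP selection keeps the lowest-position SNP per tag", {
  gm <- hwe_panel(6, rep(0.3, 4), ids = paste0("s", 1:6))
  colnames(gm) <- c("snpA", "snpB", "snpC", "snpD")
  cat <- locus_catalog(colnames(gm), length_bp = 100,
                       pos = c(500L, 120L, 130L, 40L),
                       tag_id = c("t1", "t1", "t2", "t2"))
  expect_equal(colnames(first_snp_per_locus(gm, cat)), c("snpB", "snpD"))
})

test_that("the composed filter pipeline is idempotent", {
  set.seed(12)
  gm <- hwe_panel(20, runif(60, 0.01, 0.5))
  gm[sample(length(gm), 80)] <- NA
  cat <- locus_catalog(colnames(gm), length_bp = 143)
  once <- filter_panel(gm, cat, 0.9, 0.025, 0.8)
  twice <- filter_panel(once$geno, once$catalog, 0.9, 0.025, 0.8)
  expect_identical(unclass(twice$geno), unclass(once$geno))
  expect_true(all(once$catalog$maf <= 0.5))
})

test_that("TSV round trips preserve panels, catalogs and sample tables", {
  set.seed(3)
  gm <- hwe_panel(4, runif(6, .1, .5))
  gm[1, 2] <- NA
  f <- withr::local_tempfile(fileext = ".tsv")
  write_geno_tsv(gm, f)
  expect_identical(unclass(read_geno_tsv(f)), unclass(gm))

  f <- allele_freqs(gm)
  cat <- locus_catalog(colnames(gm), length_bp = 143, maf = pmin(f, 1 - f),
                       callable_bp = 6e6)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_locus_catalog(cat, f2)
  back <- read_locus_catalog(f2)
  expect_equal(back$locus_id, cat$locus_id)
  expect_equal(attr(back, "callable_bp"), 6e6)
})
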