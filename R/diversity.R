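#' Per-individual heterozygosity rate
#'
#' The number of heterozygous genotypes per megabase of callable sequence.
#' The denominator is, per sample, the summed sequenced length of the loci
#' with a non-missing call in that sample (so missing data does not deflate
#' the rate); with `denominator = "catalog"` the full catalog length is used
#' for every sample instead. When the catalog carries a `callable_bp`
#' attribute (a total that includes monomorphic sequence not represented by
#' panel SNPs), that total is used, scaled per sample by its call rate.
#'
#' @param gm a [geno_matrix()].
#' @param cat a [locus_catalog()] providing `length_bp` for every locus of
#'   `gm` (or a `callable_bp` attribute).
#' @param denominator `"per_sample"` (default) or `"catalog"`.
#' @return A data.frame with columns `sample_id`, `n_het`, `callable_bp`,
#'   `het_snps_per_mb`.
#' @export
heterozygosity_rate <- function(gm, cat, denominator = c("per_sample", "catalog")) {
  denominator <- match.arg(denominator)
  cat <- subset_catalog(cat, colnames(gm))
  n_het <- rowSums(gm == 1L, na.rm = TRUE)
  called <- !is.na(unclass(gm))
  total_bp <- attr(cat, "callable_bp")
  if (!is.null(total_bp)) {
    callable <- if (denominator == "per_sample")
      total_bp * rowMeans(called) else rep(total_bp, nrow(gm))
  } else {
    if (any(is.na(cat$length_bp)))
      stop("catalog lacks locus lengths and has no callable_bp attribute")
    callable <- if (denominator == "per_sample")
      as.vector(called %*% cat$length_bp) else rep(sum(cat$length_bp), nrow(gm))
  }
  if (any(callable <= 0))
    stop("zero callable length for sample(s): ",
         paste(rownames(gm)[callable <= 0], collapse = ", "))
  data.frame(sample_id = rownames(gm), n_het = n_het, callable_bp = callable,
             het_snps_per_mb = 1e6 * n_het / callable,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Moment estimator of individual inbreeding
#'
#' The excess-homozygosity estimator based on observed versus expected
#' homozygous genotype counts:
#' `F = (O_hom - E_hom) / (L_called - E_hom)` with
#' `E_hom = sum over called loci of (1 - 2 p (1 - p))`. With
#' `small_sample = TRUE` the heterozygosity term `2p(1-p)` is multiplied by
#' the finite-sample factor `2n/(2n - 1)` (n = called samples at the locus),
#' the correction used by common SNP tools.
#'
#' @param gm a [geno_matrix()].
#' @param freqs per-locus allele frequencies from [allele_freqs()] on the
#'   same panel.
#' @param small_sample apply the `2n/(2n-1)` correction (default `FALSE`).
#' @return Named numeric vector of F per sample; `NA` where all called loci
#'   are monomorphic (undefined).
#' @export
inbreeding_moment <- function(gm, freqs = allele_freqs(gm), small_sample = FALSE) {
  stopifnot(length(freqs) == ncol(gm))
  ok <- !is.na(freqs)
  m <- unclass(gm)[, ok, drop = FALSE]
  p <- freqs[ok]
  het_exp <- 2 * p * (1 - p)
  if (small_sample) {
    n <- colSums(!is.na(m))
    het_exp <- het_exp * ifelse(n > 0, 2 * n / (2 * n - 1), NA_real_)
  }
  called <- !is.na(m)
  L <- rowSums(called)
  e_hom <- as.vector(called %*% (1 - het_exp))
  o_hom <- rowSums(m != 1L, na.rm = TRUE)
  denom <- L - e_hom
  out <- ifelse(abs(denom) < .Machine$double.eps^0.5, NA_real_,
                (o_hom - e_hom) / denom)
  names(out) <- rownames(gm)
  out
}

#' Maximum-likelihood estimator of individual inbreeding
#'
#' Maximizes the per-individual genotype likelihood under the
#' inbreeding-coefficient model
#' `P(hom minor) = F p + (1-F) p^2`, `P(het) = (1-F) 2 p (1-p)`,
#' `P(hom major) = F (1-p) + (1-F)(1-p)^2`,
#' over `F` in `[0, 1]` by bounded scalar optimization (tolerance 1e-6).
#' Monomorphic and missing loci are skipped.
#'
#' @param g genotype vector for one sample (codes 0/1/2/NA), or a
#'   [geno_matrix()] to estimate all samples.
#' @param freqs per-locus allele frequencies.
#' @return Estimated F in `[0, 1]` (named vector for a matrix input);
#'   `NA` where no polymorphic called loci exist.
#' @export
inbreeding_ml <- function(g, freqs) {
  if (is.matrix(g)) {
    m <- unclass(g)
    out <- vapply(seq_len(nrow(m)), function(i) inbreeding_ml(m[i, ], freqs),
                  numeric(1))
    names(out) <- rownames(m)
    return(out)
  }
  stopifnot(length(g) == length(freqs))
  use <- !is.na(g) & !is.na(freqs) & freqs > 0 & freqs < 1
  if (!any(use)) return(NA_real_)
  g <- g[use]; p <- freqs[use]
  n2 <- sum(g == 2); n1 <- sum(g == 1); n0 <- sum(g == 0)
  ll <- function(f) {
    pr2 <- f * p + (1 - f) * p^2
    pr1 <- (1 - f) * 2 * p * (1 - p)
    pr0 <- f * (1 - p) + (1 - f) * (1 - p)^2
    sum(log(pmax(ifelse(g == 2, pr2, ifelse(g == 1, pr1, pr0)),
                 .Machine$double.xmin)))
  }
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- c(0, opt$maximum, 1)
  vals <- vapply(cand, ll, numeric(1))
  cand[which.max(vals)]
}

#' Per-individual diversity summary
#'
#' Combines heterozygosity rate with the moment and maximum-likelihood
#' inbreeding estimators into one record per sample, the analysis-ready
#' diversity table of a panel.
#'
#' @inheritParams heterozygosity_rate
#' @param freqs allele frequencies (default: computed from `gm`).
#' @return A data.frame with columns `sample_id`, `n_het`, `callable_bp`,
#'   `het_snps_per_mb`, `f_moment`, `f_ml`.
#' @export
diversity_table <- function(gm, cat, freqs = allele_freqs(gm),
                            denominator = "per_sample") {
  out <- heterozygosity_rate(gm, cat, denominator)
  out$f_moment <- unname(inbreeding_moment(gm, freqs))
  out$f_ml <- unname(inbreeding_ml(gm, freqs))
  out
}
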