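#' Per-locus minor allele frequencies
#'
#' Frequency of the minor-coded allele at each locus, computed from
#' non-missing calls only: `freq = dosage sum / (2 * n called)`. Loci with
#' zero called genotypes get `NA`.
#'
#' @param gm a [geno_matrix()].
#' @return Named numeric vector of frequencies, one per locus.
#' @export
allele_freqs <- function(gm) {
  f <- colMeans(gm, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  f
}

#' Filter loci by call rate
#'
#' Retains exactly the loci whose fraction of non-missing calls is at least
#' `min_called_fraction` (boundary included). Sample order is unchanged.
#'
#' @param gm a [geno_matrix()].
#' @param min_called_fraction required fraction of called samples, in (0, 1].
#' @return The filtered [geno_matrix()]; possibly with zero loci.
#' @export
filter_call_rate <- function(gm, min_called_fraction = 0.9) {
  stopifnot(min_called_fraction > 0, min_called_fraction <= 1)
  keep <- colMeans(!is.na(gm)) >= min_called_fraction
  gm[, keep, drop = FALSE]
}

#' Filter loci by minor allele frequency
#'
#' Retains loci whose panel MAF (recomputed from non-missing calls at filter
#' time, folded to `min(f, 1 - f)`) is at least `min_maf`. Loci with no
#' called genotypes are dropped unless `min_maf` is 0.
#'
#' @param gm a [geno_matrix()].
#' @param min_maf minimum minor allele frequency, in `[0, 0.5]`.
#' @return The filtered [geno_matrix()].
#' @export
filter_maf <- function(gm, min_maf = 0.025) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  if (min_maf == 0) return(gm)
  f <- allele_freqs(gm)
  maf <- pmin(f, 1 - f)
  keep <- !is.na(maf) & maf >= min_maf
  gm[, keep, drop = FALSE]
}

#' Keep the first SNP of each sequenced locus
#'
#' ddRAD tags often carry several SNPs; panels for relatedness analysis keep
#' a single SNP per tag to approximate independence. For every group of panel
#' loci sharing a `tag_id` in the catalog, the SNP with the lowest position
#' is kept (ties broken by input order); loci without a tag are kept as is.
#'
#' @param gm a [geno_matrix()].
#' @param cat a [locus_catalog()] with `tag_id` (and ideally `pos`) filled in.
#' @return The filtered [geno_matrix()].
#' @export
first_snp_per_locus <- function(gm, cat) {
  cat <- subset_catalog(cat, colnames(gm))
  tag <- cat$tag_id
  if (all(is.na(tag))) return(gm)
  pos <- ifelse(is.na(cat$pos), seq_len(ncol(gm)), cat$pos)
  keep <- rep(TRUE, ncol(gm))
  for (t in unique(tag[!is.na(tag)])) {
    idx <- which(!is.na(tag) & tag == t)
    if (length(idx) > 1L) {
      first <- idx[which.min(pos[idx])]
      keep[setdiff(idx, first)] <- FALSE
    }
  }
  gm[, keep, drop = FALSE]
}

#' Prune loci in linkage disequilibrium
#'
#' Greedy order-preserving scan: loci are visited in panel order and a locus
#' is dropped when its squared Pearson correlation of genotype dosages
#' (pairwise-complete observations) with any previously retained locus within
#' the window exceeds `r2_max`. In the result, every retained within-window
#' pair has r^2 <= `r2_max`. Monomorphic-in-common loci (undefined
#' correlation) are treated as uncorrelated.
#'
#' @param gm a [geno_matrix()].
#' @param r2_max squared-correlation cutoff in (0, 1]; pairs strictly above
#'   it are in violation.
#' @param window compare only loci at most `window` positions apart in panel
#'   order; default `Inf` compares all pairs.
#' @return The pruned [geno_matrix()].
#' @export
ld_prune <- function(gm, r2_max = 0.8, window = Inf) {
  stopifnot(r2_max > 0, r2_max <= 1)
  L <- ncol(gm)
  if (L < 2L) return(gm)
  r2 <- suppressWarnings(stats::cor(unclass(gm),
                                    use = "pairwise.complete.obs"))^2
  r2[is.na(r2)] <- 0
  keep <- logical(L)
  kept_idx <- integer(0)
  for (j in seq_len(L)) {
    prev <- kept_idx[j - kept_idx <= window]
    if (length(prev) == 0L || all(r2[prev, j] <= r2_max)) {
      keep[j] <- TRUE
      kept_idx <- c(kept_idx, j)
    }
  }
  gm[, keep, drop = FALSE]
}

#' Apply the full SNP-panel filter pipeline
#'
#' Composes the panel filters in the standard order: call rate, one SNP per
#' sequenced locus, minor allele frequency, LD pruning. MAF is recomputed on
#' the current panel at each stage. The composed pipeline is idempotent.
#'
#' @param gm a [geno_matrix()].
#' @param cat a [locus_catalog()]; updated to the retained loci with fresh
#'   MAF values.
#' @param min_called_fraction call-rate threshold (default 0.9).
#' @param min_maf MAF threshold (default 0.025).
#' @param r2_max LD pruning cutoff (default 0.8); `NULL` to skip pruning.
#' @param window LD window, see [ld_prune()].
#' @return A list with filtered `geno` and `catalog`.
#' @export
filter_panel <- function(gm, cat, min_called_fraction = 0.9, min_maf = 0.025,
                         r2_max = 0.8, window = Inf) {
  gm <- filter_call_rate(gm, min_called_fraction)
  gm <- first_snp_per_locus(gm, cat)
  gm <- filter_maf(gm, min_maf)
  if (!is.null(r2_max)) gm <- ld_prune(gm, r2_max, window)
  out_cat <- subset_catalog(cat, colnames(gm))
  out_cat$maf <- unname(pmin(allele_freqs(gm), 1 - allele_freqs(gm)))
  list(geno = gm, catalog = out_cat)
}
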