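#' Shared-locus genotype counts for a pair of samples
#'
#' The sufficient statistics of the allele-frequency-free robust kinship
#' estimator, computed over loci called in both samples only: each sample's
#' heterozygous-locus count, the jointly heterozygous count, the
#' opposite-homozygote count (one sample 0, the other 2), and the number of
#' shared called loci.
#'
#' @param gi,gj genotype vectors (codes 0/1/2/NA) over the same locus order.
#' @return A list of class `pair_counts` with elements `n_het_i`, `n_het_j`,
#'   `n_het_both`, `n_opp_hom`, `l_shared`.
#' @export
pair_counts <- function(gi, gj) {
  stopifnot(length(gi) == length(gj))
  use <- !is.na(gi) & !is.na(gj)
  a <- gi[use]; b <- gj[use]
  out <- list(n_het_i = sum(a == 1L),
              n_het_j = sum(b == 1L),
              n_het_both = sum(a == 1L & b == 1L),
              n_opp_hom = sum((a == 0L & b == 2L) | (a == 2L & b == 0L)),
              l_shared = length(a))
  class(out) <- "pair_counts"
  out
}

#' Robust counting kinship estimator for one pair
#'
#' The allele-frequency-free within-pair kinship estimate, robust to
#' population structure because it uses only the two samples' genotypes.
#' With `m = min(n_het_i, n_het_j)`:
#' `phi = (n_het_both - 2 n_opp_hom) / (2 m) + 1/2 - (n_het_i + n_het_j) / (4 m)`.
#' Two identical genotype vectors give `phi = 1/2` (relatedness 1), the
#' replicate-sample criterion. When neither sample has a heterozygous call
#' on the shared loci the estimator is undefined and `NA` is returned.
#'
#' @param pc a [pair_counts()] object.
#' @return Kinship estimate `phi` (relatedness is `2 * phi`), or `NA`.
#' @export
king_robust_kinship <- function(pc) {
  m <- min(pc$n_het_i, pc$n_het_j)
  if (m == 0L) return(NA_real_)
  (pc$n_het_both - 2 * pc$n_opp_hom) / (2 * m) + 0.5 -
    (pc$n_het_i + pc$n_het_j) / (4 * m)
}

#' Pairwise relatedness estimates for a panel
#'
#' Fits the chosen pairwise relatedness estimator to every unordered pair of
#' samples in a panel and returns a long-format table of estimates, a classed
#' object with `print`, `summary` and `as.matrix` methods.
#'
#' Two estimators are available. `"king"` is the robust counting estimator
#' ([king_robust_kinship()]): allele-frequency-free, each pair's estimate
#' depends only on that pair's genotypes. `"dyadml"` is the
#' nine-condensed-identity-state maximum-likelihood estimator
#' ([dyad_ml()]): it uses panel allele frequencies and models inbreeding
#' explicitly, and can attach locus-bootstrap confidence intervals.
#'
#' @param gm a [geno_matrix()] with at least 2 samples.
#' @param estimator `"king"` or `"dyadml"`.
#' @param freqs allele frequencies for `"dyadml"`; default computed from the
#'   full panel (the frequencies of the given set of samples).
#' @param ci for `"dyadml"`: attach 95% locus-bootstrap confidence intervals.
#' @param n_boot bootstrap replicates for the CI (default 100).
#' @param seed integer seed controlling the bootstrap.
#' @param ... passed to [dyad_ml()] (e.g. `tol`, `max_iter`).
#' @return A data.frame of class `kin_estimates` with columns `sample_i`,
#'   `sample_j`, `estimator`, `n_loci`, `kinship`, `relatedness`, and for
#'   `"dyadml"` also `delta1..delta9`, `f_i`, `f_j`, `loglik`, and (with
#'   `ci = TRUE`) `ci_low`, `ci_high`.
#' @examples
#' gm <- geno_matrix(rbind(a = c(1, 1, 2, 0, 1, 2),
#'                         b = c(1, 0, 2, 0, 2, 1),
#'                         c = c(1, 1, 2, 0, 1, 2)))
#' kinship(gm)   # c is a duplicate of a: relatedness 1
#' @export
kinship <- function(gm, estimator = c("king", "dyadml"), freqs = NULL,
                    ci = FALSE, n_boot = 100L, seed = NULL, ...) {
  estimator <- match.arg(estimator)
  n <- nrow(gm)
  if (n < 2L) stop("need at least two samples")
  ids <- rownames(gm)
  pairs <- utils::combn(n, 2L)
  if (estimator == "king") {
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      pc <- pair_counts(gm[i, ], gm[j, ])
      phi <- king_robust_kinship(pc)
      data.frame(sample_i = ids[i], sample_j = ids[j], estimator = "king",
                 n_loci = pc$l_shared, kinship = phi, relatedness = 2 * phi,
                 stringsAsFactors = FALSE)
    })
  } else {
    if (is.null(freqs)) freqs <- allele_freqs(gm)
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      fit <- dyad_ml(gm[i, ], gm[j, ], freqs, ...)
      row <- data.frame(sample_i = ids[i], sample_j = ids[j],
                        estimator = "dyadml", n_loci = fit$n_loci,
                        kinship = fit$r / 2, relatedness = fit$r,
                        stringsAsFactors = FALSE)
      row[paste0("delta", 1:9)] <- as.list(fit$delta)
      row$f_i <- fit$f_i; row$f_j <- fit$f_j; row$loglik <- fit$loglik
      if (ci) {
        bs <- bootstrap_ci(gm[i, ], gm[j, ], freqs, n_boot = n_boot,
                           seed = if (is.null(seed)) NULL else seed + k, ...)
        row$ci_low <- bs$ci[1]; row$ci_high <- bs$ci[2]
      }
      row
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "samples") <- ids
  class(out) <- c("kin_estimates", class(out))
  out
}

#' @export
print.kin_estimates <- function(x, ...) {
  cat(sprintf("Pairwise relatedness estimates (%s): %d pairs, %d samples\n",
              x$estimator[1], nrow(x), length(attr(x, "samples"))))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more pairs\n", sep = "")
  invisible(x)
}

#' @export
summary.kin_estimates <- function(object, ...) {
  cat(sprintf("Estimator: %s; pairs: %d\n", object$estimator[1], nrow(object)))
  print(summary(object$relatedness))
  invisible(object)
}

#' @export
as.matrix.kin_estimates <- function(x, value = "relatedness", ...) {
  ids <- attr(x, "samples")
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  i <- match(x$sample_i, ids); j <- match(x$sample_j, ids)
  m[cbind(i, j)] <- x[[value]]
  m[cbind(j, i)] <- x[[value]]
  m
}

#' Cluster samples into putative individuals by a relatedness threshold
#'
#' Joins every pair of samples whose relatedness strictly exceeds the
#' threshold and returns the connected components of the resulting graph as
#' putative physical individuals (transitive closure; replicate groups are
#' equivalence classes). Singletons are included. Pairs with missing
#' estimates are treated as below the threshold.
#'
#' @param est a `kin_estimates` table from [kinship()].
#' @param threshold relatedness threshold (default 0.8, strict `>`).
#' @return A data.frame with columns `sample_id`, `cluster_id`.
#' @export
detect_duplicates <- function(est, threshold = 0.8) {
  ids <- attr(est, "samples")
  hit <- !is.na(est$relatedness) & est$relatedness > threshold
  g <- igraph::graph_from_data_frame(
    est[hit, c("sample_i", "sample_j"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  data.frame(sample_id = names(comp),
             cluster_id = paste0("ind_", unname(comp)),
             stringsAsFactors = FALSE)
}
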