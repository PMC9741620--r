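# The nine condensed identity states of a dyad are encoded as partitions of
# the four alleles (i1, i2, j1, j2) into identity-by-descent classes; for
# states whose two detailed partitions are indistinguishable at unordered
# genotype level (S3, S5), one representative partition suffices. Genotype
# probabilities are derived from these partitions at run time rather than
# transcribed from a published table.
jacquard_partitions <- list(
  S1 = list(c(1, 2, 3, 4)),
  S2 = list(c(1, 2), c(3, 4)),
  S3 = list(c(1, 2, 3), 4),
  S4 = list(c(1, 2), 3, 4),
  S5 = list(c(1, 3, 4), 2),
  S6 = list(c(3, 4), 1, 2),
  S7 = list(c(1, 3), c(2, 4)),
  S8 = list(c(1, 3), 2, 4),
  S9 = list(1, 2, 3, 4)
)

# For each state and each of the 9 ordered genotype pairs (gi, gj) in
# {0,1,2}^2, the probability as a function of the minor allele frequency p.
# Returns a 9 x 9 x length(p) array; pair index is 3*gi + gj + 1.
state_pair_probs <- function(p) {
  p <- as.numeric(p)
  out <- array(0, dim = c(9L, 9L, length(p)),
               dimnames = list(names(jacquard_partitions),
                               paste0("g", rep(0:2, each = 3), rep(0:2, 3)),
                               NULL))
  for (k in seq_along(jacquard_partitions)) {
    blocks <- jacquard_partitions[[k]]
    nb <- length(blocks)
    # each IBD block independently carries the minor allele with prob p
    for (mask in 0:(2^nb - 1L)) {
      minor <- as.logical(bitwAnd(mask, 2L^(seq_len(nb) - 1L)))
      allele <- integer(4)
      for (b in seq_len(nb)) allele[blocks[[b]]] <- as.integer(minor[b])
      gi <- allele[1] + allele[2]
      gj <- allele[3] + allele[4]
      pr <- rep(1, length(p))
      for (b in seq_len(nb)) pr <- pr * if (minor[b]) p else (1 - p)
      idx <- 3L * gi + gj + 1L
      out[k, idx, ] <- out[k, idx, ] + pr
    }
  }
  out
}

#' Genotype-pair probabilities under the nine condensed identity states
#'
#' For a biallelic locus with minor allele frequency `p`, the probability of
#' every ordered genotype pair of a dyad conditional on each of the nine
#' condensed identity-by-descent states S1..S9. Each state's distribution
#' sums to 1. The table is derived from allele-identity partitions: alleles
#' in the same IBD class are a single independent draw of the minor allele
#' with probability `p`.
#'
#' @param p minor allele frequency, strictly inside (0, 1).
#' @return A 9 x 9 matrix (states x ordered genotype pairs); columns are
#'   labelled `g<gi><gj>` with dosages 0/1/2.
#' @export
state_genotype_probs <- function(p) {
  stopifnot(length(p) == 1L)
  if (is.na(p) || p <= 0 || p >= 1)
    stop("degenerate locus: p must lie strictly in (0, 1)")
  state_pair_probs(p)[, , 1]
}

# 9 x L matrix of P(gi_l, gj_l | S_k, p_l) for loci called in both samples
# with informative frequencies; attr "kept" marks the loci used.
dyad_state_lik <- function(gi, gj, freqs) {
  use <- !is.na(gi) & !is.na(gj) & !is.na(freqs) & freqs > 0 & freqs < 1
  if (!any(use)) return(NULL)
  probs <- state_pair_probs(freqs[use])
  idx <- 3L * gi[use] + gj[use] + 1L
  L <- sum(use)
  m <- matrix(0, 9L, L)
  for (k in 1:9) m[k, ] <- probs[cbind(k, idx, seq_len(L))]
  attr(m, "kept") <- which(use)
  m
}

#' Log-likelihood of a dyad under given Jacquard coefficients
#'
#' Sum over loci (called in both samples, excluding fixed frequencies) of the
#' log of the nine-state mixture probability of the observed genotype pair.
#'
#' @param gi,gj genotype vectors over the same loci.
#' @param freqs per-locus minor allele frequencies.
#' @param delta numeric vector of the nine condensed-state probabilities,
#'   non-negative, summing to 1.
#' @return The log-likelihood; errors if every locus is skipped.
#' @export
dyad_loglik <- function(gi, gj, freqs, delta) {
  stopifnot(length(delta) == 9L, all(delta >= -1e-12),
            abs(sum(delta) - 1) < 1e-6)
  m <- dyad_state_lik(gi, gj, freqs)
  if (is.null(m)) stop("no usable loci: likelihood undefined")
  sum(log(pmax(as.vector(crossprod(m, delta)), .Machine$double.xmin)))
}

delta_to_r <- function(delta) {
  2 * (delta[1] + (delta[3] + delta[5] + delta[7]) / 2 + delta[8] / 4)
}

em_fit <- function(m, tol = 1e-6, max_iter = 2000L, start = rep(1 / 9, 9)) {
  delta <- start / sum(start)
  L <- ncol(m)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- m * delta                     # 9 x L responsibilities (unnormalized)
    s <- pmax(colSums(w), .Machine$double.xmin)
    ll <- sum(log(s))
    ll_trace <- c(ll_trace, ll)
    delta <- rowSums(w / rep(s, each = 9L)) / L
    if (ll - ll_old < tol && it > 1L) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(delta = delta, loglik = ll, trace = ll_trace, converged = converged,
       iterations = length(ll_trace))
}

#' Nine-state maximum-likelihood dyadic relatedness estimator
#'
#' Fits the nine condensed identity-state probabilities Delta1..Delta9 of a
#' dyad by maximum likelihood over the 8-simplex, using
#' expectation-maximization from a uniform start (per-locus state
#' responsibilities; the update is the mean responsibility), stopping when
#' the log-likelihood gain drops below `tol` or after `max_iter` iterations.
#' Relatedness and the two implied inbreeding coefficients follow from the
#' fitted coefficients:
#' `r = 2 (D1 + (D3 + D5 + D7)/2 + D8/4)`, `F_i = D1 + D2 + D3 + D4`,
#' `F_j = D1 + D2 + D5 + D6`. The estimator uses the allele frequencies of
#' the supplied sample set; under population structure and inbreeding `r`
#' may exceed 1 and is deliberately not truncated.
#'
#' @param gi,gj genotype vectors over the same loci (at least one shared
#'   polymorphic called locus).
#' @param freqs per-locus minor allele frequencies; fixed loci (p of 0 or 1)
#'   are skipped and counted.
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 2000).
#' @param multi_start also run 5 seeded Dirichlet(1) starts and keep the best
#'   optimum (for flat likelihoods; default `FALSE`).
#' @param seed seed for the multi-start draws.
#' @return An object of class `dyad_ml`: a list with `delta`, `r`, `f_i`,
#'   `f_j`, `loglik`, `loglik_trace`, `converged`, `iterations`, `n_loci`
#'   (loci used), `n_skipped` (uninformative or missing).
#' @examples
#' p <- rep(0.5, 200)
#' g <- rbinom(200, 2, 0.5)
#' fit <- dyad_ml(g, g, p)   # identical genotypes: r close to 1
#' fit$r
#' @export
dyad_ml <- function(gi, gj, freqs, tol = 1e-6, max_iter = 2000L,
                    multi_start = FALSE, seed = NULL) {
  stopifnot(length(gi) == length(gj), length(gi) == length(freqs))
  m <- dyad_state_lik(gi, gj, freqs)
  if (is.null(m))
    stop("no shared polymorphic called loci: dyad inestimable")
  fit <- em_fit(m, tol = tol, max_iter = max_iter)
  if (multi_start) {
    if (!is.null(seed)) set.seed(seed)
    for (s in seq_len(5L)) {
      start <- -log(stats::runif(9))
      alt <- em_fit(m, tol = tol, max_iter = max_iter, start = start)
      if (alt$loglik > fit$loglik) fit <- alt
    }
  }
  delta <- fit$delta
  names(delta) <- paste0("D", 1:9)
  out <- list(delta = delta,
              r = delta_to_r(delta),
              f_i = sum(delta[1:4]),
              f_j = sum(delta[c(1, 2, 5, 6)]),
              loglik = fit$loglik,
              loglik_trace = fit$trace,
              converged = fit$converged,
              iterations = fit$iterations,
              n_loci = ncol(m),
              n_skipped = length(gi) - ncol(m))
  class(out) <- "dyad_ml"
  out
}

#' @export
print.dyad_ml <- function(x, ...) {
  cat("Nine-state ML dyad estimate\n")
  cat(sprintf("  relatedness r = %.4f  (F_i = %.4f, F_j = %.4f)\n",
              x$r, x$f_i, x$f_j))
  cat(sprintf("  loci used: %d (skipped %d); logLik %.3f; EM %s in %d iterations\n",
              x$n_loci, x$n_skipped, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat("  Delta:", paste(sprintf("%.3f", x$delta), collapse = " "), "\n")
  invisible(x)
}

#' Locus-bootstrap confidence interval for dyadic relatedness
#'
#' Resamples the dyad's shared called loci with replacement, re-estimates
#' relatedness per replicate with [dyad_ml()], and returns the 2.5 and 97.5
#' percentiles (95% percentile interval). Deterministic given `seed`.
#' Replicates in which the dyad is inestimable are dropped and counted; if
#' more than half are dropped the interval is flagged unreliable.
#'
#' @inheritParams dyad_ml
#' @param n_boot number of bootstrap replicates (default 100, minimum 2).
#' @param seed integer seed.
#' @param zero_tol relatedness values within `zero_tol` of 0 are treated as
#'   exact zeros (EM approaches the simplex boundary geometrically and stops
#'   at the log-likelihood tolerance, leaving boundary solutions at tiny
#'   positive values; `1e-4` is orders of magnitude below any relatedness
#'   the panel could resolve). This makes intervals for unrelated dyads
#'   overlap 0 as they should.
#' @return A list with `ci` (length-2 vector), `r_boot` (replicate
#'   estimates), `n_dropped`, `reliable`.
#' @export
bootstrap_ci <- function(gi, gj, freqs, n_boot = 100L, seed = NULL,
                         tol = 1e-6, max_iter = 2000L, zero_tol = 1e-4) {
  stopifnot(n_boot >= 2L)
  if (!is.null(seed)) set.seed(seed)
  use <- which(!is.na(gi) & !is.na(gj) & !is.na(freqs) & freqs > 0 & freqs < 1)
  if (length(use) == 0L) stop("no usable loci for the bootstrap")
  r_boot <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample(use, length(use), replace = TRUE)
    fit <- tryCatch(dyad_ml(gi[idx], gj[idx], freqs[idx], tol = tol,
                            max_iter = max_iter),
                    error = function(e) NULL)
    if (!is.null(fit)) r_boot[b] <- fit$r
  }
  r_boot[!is.na(r_boot) & abs(r_boot) < zero_tol] <- 0
  ok <- !is.na(r_boot)
  list(ci = unname(stats::quantile(r_boot[ok], c(0.025, 0.975), na.rm = TRUE)),
       r_boot = r_boot,
       n_dropped = sum(!ok),
       reliable = mean(!ok) <= 0.5)
}

#' Keep estimates whose confidence interval excludes zero
#'
#' Retains the rows of a `kin_estimates` table whose bootstrap CI lower bound
#' is strictly greater than 0 (an interval touching 0 counts as overlapping).
#'
#' @param est a `kin_estimates` table carrying `ci_low`.
#' @return The filtered table, same class.
#' @export
filter_significant <- function(est) {
  if (is.null(est$ci_low)) stop("estimates carry no confidence intervals")
  out <- est[!is.na(est$ci_low) & est$ci_low > 0, , drop = FALSE]
  attr(out, "samples") <- attr(est, "samples")
  class(out) <- class(est)
  out
}
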