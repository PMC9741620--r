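#' Configuration for the synthetic panel generator
#'
#' Describes a structured low-diversity population: number of
#' subpopulations, a fixation-index-like divergence parameter for the
#' Balding-Nichols allele-frequency model, the ancestral minor-allele
#' frequency spectrum, panel size, locus lengths and a total callable
#' length (monomorphic sequence is carried by this constant rather than
#' materialized as loci), per-subpopulation sample counts and founder
#' inbreeding ranges, and a replicate-sample specification.
#'
#' @param n_subpops number of subpopulations.
#' @param fst divergence parameter in `[0, 1)`.
#' @param maf_spectrum list: `list(dist = "uniform", min =, max =)` or
#'   `list(dist = "beta", shape1 =, shape2 =)` for the ancestral minor-allele
#'   frequency (folded into `(0, 0.5]` bounds by construction of `min`/`max`).
#' @param n_loci number of polymorphic panel loci.
#' @param locus_length_bp sequenced length per locus.
#' @param callable_bp total callable length in bp (>= `n_loci *
#'   locus_length_bp`), the heterozygosity-rate denominator.
#' @param subpop_sizes integer vector (length `n_subpops`) of sample counts.
#' @param founder_f_range list (length `n_subpops`) of `c(min, max)`
#'   inbreeding ranges; each individual's F is drawn uniformly in its
#'   subpopulation's range.
#' @param replicates list: `n` (replicate pairs), `missingness`, `error`
#'   (per-call genotyping error rate).
#' @param seed default seed for [simulate_panel()].
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subpops = 2, fst = 0.1,
                         maf_spectrum = list(dist = "uniform", min = 0.05, max = 0.5),
                         n_loci = 1000, locus_length_bp = 143,
                         callable_bp = NULL,
                         subpop_sizes = rep(10, n_subpops),
                         founder_f_range = rep(list(c(0, 0)), n_subpops),
                         replicates = list(n = 0, missingness = 0.1, error = 0),
                         seed = 1L) {
  stopifnot(n_subpops >= 1, fst >= 0, fst < 1, n_loci >= 1,
            locus_length_bp > 0,
            length(subpop_sizes) == n_subpops,
            all(subpop_sizes >= 1),
            length(founder_f_range) == n_subpops)
  for (r in founder_f_range)
    stopifnot(length(r) == 2, r[1] >= 0, r[2] <= 1, r[1] <= r[2])
  stopifnot(replicates$missingness >= 0, replicates$missingness <= 1,
            replicates$error >= 0, replicates$error <= 1)
  if (is.null(callable_bp)) callable_bp <- n_loci * locus_length_bp
  stopifnot(callable_bp >= n_loci * locus_length_bp)
  out <- list(n_subpops = n_subpops, fst = fst, maf_spectrum = maf_spectrum,
              n_loci = as.integer(n_loci),
              locus_length_bp = locus_length_bp, callable_bp = callable_bp,
              subpop_sizes = as.integer(subpop_sizes),
              founder_f_range = founder_f_range,
              replicates = replicates, seed = as.integer(seed))
  class(out) <- "synth_config"
  out
}

#' Calibrated preset emulating the study panel
#'
#' The default study conditions of the package's experiments: 45 individuals
#' in 4 subpopulations (15/14/12/4), Balding-Nichols divergence 0.10,
#' ancestral MAF uniform on (0.15, 0.5), 1400 polymorphic loci of 143 bp
#' within a 6 Mb callable total, per-subpopulation founder inbreeding ranges
#' spanning 0.02 to 0.78 (the fourth, smallest subpopulation is the highly
#' inbred, isolated one), and 23 replicate pairs with 10% missingness and no
#' genotyping error. Under these settings expected per-individual
#' heterozygosity rates span roughly 20-90 SNPs/Mb.
#'
#' @param seed default simulation seed.
#' @return A [synth_config()].
#' @export
lowdiv_preset <- function(seed = 1L) {
  synth_config(
    n_subpops = 4,
    fst = 0.10,
    maf_spectrum = list(dist = "uniform", min = 0.15, max = 0.5),
    n_loci = 1400,
    locus_length_bp = 143,
    callable_bp = 6e6,
    subpop_sizes = c(15L, 14L, 12L, 4L),
    founder_f_range = list(c(0.02, 0.15), c(0.05, 0.20),
                           c(0.15, 0.40), c(0.65, 0.78)),
    replicates = list(n = 23, missingness = 0.1, error = 0),
    seed = seed)
}

draw_ancestral <- function(spec, n) {
  p <- switch(spec$dist,
              uniform = stats::runif(n, spec$min, spec$max),
              beta = stats::rbeta(n, spec$shape1, spec$shape2),
              stop("unknown MAF spectrum: ", spec$dist))
  pmin(pmax(p, 1e-3), 1 - 1e-3)
}

#' Simulate a structured low-diversity SNP panel
#'
#' Ancestral minor-allele frequencies are drawn from the configured
#' spectrum; subpopulation frequencies follow the Balding-Nichols beta model
#' `p_s ~ Beta(p (1-fst)/fst, (1-p)(1-fst)/fst)`; individual genotypes are
#' drawn with within-individual allelic correlation F (the individual's
#' inbreeding): `P(hom minor) = F p + (1-F) p^2`, `P(het) = (1-F) 2 p (1-p)`,
#' `P(hom major) = F (1-p) + (1-F)(1-p)^2`. Frequencies falling outside
#' (0, 1) are capped. Deterministic given the seed. The returned truth
#' record stores every latent value needed to recompute expected summary
#' statistics in closed form.
#'
#' @param cfg a [synth_config()].
#' @param seed overrides `cfg$seed`.
#' @return A list with `geno` ([geno_matrix()]), `catalog`
#'   ([locus_catalog()] with the `callable_bp` attribute), `samples`
#'   ([sample_table()]), and `truth` (list: `ancestral_p`, `subpop_freqs`
#'   matrix loci x subpops, `subpop`, `f` per individual).
#' @export
simulate_panel <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(seed)
  L <- cfg$n_loci
  p_anc <- draw_ancestral(cfg$maf_spectrum, L)
  sub_f <- matrix(NA_real_, L, cfg$n_subpops)
  for (s in seq_len(cfg$n_subpops)) {
    sub_f[, s] <- if (cfg$fst == 0) p_anc else
      stats::rbeta(L, p_anc * (1 - cfg$fst) / cfg$fst,
                   (1 - p_anc) * (1 - cfg$fst) / cfg$fst)
  }
  sub_f <- pmin(pmax(sub_f, 1e-4), 1 - 1e-4)

  n <- sum(cfg$subpop_sizes)
  subpop <- rep(seq_len(cfg$n_subpops), cfg$subpop_sizes)
  f_ind <- numeric(n)
  for (s in seq_len(cfg$n_subpops)) {
    rng <- cfg$founder_f_range[[s]]
    f_ind[subpop == s] <- stats::runif(cfg$subpop_sizes[s], rng[1], rng[2])
  }
  ids <- sprintf("ind%02d", seq_len(n))

  calls <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    p <- sub_f[, subpop[i]]
    f <- f_ind[i]
    pr2 <- f * p + (1 - f) * p^2
    pr1 <- (1 - f) * 2 * p * (1 - p)
    u <- stats::runif(L)
    calls[i, ] <- ifelse(u < pr2, 2L, ifelse(u < pr2 + pr1, 1L, 0L))
  }
  loci <- sprintf("L%04d", seq_len(L))
  gm <- geno_matrix(calls, samples = ids, loci = loci)
  f_obs <- allele_freqs(gm)
  cat <- locus_catalog(loci, length_bp = cfg$locus_length_bp,
                       maf = pmin(f_obs, 1 - f_obs),
                       callable_bp = cfg$callable_bp)
  st <- sample_table(ids,
                     locality = paste0("subpop", subpop),
                     sex = sample(c("F", "M"), n, replace = TRUE))
  list(geno = gm, catalog = cat, samples = st,
       truth = list(ancestral_p = p_anc, subpop_freqs = sub_f,
                    subpop = subpop, f = stats::setNames(f_ind, ids),
                    config = cfg, seed = seed))
}

#' Append replicate samples to a panel
#'
#' Each replicate copies a distinct source sample, masks calls to missing at
#' the configured missingness rate, and flips genotypes at the genotyping
#' error rate (symmetric single-step: 0 and 2 move to 1; 1 moves to 0 or 2
#' with equal probability). The sample table records the shared replicate
#' group for source and copy.
#'
#' @param gm a [geno_matrix()].
#' @param samples the panel's [sample_table()].
#' @param spec list with `n`, `missingness`, `error`; see [synth_config()].
#' @param sources optional character vector of source sample ids (default:
#'   the first `n` samples).
#' @param seed integer seed.
#' @return A list with the augmented `geno` and `samples`; replicate ids are
#'   `<source>_rep`.
#' @export
add_replicates <- function(gm, samples, spec = list(n = 1, missingness = 0.1, error = 0),
                           sources = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_rep <- spec$n
  if (n_rep == 0) return(list(geno = gm, samples = samples))
  if (is.null(sources)) sources <- rownames(gm)[seq_len(n_rep)]
  stopifnot(length(sources) == n_rep, !anyDuplicated(sources),
            all(sources %in% rownames(gm)))
  L <- ncol(gm)
  reps <- unclass(gm)[sources, , drop = FALSE]
  if (spec$error > 0) {
    flip <- matrix(stats::runif(n_rep * L) < spec$error, n_rep, L) & !is.na(reps)
    up <- matrix(stats::runif(n_rep * L) < 0.5, n_rep, L)
    new <- ifelse(reps == 1L, ifelse(up, 2L, 0L), 1L)
    reps[flip] <- new[flip]
  }
  if (spec$missingness > 0) {
    mask <- matrix(stats::runif(n_rep * L) < spec$missingness, n_rep, L)
    reps[mask] <- NA_integer_
  }
  rep_ids <- paste0(sources, "_rep")
  out_gm <- geno_matrix(rbind(unclass(gm), reps),
                        samples = c(rownames(gm), rep_ids),
                        loci = colnames(gm))
  st <- samples
  st2 <- rbind(as.data.frame(unclass(st), stringsAsFactors = FALSE),
               data.frame(sample_id = rep_ids,
                          locality = st$locality[match(sources, st$sample_id)],
                          sex = st$sex[match(sources, st$sample_id)],
                          replicate_group = sources,
                          stringsAsFactors = FALSE))
  st2$replicate_group[match(sources, st2$sample_id)] <- sources
  class(st2) <- c("sample_table", class(st2))
  list(geno = out_gm, samples = st2)
}

#' Expected heterozygosity rates from a truth record
#'
#' Closed-form expectation of each individual's heterozygosity rate (and its
#' sampling SD) from the latent subpopulation frequencies and inbreeding
#' values: expected het count `sum_l 2 p_sl (1 - p_sl) (1 - F_i)` over the
#' callable length.
#'
#' @param truth the `truth` element of [simulate_panel()] output.
#' @return A data.frame with `sample_id`, `expected_het_per_mb`,
#'   `sd_het_per_mb`.
#' @export
expected_het_rates <- function(truth) {
  cfg <- truth$config
  ids <- names(truth$f)
  h <- vapply(seq_along(ids), function(i) {
    p <- truth$subpop_freqs[, truth$subpop[i]]
    sum(2 * p * (1 - p)) * (1 - truth$f[i])
  }, numeric(1))
  v <- vapply(seq_along(ids), function(i) {
    p <- truth$subpop_freqs[, truth$subpop[i]]
    hl <- 2 * p * (1 - p) * (1 - truth$f[i])
    sum(hl * (1 - hl))
  }, numeric(1))
  data.frame(sample_id = ids,
             expected_het_per_mb = 1e6 * h / cfg$callable_bp,
             sd_het_per_mb = 1e6 * sqrt(v) / cfg$callable_bp,
             row.names = NULL, stringsAsFactors = FALSE)
}
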