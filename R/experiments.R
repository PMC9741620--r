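#' Build the individualization test panel
#'
#' Constructs the synthetic analogue of the duplicate-sample identification
#' experiment: a calibrated structured panel; a trio of highly inbred,
#' closely related full siblings born inside a small, strongly drifted deme
#' of the most inbred subpopulation; one extra replicate of the first
#' sibling; and replicate copies (with missingness) of distinct source
#' samples. The deme's divergence sets the trio's panel-referenced
#' inbreeding (its default reproduces the study's most inbred locality,
#' mean F about 0.78), and the siblings' parents are themselves inbred
#' within the deme — together these make the trio nearly identical with
#' respect to panel allele frequencies while remaining ordinary full
#' siblings with respect to their own deme. The truth lists the replicate
#' pairs and the five different-individual comparisons among the inbred
#' relatives (three sibling pairs plus the two pairs involving the
#' duplicated sibling's second sample).
#'
#' @param cfg a [synth_config()]; default [lowdiv_preset()].
#' @param n_inbred number of inbred full siblings (default 3).
#' @param deme_divergence additional Balding-Nichols drift of the trio's
#'   deme relative to its subpopulation (default 0.78; this is what the
#'   panel-referenced inbreeding of the trio converges to).
#' @param parent_f within-deme inbreeding of the siblings' parents
#'   (default 0.3).
#' @param seed integer seed.
#' @return A list with `geno`, `catalog`, `samples`, `replicate_pairs`
#'   (2-column matrix), `inbred_pairs` (2-column matrix), `truth`.
#' @export
simulate_individualization_panel <- function(cfg = lowdiv_preset(),
                                             n_inbred = 3,
                                             deme_divergence = 0.78,
                                             parent_f = 0.3,
                                             seed = cfg$seed) {
  pan <- simulate_panel(cfg, seed = seed)
  set.seed(seed + 1000003L)
  L <- cfg$n_loci
  # a small isolated deme, further drifted from the most inbred subpopulation
  p_sub <- pan$truth$subpop_freqs[, cfg$n_subpops]
  th <- deme_divergence
  p <- stats::rbeta(L, p_sub * (1 - th) / th, (1 - p_sub) * (1 - th) / th)
  p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
  draw_ind <- function(f) {
    pr2 <- f * p + (1 - f) * p^2
    pr1 <- (1 - f) * 2 * p * (1 - p)
    u <- stats::runif(L)
    ifelse(u < pr2, 2L, ifelse(u < pr2 + pr1, 1L, 0L))
  }
  parents <- geno_matrix(rbind(par1 = draw_ind(parent_f),
                               par2 = draw_ind(parent_f)),
                         loci = colnames(pan$geno))
  sib_ids <- sprintf("inbred%02d", seq_len(n_inbred))
  ped <- pedigree(c("par1", "par2", sib_ids),
                  sire = c(NA, NA, rep("par1", n_inbred)),
                  dam = c(NA, NA, rep("par2", n_inbred)))
  crossed <- cross_genotypes(ped, parents, seed = seed + 2000003L)
  sibs <- unclass(crossed)[sib_ids, , drop = FALSE]

  gm <- geno_matrix(rbind(unclass(pan$geno), sibs),
                    samples = c(rownames(pan$geno), sib_ids),
                    loci = colnames(pan$geno))
  st <- rbind(as.data.frame(unclass(pan$samples), stringsAsFactors = FALSE),
              data.frame(sample_id = sib_ids,
                         locality = paste0("subpop", cfg$n_subpops),
                         sex = "unknown", replicate_group = NA_character_,
                         stringsAsFactors = FALSE))
  class(st) <- c("sample_table", class(st))

  # replicate sources: the first sibling plus ordinary panel samples
  n_rep <- cfg$replicates$n
  sources <- c(sib_ids[1],
               rownames(pan$geno)[seq_len(n_rep - 1L)])
  aug <- add_replicates(gm, st, spec = cfg$replicates, sources = sources,
                        seed = seed + 3000017L)

  replicate_pairs <- cbind(sources, paste0(sources, "_rep"))
  sib_pairs <- t(utils::combn(sib_ids, 2))
  dup_pairs <- if (n_inbred > 1)
    cbind(paste0(sib_ids[1], "_rep"), sib_ids[-1]) else NULL
  inbred_pairs <- rbind(sib_pairs, dup_pairs)

  list(geno = aug$geno, catalog = pan$catalog, samples = aug$samples,
       replicate_pairs = replicate_pairs, inbred_pairs = inbred_pairs,
       truth = pan$truth)
}

estimate_pairs <- function(gm, pairs, estimator, freqs = NULL, ...) {
  if (estimator == "dyadml" && is.null(freqs)) freqs <- allele_freqs(gm)
  vapply(seq_len(nrow(pairs)), function(k) {
    gi <- gm[pairs[k, 1], ]; gj <- gm[pairs[k, 2], ]
    if (estimator == "king") {
      2 * king_robust_kinship(pair_counts(gi, gj))
    } else {
      tryCatch(dyad_ml(gi, gj, freqs, ...)$r, error = function(e) NA_real_)
    }
  }, numeric(1))
}

#' Duplicate-sample individualization experiment
#'
#' For each MAF filter setting and each estimator: computes relatedness for
#' every known replicate pair and every known inbred-relative
#' (different-individual) pair, then scores individualization against the
#' threshold — a replicate pair is detected when `r > threshold`; an
#' inbred-relative pair is correctly separated when `r <= threshold`.
#'
#' @param panel output of [simulate_individualization_panel()] (or any list
#'   with `geno`, `replicate_pairs`, `inbred_pairs`).
#' @param estimators subset of `c("king", "dyadml")`.
#' @param threshold relatedness threshold (default 0.8).
#' @param maf_grid MAF filter values to test (default
#'   `c(0.025, 0.1, 0.2, 0.3)`).
#' @param ... passed to [dyad_ml()].
#' @return An object of class `individualization_report`: a list with
#'   `results` (data.frame: maf, estimator, replicates_detected,
#'   replicates_total, inbred_separated, inbred_total), `values`
#'   (per-pair relatedness, long form), `threshold`.
#' @export
run_individualization <- function(panel, estimators = c("king", "dyadml"),
                                  threshold = 0.8,
                                  maf_grid = c(0.025, 0.1, 0.2, 0.3), ...) {
  if (is.null(panel$replicate_pairs) || nrow(panel$replicate_pairs) == 0)
    stop("panel contains no replicate pairs")
  res <- list(); vals <- list()
  for (maf in maf_grid) {
    gm <- filter_maf(panel$geno, maf)
    freqs <- allele_freqs(gm)
    for (est in estimators) {
      r_rep <- estimate_pairs(gm, panel$replicate_pairs, est, freqs, ...)
      r_inb <- if (!is.null(panel$inbred_pairs))
        estimate_pairs(gm, panel$inbred_pairs, est, freqs, ...) else numeric(0)
      res[[length(res) + 1L]] <- data.frame(
        maf = maf, estimator = est,
        n_loci = ncol(gm),
        replicates_detected = sum(!is.na(r_rep) & r_rep > threshold),
        replicates_total = length(r_rep),
        inbred_separated = sum(!is.na(r_inb) & r_inb <= threshold),
        inbred_total = length(r_inb),
        stringsAsFactors = FALSE)
      vals[[length(vals) + 1L]] <- data.frame(
        maf = maf, estimator = est,
        category = rep(c("replicate", "different_individual"),
                       c(length(r_rep), length(r_inb))),
        pair = c(paste(panel$replicate_pairs[, 1], panel$replicate_pairs[, 2],
                       sep = ":"),
                 if (length(r_inb)) paste(panel$inbred_pairs[, 1],
                                          panel$inbred_pairs[, 2], sep = ":")),
        relatedness = c(r_rep, r_inb),
        stringsAsFactors = FALSE)
    }
  }
  out <- list(results = do.call(rbind, res),
              values = do.call(rbind, vals),
              threshold = threshold)
  class(out) <- "individualization_report"
  out
}

#' @export
print.individualization_report <- function(x, ...) {
  cat(sprintf("Individualization at relatedness threshold %.2f\n", x$threshold))
  df <- x$results
  df$replicates <- sprintf("%d/%d", df$replicates_detected, df$replicates_total)
  df$inbred_separated <- sprintf("%d/%d", df$inbred_separated, df$inbred_total)
  print.data.frame(df[, c("maf", "estimator", "n_loci", "replicates",
                          "inbred_separated")], row.names = FALSE)
  invisible(x)
}

# Founder-source generators for the recovery experiments. Each returns a
# function(n, n_loci, subpop) -> geno_matrix drawn fresh per simulation;
# `subpop` assigns each individual to one of two subpopulations (ignored by
# the homogeneous source).
founder_source <- function(type = c("hwe", "structured"),
                           maf_range = c(0.05, 0.5), fst = 0.15,
                           founder_f_range = c(0.0175, 0.4783)) {
  type <- match.arg(type)
  function(n, n_loci, subpop = rep_len(1:2, n)) {
    p <- stats::runif(n_loci, maf_range[1], maf_range[2])
    if (type == "hwe") {
      calls <- matrix(stats::rbinom(n * n_loci, 2, rep(p, each = n)),
                      n, n_loci)
      return(geno_matrix(calls, samples = sprintf("fnd%02d", seq_len(n))))
    }
    sub_f <- cbind(stats::rbeta(n_loci, p * (1 - fst) / fst,
                                (1 - p) * (1 - fst) / fst),
                   stats::rbeta(n_loci, p * (1 - fst) / fst,
                                (1 - p) * (1 - fst) / fst))
    sub_f <- pmin(pmax(sub_f, 1e-4), 1 - 1e-4)
    f_ind <- stats::runif(n, founder_f_range[1], founder_f_range[2])
    calls <- matrix(NA_integer_, n, n_loci)
    for (i in seq_len(n)) {
      ps <- sub_f[, subpop[i]]
      pr2 <- f_ind[i] * ps + (1 - f_ind[i]) * ps^2
      pr1 <- (1 - f_ind[i]) * 2 * ps * (1 - ps)
      u <- stats::runif(n_loci)
      calls[i, ] <- ifelse(u < pr2, 2L, ifelse(u < pr2 + pr1, 1L, 0L))
    }
    geno_matrix(calls, samples = sprintf("fnd%02d", seq_len(n)))
  }
}

#' Relatedness-recovery experiment on simulated pedigrees
#'
#' Per simulation replicate: founder genotypes are drawn fresh, crossed
#' through every canonical relationship pedigree, and each labelled dyad's
#' relatedness is estimated with both estimators. Allele frequencies for the
#' likelihood estimator come from the combined simulated dataset of the
#' replicate (all pedigree members), i.e. the frequencies of the given set
#' of samples. Results are aggregated into per-category means and SDs
#' against the theoretical values.
#'
#' @param pedigrees named list of pedigrees with `dyad` and `theoretical_r`
#'   attributes; default [relationship_pedigrees()].
#' @param founders `"hwe"` for homogeneous non-inbred Hardy-Weinberg
#'   founders, `"structured"` for two diverged subpopulations with founder
#'   inbreeding drawn from 0.0175-0.4783, or a `function(n_founders,
#'   n_loci)` returning a [geno_matrix()].
#' @param n_sims simulation replicates (default 100).
#' @param n_loci loci per simulated panel (default 1400).
#' @param n_background reference samples drawn from the same source and
#'   included (with all pedigree members) in the allele-frequency
#'   computation for the likelihood estimator, mirroring a study panel the
#'   simulated families are embedded in (default 45).
#' @param seed integer seed.
#' @param estimators subset of `c("king", "dyadml")`.
#' @param ... passed to [dyad_ml()].
#' @return An object of class `recovery_report`: list with `table`
#'   (category, theoretical, per-estimator mean and sd), `raw` (per-sim
#'   estimates), `n_sims`.
#' @export
run_relatedness_recovery <- function(pedigrees = relationship_pedigrees(),
                                     founders = "hwe", n_sims = 100,
                                     n_loci = 1400, n_background = 45,
                                     seed = 1L,
                                     estimators = c("king", "dyadml"), ...) {
  gen <- if (is.function(founders)) founders else founder_source(founders)
  categories <- names(pedigrees)
  n_fnd <- vapply(pedigrees, function(p) sum(is.na(p$sire)), integer(1))
  raw <- list()
  for (sim in seq_len(n_sims)) {
    set.seed(seed + sim)
    # disjoint founders for all pedigrees plus a background reference panel,
    # drawn from one population per replicate; under structure each family's
    # founders share a subpopulation (families live in one locality) while
    # the background panel spans both
    subpop <- c(rep(rep_len(1:2, length(categories)), n_fnd),
                rep_len(1:2, n_background))
    pool <- gen(sum(n_fnd) + n_background, n_loci, subpop)
    fnd <- pool[seq_len(sum(n_fnd)), , drop = FALSE]
    offset <- 0L
    members <- list()
    for (cat in categories) {
      ped <- pedigrees[[cat]]
      ids <- ped$id[is.na(ped$sire)]
      map <- stats::setNames(rownames(fnd)[offset + seq_along(ids)], ids)
      offset <- offset + length(ids)
      gm <- cross_genotypes(ped, fnd, founder_map = map)
      rownames(gm) <- paste(cat, rownames(gm), sep = ".")
      members[[cat]] <- unclass(gm)
    }
    all_gm <- geno_matrix(do.call(rbind, members))
    bg <- unclass(pool)[-seq_len(sum(n_fnd)), , drop = FALSE]
    rownames(bg) <- paste0("bg.", seq_len(nrow(bg)))
    # frequencies of the given sample set: all simulated families embedded
    # in the background panel
    freqs <- allele_freqs(geno_matrix(rbind(unclass(all_gm), bg)))
    for (cat in categories) {
      dyad <- paste(cat, attr(pedigrees[[cat]], "dyad"), sep = ".")
      for (est in estimators) {
        r <- estimate_pairs(all_gm, matrix(dyad, 1), est, freqs, ...)
        raw[[length(raw) + 1L]] <- data.frame(
          sim = sim, category = cat, estimator = est, relatedness = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  raw <- do.call(rbind, raw)
  tab <- do.call(rbind, lapply(categories, function(cat) {
    row <- data.frame(category = cat,
                      theoretical = attr(pedigrees[[cat]], "theoretical_r"),
                      stringsAsFactors = FALSE)
    for (est in estimators) {
      r <- raw$relatedness[raw$category == cat & raw$estimator == est]
      row[[paste0(est, "_mean")]] <- mean(r, na.rm = TRUE)
      row[[paste0(est, "_sd")]] <- stats::sd(r, na.rm = TRUE)
    }
    row
  }))
  out <- list(table = tab, raw = raw, n_sims = n_sims, what = "relatedness")
  class(out) <- "recovery_report"
  out
}

#' Inbreeding-recovery experiment on simulated pedigrees
#'
#' Per simulation replicate: founders are drawn fresh and crossed through
#' every inbred-offspring pedigree; each target offspring's inbreeding
#' coefficient is estimated by the maximum-likelihood and moment estimators
#' (frequencies from the replicate's combined simulated dataset), and
#' aggregated against the theoretical values.
#'
#' @param pedigrees named list of pedigrees with `target` and
#'   `theoretical_f` attributes; default [inbreeding_pedigrees()].
#' @inheritParams run_relatedness_recovery
#' @return A `recovery_report` with `ml_mean`/`ml_sd` and
#'   `moment_mean`/`moment_sd` columns.
#' @export
run_inbreeding_recovery <- function(pedigrees = inbreeding_pedigrees(),
                                    founders = "hwe", n_sims = 100,
                                    n_loci = 1400, n_background = 45,
                                    seed = 1L) {
  gen <- if (is.function(founders)) founders else founder_source(founders)
  categories <- names(pedigrees)
  n_fnd <- vapply(pedigrees, function(p) sum(is.na(p$sire)), integer(1))
  raw <- list()
  for (sim in seq_len(n_sims)) {
    set.seed(seed + sim)
    subpop <- c(rep(rep_len(1:2, length(categories)), n_fnd),
                rep_len(1:2, n_background))
    pool <- gen(sum(n_fnd) + n_background, n_loci, subpop)
    fnd <- pool[seq_len(sum(n_fnd)), , drop = FALSE]
    offset <- 0L
    members <- list()
    for (cat in categories) {
      ped <- pedigrees[[cat]]
      ids <- ped$id[is.na(ped$sire)]
      map <- stats::setNames(rownames(fnd)[offset + seq_along(ids)], ids)
      offset <- offset + length(ids)
      gm <- cross_genotypes(ped, fnd, founder_map = map)
      rownames(gm) <- paste(cat, rownames(gm), sep = ".")
      members[[cat]] <- unclass(gm)
    }
    bg <- unclass(pool)[-seq_len(sum(n_fnd)), , drop = FALSE]
    rownames(bg) <- paste0("bg.", seq_len(nrow(bg)))
    all_gm <- geno_matrix(do.call(rbind, members))
    freqs <- allele_freqs(geno_matrix(rbind(unclass(all_gm), bg)))
    f_mom <- inbreeding_moment(geno_matrix(rbind(unclass(all_gm), bg)), freqs)
    for (cat in categories) {
      target <- paste(cat, attr(pedigrees[[cat]], "target"), sep = ".")
      raw[[length(raw) + 1L]] <- data.frame(
        sim = sim, category = cat,
        f_ml = inbreeding_ml(all_gm[target, ], freqs),
        f_moment = unname(f_mom[target]),
        stringsAsFactors = FALSE)
    }
  }
  raw <- do.call(rbind, raw)
  tab <- do.call(rbind, lapply(categories, function(cat) {
    r <- raw[raw$category == cat, ]
    data.frame(category = cat,
               theoretical = attr(pedigrees[[cat]], "theoretical_f"),
               ml_mean = mean(r$f_ml, na.rm = TRUE),
               ml_sd = stats::sd(r$f_ml, na.rm = TRUE),
               moment_mean = mean(r$f_moment, na.rm = TRUE),
               moment_sd = stats::sd(r$f_moment, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  out <- list(table = tab, raw = raw, n_sims = n_sims, what = "inbreeding")
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("%s recovery over %d simulations per pedigree\n",
              x$what, x$n_sims))
  print.data.frame(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
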