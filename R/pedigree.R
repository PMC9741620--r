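#' Pedigree with founder inbreeding
#'
#' A directed acyclic parentage structure. Founders have no recorded parents
#' and may carry a known inbreeding coefficient; every non-founder has
#' exactly two recorded parents. Use `"0"`, `""` or `NA` for an absent
#' parent in file input.
#'
#' @param id member identifiers (unique).
#' @param sire,dam parent identifiers, `NA` for founders (both or neither
#'   must be given).
#' @param founder_f founder inbreeding coefficients in `[0, 1]`
#'   (ignored for non-founders; default 0).
#' @param cohort optional cohort labels.
#' @return A data.frame of class `pedigree`, ordered topologically
#'   (parents before offspring).
#' @examples
#' ped <- pedigree(c("p1", "p2", "kid"), sire = c(NA, NA, "p1"),
#'                 dam = c(NA, NA, "p2"))
#' theoretical_kinship(ped, "p1", "kid")   # 0.25
#' @export
pedigree <- function(id, sire = NA, dam = NA, founder_f = 0, cohort = NA) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("pedigree member ids must be unique")
  clean <- function(x) {
    x <- as.character(x)
    x[x %in% c("", "0")] <- NA_character_
    x
  }
  sire <- rep_len(clean(sire), length(id))
  dam <- rep_len(clean(dam), length(id))
  founder_f <- rep_len(as.numeric(founder_f), length(id))
  cohort <- rep_len(as.character(cohort), length(id))
  if (any(xor(is.na(sire), is.na(dam))))
    stop("each member must have either two recorded parents or none")
  miss <- setdiff(c(sire, dam), c(id, NA))
  if (length(miss)) stop("unknown parent id(s): ", paste(miss, collapse = ", "))
  founder <- is.na(sire)
  if (any(founder_f[founder] < 0 | founder_f[founder] > 1))
    stop("founder inbreeding must lie in [0, 1]")
  founder_f[!founder] <- NA_real_

  # topological order; also proves acyclicity
  ord <- integer(0)
  placed <- logical(length(id))
  names(placed) <- id
  repeat {
    ready <- which(!placed &
                     (is.na(sire) | placed[sire]) &
                     (is.na(dam) | placed[dam]))
    if (!length(ready)) break
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  if (!all(placed)) stop("parentage graph contains a cycle")

  out <- data.frame(id = id, sire = sire, dam = dam, founder_f = founder_f,
                    cohort = cohort, stringsAsFactors = FALSE)[ord, ]
  rownames(out) <- NULL
  class(out) <- c("pedigree", class(out))
  out
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- sum(is.na(x$sire))
  cat(sprintf("pedigree: %d members (%d founders)\n", nrow(x), nf))
  print.data.frame(x)
  invisible(x)
}

#' Read a pedigree from TSV
#'
#' Columns: `id`, `sire`, `dam` (use `0` or empty for unknown), and
#' optionally `founder_f`, `cohort`.
#' @param path file path.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  pedigree(df$id, df$sire, df$dam,
           founder_f = if ("founder_f" %in% names(df))
             ifelse(is.na(df$founder_f), 0, df$founder_f) else 0,
           cohort = if ("cohort" %in% names(df)) df$cohort else NA)
}

# Full kinship matrix by the standard tabular recursion:
# phi(x, x) = (1 + F_x)/2 with F_x = phi(sire_x, dam_x) (founders: assigned F);
# phi(x, y) = (phi(sire_x, y) + phi(dam_x, y))/2 taking for x the member that
# is later in topological order; founders are mutually unrelated.
kinship_table <- function(ped) {
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  for (x in seq_len(n)) {
    if (is.na(si[x])) {
      phi[x, x] <- (1 + ped$founder_f[x]) / 2
    } else {
      phi[x, x] <- (1 + phi[si[x], di[x]]) / 2
      for (y in seq_len(x - 1L)) {
        v <- (phi[si[x], y] + phi[di[x], y]) / 2
        phi[x, y] <- v
        phi[y, x] <- v
      }
    }
  }
  phi
}

#' Exact pedigree kinship
#'
#' The theoretical kinship coefficient between two pedigree members by the
#' classical recursion (founders mutually unrelated; founder inbreeding
#' enters through the self-kinship `phi(x, x) = (1 + F_x)/2`). Relatedness
#' is twice the kinship.
#'
#' @param ped a [pedigree()].
#' @param a,b member ids.
#' @return Kinship `phi` as a number.
#' @export
theoretical_kinship <- function(ped, a, b) {
  if (!all(c(a, b) %in% ped$id))
    stop("unknown pedigree member: ", paste(setdiff(c(a, b), ped$id), collapse = ", "))
  kinship_table(ped)[a, b]
}

#' Exact pedigree inbreeding
#'
#' The theoretical inbreeding coefficient of a member: the kinship of its
#' parents, or the assigned founder value for founders.
#'
#' @inheritParams theoretical_kinship
#' @param a member id.
#' @return Inbreeding coefficient `F`.
#' @export
theoretical_inbreeding <- function(ped, a) {
  if (!a %in% ped$id) stop("unknown pedigree member: ", a)
  row <- match(a, ped$id)
  if (is.na(ped$sire[row])) return(ped$founder_f[row])
  kinship_table(ped)[ped$sire[row], ped$dam[row]]
}

#' Cross founder genotypes through a pedigree
#'
#' Gene-dropping of observed genotypes: every non-founder's genotype at each
#' locus is formed by drawing one allele uniformly from each parent's two
#' alleles, independently across loci (unlinked), in topological generation
#' order. A missing parental call makes the offspring call missing at that
#' locus. Deterministic given `seed`. Founder inbreeding is not re-imposed:
#' the founders' realized genotypes already embody it.
#'
#' @param ped a [pedigree()].
#' @param founder_gm a [geno_matrix()] whose row names cover every founder id
#'   (or see `founder_map`).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param founder_map optional named character vector mapping founder ids to
#'   row names of `founder_gm`.
#' @return A [geno_matrix()] with one row per pedigree member.
#' @export
cross_genotypes <- function(ped, founder_gm, seed = NULL, founder_map = NULL) {
  if (!is.null(seed)) set.seed(seed)
  founders <- ped$id[is.na(ped$sire)]
  src <- if (is.null(founder_map)) stats::setNames(founders, founders)
         else founder_map
  if (!all(founders %in% names(src)) || !all(src[founders] %in% rownames(founder_gm)))
    stop("founder genotypes missing for: ",
         paste(setdiff(founders, names(src)[src %in% rownames(founder_gm)]),
               collapse = ", "))
  L <- ncol(founder_gm)
  out <- matrix(NA_integer_, nrow(ped), L,
                dimnames = list(ped$id, colnames(founder_gm)))
  out[founders, ] <- unclass(founder_gm)[src[founders], , drop = FALSE]
  transmit <- function(g) {
    # one allele drawn uniformly from the parent's two: minor with prob g/2
    a <- ifelse(is.na(g), NA_integer_,
                as.integer(stats::runif(length(g)) < g / 2))
    a
  }
  for (x in seq_len(nrow(ped))) {
    if (is.na(ped$sire[x])) next
    out[x, ] <- transmit(out[ped$sire[x], ]) + transmit(out[ped$dam[x], ])
  }
  geno_matrix(out)
}

#' Gene-drop Monte Carlo kinship
#'
#' Drops unique founder-allele labels through the pedigree and estimates the
#' kinship of two members as the probability that one allele sampled from
#' each is identical by descent. Founder inbreeding is honoured: a founder's
#' second allele copies its first with probability `founder_f`. This is the
#' simulation oracle for [theoretical_kinship()].
#'
#' @param ped a [pedigree()].
#' @param a,b member ids.
#' @param n_reps Monte Carlo replicates (default 10000).
#' @param seed integer seed.
#' @return A list with `kinship` (estimate), `se` (binomial-style standard
#'   error of the mean IBD indicator), `n_reps`.
#' @export
gene_drop_ibd <- function(ped, a, b, n_reps = 10000L, seed = NULL) {
  stopifnot(n_reps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (!all(c(a, b) %in% ped$id))
    stop("unknown pedigree member: ", paste(setdiff(c(a, b), ped$id), collapse = ", "))
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  A1 <- matrix(0L, n, n_reps)
  A2 <- matrix(0L, n, n_reps)
  next_label <- 1L
  for (x in seq_len(n)) {
    if (is.na(si[x])) {
      A1[x, ] <- next_label
      copy <- stats::runif(n_reps) < ped$founder_f[x]
      A2[x, ] <- ifelse(copy, next_label, next_label + 1L)
      next_label <- next_label + 2L
    } else {
      pick1 <- stats::runif(n_reps) < 0.5
      A1[x, ] <- ifelse(pick1, A1[si[x], ], A2[si[x], ])
      pick2 <- stats::runif(n_reps) < 0.5
      A2[x, ] <- ifelse(pick2, A1[di[x], ], A2[di[x], ])
    }
  }
  ia <- match(a, ped$id); ib <- match(b, ped$id)
  # average IBD indicator over the four allele pairings
  ibd <- (
    (A1[ia, ] == A1[ib, ]) + (A1[ia, ] == A2[ib, ]) +
    (A2[ia, ] == A1[ib, ]) + (A2[ia, ] == A2[ib, ])) / 4
  list(kinship = mean(ibd), se = stats::sd(ibd) / sqrt(n_reps), n_reps = n_reps)
}

#' Simulate genotypes for a pedigree
#'
#' `simulate` method wrapping [cross_genotypes()]: returns `nsim` independent
#' genotype-crossing realizations of the pedigree from the same founder
#' panel.
#'
#' @param object a [pedigree()].
#' @param nsim number of realizations.
#' @param seed integer seed (replicate `k` uses `seed + k - 1`).
#' @param founder_gm,founder_map see [cross_genotypes()].
#' @param ... unused.
#' @return A list of [geno_matrix()] objects (a single object if `nsim = 1`).
#' @export
simulate.pedigree <- function(object, nsim = 1, seed = NULL, founder_gm,
                              founder_map = NULL, ...) {
  out <- lapply(seq_len(nsim), function(k)
    cross_genotypes(object, founder_gm,
                    seed = if (is.null(seed)) NULL else seed + k - 1L,
                    founder_map = founder_map))
  if (nsim == 1) out[[1]] else out
}
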