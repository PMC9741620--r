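#' Genotype matrix for a biallelic SNP panel
#'
#' A `geno_matrix` is an integer matrix of minor-allele dosages with samples
#' in rows and loci in columns. Every call is 0, 1 or 2 (count of the
#' panel-minor allele) or `NA` for a missing genotype. Row names are sample
#' identifiers and column names locus identifiers; both must be unique.
#'
#' @param calls numeric or integer matrix of genotype codes in `{0, 1, 2, NA}`.
#' @param samples character vector of sample identifiers (defaults to the
#'   row names of `calls`).
#' @param loci character vector of locus identifiers (defaults to the column
#'   names of `calls`).
#' @return An object of class `geno_matrix`.
#' @examples
#' g <- geno_matrix(rbind(a = c(0, 1, 2), b = c(1, 1, NA)),
#'                  loci = c("L1", "L2", "L3"))
#' g
#' @export
geno_matrix <- function(calls, samples = rownames(calls), loci = colnames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(samples))
    samples <- sprintf("S%d", seq_len(nrow(calls)))
  if (is.null(loci))
    loci <- sprintf("L%d", seq_len(ncol(calls)))
  samples <- as.character(samples)
  loci <- as.character(loci)
  if (length(samples) != nrow(calls))
    stop("length of 'samples' does not match nrow(calls)")
  if (length(loci) != ncol(calls))
    stop("length of 'loci' does not match ncol(calls)")
  if (anyDuplicated(samples)) stop("sample identifiers must be unique")
  if (anyDuplicated(loci)) stop("locus identifiers must be unique")
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or NA; found ",
         paste(unique(calls[bad]), collapse = ", "))
  dimnames(calls) <- list(samples, loci)
  class(calls) <- c("geno_matrix", class(calls))
  calls
}

#' @export
`[.geno_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("geno_matrix", class(out))
  out
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d loci\n", nrow(x), ncol(x)))
  miss <- mean(is.na(x))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  n <- min(nrow(x), 6L); m <- min(ncol(x), 8L)
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) cat("  ...\n")
  invisible(x)
}

#' @export
summary.geno_matrix <- function(object, ...) {
  structure(
    list(n_samples = nrow(object), n_loci = ncol(object),
         call_rate = mean(!is.na(object)),
         maf = pmin(allele_freqs(object), 1 - allele_freqs(object))),
    class = "summary.geno_matrix")
}

#' @export
print.summary.geno_matrix <- function(x, ...) {
  cat(sprintf("SNP panel: %d samples, %d loci, call rate %.3f\n",
              x$n_samples, x$n_loci, x$call_rate))
  cat("minor allele frequency:\n")
  print(summary(x$maf))
  invisible(x)
}

#' Locus catalog
#'
#' Per-locus metadata for a SNP panel: the sequenced length of the parent
#' ddRAD locus (the denominator of heterozygosity rates), the panel minor
#' allele frequency, and optional genomic coordinates (1-based, as in VCF).
#' An optional attribute `callable_bp` carries the total callable length of
#' the catalog (including monomorphic sequence not represented by any SNP),
#' used as the heterozygosity-rate denominator when present.
#'
#' @param locus_id character vector of unique locus identifiers.
#' @param length_bp sequenced length of each locus in bp (> 0).
#' @param maf optional minor allele frequency per locus, in `[0, 0.5]`.
#' @param chrom,pos optional chromosome and 1-based position.
#' @param tag_id optional identifier of the parent ddRAD tag, shared by SNPs
#'   that come from the same sequenced locus (used by [first_snp_per_locus()]).
#' @param callable_bp optional total callable length in bp for the whole
#'   catalog; stored as an attribute.
#' @return A `data.frame` of class `locus_catalog`.
#' @export
locus_catalog <- function(locus_id, length_bp, maf = NA_real_, chrom = NA_character_,
                          pos = NA_integer_, tag_id = NA_character_,
                          callable_bp = NULL) {
  locus_id <- as.character(locus_id)
  if (anyDuplicated(locus_id)) stop("locus identifiers must be unique")
  length_bp <- as.numeric(length_bp)
  if (any(!is.na(length_bp) & length_bp <= 0)) stop("locus lengths must be > 0")
  maf <- as.numeric(maf)
  if (any(!is.na(maf) & (maf < 0 | maf > 0.5)))
    stop("MAF must lie in [0, 0.5]")
  out <- data.frame(locus_id = locus_id, length_bp = length_bp, maf = maf,
                    chrom = as.character(chrom), pos = as.integer(pos),
                    tag_id = as.character(tag_id), stringsAsFactors = FALSE)
  if (!is.null(callable_bp)) attr(out, "callable_bp") <- as.numeric(callable_bp)
  class(out) <- c("locus_catalog", class(out))
  out
}

subset_catalog <- function(cat, keep_ids) {
  out <- cat[match(keep_ids, cat$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "callable_bp") <- attr(cat, "callable_bp")
  class(out) <- unique(c("locus_catalog", class(out)))
  out
}

#' Sample table
#'
#' Sample metadata: locality label, sex and replicate group. Samples that are
#' repeated sequencing runs of the same physical individual share a
#' replicate-group identifier; all other samples carry `NA`.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param locality locality label per sample.
#' @param sex one of `"F"`, `"M"`, `"unknown"`.
#' @param replicate_group replicate-group id or `NA`.
#' @return A `data.frame` of class `sample_table`.
#' @export
sample_table <- function(sample_id, locality = NA_character_, sex = "unknown",
                         replicate_group = NA_character_) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("sample identifiers must be unique")
  sex <- as.character(sex)
  if (length(sex) == 1L) sex <- rep(sex, length(sample_id))
  if (!all(sex %in% c("F", "M", "unknown")))
    stop("sex must be 'F', 'M' or 'unknown'")
  out <- data.frame(sample_id = sample_id,
                    locality = as.character(locality),
                    sex = sex,
                    replicate_group = as.character(replicate_group),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_table", class(out))
  out
}

#' Read and write genotype matrices as TSV
#'
#' The TSV layout has samples in rows and loci in columns, a `sample_id`
#' first column, and cells 0/1/2/NA.
#'
#' @param path file path.
#' @return `read_geno_tsv` returns a [geno_matrix()].
#' @export
read_geno_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("genotype TSV must have a sample_id column")
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  geno_matrix(m, samples = df$sample_id)
}

#' @rdname read_geno_tsv
#' @param gm a [geno_matrix()].
#' @export
write_geno_tsv <- function(gm, path) {
  df <- data.frame(sample_id = rownames(gm), unclass(gm),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a locus catalog TSV
#'
#' Expected columns: `locus_id`, `length_bp`, and optionally `maf`, `chrom`,
#' `pos`, `tag_id`. A comment line `# callable_bp=<n>` is honoured.
#' @param path file path.
#' @return A [locus_catalog()].
#' @export
read_locus_catalog <- function(path) {
  first <- readLines(path, n = 1L)
  callable <- NULL
  if (grepl("^#\\s*callable_bp=", first))
    callable <- as.numeric(sub("^#\\s*callable_bp=", "", first))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  locus_catalog(df$locus_id, df$length_bp,
                maf = if ("maf" %in% names(df)) df$maf else NA_real_,
                chrom = if ("chrom" %in% names(df)) df$chrom else NA_character_,
                pos = if ("pos" %in% names(df)) df$pos else NA_integer_,
                tag_id = if ("tag_id" %in% names(df)) df$tag_id else NA_character_,
                callable_bp = callable)
}

#' @rdname read_locus_catalog
#' @param cat a [locus_catalog()].
#' @export
write_locus_catalog <- function(cat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cb <- attr(cat, "callable_bp")
  if (!is.null(cb)) writeLines(sprintf("# callable_bp=%.0f", cb), con)
  utils::write.table(as.data.frame(unclass(cat)), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample table TSV
#'
#' Expected columns: `sample_id` and optionally `locality`, `sex`,
#' `replicate_group`.
#' @param path file path.
#' @return A [sample_table()].
#' @export
read_sample_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sample_table(df$sample_id,
               locality = if ("locality" %in% names(df)) df$locality else NA_character_,
               sex = if ("sex" %in% names(df)) df$sex else "unknown",
               replicate_group = if ("replicate_group" %in% names(df))
                 df$replicate_group else NA_character_)
}
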