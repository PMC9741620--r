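#' Read a genotype panel from VCF
#'
#' Reads the GT field of a VCF 4.x file into a [geno_matrix()], keeping only
#' biallelic SNP sites. Genotypes are re-polarized so that codes count the
#' panel-minor allele (after polarization every locus has MAF <= 0.5);
#' missing genotypes (`./.`) become `NA`. The per-locus MAF in the returned
#' catalog is computed from non-missing calls.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param skip_nonbiallelic if `TRUE` (default) multiallelic or non-SNP sites
#'   are skipped silently; if `FALSE`, their presence is an error.
#' @return A list with elements `geno` ([geno_matrix()]) and
#'   `catalog` ([locus_catalog()]).
#' @seealso [write_vcf()]
#' @export
read_vcf <- function(path, skip_nonbiallelic = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  is_snp <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"]) & !is.na(fix[, "ALT"])
  if (!all(is_snp) && !skip_nonbiallelic)
    stop("VCF contains multiallelic or non-SNP sites")
  if (!any(is_snp)) stop("no biallelic SNP sites found in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(fix[, "ID"], names(gt)))
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]

  # ALT dosage from GT strings; any malformed token is a parse error
  dose <- parse_gt(gt)
  ids <- fix[, "ID"]
  if (all(is.na(ids)) || anyDuplicated(ids[!is.na(ids)]))
    ids <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  dimnames(dose) <- list(ids, colnames(gt))
  gm <- geno_matrix(t(dose))

  # polarize to the minor allele
  f_alt <- colMeans(gm, na.rm = TRUE) / 2
  flip <- !is.na(f_alt) & f_alt > 0.5
  if (any(flip)) gm[, flip] <- 2L - gm[, flip, drop = FALSE]
  maf <- colMeans(gm, na.rm = TRUE) / 2
  maf[is.nan(maf)] <- NA_real_

  cat <- locus_catalog(colnames(gm), length_bp = NA_real_, maf = maf,
                       chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]))
  list(geno = gm, catalog = cat)
}

parse_gt <- function(gt) {
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  code <- vapply(u, function(s) {
    alleles <- strsplit(s, "[/|]")[[1]]
    if (length(alleles) != 2L) stop("malformed GT field: '", s, "'")
    if (any(alleles == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(alleles))
    if (any(is.na(a)) || any(a < 0L | a > 1L))
      stop("malformed or multiallelic GT field: '", s, "'")
    sum(a)
  }, integer(1))
  out <- matrix(code[match(as.vector(gt), u)], nrow = nrow(gt))
  out
}

#' Write a genotype panel to VCF
#'
#' Writes a plain-text VCF 4.2 file with GT-only genotype columns. Loci
#' without genomic coordinates in the catalog are placed on a synthetic
#' contig at consecutive 1-based positions. Because genotype codes count the
#' minor allele, the minor allele is written as ALT, so a read/write
#' round trip preserves genotype codes exactly for panels with MAF <= 0.5.
#'
#' @param gm a [geno_matrix()].
#' @param cat a [locus_catalog()] covering exactly the loci of `gm`
#'   (order may differ); `NULL` for a coordinate-free panel.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, cat = NULL, path) {
  loci <- colnames(gm)
  if (!is.null(cat)) {
    if (!setequal(cat$locus_id, loci))
      stop("locus catalog does not match the panel's locus set")
    cat <- subset_catalog(cat, loci)
    chrom <- ifelse(is.na(cat$chrom), "synthetic_1", cat$chrom)
    pos <- ifelse(is.na(cat$pos), seq_along(loci), cat$pos)
  } else {
    chrom <- rep("synthetic_1", length(loci))
    pos <- seq_along(loci)
  }
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_along(loci), function(j) {
    g <- gm[, j]
    gt <- ifelse(is.na(g), "./.", gt_str[as.character(g)])
    paste(c(chrom[j], pos[j], loci[j], "A", "C", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gm)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}
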