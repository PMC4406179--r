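#' Construct a genotype dosage matrix
#'
#' Container for per-variant effect-allele counts (0/1/2, `NA` for a
#' failed call) across carriers, with variant metadata.  Per-variant call
#' rate, effect-allele frequency and minor allele frequency are computed
#' over non-missing dosages.
#'
#' @param dosages Integer matrix, variants x carriers, values in
#'   `{0, 1, 2, NA}`; rownames are variant ids, colnames carrier ids.
#' @param variants Data frame with columns `snp_id`, `chrom`, `pos`
#'   (1-based), `ref`, `eff`; one row per row of `dosages`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `variants`, `dosages`.
#' @export
genotype_matrix <- function(dosages, variants) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != nrow(variants))
    stop("dosages and variants disagree on the number of variants")
  bad <- !is.na(dosages) & !dosages %in% c(0L, 1L, 2L)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  need <- c("snp_id", "chrom", "pos", "ref", "eff")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variant table missing column(s): ",
                         paste(miss, collapse = ", "))
  rownames(dosages) <- variants$snp_id
  storage.mode(dosages) <- "integer"
  structure(list(variants = as.data.frame(variants, stringsAsFactors = FALSE),
                 dosages = dosages),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "variants x",
      ncol(x$dosages), "carriers\n")
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x A `genotype_matrix`.
#' @export
call_rate <- function(x) {
  rowMeans(!is.na(x$dosages))
}

#' @rdname genotype_matrix
#' @export
effect_allele_freq <- function(x) {
  rowMeans(x$dosages, na.rm = TRUE) / 2
}

#' @rdname genotype_matrix
#' @export
maf <- function(x) {
  eaf <- effect_allele_freq(x)
  pmin(eaf, 1 - eaf)
}

#' Read genotype dosages
#'
#' Two on-disk formats are supported: a dosage TSV (columns `snp_id`,
#' `chrom`, `pos`, `ref`, `eff`, then one column per carrier, values
#' 0/1/2 or `NA`) and VCF 4.x, from which GT genotypes are converted to
#' effect-allele counts with the ALT allele as the effect allele.
#'
#' @param path File path.
#' @param format `"dosage"` or `"vcf"`; guessed from the file extension
#'   by default.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "dosage", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") .read_vcf_dosages(path) else .read_dosage_tsv(path)
}

.read_dosage_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("NA", ""))
  meta_cols <- c("snp_id", "chrom", "pos", "ref", "eff")
  miss <- setdiff(meta_cols, names(d))
  if (length(miss)) stop("dosage file missing column(s): ",
                         paste(miss, collapse = ", "))
  carriers <- setdiff(names(d), meta_cols)
  if (!length(carriers)) stop("dosage file has no carrier columns")
  dos <- as.matrix(d[, carriers, drop = FALSE])
  storage.mode(dos) <- "integer"
  genotype_matrix(dos, d[, meta_cols])
}

.read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  # count ALT alleles; handles phased and unphased diploid calls
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_integer_,
           vapply(strsplit(g, "[/|]"), function(a)
             sum(a == "1"), integer(1)))
  }
  dos <- apply(gt, 2L, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(gt),
                                       dimnames = dimnames(gt))
  fix <- vcfR::getFIX(v)
  variants <- data.frame(snp_id = fix[, "ID"],
                         chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"],
                         eff = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, variants)
}

#' Write a genotype matrix as a dosage TSV
#'
#' Round-trips exactly through [read_genotypes()].
#'
#' @param x A [genotype_matrix()].
#' @param path Output file path.
#' @export
write_dosage_tsv <- function(x, path) {
  out <- cbind(x$variants[, c("snp_id", "chrom", "pos", "ref", "eff")],
               as.data.frame(x$dosages, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align genotype samples to the phenotype carrier order
#'
#' Carriers in the genotype file but absent from the phenotype table are
#' dropped with a warning; a phenotype carrier without genotypes gets a
#' column of missing dosages.  Errors when the overlap is empty.
#'
#' @param x A [genotype_matrix()].
#' @param carrier_ids Character vector, the phenotype carrier order.
#' @return A `genotype_matrix` whose columns match `carrier_ids`.
#' @export
align_genotypes <- function(x, carrier_ids) {
  have <- colnames(x$dosages)
  extra <- setdiff(have, carrier_ids)
  if (length(extra) == length(have))
    stop("no overlap between genotype samples and phenotype carrier_ids")
  if (length(extra))
    warning(length(extra), " genotyped sample(s) absent from phenotypes; dropped")
  idx <- match(carrier_ids, have)
  dos <- x$dosages[, ifelse(is.na(idx), 1L, idx), drop = FALSE]
  dos[, is.na(idx)] <- NA_integer_
  colnames(dos) <- carrier_ids
  genotype_matrix(dos, x$variants)
}
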