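# Small builders shared across test files.

toy_phenotypes <- function() {
  data.frame(
    carrier_id = c("c1", "c2", "c3"),
    family_id = c("f1", "f1", "f2"),
    gene = "BRCA1", stratum = "UK",
    age_bc = c(45, 40, NA), age_oc = c(43, NA, NA),
    age_mastectomy = c(NA, NA, 38), age_last_followup = c(50, 55, 50),
    age_recruitment = c(44, 47, 45),
    ER = c("positive", "negative", NA),
    stringsAsFactors = FALSE)
}

write_phenotype_tsv <- function(d, path = tempfile(fileext = ".tsv")) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  path
}

# minimal but valid VCF with the genotype calls the reader must handle
write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "##contig=<ID=1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
    paste("1", "1000", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", "./.", sep = "\t"),
    paste("1", "2000", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "0|1", "1|1", "0/0", "0/1", sep = "\t")
  ), path)
  path
}

# tiny survival table for likelihood toys (no family structure needed)
toy_survival <- function(t, d, s = NULL) {
  out <- data.frame(t = as.integer(t), d = as.integer(d))
  if (!is.null(s)) out$s <- factor(s)
  out
}

toy_mu <- function(n = 10, rate = 0.02) rep(rate, n)
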