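#' Read biallelic SNPs from a VCF into a genotype matrix
#'
#' Multiallelic records (comma-separated ALT) are excluded and counted.
#' Per-genotype DP is retained when the FORMAT carries it, for use by the
#' discovery depth filter.
#'
#' @param vcf_path path to a VCF 4.x file (plain text or gzipped).
#' @return A [geno_matrix()] with attribute `n_excluded_multiallelic`.
#' @export
read_vcf_biallelic <- function(vcf_path) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (!"FORMAT" %in% colnames(v@gt) || !any(grepl("GT", v@gt[, "FORMAT"])))
    stop("VCF has no GT field")
  alt <- v@fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  n_excl <- sum(multi)
  keep <- which(!multi)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt %in% c("0/0", "0|0")] <- 0L
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt %in% c("1/1", "1|1")] <- 2L
  dp <- NULL
  if (any(grepl("DP", v@gt[, "FORMAT"]))) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    dp <- t(dp[keep, , drop = FALSE])
  }
  ids <- v@fix[keep, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(v@fix[keep, "CHROM"], "_", v@fix[keep, "POS"])[is.na(ids) | ids == "."]
  loci <- data.frame(snp_id = ids,
                     scaffold = v@fix[keep, "CHROM"],
                     pos_bp = as.integer(v@fix[keep, "POS"]),
                     allele_a = v@fix[keep, "REF"],
                     allele_b = alt[keep],
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = colnames(gt), stringsAsFactors = FALSE)
  out <- geno_matrix(t(code), loci, samples, dp = dp)
  attr(out, "n_excluded_multiallelic") <- n_excl
  out
}
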