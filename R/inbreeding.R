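#' Remove loci mapping to the X chromosome
#'
#' Sex-linked markers bias inbreeding estimates in the heterogametic sex;
#' loci whose best flanking-sequence alignment (against an outgroup genome
#' with a well-assembled X, supplied as a table) is on "X" are dropped.
#' Unaligned loci are retained.
#'
#' @param x a [geno_matrix()].
#' @param alignment_table data.frame with `snp_id` and `chromosome`.
#' @return A `geno_matrix` without X-mapped loci.
#' @export
filter_sex_linked <- function(x, alignment_table) {
  chrom <- alignment_table$chromosome[match(x$loci$snp_id,
                                            alignment_table$snp_id)]
  drop <- !is.na(chrom) & chrom == "X"
  if (all(drop)) warning("all loci map to the X chromosome")
  subset_geno(x, loci = which(!drop))
}

#' Standardised multi-locus heterozygosity
#'
#' sMLH of individual i is its proportion of heterozygous loci divided by
#' the mean, over the loci typed in i, of those loci's population
#' heterozygosity. The population average is ~1 when individuals are typed
#' at comparable loci.
#'
#' @param x a [geno_matrix()].
#' @return named numeric vector, NA (with warning) for individuals typed at
#'   no loci.
#' @export
smlh <- function(x) {
  g <- geno_codes(x)
  if (nrow(g) < 2L) stop("sMLH needs at least 2 individuals")
  typed <- !is.na(g)
  het <- !is.na(g) & g == 1L
  locus_het <- colSums(het) / pmax(colSums(typed), 1L)
  n_i <- rowSums(typed)
  h_i <- rowSums(het)
  mean_ref <- as.vector(typed %*% locus_het) / pmax(n_i, 1L)
  out <- ifelse(n_i > 0 & mean_ref > 0, (h_i / pmax(n_i, 1L)) / mean_ref,
                NA_real_)
  if (any(n_i == 0)) warning("individual(s) typed at no loci: sMLH undefined")
  stats::setNames(out, rownames(g))
}

#' Inbreeding from the correlation of uniting gametes
#'
#' Per individual, averages over typed polymorphic loci the term
#' \eqn{(x^2 - (1+2p)x + 2p^2) / (2p(1-p))} where x is the allele-a dosage
#' and p the allele-a frequency. Expectation 0 for non-inbred individuals
#' under Hardy-Weinberg; +1 for fully homozygous, -1 for fully heterozygous
#' individuals at p = 0.5.
#'
#' @param x a [geno_matrix()].
#' @param freqs allele-a frequency per locus; defaults to frequencies
#'   estimated from the sample itself.
#' @return named numeric vector.
#' @export
fhat3 <- function(x, freqs = NULL) {
  g <- geno_codes(x)
  if (is.null(freqs)) {
    n_called <- colSums(!is.na(g))
    freqs <- ifelse(n_called > 0, 1 - colSums(g, na.rm = TRUE) / (2 * n_called),
                    NA_real_)
  }
  usable <- !is.na(freqs) & freqs > 0 & freqs < 1
  gg <- g[, usable, drop = FALSE]
  p <- freqs[usable]
  xa <- 2 - gg  # allele-a dosage
  t1 <- xa * xa
  t2 <- sweep(xa, 2, 1 + 2 * p, "*")
  t3 <- matrix(2 * p^2, nrow(gg), ncol(gg), byrow = TRUE)
  den <- matrix(2 * p * (1 - p), nrow(gg), ncol(gg), byrow = TRUE)
  term <- (t1 - t2 + t3) / den
  term[is.na(gg)] <- NA
  m_i <- rowSums(!is.na(gg))
  out <- rowSums(term, na.rm = TRUE) / pmax(m_i, 1L)
  out[m_i == 0] <- NA_real_
  stats::setNames(out, rownames(g))
}

#' Genomic inbreeding from runs of homozygosity
#'
#' F_ROH = total length of an individual's ROH segments divided by the
#' genome (assembly) length. Individuals without segments get 0.
#'
#' @param segments data.frame from [call_roh()].
#' @param sample_ids individuals to report (default: those in `segments`).
#' @param genome_length_bp assembly length; default 2.3e9 bp.
#' @return named numeric vector.
#' @export
f_roh <- function(segments, sample_ids = NULL, genome_length_bp = 2.3e9) {
  if (genome_length_bp <= 0) stop("genome_length_bp must be positive")
  if (is.null(sample_ids)) sample_ids <- unique(segments$sample_id)
  len <- segments$end_bp - segments$start_bp + 1
  tot <- tapply(len, segments$sample_id, sum)
  out <- stats::setNames(rep(0, length(sample_ids)), sample_ids)
  hit <- intersect(names(tot), sample_ids)
  out[hit] <- tot[hit] / genome_length_bp
  out
}

#' All three genomic inbreeding estimates per individual
#'
#' Convenience wrapper: sMLH, the uniting-gametes estimator and F_ROH on a
#' shared post-QC matrix.
#'
#' @param x a [geno_matrix()].
#' @param params a [roh_params()] list.
#' @param genome_length_bp F_ROH denominator (default 2.3e9).
#' @return data.frame: `sample_id`, `smlh`, `fhat3`, `f_roh`,
#'   `roh_total_kb`.
#' @export
inbreeding_estimates <- function(x, params = roh_params(),
                                 genome_length_bp = 2.3e9) {
  segs <- call_roh(x, params = params)
  fr <- f_roh(segs, sample_ids = x$samples$sample_id,
              genome_length_bp = genome_length_bp)
  data.frame(sample_id = x$samples$sample_id,
             smlh = unname(smlh(x)[x$samples$sample_id]),
             fhat3 = unname(fhat3(x)[x$samples$sample_id]),
             f_roh = unname(fr[x$samples$sample_id]),
             roh_total_kb = unname(fr[x$samples$sample_id]) *
               genome_length_bp / 1000,
             stringsAsFactors = FALSE)
}
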