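#' Genotype matrix container
#'
#' Biallelic genotypes for a set of individuals, coded as allele-b dosage:
#' 0 = homozygous for `allele_a`, 1 = heterozygous, 2 = homozygous for
#' `allele_b`, `NA` = missing. Loci and samples carry metadata tables;
#' per-genotype sequencing depth is optional (needed only by the discovery
#' depth filter).
#'
#' @param geno integer matrix, individuals in rows, loci in columns.
#' @param loci data.frame with at least `snp_id`, `scaffold`, `pos_bp`,
#'   `allele_a`, `allele_b`; one row per column of `geno`. A `source` column
#'   (one of `"rad"`, `"transcriptomic"`, `"prevalidated_canine"`,
#'   `"prevalidated_goldengate"`, `"prevalidated_sanger"`, `"mhc"`) is kept
#'   when present.
#' @param samples data.frame with at least `sample_id`; one row per row of
#'   `geno`. See [read_sample_metadata()] for the full set of recognised
#'   columns.
#' @param dp optional numeric matrix of per-genotype depths, same shape as
#'   `geno`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, loci, samples, dp = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(loci) != ncol(geno))
    stop("loci table has ", nrow(loci), " rows but geno has ", ncol(geno),
         " columns")
  if (nrow(samples) != nrow(geno))
    stop("samples table has ", nrow(samples), " rows but geno has ",
         nrow(geno), " rows")
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in samples table")
  if (anyDuplicated(loci$snp_id))
    stop("duplicated snp_id in loci table")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (!is.null(dp)) {
    dp <- as.matrix(dp)
    if (!all(dim(dp) == dim(geno))) stop("dp matrix shape mismatch")
  }
  rownames(geno) <- samples$sample_id
  colnames(geno) <- loci$snp_id
  structure(list(geno = geno, loci = as.data.frame(loci),
                 samples = as.data.frame(samples), dp = dp),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$geno), "samples x", ncol(x$geno), "loci\n")
  cr <- if (length(x$geno)) mean(!is.na(x$geno)) else NA_real_
  cat("  overall call rate:", format(round(cr, 4)), "\n")
  if (!is.null(x$dp)) cat("  per-genotype depth: present\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param x a [geno_matrix()].
#' @param samples,loci index vectors (logical, integer or character ids).
#'   `NULL` keeps everything.
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(x, samples = NULL, loci = NULL) {
  si <- resolve_index(samples, x$samples$sample_id, nrow(x$geno))
  li <- resolve_index(loci, x$loci$snp_id, ncol(x$geno))
  geno_matrix(x$geno[si, li, drop = FALSE],
              x$loci[li, , drop = FALSE],
              x$samples[si, , drop = FALSE],
              dp = if (is.null(x$dp)) NULL else x$dp[si, li, drop = FALSE])
}

resolve_index <- function(idx, ids, n) {
  if (is.null(idx)) return(seq_len(n))
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) stop("unknown ids: ", paste(idx[is.na(pos)], collapse = ", "))
    return(pos)
  }
  if (is.logical(idx)) return(which(idx))
  idx
}

#' Swap the reference/alternate allele labels of loci
#'
#' Maps genotype code g to 2 - g at the selected loci and exchanges
#' `allele_a`/`allele_b` in the locus table. Heterozygosity-based statistics
#' are invariant under this relabelling.
#'
#' @param x a [geno_matrix()].
#' @param loci loci to flip (default all).
#' @return A `geno_matrix`.
#' @export
swap_alleles <- function(x, loci = NULL) {
  li <- resolve_index(loci, x$loci$snp_id, ncol(x$geno))
  g <- x$geno
  g[, li] <- 2L - g[, li]
  lt <- x$loci
  tmp <- lt$allele_a[li]
  lt$allele_a[li] <- lt$allele_b[li]
  lt$allele_b[li] <- tmp
  geno_matrix(g, lt, x$samples, dp = x$dp)
}

#' Per-individual heterozygosity indicator matrix
#'
#' @param x a [geno_matrix()] or a genotype code matrix.
#' @return Integer matrix: 1 heterozygous, 0 homozygous, NA missing.
#' @keywords internal
het_matrix <- function(x) {
  g <- if (inherits(x, "geno_matrix")) x$geno else x
  h <- (g == 1L) * 1L
  h
}

geno_codes <- function(x) if (inherits(x, "geno_matrix")) x$geno else as.matrix(x)
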