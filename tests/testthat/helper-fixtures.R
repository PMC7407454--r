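# small builders and independent oracles shared across test files

# genotype matrix from a plain code matrix; loci evenly spaced on one scaffold
# unless positions/scaffolds are given
make_gm <- function(mat, pos = NULL, scaffold = NULL, spacing = 1000L) {
  mat <- as.matrix(mat)
  L <- ncol(mat)
  if (is.null(pos)) pos <- seq.int(spacing, by = spacing, length.out = L)
  if (is.null(scaffold)) scaffold <- rep("sc1", L)
  loci <- data.frame(snp_id = sprintf("s%04d", seq_len(L)),
                     scaffold = scaffold, pos_bp = as.integer(pos),
                     allele_a = "A", allele_b = "C",
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("ind%03d", seq_len(nrow(mat))),
                        stringsAsFactors = FALSE)
  geno_matrix(mat, loci, samples)
}

# independent re-validation of ROH segment constraints, written directly from
# the segment definition (no shared code with the caller)
revalidate_roh <- function(segments, x, params) {
  ok <- TRUE
  for (k in seq_len(nrow(segments))) {
    s <- segments[k, ]
    li <- which(x$loci$scaffold == s$scaffold &
                  x$loci$pos_bp >= s$start_bp & x$loci$pos_bp <= s$end_bp)
    g <- x$geno[match(s$sample_id, x$samples$sample_id), li]
    pos <- sort(x$loci$pos_bp[li])
    len_kb <- (s$end_bp - s$start_bp + 1) / 1000
    ok <- ok &&
      s$n_snps == length(li) &&
      s$n_het == sum(g == 1L, na.rm = TRUE) &&
      s$n_het <= params$seg_max_het &&
      s$n_snps >= params$min_snps &&
      len_kb >= params$min_length_kb &&
      len_kb / s$n_snps <= params$max_kb_per_snp &&
      (length(pos) < 2 || max(diff(pos)) <= params$max_gap_kb * 1000)
  }
  # per-sample, per-scaffold non-overlap
  for (grp in split(segments, paste(segments$sample_id, segments$scaffold))) {
    if (nrow(grp) < 2) next
    grp <- grp[order(grp$start_bp), ]
    ok <- ok && all(grp$start_bp[-1] > grp$end_bp[-nrow(grp)])
  }
  ok
}

# direct Newton-Raphson maximisation of the Bernoulli-logit log-likelihood;
# independent oracle for the GLM fit
newton_logistic <- function(X, y, tol = 1e-10, maxit = 50) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    score <- drop(crossprod(X, y - p))
    W <- p * (1 - p)
    H <- crossprod(X * W, X)
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# diploid genotypes (allele-b dosage) for one individual with inbreeding F:
# with probability F the two alleles are identical by descent
rgeno_inbred <- function(L, freq_b, F) {
  ibd <- stats::runif(L) < F
  a1 <- stats::rbinom(L, 1, freq_b)
  a2 <- ifelse(ibd, a1, stats::rbinom(L, 1, freq_b))
  a1 + a2
}
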