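#' Identity disequilibrium (g2)
#'
#' g2 measures the excess probability of being heterozygous at two loci
#' simultaneously, relative to the product of single-locus heterozygosity
#' probabilities, averaged over locus pairs. It is positive when inbreeding
#' varies among individuals. The estimator used here, for locus pair (k, l):
#' the joint-heterozygosity term sums h_ik * h_il over individuals typed at
#' both loci, normalised by their count; the independence reference sums
#' h_ik * h_jl over ordered pairs of distinct individuals typed at k and l
#' respectively, normalised by the number of such pairs. g2 is the ratio of
#' the two pair-averaged terms minus 1. With complete data this reduces to
#' the classic two-locus heterozygosity-disequilibrium estimator; with
#' missing data every term is normalised by the exact count of observations
#' that enter it.
#'
#' The production path evaluates the sums by matrix algebra (exactly, not
#' approximately); [g2_direct()] is the transparent O(L^2) double loop over
#' locus pairs.
#'
#' @param x a [geno_matrix()] or a 0/1 heterozygosity matrix (individuals in
#'   rows, NA = missing).
#' @param n_boot bootstrap replicates over individuals for the percentile CI
#'   (default 1000).
#' @param n_perm permutations (independent shuffles of each locus column)
#'   for the p-value (default 1000).
#' @param seed integer seed controlling all randomness.
#' @param conf confidence level (default 0.95).
#' @return object of class `g2_fit`: `g2_hat`, `ci_low`, `ci_high`,
#'   `p_perm`, `n_boot`, `n_perm`, `seed`, `boot` (replicate estimates).
#' @export
g2_identity_disequilibrium <- function(x, n_boot = 1000L, n_perm = 1000L,
                                       seed = 1L, conf = 0.95) {
  h <- as_het01(x)
  est <- g2_point(h)
  if (!is.finite(est)) stop("g2 undefined: no heterozygosity variance (monomorphic data?)")
  set.seed(seed)
  boot <- numeric(0)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boot <- vapply(seq_len(n_boot), function(b) {
      g2_point(h[sample.int(nrow(h), replace = TRUE), , drop = FALSE])
    }, numeric(1))
    ci <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
  }
  p_perm <- NA_real_
  if (n_perm > 0) {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      hp <- apply(h, 2, function(col) col[sample.int(length(col))])
      if (g2_point(hp) >= est) exceed <- exceed + 1L
    }
    p_perm <- (exceed + 1) / (n_perm + 1)
  }
  structure(list(g2_hat = est, ci_low = ci[1], ci_high = ci[2],
                 p_perm = p_perm, n_boot = n_boot, n_perm = n_perm,
                 seed = seed, boot = boot),
            class = "g2_fit")
}

#' @export
print.g2_fit <- function(x, ...) {
  cat("g2 identity disequilibrium\n")
  cat(sprintf("  g2 = %.6g", x$g2_hat))
  if (!is.na(x$ci_low))
    cat(sprintf("  (95%% CI %.6g - %.6g, %d bootstraps)",
                x$ci_low, x$ci_high, x$n_boot))
  cat("\n")
  if (!is.na(x$p_perm))
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$p_perm, x$n_perm))
  invisible(x)
}

# heterozygosity indicator with NA for missing, from geno_matrix or matrix
as_het01 <- function(x) {
  g <- geno_codes(x)
  if (nrow(g) < 2L || ncol(g) < 2L) stop("g2 needs >= 2 individuals and loci")
  h <- matrix(NA_real_, nrow(g), ncol(g))
  h[!is.na(g)] <- as.numeric(g[!is.na(g)] == 1L)
  h
}

# point estimate, matrix-algebra path (exact)
g2_point <- function(h) {
  typed <- !is.na(h)
  h0 <- h
  h0[!typed] <- 0
  n <- nrow(h0)
  if (!anyNA(h)) {
    r <- rowSums(h0)
    cc <- colSums(h0)
    sum_s <- sum(r * r - r)                 # sum over k != l of s_kl
    sum_cc <- sum(cc)^2 - sum(cc^2)         # sum over k != l of c_k c_l
    num <- sum_s / n
    den <- (sum_cc - sum_s) / (n * (n - 1))
  } else {
    tt <- matrix(as.numeric(typed), nrow(h0))
    S <- crossprod(h0)        # s_kl
    Np <- crossprod(tt)       # n_kl
    cc <- colSums(h0)
    nk <- colSums(tt)
    C <- tcrossprod(cc, cc)   # c_k c_l
    Dn <- tcrossprod(nk, nk) - Np
    off <- upper.tri(S) | lower.tri(S)
    # numerator and denominator run over the same set of usable pairs
    both <- off & Np > 0 & Dn > 0
    num <- sum(S[both] / Np[both])
    den <- sum((C[both] - S[both]) / Dn[both])
  }
  if (den <= 0) return(NA_real_)
  num / den - 1
}

#' Direct O(L^2) two-locus g2 estimator
#'
#' Transparent double loop over locus pairs implementing the same formula
#' as the fast path in [g2_identity_disequilibrium()]; intended as a
#' cross-check at small problem sizes.
#'
#' @param x a [geno_matrix()] or 0/1 heterozygosity matrix.
#' @return numeric point estimate.
#' @export
g2_direct <- function(x) {
  h <- as_het01(x)
  typed <- !is.na(h)
  L <- ncol(h)
  num <- 0; den <- 0
  for (k in seq_len(L - 1)) for (l in (k + 1):L) {
    both <- typed[, k] & typed[, l]
    n_kl <- sum(both)
    n_k <- sum(typed[, k]); n_l <- sum(typed[, l])
    d_kl <- n_k * n_l - n_kl
    if (n_kl == 0 || d_kl == 0) next
    s_kl <- sum(h[both, k] * h[both, l])
    cross <- sum(h[typed[, k], k]) * sum(h[typed[, l], l]) - s_kl
    num <- num + s_kl / n_kl
    den <- den + cross / d_kl
  }
  if (den <= 0) return(NA_real_)
  num / den - 1
}
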