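#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed minor-allele count, every
#' compatible heterozygote count h has probability proportional to
#' 2^h / (n_hom_minor! h! n_hom_major!). The p-value is the total
#' probability of outcomes no more likely than the observed one (standard
#' cumulative rule, no mid-p correction).
#'
#' @param n_hom_a,n_het,n_hom_b genotype counts at one biallelic locus.
#' @return p-value in (0, 1]; monomorphic input returns 1.
#' @export
hwe_exact <- function(n_hom_a, n_het, n_hom_b) {
  if (any(c(n_hom_a, n_het, n_hom_b) < 0)) stop("negative genotype count")
  n <- n_hom_a + n_het + n_hom_b
  if (n < 1) stop("no genotypes")
  n_a <- 2L * n_hom_a + n_het
  n_b <- 2L * n_hom_b + n_het
  m <- min(n_a, n_b)
  if (m == 0L) return(1)
  dist <- hwe_het_distribution(n, m)
  obs <- n_het
  p_obs <- dist$prob[match(obs, dist$het)]
  if (is.na(p_obs)) stop("observed heterozygote count incompatible with counts")
  # tolerance guards against ties lost to floating point
  sum(dist$prob[dist$prob <= p_obs * (1 + 1e-7)])
}

#' Exact conditional distribution of the heterozygote count
#'
#' Support and probabilities of the heterozygote count conditional on sample
#' size `n` and minor-allele count `m` under Hardy-Weinberg equilibrium.
#'
#' @param n number of diploid individuals.
#' @param m minor-allele count (0..n).
#' @return data.frame with columns `het` and `prob` (sums to 1).
#' @export
hwe_het_distribution <- function(n, m) {
  m <- as.integer(m)
  hets <- seq.int(m %% 2L, m, by = 2L)
  hom_minor <- (m - hets) %/% 2L
  hom_major <- n - hets - hom_minor
  ok <- hom_major >= 0L
  hets <- hets[ok]; hom_minor <- hom_minor[ok]; hom_major <- hom_major[ok]
  lp <- hets * log(2) - lfactorial(hom_minor) - lfactorial(hets) -
    lfactorial(hom_major)
  lp <- lp - max(lp)
  p <- exp(lp)
  data.frame(het = hets, prob = p / sum(p))
}
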