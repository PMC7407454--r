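#' LD pruning by variance inflation factor
#'
#' Sliding windows of `window` loci advancing by `step`; within each window
#' the locus with the highest VIF (1 / (1 - R^2) from regressing its
#' mean-imputed dosage on the other loci in the window) is removed
#' repeatedly until all VIFs are at or below `vif_max`. Removals are global
#' and permanent. Mean imputation is used for the regressions only.
#'
#' @param x a [geno_matrix()] or dosage matrix.
#' @param window,step window size and step in SNPs (defaults 50 and 5).
#' @param vif_max VIF threshold (default 2, i.e. R^2 = 0.5).
#' @return integer vector of kept locus indices (in original order).
#' @export
ld_prune_vif <- function(x, window = 50L, step = 5L, vif_max = 2.0) {
  g <- geno_codes(x)
  L <- ncol(g)
  if (L <= 1L) return(seq_len(L))
  # mean-impute per locus
  z <- apply(g, 2, function(col) {
    mu <- mean(col, na.rm = TRUE)
    col[is.na(col)] <- if (is.nan(mu)) 0 else mu
    col
  })
  removed <- logical(L)
  starts <- seq.int(1L, L, by = step)
  for (s in starts) {
    win <- s:min(s + window - 1L, L)
    repeat {
      act <- win[!removed[win]]
      if (length(act) <= 1L) break
      v <- window_vifs(z[, act, drop = FALSE])
      worst <- max(v)
      if (worst <= vif_max) break
      # deterministic tie-break: remove the latest locus among the worst
      drop_local <- max(which(v >= worst - 1e-12))
      removed[act[drop_local]] <- TRUE
    }
    if (s + window - 1L >= L) break
  }
  which(!removed)
}

# VIF of each column given the others (with intercept), via QR regressions
window_vifs <- function(z) {
  m <- ncol(z)
  v <- numeric(m)
  for (j in seq_len(m)) {
    y <- z[, j]
    tss <- sum((y - mean(y))^2)
    if (tss < 1e-12) { v[j] <- 1; next }
    X <- cbind(1, z[, -j, drop = FALSE])
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    r2 <- 1 - rss / tss
    v[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  v
}

#' Maximally informative locus subset for relatedness inference
#'
#' Keeps loci with MAF at least `min_maf`, call rate at least
#' `min_call_rate` and Hardy-Weinberg p-value at least `hwe_alpha`.
#'
#' @param stats output of [locus_stats()].
#' @param min_maf,min_call_rate,hwe_alpha thresholds (defaults 0.3, 0.90,
#'   0.001).
#' @return character vector of kept snp_ids.
#' @export
informative_subset <- function(stats, min_maf = 0.3, min_call_rate = 0.90,
                               hwe_alpha = 0.001) {
  keep <- stats$maf >= min_maf & stats$call_rate >= min_call_rate &
    stats$hwe_p >= hwe_alpha
  stats$snp_id[keep]
}

#' Nine-cell genotype combination counts for one pair
#'
#' @param x a [geno_matrix()].
#' @param id_a,id_b sample ids.
#' @return list: `id_a`, `id_b`, `n` (3x3 matrix, rows = a's code 0/1/2,
#'   cols = b's code), `n_used`.
#' @export
pair_counts <- function(x, id_a, id_b) {
  ia <- match(id_a, x$samples$sample_id)
  ib <- match(id_b, x$samples$sample_id)
  if (is.na(ia) || is.na(ib)) stop("unknown sample id")
  ga <- x$geno[ia, ]
  gb <- x$geno[ib, ]
  joint <- !is.na(ga) & !is.na(gb)
  n <- matrix(0L, 3, 3, dimnames = list(c("0", "1", "2"), c("0", "1", "2")))
  if (any(joint)) {
    tab <- table(factor(ga[joint], levels = 0:2),
                 factor(gb[joint], levels = 0:2))
    n[] <- as.integer(tab)
  }
  list(id_a = id_a, id_b = id_b, n = n, n_used = sum(n))
}

#' Allele-sharing statistics from nine-cell counts
#'
#' KING-robust kinship = (HETHET - 2 IBS0) / (HET_a + HET_b);
#' R0 = IBS0 / HETHET; R1 = HETHET / DISC, where HETHET is the count of
#' loci where both individuals are heterozygous, IBS0 the count of opposite
#' homozygotes, HET_a/HET_b the per-individual heterozygote counts over
#' jointly called loci and DISC the count of all discordant genotype pairs.
#' These need no allele frequencies and are robust to ascertainment bias.
#'
#' @param counts output of [pair_counts()] (or any list with an `n` 3x3
#'   matrix).
#' @return list: `kinship`, `r0`, `r1` (NA when a denominator is zero).
#' @export
allele_sharing_stats <- function(counts) {
  n <- counts$n
  hethet <- n[2, 2]
  ibs0 <- n[1, 3] + n[3, 1]
  het_a <- sum(n[2, ])
  het_b <- sum(n[, 2])
  disc <- sum(n) - n[1, 1] - n[2, 2] - n[3, 3]
  list(kinship = if (het_a + het_b > 0) (hethet - 2 * ibs0) / (het_a + het_b)
       else NA_real_,
       r0 = if (hethet > 0) ibs0 / hethet else NA_real_,
       r1 = if (disc > 0) hethet / disc else NA_real_)
}

# per-locus expected IBS-given-IBD probabilities with without-replacement
# (finite-sample) corrections; freqs = allele-a frequency, counts from ns
# individuals per locus
ibs_expectations <- function(freqs, n_called) {
  T <- 2 * n_called
  X <- round(freqs * T)
  Y <- T - X
  d4 <- T * (T - 1) * (T - 2) * (T - 3)
  d3 <- T * (T - 1) * (T - 2)
  p2q2 <- X * (X - 1) * Y * (Y - 1) / d4
  p3q <- X * (X - 1) * (X - 2) * Y / d4
  pq3 <- X * Y * (Y - 1) * (Y - 2) / d4
  p4 <- X * (X - 1) * (X - 2) * (X - 3) / d4
  q4 <- Y * (Y - 1) * (Y - 2) * (Y - 3) / d4
  p2q <- X * (X - 1) * Y / d3
  pq2 <- X * Y * (Y - 1) / d3
  p3 <- X * (X - 1) * (X - 2) / d3
  q3 <- Y * (Y - 1) * (Y - 2) / d3
  list(e00 = 2 * p2q2,
       e10 = 4 * p3q + 4 * pq3,
       e20 = p4 + q4 + 4 * p2q2,
       e11 = 2 * p2q + 2 * pq2,
       e21 = p3 + q3 + p2q + pq2)
}

# method-of-moments IBD for one pair of genotype vectors; n_called is the
# per-locus sample size behind the frequency estimates
mom_ibd_pair <- function(ga, gb, freqs, n_called) {
  joint <- !is.na(ga) & !is.na(gb)
  usable <- joint & !is.na(freqs) & freqs > 0 & freqs < 1 & n_called >= 2
  if (!any(usable))
    return(c(z0 = NA_real_, z1 = NA_real_, z2 = NA_real_, pi_hat = NA_real_))
  e <- ibs_expectations(freqs[usable], n_called[usable])
  d <- abs(ga[usable] - gb[usable])
  O0 <- sum(d == 2); O1 <- sum(d == 1); O2 <- sum(d == 0)
  solve_mom_z(O0, O1, O2, sum(e$e00), sum(e$e10), sum(e$e20),
              sum(e$e11), sum(e$e21), sum(usable))
}

solve_mom_z <- function(O0, O1, O2, E00, E10, E20, E11, E21, n_used) {
  z0 <- O0 / E00
  z1 <- (O1 - z0 * E10) / E11
  z2 <- (O2 - z0 * E20 - z1 * E21) / n_used
  if (!is.finite(z0) || !is.finite(z1) || !is.finite(z2))
    return(c(z0 = NA_real_, z1 = NA_real_, z2 = NA_real_, pi_hat = NA_real_))
  if (z0 > 1) { z <- c(1, 0, 0) } else {
    z <- pmax(c(z0, z1, z2), 0)
    z <- z / sum(z)
  }
  c(z0 = z[1], z1 = z[2], z2 = z[3], pi_hat = z[3] + z[2] / 2)
}

#' Method-of-moments IBD coefficients for one pair
#'
#' Estimates the proportions of the genome where the pair shares 0, 1 or 2
#' alleles identical by descent (Z0/Z1/Z2) and PI_HAT = Z2 + Z1/2, by
#' equating observed IBS counts to their expectations given IBD state.
#' Expected IBS probabilities use sample allele frequencies with
#' without-replacement finite-sample corrections; Z's are solved
#' sequentially (IBS0 identifies Z0, then IBS1 gives Z1, then IBS2 gives
#' Z2), clipped to [0,1] and renormalised. Monomorphic loci are excluded.
#'
#' @param x a [geno_matrix()].
#' @param id_a,id_b sample ids.
#' @param freqs allele-a frequency per locus (default: estimated from the
#'   full matrix).
#' @param n_called per-locus count of called individuals behind `freqs`
#'   (default: computed from the matrix).
#' @return named numeric vector: `z0`, `z1`, `z2`, `pi_hat`.
#' @export
mom_ibd <- function(x, id_a, id_b, freqs = NULL, n_called = NULL) {
  ia <- match(id_a, x$samples$sample_id)
  ib <- match(id_b, x$samples$sample_id)
  if (is.na(ia) || is.na(ib)) stop("unknown sample id")
  if (is.null(freqs)) freqs <- allele_a_freq(x)
  if (is.null(n_called)) n_called <- colSums(!is.na(x$geno))
  mom_ibd_pair(x$geno[ia, ], x$geno[ib, ], freqs, n_called)
}

#' All pairwise relatedness statistics
#'
#' Computes, for every pair of samples (or a requested subset of pairs),
#' the nine-cell summaries, KING-robust kinship, R0, R1, the
#' method-of-moments Z0/Z1/Z2/PI_HAT and, when a threshold table is given,
#' the relationship classification. Uses matrix algebra across all pairs.
#'
#' @param x a [geno_matrix()] (typically the informative subset).
#' @param freqs allele-a frequency per locus for the MoM step (default:
#'   from the matrix itself, all samples).
#' @param thresholds a threshold table from [default_threshold_table()] or
#'   NULL to skip classification.
#' @param difficult_margin distance to a decision bound below which a call
#'   is flagged difficult (default 0.01).
#' @return data.frame, one row per unordered pair.
#' @export
relatedness_pairs <- function(x, freqs = NULL,
                              thresholds = default_threshold_table(),
                              difficult_margin = 0.01) {
  g <- x$geno
  n <- nrow(g)
  if (n < 2L) stop("need at least two samples")
  if (is.null(freqs)) freqs <- allele_a_freq(x)
  n_called <- colSums(!is.na(g))
  Tm <- matrix(as.numeric(!is.na(g)), n)
  G0 <- matrix(as.numeric(!is.na(g) & g == 0L), n)
  G1 <- matrix(as.numeric(!is.na(g) & g == 1L), n)
  G2 <- matrix(as.numeric(!is.na(g) & g == 2L), n)
  N11 <- tcrossprod(G1)
  IBS0 <- tcrossprod(G0, G2) + tcrossprod(G2, G0)
  HETa <- tcrossprod(G1, Tm)
  Nused <- tcrossprod(Tm)
  CONC <- tcrossprod(G0) + N11 + tcrossprod(G2)
  DISC <- Nused - CONC
  kin <- (N11 - 2 * IBS0) / (HETa + t(HETa))
  r0 <- IBS0 / N11
  r1 <- N11 / DISC
  # MoM on polymorphic loci with usable frequencies
  usable <- !is.na(freqs) & freqs > 0 & freqs < 1 & n_called >= 2
  e <- ibs_expectations(freqs[usable], n_called[usable])
  TU <- Tm[, usable, drop = FALSE]
  G0U <- G0[, usable, drop = FALSE]
  G1U <- G1[, usable, drop = FALSE]
  G2U <- G2[, usable, drop = FALSE]
  NU <- tcrossprod(TU)
  O0 <- tcrossprod(G0U, G2U) + tcrossprod(G2U, G0U)
  O2 <- tcrossprod(G0U) + tcrossprod(G1U) + tcrossprod(G2U)
  O1 <- NU - O0 - O2
  epair <- function(ev) tcrossprod(sweep(TU, 2, ev, "*"), TU)
  E00 <- epair(e$e00); E10 <- epair(e$e10); E20 <- epair(e$e20)
  E11 <- epair(e$e11); E21 <- epair(e$e21)
  ids <- x$samples$sample_id
  ut <- which(upper.tri(N11), arr.ind = TRUE)
  res <- data.frame(id_a = ids[ut[, 1]], id_b = ids[ut[, 2]],
                    n_used = Nused[ut], hethet = N11[ut], ibs0 = IBS0[ut],
                    kinship = kin[ut], r0 = r0[ut], r1 = r1[ut],
                    stringsAsFactors = FALSE)
  zmat <- t(vapply(seq_len(nrow(ut)), function(k) {
    i <- ut[k, 1]; j <- ut[k, 2]
    solve_mom_z(O0[i, j], O1[i, j], O2[i, j], E00[i, j], E10[i, j],
                E20[i, j], E11[i, j], E21[i, j], NU[i, j])
  }, c(z0 = 0, z1 = 0, z2 = 0, pi_hat = 0)))
  res <- cbind(res, as.data.frame(zmat))
  if (!is.null(thresholds)) {
    cl <- classify_relationship(res, thresholds,
                                difficult_margin = difficult_margin)
    res$category <- cl$category
    res$difficult <- cl$difficult
  }
  res
}

#' Default relationship threshold table
#'
#' Category ranges over (z0, z1, z2, pi_hat) built from kinship-degree
#' midpoints, evaluated in declared order with first match winning. Fully
#' replaceable by a user-supplied table of the same shape (e.g. loaded from
#' a supplementary-table file).
#'
#' @return data.frame: `category`, `coef`, `lo`, `hi`; category order
#'   defines evaluation order.
#' @export
default_threshold_table <- function() {
  rbind(
    data.frame(category = "parent_offspring",
               coef = c("z1", "z0", "pi_hat"),
               lo = c(0.8, 0, 0.354), hi = c(1, 0.1, 0.707)),
    data.frame(category = "full_sib",
               coef = c("z2", "z0", "pi_hat"),
               lo = c(0.1, 0.1, 0.354), hi = c(0.425, 0.425, 0.707)),
    data.frame(category = "second_degree", coef = "pi_hat",
               lo = 0.177, hi = 0.354),
    data.frame(category = "third_degree", coef = "pi_hat",
               lo = 0.0884, hi = 0.177),
    data.frame(category = "unrelated", coef = "pi_hat",
               lo = 0, hi = 0.0884))
}

#' Rule-based relationship classification
#'
#' Assigns the first category (in table order) whose ranges all contain the
#' pair's coefficients; pairs matching no category are `unknown`. A call is
#' flagged `difficult` when any of its coefficients lies within
#' `difficult_margin` of a bounding threshold of the assigned category or
#' an adjacent category in table order. Bounds at the theoretical extremes
#' (exactly 0 or 1) are not treated as inference thresholds.
#'
#' @param stats data.frame with columns `z0`, `z1`, `z2`, `pi_hat` (one row
#'   per pair), or a single named vector.
#' @param table threshold table (see [default_threshold_table()]).
#' @param difficult_margin default 0.01.
#' @return data.frame: `category`, `difficult`.
#' @export
classify_relationship <- function(stats, table = default_threshold_table(),
                                  difficult_margin = 0.01) {
  if (is.null(dim(stats))) stats <- as.data.frame(as.list(stats))
  stopifnot(all(table$lo <= table$hi))
  cats <- unique(table$category)
  m <- nrow(stats)
  category <- rep("unknown", m)
  difficult <- rep(FALSE, m)
  in_cat <- sapply(cats, function(cc) {
    sub <- table[table$category == cc, , drop = FALSE]
    ok <- rep(TRUE, m)
    for (r in seq_len(nrow(sub))) {
      v <- stats[[sub$coef[r]]]
      ok <- ok & !is.na(v) & v >= sub$lo[r] & v <= sub$hi[r]
    }
    ok
  })
  in_cat <- matrix(in_cat, nrow = m)
  for (k in seq_along(cats)) {
    hit <- category == "unknown" & in_cat[, k]
    category[hit] <- cats[k]
  }
  for (i in seq_len(m)) {
    if (category[i] == "unknown") next
    ci <- match(category[i], cats)
    near <- cats[intersect(seq_along(cats), (ci - 1):(ci + 1))]
    sub <- table[table$category %in% near, , drop = FALSE]
    dmin <- Inf
    for (r in seq_len(nrow(sub))) {
      v <- stats[[sub$coef[r]]][i]
      if (is.na(v)) next
      for (bound in c(sub$lo[r], sub$hi[r])) {
        if (bound <= 0 || bound >= 1) next  # theoretical extremes
        dmin <- min(dmin, abs(v - bound))
      }
    }
    difficult[i] <- dmin <= difficult_margin
  }
  data.frame(category = category, difficult = difficult,
             stringsAsFactors = FALSE)
}

#' Audit classified pairs against known mother-offspring links
#'
#' Cross-tabulates field-recorded maternal links against genomic
#' parent-offspring calls: a known link is `confirmed` when classified
#' parent-offspring and `contradicted` when classified below first degree
#' (neither parent-offspring nor full-sib); parent-offspring calls without
#' a field record are `novel`.
#'
#' @param calls data.frame with `id_a`, `id_b`, `category` (from
#'   [relatedness_pairs()]).
#' @param metadata sample metadata with `known_mother_id`.
#' @return list of data.frames: `confirmed`, `novel`, `contradicted`.
#' @export
known_pair_audit <- function(calls, metadata) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  known <- metadata[!is.na(metadata$known_mother_id) &
                      metadata$known_mother_id != "", , drop = FALSE]
  known_keys <- key(known$sample_id, known$known_mother_id)
  call_key <- key(calls$id_a, calls$id_b)
  po <- calls$category == "parent_offspring"
  first_degree <- calls$category %in% c("parent_offspring", "full_sib")
  ki <- match(known_keys, call_key)
  confirmed <- known[!is.na(ki) & po[ki], , drop = FALSE]
  contradicted <- known[!is.na(ki) & !first_degree[ki], , drop = FALSE]
  novel <- calls[po & !(call_key %in% known_keys), , drop = FALSE]
  list(confirmed = confirmed, novel = novel, contradicted = contradicted)
}
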