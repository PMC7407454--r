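#' Post-genotyping sample quality control
#'
#' A sample passes when its array dish-QC value (if available) is at least
#' `min_dish_qc` and its call rate over all loci in the matrix is at least
#' `min_call_rate`. Dish QC is checked first, so a sample appears in at most
#' one failure list.
#'
#' @param x a [geno_matrix()].
#' @param metadata sample metadata (see [read_sample_metadata()]); matched to
#'   the matrix by `sample_id`.
#' @param min_dish_qc,min_call_rate thresholds (defaults 0.82 and 0.97).
#' @return list: `included` (sample ids), `report` with failure lists and
#'   per-sample call rates.
#' @export
sample_qc <- function(x, metadata, min_dish_qc = 0.82, min_call_rate = 0.97) {
  ids <- x$samples$sample_id
  md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  call_rate <- rowMeans(!is.na(x$geno))
  fail_dish <- !is.na(md$dish_qc) & md$dish_qc < min_dish_qc
  fail_cr <- !fail_dish & call_rate < min_call_rate
  list(included = ids[!fail_dish & !fail_cr],
       report = list(samples_failed_dishqc = ids[fail_dish],
                     samples_failed_callrate = ids[fail_cr],
                     call_rate = stats::setNames(call_rate, ids)))
}

#' Per-locus summary statistics
#'
#' Computes call rate, minor allele frequency/count, an exact
#' Hardy-Weinberg p-value and a polymorphism flag per locus. Pups and
#' replicate samples are excluded from the calculation by default to avoid
#' pseudo-replication of parental alleles.
#'
#' @param x a [geno_matrix()].
#' @param metadata optional sample metadata; when given, samples with
#'   `is_pup = TRUE` or a non-missing `is_replicate_of` are excluded.
#' @param include optional character vector of sample ids to restrict to
#'   (applied before the pup/replicate exclusion).
#' @return data.frame: `snp_id`, `n_called`, `call_rate`, `maf`, `mac`,
#'   `hwe_p`, `polymorphic`.
#' @export
locus_stats <- function(x, metadata = NULL, include = NULL) {
  keep <- rep(TRUE, nrow(x$geno))
  if (!is.null(include)) keep <- x$samples$sample_id %in% include
  if (!is.null(metadata)) {
    md <- metadata[match(x$samples$sample_id, metadata$sample_id), , drop = FALSE]
    excl <- (!is.na(md$is_pup) & md$is_pup) |
      (!is.na(md$is_replicate_of) & md$is_replicate_of != "")
    keep <- keep & !excl
  }
  g <- x$geno[keep, , drop = FALSE]
  n_incl <- nrow(g)
  n_called <- colSums(!is.na(g))
  n_het <- colSums(g == 1L, na.rm = TRUE)
  n_hom_b <- colSums(g == 2L, na.rm = TRUE)
  n_hom_a <- n_called - n_het - n_hom_b
  cnt_a <- 2L * n_hom_a + n_het
  cnt_b <- 2L * n_hom_b + n_het
  p <- ifelse(n_called > 0, cnt_a / (2 * n_called), NA_real_)
  maf <- ifelse(n_called > 0, pmin(p, 1 - p), 0)
  mac <- pmin(cnt_a, cnt_b)
  hwe_p <- vapply(seq_len(ncol(g)), function(l) {
    if (n_called[l] == 0) return(1)
    hwe_exact(n_hom_a[l], n_het[l], n_hom_b[l])
  }, numeric(1))
  data.frame(snp_id = x$loci$snp_id, n_called = n_called,
             call_rate = if (n_incl > 0) n_called / n_incl else 0,
             maf = maf, mac = mac, hwe_p = hwe_p,
             polymorphic = mac >= 1L,
             zero_calls = n_called == 0L,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Locus filter for the inbreeding dataset
#'
#' Keeps loci with call rate strictly above `min_call_rate`, MAF strictly
#' above `min_maf` and Hardy-Weinberg p-value at least `hwe_alpha`.
#'
#' @param stats output of [locus_stats()].
#' @param min_call_rate,min_maf,hwe_alpha thresholds (defaults 0.90, 0.01,
#'   0.001).
#' @return character vector of kept `snp_id`s.
#' @export
locus_filter <- function(stats, min_call_rate = 0.90, min_maf = 0.01,
                         hwe_alpha = 0.001) {
  keep <- stats$call_rate > min_call_rate & stats$maf > min_maf &
    stats$hwe_p >= hwe_alpha
  stats$snp_id[keep]
}

#' Genotyping error estimation from replicate samples
#'
#' For every declared replicate pair (samples genotyped more than once;
#' triplicates contribute all three pairs) reports the discordance rate over
#' jointly called loci and the method-of-moments Z2 (probability of sharing
#' both alleles IBD), the latter as used for array error-rate reporting.
#'
#' @param x a [geno_matrix()].
#' @param metadata sample metadata with `is_replicate_of` links.
#' @return list: `pairs` data.frame (`id_a`, `id_b`, `n_joint`,
#'   `n_discordant`, `discordance`, `z2`) and `mean_discordance`.
#' @export
replicate_error <- function(x, metadata) {
  md <- metadata[match(x$samples$sample_id, metadata$sample_id), , drop = FALSE]
  link <- md$is_replicate_of
  link[is.na(link) | link == ""] <- NA
  groups <- split(md$sample_id,
                  ifelse(is.na(link), md$sample_id, link))
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  if (!length(groups))
    return(list(pairs = data.frame(id_a = character(), id_b = character(),
                                   n_joint = integer(), n_discordant = integer(),
                                   discordance = numeric(), z2 = numeric()),
                mean_discordance = NA_real_))
  md_keep <- is.na(link)
  gg <- x$geno[md_keep & !(!is.na(md$is_pup) & md$is_pup), , drop = FALSE]
  n_called <- colSums(!is.na(gg))
  freqs <- ifelse(n_called > 0, 1 - colSums(gg, na.rm = TRUE) / (2 * n_called),
                  NA_real_)
  rows <- list()
  for (grp in groups) {
    cmb <- utils::combn(sort(grp), 2L)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1L, k]; b <- cmb[2L, k]
      ga <- x$geno[match(a, x$samples$sample_id), ]
      gb <- x$geno[match(b, x$samples$sample_id), ]
      joint <- !is.na(ga) & !is.na(gb)
      nd <- sum(ga[joint] != gb[joint])
      ibd <- mom_ibd_pair(ga, gb, freqs, n_called)
      rows[[length(rows) + 1L]] <- data.frame(
        id_a = a, id_b = b, n_joint = sum(joint), n_discordant = nd,
        discordance = if (sum(joint)) nd / sum(joint) else NA_real_,
        z2 = ibd["z2"], stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  list(pairs = pairs, mean_discordance = mean(pairs$discordance, na.rm = TRUE))
}

#' Call-rate and polymorphism summaries per sample group
#'
#' Used e.g. for cross-species amplification panels: per group, summarises
#' the per-sample call rates and the fraction of loci, among those called at
#' least once in the group, that are polymorphic within the group.
#'
#' @param x a [geno_matrix()].
#' @param groups character vector of group labels, one per sample.
#' @return data.frame, one row per non-empty group.
#' @export
cross_sample_summary <- function(x, groups) {
  stopifnot(length(groups) == nrow(x$geno))
  labs <- unique(groups)
  out <- lapply(labs, function(lab) {
    sel <- which(groups == lab)
    g <- x$geno[sel, , drop = FALSE]
    cr <- rowMeans(!is.na(g))
    called <- colSums(!is.na(g)) > 0L
    poly <- if (any(called)) {
      sub <- g[, called, drop = FALSE]
      n_het <- colSums(sub == 1L, na.rm = TRUE)
      n_b <- colSums(sub == 2L, na.rm = TRUE)
      n_cal <- colSums(!is.na(sub))
      cnt_a <- 2L * (n_cal - n_het - n_b) + n_het
      cnt_b <- 2L * n_b + n_het
      mean(pmin(cnt_a, cnt_b) >= 1L)
    } else NA_real_
    data.frame(group = lab, n_samples = length(sel),
               mean_call_rate = mean(cr), min_call_rate = min(cr),
               max_call_rate = max(cr),
               frac_called_loci_polymorphic = poly,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# allele-a frequency per locus (unfolded), over non-pup, non-replicate samples
allele_a_freq <- function(x, metadata = NULL, include = NULL) {
  keep <- rep(TRUE, nrow(x$geno))
  if (!is.null(include)) keep <- x$samples$sample_id %in% include
  if (!is.null(metadata)) {
    md <- metadata[match(x$samples$sample_id, metadata$sample_id), , drop = FALSE]
    excl <- (!is.na(md$is_pup) & md$is_pup) |
      (!is.na(md$is_replicate_of) & md$is_replicate_of != "")
    keep <- keep & !excl
  }
  g <- x$geno[keep, , drop = FALSE]
  n_called <- colSums(!is.na(g))
  dose_b <- colSums(g, na.rm = TRUE)
  ifelse(n_called > 0, 1 - dose_b / (2 * n_called), NA_real_)
}
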