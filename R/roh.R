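#' ROH caller parameters
#'
#' Defaults reproduce a PLINK-style sliding-window screen: windows of
#' `window_snps` consecutive SNPs count as homozygous when they contain at
#' most `window_max_het` heterozygous and `window_max_missing` missing
#' calls; a SNP is a "hit" when at least `hit_threshold` of the windows
#' containing it are homozygous; maximal hit runs become segments when they
#' hold at least `min_snps` SNPs, span at least `min_length_kb`, carry at
#' most `seg_max_het` heterozygotes, average at most `max_kb_per_snp` kb per
#' SNP, and contain no adjacent-SNP gap above `max_gap_kb`.
#'
#' @param window_snps,window_max_het,window_max_missing window screen.
#' @param hit_threshold minimum fraction of homozygous windows per SNP.
#' @param min_snps,seg_max_het,max_kb_per_snp,min_length_kb,max_gap_kb
#'   segment-level constraints (kb values are kilobases).
#' @return list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 20L, window_max_het = 1L,
                       window_max_missing = 5L, hit_threshold = 0.05,
                       min_snps = 20L, seg_max_het = 1L,
                       max_kb_per_snp = 100, min_length_kb = 1000,
                       max_gap_kb = 1000) {
  p <- list(window_snps = window_snps, window_max_het = window_max_het,
            window_max_missing = window_max_missing,
            hit_threshold = hit_threshold, min_snps = min_snps,
            seg_max_het = seg_max_het, max_kb_per_snp = max_kb_per_snp,
            min_length_kb = min_length_kb, max_gap_kb = max_gap_kb)
  stopifnot(all(unlist(p) > 0), hit_threshold <= 1)
  class(p) <- "roh_params"
  p
}

#' Call runs of homozygosity
#'
#' Two-stage sliding-window caller (see [roh_params()]). Stage one screens
#' each individual's scaffolds with fixed-size SNP windows and marks hit
#' SNPs; only windows that physically fit on the scaffold count towards a
#' SNP's hit rate, so scaffold-edge SNPs are not penalised. Stage two joins
#' consecutive hit SNPs into candidate runs, splits runs at adjacent-SNP
#' gaps above `max_gap_kb` and, when a run exceeds the segment heterozygote
#' limit, immediately before each heterozygote after the first, then emits
#' runs passing all segment constraints. Segment bounds are the first and
#' last SNP positions (1-based inclusive).
#'
#' @param x a [geno_matrix()] (loci carry `scaffold` and `pos_bp`).
#' @param params a [roh_params()] list.
#' @return data.frame: `sample_id`, `scaffold`, `start_bp`, `end_bp`,
#'   `n_snps`, `n_het`, `length_kb`.
#' @export
call_roh <- function(x, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  loci <- x$loci
  out <- list()
  scafs <- sort(unique(loci$scaffold))
  for (scaf in scafs) {
    li <- which(loci$scaffold == scaf)
    li <- li[order(loci$pos_bp[li])]
    if (length(li) < params$window_snps) next
    pos <- loci$pos_bp[li]
    for (si in seq_len(nrow(x$geno))) {
      g <- x$geno[si, li]
      segs <- roh_one(g, pos, params)
      if (nrow(segs)) {
        segs$sample_id <- x$samples$sample_id[si]
        segs$scaffold <- scaf
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), scaffold = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), n_het = integer(),
                      length_kb = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$sample_id, res$scaffold, res$start_bp), ]
  rownames(res) <- NULL
  res[, c("sample_id", "scaffold", "start_bp", "end_bp", "n_snps", "n_het",
          "length_kb")]
}

# stage 1+2 for one individual on one sorted scaffold
roh_one <- function(g, pos, p) {
  S <- length(g)
  W <- p$window_snps
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  nw <- S - W + 1L
  cs_het <- cumsum(c(0L, het))
  cs_mis <- cumsum(c(0L, mis))
  win_hom <- (cs_het[(W + 1L):(S + 1L)] - cs_het[1:nw]) <= p$window_max_het &
    (cs_mis[(W + 1L):(S + 1L)] - cs_mis[1:nw]) <= p$window_max_missing
  cs_win <- cumsum(c(0L, win_hom))
  i <- seq_len(S)
  lo <- pmax(1L, i - W + 1L)
  hi <- pmin(i, nw)
  n_win <- pmax(hi - lo + 1L, 0L)
  n_hom <- ifelse(n_win > 0L, cs_win[hi + 1L] - cs_win[lo], 0L)
  hit <- n_win > 0L & n_hom / pmax(n_win, 1L) >= p$hit_threshold
  # maximal runs of hit SNPs
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  pieces <- list()
  max_gap_bp <- p$max_gap_kb * 1000
  for (k in seq_len(nrow(runs))) {
    a <- runs[k, 1L]; b <- runs[k, 2L]
    idx <- a:b
    # split at large gaps
    gaps <- which(diff(pos[idx]) > max_gap_bp)
    bounds <- c(0L, gaps, length(idx))
    for (j in seq_len(length(bounds) - 1L)) {
      sub <- idx[(bounds[j] + 1L):bounds[j + 1L]]
      pieces <- c(pieces, split_excess_hets(sub, het, p$seg_max_het))
    }
  }
  res <- list()
  for (sub in pieces) {
    n_snps <- length(sub)
    n_het <- sum(het[sub])
    len_bp <- pos[sub[n_snps]] - pos[sub[1L]] + 1
    len_kb <- len_bp / 1000
    if (n_snps >= p$min_snps && n_het <= p$seg_max_het &&
        len_kb >= p$min_length_kb && len_kb / n_snps <= p$max_kb_per_snp) {
      res[[length(res) + 1L]] <- data.frame(
        start_bp = pos[sub[1L]], end_bp = pos[sub[n_snps]],
        n_snps = n_snps, n_het = n_het, length_kb = len_kb)
    }
  }
  if (!length(res)) return(data.frame())
  do.call(rbind, res)
}

# cut a run immediately before each heterozygote beyond the allowance, so
# every piece carries at most max_het heterozygotes
split_excess_hets <- function(idx, het, max_het) {
  hpos <- which(het[idx])
  if (length(hpos) <= max_het) return(list(idx))
  cut_at <- hpos[-seq_len(max_het)]
  bounds <- c(0L, cut_at - 1L, length(idx))
  bounds <- unique(bounds)
  out <- list()
  for (j in seq_len(length(bounds) - 1L)) {
    piece <- idx[(bounds[j] + 1L):bounds[j + 1L]]
    out <- c(out, list(piece))
  }
  out
}
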