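#' Discovery-stage genotype filters for candidate SNPs
#'
#' Applies, in order: (1) per-genotype depth masking — calls with depth
#' outside `[min_dp, max_dp]` are set missing; (2) a minor-allele-frequency
#' filter; (3) a call-rate filter. MAF and call rate are computed on the
#' depth-masked genotypes.
#'
#' @param x a [geno_matrix()]; the depth stage needs `x$dp` and is skipped
#'   (with `depth_skipped = TRUE` in the counts) when absent.
#' @param min_dp,max_dp inclusive depth bounds (defaults 5 and 18).
#' @param min_maf minimum MAF, strict `>=` not applied: loci with
#'   `maf < min_maf` are dropped (default 0.05).
#' @param min_callrate minimum genotyping rate; loci below it are dropped
#'   (default 0.60).
#' @return list: `matrix` (filtered `geno_matrix`), `counts` per stage.
#' @export
apply_discovery_filters <- function(x, min_dp = 5, max_dp = 18,
                                    min_maf = 0.05, min_callrate = 0.60) {
  counts <- list(input_loci = ncol(x$geno), depth_skipped = FALSE,
                 genotypes_masked_depth = 0L,
                 dropped_maf = 0L, dropped_callrate = 0L)
  g <- x$geno
  if (is.null(x$dp)) {
    warning("no per-genotype depth table; depth stage skipped")
    counts$depth_skipped <- TRUE
  } else {
    bad <- !is.na(g) & !is.na(x$dp) & (x$dp < min_dp | x$dp > max_dp)
    counts$genotypes_masked_depth <- sum(bad)
    g[bad] <- NA_integer_
  }
  n_called <- colSums(!is.na(g))
  n_samp <- nrow(g)
  dose_b <- colSums(g, na.rm = TRUE)
  p <- ifelse(n_called > 0, dose_b / (2 * n_called), 0)
  maf <- pmin(p, 1 - p)
  fail_maf <- maf < min_maf
  counts$dropped_maf <- sum(fail_maf)
  cr <- if (n_samp > 0) n_called / n_samp else rep(0, ncol(g))
  fail_cr <- !fail_maf & cr < min_callrate
  counts$dropped_callrate <- sum(fail_cr)
  keep <- which(!fail_maf & !fail_cr)
  out <- geno_matrix(g, x$loci, x$samples, dp = x$dp)
  out <- subset_geno(out, loci = keep)
  counts$output_loci <- length(keep)
  list(matrix = out, counts = counts)
}

#' Build a candidate-SNP table
#'
#' Joins locus identity, flanking sequences, mapping summaries and array
#' design recommendations into the per-candidate record used by the
#' prioritisation rules.
#'
#' @param loci data.frame: `snp_id`, `scaffold`, `pos_bp`, `allele_a`,
#'   `allele_b`, `source`.
#' @param flanks output of [read_flank_fasta()] (or same columns).
#' @param mapping output of [read_blast_tab()].
#' @param recommendations data.frame: `snp_id`, `affy_forward`,
#'   `affy_reverse` with values in `recommended`, `neutral`,
#'   `not_recommended`, `unknown`. Candidates missing from the table get
#'   `unknown`.
#' @param maf_south_georgia optional named numeric vector of discovery-pool
#'   MAFs.
#' @param prevalidated optional character vector of pre-validated snp_ids;
#'   defaults to sources starting with `prevalidated` plus `mhc`.
#' @return data.frame of candidate records (one row per SNP).
#' @export
candidate_table <- function(loci, flanks, mapping, recommendations,
                            maf_south_georgia = NULL, prevalidated = NULL) {
  cand <- loci
  fi <- match(cand$snp_id, flanks$snp_id)
  cand$left_flank <- flanks$left_flank[fi]
  cand$right_flank <- flanks$right_flank[fi]
  cand$left_len <- flanks$left_len[fi]
  cand$right_len <- flanks$right_len[fi]
  cand$probe_length <- cand$left_len + cand$right_len + 1L
  mi <- match(cand$snp_id, mapping$snp_id)
  cand$n_mappings <- mapping$n_mappings[mi]
  cand$top_alignment_length <- mapping$top_alignment_length[mi]
  ri <- match(cand$snp_id, recommendations$snp_id)
  cand$affy_forward <- ifelse(is.na(ri), "unknown", recommendations$affy_forward[ri])
  cand$affy_reverse <- ifelse(is.na(ri), "unknown", recommendations$affy_reverse[ri])
  pair <- paste(pmin(cand$allele_a, cand$allele_b),
                pmax(cand$allele_a, cand$allele_b))
  cand$is_at_or_cg <- pair %in% c("A T", "C G")
  cand$maf_south_georgia <- if (is.null(maf_south_georgia)) NA_real_ else
    unname(maf_south_georgia[cand$snp_id])
  cand$prevalidated <- if (is.null(prevalidated))
    grepl("^prevalidated", cand$source) | cand$source == "mhc"
  else cand$snp_id %in% prevalidated
  cand$unique_complete <- cand$n_mappings == 1L &
    cand$top_alignment_length == cand$probe_length
  cand$flanks_sufficient <- check_flanks(cand)
  cand$has_secondary_snp_in_flank <- detect_secondary_snps(cand)
  cand
}

#' Flanking-sequence sufficiency for probe design
#'
#' A candidate has sufficient flanks when both sides are at least
#' `min_flank` bp long.
#'
#' @param cand candidate table (needs `left_len`, `right_len`).
#' @param min_flank default 35.
#' @return logical vector.
#' @export
check_flanks <- function(cand, min_flank = 35L) {
  cand$left_len >= min_flank & cand$right_len >= min_flank
}

#' Attach mapping context to candidates
#'
#' Sets `n_mappings`, `top_alignment_length` and the `unique_complete` flag
#' (exactly one genomic mapping whose alignment spans the full probe).
#'
#' @param cand candidate table.
#' @param mapping output of [read_blast_tab()].
#' @return candidate table with updated columns.
#' @export
annotate_mapping <- function(cand, mapping) {
  mi <- match(cand$snp_id, mapping$snp_id)
  cand$n_mappings <- mapping$n_mappings[mi]
  cand$top_alignment_length <- mapping$top_alignment_length[mi]
  cand$unique_complete <- cand$n_mappings == 1L &
    cand$top_alignment_length == cand$probe_length
  cand
}

#' Flag candidates with a secondary SNP inside the probe flanks
#'
#' A candidate is flagged when any other candidate on the same scaffold lies
#' within `[pos - left_len, pos + right_len]`.
#'
#' @param cand candidate table (needs `scaffold`, `pos_bp`, `left_len`,
#'   `right_len`).
#' @return logical vector.
#' @export
detect_secondary_snps <- function(cand) {
  flag <- logical(nrow(cand))
  for (idx in split(seq_len(nrow(cand)), cand$scaffold)) {
    if (length(idx) < 2L) next
    pos <- cand$pos_bp[idx]
    for (k in seq_along(idx)) {
      i <- idx[k]
      lo <- cand$pos_bp[i] - cand$left_len[i]
      hi <- cand$pos_bp[i] + cand$right_len[i]
      flag[i] <- any(pos >= lo & pos <= hi & seq_along(idx) != k)
    }
  }
  flag
}

rec_either <- function(cand, level) {
  cand$affy_forward == level | cand$affy_reverse == level
}

#' Assign array-design priority categories
#'
#' Seven-tier scheme, evaluated strictly in order with first match winning;
#' candidates matching no rule get priority 0 and are excluded from the
#' panel. Briefly: P1 = recommended + uniquely/completely mapped + not
#' A/T-or-C/G, or any pre-validated/MHC SNP; P2 = neutral equivalent of P1
#' with no secondary flank SNP; P3/P4 = recommended RAD SNPs with relaxed
#' mapping (<=2 / <=3 locations), P3 additionally requiring discovery-pool
#' MAF >= `min_maf_sg`; P5 = high-quality A/T or C/G SNPs; P6/P7 = neutral
#' RAD fallbacks.
#'
#' @param cand candidate table from [candidate_table()].
#' @param min_maf_sg MAF cutoff for P3; default [p3_maf_cutoff()] with 57
#'   discovery individuals.
#' @return integer vector of priorities (0..7).
#' @export
assign_priority <- function(cand, min_maf_sg = p3_maf_cutoff()) {
  rec <- rec_either(cand, "recommended")
  neu <- rec_either(cand, "neutral")
  uc <- cand$unique_complete
  notATCG <- !cand$is_at_or_cg
  rad <- cand$source == "rad"
  nosec <- !cand$has_secondary_snp_in_flank
  maf_sg <- cand$maf_south_georgia
  maf_ok <- !is.na(maf_sg) & maf_sg >= min_maf_sg
  p <- integer(nrow(cand))
  rules <- list(
    (rec & uc & notATCG) | cand$prevalidated | cand$source == "mhc",
    neu & uc & notATCG & nosec,
    rad & rec & cand$n_mappings <= 2L & notATCG & maf_ok,
    rad & rec & cand$n_mappings <= 3L & notATCG,
    cand$is_at_or_cg & rec & uc,
    rad & neu & cand$n_mappings <= 2L & notATCG & nosec,
    rad & neu)
  for (k in seq_along(rules)) {
    hit <- p == 0L & rules[[k]]
    p[hit] <- k
  }
  p
}

#' Minor-allele-frequency cutoff implied by a minimum allele count
#'
#' Frequency of `min_copies` minor-allele copies among `n_individuals`
#' diploids, floored to 3 decimals: with the defaults, 2 copies among 57
#' individuals gives 2/114 = 0.01754..., floored to 0.017.
#'
#' @param n_individuals diploid discovery-pool size (default 57).
#' @param min_copies minimum minor-allele copies (default 2).
#' @return numeric cutoff.
#' @export
p3_maf_cutoff <- function(n_individuals = 57, min_copies = 2) {
  floor(1000 * min_copies / (2 * n_individuals)) / 1000
}

#' Thin prioritised SNPs by physical distance
#'
#' Greedy per-scaffold scan in order of priority (1 best), then descending
#' discovery MAF, then ascending position. A candidate is dropped when it
#' violates its own class's spacing against any already-retained SNP on the
#' scaffold: RAD SNPs of priority >= 3 must be at least
#' `spacing_low_priority` bp from the nearest retained SNP; priority 1-2
#' SNPs at least `spacing_high_priority` bp. Spacing is enforced across
#' priority classes.
#'
#' @param cand candidate table with a `priority` column.
#' @param spacing_low_priority,spacing_high_priority minimum distances in bp
#'   (defaults 1000 and 100).
#' @return logical vector `retained` aligned to `cand` rows.
#' @export
thin_by_distance <- function(cand, spacing_low_priority = 1000L,
                             spacing_high_priority = 100L) {
  stopifnot("priority" %in% names(cand))
  retained <- logical(nrow(cand))
  maf <- cand$maf_south_georgia
  maf[is.na(maf)] <- -1
  ord <- order(cand$priority, -maf, cand$pos_bp)
  ord <- ord[cand$priority[ord] > 0L]
  own_spacing <- ifelse(cand$priority <= 2L, spacing_high_priority,
                        ifelse(cand$source == "rad", spacing_low_priority,
                               0))  # non-RAD P3+: no spacing rule stated
  kept_by_scaf <- new.env(parent = emptyenv())
  for (i in ord) {
    scaf <- cand$scaffold[i]
    kept <- kept_by_scaf[[scaf]]  # matrix cols: pos, spacing
    # a pair must satisfy the stricter of the two SNPs' spacing rules, so
    # the final panel obeys every class constraint exhaustively
    ok <- is.null(kept) ||
      all(abs(kept[, 1L] - cand$pos_bp[i]) >=
            pmax(kept[, 2L], own_spacing[i]))
    if (ok) {
      retained[i] <- TRUE
      kept_by_scaf[[scaf]] <- rbind(kept, c(cand$pos_bp[i], own_spacing[i]))
    }
  }
  retained
}

#' Collapse duplicate candidates discovered by more than one approach
#'
#' Duplicates share (scaffold, pos_bp). Exactly one record per site
#' survives; preference order pre-validated/MHC > RAD > transcriptomic,
#' ties broken by lexicographically smaller snp_id.
#'
#' @param cand candidate table.
#' @return list: `keep` logical vector, `duplicate_of` character vector
#'   (NA for survivors).
#' @export
deduplicate <- function(cand) {
  keep <- rep(TRUE, nrow(cand))
  dup_of <- rep(NA_character_, nrow(cand))
  pref <- ifelse(cand$prevalidated | cand$source == "mhc", 0L,
                 ifelse(cand$source == "rad", 1L, 2L))
  site <- paste(cand$scaffold, cand$pos_bp)
  for (idx in split(seq_len(nrow(cand)), site)) {
    if (length(idx) < 2L) next
    best <- idx[order(pref[idx], cand$snp_id[idx])][1L]
    losers <- setdiff(idx, best)
    keep[losers] <- FALSE
    dup_of[losers] <- cand$snp_id[best]
  }
  list(keep = keep, duplicate_of = dup_of)
}

#' Run the full panel-design chain
#'
#' Deduplicates candidate records, assigns priorities and thins by distance,
#' returning per-candidate decisions and a stage-count summary.
#'
#' @param cand candidate table from [candidate_table()].
#' @param min_maf_sg P3 MAF cutoff; see [assign_priority()].
#' @param spacing_low_priority,spacing_high_priority see
#'   [thin_by_distance()].
#' @return list: `decisions` data.frame (`snp_id`, `priority`,
#'   `retained_after_thinning`, `duplicate_of`, `exclusion_reason`),
#'   `counts` summary.
#' @export
design_panel <- function(cand, min_maf_sg = p3_maf_cutoff(),
                         spacing_low_priority = 1000L,
                         spacing_high_priority = 100L) {
  dd <- deduplicate(cand)
  pri <- assign_priority(cand, min_maf_sg = min_maf_sg)
  pri[!dd$keep] <- 0L
  cand2 <- cand
  cand2$priority <- pri
  ret <- thin_by_distance(cand2, spacing_low_priority, spacing_high_priority)
  reason <- rep(NA_character_, nrow(cand))
  reason[!dd$keep] <- "duplicate"
  reason[dd$keep & pri == 0L] <- "priority_zero"
  reason[dd$keep & pri > 0L & !ret] <- "thinned"
  decisions <- data.frame(snp_id = cand$snp_id, priority = pri,
                          retained_after_thinning = ret,
                          duplicate_of = dd$duplicate_of,
                          exclusion_reason = reason,
                          stringsAsFactors = FALSE)
  counts <- list(input = nrow(cand), duplicates_removed = sum(!dd$keep),
                 per_priority = table(factor(pri[dd$keep], levels = 0:7)),
                 priority_zero = sum(pri[dd$keep] == 0L),
                 thinned = sum(dd$keep & pri > 0L & !ret),
                 panel_size = sum(ret))
  list(decisions = decisions, counts = counts)
}
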