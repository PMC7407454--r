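test_that("discovery filters mask by depth then drop by MAF and call rate", {
  # 10 samples x 3 loci; locus 1 loses one call to low depth but stays,
  # locus 2 fails MAF, locus 3 fails call rate
  g <- cbind(rep(c(0L, 1L), 5), c(1L, rep(0L, 9)), c(rep(0L, 4), 1L, rep(NA, 5)))
  dp <- matrix(10, 10, 3)
  dp[1, 1] <- 4   # below min_dp -> masked
  g[2, 2] <- 0L   # MAF of locus 2 = 1/20 = 0.05 without the het; force below
  x <- make_gm(g)
  x$dp <- dp
  res <- apply_discovery_filters(x)
  expect_equal(res$counts$genotypes_masked_depth, 1L)
  # locus 1: 9/10 called, MAF ~ 4/18 -> kept
  expect_true("s0001" %in% res$matrix$loci$snp_id)
  # locus 2: MAF = 1/20 = 0.05 -> kept at threshold? it is 0.05 -> not below
  # locus 3: call rate 0.5 < 0.6 -> dropped
  expect_false("s0003" %in% res$matrix$loci$snp_id)
  expect_equal(res$counts$dropped_callrate, 1L)

  # MAF 0.04 is below 0.05 and dropped
  g2 <- cbind(c(rep(0L, 23), 1L, 0L), rep(c(0L, 1L), length.out = 25))
  x2 <- make_gm(g2)
  x2$dp <- matrix(10, 25, 2)
  res2 <- apply_discovery_filters(x2)
  expect_equal(res2$counts$dropped_maf, 1L)
  expect_false("s0001" %in% res2$matrix$loci$snp_id)

  # absent depth table skips that stage with a warning
  expect_warning(res3 <- apply_discovery_filters(make_gm(g2)), "depth")
  expect_true(res3$counts$depth_skipped)
})

test_that("flank sufficiency requires 35 bp on both sides", {
  cand <- data.frame(left_len = c(35L, 34L, 0L, 100L),
                     right_len = c(35L, 100L, 0L, 35L))
  expect_equal(check_flanks(cand), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("unique-complete mapping requires one hit spanning the full probe", {
  cand <- data.frame(snp_id = c("a", "b", "c"), probe_length = 71L)
  mapping <- data.frame(snp_id = c("a", "b", "c"),
                        n_mappings = c(1L, 1L, 2L),
                        top_alignment_length = c(71L, 70L, 71L))
  out <- annotate_mapping(cand, mapping)
  expect_equal(out$unique_complete, c(TRUE, FALSE, FALSE))
})

test_that("secondary-SNP detection uses exact flank boundaries", {
  cand <- data.frame(snp_id = c("a", "b"), scaffold = "sc1",
                     pos_bp = c(100L, 110L), left_len = 35L, right_len = 35L)
  expect_equal(detect_secondary_snps(cand), c(TRUE, TRUE))
  cand$pos_bp <- c(100L, 136L)  # 36 bp apart, just outside the 35 bp flank
  expect_equal(detect_secondary_snps(cand), c(FALSE, FALSE))
  cand$pos_bp <- c(100L, 135L)  # exactly at the boundary -> inside
  expect_equal(detect_secondary_snps(cand), c(TRUE, TRUE))
  single <- cand[1, ]
  expect_equal(detect_secondary_snps(single), FALSE)
})

base_cand <- function(...) {
  d <- data.frame(snp_id = "x", scaffold = "sc1", pos_bp = 1000L,
                  source = "rad", affy_forward = "recommended",
                  affy_reverse = "not_recommended", n_mappings = 1L,
                  top_alignment_length = 71L, probe_length = 71L,
                  is_at_or_cg = FALSE, maf_south_georgia = 0.25,
                  prevalidated = FALSE, unique_complete = TRUE,
                  has_secondary_snp_in_flank = FALSE,
                  stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) d[[nm]] <- mods[[nm]]
  d
}

test_that("priority cascade matches the seven-tier rules", {
  expect_equal(assign_priority(base_cand()), 1L)
  # MHC SNPs are priority one regardless of design scores or mapping
  expect_equal(assign_priority(base_cand(
    source = "mhc", affy_forward = "not_recommended",
    affy_reverse = "not_recommended", unique_complete = FALSE,
    prevalidated = TRUE)), 1L)
  # neutral + unique + no secondary -> 2; with a secondary SNP falls to 7
  p2 <- base_cand(affy_forward = "neutral")
  expect_equal(assign_priority(p2), 2L)
  p2sec <- base_cand(affy_forward = "neutral",
                     has_secondary_snp_in_flank = TRUE)
  expect_equal(assign_priority(p2sec), 7L)
  # transcriptomic neutral with 3 mappings matches nothing
  expect_equal(assign_priority(base_cand(
    source = "transcriptomic", affy_forward = "neutral",
    n_mappings = 3L, unique_complete = FALSE)), 0L)
  # recommended RAD, 2 mappings, MAF below the cutoff -> 4 not 3
  expect_equal(assign_priority(base_cand(
    n_mappings = 2L, unique_complete = FALSE, maf_south_georgia = 0.01)), 4L)
  expect_equal(assign_priority(base_cand(
    n_mappings = 2L, unique_complete = FALSE, maf_south_georgia = 0.017)), 3L)
  # A/T SNPs only qualify through priority 5
  expect_equal(assign_priority(base_cand(is_at_or_cg = TRUE)), 5L)
  # unknown recommendation fails both the recommended and neutral tests
  expect_equal(assign_priority(base_cand(
    affy_forward = "unknown", affy_reverse = "unknown")), 0L)
})

test_that("priorities are order-invariant and monotone in quality", {
  sim <- simulate_candidate_table(n_per_class = 25L, seed = 5L)
  cand <- sim$candidates
  p1 <- assign_priority(cand)
  perm <- sample(nrow(cand))
  p2 <- assign_priority(cand[perm, ])
  expect_equal(p2, p1[perm])
  # upgrading neutral -> recommended never worsens a nonzero priority
  upgraded <- cand
  upgraded$affy_forward[upgraded$affy_forward == "neutral"] <- "recommended"
  p3 <- assign_priority(upgraded)
  nz <- p1 > 0L & p3 > 0L
  expect_true(all(p3[nz] <= p1[nz]))
})

test_that("distance thinning honours the class-specific spacing rules", {
  two <- function(pos, priority, source = "rad") {
    data.frame(snp_id = c("a", "b"), scaffold = "sc1", pos_bp = pos,
               source = source, priority = priority,
               maf_south_georgia = c(0.4, 0.3), stringsAsFactors = FALSE)
  }
  # two P1 SNPs 50 bp apart: one dropped
  expect_equal(sum(thin_by_distance(two(c(1000L, 1050L), 1L))), 1L)
  # 100 bp apart satisfies the high-priority rule
  expect_equal(sum(thin_by_distance(two(c(1000L, 1100L), 1L))), 2L)
  # two P3 RAD SNPs 500 bp apart: one dropped (1 kb rule)
  expect_equal(sum(thin_by_distance(two(c(1000L, 1500L), 3L))), 1L)
  expect_equal(sum(thin_by_distance(two(c(1000L, 2000L), 3L))), 2L)
  # P1 retained first; P3 500 bp away violates its own 1 kb rule cross-class
  mix <- two(c(1000L, 1500L), c(1L, 3L))
  ret <- thin_by_distance(mix)
  expect_true(ret[1])
  expect_false(ret[2])
  # retained set always satisfies both constraints (exhaustive check)
  sim <- simulate_candidate_table(n_per_class = 30L, seed = 8L)
  cand <- sim$candidates
  cand$priority <- assign_priority(cand)
  # compress positions to force conflicts
  cand$pos_bp <- as.integer(200L * (seq_len(nrow(cand)) %/% 20L + 1L))
  ret <- thin_by_distance(cand)
  kept <- cand[ret, ]
  for (scaf in unique(kept$scaffold)) {
    k <- kept[kept$scaffold == scaf, ]
    if (nrow(k) < 2) next
    d <- as.matrix(dist(k$pos_bp)); diag(d) <- Inf
    mind <- apply(d, 1, min)
    need <- ifelse(k$priority <= 2L, 100, ifelse(k$source == "rad", 1000, 0))
    expect_true(all(mind >= need))
  }
})

test_that("deduplication keeps one record per site with source preference", {
  cand <- data.frame(
    snp_id = c("rad1", "tx1", "pre1", "tx2", "rad9"),
    scaffold = c("sc1", "sc1", "sc2", "sc2", "sc3"),
    pos_bp = c(500L, 500L, 900L, 900L, 100L),
    source = c("rad", "transcriptomic", "prevalidated_canine",
               "transcriptomic", "rad"),
    prevalidated = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  dd <- deduplicate(cand)
  expect_equal(dd$keep, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(dd$duplicate_of[2], "rad1")
  expect_equal(dd$duplicate_of[4], "pre1")
  # no duplicates -> identity
  solo <- cand[c(1, 3, 5), ]
  expect_true(all(deduplicate(solo)$keep))
  # three-way duplicate -> one survivor
  tri <- cand[c(1, 1, 1), ]
  tri$snp_id <- c("b", "a", "c")
  ddt <- deduplicate(tri)
  expect_equal(sum(ddt$keep), 1L)
  expect_equal(tri$snp_id[ddt$keep], "a")
})

test_that("planted candidate classes are recovered exactly end to end", {
  sim <- simulate_candidate_table(n_per_class = 100L, seed = 2L)
  p <- assign_priority(sim$candidates)
  expect_equal(p, sim$truth_priority)
  # planted duplicates collapse to the planted count
  cand <- sim$candidates
  dup <- cand[1:10, ]
  dup$snp_id <- paste0(dup$snp_id, "_dup")
  dup$source <- "transcriptomic"
  both <- rbind(cand, dup)
  dd <- deduplicate(both)
  expect_equal(sum(!dd$keep), 10L)
  expect_true(all(grepl("_dup", both$snp_id[!dd$keep])))
  # planted 50 bp-spaced priority-one pairs: thinning removes one per pair
  pairs <- cand[cand$n_mappings == 1L & !cand$is_at_or_cg &
                  cand$affy_forward == "recommended", ][1:20, ]
  pairs$scaffold <- rep(sprintf("thin%02d", 1:10), each = 2)
  pairs$pos_bp <- rep(c(5000L, 5050L), 10)
  pairs$priority <- assign_priority(pairs)
  expect_true(all(pairs$priority == 1L))
  ret <- thin_by_distance(pairs)
  expect_equal(sum(ret), 10L)
  expect_equal(as.vector(table(pairs$scaffold[ret])), rep(1L, 10))
})

test_that("the full design chain reports consistent stage counts", {
  sim <- simulate_candidate_table(n_per_class = 40L, seed = 3L)
  res <- design_panel(sim$candidates)
  d <- res$decisions
  expect_equal(nrow(d), nrow(sim$candidates))
  expect_equal(sum(d$priority == 0L & d$retained_after_thinning), 0L)
  expect_equal(res$counts$panel_size, sum(d$retained_after_thinning))
  expect_equal(res$counts$input - res$counts$duplicates_removed -
                 res$counts$priority_zero - res$counts$thinned,
               res$counts$panel_size)
})
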