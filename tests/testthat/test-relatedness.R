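test_that("VIF pruning removes collinear loci and leaves orthogonal ones", {
  # orthogonal dosage vectors: nothing removed
  z <- cbind(c(0, 0, 1, 1, 2, 2), c(0, 1, 0, 2, 1, 2), c(2, 0, 1, 1, 0, 2))
  expect_equal(ld_prune_vif(z, window = 3, step = 1), 1:3)
  # an exactly duplicated locus: one copy removed
  set.seed(81)
  g <- matrix(rbinom(40 * 10, 2, 0.4), 40, 10)
  g[, 7] <- g[, 3]
  kept <- ld_prune_vif(g, window = 10, step = 5)
  expect_equal(length(kept), 9L)
  expect_true(xor(3 %in% kept, 7 %in% kept))
  # crafted l3 ~ l1 + l2 (a few flips): highest VIF by direct linear
  # algebra, removed first; l1 and l2 then fall below the threshold
  set.seed(82)
  l1 <- rbinom(60, 1, 0.5); l2 <- rbinom(60, 1, 0.5)
  l3 <- l1 + l2
  flip <- sample(60, 6)
  l3[flip] <- pmin(pmax(l3[flip] + sample(c(-1, 1), 6, TRUE), 0), 2)
  w <- cbind(l1, l2, l3)
  vifs <- sapply(1:3, function(j) {
    r2 <- summary(lm(w[, j] ~ w[, -j]))$r.squared
    1 / (1 - r2)
  })
  expect_equal(which.max(vifs), 3L)
  expect_gt(max(vifs), 2)
  kept3 <- ld_prune_vif(w, window = 3, step = 1)
  expect_equal(kept3, c(1L, 2L))
  # final state: recomputing VIF over every window gives max <= 2 + 1e-9
  set.seed(83)
  n <- 80L; L <- 60L
  base <- matrix(rbinom(n * L, 2, 0.4), n, L)
  for (j in seq(5, L, by = 7)) base[, j] <- pmin(base[, j - 1] +
                                                   rbinom(n, 1, 0.2), 2)
  kept4 <- ld_prune_vif(base, window = 20, step = 5)
  zz <- apply(base[, kept4, drop = FALSE], 2, function(cl) cl)
  for (s in seq(1, length(kept4), by = 5)) {
    win <- s:min(s + 19, length(kept4))
    if (length(win) < 2) next
    for (j in win) {
      r2 <- summary(lm(zz[, j] ~ zz[, setdiff(win, j), drop = FALSE]))$r.squared
      expect_lte(1 / (1 - r2), 2 + 1e-9)
    }
  }
})

test_that("informative subset applies the MAF 0.3 and call-rate bounds", {
  st <- data.frame(snp_id = c("a", "b", "c", "d"),
                   maf = c(0.29, 0.5, 0.35, 0.35),
                   call_rate = c(1, 0.89, 1, 1),
                   hwe_p = c(0.5, 0.5, 0.0005, 0.5))
  expect_equal(informative_subset(st), "d")
  st2 <- data.frame(snp_id = "e", maf = 0.3, call_rate = 0.9, hwe_p = 0.001)
  expect_equal(informative_subset(st2), "e")  # bounds are inclusive
})

test_that("nine-cell counts match a manual tally and transpose symmetry", {
  g <- rbind(c(0L, 1L, 2L, 1L, NA, 0L),
             c(1L, 1L, 2L, 0L, 2L, NA))
  x <- make_gm(g)
  pc <- pair_counts(x, "ind001", "ind002")
  expect_equal(pc$n_used, 4L)
  expect_equal(pc$n["0", "1"], 1L)
  expect_equal(pc$n["1", "1"], 1L)
  expect_equal(pc$n["2", "2"], 1L)
  expect_equal(pc$n["1", "0"], 1L)
  pc2 <- pair_counts(x, "ind002", "ind001")
  expect_equal(pc2$n, t(pc$n))
  # identical samples: off-diagonal zero
  xx <- make_gm(rbind(g[1, ], g[1, ]))
  pid <- pair_counts(xx, "ind001", "ind002")
  expect_equal(sum(pid$n) - sum(diag(pid$n)), 0L)
})

test_that("allele-sharing statistics follow the KING-robust formulas", {
  # duplicates without error: kinship 0.5, r0 = 0, r1 undefined
  n <- matrix(0L, 3, 3); diag(n) <- c(40L, 30L, 30L)
  s <- allele_sharing_stats(list(n = n))
  expect_equal(s$kinship, 0.5)
  expect_equal(s$r0, 0)
  expect_true(is.na(s$r1))
  # arithmetic case: HETHET 30, IBS0 10, HET_a = HET_b = 50
  n2 <- matrix(0L, 3, 3)
  n2[2, 2] <- 30L; n2[1, 3] <- 5L; n2[3, 1] <- 5L
  n2[2, 1] <- 12L; n2[2, 3] <- 8L   # a het elsewhere: 30+12+8 = 50
  n2[1, 2] <- 9L; n2[3, 2] <- 11L   # b het: 30+9+11 = 50
  s2 <- allele_sharing_stats(list(n = n2))
  expect_equal(s2$kinship, (30 - 20) / 100)
  expect_equal(s2$r0, 1 / 3)
  expect_equal(s2$r1, 30 / (10 + 12 + 8 + 9 + 11))
})

test_that("unrelated and parent-offspring pairs match analytic expectations", {
  set.seed(84)
  L <- 10000L
  freq <- runif(L, 0.3, 0.5)
  unrel <- rbind(rbinom(L, 2, freq), rbinom(L, 2, freq))
  x <- make_gm(unrel)
  s <- allele_sharing_stats(pair_counts(x, "ind001", "ind002"))
  # E[IBS0] = 2 p^2 q^2 and E[HETHET] = 4 p^2 q^2 per locus -> r0 ~ 0.5
  expect_equal(s$r0, 0.5, tolerance = 0.05)
  expect_equal(s$kinship, 0, tolerance = 0.02)
  # parent-offspring: child inherits one allele from the parent
  parent <- rbinom(L, 2, freq)
  from_parent <- ifelse(parent == 1L, rbinom(L, 1, 0.5), parent / 2)
  child <- as.integer(from_parent + rbinom(L, 1, freq))
  po <- make_gm(rbind(parent, child))
  spo <- allele_sharing_stats(pair_counts(po, "ind001", "ind002"))
  expect_equal(spo$kinship, 0.25, tolerance = 0.02)
  expect_equal(pair_counts(po, "ind001", "ind002")$n[1, 3], 0L)
})

test_that("method-of-moments IBD solves the hand-evaluated toy exactly", {
  # two individuals, genotypes at 4 loci with frequencies estimated from
  # n_called = 10 individuals; hand evaluation of the moment equations
  ga <- c(0L, 1L, 2L, 1L)
  gb <- c(0L, 1L, 2L, 0L)
  freqs <- c(0.5, 0.4, 0.3, 0.5)
  n_called <- rep(10L, 4)
  got <- sealpanel:::mom_ibd_pair(ga, gb, freqs, n_called)
  # independent evaluation written out longhand
  T <- 2 * n_called; X <- round(freqs * T); Y <- T - X
  d4 <- T * (T - 1) * (T - 2) * (T - 3); d3 <- T * (T - 1) * (T - 2)
  e00 <- 2 * X * (X - 1) * Y * (Y - 1) / d4
  e10 <- 4 * X * (X - 1) * (X - 2) * Y / d4 + 4 * X * Y * (Y - 1) * (Y - 2) / d4
  e20 <- X * (X - 1) * (X - 2) * (X - 3) / d4 + Y * (Y - 1) * (Y - 2) * (Y - 3) / d4 +
    4 * X * (X - 1) * Y * (Y - 1) / d4
  e11 <- 2 * X * (X - 1) * Y / d3 + 2 * X * Y * (Y - 1) / d3
  e21 <- X * (X - 1) * (X - 2) / d3 + Y * (Y - 1) * (Y - 2) / d3 +
    X * (X - 1) * Y / d3 + X * Y * (Y - 1) / d3
  O0 <- 0; O1 <- 1; O2 <- 3
  z0 <- O0 / sum(e00)
  z1 <- (O1 - z0 * sum(e10)) / sum(e11)
  z2 <- (O2 - z0 * sum(e20) - z1 * sum(e21)) / 4
  z <- pmax(c(z0, z1, z2), 0); z <- z / sum(z)
  expect_equal(unname(got), c(z, z[3] + z[2] / 2), tolerance = 1e-12)
  # identical genotype vectors -> z2 ~ 1, pi_hat ~ 1
  set.seed(85)
  L <- 2000L
  freq <- runif(L, 0.3, 0.5)
  gg <- rbinom(L, 2, freq)
  dup <- make_gm(rbind(gg, gg, rbinom(L, 2, freq)))
  got2 <- mom_ibd(dup, "ind001", "ind002")
  expect_gt(got2["z2"], 0.95)
  expect_gt(got2["pi_hat"], 0.95)
})

test_that("simulated parent-offspring pairs recover z = (0, 1, 0)", {
  cfg <- sim_config(n_snps = 5000L, n_scaffolds = 10L,
                    maf_range = c(0.3, 0.5),
                    genotype_error_rate = 0, missing_rate = 0)
  col <- simulate_colony(n_total = 30L, n_mo = 10L, n_hs = 0L,
                         n_halfsib_matings = 0L, n_fullsib_matings = 0L,
                         n_unknown_mothers = 0L, n_false_mother_links = 0L,
                         config = cfg, seed = 86L)
  x <- col$matrix
  po <- col$truth$pairs[col$truth$pairs$category == "parent_offspring", ]
  for (k in seq_len(nrow(po))) {
    pc <- pair_counts(x, po$id_a[k], po$id_b[k])
    expect_equal(pc$n[1, 3] + pc$n[3, 1], 0L)  # IBS0 = 0 without error
    z <- mom_ibd(x, po$id_a[k], po$id_b[k])
    expect_equal(unname(z["z1"]), 1, tolerance = 0.05)
    expect_equal(unname(z["pi_hat"]), 0.5, tolerance = 0.05)
  }
})

test_that("classification matches theoretical points and flags near-bound
           calls", {
  tab <- default_threshold_table()
  po <- classify_relationship(c(z0 = 0, z1 = 1, z2 = 0, pi_hat = 0.5), tab)
  expect_equal(po$category, "parent_offspring")
  expect_false(po$difficult)
  fs <- classify_relationship(c(z0 = 0.25, z1 = 0.5, z2 = 0.25, pi_hat = 0.5),
                              tab)
  expect_equal(fs$category, "full_sib")
  un <- classify_relationship(c(z0 = 1, z1 = 0, z2 = 0, pi_hat = 0), tab)
  expect_equal(un$category, "unrelated")
  # 0.005 inside the second-degree lower pi bound: assigned and difficult
  nd <- classify_relationship(c(z0 = 0.6, z1 = 0.3, z2 = 0.1,
                                pi_hat = 0.177 + 0.005), tab)
  expect_equal(nd$category, "second_degree")
  expect_true(nd$difficult)
  # far from every interior bound: not difficult
  mid <- classify_relationship(c(z0 = 0.55, z1 = 0.4, z2 = 0.05,
                                 pi_hat = 0.25), tab)
  expect_equal(mid$category, "second_degree")
  expect_false(mid$difficult)
  # nothing matches -> unknown, never difficult
  uk <- classify_relationship(c(z0 = 0.2, z1 = 0.1, z2 = 0.7, pi_hat = 0.75),
                              tab)
  expect_equal(uk$category, "unknown")
  expect_false(uk$difficult)
})

test_that("pairwise engine is symmetric and classifies pedigree classes", {
  cfg <- sim_config(n_snps = 6000L, n_scaffolds = 10L,
                    maf_range = c(0.32, 0.5),
                    genotype_error_rate = 0.002, missing_rate = 0.005)
  ped <- build_pedigree(n_po = 15L, n_fs = 15L, n_hs = 15L,
                        n_unrelated = 15L)
  founders <- simulate_founders(sum(is.na(ped$pedigree$mother)), cfg,
                                seed = 87L)
  sim <- gene_drop(ped$pedigree, founders, cfg, seed = 88L)
  x <- apply_error_missingness(sim_genotypes(sim, ped$sampled),
                               cfg$genotype_error_rate, cfg$missing_rate, 89L)
  st <- locus_stats(x)
  x <- subset_geno(x, loci = informative_subset(st))
  pr <- relatedness_pairs(x)
  # symmetry: recompute one pair with the ids swapped
  one <- pr[1, ]
  pc_ab <- allele_sharing_stats(pair_counts(x, one$id_a, one$id_b))
  pc_ba <- allele_sharing_stats(pair_counts(x, one$id_b, one$id_a))
  expect_equal(pc_ab$kinship, pc_ba$kinship)
  expect_equal(pc_ab$kinship, one$kinship, tolerance = 1e-12)
  z_ab <- mom_ibd(x, one$id_a, one$id_b)
  z_ba <- mom_ibd(x, one$id_b, one$id_a)
  expect_equal(z_ab, z_ba)
  # z's sum to one and pi_hat stays in range
  expect_equal(pr$z0 + pr$z1 + pr$z2, rep(1, nrow(pr)), tolerance = 1e-9)
  expect_true(all(pr$pi_hat >= 0 & pr$pi_hat <= 1))
  expect_equal(pr$pi_hat, pr$z2 + pr$z1 / 2, tolerance = 1e-12)
  # accuracy per designed class
  key <- paste(pmin(pr$id_a, pr$id_b), pmax(pr$id_a, pr$id_b))
  tkey <- paste(pmin(ped$pairs$id_a, ped$pairs$id_b),
                pmax(ped$pairs$id_a, ped$pairs$id_b))
  hit <- match(tkey, key)
  got <- pr$category[hit]
  acc <- function(cl) mean(got[ped$pairs$category == cl] == cl)
  expect_gte(acc("parent_offspring"), 0.95)
  expect_gte(acc("unrelated"), 0.95)
  expect_gte(acc("second_degree"), 0.8)
})

test_that("maternal-link audit separates confirmed, novel and contradicted", {
  calls <- data.frame(
    id_a = c("mumA", "mumB", "pupX", "mumD"),
    id_b = c("pupA", "pupB", "pupY", "pupD"),
    category = c("parent_offspring", "unrelated", "parent_offspring",
                 "second_degree"),
    stringsAsFactors = FALSE)
  md <- data.frame(
    sample_id = c("mumA", "pupA", "mumB", "pupB", "pupX", "pupY",
                  "mumD", "pupD"),
    known_mother_id = c(NA, "mumA", NA, "mumB", NA, NA, NA, "mumD"),
    stringsAsFactors = FALSE)
  aud <- known_pair_audit(calls, md)
  expect_equal(aud$confirmed$sample_id, "pupA")
  expect_equal(aud$novel$id_a, "pupX")
  expect_setequal(aud$contradicted$sample_id, c("pupB", "pupD"))
  # no metadata links: every PO call is novel
  md0 <- md; md0$known_mother_id <- NA_character_
  aud0 <- known_pair_audit(calls, md0)
  expect_equal(nrow(aud0$novel), 2L)
  expect_equal(nrow(aud0$confirmed), 0L)
  # perfect records: nothing novel or contradicted
  calls2 <- calls[c(1, 4), ]
  calls2$category <- "parent_offspring"
  md2 <- md[md$sample_id %in% c("mumA", "pupA", "mumD", "pupD"), ]
  aud2 <- known_pair_audit(calls2, md2)
  expect_equal(nrow(aud2$novel), 0L)
  expect_equal(nrow(aud2$contradicted), 0L)
})
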