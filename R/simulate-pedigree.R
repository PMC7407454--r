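#' Build a designed pedigree with known relationship pairs
#'
#' Constructs disjoint family units per relationship class so that each
#' designed pair has its exact theoretical IBD expectation and all
#' cross-unit pairs are unrelated. Consanguineous matings (half-sib and
#' full-sib) produce individuals with pedigree F of 0.125 and 0.25.
#'
#' @param n_po mother-offspring pairs (mother and pup both in `sampled`).
#' @param n_fs full-sib pairs.
#' @param n_hs paternal half-sib pairs.
#' @param n_avuncular,n_grandparent,n_cousin further designed classes.
#' @param n_unrelated designated unrelated founder pairs.
#' @param n_halfsib_matings,n_fullsib_matings consanguineous matings; only
#'   the inbred offspring is marked for sampling.
#' @param n_extra_founders additional unrelated sampled founders.
#' @return list: `pedigree` (id, mother, father; parents precede children),
#'   `pairs` (id_a, id_b, category, detail), `sampled` ids, `mothers`
#'   (named vector pup -> true mother among sampled), `inbred`
#'   (id, pedigree_f).
#' @export
build_pedigree <- function(n_po = 0L, n_fs = 0L, n_hs = 0L,
                           n_avuncular = 0L, n_grandparent = 0L,
                           n_cousin = 0L, n_unrelated = 0L,
                           n_halfsib_matings = 0L, n_fullsib_matings = 0L,
                           n_extra_founders = 0L) {
  rows <- list(); pairs <- list(); sampled <- character()
  mothers <- character(); inbred <- list()
  cnt <- new.env(parent = emptyenv()); cnt$f <- 0L; cnt$i <- 0L
  newf <- function(n = 1L) {
    ids <- sprintf("F%04d", cnt$f + seq_len(n)); cnt$f <- cnt$f + n
    for (id in ids) rows[[length(rows) + 1L]] <<-
      data.frame(id = id, mother = NA_character_, father = NA_character_)
    ids
  }
  newi <- function(mo, fa) {
    cnt$i <- cnt$i + 1L
    id <- sprintf("I%04d", cnt$i)
    rows[[length(rows) + 1L]] <<- data.frame(id = id, mother = mo, father = fa)
    id
  }
  addpair <- function(a, b, cat, detail) pairs[[length(pairs) + 1L]] <<-
    data.frame(id_a = a, id_b = b, category = cat, detail = detail)
  for (k in seq_len(n_po)) {
    p <- newf(2L); c1 <- newi(p[1], p[2])
    addpair(p[1], c1, "parent_offspring", "mother_offspring")
    sampled <- c(sampled, p[1], c1)
    mothers[c1] <- p[1]
  }
  for (k in seq_len(n_fs)) {
    p <- newf(2L); c1 <- newi(p[1], p[2]); c2 <- newi(p[1], p[2])
    addpair(c1, c2, "full_sib", "full_sib")
    sampled <- c(sampled, c1, c2)
  }
  for (k in seq_len(n_hs)) {
    m <- newf(2L); f <- newf(1L)
    c1 <- newi(m[1], f); c2 <- newi(m[2], f)
    addpair(c1, c2, "second_degree", "paternal_half_sib")
    sampled <- c(sampled, c1, c2)
  }
  for (k in seq_len(n_avuncular)) {
    p <- newf(2L); s1 <- newi(p[1], p[2]); s2 <- newi(p[1], p[2])
    e <- newf(1L); n1 <- newi(s2, e)
    addpair(s1, n1, "second_degree", "avuncular")
    sampled <- c(sampled, s1, n1)
  }
  for (k in seq_len(n_grandparent)) {
    p <- newf(2L); c1 <- newi(p[1], p[2])
    d <- newf(1L); e1 <- newi(c1, d)
    addpair(p[1], e1, "second_degree", "grandparent")
    sampled <- c(sampled, p[1], e1)
  }
  for (k in seq_len(n_cousin)) {
    p <- newf(2L); s1 <- newi(p[1], p[2]); s2 <- newi(p[1], p[2])
    e <- newf(2L); x1 <- newi(s1, e[1]); x2 <- newi(s2, e[2])
    addpair(x1, x2, "third_degree", "first_cousin")
    sampled <- c(sampled, x1, x2)
  }
  for (k in seq_len(n_unrelated)) {
    p <- newf(2L)
    addpair(p[1], p[2], "unrelated", "founder_pair")
    sampled <- c(sampled, p)
  }
  for (k in seq_len(n_halfsib_matings)) {
    m <- newf(2L); f <- newf(1L)
    h1 <- newi(m[1], f); h2 <- newi(m[2], f)
    i1 <- newi(h1, h2)
    inbred[[length(inbred) + 1L]] <- data.frame(id = i1, pedigree_f = 0.125)
    sampled <- c(sampled, i1)
  }
  for (k in seq_len(n_fullsib_matings)) {
    p <- newf(2L); s1 <- newi(p[1], p[2]); s2 <- newi(p[1], p[2])
    i1 <- newi(s1, s2)
    inbred[[length(inbred) + 1L]] <- data.frame(id = i1, pedigree_f = 0.25)
    sampled <- c(sampled, i1)
  }
  if (n_extra_founders > 0L) sampled <- c(sampled, newf(n_extra_founders))
  list(pedigree = do.call(rbind, rows),
       pairs = if (length(pairs)) do.call(rbind, pairs) else NULL,
       sampled = sampled, mothers = mothers,
       inbred = if (length(inbred)) do.call(rbind, inbred) else NULL)
}

#' Simulate a genotyped breeding colony with ground truth
#'
#' End-to-end dataset emulating the structure of a monitored breeding
#' colony: mother-offspring pairs, paternal half-sibs, inbred individuals
#' from consanguineous matings and unrelated animals, genotyped with error
#' and missingness. Field records (`known_mother_id`) are generated with a
#' configurable number of unrecorded true mothers and planted false links.
#'
#' @param n_total total genotyped individuals (default 270).
#' @param n_mo mother-offspring pairs (default 53).
#' @param n_hs paternal half-sib pairs (default 4).
#' @param n_halfsib_matings,n_fullsib_matings consanguineous matings
#'   (defaults 3 and 2).
#' @param n_unknown_mothers true maternal links left out of the field
#'   records (default 3).
#' @param n_false_mother_links planted wrong maternal assignments
#'   (default 3).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param replicate_triplicate when TRUE, the first sample is genotyped
#'   three times (two extra entries with independent noise), mirroring an
#'   on-plate positive control.
#' @return list: `matrix` (observed [geno_matrix()]), `metadata`,
#'   `truth` (designed pairs, true mothers, false links, inbred ids,
#'   realized inbreeding), `sim` (the underlying [gene_drop()]).
#' @export
simulate_colony <- function(n_total = 270L, n_mo = 53L, n_hs = 4L,
                            n_halfsib_matings = 3L, n_fullsib_matings = 2L,
                            n_unknown_mothers = 3L, n_false_mother_links = 3L,
                            config = sim_config(), seed = 1L,
                            replicate_triplicate = FALSE) {
  base <- 2L * n_mo + 2L * n_hs + n_halfsib_matings + n_fullsib_matings
  if (n_total < base + n_false_mother_links)
    stop("n_total too small for the requested family structure")
  ped <- build_pedigree(n_po = n_mo, n_hs = n_hs,
                        n_halfsib_matings = n_halfsib_matings,
                        n_fullsib_matings = n_fullsib_matings,
                        n_extra_founders = n_total - base)
  n_founders <- sum(is.na(ped$pedigree$mother))
  founders <- simulate_founders(n_founders, config, seed = seed)
  sim <- gene_drop(ped$pedigree, founders, config, seed = seed + 1L)
  clean <- sim_genotypes(sim, ids = ped$sampled)
  samples <- clean$samples
  if (replicate_triplicate) {
    rep_src <- samples$sample_id[1L]
    rep_ids <- paste0(rep_src, c("_rep1", "_rep2"))
    g <- rbind(clean$geno, clean$geno[1L, ], clean$geno[1L, ])
    samples <- rbind(samples, data.frame(sample_id = rep_ids))
    clean <- geno_matrix(g, clean$loci, samples)
  }
  obs <- apply_error_missingness(clean, config$genotype_error_rate,
                                 config$missing_rate, seed = seed + 2L)
  set.seed(seed + 3L)
  ids <- samples$sample_id
  pups <- names(ped$mothers)
  known_mother <- rep(NA_character_, length(ids))
  names(known_mother) <- ids
  recorded <- pups
  if (n_unknown_mothers > 0L)
    recorded <- setdiff(pups, sample(pups, min(n_unknown_mothers, length(pups))))
  known_mother[recorded] <- ped$mothers[recorded]
  # plant false links: extra founders credited with motherhood of non-offspring
  extra <- setdiff(ids, c(pups, ped$mothers, grep("_rep", ids, value = TRUE)))
  false_links <- character(0)
  if (n_false_mother_links > 0L && length(extra) >= 2L * n_false_mother_links) {
    pick <- sample(extra, 2L * n_false_mother_links)
    fake_child <- pick[seq_len(n_false_mother_links)]
    fake_mother <- pick[n_false_mother_links + seq_len(n_false_mother_links)]
    known_mother[fake_child] <- fake_mother
    false_links <- fake_child
  }
  metadata <- data.frame(
    sample_id = ids,
    population = "colony",
    birth_year = sample(1984:2016, length(ids), replace = TRUE),
    is_pup = ids %in% pups,
    is_replicate_of = ifelse(grepl("_rep", ids),
                             sub("_rep[0-9]+$", "", ids), NA_character_),
    dish_qc = round(stats::runif(length(ids), 0.88, 0.99), 3),
    dna_conc_ng_ul = round(stats::runif(length(ids), 40, 120), 1),
    known_mother_id = unname(known_mother[ids]),
    stringsAsFactors = FALSE)
  truth <- list(pairs = ped$pairs, mothers = ped$mothers,
                false_mother_links = false_links,
                unrecorded_mothers = setdiff(pups, recorded),
                inbred = ped$inbred,
                f_realized = realized_inbreeding(sim, ids = ped$sampled))
  list(matrix = obs, metadata = metadata, truth = truth, sim = sim)
}

#' Simulate a candidate-SNP table with planted priority classes
#'
#' Generates candidates whose attributes force a known priority class by
#' construction (one sub-population per class 1-7 plus class 0), widely
#' spaced so that neither secondary-SNP detection nor thinning interferes.
#' Used to verify the prioritisation cascade end to end.
#'
#' @param n_per_class candidates per class (default 100).
#' @param seed integer seed (controls id shuffling).
#' @return list: `candidates` (table accepted by [assign_priority()]),
#'   `truth_priority` (integer vector of planted classes).
#' @export
simulate_candidate_table <- function(n_per_class = 100L, seed = 1L) {
  set.seed(seed)
  cls <- function(priority, source, fwd, rev, n_map, at_cg, maf, preval) {
    data.frame(priority = priority, source = source, affy_forward = fwd,
               affy_reverse = rev, n_mappings = n_map, is_at_or_cg = at_cg,
               maf_south_georgia = maf, prevalidated = preval,
               stringsAsFactors = FALSE)
  }
  spec <- rbind(
    cls(1L, "rad", "recommended", "neutral", 1L, FALSE, 0.25, FALSE),
    cls(2L, "rad", "neutral", "neutral", 1L, FALSE, 0.25, FALSE),
    cls(3L, "rad", "recommended", "not_recommended", 2L, FALSE, 0.30, FALSE),
    cls(4L, "rad", "not_recommended", "recommended", 3L, FALSE, 0.005, FALSE),
    cls(5L, "transcriptomic", "recommended", "neutral", 1L, TRUE, 0.20, FALSE),
    cls(6L, "rad", "neutral", "not_recommended", 2L, FALSE, 0.10, FALSE),
    cls(7L, "rad", "not_recommended", "neutral", 4L, FALSE, 0.10, FALSE),
    cls(0L, "transcriptomic", "neutral", "neutral", 3L, FALSE, 0.10, FALSE))
  n <- n_per_class * nrow(spec)
  rows <- spec[rep(seq_len(nrow(spec)), each = n_per_class), , drop = FALSE]
  ord <- sample.int(n)
  rows <- rows[ord, , drop = FALSE]
  alle <- ifelse(rows$is_at_or_cg, "T", "C")
  cand <- data.frame(
    snp_id = sprintf("cand%05d", seq_len(n)),
    scaffold = sprintf("scaf%02d", 1L + (seq_len(n) %% 20L)),
    pos_bp = 1e5L * (seq_len(n) %/% 20L + 1L),
    allele_a = "A", allele_b = alle,
    source = rows$source,
    left_len = 35L, right_len = 35L, probe_length = 71L,
    n_mappings = rows$n_mappings,
    top_alignment_length = 71L,
    affy_forward = rows$affy_forward, affy_reverse = rows$affy_reverse,
    is_at_or_cg = rows$is_at_or_cg,
    maf_south_georgia = rows$maf_south_georgia,
    prevalidated = rows$prevalidated,
    stringsAsFactors = FALSE)
  cand$unique_complete <- cand$n_mappings == 1L &
    cand$top_alignment_length == cand$probe_length
  cand$flanks_sufficient <- check_flanks(cand)
  cand$has_secondary_snp_in_flank <- detect_secondary_snps(cand)
  list(candidates = cand, truth_priority = rows$priority)
}
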