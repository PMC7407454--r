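#' Simulation configuration
#'
#' Defaults emulate the study system: a 2.3 Gb genome in 20 scaffolds of
#' 115 Mb, array-scale SNP density, discovery-filtered allele frequencies
#' (MAF uniform on 0.05-0.5), a sex-averaged uniform recombination map of
#' 1 cM/Mb without interference, per-genotype error of 0.004 and ~0.5%
#' missing calls.
#'
#' @param n_scaffolds,scaffold_length_bp genome structure.
#' @param n_snps total SNP count, spread evenly across scaffolds.
#' @param maf_range uniform bounds for the simulated minor-allele (allele-b)
#'   frequency.
#' @param recomb_rate_cM_per_Mb recombination rate.
#' @param genotype_error_rate,missing_rate observation noise.
#' @param block_ld,block_size,pool_size optional block-LD founder mode:
#'   haplotypes are copied blockwise from a small pool, creating local LD.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_scaffolds = 20L, scaffold_length_bp = 115e6,
                       n_snps = 2000L, maf_range = c(0.05, 0.5),
                       recomb_rate_cM_per_Mb = 1.0,
                       genotype_error_rate = 0.004, missing_rate = 0.005,
                       block_ld = FALSE, block_size = 10L, pool_size = 4L) {
  stopifnot(n_snps >= 1L, scaffold_length_bp > 0,
            all(maf_range >= 0 & maf_range <= 0.5),
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(list(n_scaffolds = n_scaffolds,
                 scaffold_length_bp = scaffold_length_bp,
                 n_snps = n_snps, maf_range = maf_range,
                 recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
                 genotype_error_rate = genotype_error_rate,
                 missing_rate = missing_rate, block_ld = block_ld,
                 block_size = block_size, pool_size = pool_size),
            class = "sim_config")
}

#' Simulate founder haplotypes and a locus table
#'
#' Per-locus allele-b frequency is drawn from `maf_range`; founder
#' haplotypes carry independent Bernoulli draws per locus (linkage
#' equilibrium), or blockwise copies from a small haplotype pool in block-LD
#' mode. Every founder haplotype gets a unique integer label used for IBD
#' tracking.
#'
#' @param n_founders number of diploid founders.
#' @param config a [sim_config()].
#' @param seed integer seed (mandatory for reproducibility).
#' @return list: `loci` (locus table), `freq_b` (simulated allele-b
#'   frequency), `hap` (2*n_founders x L 0/1 matrix, rows are founder
#'   haplotypes labelled by row number).
#' @export
simulate_founders <- function(n_founders, config = sim_config(), seed = 1L) {
  set.seed(seed)
  L <- config$n_snps
  ns <- config$n_scaffolds
  per <- diff(round(seq(0, L, length.out = ns + 1)))
  scaffold <- rep(sprintf("scaf%02d", seq_len(ns)), per)
  pos <- unlist(lapply(per, function(k)
    sort(sample.int(config$scaffold_length_bp - 1L, k))), use.names = FALSE)
  loci <- data.frame(snp_id = sprintf("snp%06d", seq_len(L)),
                     scaffold = scaffold, pos_bp = as.integer(pos),
                     allele_a = "A", allele_b = "C", source = "rad",
                     stringsAsFactors = FALSE)
  freq_b <- stats::runif(L, config$maf_range[1], config$maf_range[2])
  nh <- 2L * n_founders
  if (!config$block_ld) {
    hap <- matrix(stats::rbinom(nh * L, 1L, rep(freq_b, each = nh)), nh, L)
  } else {
    hap <- matrix(0L, nh, L)
    start <- 1L
    while (start <= L) {
      end <- min(start + config$block_size - 1L, L)
      idx <- start:end
      pool <- matrix(stats::rbinom(config$pool_size * length(idx), 1L,
                                   rep(freq_b[idx], each = config$pool_size)),
                     config$pool_size, length(idx))
      pick <- sample.int(config$pool_size, nh, replace = TRUE)
      hap[, idx] <- pool[pick, , drop = FALSE]
      start <- end + 1L
    }
  }
  list(loci = loci, freq_b = freq_b, hap = hap)
}

#' Gene-drop a pedigree over founder haplotypes
#'
#' Transmits gametes down an acyclic pedigree (parents before children).
#' Each gamete draws a Poisson number of crossovers per scaffold (mean =
#' scaffold length in Mb times the map rate in Morgans/Mb), with uniform
#' positions and no interference, and alternates between the parent's two
#' haplotypes. Founder-haplotype labels are tracked both per locus and as
#' exact bp intervals, giving the true IBD structure.
#'
#' @param pedigree data.frame: `id`, `mother`, `father` (NA for founders),
#'   ordered so parents precede children.
#' @param founders output of [simulate_founders()]; founder haplotype rows
#'   are assigned to pedigree founders in order.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return object of class `gene_drop`: per-individual haplotypes
#'   (`alleles`, `labels`, `segs`), the locus table, frequencies and the
#'   pedigree. See [sim_genotypes()], [autozygous_segments()],
#'   [realized_inbreeding()], [true_ibd_pair()].
#' @export
gene_drop <- function(pedigree, founders, config = sim_config(), seed = 1L) {
  set.seed(seed)
  loci <- founders$loci
  scafs <- unique(loci$scaffold)
  loci_by_scaf <- lapply(scafs, function(s) which(loci$scaffold == s))
  names(loci_by_scaf) <- scafs
  founder_ids <- pedigree$id[is.na(pedigree$mother) & is.na(pedigree$father)]
  if (2L * length(founder_ids) > nrow(founders$hap))
    stop("not enough founder haplotypes for ", length(founder_ids), " founders")
  ind <- new.env(parent = emptyenv())
  nf <- 0L
  for (r in seq_len(nrow(pedigree))) {
    id <- pedigree$id[r]
    mo <- pedigree$mother[r]; fa <- pedigree$father[r]
    if (is.na(mo) != is.na(fa)) stop("individual ", id, " has one parent")
    if (is.na(mo)) {
      l1 <- 2L * nf + 1L; l2 <- 2L * nf + 2L
      nf <- nf + 1L
      segs <- data.frame(scaffold = scafs, start_bp = 1,
                         end_bp = config$scaffold_length_bp,
                         stringsAsFactors = FALSE)
      ind[[id]] <- list(
        h1 = list(alleles = founders$hap[l1, ], labels = rep(l1, nrow(loci)),
                  segs = cbind(segs, label = l1)),
        h2 = list(alleles = founders$hap[l2, ], labels = rep(l2, nrow(loci)),
                  segs = cbind(segs, label = l2)))
    } else {
      if (is.null(ind[[mo]]) || is.null(ind[[fa]]))
        stop("parents of ", id, " not simulated yet")
      ind[[id]] <- list(h1 = make_gamete(ind[[mo]], loci, loci_by_scaf, config),
                        h2 = make_gamete(ind[[fa]], loci, loci_by_scaf, config))
    }
  }
  structure(list(individuals = ind, ids = pedigree$id, loci = loci,
                 freq_b = founders$freq_b, pedigree = pedigree,
                 config = config),
            class = "gene_drop")
}

# one recombinant gamete from a parent's pair of haplotypes
make_gamete <- function(parent, loci, loci_by_scaf, config) {
  L <- nrow(loci)
  alleles <- integer(L)
  labels <- integer(L)
  segs <- list()
  morgans_per_bp <- config$recomb_rate_cM_per_Mb / 100 / 1e6
  for (scaf in names(loci_by_scaf)) {
    len <- config$scaffold_length_bp
    n_co <- stats::rpois(1L, len * morgans_per_bp)
    # integer crossover points: a cut at c separates bp c from bp c+1
    cuts <- sort(unique(floor(stats::runif(n_co, 1, len))))
    bounds <- c(0, cuts, len)
    cur <- sample(c("h1", "h2"), 1L)
    li <- loci_by_scaf[[scaf]]
    pos <- loci$pos_bp[li]
    for (k in seq_len(length(bounds) - 1L)) {
      a <- bounds[k] + 1; b <- bounds[k + 1L]
      src <- parent[[cur]]
      sel <- li[pos >= a & pos <= b]
      if (length(sel)) {
        alleles[sel] <- src$alleles[sel]
        labels[sel] <- src$labels[sel]
      }
      ss <- src$segs
      ss <- ss[ss$scaffold == scaf & ss$end_bp >= a & ss$start_bp <= b, ,
               drop = FALSE]
      if (nrow(ss)) {
        ss$start_bp <- pmax(ss$start_bp, a)
        ss$end_bp <- pmin(ss$end_bp, b)
        segs[[length(segs) + 1L]] <- ss
      }
      cur <- if (cur == "h1") "h2" else "h1"
    }
  }
  segs <- do.call(rbind, segs)
  # merge adjacent intervals with identical labels
  segs <- segs[order(segs$scaffold, segs$start_bp), , drop = FALSE]
  keep <- rep(TRUE, nrow(segs))
  for (k in seq_len(nrow(segs))[-1]) {
    if (segs$scaffold[k] == segs$scaffold[k - 1L] &&
        segs$label[k] == segs$label[k - 1L] &&
        segs$start_bp[k] <= segs$end_bp[k - 1L] + 1) {
      segs$start_bp[k] <- segs$start_bp[k - 1L]
      keep[k - 1L] <- FALSE
    }
  }
  list(alleles = alleles, labels = labels, segs = segs[keep, , drop = FALSE])
}

#' Genotype codes from a gene-drop
#'
#' @param sim a [gene_drop()] result.
#' @param ids individuals to include (default all).
#' @return A [geno_matrix()] of error-free genotypes (allele-b dosage).
#' @export
sim_genotypes <- function(sim, ids = NULL) {
  if (is.null(ids)) ids <- sim$ids
  g <- t(vapply(ids, function(id) {
    h <- sim$individuals[[id]]
    h$h1$alleles + h$h2$alleles
  }, integer(nrow(sim$loci))))
  geno_matrix(g, sim$loci,
              data.frame(sample_id = ids, stringsAsFactors = FALSE))
}

#' True autozygous segments of one individual
#'
#' Intervals where the two haplotypes carry the same founder label.
#'
#' @param sim a [gene_drop()] result.
#' @param id individual id.
#' @return data.frame: `scaffold`, `start_bp`, `end_bp`.
#' @export
autozygous_segments <- function(sim, id) {
  h <- sim$individuals[[id]]
  out <- list()
  s1 <- h$h1$segs; s2 <- h$h2$segs
  for (i in seq_len(nrow(s1))) for (j in seq_len(nrow(s2))) {
    if (s1$scaffold[i] != s2$scaffold[j]) next
    if (s1$label[i] != s2$label[j]) next
    a <- max(s1$start_bp[i], s2$start_bp[j])
    b <- min(s1$end_bp[i], s2$end_bp[j])
    if (a <= b)
      out[[length(out) + 1L]] <- data.frame(scaffold = s1$scaffold[i],
                                            start_bp = a, end_bp = b)
  }
  if (!length(out))
    return(data.frame(scaffold = character(), start_bp = numeric(),
                      end_bp = numeric()))
  res <- do.call(rbind, out)
  res[order(res$scaffold, res$start_bp), , drop = FALSE]
}

#' Realized inbreeding per individual
#'
#' Autozygous bp over total genome bp, from the tracked IBD labels.
#'
#' @param sim a [gene_drop()] result.
#' @param ids individuals (default all).
#' @return named numeric vector.
#' @export
realized_inbreeding <- function(sim, ids = NULL) {
  if (is.null(ids)) ids <- sim$ids
  genome <- sim$config$n_scaffolds * sim$config$scaffold_length_bp
  vapply(stats::setNames(ids, ids), function(id) {
    az <- autozygous_segments(sim, id)
    if (!nrow(az)) return(0)
    sum(az$end_bp - az$start_bp + 1) / genome
  }, numeric(1))
}

#' True pairwise IBD-sharing fractions
#'
#' Exact genome fractions where a pair shares 0, 1 or 2 founder haplotypes
#' identical by descent, from the tracked label intervals.
#'
#' @param sim a [gene_drop()] result.
#' @param id_a,id_b individual ids.
#' @return named vector: `z0`, `z1`, `z2`, `pi_hat`, `kinship`.
#' @export
true_ibd_pair <- function(sim, id_a, id_b) {
  A <- sim$individuals[[id_a]]; B <- sim$individuals[[id_b]]
  genome <- sim$config$n_scaffolds * sim$config$scaffold_length_bp
  shared <- c(0, 0, 0)
  for (scaf in unique(sim$loci$scaffold)) {
    tracks <- lapply(list(A$h1$segs, A$h2$segs, B$h1$segs, B$h2$segs),
                     function(s) s[s$scaffold == scaf, , drop = FALSE])
    cuts <- sort(unique(c(1, sim$config$scaffold_length_bp + 1,
                          unlist(lapply(tracks, function(s) c(s$start_bp, s$end_bp + 1))))))
    for (k in seq_len(length(cuts) - 1L)) {
      a <- cuts[k]; b <- cuts[k + 1L] - 1
      if (b < a) next
      lab <- vapply(tracks, function(s) {
        hit <- which(s$start_bp <= a & s$end_bp >= a)
        if (length(hit)) s$label[hit[1L]] else NA_integer_
      }, integer(1))
      la <- lab[1:2]; lb <- lab[3:4]
      m <- 0L
      for (u in unique(la[!is.na(la)]))
        m <- m + min(sum(la == u, na.rm = TRUE), sum(lb == u, na.rm = TRUE))
      m <- min(m, 2L)
      shared[m + 1L] <- shared[m + 1L] + (b - a + 1)
    }
  }
  z <- shared / genome
  # scaffolds without tracked segments cannot occur: founders span everything
  c(z0 = z[1], z1 = z[2], z2 = z[3], pi_hat = z[3] + z[2] / 2,
    kinship = z[3] / 2 + z[2] / 4)
}

#' Add genotyping error and missingness
#'
#' Each called genotype is independently replaced, with probability
#' `error_rate`, by one of the other two codes (uniformly), then set
#' missing with probability `missing_rate`.
#'
#' @param x a [geno_matrix()].
#' @param error_rate,missing_rate probabilities.
#' @param seed integer seed.
#' @return A `geno_matrix`.
#' @export
apply_error_missingness <- function(x, error_rate, missing_rate, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 1, missing_rate >= 0,
            missing_rate <= 1)
  set.seed(seed)
  g <- x$geno
  called <- which(!is.na(g))
  if (error_rate > 0 && length(called)) {
    flip <- called[stats::runif(length(called)) < error_rate]
    if (length(flip)) {
      old <- g[flip]
      shift <- sample(1:2, length(flip), replace = TRUE)
      g[flip] <- (old + shift) %% 3L
    }
  }
  if (missing_rate > 0 && length(called)) {
    drop <- called[stats::runif(length(called)) < missing_rate]
    g[drop] <- NA_integer_
  }
  geno_matrix(g, x$loci, x$samples, dp = x$dp)
}
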