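#' Read PLINK text PED/MAP files into a genotype matrix
#'
#' PED dialect: six leading columns (FID, IID, PAT, MAT, SEX, PHENO) followed
#' by one allele pair per locus, alleles coded as A/C/G/T with 0 for missing.
#' The first observed allele at each locus becomes `allele_a` unless the MAP
#' is accompanied by explicit alleles. Genotypes are coded 0 (hom
#' `allele_a`), 1 (het), 2 (hom `allele_b`), NA for 0/0 entries. Locus order
#' follows the MAP file.
#'
#' @param ped_path,map_path file paths.
#' @return A [geno_matrix()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character",
                           col.names = c("scaffold", "snp_id", "cm", "pos_bp"))
  n_loci <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n_samp <- length(lines)
  geno <- matrix(NA_integer_, n_samp, max(n_loci, 0L))
  a1 <- rep(NA_character_, n_loci)
  a2 <- rep(NA_character_, n_loci)
  meta <- vector("list", n_samp)
  for (i in seq_len(n_samp)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * n_loci)
      stop("PED parse error at line ", i, ": expected ", 6L + 2L * n_loci,
           " fields, found ", length(f))
    meta[[i]] <- f[1:6]
    al <- f[-(1:6)]
    x <- al[seq(1L, by = 2L, length.out = n_loci)]
    y <- al[seq(2L, by = 2L, length.out = n_loci)]
    miss <- x == "0" | y == "0"
    for (l in which(!miss)) {
      for (a in c(x[l], y[l])) {
        if (is.na(a1[l])) a1[l] <- a
        else if (a != a1[l] && is.na(a2[l])) a2[l] <- a
        else if (a != a1[l] && a != a2[l])
          stop("non-biallelic locus ", map$snp_id[l], ": alleles ",
               paste(unique(c(a1[l], a2[l], x[l], y[l])), collapse = "/"))
      }
      geno[i, l] <- (x[l] != a1[l]) + (y[l] != a1[l])
    }
    geno[i, miss] <- NA_integer_
  }
  # enforce a stable orientation: allele_a is the lexicographically smaller
  # observed allele so that coding does not depend on sample order
  for (l in seq_len(n_loci)) {
    if (!is.na(a1[l]) && !is.na(a2[l]) && a2[l] < a1[l]) {
      tmp <- a1[l]; a1[l] <- a2[l]; a2[l] <- tmp
      geno[, l] <- 2L - geno[, l]
    }
  }
  fam <- do.call(rbind, meta)
  samples <- data.frame(
    sample_id = if (n_samp) fam[, 2] else character(),
    family_id = if (n_samp) fam[, 1] else character(),
    stringsAsFactors = FALSE)
  a1[is.na(a1)] <- "A"
  a2[is.na(a2)] <- ifelse(a1[is.na(a2)] == "C", "G", "C")
  loci <- data.frame(snp_id = map$snp_id, scaffold = map$scaffold,
                     pos_bp = as.integer(map$pos_bp),
                     allele_a = a1, allele_b = a2,
                     stringsAsFactors = FALSE)
  geno_matrix(geno, loci, samples)
}

#' Write a genotype matrix as PLINK text PED/MAP
#'
#' @param x a [geno_matrix()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(x, ped_path, map_path) {
  loci <- x$loci
  map <- data.frame(loci$scaffold, loci$snp_id, 0L, loci$pos_bp)
  utils::write.table(map, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  n_loci <- ncol(x$geno)
  con <- file(ped_path, "w")
  on.exit(close(con))
  fam <- if ("family_id" %in% names(x$samples)) x$samples$family_id
         else x$samples$sample_id
  for (i in seq_len(nrow(x$geno))) {
    g <- x$geno[i, ]
    a <- ifelse(is.na(g), "0", ifelse(g >= 1L, loci$allele_b, loci$allele_a))
    b <- ifelse(is.na(g), "0", ifelse(g == 2L, loci$allele_b, loci$allele_a))
    pair <- character(2L * n_loci)
    if (n_loci) {
      pair[seq(1L, by = 2L, length.out = n_loci)] <- a
      pair[seq(2L, by = 2L, length.out = n_loci)] <- b
    }
    writeLines(paste(c(fam[i], x$samples$sample_id[i], "0", "0", "0", "-9",
                       pair), collapse = " "), con)
  }
  invisible(c(ped = ped_path, map = map_path))
}
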