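#' Summarise BLAST tabular output per query
#'
#' Consumes outfmt-6 tables (qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore) and reports, per
#' query, the number of mappings and the alignment length of the top hit
#' (highest bitscore; ties broken by lowest e-value, then first occurrence).
#' Queries listed in `probe_lengths` but absent from the table get
#' `n_mappings = 0`.
#'
#' @param path BLAST outfmt-6 file.
#' @param probe_lengths named integer vector of probe lengths per query id;
#'   names define the set of queries reported.
#' @return data.frame: `snp_id`, `n_mappings`, `top_alignment_length`,
#'   `probe_length`.
#' @export
read_blast_tab <- function(path, probe_lengths) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (!file.exists(path)) stop("BLAST table not found: ", path)
  has_rows <- length(readLines(path, n = 1L)) > 0
  if (has_rows) {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(tab) != 12L)
      stop("BLAST outfmt 6 parse error: expected 12 columns, found ", ncol(tab))
    names(tab) <- cols
  } else {
    tab <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 12)), cols)
  }
  ids <- names(probe_lengths)
  n_map <- integer(length(ids))
  top_len <- integer(length(ids))
  byq <- split(seq_len(nrow(tab)), factor(tab$qseqid, levels = ids))
  for (k in seq_along(ids)) {
    rows <- byq[[k]]
    n_map[k] <- length(rows)
    if (length(rows)) {
      sub <- tab[rows, , drop = FALSE]
      best <- order(-sub$bitscore, sub$evalue, seq_len(nrow(sub)))[1L]
      top_len[k] <- sub$length[best]
    }
  }
  data.frame(snp_id = ids, n_mappings = n_map, top_alignment_length = top_len,
             probe_length = as.integer(probe_lengths), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Read SNP flanking sequences from FASTA
#'
#' Each record holds the probe context of one SNP with the variant site
#' marked by bracketed alleles, e.g. `ACGT[A/G]TTCA`. The header's first
#' word is taken as the SNP id. Sequences are upper-cased; records with
#' either flank shorter than `min_flank` are flagged.
#'
#' @param path FASTA file.
#' @param min_flank minimum flank length on each side (default 35 bp).
#' @return data.frame: `snp_id`, `left_flank`, `right_flank`, `allele_a`,
#'   `allele_b`, `left_len`, `right_len`, `sufficient`.
#' @export
read_flank_fasta <- function(path, min_flank = 35L) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  if (any(ids == ">" | ids == "")) stop("FASTA header without parseable id")
  seqs <- toupper(vapply(seq_along(hdr), function(k) {
    paste(lines[(hdr[k] + 1L):ends[k]], collapse = "")
  }, character(1)))
  m <- regmatches(seqs, regexec("^([ACGTN]*)\\[([ACGT])/([ACGT])\\]([ACGTN]*)$", seqs))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad))
    stop("missing or malformed [X/Y] SNP bracket in record(s): ",
         paste(ids[bad], collapse = ", "))
  left <- vapply(m, `[`, character(1), 2L)
  right <- vapply(m, `[`, character(1), 5L)
  data.frame(snp_id = ids, left_flank = left, right_flank = right,
             allele_a = vapply(m, `[`, character(1), 3L),
             allele_b = vapply(m, `[`, character(1), 4L),
             left_len = nchar(left), right_len = nchar(right),
             sufficient = nchar(left) >= min_flank & nchar(right) >= min_flank,
             stringsAsFactors = FALSE)
}

#' Read sample metadata TSV
#'
#' Recognised columns: `sample_id` (required), `population`, `birth_year`,
#' `is_pup`, `is_replicate_of`, `dish_qc`, `dna_conc_ng_ul`,
#' `known_mother_id`. Missing optional columns are filled with NA/FALSE.
#'
#' @param path TSV with a header row.
#' @return data.frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md)) stop("metadata lacks sample_id column")
  if (anyDuplicated(md$sample_id))
    stop("duplicated sample_id in metadata")
  defaults <- list(population = NA_character_, birth_year = NA_integer_,
                   is_pup = FALSE, is_replicate_of = NA_character_,
                   dish_qc = NA_real_, dna_conc_ng_ul = NA_real_,
                   known_mother_id = NA_character_)
  for (nm in names(defaults))
    if (!nm %in% names(md)) md[[nm]] <- defaults[[nm]]
  md$is_pup <- as.logical(md$is_pup)
  rep_of <- md$is_replicate_of[!is.na(md$is_replicate_of) & md$is_replicate_of != ""]
  if (!all(rep_of %in% md$sample_id))
    stop("is_replicate_of names unknown sample(s): ",
         paste(setdiff(rep_of, md$sample_id), collapse = ", "))
  md
}

#' Write ROH segments as BED-like TSV
#'
#' Internal coordinates are 1-based inclusive; the export converts to
#' 0-based half-open (BED convention).
#'
#' @param segments data.frame from [call_roh()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_roh_bed <- function(segments, path) {
  out <- data.frame(sample_id = segments$sample_id,
                    scaffold = segments$scaffold,
                    start0 = segments$start_bp - 1L,
                    end = segments$end_bp,
                    n_snps = segments$n_snps,
                    n_het = segments$n_het,
                    length_kb = segments$length_kb)
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read ROH segments from a BED-like TSV written by [write_roh_bed()]
#'
#' @param path input path.
#' @return data.frame with 1-based inclusive `start_bp`/`end_bp`.
#' @export
read_roh_bed <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(sample_id = as.character(x$sample_id),
             scaffold = as.character(x$scaffold),
             start_bp = x$start0 + 1L, end_bp = x$end,
             n_snps = x$n_snps, n_het = x$n_het, length_kb = x$length_kb,
             stringsAsFactors = FALSE)
}
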