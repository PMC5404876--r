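# Read input, minimal cleaning (3' adapter trim, length filter, N
# filter), QC statistics and duplicate collapsing for sRNA-seq reads.
#
# Cleaning is deliberately minimal: the >=15 nt length filter is the
# one hard contract; adapter trimming and the N filter follow standard
# sRNA-seq practice. Base-quality filtering is off by default — Q20 is
# a reported statistic, not a filter.

#' Read small RNA reads from FASTQ or FASTA
#'
#' FASTQ (4-line, Phred+33) or FASTA, optionally gzip-compressed; the
#' format is detected from the first non-empty byte. FASTA headers of
#' the form `name_x<count>` (collapsed-read convention) populate the
#' `count` column; all other reads get count 1.
#'
#' @param path input file path.
#' @return data.frame with columns `id`, `sequence`, `qualities`
#'   (Phred+33 string, `NA` for FASTA) and `count`.
#' @export
read_small_rna <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1)
  close(con)
  if (length(first) == 0) {
    return(data.frame(id = character(0), sequence = character(0),
                      qualities = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  fmt <- if (startsWith(first, "@")) "fastq" else if (startsWith(first, ">")) "fasta"
         else stop("unrecognized read format (expected FASTA or FASTQ): ", path,
                   call. = FALSE)
  if (fmt == "fastq") {
    parsed <- tryCatch({
      ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                         with.qualities = TRUE)
      list(seqs = ss, qual = as.character(S4Vectors::mcols(ss)$qualities))
    }, error = function(e) stop("malformed FASTQ in ", path, ": ",
                                conditionMessage(e), call. = FALSE))
    seqs <- parsed$seqs
    qual <- parsed$qual
    bad <- which(nchar(qual) != Biostrings::width(seqs))
    if (length(bad) > 0) {
      stop(sprintf("malformed FASTQ record %d in %s: sequence/quality length mismatch",
                   bad[1], path), call. = FALSE)
    }
  } else {
    seqs <- Biostrings::readDNAStringSet(path)
    qual <- rep(NA_character_, length(seqs))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  count <- rep(1L, length(seqs))
  m <- regmatches(ids, regexec("_x(\\d+)$", ids))
  has <- lengths(m) == 2
  count[has] <- as.integer(vapply(m[has], `[`, character(1), 2))
  data.frame(id = ids, sequence = toupper(as.character(seqs)),
             qualities = qual, count = count, stringsAsFactors = FALSE)
}

# Leftmost 3' adapter start within a read: position i (1-based) such
# that read[i..] matches an adapter prefix of overlap >= seed_len with
# at most one mismatch. Returns i, or 0 when no adapter is found.
find_adapter_start <- function(seq, adapter_raw, seed_len) {
  sr <- charToRaw(seq)
  m <- length(sr)
  last <- m - seed_len + 1L
  if (last < 1L) return(0L)
  for (i in seq_len(last)) {
    o <- min(length(adapter_raw), m - i + 1L)
    if (sum(sr[i:(i + o - 1L)] != adapter_raw[seq_len(o)]) <= 1L) return(i)
  }
  0L
}

#' Clean raw reads
#'
#' Applies, in order: 3' adapter trimming (leftmost match of an
#' adapter prefix of at least `adapter_seed` nt with at most one
#' mismatch; untrimmed reads are kept, since short inserts may lack
#' adapter read-through), a minimum-length filter, an N-content filter
#' (reads with more than `max_n_frac` ambiguous bases are dropped) and
#' an optional mean-quality filter.
#'
#' @param reads data.frame from [read_small_rna()] (columns `id`,
#'   `sequence`, `qualities`, `count`).
#' @param adapter 3' adapter sequence, or `NULL` for no trimming.
#' @param min_len minimum read length after trimming (default 15 nt;
#'   shorter reads are dropped).
#' @param min_mean_q optional mean Phred threshold; `NULL` (default)
#'   disables quality filtering.
#' @param adapter_seed minimum adapter overlap required to trim
#'   (default 8 nt).
#' @param max_n_frac maximum tolerated fraction of N bases (default 0.1).
#' @return list with `reads` (the cleaned data.frame) and `stats`, a
#'   `qc_stats` list: `n_raw`, `n_cleaned`, `q20_percent` (`NA` without
#'   qualities) and `length_histogram` over the survivors.
#' @export
clean_reads <- function(reads, adapter = NULL, min_len = 15, min_mean_q = NULL,
                        adapter_seed = 8, max_n_frac = 0.1) {
  stopifnot(min_len >= 1)
  n_raw <- sum(reads$count)
  seqs <- reads$sequence
  quals <- reads$qualities
  if (!is.null(adapter) && nzchar(adapter) && nrow(reads) > 0) {
    adapter <- toupper(adapter)
    check_dna_alphabet(adapter, "adapter")
    araw <- charToRaw(adapter)
    cut <- vapply(seqs, find_adapter_start, integer(1),
                  adapter_raw = araw, seed_len = as.integer(adapter_seed),
                  USE.NAMES = FALSE)
    trim <- cut > 0L
    seqs[trim] <- substr(seqs[trim], 1L, cut[trim] - 1L)
    quals[trim & !is.na(quals)] <-
      substr(quals[trim & !is.na(quals)], 1L, cut[trim & !is.na(quals)] - 1L)
  }
  len <- nchar(seqs)
  n_count <- nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE))
  keep <- len >= min_len & (len == 0 | n_count / pmax(len, 1L) <= max_n_frac)
  if (!is.null(min_mean_q)) {
    meanq <- vapply(quals, function(q) {
      if (is.na(q) || !nzchar(q)) return(NA_real_)
      mean(phred_scores(q))
    }, numeric(1), USE.NAMES = FALSE)
    keep <- keep & (is.na(meanq) | meanq >= min_mean_q)
  }
  out <- reads[keep, , drop = FALSE]
  out$sequence <- seqs[keep]
  out$qualities <- quals[keep]
  rownames(out) <- NULL
  n_cleaned <- sum(out$count)
  hist <- length_distribution(out)
  q20 <- if (nrow(out) > 0 && !anyNA(out$qualities)) q20_percent(out) else NA_real_
  list(reads = out,
       stats = structure(list(n_raw = n_raw, n_cleaned = n_cleaned,
                              q20_percent = q20, length_histogram = hist),
                         class = "qc_stats"))
}

#' Q20 percentage
#'
#' Percentage of sequenced bases with Phred quality >= 20, weighted by
#' duplicate count, rounded half-up to one decimal.
#'
#' @param reads data.frame with `qualities` (Phred+33) and `count`.
#' @return numeric percentage in `[0, 100]`.
#' @export
q20_percent <- function(reads) {
  if (nrow(reads) == 0 || anyNA(reads$qualities)) {
    stop("Q20 not computable: base qualities are absent (FASTA input?)",
         call. = FALSE)
  }
  per_read <- vapply(reads$qualities, function(q) {
    s <- phred_scores(q)
    c(sum(s >= 20L), length(s))
  }, numeric(2), USE.NAMES = FALSE)
  good <- sum(per_read[1, ] * reads$count)
  total <- sum(per_read[2, ] * reads$count)
  percent_of(good, total, digits = 1)
}

#' Collapse reads to unique sequences with counts
#'
#' @param reads cleaned read data.frame (or a character vector of
#'   sequences); existing `count` columns are respected, so collapsing
#'   is idempotent.
#' @return data.frame with columns `sequence` and `count`, one row per
#'   distinct sequence, sorted by descending count with ties broken
#'   lexicographically. The counts sum to the number of input reads.
#' @export
collapse_reads <- function(reads) {
  if (is.character(reads)) {
    reads <- data.frame(sequence = reads, count = rep(1L, length(reads)),
                        stringsAsFactors = FALSE)
  }
  if (nrow(reads) == 0) {
    return(data.frame(sequence = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  counts <- tapply(reads$count, reads$sequence, sum)
  out <- data.frame(sequence = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order_by_count_then_seq(out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write collapsed reads as FASTA
#'
#' Headers follow the `seq<rank>_x<count>` convention, which
#' [read_small_rna()] parses back into counts.
#'
#' @param collapsed data.frame from [collapse_reads()].
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  dna <- Biostrings::DNAStringSet(collapsed$sequence)
  names(dna) <- sprintf("seq%d_x%d", seq_len(nrow(collapsed)), collapsed$count)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Write collapsed reads as TSV (sequence, count)
#'
#' @param collapsed data.frame from [collapse_reads()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_collapsed_tsv <- function(collapsed, path) {
  utils::write.table(collapsed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
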