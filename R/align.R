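# Bespoke short-read aligner for a single rDNA reference, allowing at
# most one edit per read: one mismatch OR one 1-nt insertion/deletion,
# never both. Search is seed-and-verify with a pigeonhole guarantee:
# any alignment with <= 1 edit leaves at least one read half exact, so
# seeding the leading k-mer of both halves (on both strands) and
# verifying every candidate placement finds all <= 1-edit alignments.
#
# N bases never match anything, in reads or in the reference.
#
# Tie-breaking is fully deterministic: lower edit cost, then sense
# over antisense, then smaller ref_start, then mismatch over gap
# (insertion preferred over deletion among gapped placements).

RAW_N <- charToRaw("N")

#' Build a k-mer seed index of the reference
#'
#' Exact-match lookup of any reference k-mer in expected O(1). Only the
#' sense strand is indexed; antisense placements are found by querying
#' the reverse complement of the read (this is the one strand
#' convention used throughout).
#'
#' @param ref an [annotated_reference()].
#' @param k seed length, minimum 7 (default 7). Shorter seeds are too
#'   unspecific for a multi-kb reference.
#' @return a `seed_index` list used by [align_read()].
#' @export
build_index <- function(ref, k = 7) {
  k <- as.integer(k)
  if (k < 7) stop("seed length k must be >= 7", call. = FALSE)
  s <- ref$sequence
  L <- nchar(s)
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (L >= k) {
    starts <- seq_len(L - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    pos0 <- split(starts - 1L, kmers)  # 0-based positions
    for (nm in names(pos0)) assign(nm, pos0[[nm]], envir = env)
  }
  structure(list(env = env, k = k, ref_id = ref$id, ref_len = L),
            class = "seed_index")
}

# Look up a k-mer; integer(0) when absent (k-mers containing N are
# indexed literally but can never verify, so hits are harmless).
index_lookup <- function(index, kmer) {
  v <- get0(kmer, envir = index$env, ifnotfound = NULL)
  if (is.null(v)) integer(0) else v
}

# Verify one candidate placement of query (raw vector) at 0-based ref
# position s. Returns NULL or list(cost, span, type) where type is one
# of "exact", "mismatch", "ins" (extra base in read, ref span m-1),
# "del" (missing base in read, ref span m+1). Priority among valid
# placements at one position: exact > mismatch > ins > del.
verify_candidate <- function(qraw, refraw, s) {
  m <- length(qraw)
  L <- length(refraw)
  # same-span: exact or single mismatch
  if (s >= 0L && s + m <= L) {
    w <- refraw[(s + 1L):(s + m)]
    neq <- qraw != w | qraw == RAW_N | w == RAW_N
    nm <- sum(neq)
    if (nm == 0L) return(list(cost = 0L, span = m, type = "exact"))
    if (nm == 1L) return(list(cost = 1L, span = m, type = "mismatch"))
  }
  # one extra base in the read (ref span m-1)
  if (m >= 2L && s >= 0L && s + m - 1L <= L) {
    w <- refraw[(s + 1L):(s + m - 1L)]
    if (one_gap_fits(qraw, w)) return(list(cost = 1L, span = m - 1L, type = "ins"))
  }
  # one missing base in the read (ref span m+1)
  if (s >= 0L && s + m + 1L <= L) {
    w <- refraw[(s + 1L):(s + m + 1L)]
    if (one_gap_fits(w, qraw)) return(list(cost = 1L, span = m + 1L, type = "del"))
  }
  NULL
}

# TRUE when `longer` (length n+1) equals `shorter` (length n) after
# deleting exactly one base, with zero mismatches; N never matches.
one_gap_fits <- function(longer, shorter) {
  n <- length(shorter)
  eq_pre <- longer[seq_len(n)] == shorter & shorter != RAW_N & longer[seq_len(n)] != RAW_N
  lcp <- if (all(eq_pre)) n else which(!eq_pre)[1] - 1L
  if (lcp == n) return(TRUE)  # deletion at the very end
  eq_suf <- longer[2L:(n + 1L)] == shorter & shorter != RAW_N & longer[2L:(n + 1L)] != RAW_N
  neq_suf <- which(!eq_suf)
  lcs <- if (length(neq_suf) == 0) n else n - neq_suf[length(neq_suf)]
  lcp + lcs >= n
}

# All verified placements of one query string on one strand.
strand_hits <- function(query, index, refraw) {
  m <- nchar(query)
  k <- index$k
  if (m < k) return(NULL)
  qraw <- charToRaw(query)
  offs <- unique(c(0L, m %/% 2L))
  offs <- offs[offs + k <= m]
  starts <- integer(0)
  for (off in offs) {
    hits <- index_lookup(index, substr(query, off + 1L, off + k))
    if (length(hits) > 0) starts <- c(starts, hits - off)
  }
  if (length(starts) == 0) return(NULL)
  cand <- sort(unique(c(starts - 1L, starts, starts + 1L)))
  cand <- cand[cand >= -1L & cand <= index$ref_len]
  res <- vector("list", length(cand))
  n <- 0L
  for (s in cand) {
    v <- verify_candidate(qraw, refraw, s)
    if (!is.null(v)) {
      n <- n + 1L
      res[[n]] <- c(s, v$cost, v$span, match(v$type, c("exact", "mismatch", "ins", "del")))
    }
  }
  if (n == 0L) return(NULL)
  do.call(rbind, res[seq_len(n)])
}

#' Align one read to the reference with at most one edit
#'
#' Finds the single best placement: edit cost 0 if any exists, else
#' cost 1 (one mismatch or one 1-nt gap), else unmapped. Ties are
#' broken deterministically (sense over antisense, smallest start,
#' mismatch over gap).
#'
#' @param seq read sequence over A, C, G, T, N (length >= the seed
#'   size; upstream cleaning enforces >= 15 nt).
#' @param index a [build_index()] result.
#' @param ref the [annotated_reference()] the index was built from.
#' @return a one-row data.frame with columns `read_sequence`,
#'   `ref_start`, `ref_end` (0-based half-open), `strand` (`"sense"` or
#'   `"antisense"`), `n_mismatch`, `n_gap` — or `NULL` when unmapped.
#' @export
align_read <- function(seq, index, ref) {
  check_dna_alphabet(seq, "read")
  if (nchar(seq) > index$ref_len) return(NULL)
  refraw <- charToRaw(ref$sequence)
  b <- pick_best_hit(strand_hits(seq, index, refraw),
                     strand_hits(reverse_complement(seq), index, refraw))
  if (is.null(b)) return(NULL)
  hit_as_record(seq, b)
}

# Best placement as c(start, cost, span, type_idx, strand01), or NULL.
pick_best_hit <- function(hits_s, hits_a) {
  tab <- NULL
  if (!is.null(hits_s)) tab <- cbind(hits_s, 0L)
  if (!is.null(hits_a)) tab <- rbind(tab, cbind(hits_a, 1L))
  if (is.null(tab)) return(NULL)
  # order: cost, strand (sense first), start, edit type priority
  o <- order(tab[, 2], tab[, 5], tab[, 1], tab[, 4])[1]
  tab[o, ]
}

hit_as_record <- function(seq, b) {
  type <- c("exact", "mismatch", "ins", "del")[b[4]]
  data.frame(
    read_sequence = seq,
    ref_start = as.integer(b[1]),
    ref_end = as.integer(b[1] + b[3]),
    strand = if (b[5] == 0L) "sense" else "antisense",
    n_mismatch = as.integer(type == "mismatch"),
    n_gap = as.integer(type %in% c("ins", "del")),
    stringsAsFactors = FALSE
  )
}

#' Align a collection of collapsed reads
#'
#' Each unique sequence is aligned once; mapping statistics are
#' weighted by duplicate counts.
#'
#' @param collapsed data.frame from [collapse_reads()] (`sequence`,
#'   `count`).
#' @param ref an [annotated_reference()].
#' @param k seed length passed to [build_index()].
#' @return list with `alignments` (data.frame of alignment records
#'   carrying `count`) and `stats`, a `mapping_stats` list with
#'   `n_cleaned_reads`, `n_aligned_reads`, `n_sense`, `n_antisense`.
#' @export
align_all <- function(collapsed, ref, k = 7) {
  index <- build_index(ref, k)
  refraw <- charToRaw(ref$sequence)
  n <- nrow(collapsed)
  check_dna_alphabet(collapsed$sequence, "read")
  rc <- reverse_complement(collapsed$sequence)
  best <- matrix(NA_integer_, nrow = n, ncol = 5)
  for (i in seq_len(n)) {
    seq <- collapsed$sequence[i]
    if (nchar(seq) > index$ref_len) next
    b <- pick_best_hit(strand_hits(seq, index, refraw),
                       strand_hits(rc[i], index, refraw))
    if (!is.null(b)) best[i, ] <- b
  }
  mapped <- which(!is.na(best[, 1]))
  type <- c("exact", "mismatch", "ins", "del")[best[mapped, 4]]
  alns <- data.frame(
    read_sequence = collapsed$sequence[mapped],
    ref_start = as.integer(best[mapped, 1]),
    ref_end = as.integer(best[mapped, 1] + best[mapped, 3]),
    strand = ifelse(best[mapped, 5] == 0L, "sense", "antisense"),
    n_mismatch = as.integer(type == "mismatch"),
    n_gap = as.integer(type %in% c("ins", "del")),
    count = collapsed$count[mapped],
    stringsAsFactors = FALSE
  )
  rownames(alns) <- NULL
  n_cleaned <- if (n == 0) 0L else sum(collapsed$count)
  n_sense <- sum(alns$count[alns$strand == "sense"])
  n_anti <- sum(alns$count[alns$strand == "antisense"])
  stats <- structure(list(n_cleaned_reads = n_cleaned,
                          n_aligned_reads = n_sense + n_anti,
                          n_sense = n_sense, n_antisense = n_anti),
                     class = "mapping_stats")
  list(alignments = alns, stats = stats)
}

#' Percentage of cleaned reads that aligned
#'
#' @param stats a `mapping_stats` list (or anything with
#'   `n_aligned_reads` and `n_cleaned_reads`).
#' @param digits decimal places (default 1, as reported).
#' @return numeric percentage.
#' @export
mapping_rate <- function(stats, digits = 1) {
  if (stats$n_cleaned_reads == 0) {
    stop("mapping rate not computable: no cleaned reads", call. = FALSE)
  }
  percent_of(stats$n_aligned_reads, stats$n_cleaned_reads, digits)
}

#' Percentage of aligned reads on the sense strand
#'
#' @param stats a `mapping_stats` list.
#' @param digits decimal places (default 2, as reported).
#' @return numeric percentage.
#' @export
strand_fraction <- function(stats, digits = 2) {
  if (stats$n_aligned_reads == 0) {
    stop("strand fraction not computable: no aligned reads", call. = FALSE)
  }
  percent_of(stats$n_sense, stats$n_aligned_reads, digits)
}

# CIGAR string for an internal alignment record (re-derives the gap
# placement from the sequences; mismatches stay within M runs).
alignment_cigar <- function(seq, ref, ref_start, ref_end, strand) {
  m <- nchar(seq)
  span <- ref_end - ref_start
  q <- if (strand == "antisense") reverse_complement(seq) else seq
  if (span == m) return(sprintf("%dM", m))
  qraw <- charToRaw(q)
  wraw <- charToRaw(substr(ref$sequence, ref_start + 1L, ref_end))
  if (span == m - 1L) {  # insertion in read
    n <- length(wraw)
    eq <- qraw[seq_len(n)] == wraw & wraw != RAW_N & qraw[seq_len(n)] != RAW_N
    j <- if (all(eq)) n else which(!eq)[1] - 1L
    if (j == 0L) return(sprintf("1I%dM", m - 1L))
    if (j >= m - 1L) return(sprintf("%dM1I", m - 1L))
    return(sprintf("%dM1I%dM", j, m - 1L - j))
  }
  # deletion in read
  n <- length(qraw)
  eq <- wraw[seq_len(n)] == qraw & qraw != RAW_N & wraw[seq_len(n)] != RAW_N
  j <- if (all(eq)) n else which(!eq)[1] - 1L
  if (j == 0L) return(sprintf("1D%dM", m))
  if (j >= m) return(sprintf("%dM1D", m))
  sprintf("%dM1D%dM", j, m - j)
}

#' Write alignments as SAM
#'
#' Minimal single-reference SAM with `@SQ` header and `NM` tags;
#' unmapped reads are omitted. Antisense records store the
#' reverse-complemented (reference-forward) sequence, per the SAM
#' standard.
#'
#' @param alns alignment data.frame from [align_all()].
#' @param ref the [annotated_reference()].
#' @param path output SAM path.
#' @return the path, invisibly.
#' @export
write_sam <- function(alns, ref, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", ref$id, nchar(ref$sequence)),
              "@PG\tID:rrfscan\tPN:rrfscan")
  n <- nrow(alns)
  recs <- character(n)
  for (i in seq_len(n)) {
    a <- alns[i, ]
    flag <- if (a$strand == "antisense") 16L else 0L
    seq_fwd <- if (a$strand == "antisense") reverse_complement(a$read_sequence)
               else a$read_sequence
    cig <- alignment_cigar(a$read_sequence, ref, a$ref_start, a$ref_end, a$strand)
    cnt <- if ("count" %in% names(alns)) a$count else 1L
    recs[i] <- sprintf("seq%d_x%d\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                       i, cnt, flag, ref$id, a$ref_start + 1L, cig, seq_fwd,
                       a$n_mismatch + a$n_gap)
  }
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Import external alignments from SAM
#'
#' Compatibility path for alignments produced by an external mapper.
#' Records are filtered to the same contract as the internal aligner:
#' anything with NM >= 2, an indel longer than 1 nt, or clipped bases
#' is discarded. Read counts are recovered from `name_x<count>` query
#' names when present, else 1.
#'
#' @param sam_source path to a SAM file whose records refer to `ref`.
#' @param ref the [annotated_reference()].
#' @return list with `alignments`, `stats` (as [align_all()]) and
#'   `n_discarded` (records dropped by the edit filter).
#' @export
import_sam <- function(sam_source, ref) {
  bam <- Rsamtools::asBam(sam_source,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = "NM")
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  rname <- as.character(b$rname)
  mapped <- !is.na(b$pos)
  if (any(mapped & rname != ref$id)) {
    stop(sprintf("SAM records reference '%s', expected '%s'",
                 paste(unique(rname[mapped & rname != ref$id]), collapse = ","),
                 ref$id), call. = FALSE)
  }
  nm_tag <- b$tag$NM
  if (is.null(nm_tag)) nm_tag <- rep(NA_integer_, length(b$pos))
  qcount <- rep(1L, length(b$qname))
  mt <- regmatches(b$qname, regexec("_x(\\d+)$", b$qname))
  has <- lengths(mt) == 2
  qcount[has] <- as.integer(vapply(mt[has], `[`, character(1), 2))

  keep <- logical(length(b$pos))
  span <- integer(length(b$pos))
  nmis <- integer(length(b$pos))
  ngap <- integer(length(b$pos))
  n_discarded <- 0L
  for (i in seq_along(b$pos)) {
    if (!mapped[i]) next
    ops <- cigar_ops(b$cigar[i])
    if (is.null(ops)) { n_discarded <- n_discarded + 1L; next }
    if (any(ops$op %in% c("S", "H"))) { n_discarded <- n_discarded + 1L; next }
    indel <- ops$op %in% c("I", "D")
    if (any(indel & ops$len > 1L) || sum(ops$len[indel]) > 1L) {
      n_discarded <- n_discarded + 1L; next
    }
    nm <- nm_tag[i]
    if (is.na(nm)) nm <- sum(ops$len[indel])
    if (nm >= 2L) { n_discarded <- n_discarded + 1L; next }
    g <- as.integer(sum(ops$len[indel]))
    keep[i] <- TRUE
    span[i] <- sum(ops$len[ops$op %in% c("M", "=", "X", "D")])
    ngap[i] <- g
    nmis[i] <- max(0L, as.integer(nm) - g)
  }
  idx <- which(keep)
  strand <- ifelse(bitwAnd(b$flag[idx], 16L) > 0L, "antisense", "sense")
  seqs <- as.character(b$seq[idx])
  # SAM stores the reference-forward sequence; recover the read as sequenced
  anti <- strand == "antisense"
  seqs[anti] <- reverse_complement(seqs[anti])
  alns <- data.frame(
    read_sequence = seqs,
    ref_start = b$pos[idx] - 1L,
    ref_end = b$pos[idx] - 1L + span[idx],
    strand = strand,
    n_mismatch = nmis[idx],
    n_gap = ngap[idx],
    count = qcount[idx],
    stringsAsFactors = FALSE
  )
  n_sense <- sum(alns$count[alns$strand == "sense"])
  n_anti <- sum(alns$count[alns$strand == "antisense"])
  n_total <- sum(qcount)  # all records, incl. unmapped
  stats <- structure(list(n_cleaned_reads = n_total,
                          n_aligned_reads = n_sense + n_anti,
                          n_sense = n_sense, n_antisense = n_anti),
                     class = "mapping_stats")
  list(alignments = alns, stats = stats, n_discarded = n_discarded)
}

# Parse a CIGAR string into op/len vectors; NULL when unparseable.
cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(NULL)
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)[[1]]
  if (m[1] == -1) return(NULL)
  toks <- regmatches(cigar, gregexpr("(\\d+)([MIDNSHP=X])", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) return(NULL)
  list(op = sub("^\\d+", "", toks),
       len = as.integer(sub("[MIDNSHP=X]$", "", toks)))
}
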