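# Test helpers: an independent brute-force alignment oracle and small
# fixture builders. The oracle scans every (offset, strand, span)
# placement computing full edit distance via utils::adist — a C
# implementation independent of the package's seed-and-verify search.
# N never matches: reads map N to X, the reference maps N to Z, so the
# two can never compare equal.

brute_force_align <- function(seq, ref_seq) {
  m <- nchar(seq)
  L <- nchar(ref_seq)
  refz <- chartr("N", "Z", ref_seq)
  best <- Inf
  for (q in c(seq, rrfscan::reverse_complement(seq))) {
    qx <- chartr("N", "X", q)
    for (span in c(m - 1L, m, m + 1L)) {
      if (span < 1L || span > L) next
      starts <- seq_len(L - span + 1L)
      windows <- substring(refz, starts, starts + span - 1L)
      d <- min(utils::adist(qx, windows))
      if (d < best) best <- d
    }
  }
  list(mapped = best <= 1, cost = if (best <= 1) as.integer(best) else NA_integer_)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_base <- function(s, pos) {
  old <- substr(s, pos, pos)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  paste0(substr(s, 1, pos - 1), new, substr(s, pos + 1, nchar(s)))
}

# A read planted on ref_seq with a prescribed edit type; may be
# emitted as its reverse complement. The oracle, not the plant,
# defines the expected mapped status and cost (reference repeats can
# make a 2-edit plant alignable with fewer edits elsewhere).
plant_read <- function(ref_seq, type = c("exact", "mismatch", "ins", "del",
                                         "twomm", "random"),
                       len = sample(15:40, 1)) {
  type <- match.arg(type)
  L <- nchar(ref_seq)
  if (type == "random") {
    s <- random_dna(len)
  } else {
    start <- sample.int(L - len + 1L, 1)
    s <- substr(ref_seq, start, start + len - 1L)
    if (type == "mismatch") {
      s <- mutate_base(s, sample.int(len, 1))
    } else if (type == "twomm") {
      pos <- sample.int(len, 2)
      s <- mutate_base(mutate_base(s, pos[1]), pos[2])
    } else if (type == "ins") {
      p <- sample.int(len, 1)
      s <- paste0(substr(s, 1, p), sample(c("A", "C", "G", "T"), 1),
                  substr(s, p + 1, len))
    } else if (type == "del") {
      p <- sample.int(len, 1)
      s <- paste0(substr(s, 1, p - 1), substr(s, p + 1, len))
    }
  }
  if (nchar(s) < 15) s <- substr(ref_seq, 1, 15)  # guard tiny dels
  if (stats::runif(1) < 0.5) s <- rrfscan::reverse_complement(s)
  s
}

# Small annotated reference with one spacer flanked by two genes.
fixture_reference <- function(seed = 1) {
  set.seed(seed)
  rrfscan::annotated_reference(
    id = "fixref",
    sequence = random_dna(400),
    regions = data.frame(
      name = c("geneA", "spacer1", "geneB"),
      start = c(0L, 120L, 180L),
      end = c(120L, 180L, 360L),
      role = c("gene", "spacer", "gene"),
      stringsAsFactors = FALSE))
}

# Alignment-record rows built by hand (for classifier/series tests).
aln_row <- function(start, end, strand = "sense", count = 1,
                    seq = strrep("A", end - start)) {
  data.frame(read_sequence = seq, ref_start = as.integer(start),
             ref_end = as.integer(end), strand = strand,
             n_mismatch = 0L, n_gap = 0L, count = as.integer(count),
             stringsAsFactors = FALSE)
}

# Default planted-ladder study design: four ladders at both termini of
# the 5.8S and 28S genes, nine lengths each, Poisson mean 100 reads
# per length, background at 10% of the expected planted read count.
default_ladders <- function() {
  rbind(rrfscan::ladder_spec("5.8S", "5p", 25, 33, 100),
        rrfscan::ladder_spec("5.8S", "3p", 25, 33, 100),
        rrfscan::ladder_spec("28S", "5p", 25, 33, 100),
        rrfscan::ladder_spec("28S", "3p", 25, 33, 100))
}

# Simulated library -> called-series table via the standard stages
# (clean, collapse, align, classify, group, call).
run_sim_through_pipeline <- function(sim, ref, tol = 0, min_run = 3,
                                     min_total = 10) {
  cleaned <- rrfscan::clean_reads(sim$reads, min_len = 15)
  col <- rrfscan::collapse_reads(cleaned$reads)
  res <- rrfscan::align_all(col, ref)
  cl <- rrfscan::classify_alignments(res$alignments, ref, tol = tol)
  rrfscan::call_series(rrfscan::group_by_anchor(cl, ref),
                       min_run = min_run, min_total = min_total)
}
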