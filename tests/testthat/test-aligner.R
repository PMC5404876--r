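# Seed-and-verify <=1-edit aligner: seed index, single-read search,
# weighted library alignment, SAM import/export, strand accounting.

one_region_ref <- function(seq, id = "r") {
  annotated_reference(id, seq,
                      data.frame(name = "g", start = 0L, end = nchar(seq),
                                 role = "gene"))
}

test_that("seed index finds exact k-mers and rejects unspecific seeds", {
  ref <- one_region_ref("ACGTACGTTGCATGCA")
  idx <- build_index(ref, k = 7)
  expect_equal(rrfscan:::index_lookup(idx, "CGTACGT"), 1L) # 0-based
  expect_equal(rrfscan:::index_lookup(idx, "AAAAAAA"), integer(0))
  expect_error(build_index(ref, k = 6), "k must be >= 7")
})

test_that("exact, one-mismatch, antisense and unmappable reads resolve correctly", {
  set.seed(21)
  core <- "CGTACGTACGCTGATT" # 16 nt query
  ref_seq <- paste0("AAA", core, random_dna(60))
  ref <- one_region_ref(ref_seq)
  idx <- build_index(ref)

  exact <- align_read(core, idx, ref)
  expect_equal(exact$ref_start, 3L)
  expect_equal(exact$ref_end, 19L)
  expect_equal(exact$strand, "sense")
  expect_equal(exact$n_mismatch + exact$n_gap, 0L)

  mm <- mutate_base(core, 12)
  got <- align_read(mm, idx, ref)
  oracle <- brute_force_align(mm, ref_seq)
  expect_true(oracle$mapped)
  expect_equal(oracle$cost, 1L)
  expect_equal(got$ref_start, 3L)
  expect_equal(got$n_mismatch, 1L)
  expect_equal(got$n_gap, 0L)

  anti <- align_read(reverse_complement(core), idx, ref)
  expect_equal(anti$ref_start, 3L)
  expect_equal(anti$ref_end, 19L)
  expect_equal(anti$strand, "antisense")

  twomm <- mutate_base(mutate_base(core, 3), 13)
  expect_false(brute_force_align(twomm, ref_seq)$mapped)
  expect_null(align_read(twomm, idx, ref))
})

test_that("single-nucleotide gaps align with reference span off by one", {
  set.seed(22)
  ref_seq <- random_dna(300)
  ref <- one_region_ref(ref_seq)
  idx <- build_index(ref)
  frag <- substr(ref_seq, 101, 130) # 30 nt at 0-based 100
  ins <- paste0(substr(frag, 1, 14), "A", substr(frag, 15, 30))
  # guard against the random flank absorbing the edit another way
  if (brute_force_align(ins, ref_seq)$cost == 1L) {
    got <- align_read(ins, idx, ref)
    expect_equal(got$n_gap, 1L)
    expect_equal(got$ref_end - got$ref_start, nchar(ins) - 1L)
  }
  del <- paste0(substr(frag, 1, 14), substr(frag, 16, 30))
  if (brute_force_align(del, ref_seq)$cost == 1L) {
    got <- align_read(del, idx, ref)
    expect_equal(got$n_gap, 1L)
    expect_equal(got$ref_end - got$ref_start, nchar(del) + 1L)
  }
})

test_that("aligner matches the brute-force oracle on randomized cases", {
  set.seed(23)
  ref_seq <- random_dna(800)
  ref <- one_region_ref(ref_seq)
  idx <- build_index(ref)
  types <- c("exact", "mismatch", "ins", "del", "twomm", "random")
  for (i in 1:60) {
    s <- plant_read(ref_seq, types[(i %% 6) + 1])
    got <- align_read(s, idx, ref)
    oracle <- brute_force_align(s, ref_seq)
    expect_equal(!is.null(got), oracle$mapped, info = s)
    if (oracle$mapped) {
      expect_equal(got$n_mismatch + got$n_gap, oracle$cost, info = s)
    }
  }
})

test_that("reverse-complemented reads keep their span with flipped strand", {
  set.seed(24)
  ref_seq <- random_dna(500)
  ref <- one_region_ref(ref_seq)
  idx <- build_index(ref)
  for (i in 1:20) {
    s <- plant_read(ref_seq, "mismatch", len = 30)
    a <- align_read(s, idx, ref)
    b <- align_read(reverse_complement(s), idx, ref)
    if (is.null(a)) { expect_null(b); next }
    expect_equal(b$ref_start, a$ref_start)
    expect_equal(b$ref_end, a$ref_end)
    expect_false(b$strand == a$strand)
  }
})

test_that("ties resolve to sense strand and smallest reference start", {
  motif <- "ACGTTGCACGGATCCA" # 16 nt, planted twice
  ref <- one_region_ref(paste0(motif, strrep("T", 20), motif, strrep("G", 8)))
  idx <- build_index(ref)
  got <- align_read(motif, idx, ref)
  expect_equal(got$ref_start, 0L)
  expect_equal(got$strand, "sense")
})

test_that("N never matches: a read with 2 Ns in one window stays unmapped", {
  set.seed(25)
  ref_seq <- random_dna(200)
  ref <- one_region_ref(ref_seq)
  idx <- build_index(ref)
  frag <- substr(ref_seq, 51, 80)
  oneN <- paste0(substr(frag, 1, 20), "N", substr(frag, 22, 30))
  a <- align_read(oneN, idx, ref)
  expect_equal(a$n_mismatch, 1L) # the N costs the single allowed edit
  twoN <- paste0("N", substr(frag, 2, 20), "N", substr(frag, 22, 30))
  expect_null(align_read(twoN, idx, ref))
})

test_that("reads longer than the reference are unmapped, not an error", {
  ref <- one_region_ref("ACGTACGTACGTACGTACGT")
  idx <- build_index(ref)
  expect_null(align_read(strrep("ACGT", 10), idx, ref))
})

test_that("align_all weights statistics by duplicate counts", {
  set.seed(26)
  ref_seq <- random_dna(300)
  ref <- one_region_ref(ref_seq)
  inside <- substr(ref_seq, 21, 50)
  outside <- strrep("ACGTG", 6) # almost surely 2+ edits from ref
  col <- data.frame(sequence = c(inside, reverse_complement(inside), outside),
                    count = c(10L, 2L, 5L), stringsAsFactors = FALSE)
  res <- align_all(col, ref)
  expect_equal(res$stats$n_cleaned_reads, 17L)
  expect_lte(res$stats$n_aligned_reads, 17L)
  expect_equal(res$stats$n_sense + res$stats$n_antisense,
               res$stats$n_aligned_reads)
  expect_equal(res$stats$n_sense, 10L)
  expect_equal(res$stats$n_antisense, 2L)
  # empty input
  empty <- align_all(data.frame(sequence = character(0), count = integer(0)),
                     ref)
  expect_equal(empty$stats$n_cleaned_reads, 0L)
  expect_equal(empty$stats$n_aligned_reads, 0L)
})

test_that("repeated alignment runs are identical", {
  set.seed(27)
  ref <- one_region_ref(random_dna(400))
  col <- collapse_reads(vapply(1:30, function(i) plant_read(ref$sequence, "mismatch"),
                               character(1)))
  expect_identical(align_all(col, ref), align_all(col, ref))
})

test_that("mapping rate and strand fraction reproduce from stored counts", {
  st <- list(n_cleaned_reads = 2L, n_aligned_reads = 2L, n_sense = 1L,
             n_antisense = 1L)
  expect_equal(strand_fraction(st), 50.00)
  st$n_sense <- 2L; st$n_antisense <- 0L
  expect_equal(strand_fraction(st), 100.00)
  empty <- list(n_cleaned_reads = 0L, n_aligned_reads = 0L)
  expect_error(mapping_rate(empty), "not computable")
  expect_error(strand_fraction(empty), "not computable")
})

test_that("SAM import converts coordinates, filters edits and flags strand", {
  set.seed(28)
  ref_seq <- random_dna(120)
  ref <- one_region_ref(ref_seq, id = "samref")
  sam <- tempfile(fileext = ".sam")
  r1 <- substr(ref_seq, 4, 23)            # POS=4, 20M, NM=0
  r2 <- substr(ref_seq, 11, 30)           # NM=2 -> discarded
  r3 <- reverse_complement(substr(ref_seq, 31, 50)) # flag 16
  writeLines(c(
    "@HD\tVN:1.6",
    sprintf("@SQ\tSN:samref\tLN:%d", nchar(ref_seq)),
    sprintf("q1\t0\tsamref\t4\t255\t20M\t*\t0\t0\t%s\t*\tNM:i:0", r1),
    sprintf("q2\t0\tsamref\t11\t255\t20M\t*\t0\t0\t%s\t*\tNM:i:2", r2),
    sprintf("q3_x7\t16\tsamref\t31\t255\t20M\t*\t0\t0\t%s\t*\tNM:i:0",
            reverse_complement(r3)),
    sprintf("q4\t0\tsamref\t60\t255\t5S15M\t*\t0\t0\t%s\t*\tNM:i:0",
            substr(ref_seq, 55, 74))
  ), sam)
  res <- import_sam(sam, ref)
  expect_equal(nrow(res$alignments), 2L)
  a1 <- res$alignments[res$alignments$strand == "sense", ]
  expect_equal(a1$ref_start, 3L)
  expect_equal(a1$ref_end, 23L)
  a3 <- res$alignments[res$alignments$strand == "antisense", ]
  expect_equal(a3$read_sequence, r3)
  expect_equal(a3$count, 7L)
  expect_equal(res$n_discarded, 2L) # NM=2 and the soft-clipped record
})

test_that("internally written SAM re-imports to the same placements", {
  set.seed(29)
  ref <- one_region_ref(random_dna(500), id = "rt")
  reads <- vapply(1:25, function(i)
    plant_read(ref$sequence, sample(c("exact", "mismatch", "ins", "del"), 1)),
    character(1))
  res <- align_all(collapse_reads(reads), ref)
  sam <- tempfile(fileext = ".sam")
  write_sam(res$alignments, ref, sam)
  back <- import_sam(sam, ref)
  o1 <- order(res$alignments$ref_start, res$alignments$read_sequence)
  o2 <- order(back$alignments$ref_start, back$alignments$read_sequence)
  expect_equal(back$alignments$ref_start[o2], res$alignments$ref_start[o1])
  expect_equal(back$alignments$ref_end[o2], res$alignments$ref_end[o1])
  expect_equal(back$alignments$strand[o2], res$alignments$strand[o1])
  expect_equal(back$alignments$count[o2], res$alignments$count[o1])
})
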