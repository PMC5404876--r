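# Synthetic-library generator: toy reference construction, planted
# ladders, uniform background, duplication, determinism, ground truth.

test_that("toy reference lays out canonical regions contiguously", {
  ref <- make_toy_reference(c("18S" = 200, "ITS1" = 50, "5.8S" = 157,
                              "ITS2" = 60, "28S" = 400), seed = 9)
  expect_equal(nchar(ref$sequence), 867L)
  r58 <- ref$regions[ref$regions$name == "5.8S", ]
  expect_equal(r58$start, 250L)
  expect_equal(r58$end, 407L)
  expect_equal(ref$regions$role,
               c("gene", "spacer", "gene", "spacer", "gene"))
  expect_identical(make_toy_reference(seed = 4)$sequence,
                   make_toy_reference(seed = 4)$sequence)
  expect_error(make_toy_reference(c("18S" = 10), seed = 1), "at least 30")
})

test_that("identical configuration gives byte-identical FASTQ and truth", {
  ref <- make_toy_reference(seed = 2)
  f1 <- tempfile(); f2 <- tempfile()
  t1 <- tempfile(); t2 <- tempfile()
  for (fq in list(c(f1, t1), c(f2, t2))) {
    simulate_library(ref, default_ladders(), n_background = 500,
                     error_rate = 0.002, seed = 77,
                     fastq_path = fq[1], truth_path = fq[2])
  }
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
})

test_that("3'-anchored ladder reads all end at the gene boundary", {
  ref <- make_toy_reference(seed = 2)
  sim <- simulate_library(ref, ladder_spec("5.8S", "3p", 25, 33, 100),
                          n_background = 0, antisense_fraction = 0,
                          error_rate = 0, seed = 5)
  end58 <- ref$regions$end[ref$regions$name == "5.8S"]
  expect_true(all(sim$truth$ref_end == end58))
  expect_equal(sort(unique(sim$truth$ref_end - sim$truth$ref_start)), 25:33)
  expect_equal(nrow(sim$reads), nrow(sim$truth))
})

test_that("error-free planted reads realign at their true coordinates", {
  ref <- make_toy_reference(seed = 2)
  sim <- simulate_library(ref, default_ladders(), n_background = 100,
                          error_rate = 0, seed = 6)
  col <- collapse_reads(sim$reads)
  res <- align_all(col, ref)
  expect_equal(res$stats$n_aligned_reads, res$stats$n_cleaned_reads)
  expect_true(all(res$alignments$n_mismatch + res$alignments$n_gap == 0))
  by_seq <- stats::setNames(
    paste(res$alignments$ref_start, res$alignments$ref_end),
    res$alignments$read_sequence)
  truth_seq <- substring(ref$sequence, sim$truth$ref_start + 1L,
                         sim$truth$ref_end)
  anti <- sim$truth$strand == "antisense"
  truth_seq[anti] <- reverse_complement(truth_seq[anti])
  # every unique planted sequence aligns somewhere it truly occurs
  agree <- by_seq[truth_seq] == paste(sim$truth$ref_start, sim$truth$ref_end)
  expect_gte(mean(agree), 0.99) # repeats may tie to an earlier exact copy
})

test_that("with a light error rate, planted-read alignment recall stays high", {
  ref <- make_toy_reference(seed = 2)
  sim <- simulate_library(ref, default_ladders(), n_background = 0,
                          error_rate = 0.003, seed = 8)
  res <- align_all(collapse_reads(sim$reads), ref)
  expect_gte(res$stats$n_aligned_reads / res$stats$n_cleaned_reads, 0.99)
})

test_that("a duplication factor fixes a sequence's library share exactly", {
  ref <- make_toy_reference(seed = 2)
  sim <- simulate_library(ref, ladder_spec("5.8S", "5p", 20, 24, 10),
                          n_background = 50, error_rate = 0,
                          antisense_fraction = 0,
                          dup_factors = c("1" = 1000), seed = 10)
  key <- paste(sim$truth$ref_start[1], sim$truth$ref_end[1])
  n_copy <- sum(paste(sim$truth$ref_start, sim$truth$ref_end) == key)
  expect_gte(n_copy, 1000L)
  col <- collapse_reads(sim$reads)
  top <- col$count[1] / sum(col$count)
  expect_equal(col$count[1], n_copy)
  expect_equal(top, n_copy / nrow(sim$reads))
})

test_that("antisense fraction controls strand balance", {
  ref <- make_toy_reference(seed = 2)
  set.seed(12)
  truth <- simulate_fragments(ref, NULL, n_background = 20000,
                              antisense_fraction = 0.2)
  frac <- mean(truth$strand == "antisense")
  expect_gt(frac, 0.15); expect_lt(frac, 0.25)
  set.seed(12)
  none <- simulate_fragments(ref, NULL, n_background = 100,
                             antisense_fraction = 0)
  expect_true(all(none$strand == "sense"))
})

test_that("ladders longer than their region are rejected", {
  ref <- make_toy_reference(seed = 2)
  expect_error(
    simulate_library(ref, ladder_spec("5.8S", "5p", 20, 200, 10), seed = 1),
    "exceeds region")
})

test_that("truth_compare scores recovery, misses and sub-threshold plants", {
  ref <- make_toy_reference(seed = 2)
  # recovered case
  sim <- simulate_library(ref, default_ladders(), n_background = 320,
                          error_rate = 0, seed = 13)
  s <- run_sim_through_pipeline(sim, ref)
  tc <- truth_compare(sim$truth, s, ref)
  expect_equal(tc$precision, 1)
  expect_equal(tc$recall, 1)
  expect_true(all(tc$per_ladder$anchor_match))
  expect_true(all(tc$per_ladder$recovered_run >= tc$per_ladder$planted_range - 1))
  # nothing planted: any call would hurt precision; here none expected
  set.seed(14)
  bg <- simulate_library(ref, NULL, n_background = 500, seed = 14)
  s0 <- run_sim_through_pipeline(bg, ref)
  tc0 <- truth_compare(bg$truth, s0, ref)
  expect_equal(tc0$n_called, 0L)
  # planted but below the abundance threshold
  shallow <- simulate_library(ref, ladder_spec("5.8S", "5p", 25, 27, 1),
                              n_background = 0, error_rate = 0, seed = 15)
  s1 <- run_sim_through_pipeline(shallow, ref)
  tc1 <- truth_compare(shallow$truth, s1, ref)
  if (nrow(shallow$truth) < 10) {
    expect_equal(tc1$per_ladder$status, "missed_below_threshold")
  }
})
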