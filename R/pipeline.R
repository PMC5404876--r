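# End-to-end orchestration: clean -> align (or import SAM) ->
# classify -> series -> enrichment -> report. Per-stage read-count
# conservation is logged so silent read loss is detectable, and every
# reported percentage is stored with its numerator and denominator.

#' Run the rRF discovery pipeline
#'
#' @param reads_path FASTQ/FASTA input (optionally gzipped), or `NULL`
#'   when `sam_path` provides pre-computed alignments.
#' @param ref_path single-record reference FASTA.
#' @param regions_path BED or GFF3 region annotation.
#' @param out_dir output directory for the summary and tables; `NULL`
#'   skips writing.
#' @param sam_path optional SAM file of external alignments (used
#'   instead of the internal aligner; cleaning is skipped).
#' @param adapter optional 3' adapter to trim.
#' @param min_len minimum read length (default 15 nt).
#' @param end_tolerance terminus tolerance in nt (default 0).
#' @param min_run minimum ladder run for a called series (default 3).
#' @param min_total minimum series read count (default 10).
#' @param min_count ladder support per length (default 1).
#' @param exclude read sequences excluded from the coverage profile.
#' @param seed_k aligner seed length (default 7).
#' @param top_n number of top sequences to report (default 10).
#' @param quiet suppress per-stage messages.
#' @return the run summary list (also written to `out_dir` when set):
#'   parameters, QC and mapping statistics, region/class table, series
#'   and enrichment tables, top sequences, coverage.
#' @export
run_pipeline <- function(reads_path = NULL, ref_path, regions_path,
                         out_dir = NULL, sam_path = NULL, adapter = NULL,
                         min_len = 15, end_tolerance = 0, min_run = 3,
                         min_total = 10, min_count = 1,
                         exclude = character(0), seed_k = 7, top_n = 10,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  for (p in c(ref_path, regions_path, reads_path, sam_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file not found: ", p, call. = FALSE)
    }
  }
  if (is.null(reads_path) && is.null(sam_path)) {
    stop("either reads_path or sam_path is required", call. = FALSE)
  }
  ref <- load_reference(ref_path, regions_path)
  say("reference: %s (%d nt, %d regions)", ref$id, nchar(ref$sequence),
      nrow(ref$regions))

  if (is.null(sam_path)) {
    raw <- read_small_rna(reads_path)
    cleaned <- clean_reads(raw, adapter = adapter, min_len = min_len)
    qc <- cleaned$stats
    say("clean: %d raw -> %d cleaned reads", qc$n_raw, qc$n_cleaned)
    collapsed <- collapse_reads(cleaned$reads)
    stopifnot(sum(collapsed$count) == qc$n_cleaned)  # conservation
    aln <- align_all(collapsed, ref, k = seed_k)
  } else {
    aln <- import_sam(sam_path, ref)
    collapsed <- collapse_reads(
      data.frame(sequence = aln$alignments$read_sequence,
                 count = aln$alignments$count, stringsAsFactors = FALSE))
    qc <- structure(list(n_raw = aln$stats$n_cleaned_reads,
                         n_cleaned = aln$stats$n_cleaned_reads,
                         q20_percent = NA_real_,
                         length_histogram = length_distribution(collapsed)),
                    class = "qc_stats")
  }
  ms <- aln$stats
  say("align: %d of %d reads mapped (%d sense / %d antisense)",
      ms$n_aligned_reads, ms$n_cleaned_reads, ms$n_sense, ms$n_antisense)

  classified <- classify_alignments(aln$alignments, ref, tol = end_tolerance)
  stopifnot(sum(classified$count) == ms$n_aligned_reads)  # conservation
  rc <- region_counts(classified, ref)
  series <- call_series(
    group_by_anchor(classified, ref, min_count = min_count),
    min_run = min_run, min_total = min_total)
  enr <- enrichment_table(classified, ref, tol = end_tolerance,
                          min_len = min_len)
  say("series: %d anchored, %d called", nrow(series), sum(series$called))
  cov <- coverage_profile(classified, ref, exclude = exclude)
  tops <- top_sequences(collapsed, max(qc$n_cleaned, 1L), n = top_n)

  summary <- list(
    parameters = list(min_len = min_len, max_edits = 1,
                      end_tolerance = end_tolerance, min_run = min_run,
                      min_total = min_total, min_count = min_count,
                      seed_k = seed_k, adapter = adapter,
                      exclude = as.list(exclude)),
    reference = list(id = ref$id, length = nchar(ref$sequence)),
    qc = list(n_raw = qc$n_raw, n_cleaned = qc$n_cleaned,
              q20_percent = qc$q20_percent),
    mapping = list(
      n_cleaned_reads = ms$n_cleaned_reads,
      n_aligned_reads = ms$n_aligned_reads,
      n_sense = ms$n_sense, n_antisense = ms$n_antisense,
      mapping_rate_percent = if (ms$n_cleaned_reads > 0) mapping_rate(ms)
                             else NA_real_,
      sense_percent = if (ms$n_aligned_reads > 0) strand_fraction(ms)
                      else NA_real_),
    gene_fraction = list(
      n_gene = sum(classified$count[classified$region_name %in%
                                    gene_regions(ref)$name]),
      n_aligned = rc$n_aligned,
      percent = rc$gene_fraction_percent),
    tables = list(
      length_hist = length_histograms(collapsed, classified),
      regions = rc$table,
      series = series_report_table(series),
      enrichment = enr,
      top_seqs = tops,
      coverage = cov$coverage)
  )
  if (!is.null(out_dir)) {
    write_summary(summary, out_dir)
    say("report: written to %s", out_dir)
  }
  # full objects for programmatic use, not serialized to JSON
  summary$objects <- list(reference = ref, collapsed = collapsed,
                          alignments = classified, series = series,
                          mapping_stats = ms, qc_stats = qc)
  invisible(summary)
}
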