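# Descriptive outputs: length distributions, per-base coverage with
# configurable sequence exclusion (to blunt PCR-duplication bias from
# extremely abundant sequences), top-sequence abundance, and a
# machine-readable run summary whose every percentage is recomputable
# from its stored numerator and denominator.

#' Read-length histogram, duplicate-weighted
#'
#' @param items data.frame with a `sequence` (or `read_sequence`)
#'   column and optionally `count` (default 1 per row).
#' @return named integer vector mapping length to read count (names
#'   sorted numerically).
#' @export
length_distribution <- function(items) {
  seqcol <- if ("sequence" %in% names(items)) "sequence" else "read_sequence"
  if (nrow(items) == 0) return(stats::setNames(integer(0), character(0)))
  counts <- if ("count" %in% names(items)) items$count else rep(1L, nrow(items))
  len <- nchar(items[[seqcol]])
  h <- tapply(counts, len, sum)
  h <- h[order(as.integer(names(h)))]
  stats::setNames(as.integer(h), names(h))
}

#' Paired length histograms for all reads and aligned (rRNA) reads
#'
#' @param collapsed collapsed cleaned reads (`sequence`, `count`).
#' @param alns alignment data.frame (`read_sequence`, `count`); read
#'   lengths, not reference spans, are histogrammed.
#' @return data.frame with columns `length`, `all_count`,
#'   `rrna_count`, covering the union of observed lengths.
#' @export
length_histograms <- function(collapsed, alns) {
  h_all <- length_distribution(collapsed)
  h_rrna <- length_distribution(alns)
  lens <- sort(unique(as.integer(c(names(h_all), names(h_rrna)))))
  data.frame(
    length = lens,
    all_count = as.integer(ifelse(is.na(h_all[as.character(lens)]), 0L,
                                  h_all[as.character(lens)])),
    rrna_count = as.integer(ifelse(is.na(h_rrna[as.character(lens)]), 0L,
                                   h_rrna[as.character(lens)])),
    stringsAsFactors = FALSE
  )
}

#' Per-base sense-strand coverage along the reference
#'
#' Each non-excluded sense alignment adds its duplicate count to every
#' reference position it covers. Exclusion is by exact read sequence,
#' mirroring the practice of dropping named, extremely abundant
#' (likely PCR-duplicated) sequences from coverage plots.
#'
#' @param alns alignment data.frame with `count`.
#' @param ref an [annotated_reference()].
#' @param exclude character vector of read sequences to omit.
#' @return list with `coverage` (numeric vector of length
#'   `nchar(ref$sequence)`) and `excluded_sequences`.
#' @export
coverage_profile <- function(alns, ref, exclude = character(0)) {
  L <- nchar(ref$sequence)
  delta <- numeric(L + 1L)
  use <- alns$strand == "sense" & !(alns$read_sequence %in% exclude)
  a <- alns[use, , drop = FALSE]
  for (i in seq_len(nrow(a))) {
    delta[a$ref_start[i] + 1L] <- delta[a$ref_start[i] + 1L] + a$count[i]
    delta[a$ref_end[i] + 1L] <- delta[a$ref_end[i] + 1L] - a$count[i]
  }
  list(coverage = cumsum(delta)[seq_len(L)], excluded_sequences = exclude)
}

#' Most abundant unique sequences
#'
#' @param collapsed data.frame from [collapse_reads()].
#' @param n_cleaned total cleaned read count (percentage denominator).
#' @param n number of sequences to report (default 10).
#' @return data.frame `sequence`, `count`, `percent_of_cleaned`
#'   (half-up, two decimals).
#' @export
top_sequences <- function(collapsed, n_cleaned, n = 10) {
  stopifnot(n >= 1)
  top <- utils::head(collapsed, n)
  data.frame(sequence = top$sequence, count = top$count,
             percent_of_cleaned = percent_of(top$count, n_cleaned, 2),
             stringsAsFactors = FALSE)
}

# Flatten a series data.frame (with its histogram list-column) into a
# plain report table; per-length counts serialize as "len:count" lists.
series_report_table <- function(series) {
  if (nrow(series) == 0) {
    return(data.frame(region_name = character(0), terminus = character(0),
                      anchor_1based = integer(0), total_count = integer(0),
                      max_ladder_run = integer(0), called = logical(0),
                      length_counts = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    region_name = series$region_name,
    terminus = series$terminus,
    anchor_1based = series$anchor + 1L,
    total_count = series$total_count,
    max_ladder_run = series$max_ladder_run,
    called = if ("called" %in% names(series)) series$called else NA,
    length_counts = vapply(series$length_histogram, function(h) {
      paste(sprintf("%s:%d", names(h), as.integer(h)), collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write the run summary and report tables
#'
#' Writes `summary.json` plus TSV tables (`length_hist.tsv`,
#' `coverage.tsv` with 1-based positions, `regions.tsv`, `series.tsv`,
#' `enrichment.tsv`, `top_seqs.tsv`) into a directory. Output is
#' byte-identical across repeated runs on identical input.
#'
#' @param summary run summary list, as assembled by [run_pipeline()].
#' @param destination output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_summary <- function(summary, destination) {
  dir.create(destination, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(destination)) {
    stop("cannot create output directory: ", destination, call. = FALSE)
  }
  tsv <- function(df, name) {
    utils::write.table(df, file.path(destination, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(summary$tables$length_hist, "length_hist.tsv")
  cov <- summary$tables$coverage
  tsv(data.frame(position = seq_along(cov), count = cov), "coverage.tsv")
  tsv(summary$tables$regions, "regions.tsv")
  tsv(summary$tables$series, "series.tsv")
  if (!is.null(summary$tables$enrichment)) {
    tsv(summary$tables$enrichment, "enrichment.tsv")
  }
  tsv(summary$tables$top_seqs, "top_seqs.tsv")
  json <- summary[setdiff(names(summary), "tables")]
  json$tables <- list(
    length_hist = summary$tables$length_hist,
    regions = summary$tables$regions,
    series = summary$tables$series,
    top_seqs = summary$tables$top_seqs
  )
  jsonlite::write_json(json, file.path(destination, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(destination)
}

#' Reload a written run summary
#'
#' @param destination directory written by [write_summary()].
#' @return the summary list parsed from `summary.json`.
#' @export
read_summary <- function(destination) {
  jsonlite::read_json(file.path(destination, "summary.json"),
                      simplifyVector = TRUE)
}
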