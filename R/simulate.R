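# Synthetic sRNA-seq libraries with the statistical structure the
# analysis assumes: terminus-anchored 1-bp ladders over a uniform-
# breakpoint degradation background, near-exclusive sense-strand
# origin, optional substitution error and heavy PCR duplication of a
# few sequences — plus a ground-truth table so every pipeline stage is
# testable without external data.

# Metazoan-scale rDNA unit (~7.7 kb): mature genes at realistic
# lengths with internal transcribed spacers between them.
DEFAULT_REGION_LENGTHS <- c("18S" = 1800L, "ITS1" = 700L, "5.8S" = 157L,
                            "ITS2" = 1100L, "28S" = 3900L)

#' Build a toy annotated rDNA reference
#'
#' Random sequence with contiguous regions in the canonical
#' 18S-ITS1-5.8S-ITS2-28S order (any other names keep their given
#' order). Deterministic under `seed`. Defaults approximate a
#' metazoan rDNA transcription unit.
#'
#' @param region_lengths named integer vector of region lengths in nt
#'   (each >= 30).
#' @param seed integer random seed.
#' @param id reference id label.
#' @return an [annotated_reference()].
#' @export
make_toy_reference <- function(region_lengths = DEFAULT_REGION_LENGTHS,
                               seed = 1, id = "toy_rDNA") {
  if (any(region_lengths < 30)) {
    stop("every region must be at least 30 nt", call. = FALSE)
  }
  canonical <- c("18S", "ITS1", "5.8S", "ITS2", "28S")
  if (all(names(region_lengths) %in% canonical)) {
    region_lengths <- region_lengths[intersect(canonical, names(region_lengths))]
  }
  total <- sum(region_lengths)
  set.seed(as.integer(seed))
  sequence <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
                    collapse = "")
  ends <- cumsum(region_lengths)
  regions <- data.frame(
    name = names(region_lengths),
    start = as.integer(ends - region_lengths),
    end = as.integer(ends),
    role = infer_region_role(names(region_lengths)),
    stringsAsFactors = FALSE
  )
  annotated_reference(id, sequence, regions)
}

#' Specify a planted terminus-anchored ladder
#'
#' @param region_name gene region carrying the ladder.
#' @param terminus `"5p"` or `"3p"` (which gene boundary anchors it).
#' @param length_min,length_max fragment length range in nt; members
#'   are emitted at every integer length in the range.
#' @param count_per_length expected reads per length (Poisson mean).
#' @return one-row data.frame ladder specification; row-bind several
#'   to form a ladder set.
#' @export
ladder_spec <- function(region_name, terminus, length_min, length_max,
                        count_per_length) {
  stopifnot(terminus %in% c("5p", "3p"), length_min >= 15,
            length_min <= length_max, count_per_length > 0)
  data.frame(region_name = region_name, terminus = terminus,
             length_min = as.integer(length_min),
             length_max = as.integer(length_max),
             count_per_length = count_per_length,
             stringsAsFactors = FALSE)
}

#' Draw fragment coordinates under the generative model
#'
#' The generative core shared by [simulate_library()] and by fast
#' statistical calibrations that do not need the sequencing layer:
#' planted ladder fragments anchored at gene boundaries plus uniform-
#' breakpoint background fragments. Randomness uses the current RNG
#' state (seed it with `set.seed()`; [simulate_library()] does so).
#'
#' @inheritParams simulate_library
#' @param bg_length_range background fragment length range (default
#'   15-40 nt, the observed sRNA length span).
#' @return truth data.frame: `origin`, `ref_start`, `ref_end` (0-based
#'   half-open), `strand`.
#' @export
simulate_fragments <- function(ref, ladders = NULL, n_background = 0,
                               antisense_fraction = 2e-4,
                               bg_length_range = c(15L, 40L)) {
  L <- nchar(ref$sequence)
  rg <- ref$regions
  rows <- list()
  if (!is.null(ladders) && nrow(ladders) > 0) {
    for (i in seq_len(nrow(ladders))) {
      ld <- ladders[i, ]
      region <- rg[rg$name == ld$region_name, , drop = FALSE]
      if (nrow(region) != 1) {
        stop("ladder references unknown region: ", ld$region_name, call. = FALSE)
      }
      if (ld$length_max > region$end - region$start) {
        stop(sprintf("ladder length %d exceeds region %s length %d",
                     ld$length_max, ld$region_name, region$end - region$start),
             call. = FALSE)
      }
      lens <- seq.int(ld$length_min, ld$length_max)
      counts <- stats::rpois(length(lens), ld$count_per_length)
      lens <- rep(lens, counts)
      if (length(lens) == 0) next
      if (ld$terminus == "5p") {
        rs <- rep(region$start, length(lens)); re <- region$start + lens
      } else {
        re <- rep(region$end, length(lens)); rs <- region$end - lens
      }
      rows[[length(rows) + 1L]] <- data.frame(
        origin = sprintf("ladder_%s_%s", ld$region_name, ld$terminus),
        ref_start = as.integer(rs), ref_end = as.integer(re),
        stringsAsFactors = FALSE)
    }
  }
  if (n_background > 0) {
    # uniform breakpoints: draw the length, then place the fragment
    # uniformly among positions where it fits. Placing the start first
    # and clipping the length at the reference end would concentrate
    # fragment 3' ends on the last coordinate — an artifact a uniform-
    # breakpoint null does not have.
    len <- sample.int(bg_length_range[2] - bg_length_range[1] + 1L,
                      n_background, replace = TRUE) + bg_length_range[1] - 1L
    len <- pmin(len, L)
    rs <- as.integer(floor(stats::runif(n_background) * (L - len + 1L)))
    rows[[length(rows) + 1L]] <- data.frame(
      origin = "background", ref_start = rs, ref_end = as.integer(rs + len),
      stringsAsFactors = FALSE)
  }
  truth <- if (length(rows) > 0) do.call(rbind, rows)
           else data.frame(origin = character(0), ref_start = integer(0),
                           ref_end = integer(0), stringsAsFactors = FALSE)
  n <- nrow(truth)
  truth$strand <- ifelse(stats::runif(n) < antisense_fraction,
                         "antisense", "sense")
  truth
}

#' Convert a truth table to alignment records
#'
#' Coordinate-level truth as a perfect-alignment data.frame (every
#' fragment placed at its true position with zero edits), for feeding
#' classification and enrichment directly in calibrations.
#'
#' @param truth data.frame from [simulate_fragments()].
#' @return alignment-record data.frame compatible with
#'   [classify_alignments()].
#' @export
truth_as_alignments <- function(truth) {
  data.frame(read_sequence = sprintf("frag%d", seq_len(nrow(truth))),
             ref_start = truth$ref_start, ref_end = truth$ref_end,
             strand = truth$strand, n_mismatch = 0L, n_gap = 0L,
             count = 1L, stringsAsFactors = FALSE)
}

#' Simulate a small RNA sequencing library
#'
#' Planted ladder reads are exact subsequences anchored at the
#' specified gene boundary covering every length in their range
#' (Poisson counts per length); background fragments have uniform
#' start over the reference and uniform length in `bg_length_range`
#' (clipped at the reference end), the simplest random-degradation
#' null. Antisense reads are reverse complements of sense fragments.
#' Substitution errors are applied per base at `error_rate`;
#' duplicated sequences model PCR jackpots.
#'
#' @param ref an [annotated_reference()], e.g. [make_toy_reference()].
#' @param ladders data.frame of [ladder_spec()] rows (or `NULL`).
#' @param n_background number of uniform-breakpoint fragments.
#' @param antisense_fraction probability a fragment is emitted
#'   antisense (default 2e-4, mirroring a 99.98% sense library).
#' @param error_rate per-base substitution probability (default 0).
#' @param dup_factors named integer vector of PCR-duplication factors:
#'   total copies per template fragment, selected by 1-based truth row
#'   index (names); `c("1" = 1000)` emits truth row 1 a thousand times
#'   in total.
#' @param seed integer random seed; fixed seed gives byte-identical
#'   output.
#' @param fastq_path optional path; when given, reads are also written
#'   as Phred+33 FASTQ (constant quality 40).
#' @param truth_path optional path for the truth TSV.
#' @return list with `reads` (data.frame `id`, `sequence`,
#'   `qualities`, `count`) and `truth` (data.frame `read_id`,
#'   `origin`, `ref_start`, `ref_end`, `strand`).
#' @export
simulate_library <- function(ref, ladders = NULL, n_background = 0,
                             antisense_fraction = 2e-4, error_rate = 0,
                             dup_factors = NULL, seed = 1,
                             fastq_path = NULL, truth_path = NULL) {
  stopifnot(antisense_fraction >= 0, antisense_fraction <= 1,
            error_rate >= 0, error_rate <= 1, n_background >= 0)
  set.seed(as.integer(seed))
  truth <- simulate_fragments(ref, ladders, n_background, antisense_fraction)
  if (!is.null(dup_factors) && length(dup_factors) > 0 && nrow(truth) > 0) {
    idx <- as.integer(names(dup_factors))
    f <- as.integer(dup_factors)
    stopifnot(all(idx >= 1 & idx <= nrow(truth)), all(f >= 1))
    # factor f = total copies of the fragment in the library
    truth <- truth[c(seq_len(nrow(truth)),
                     rep(idx, times = f - 1L)), , drop = FALSE]
    rownames(truth) <- NULL
  }
  n <- nrow(truth)
  seqs <- substring(ref$sequence, truth$ref_start + 1L, truth$ref_end)
  anti <- truth$strand == "antisense"
  seqs[anti] <- reverse_complement(seqs[anti])
  if (error_rate > 0 && n > 0) {
    seqs <- vapply(seqs, function(s) {
      m <- nchar(s)
      hit <- which(stats::runif(m) < error_rate)
      if (length(hit) == 0) return(s)
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      for (j in hit) {
        ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
      }
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  ids <- sprintf("read%06d", seq_len(n))
  reads <- data.frame(id = ids, sequence = seqs,
                      qualities = strrep("I", nchar(seqs)),
                      count = rep(1L, n), stringsAsFactors = FALSE)
  truth <- data.frame(read_id = ids, truth, stringsAsFactors = FALSE)
  if (!is.null(fastq_path)) write_fastq(reads, fastq_path)
  if (!is.null(truth_path)) {
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(reads = reads, truth = truth)
}

#' Write reads as Phred+33 FASTQ
#'
#' @param reads data.frame with `id`, `sequence`, `qualities`.
#' @param path output path (".gz" suffix writes gzip).
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  if (nrow(reads) > 0) {
    writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n",
                      reads$qualities), con)
  }
  invisible(path)
}

#' Compare called series against the planted truth
#'
#' @param truth truth data.frame from [simulate_library()].
#' @param called_series data.frame from [call_series()].
#' @param ref the [annotated_reference()] used for both.
#' @param min_total the abundance threshold in force, used to label
#'   planted ladders too shallow to be callable as
#'   `"missed_below_threshold"` rather than pipeline failures.
#' @return list with `per_ladder` (planted anchor, recovered flag,
#'   planted range size vs recovered ladder run, count recall and
#'   status) and scalars `precision`, `recall` over called series
#'   (both `NA` when no ladder was planted and nothing was called).
#' @export
truth_compare <- function(truth, called_series, ref, min_total = 10) {
  rg <- ref$regions
  planted_keys <- unique(truth$origin[startsWith(truth$origin, "ladder_")])
  called <- called_series[called_series$called %in% TRUE, , drop = FALSE]
  called_keys <- sprintf("ladder_%s_%s", called$region_name, called$terminus)
  per <- lapply(planted_keys, function(key) {
    part <- truth[truth$origin == key & truth$strand == "sense", , drop = FALSE]
    nm <- sub("^ladder_", "", key)
    terminus <- sub("^.*_", "", nm)
    region_name <- sub("_[^_]*$", "", nm)
    region <- rg[rg$name == region_name, , drop = FALSE]
    anchor <- if (terminus == "5p") region$start else region$end
    planted_lengths <- sort(unique(part$ref_end - part$ref_start))
    hit <- called[called$region_name == region_name &
                  called$terminus == terminus, , drop = FALSE]
    recovered <- nrow(hit) == 1
    status <- if (recovered) "recovered"
              else if (nrow(part) < min_total) "missed_below_threshold"
              else "missed"
    data.frame(
      ladder = key, region_name = region_name, terminus = terminus,
      planted_anchor = as.integer(anchor),
      recovered = recovered,
      anchor_match = recovered && hit$anchor == anchor,
      planted_range = length(planted_lengths),
      recovered_run = if (recovered) hit$max_ladder_run else 0L,
      count_recall = if (recovered) min(1, hit$total_count / nrow(part))
                     else 0,
      status = status, stringsAsFactors = FALSE)
  })
  per <- if (length(per) > 0) do.call(rbind, per)
         else data.frame(ladder = character(0), recovered = logical(0),
                         status = character(0), stringsAsFactors = FALSE)
  callable <- planted_keys %in% per$ladder[per$status != "missed_below_threshold"]
  tp <- sum(called_keys %in% planted_keys)
  precision <- if (nrow(called) == 0) NA_real_ else tp / nrow(called)
  recall <- if (sum(callable) == 0) NA_real_
            else sum(per$recovered[callable]) / sum(callable)
  list(per_ladder = per, precision = precision, recall = recall,
       n_called = nrow(called), n_planted = length(planted_keys))
}
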