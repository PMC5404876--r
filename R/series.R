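# Terminus-anchored fragment series: grouping by anchor, 1-bp ladder
# detection, and terminal enrichment testing against a uniform-
# degradation null.
#
# A series is the set of fragments sharing one anchored terminus of a
# gene (5' start for rRF5, 3' end for rRF3). The signature of
# nuclease-generated series, as opposed to random degradation, is a
# ladder: consecutive integer fragment lengths all represented.

#' Longest 1-bp ladder run in a length histogram
#'
#' Length of the longest run of consecutive integer lengths L, L+1,
#' ..., L+r-1 each supported by at least `min_count` reads.
#'
#' @param hist named numeric vector mapping fragment length to read
#'   count (names are integer lengths).
#' @param min_count minimum count for a length to support the ladder
#'   (default 1).
#' @return integer run length (0 for an empty histogram or when no
#'   length reaches `min_count`).
#' @export
max_ladder_run <- function(hist, min_count = 1) {
  if (length(hist) == 0) return(0L)
  lens <- sort(as.integer(names(hist)[hist >= min_count]))
  if (length(lens) == 0) return(0L)
  r <- rle(c(TRUE, diff(lens) == 1L))
  max(r$lengths[r$values])
}

#' Group terminal fragments into anchored series
#'
#' One series per (gene, terminus) with at least one member fragment.
#' rRF5 members share the gene-start coordinate (within the tolerance
#' already applied by [classify_alignments()]); rRF3 members share the
#' gene end. Fragment length is the reference span `ref_end -
#' ref_start`, so a 1-nt-deletion variant of a 30-nt fragment counts
#' at reference length 30 — anchors live in reference coordinates.
#' Full-length fragments (both offsets within tolerance) count toward
#' the 5' series, where the rRF5-first classification placed them.
#'
#' @param classified data.frame from [classify_alignments()] with
#'   `count`.
#' @param ref an [annotated_reference()].
#' @param min_count ladder support threshold passed to
#'   [max_ladder_run()] (default 1).
#' @param include_antisense include antisense fragments (default
#'   FALSE; terminal antisense fragments are tallied separately
#'   upstream and are near-absent in sense-dominated libraries).
#' @return data.frame with one row per series: `region_name`,
#'   `terminus` (`"5p"`/`"3p"`), `anchor` (0-based boundary
#'   coordinate), `total_count`, `n_lengths`, `max_ladder_run`, and a
#'   `length_histogram` list-column of named count vectors.
#' @export
group_by_anchor <- function(classified, ref, min_count = 1,
                            include_antisense = FALSE) {
  stopifnot(min_count >= 1)
  keep <- classified$terminus_class %in% c("rRF5", "rRF3")
  if (!include_antisense) keep <- keep & classified$strand == "sense"
  x <- classified[keep, , drop = FALSE]
  empty <- data.frame(region_name = character(0), terminus = character(0),
                      anchor = integer(0), total_count = integer(0),
                      n_lengths = integer(0), max_ladder_run = integer(0),
                      stringsAsFactors = FALSE)
  empty$length_histogram <- list()
  if (nrow(x) == 0) return(empty)
  x$terminus <- ifelse(x$terminus_class == "rRF5", "5p", "3p")
  key <- paste(x$region_name, x$terminus, sep = "\r")
  rg <- ref$regions
  rows <- lapply(split(seq_len(nrow(x)), key), function(ii) {
    g <- x[ii, , drop = FALSE]
    region <- rg[rg$name == g$region_name[1], , drop = FALSE]
    anchor <- if (g$terminus[1] == "5p") region$start else region$end
    lens <- g$ref_end - g$ref_start
    h <- tapply(g$count, lens, sum)
    hist <- stats::setNames(as.numeric(h), names(h))
    out <- data.frame(region_name = g$region_name[1],
                      terminus = g$terminus[1],
                      anchor = as.integer(anchor),
                      total_count = sum(g$count),
                      n_lengths = length(hist),
                      max_ladder_run = max_ladder_run(hist, min_count),
                      stringsAsFactors = FALSE)
    out$length_histogram <- list(hist)
    out
  })
  out <- do.call(rbind, rows)
  o <- order(out$region_name, out$terminus)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call series passing ladder and abundance thresholds
#'
#' A series is called when its longest 1-bp ladder spans at least
#' `min_run` consecutive lengths and its total read count reaches
#' `min_total`. The defaults (run 3, total 10) ensure a lone fragment
#' or a pair never constitutes a series.
#'
#' @param series data.frame from [group_by_anchor()].
#' @param min_run minimum ladder run (default 3).
#' @param min_total minimum total read count (default 10).
#' @return the input with a logical `called` column, sorted by
#'   descending `total_count`.
#' @export
call_series <- function(series, min_run = 3, min_total = 10) {
  stopifnot(min_run >= 1, min_total >= 1)
  if (nrow(series) == 0) {
    series$called <- logical(0)
    return(series)
  }
  series$called <- series$max_ladder_run >= min_run &
                   series$total_count >= min_total
  series <- series[order(-series$total_count, series$region_name,
                         series$terminus), , drop = FALSE]
  rownames(series) <- NULL
  series
}

#' Terminal enrichment test for one gene terminus
#'
#' Tests whether fragments anchor at a gene boundary more often than
#' expected under a uniform-degradation null, in which each fragment's
#' anchored coordinate (5' start or 3' end) is uniform over the
#' region's possible positions. Only sense fragments fully contained
#' in the region enter the test. The p-value is the one-sided binomial
#' tail P[X >= observed] with X ~ Binomial(total, p0), where p0 is the
#' number of anchor positions within tolerance of the boundary
#' (1 + tol at a region edge, clipped to the region) over
#' `n_start_positions = region length - min_len + 1`.
#'
#' @param classified data.frame from [classify_alignments()] with
#'   `count`.
#' @param ref an [annotated_reference()].
#' @param region_name a gene region name.
#' @param terminus `"5p"` or `"3p"`.
#' @param tol boundary tolerance in nt (default 0).
#' @param min_len minimum fragment length the library can contain
#'   (default 15), which bounds the number of distinct anchor
#'   positions.
#' @return one-row data.frame: `region_name`, `terminus`,
#'   `observed_terminal_count`, `total_region_count`,
#'   `n_start_positions`, `expected_fraction`, `fold_enrichment`,
#'   `p_value`.
#' @export
end_vs_body_enrichment <- function(classified, ref, region_name, terminus,
                                   tol = 0, min_len = 15) {
  stopifnot(terminus %in% c("5p", "3p"), tol >= 0)
  rg <- ref$regions
  region <- rg[rg$name == region_name, , drop = FALSE]
  if (nrow(region) != 1) stop("unknown region: ", region_name, call. = FALSE)
  L <- region$end - region$start
  n_pos <- L - min_len + 1L
  if (n_pos < 2) {
    stop(sprintf("region %s degenerate for enrichment (%d anchor positions)",
                 region_name, n_pos), call. = FALSE)
  }
  inside <- classified$region_name == region_name &
            classified$strand == "sense"
  x <- classified[inside, , drop = FALSE]
  total <- sum(x$count)
  if (total == 0) {
    stop(sprintf("no fragments in region %s", region_name), call. = FALSE)
  }
  anchor_coord <- if (terminus == "5p") x$ref_start else x$ref_end
  boundary <- if (terminus == "5p") region$start else region$end
  observed <- sum(x$count[abs(anchor_coord - boundary) <= tol])
  # anchor positions within tol of the boundary that a contained
  # >= min_len fragment can actually occupy
  n_boundary_pos <- min(tol + 1L, n_pos)
  p0 <- n_boundary_pos / n_pos
  p <- stats::pbinom(observed - 1, size = total, prob = p0, lower.tail = FALSE)
  data.frame(region_name = region_name, terminus = terminus,
             observed_terminal_count = observed,
             total_region_count = total,
             n_start_positions = n_pos,
             expected_fraction = p0,
             fold_enrichment = (observed / total) / p0,
             p_value = p,
             stringsAsFactors = FALSE)
}

#' Enrichment table over all gene termini
#'
#' Runs [end_vs_body_enrichment()] for every (gene, terminus) pair
#' with at least one contained fragment and applies Benjamini-Hochberg
#' correction across the pairs.
#'
#' @inheritParams end_vs_body_enrichment
#' @return data.frame with one row per testable (gene, terminus) pair
#'   and a BH-adjusted `q_value` column; zero rows when no gene holds
#'   fragments.
#' @export
enrichment_table <- function(classified, ref, tol = 0, min_len = 15) {
  genes <- gene_regions(ref)$name
  rows <- list()
  for (g in genes) {
    has <- any(classified$region_name == g & classified$strand == "sense")
    if (!has) next
    for (term in c("5p", "3p")) {
      rows[[paste(g, term)]] <-
        end_vs_body_enrichment(classified, ref, g, term, tol, min_len)
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(region_name = character(0), terminus = character(0),
                      observed_terminal_count = integer(0),
                      total_region_count = integer(0),
                      n_start_positions = integer(0),
                      expected_fraction = numeric(0),
                      fold_enrichment = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
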