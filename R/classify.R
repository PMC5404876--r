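# Terminus classification of aligned fragments relative to annotated
# gene boundaries. A fragment whose 5' end coincides with a gene's 5'
# boundary (within tolerance) is an rRF5; one whose 3' end coincides
# with the gene's 3' boundary is an rRF3; other fragments contained in
# a region are "body". Fragments crossing a region edge are "spanning"
# and fragments in annotation gaps "unannotated".

TERMINUS_CLASSES <- c("rRF5", "rRF3", "body", "spanning", "unannotated")

#' Classify alignments by region and terminus
#'
#' The rRF5 check precedes the rRF3 check, so a fragment matching an
#' entire short gene (both offsets within tolerance) is classed rRF5
#' and additionally flagged `full_length`. Antisense alignments are
#' classified against the same sense-strand boundaries (a gene's 5'
#' end means the sense-strand 5' boundary) and distinguished only by
#' their `strand` column. Only gene regions can yield rRF5/rRF3;
#' spacer-contained fragments are "body".
#'
#' @param alns alignment data.frame ([align_all()] `$alignments`).
#' @param ref an [annotated_reference()].
#' @param tol boundary tolerance in nt (default 0: "precisely
#'   aligned"). Mature-rRNA annotations are often off by 1-2 nt, so
#'   this is exposed rather than hard-coded.
#' @return the input data.frame with columns `region_name` (a region
#'   name, `"spanning"` or `"unannotated"`), `offset5`
#'   (`ref_start - region start`), `offset3` (`region end - ref_end`;
#'   both `NA` outside a single region), `terminus_class` and
#'   `full_length` appended.
#' @export
classify_alignments <- function(alns, ref, tol = 0) {
  stopifnot(tol >= 0)
  n <- nrow(alns)
  rg <- ref$regions
  region_name <- rep("unannotated", n)
  offset5 <- rep(NA_integer_, n)
  offset3 <- rep(NA_integer_, n)
  cls <- rep("unannotated", n)
  full <- rep(FALSE, n)
  if (n > 0 && nrow(rg) > 0) {
    rs <- alns$ref_start
    re <- alns$ref_end
    # candidate containing region: the last region starting at or
    # before rs (regions are sorted and non-overlapping)
    i <- findInterval(rs, rg$start)
    contained <- i >= 1 & i <= nrow(rg)
    contained[contained] <- rs[contained] < rg$end[i[contained]] &
                            re[contained] <= rg$end[i[contained]]
    # overlap count for the rest
    for (j in which(!contained)) {
      ov <- rg$start < re[j] & rg$end > rs[j]
      if (any(ov)) {
        region_name[j] <- "spanning"
        cls[j] <- "spanning"
      }
    }
    idx <- which(contained)
    if (length(idx) > 0) {
      ri <- i[idx]
      region_name[idx] <- rg$name[ri]
      offset5[idx] <- rs[idx] - rg$start[ri]
      offset3[idx] <- rg$end[ri] - re[idx]
      is_gene <- rg$role[ri] == "gene"
      is5 <- is_gene & offset5[idx] <= tol
      is3 <- is_gene & offset3[idx] <= tol
      cls[idx] <- ifelse(is5, "rRF5", ifelse(is3, "rRF3", "body"))
      full[idx] <- is5 & is3
    }
  }
  alns$region_name <- region_name
  alns$offset5 <- offset5
  alns$offset3 <- offset3
  alns$terminus_class <- cls
  alns$full_length <- full
  alns
}

#' Count-weighted region/class table
#'
#' @param classified data.frame from [classify_alignments()] (must
#'   carry a `count` column).
#' @param ref an [annotated_reference()].
#' @return list with `table` (counts by `region_name` x
#'   `terminus_class`), `n_aligned` (total read count; the table sums
#'   to it), and `gene_fraction_percent` — the percentage of aligned
#'   reads derived from gene regions (spanning reads count toward the
#'   denominator only), `NA` for empty input.
#' @export
region_counts <- function(classified, ref) {
  if (nrow(classified) == 0) {
    return(list(table = data.frame(region_name = character(0),
                                   terminus_class = character(0),
                                   count = integer(0),
                                   stringsAsFactors = FALSE),
                n_aligned = 0L, gene_fraction_percent = NA_real_))
  }
  agg <- stats::aggregate(count ~ region_name + terminus_class,
                          data = classified, FUN = sum)
  agg <- agg[order(agg$region_name, agg$terminus_class), , drop = FALSE]
  rownames(agg) <- NULL
  total <- sum(classified$count)
  genes <- gene_regions(ref)$name
  in_gene <- sum(classified$count[classified$region_name %in% genes])
  list(table = agg, n_aligned = total,
       gene_fraction_percent = percent_of(in_gene, total, digits = 1))
}
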