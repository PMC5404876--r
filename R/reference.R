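# Annotated rDNA reference: a single sequence plus ordered, named,
# non-overlapping regions (mature rRNA genes and transcribed spacers).
# All internal coordinates are 0-based half-open; 1-based coordinates
# appear only in human-readable reports and in GFF3/SAM I/O.

#' Construct an annotated rDNA reference
#'
#' @param id reference identifier (e.g. an accession label).
#' @param sequence nucleotide string over A, C, G, T, N.
#' @param regions data.frame with columns `name`, `start` (0-based
#'   inclusive), `end` (0-based exclusive), `role` (`"gene"` or
#'   `"spacer"`). Regions must be non-overlapping and within the
#'   sequence; they are stored sorted by `start`.
#' @return an object of class `annotated_reference`.
#' @export
annotated_reference <- function(id, sequence, regions) {
  stopifnot(is.character(id), length(id) == 1,
            is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("reference sequence is empty", call. = FALSE)
  check_dna_alphabet(sequence, "reference sequence")
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  required <- c("name", "start", "end", "role")
  if (!all(required %in% names(regions))) {
    stop("regions must have columns name, start, end, role", call. = FALSE)
  }
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  validate_regions(regions, nchar(sequence))
  regions <- regions[order(regions$start), required, drop = FALSE]
  rownames(regions) <- NULL
  structure(list(id = id, sequence = sequence, regions = regions),
            class = "annotated_reference")
}

validate_regions <- function(regions, ref_len) {
  if (nrow(regions) == 0) return(invisible(regions))
  bad <- regions$start >= regions$end
  if (any(bad)) {
    stop("invalid region(s) with start >= end: ",
         paste(regions$name[bad], collapse = ", "), call. = FALSE)
  }
  oob <- regions$start < 0 | regions$end > ref_len
  if (any(oob)) {
    stop("region(s) out of reference bounds [0,", ref_len, "): ",
         paste(regions$name[oob], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(regions$name)) {
    stop("duplicated region name(s): ",
         paste(unique(regions$name[duplicated(regions$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(regions$role %in% c("gene", "spacer"))) {
    stop("region role must be 'gene' or 'spacer'", call. = FALSE)
  }
  o <- order(regions$start)
  s <- regions$start[o]; e <- regions$end[o]; nm <- regions$name[o]
  if (nrow(regions) > 1) {
    ov <- which(s[-1] < e[-nrow(regions)])
    if (length(ov) > 0) {
      stop("overlapping regions: ",
           paste(sprintf("%s/%s", nm[ov], nm[ov + 1]), collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(regions)
}

#' @export
print.annotated_reference <- function(x, ...) {
  cat(sprintf("annotated_reference '%s' (%d nt, %d regions)\n",
              x$id, nchar(x$sequence), nrow(x$regions)))
  if (nrow(x$regions) > 0) print(x$regions)
  invisible(x)
}

# Infer gene/spacer role from a region name: transcribed spacers
# (ITS1, ITS2, 5'ETS, ...) are spacers, everything else a gene.
infer_region_role <- function(name) {
  ifelse(grepl("ITS|ETS|SPACER", toupper(name)), "spacer", "gene")
}

#' Load an annotated reference from FASTA plus BED or GFF3
#'
#' The FASTA must contain exactly one record. BED intervals are taken as
#' 0-based half-open with the region name in column 4; GFF3 intervals are
#' 1-based inclusive (converted internally) with the region name from the
#' `Name` (or, failing that, `ID`) attribute. Region roles are inferred
#' from names (`ITS`/`ETS` -> spacer, otherwise gene) unless overridden.
#'
#' @param fasta_source path to a single-record FASTA file.
#' @param annotation_source path to a BED or GFF3 file whose intervals
#'   reference the FASTA record id.
#' @param roles optional named character vector mapping region names to
#'   `"gene"`/`"spacer"`, overriding the name-based inference.
#' @return an [annotated_reference()].
#' @export
load_reference <- function(fasta_source, annotation_source, roles = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_source)
  if (length(seqs) != 1) {
    stop(sprintf("reference FASTA must contain exactly one record, found %d",
                 length(seqs)), call. = FALSE)
  }
  ref_id <- sub("\\s.*$", "", names(seqs)[1])
  gr <- rtracklayer::import(annotation_source)
  if (length(gr) == 0) stop("annotation contains no intervals", call. = FALSE)
  seqn <- as.character(GenomicRanges::seqnames(gr))
  if (!all(seqn == ref_id)) {
    stop(sprintf("annotation references '%s' but FASTA record is '%s'",
                 paste(unique(setdiff(seqn, ref_id)), collapse = ","), ref_id),
         call. = FALSE)
  }
  mc <- S4Vectors::mcols(gr)
  nm <- if ("name" %in% names(mc)) as.character(mc$name)
        else if ("Name" %in% names(mc) && !all(is.na(mc$Name))) as.character(mc$Name)
        else if ("ID" %in% names(mc)) as.character(mc$ID)
        else stop("annotation intervals carry no name (BED column 4 or GFF3 Name/ID)",
                  call. = FALSE)
  if (anyNA(nm)) stop("annotation interval(s) without a name", call. = FALSE)
  # GRanges is 1-based inclusive regardless of source format; rtracklayer
  # has already applied the BED offset. Convert to 0-based half-open.
  regions <- data.frame(
    name = nm,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  regions$role <- infer_region_role(regions$name)
  if (!is.null(roles)) {
    hit <- regions$name %in% names(roles)
    regions$role[hit] <- unname(roles[regions$name[hit]])
  }
  annotated_reference(ref_id, as.character(seqs[[1]]), regions)
}

#' Write reference regions to BED
#'
#' Coordinates round-trip exactly through [load_reference()].
#'
#' @param ref an [annotated_reference()].
#' @param path output BED path.
#' @return the path, invisibly.
#' @export
write_regions_bed <- function(ref, path) {
  df <- ref$regions
  lines <- sprintf("%s\t%d\t%d\t%s", ref$id, df$start, df$end, df$name)
  writeLines(lines, path)
  invisible(path)
}

#' Assign an interval to a reference region
#'
#' @param ref an [annotated_reference()].
#' @param start,end 0-based half-open interval on the reference.
#' @return a list with `status` (`"region"`, `"spanning"` or
#'   `"unannotated"`) and `regions` (names of the containing region, or
#'   all overlapped regions for `"spanning"`).
#' @export
region_at <- function(ref, start, end) {
  if (start >= end) stop("start must be < end", call. = FALSE)
  if (start < 0 || end > nchar(ref$sequence)) {
    stop("interval out of reference bounds", call. = FALSE)
  }
  rg <- ref$regions
  overlapped <- which(rg$start < end & rg$end > start)
  if (length(overlapped) == 0) {
    return(list(status = "unannotated", regions = character(0)))
  }
  containing <- overlapped[rg$start[overlapped] <= start &
                           rg$end[overlapped] >= end]
  if (length(containing) == 1) {
    return(list(status = "region", regions = rg$name[containing]))
  }
  list(status = "spanning", regions = rg$name[overlapped])
}

# Region rows restricted to genes, in reference order.
gene_regions <- function(ref) {
  ref$regions[ref$regions$role == "gene", , drop = FALSE]
}
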