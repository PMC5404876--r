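# Shared helpers: rounding, percentages, sequence utilities.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (half-up for positive values), the convention used for all reported
#' percentages. Base R's `round()` rounds half to even, which does not
#' reproduce conventional report rounding of e.g. 30.35 to 30.4.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up. This single formula
#' backs every percentage the pipeline reports (mapping rate, strand
#' fraction, top-sequence shares, gene-derived fraction), so each is
#' recomputable from its stored numerator and denominator.
#'
#' @param numerator,denominator numeric.
#' @param digits decimal places to keep (default 2).
#' @return numeric percentage in `[0, 100]` for valid inputs.
#' @export
percent_of <- function(numerator, denominator, digits = 2) {
  round_half_up(100 * numerator / denominator, digits)
}

#' Reverse complement of DNA sequences
#'
#' @param x character vector of sequences over A, C, G, T, N.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0) return(character(0))
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) rawToChar(rev(charToRaw(s))),
         character(1), USE.NAMES = FALSE)
}

# Validate sequence alphabet; returns invisibly or stops.
check_dna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N} (first offender: %s)",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}

# Integer Phred scores from a Phred+33 quality string.
phred_scores <- function(qual) {
  as.integer(charToRaw(qual)) - 33L
}

# Stable deterministic ordering helper: by descending count, ties
# broken lexicographically by sequence (C locale).
order_by_count_then_seq <- function(count, sequence) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  order(-count, sequence)
}
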