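# Per-contig and whole-assembly numeric statistics.

as_dna <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  out <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(out) <- names(x)
  out
}

#' GC fraction of contigs
#'
#' GC is computed over unambiguous bases only: (G + C) / (A + C + G + T),
#' case-insensitive.  N and other IUPAC ambiguity codes are excluded
#' from both numerator and denominator, so gappy scaffolds are not
#' systematically dragged toward mid-GC.  A contig with no unambiguous
#' base gets GC 0 and its id is recorded in the `"no_acgt"` attribute.
#'
#' @param contigs a [Biostrings::DNAStringSet] or character vector of
#'   sequences.
#' @return Numeric vector in `[0, 1]`, named when the input is named.
#' @examples
#' gc_fraction(c("ACGT", "ACGN"))   # 0.5, 2/3
#' @export
gc_fraction <- function(contigs) {
  x <- as_dna(contigs)
  counts <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  denom <- rowSums(counts)
  gc <- ifelse(denom > 0, (counts[, "C"] + counts[, "G"]) / denom, 0)
  gc <- as.numeric(gc)
  names(gc) <- names(x)
  degenerate <- which(denom == 0)
  if (length(degenerate)) {
    attr(gc, "no_acgt") <- if (is.null(names(x))) degenerate else names(x)[degenerate]
  }
  gc
}

#' Drop contigs shorter than a minimum length
#'
#' The boundary is kept: "smaller than `min_len`" is removed, a contig
#' of exactly `min_len` bases survives.  Input order is preserved.
#'
#' @param contigs a [Biostrings::DNAStringSet].
#' @param min_len minimum length in bases (default 200).
#' @return The filtered `DNAStringSet`.
#' @export
filter_min_length <- function(contigs, min_len = 200L) {
  stopifnot(min_len >= 0)
  contigs[Biostrings::width(contigs) >= min_len]
}

#' Whole-assembly summary statistics
#'
#' Span counts every residue including N.  N50 is the length-weighted
#' median: sort contigs by descending length (ties broken by seqid for
#' determinism) and report the length of the first contig at which the
#' cumulative sum reaches at least half the span.
#'
#' @param contigs a [Biostrings::DNAStringSet], or a numeric vector of
#'   contig lengths.
#' @param min_length_applied the minimum-length filter already applied
#'   to `contigs`, recorded in the summary (default 0).
#' @return An `assembly_summary`: list with `n_contigs`, `span`,
#'   `mean_length`, `n50`, `min_length_applied`.
#' @examples
#' assembly_summary(c(5, 4, 3, 2, 1))  # span 15, N50 4
#' @export
assembly_summary <- function(contigs, min_length_applied = 0L) {
  if (is.numeric(contigs)) {
    lens <- as.numeric(contigs)
    ids <- if (is.null(names(contigs))) as.character(seq_along(lens)) else names(contigs)
  } else {
    lens <- as.numeric(Biostrings::width(contigs))
    ids <- names(contigs)
    if (is.null(ids)) ids <- as.character(seq_along(lens))
  }
  if (!length(lens)) {
    return(structure(list(n_contigs = 0L, span = 0L, mean_length = 0,
                          n50 = 0L, min_length_applied = as.integer(min_length_applied)),
                     class = "assembly_summary"))
  }
  ord <- order(-lens, ids)
  sorted <- lens[ord]
  span <- sum(sorted)
  n50 <- sorted[which(cumsum(sorted) >= span / 2)[1]]
  structure(list(n_contigs = length(lens),
                 span = span,
                 mean_length = span / length(lens),
                 n50 = as.integer(n50),
                 min_length_applied = as.integer(min_length_applied)),
            class = "assembly_summary")
}

#' @export
print.assembly_summary <- function(x, ...) {
  cat(sprintf("Assembly summary (min length filter: %d bp)\n",
              x$min_length_applied))
  cat(sprintf("  contigs:     %s\n", format(x$n_contigs, big.mark = ",")))
  cat(sprintf("  span (bp):   %s\n", format(x$span, big.mark = ",")))
  cat(sprintf("  mean (bp):   %s\n",
              format(round(x$mean_length), big.mark = ",")))
  cat(sprintf("  N50 (bp):    %s\n", format(x$n50, big.mark = ",")))
  invisible(x)
}

# machine-readable one-row TSV rendering of a summary
format_summary_tsv <- function(x) {
  c("n_contigs\tspan\tmean_length\tn50\tmin_length_applied",
    sprintf("%d\t%.0f\t%.2f\t%d\t%d", x$n_contigs, x$span, x$mean_length,
            x$n50, x$min_length_applied))
}
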