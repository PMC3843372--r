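# Per-contig, per-library mean read depth from alignments.
#
# Depth of a contig is the total read-supported reference length of its
# primary mapped alignments divided by the contig length; this is the
# base-depth semantic (reads contribute the bases they align, not a
# flat count).  Secondary and supplementary records are excluded so a
# read contributes at most once, mirroring `-k 1` style mapping.
# Duplicates are not removed: relative molarity, not precision, is the
# goal.

#' Compute per-contig mean read depth for one library
#'
#' @param alignments a `tagc_alignments` data frame from
#'   [read_alignments()].
#' @param contig_lengths named integer vector giving the length of
#'   every contig in the assembly; mapped records naming a contig
#'   outside this set are an error (guards against an assembly/BAM
#'   mismatch).
#' @param label library label for the resulting coverage column.
#' @return A `library_coverage`: list with `library_label`,
#'   `depth_by_contig` (named numeric over all contigs, 0 when no
#'   alignment), `n_reads_total` and `n_reads_mapped` (primary records
#'   only).
#' @export
compute_coverage <- function(alignments, contig_lengths, label) {
  stopifnot(!is.null(names(contig_lengths)))
  prim <- alignments[alignments$is_primary, , drop = FALSE]
  mapped <- prim[prim$is_mapped, , drop = FALSE]
  unknown <- setdiff(unique(mapped$contig_id), names(contig_lengths))
  if (length(unknown)) {
    format_error("library '%s': mapped record(s) name contig(s) absent from the assembly: %s",
                 label, paste(unknown, collapse = ", "))
  }
  depth <- stats::setNames(numeric(length(contig_lengths)),
                           names(contig_lengths))
  if (nrow(mapped)) {
    bases <- ref_consumed_len(mapped$cigar)
    per_contig <- tapply(bases, mapped$contig_id, sum)
    depth[names(per_contig)] <- as.numeric(per_contig) /
      as.numeric(contig_lengths[names(per_contig)])
  }
  structure(list(library_label = label,
                 depth_by_contig = depth,
                 n_reads_total = nrow(prim),
                 n_reads_mapped = nrow(mapped)),
            class = "library_coverage")
}

#' Fraction of reads mapped
#'
#' @param cov a `library_coverage`.
#' @return `n_reads_mapped / n_reads_total`.
#' @export
mapped_fraction <- function(cov) {
  if (cov$n_reads_total <= 0L) {
    format_error("library '%s': cannot compute mapped fraction of zero reads",
                 cov$library_label)
  }
  cov$n_reads_mapped / cov$n_reads_total
}

#' Merge per-library coverages into a combined library
#'
#' Depth is additive in reads, so the combined depth is the per-contig
#' sum; read counts are summed likewise.
#'
#' @param covs list of `library_coverage` objects over the same contig
#'   set.
#' @param combined_label label for the merged pseudo-library.
#' @return A `library_coverage`.
#' @export
merge_coverages <- function(covs, combined_label = "total") {
  stopifnot(length(covs) >= 1L)
  ref <- sort(names(covs[[1]]$depth_by_contig))
  for (cv in covs[-1]) {
    if (!identical(sort(names(cv$depth_by_contig)), ref)) {
      format_error("cannot merge coverages computed over different contig sets")
    }
  }
  depth <- covs[[1]]$depth_by_contig
  if (length(covs) > 1L) {
    for (cv in covs[-1]) {
      depth <- depth + cv$depth_by_contig[names(depth)]
    }
  }
  structure(list(library_label = combined_label,
                 depth_by_contig = depth,
                 n_reads_total = sum(vapply(covs, `[[`, numeric(1), "n_reads_total")),
                 n_reads_mapped = sum(vapply(covs, `[[`, numeric(1), "n_reads_mapped"))),
            class = "library_coverage")
}

#' @export
print.library_coverage <- function(x, ...) {
  cat(sprintf("library_coverage '%s': %d contigs, %d/%d primary reads mapped\n",
              x$library_label, length(x$depth_by_contig),
              x$n_reads_mapped, x$n_reads_total))
  invisible(x)
}
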