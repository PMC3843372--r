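# Collation of GC, coverage and taxonomy into the central TAGC table,
# plus subsampling, the legend threshold rule, and the relative
# molarity calculation that motivates coverage as a molarity proxy.

#' Build the TAGC table
#'
#' One row per contig, in assembly order: seqid, length, GC, one
#' coverage column per library plus a combined `cov_total` column
#' (depth is additive across libraries), then one taxon column per
#' rank.  This is the single artifact every downstream step (plotting,
#' selection, binning) consumes.
#'
#' @param contigs a named [Biostrings::DNAStringSet] (the assembly).
#' @param coverages list of `library_coverage` objects, each computed
#'   over exactly the assembly's contig set.
#' @param annotations data frame from [annotate_contigs()] covering all
#'   contigs.
#' @param ranks ranks to include; default: every non-`seqid` column of
#'   `annotations`.
#' @return A `tagc_table` data frame.
#' @export
build_table <- function(contigs, coverages, annotations, ranks = NULL) {
  seqids <- names(contigs)
  if (is.null(seqids)) format_error("assembly contigs must be named")
  if (is.null(ranks)) ranks <- setdiff(names(annotations), "seqid")
  labels <- vapply(coverages, `[[`, character(1), "library_label")
  if (anyDuplicated(labels) || "total" %in% labels) {
    format_error("library labels must be unique and must not include 'total'")
  }
  for (cv in coverages) {
    missing <- setdiff(seqids, names(cv$depth_by_contig))
    if (length(missing)) {
      format_error("coverage '%s' is missing contig(s): %s",
                   cv$library_label, paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  ann_idx <- match(seqids, annotations$seqid)
  if (anyNA(ann_idx)) {
    format_error("annotations are missing contig(s): %s",
                 paste(utils::head(seqids[is.na(ann_idx)], 5), collapse = ", "))
  }
  out <- data.frame(seqid = seqids,
                    length = as.integer(Biostrings::width(contigs)),
                    gc = unname(gc_fraction(contigs)),
                    stringsAsFactors = FALSE)
  for (cv in coverages) {
    out[[paste0("cov_", cv$library_label)]] <-
      unname(cv$depth_by_contig[seqids])
  }
  total <- merge_coverages(coverages, "total")
  out[["cov_total"]] <- unname(total$depth_by_contig[seqids])
  for (rk in ranks) {
    if (!rk %in% names(annotations)) {
      format_error("annotations lack requested rank '%s'", rk)
    }
    out[[paste0("taxlevel_", rk)]] <- annotations[[rk]][ann_idx]
  }
  validate_tagc_table(out)
}

#' Subsample a TAGC table
#'
#' Uniform sample without replacement of `min(n, nrow)` rows, keeping
#' the original row order among survivors.  Deterministic for a fixed
#' `(table, n, seed)`; large assemblies are typically thinned to around
#' 20,000 contigs for responsive plotting.
#'
#' @param table a `tagc_table`.
#' @param n number of rows to keep.
#' @param seed integer seed (required: no hidden global randomness).
#' @return The subsampled `tagc_table`.
#' @export
subsample_table <- function(table, n, seed) {
  stopifnot(n >= 0)
  if (n >= nrow(table)) return(table)
  keep <- with_seed(seed, sort(sample.int(nrow(table), n)))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  validate_tagc_table(out)
}

#' Relative molar abundance of genomes in a read mixture
#'
#' For a mixture where component *c* contributes a fraction *f_c* of
#' the reads and has genome size *g_c*, the molarity of *c* is
#' proportional to *f_c / g_c*.  Values are normalized so the reference
#' component equals 1.  Example: a sample of 45% parasite (100 Mb),
#' 45% host (3000 Mb) and 10% bacterial (5 Mb) reads has molar ratios
#' of one parasite to 0.03 host to about 4.4 bacterium — which is why
#' read coverage of contigs separates the genomes so cleanly.
#'
#' @param components data frame with columns `label`, `read_fraction`,
#'   `genome_size` (any consistent unit, e.g. Mb).
#' @param reference_label label of the component normalized to 1.
#' @return Named numeric vector of relative molarities.
#' @examples
#' relative_molarity(data.frame(
#'   label = c("parasite", "host", "bacterium"),
#'   read_fraction = c(0.45, 0.45, 0.10),
#'   genome_size = c(100, 3000, 5)), "parasite")
#' @export
relative_molarity <- function(components, reference_label) {
  stopifnot(all(c("label", "read_fraction", "genome_size") %in%
                  names(components)))
  if (any(components$genome_size <= 0)) {
    format_error("genome sizes must be positive")
  }
  if (sum(components$read_fraction) > 1 + 1e-9) {
    format_error("read fractions sum to more than 1")
  }
  if (!reference_label %in% components$label) {
    format_error("reference component '%s' not in mixture", reference_label)
  }
  mol <- components$read_fraction / components$genome_size
  names(mol) <- components$label
  mol / mol[[reference_label]]
}

#' Taxa shown in the plot legend
#'
#' A taxon is shown only if it annotates at least `threshold` (default
#' 1%) of the annotated contigs; rarer taxa are hidden (their contigs
#' plot gray).  Sentinel labels ([TAXON_NOT_ANNOTATED],
#' [TAXON_UNRESOLVED]) are excluded from both the counts and the
#' denominator.  Exactly-at-threshold taxa are shown.
#'
#' @param table a `tagc_table`.
#' @param rank rank whose `taxlevel_` column is counted.
#' @param threshold minimum annotated-contig fraction (default 0.01).
#' @return Character vector of taxon names, by descending count then
#'   name; the counts are attached as the `"counts"` attribute.
#' @export
legend_taxa <- function(table, rank, threshold = 0.01) {
  col <- paste0("taxlevel_", rank)
  if (!col %in% names(table)) {
    format_error("rank '%s' not present in table", rank)
  }
  taxa <- table[[col]]
  taxa <- taxa[!taxa %in% c(TAXON_NOT_ANNOTATED, TAXON_UNRESOLVED)]
  if (!length(taxa)) {
    return(structure(character(0), counts = integer(0)))
  }
  counts <- table(taxa)
  shown <- counts[counts >= threshold * length(taxa)]
  ord <- order(-as.integer(shown), names(shown))
  structure(names(shown)[ord], counts = as.integer(shown)[ord])
}
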