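# Best-hit resolution and lineage rollup against a taxonomy tree.

#' Canonical taxonomic ranks, most to least inclusive
#' @export
CANONICAL_RANKS <- c("superkingdom", "phylum", "order", "family",
                     "genus", "species")

#' Sentinel label for contigs with no database hit
#' @export
TAXON_NOT_ANNOTATED <- "not-annotated"

#' Sentinel label for lineages lacking the requested rank
#' @export
TAXON_UNRESOLVED <- "unresolved"

#' Pick the best hit per contig
#'
#' The best hit is the one with lowest e-value; ties are broken by
#' highest bit score, then by input-file order.  When the e-value
#' column is absent (plain two-column `qseqid staxids` input) the first
#' row per contig wins, i.e. file order stands in for rank.  Of a
#' multi-taxid `staxids` field the first taxid is used.
#'
#' @param hits data frame from [read_hits()].
#' @return Named integer vector, contig id to taxid.
#' @export
best_hit_per_contig <- function(hits) {
  if (!nrow(hits)) return(stats::setNames(integer(0), character(0)))
  ev <- hits$evalue
  ev[is.na(ev)] <- Inf
  bs <- hits$bitscore
  bs[is.na(bs)] <- -Inf
  ord <- order(hits$query_id, ev, -bs, hits$file_rank)
  h <- hits[ord, , drop = FALSE]
  first <- !duplicated(h$query_id)
  stats::setNames(h$taxid[first], h$query_id[first])
}

tax_index <- function(tree, taxid) match(taxid, tree$taxid)

#' Name of a taxon's ancestor at a given rank
#'
#' Walks the parent chain from `taxid` to the root and returns the name
#' of the first node (self included) whose rank matches.  Lineages
#' lacking the rank, and taxids absent from the tree, yield the
#' [TAXON_UNRESOLVED] sentinel; unknown taxids additionally raise one
#' summarizing warning, since public databases routinely contain
#' retired ids.
#'
#' @param tree a `taxonomy_tree` from [read_taxdump()].
#' @param taxid integer vector of taxids.
#' @param rank a single rank name (see [CANONICAL_RANKS]).
#' @return Character vector of taxon names / sentinels, one per taxid.
#' @export
rank_of <- function(tree, taxid, rank) {
  stopifnot(length(rank) == 1L)
  n <- length(tree$taxid)
  out <- character(length(taxid))
  n_unknown <- 0L
  for (i in seq_along(taxid)) {
    idx <- tax_index(tree, taxid[i])
    if (is.na(idx)) {
      n_unknown <- n_unknown + 1L
      out[i] <- TAXON_UNRESOLVED
      next
    }
    res <- TAXON_UNRESOLVED
    steps <- 0L
    repeat {
      if (tree$rank[idx] == rank) {
        res <- tree$name[idx]
        break
      }
      parent <- tree$parent[idx]
      if (parent == tree$taxid[idx]) break  # reached root
      idx <- tax_index(tree, parent)
      steps <- steps + 1L
      if (steps > n) {
        format_error("taxonomy tree contains a cycle involving taxid %d",
                     taxid[i])
      }
    }
    out[i] <- res
  }
  if (n_unknown > 0L) {
    warning(sprintf("%d taxid(s) absent from the taxonomy tree; marked %s",
                    n_unknown, TAXON_UNRESOLVED), call. = FALSE)
  }
  out
}

#' Annotate every assembly contig at the requested ranks
#'
#' Contigs without a best hit get the [TAXON_NOT_ANNOTATED] sentinel at
#' every rank; no contig is dropped.
#'
#' @param tree a `taxonomy_tree`.
#' @param best_hits named integer vector from [best_hit_per_contig()].
#' @param all_contigs character vector of every contig id in the
#'   assembly.
#' @param ranks character vector of ranks (default `"order"`).
#' @return Data frame with a `seqid` column and one column per rank, in
#'   `all_contigs` order.
#' @export
annotate_contigs <- function(tree, best_hits, all_contigs, ranks = "order") {
  stopifnot(length(ranks) >= 1L)
  out <- data.frame(seqid = all_contigs, stringsAsFactors = FALSE)
  hit_idx <- match(all_contigs, names(best_hits))
  has_hit <- !is.na(hit_idx)
  for (rk in ranks) {
    col <- rep(TAXON_NOT_ANNOTATED, length(all_contigs))
    if (any(has_hit)) {
      col[has_hit] <- rank_of(tree, unname(best_hits[hit_idx[has_hit]]), rk)
    }
    out[[rk]] <- col
  }
  out
}
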