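# Declarative selection of contig subsets in taxon/GC/coverage space,
# the conservative discard rule for chimeric assemblies, and derivation
# of cleaned (or inverted, symbiont-targeted) read sets with mate
# rescue.

#' Construct an ellipse in GC / log10-coverage space
#'
#' The same geometry a user would draw interactively on a blob plot:
#' a center, two semi-axes (along GC and along log10 coverage) and a
#' counterclockwise rotation.
#'
#' @param gc,log10_cov center coordinates.
#' @param a,b positive semi-axis lengths along GC and log10 coverage.
#' @param rotation rotation in radians, counterclockwise.
#' @return A `tagc_ellipse`.
#' @export
tagc_ellipse <- function(gc, log10_cov, a, b, rotation = 0) {
  stopifnot(a > 0, b > 0)
  structure(list(gc = gc, log10_cov = log10_cov, a = a, b = b,
                 rotation = rotation),
            class = "tagc_ellipse")
}

#' Test points against an ellipse
#'
#' Translates by minus the center, rotates by minus the rotation, and
#' applies the axis-aligned test `(x/a)^2 + (y/b)^2 <= 1`
#' (boundary-inclusive).
#'
#' @param e a `tagc_ellipse`.
#' @param gc,log10_cov numeric vectors of point coordinates.
#' @return Logical vector.
#' @export
point_in_ellipse <- function(e, gc, log10_cov) {
  dx <- gc - e$gc
  dy <- log10_cov - e$log10_cov
  ct <- cos(e$rotation)
  st <- sin(e$rotation)
  x <- ct * dx + st * dy
  y <- -st * dx + ct * dy
  (x / e$a)^2 + (y / e$b)^2 <= 1
}

#' Construct a contig selection rule
#'
#' Criteria present in one rule combine by AND; a list of ellipses
#' matches the union of their interiors.  Rules are applied in order by
#' [select_contigs()]: `keep` rules intersect the running set with
#' their matches, `exclude` rules subtract theirs — mirroring a mix of
#' positive and negative filters.
#'
#' @param mode `"keep"` or `"exclude"`.
#' @param taxa optional character vector of taxon names.
#' @param rank rank at which `taxa` are interpreted (default "order").
#' @param gc_range optional closed interval `c(min, max)` on GC.
#' @param cov_range optional closed interval on coverage.
#' @param cov_lib library label whose coverage `cov_range` (and
#'   ellipses) use; default `"total"`.
#' @param ellipses optional list of [tagc_ellipse()] objects (a single
#'   ellipse is accepted).
#' @return A `selection_rule`.
#' @export
selection_rule <- function(mode = c("keep", "exclude"), taxa = NULL,
                           rank = "order", gc_range = NULL,
                           cov_range = NULL, cov_lib = "total",
                           ellipses = NULL) {
  mode <- match.arg(mode)
  if (inherits(ellipses, "tagc_ellipse")) ellipses <- list(ellipses)
  if (is.null(taxa) && is.null(gc_range) && is.null(cov_range) &&
      is.null(ellipses)) {
    format_error("selection rule must carry at least one criterion")
  }
  structure(list(mode = mode, taxa = taxa, rank = rank,
                 gc_range = gc_range, cov_range = cov_range,
                 cov_lib = cov_lib, ellipses = ellipses),
            class = "selection_rule")
}

rule_matches <- function(table, rule, y_floor) {
  ok <- rep(TRUE, nrow(table))
  if (!is.null(rule$taxa)) {
    col <- paste0("taxlevel_", rule$rank)
    if (!col %in% names(table)) {
      format_error("rule refers to rank '%s' absent from table", rule$rank)
    }
    unknown <- setdiff(rule$taxa, unique(table[[col]]))
    if (length(unknown)) {
      warning(sprintf("taxon name(s) not present at rank '%s': %s",
                      rule$rank, paste(unknown, collapse = ", ")),
              call. = FALSE)
    }
    ok <- ok & table[[col]] %in% rule$taxa
  }
  if (!is.null(rule$gc_range)) {
    ok <- ok & in_range(table$gc, rule$gc_range)
  }
  if (!is.null(rule$cov_range) || !is.null(rule$ellipses)) {
    col <- paste0("cov_", rule$cov_lib)
    if (!col %in% names(table)) {
      format_error("rule refers to library '%s' absent from table",
                   rule$cov_lib)
    }
    if (!is.null(rule$cov_range)) {
      ok <- ok & in_range(table[[col]], rule$cov_range)
    }
    if (!is.null(rule$ellipses)) {
      # zero-coverage contigs sit at the plotting floor on the log axis
      y <- log10(pmax(table[[col]], y_floor))
      inside <- rep(FALSE, nrow(table))
      for (e in rule$ellipses) {
        inside <- inside | point_in_ellipse(e, table$gc, y)
      }
      ok <- ok & inside
    }
  }
  ok
}

#' Select contigs by a sequence of rules
#'
#' Starts from all contigs; each rule then either intersects (`keep`)
#' or subtracts (`exclude`) its matching rows.  An empty rule list
#' selects everything.
#'
#' @param table a `tagc_table`.
#' @param rules list of [selection_rule()] objects (a single rule is
#'   accepted).
#' @param y_floor pseudo-coverage for zero-depth contigs in ellipse
#'   tests, matching the plotting floor (default 0.01).
#' @return Character vector of selected contig ids, in table order.
#' @export
select_contigs <- function(table, rules = list(), y_floor = 0.01) {
  if (inherits(rules, "selection_rule")) rules <- list(rules)
  current <- rep(TRUE, nrow(table))
  for (rule in rules) {
    m <- rule_matches(table, rule, y_floor)
    current <- if (rule$mode == "keep") current & m else current & !m
  }
  table$seqid[current]
}

#' Conservative discard policy
#'
#' Co-assembled contigs can be chimeric, so discarding every contig
#' whose best hit is a contaminant risks losing target data.  Under
#' this policy a contig is discarded only if its best hit is to a
#' contaminant taxon AND it has no hit to the target taxon better than
#' a relatively permissive e-value cutoff.
#'
#' @param contaminant_taxa character vector of contaminant taxon names
#'   at `rank`.
#' @param target_taxon the target organism's taxon name at `rank`.
#' @param rank rank at which taxa are compared (default "order").
#' @param permissive_evalue cutoff for rescuing target matches;
#'   default `1e-2`, three orders of magnitude looser than a typical
#'   `1e-5` search cutoff.
#' @return A `discard_policy`.
#' @export
discard_policy <- function(contaminant_taxa, target_taxon, rank = "order",
                           permissive_evalue = 1e-2) {
  stopifnot(permissive_evalue > 0)
  structure(list(contaminant_taxa = contaminant_taxa,
                 target_taxon = target_taxon, rank = rank,
                 permissive_evalue = permissive_evalue),
            class = "discard_policy")
}

#' Apply the conservative discard rule
#'
#' @param hits data frame from [read_hits()]; the e-value column must
#'   be populated (multi-hit input, not the two-column best-hit table).
#' @param tree a `taxonomy_tree` used to roll each hit's taxid up to
#'   the policy's rank.
#' @param policy a [discard_policy()].
#' @return Character vector of contig ids to discard.
#' @export
conservative_discard <- function(hits, tree, policy) {
  if (!nrow(hits)) return(character(0))
  if (all(is.na(hits$evalue))) {
    format_error("conservative_discard requires an e-value column in the hits")
  }
  taxon <- rank_of(tree, hits$taxid, policy$rank)
  ev <- hits$evalue
  ev[is.na(ev)] <- Inf
  bs <- hits$bitscore
  bs[is.na(bs)] <- -Inf
  ord <- order(hits$query_id, ev, -bs, hits$file_rank)
  best_taxon <- taxon[ord][!duplicated(hits$query_id[ord])]
  best_contig <- hits$query_id[ord][!duplicated(hits$query_id[ord])]
  rescued <- unique(hits$query_id[taxon == policy$target_taxon &
                                    ev <= policy$permissive_evalue])
  discard <- best_contig[best_taxon %in% policy$contaminant_taxa &
                           !(best_contig %in% rescued)]
  discard
}

#' Reads attached to a contig set, closed over mate pairs
#'
#' Returns every read with a primary alignment to a contig in the set,
#' plus the mates of those reads (mapped elsewhere or unmapped).  Ids
#' are canonical ([normalize_read_id()]), under which both mates share
#' one id, so the returned set is pair-closed by construction.
#'
#' @param alignments a `tagc_alignments` data frame.
#' @param contig_set character vector of contig ids.
#' @return Character vector of canonical read ids.
#' @export
reads_for_contigs <- function(alignments, contig_set) {
  hit <- alignments$is_primary & alignments$is_mapped &
    alignments$contig_id %in% contig_set
  unique(normalize_read_id(alignments$read_id[hit]))
}

#' Filter paired FASTQ files against a read-id set
#'
#' Exclusion is pair-level: a pair is excluded when its canonical id is
#' in `exclusion` (assemblers consume pairs, and mates of removed reads
#' are removed with them).  With `invert = TRUE` only the excluded
#' pairs are written — the route to a contaminant- or
#' symbiont-targeted read set.  Output files stay synchronized.
#'
#' @param in1,in2 input R1/R2 FASTQ paths.
#' @param exclusion character vector of canonical read ids.
#' @param out1,out2 output R1/R2 FASTQ paths.
#' @param invert write excluded pairs instead of kept ones.
#' @return invisibly, a list with `n_in`, `n_out`.
#' @export
filter_fastq <- function(in1, in2, exclusion, out1, out2, invert = FALSE) {
  pairs <- read_fastq_pairs(in1, in2)
  excluded <- pairs$id %in% exclusion
  keep <- if (invert) excluded else !excluded
  write_fastq(pairs$r1[keep, , drop = FALSE], out1)
  write_fastq(pairs$r2[keep, , drop = FALSE], out2)
  invisible(list(n_in = length(pairs$id), n_out = sum(keep)))
}
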