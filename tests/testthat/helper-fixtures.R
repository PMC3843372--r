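# Shared fixtures, built once per test session.

# Full-scale standard fixture plus everything derived from it through
# the public pipeline.  Building it (and parsing 300k alignment
# records) takes ~1 minute, so it is cached and reused by all files.
std_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    bundle <- make_standard_fixture(seed = 20130101)
    contigs <- read_fasta(bundle$paths$assembly)
    aln <- read_alignments(bundle$paths$sam)
    lens <- stats::setNames(Biostrings::width(contigs), names(contigs))
    cov <- compute_coverage(aln, lens, "lib1")
    tree <- read_taxdump(bundle$paths$nodes, bundle$paths$names)
    hits <- read_hits(bundle$paths$hits)
    best <- best_hit_per_contig(hits)
    ann <- annotate_contigs(tree, best, names(contigs),
                            c("superkingdom", "order"))
    table <- build_table(contigs, list(cov), ann)
    cache <<- list(bundle = bundle, contigs = contigs, aln = aln,
                   lens = lens, cov = cov, tree = tree, hits = hits,
                   best = best, ann = ann, table = table)
    cache
  }
})

# A hand-sized taxonomy mirroring real lineages: nematodes under order
# Rhabditida, a Wolbachia-like leaf under order Rickettsiales.
mini_real_tree <- function() {
  rows <- list(
    #     taxid parent rank             name
    list(1L, 1L, "no rank",      "root"),
    list(2L, 1L, "superkingdom", "Bacteria"),
    list(3L, 1L, "superkingdom", "Eukaryota"),
    list(4L, 3L, "phylum",       "Nematoda"),
    list(5L, 4L, "order",        "Rhabditida"),
    list(6L, 5L, "genus",        "Caenorhabditis"),
    list(7L, 6L, "species",      "Caenorhabditis briggsae"),
    list(8L, 2L, "phylum",       "Proteobacteria"),
    list(9L, 8L, "order",        "Rickettsiales"),
    list(10L, 9L, "species",     "Wolbachia pipientis"))
  structure(list(taxid = vapply(rows, `[[`, integer(1), 1),
                 parent = vapply(rows, `[[`, integer(1), 2),
                 rank = vapply(rows, `[[`, character(1), 3),
                 name = vapply(rows, `[[`, character(1), 4),
                 root_taxid = 1L),
            class = "taxonomy_tree")
}

# small TAGC table built by hand for selection/plotting tests
toy_tagc_table <- function() {
  df <- data.frame(
    seqid = sprintf("t%02d", 1:8),
    length = rep(1000L, 8),
    gc = c(0.40, 0.45, 0.50, 0.62, 0.64, 0.66, 0.38, 0.55),
    cov_lib1 = c(100, 90, 110, 10, 12, 200, 0, 95),
    cov_lib2 = c(50, 45, 55, 5, 6, 100, 0, 50),
    cov_total = c(150, 135, 165, 15, 18, 300, 0, 145),
    taxlevel_order = c("Rhabditida", "Rhabditida", "Rhabditida",
                       "Pseudomonadales", "Pseudomonadales",
                       "Actinomycetales", TAXON_NOT_ANNOTATED,
                       TAXON_UNRESOLVED),
    stringsAsFactors = FALSE)
  tagctools:::validate_tagc_table(df)
}

write_tmp_sam <- function(lines) {
  path <- tempfile("aln", fileext = ".sam")
  writeLines(lines, path)
  path
}
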