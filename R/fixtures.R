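# Seeded synthetic-data generator.  Produces every input the pipeline
# consumes -- assembly FASTA, per-library SAM, best-hit table, miniature
# taxonomy dump, paired FASTQ -- with full ground truth, emulating a
# nematode assembly contaminated by bacteria at distinct GC and
# molarity.  Alignments are emitted from the known simulation
# coordinates rather than by running a mapper, so tests are hermetic;
# substitute a real mapper's BAM at any point if you want one.

#' Specification of one simulated genome
#'
#' @param label short genome label, used as a contig-id prefix.
#' @param planted_order taxon name planted at rank "order".
#' @param planted_taxid species-level taxid assigned to this genome's
#'   contigs in the hits table.
#' @param size genome size in bases.
#' @param gc target GC fraction, strictly inside (0, 1).
#' @param target_depth requested mean read depth.
#' @param n_contigs number of near-equal contigs the genome is split
#'   into; `size` must be at least `500 * n_contigs`.
#' @return A `genome_spec`.
#' @export
genome_spec <- function(label, planted_order, planted_taxid, size, gc,
                        target_depth, n_contigs) {
  if (size < n_contigs * 500) {
    format_error("genome '%s': size %d too small for %d contigs (min 500 bp each)",
                 label, size, n_contigs)
  }
  if (gc <= 0 || gc >= 1) format_error("genome '%s': gc must be in (0,1)", label)
  stopifnot(target_depth > 0)
  structure(list(label = label, planted_order = planted_order,
                 planted_taxid = as.integer(planted_taxid),
                 size = as.integer(size), gc = gc,
                 target_depth = target_depth,
                 n_contigs = as.integer(n_contigs)),
            class = "genome_spec")
}

#' Simulate a genome as i.i.d. bases at a target GC
#'
#' Bases are drawn independently with P(G) = P(C) = gc/2 and
#' P(A) = P(T) = (1-gc)/2, then partitioned into `n_contigs` contigs of
#' near-equal length named `<label>_c<i>`.  Deterministic for a fixed
#' seed.
#'
#' @param spec a [genome_spec()].
#' @param seed integer seed.
#' @return A named [Biostrings::DNAStringSet].
#' @export
simulate_genome <- function(spec, seed) {
  bases <- with_seed(seed, sample(c("A", "C", "G", "T"), spec$size,
                                  replace = TRUE,
                                  prob = c((1 - spec$gc) / 2, spec$gc / 2,
                                           spec$gc / 2, (1 - spec$gc) / 2)))
  genome <- paste(bases, collapse = "")
  bounds <- round(seq(0, spec$size, length.out = spec$n_contigs + 1))
  seqs <- substring(genome, bounds[-length(bounds)] + 1, bounds[-1])
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("%s_c%02d", spec$label, seq_len(spec$n_contigs))
  x
}

random_seq <- function(n, len) {
  if (n == 0L) return(character(0))
  pool <- paste(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
                collapse = "")
  substring(pool, (seq_len(n) - 1L) * len + 1L, seq_len(n) * len)
}

#' Simulate error-free paired reads and their alignments
#'
#' Fragments of length `insert` are sampled uniformly along each
#' contig; both mates are error-free copies (the second mate
#' reverse-complemented in FASTQ, forward-oriented with the reverse
#' flag in SAM, per the SAM convention).  The number of fragments per
#' contig is `round(depth * length / (2 * read_len))`, so realized mean
#' depth matches the request up to rounding and contig-end effects.  An
#' optional unmapped spike-in adds read pairs (random sequence, both
#' mates unmapped) so that they make up a fraction `p_unmapped` of all
#' reads.
#'
#' @param contigs named [Biostrings::DNAStringSet] to sequence from;
#'   contigs shorter than `insert` are skipped with a warning.
#' @param depth requested mean read depth.
#' @param read_len read length in bases (default 100).
#' @param insert fragment length, at least `2 * read_len`
#'   (default 300).
#' @param seed integer seed.
#' @param label library/read-id prefix.
#' @param p_unmapped fraction of all reads that are unmapped spike-ins
#'   (default 0).
#' @return list with `r1`, `r2` (FASTQ data frames, ids suffixed
#'   `/1`, `/2`), `sam` (record data frame for [write_sam()]) and
#'   `truth` (data frame `read_id`, `contig_id`; `NA` contig for
#'   spike-ins).
#' @export
simulate_reads_and_alignments <- function(contigs, depth, read_len = 100L,
                                          insert = 300L, seed,
                                          label = "lib1", p_unmapped = 0) {
  if (insert < 2L * read_len) {
    format_error("insert (%d) must be at least twice the read length (%d)",
                 insert, read_len)
  }
  stopifnot(p_unmapped >= 0, p_unmapped < 1)
  lens <- Biostrings::width(contigs)
  short <- lens < insert
  if (any(short)) {
    warning(sprintf("skipping %d contig(s) shorter than the insert size",
                    sum(short)), call. = FALSE)
    contigs <- contigs[!short]
    lens <- lens[!short]
  }
  qual <- strrep("I", read_len)
  with_seed(seed, {
    parts <- lapply(seq_along(contigs), function(i) {
      L <- lens[i]
      n_frag <- round(depth * L / (2 * read_len))
      if (n_frag < 1L) return(NULL)
      starts <- sample.int(L - insert + 1L, n_frag, replace = TRUE) - 1L
      cs <- as.character(contigs[[i]])
      fwd <- substring(cs, starts + 1L, starts + read_len)
      rev_ref <- substring(cs, starts + insert - read_len + 1L,
                           starts + insert)
      ids <- sprintf("%s_%s_%05d", label, names(contigs)[i], seq_len(n_frag))
      list(contig = names(contigs)[i], ids = ids, starts = starts,
           fwd = fwd, rev_ref = rev_ref)
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    n_pairs <- sum(vapply(parts, function(p) length(p$ids), integer(1)))
    n_un <- if (p_unmapped > 0) {
      round(p_unmapped / (1 - p_unmapped) * n_pairs)
    } else 0L

    ids <- unlist(lapply(parts, `[[`, "ids"))
    contig <- rep(vapply(parts, `[[`, character(1), "contig"),
                  vapply(parts, function(p) length(p$ids), integer(1)))
    starts <- unlist(lapply(parts, `[[`, "starts"))
    fwd <- unlist(lapply(parts, `[[`, "fwd"))
    rev_ref <- unlist(lapply(parts, `[[`, "rev_ref"))
    rev_read <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(rev_ref)))

    un_ids <- if (n_un > 0) sprintf("%s_unmapped_%05d", label, seq_len(n_un))
              else character(0)
    un_seq1 <- random_seq(n_un, read_len)
    un_seq2 <- random_seq(n_un, read_len)

    all_ids <- c(ids, un_ids)   # c() before paste0: paste0 pads empties
    if (!length(all_ids)) {
      format_error("no fragments to simulate (depth or contigs too small)")
    }
    r1 <- data.frame(id = paste0(all_ids, "/1"),
                     seq = c(fwd, un_seq1),
                     qual = qual, stringsAsFactors = FALSE)
    r2 <- data.frame(id = paste0(all_ids, "/2"),
                     seq = c(rev_read, un_seq2),
                     qual = qual, stringsAsFactors = FALSE)

    pos1 <- starts + 1L
    pos2 <- starts + insert - read_len + 1L
    cig <- sprintf("%dM", read_len)
    sam <- data.frame(
      qname = c(ids, ids, un_ids, un_ids),
      flag = c(rep(99L, n_pairs), rep(147L, n_pairs),
               rep(77L, n_un), rep(141L, n_un)),
      rname = c(contig, contig, rep("*", 2L * n_un)),
      pos = c(pos1, pos2, rep(0L, 2L * n_un)),
      mapq = c(rep(60L, 2L * n_pairs), rep(0L, 2L * n_un)),
      cigar = c(rep(cig, 2L * n_pairs), rep("*", 2L * n_un)),
      rnext = c(rep("=", 2L * n_pairs), rep("*", 2L * n_un)),
      pnext = c(pos2, pos1, rep(0L, 2L * n_un)),
      tlen = c(rep(insert, n_pairs), rep(-insert, n_pairs),
               rep(0L, 2L * n_un)),
      seq = c(fwd, rev_ref, un_seq1, un_seq2),
      qual = qual,
      stringsAsFactors = FALSE)

    truth <- data.frame(read_id = c(ids, un_ids),
                        contig_id = c(contig, rep(NA_character_, n_un)),
                        stringsAsFactors = FALSE)
    list(r1 = r1, r2 = r2, sam = sam, truth = truth)
  })
}

# Miniature taxonomy: root -> two superkingdoms -> three orders ->
# three species, with small fixed taxids so fixtures are
# self-describing.
standard_taxonomy <- function() {
  structure(list(
    taxid  = c(1L, 2L, 3L, 10L, 11L, 12L, 20L, 21L, 22L),
    parent = c(1L, 1L, 1L, 3L, 2L, 2L, 10L, 11L, 12L),
    rank   = c("no rank", "superkingdom", "superkingdom", "order", "order",
               "order", "species", "species", "species"),
    name   = c("root", "Bacteria", "Eukaryota", "Rhabditida",
               "Pseudomonadales", "Actinomycetales",
               "Rhabditida sp. SIM", "Pseudomonadales sp. SIM",
               "Actinomycetales sp. SIM"),
    root_taxid = 1L), class = "taxonomy_tree")
}

#' Genome specifications of the standard fixture
#'
#' A nematode-like target (order Rhabditida, GC 0.40, 100-fold depth)
#' plus two bacterial contaminants at distinct GC and molarity:
#' Pseudomonadales at ~10-fold and Actinomycetales at ~200-fold --
#' the canonical "one major blob flanked by high-GC bacterial blobs"
#' situation.
#'
#' @return list of three [genome_spec()] objects.
#' @export
standard_genome_specs <- function() {
  list(
    target = genome_spec("target", "Rhabditida", 20L,
                         size = 200000L, gc = 0.40, target_depth = 100,
                         n_contigs = 20L),
    contamA = genome_spec("contamA", "Pseudomonadales", 21L,
                          size = 100000L, gc = 0.62, target_depth = 10,
                          n_contigs = 10L),
    contamB = genome_spec("contamB", "Actinomycetales", 22L,
                          size = 50000L, gc = 0.66, target_depth = 200,
                          n_contigs = 5L))
}

#' Generate the standard synthetic fixture bundle
#'
#' Writes a complete, ground-truthed input set to `dir`: the
#' three-genome assembly (`assembly.fasta`), one library of simulated
#' alignments (`lib1.sam`) and paired reads (`reads_1.fastq`,
#' `reads_2.fastq`, with an unmapped spike-in of 1.31% so the mapped
#' fraction is 98.69%), a two-column best-hit table (`hits.tsv`, with
#' every 10th target contig left without a hit, i.e. 10% unannotated),
#' a miniature taxonomy dump (`taxdump/nodes.dmp`, `names.dmp`) and
#' truth tables (`truth_contigs.tsv`, `truth_reads.tsv`).
#'
#' @param dir output directory (created if needed).
#' @param seed integer master seed; per-genome seeds are derived from
#'   it.
#' @param scale genome-size multiplier in (0, 1]; depths, GC values and
#'   contig counts are untouched, only contig lengths shrink.  The
#'   default 1 is the stated world every recovery guarantee refers to;
#'   smaller values exist for fast smoke tests only.
#' @return invisibly, a list with the genome `specs`, the in-memory
#'   `contigs`, `tree`, `truth_contigs`, `truth_reads`, and a `paths`
#'   list of every file written.
#' @export
make_standard_fixture <- function(dir = tempfile("tagc_fixture"), seed = 1,
                                  scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "taxdump"), showWarnings = FALSE)
  specs <- standard_genome_specs()
  if (scale < 1) {
    specs <- lapply(specs, function(sp) {
      genome_spec(sp$label, sp$planted_order, sp$planted_taxid,
                  size = max(sp$n_contigs * 500L, round(sp$size * scale)),
                  gc = sp$gc, target_depth = sp$target_depth,
                  n_contigs = sp$n_contigs)
    })
  }

  contigs <- NULL
  sims <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    genome <- simulate_genome(sp, seed = seed * 13L + k)
    contigs <- if (is.null(contigs)) genome else c(contigs, genome)
    sims[[sp$label]] <- simulate_reads_and_alignments(
      genome, depth = sp$target_depth, seed = seed * 17L + k,
      label = "lib1", p_unmapped = 0.0131)
  }

  paths <- list(
    assembly = file.path(dir, "assembly.fasta"),
    sam = file.path(dir, "lib1.sam"),
    hits = file.path(dir, "hits.tsv"),
    nodes = file.path(dir, "taxdump", "nodes.dmp"),
    names = file.path(dir, "taxdump", "names.dmp"),
    fastq1 = file.path(dir, "reads_1.fastq"),
    fastq2 = file.path(dir, "reads_2.fastq"),
    truth_contigs = file.path(dir, "truth_contigs.tsv"),
    truth_reads = file.path(dir, "truth_reads.tsv"))

  write_fasta(contigs, paths$assembly)

  sam <- do.call(rbind, lapply(sims, `[[`, "sam"))
  lens <- stats::setNames(Biostrings::width(contigs), names(contigs))
  write_sam(sam, lens, paths$sam)

  r1 <- do.call(rbind, lapply(sims, `[[`, "r1"))
  r2 <- do.call(rbind, lapply(sims, `[[`, "r2"))
  write_fastq(r1, paths$fastq1)
  write_fastq(r2, paths$fastq2)

  # hits: each contig gets its genome's species taxid; every 10th
  # target contig is left unannotated
  hit_rows <- character(0)
  truth_contigs <- NULL
  for (sp in specs) {
    ids <- sprintf("%s_c%02d", sp$label, seq_len(sp$n_contigs))
    annotated <- if (sp$label == "target") {
      seq_along(ids) %% 10L != 0L
    } else {
      rep(TRUE, length(ids))
    }
    hit_rows <- c(hit_rows,
                  sprintf("%s\t%d", ids[annotated], sp$planted_taxid))
    truth_contigs <- rbind(truth_contigs, data.frame(
      contig_id = ids, genome = sp$label, planted_order = sp$planted_order,
      planted_gc = sp$gc, planted_depth = sp$target_depth,
      has_hit = annotated, stringsAsFactors = FALSE))
  }
  writeLines(hit_rows, paths$hits)

  tree <- standard_taxonomy()
  write_taxdump(tree, paths$nodes, paths$names)

  truth_reads <- do.call(rbind, lapply(names(sims), function(lab) {
    tr <- sims[[lab]]$truth
    tr$genome <- ifelse(is.na(tr$contig_id), "unmapped-spike", lab)
    tr
  }))
  utils::write.table(truth_contigs, paths$truth_contigs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth_reads, paths$truth_reads, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(list(dir = dir, specs = specs, contigs = contigs, tree = tree,
                 truth_contigs = truth_contigs, truth_reads = truth_reads,
                 paths = paths))
}
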