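# IO layer: FASTA, SAM/BAM, hits, taxdump, TAGC TSV, FASTQ.

test_that("read_fasta parses headers, order and case per contract", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">c1 description text", "acgt", ">c2", "NNAA", "CCGG"), f)
  x <- read_fasta(f)
  expect_equal(names(x), c("c1", "c2"))
  expect_equal(as.character(x), c(c1 = "ACGT", c2 = "NNAACCGG"))

  bad <- tempfile(fileext = ".fasta")
  writeLines(c("ACGT", ">c1", "AAAA"), bad)
  expect_error(read_fasta(bad), "line 1")

  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">c1", "AA", ">c1 again", "CC"), dup)
  expect_error(read_fasta(dup), "duplicate")
})

test_that("FASTA round-trip reproduces ids and residues exactly", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(1:10, 1)
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T", "N"), sample(10:200, 1),
                   replace = TRUE), collapse = "")
    }, character(1))
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- paste0("contig", seq_len(n))
    f <- tempfile(fileext = ".fa")
    write_fasta(x, f)
    y <- read_fasta(f)
    expect_identical(names(y), names(x))
    expect_identical(as.character(y), as.character(x))
  }
})

test_that("SAM records decompose into reference intervals correctly", {
  expect_equal(unname(ref_intervals(0L, "10M")),
               unname(cbind(0L, 10L)))
  # deletion consumes reference but contributes no read support
  expect_equal(unname(ref_intervals(2L, "3M2D4M")),
               unname(cbind(c(2L, 7L), c(5L, 11L))))
  # insertions and clips consume no reference
  expect_equal(unname(ref_intervals(5L, "2S3M1I3M")),
               unname(cbind(c(5L, 8L), c(8L, 11L))))
  expect_error(ref_intervals(0L, "10Q"), "malformed CIGAR")
})

test_that("read_alignments parses SAM flags, positions and roles", {
  sam <- c("@HD\tVN:1.6",
           "@SQ\tSN:c1\tLN:100",
           "r1/1\t99\tc1\t1\t60\t10M\t=\t21\t30\tAAAAAAAAAA\tIIIIIIIIII",
           "r1/2\t147\tc1\t21\t60\t10M\t=\t1\t-30\tAAAAAAAAAA\tIIIIIIIIII",
           "r2\t0\tc1\t3\t60\t3M2D4M\t*\t0\t0\tAAAAAAA\tIIIIIII",
           "r3\t4\t*\t0\t0\t*\t*\t0\t0\tAAAA\tIIII",
           "r4\t256\tc1\t11\t0\t5M\t*\t0\t0\tAAAAA\tIIIII")
  aln <- read_alignments(write_tmp_sam(sam))
  expect_equal(nrow(aln), 5L)
  expect_equal(aln$pos0, c(0L, 20L, 2L, NA, 10L))
  expect_equal(aln$is_mapped, c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(aln$is_primary, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(aln$mate_role, c("first", "second", "unpaired",
                                "unpaired", "unpaired"))
  expect_true(is.na(aln$contig_id[4]))

  # mapped record missing a CIGAR is skipped with a warning
  sam2 <- c("@SQ\tSN:c1\tLN:100",
            "r1\t0\tc1\t1\t60\t*\t*\t0\t0\tAAAA\tIIII",
            "r2\t0\tc1\t1\t60\t4M\t*\t0\t0\tAAAA\tIIII")
  expect_warning(aln2 <- read_alignments(write_tmp_sam(sam2)),
                 "without a CIGAR")
  expect_equal(nrow(aln2), 1L)
  expect_equal(attr(aln2, "n_skipped_no_cigar"), 1L)

  # reference absent from the header is a format error
  sam3 <- c("@SQ\tSN:c1\tLN:100",
            "r1\t0\tc9\t1\t60\t4M\t*\t0\t0\tAAAA\tIIII")
  expect_error(read_alignments(write_tmp_sam(sam3)), "absent from header")
})

test_that("BAM route agrees with SAM route", {
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           "@SQ\tSN:c1\tLN:50",
           "r1\t0\tc1\t1\t60\t10M\t*\t0\t0\tAAAAAAAAAA\tIIIIIIIIII",
           "r2\t16\tc1\t5\t60\t5M2D5M\t*\t0\t0\tAAAAAAAAAA\tIIIIIIIIII")
  sam_path <- write_tmp_sam(sam)
  bam_path <- suppressMessages(
    Rsamtools::asBam(sam_path, tempfile(), indexDestination = FALSE))
  a <- read_alignments(sam_path)
  b <- read_alignments(bam_path)
  key <- function(df) df[order(df$read_id),
                         c("read_id", "flag", "contig_id", "pos0", "cigar")]
  expect_equal(key(as.data.frame(a)), key(as.data.frame(b)),
               ignore_attr = TRUE)
})

test_that("read_hits handles the two-column dialect and extensions", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("contig1\t6239",
               "contig1\t6239;6279",
               "contig2\t100\t1e-30\t250.1"), f)
  h <- read_hits(f)
  expect_equal(h$query_id, c("contig1", "contig1", "contig2"))
  expect_equal(h$taxids[[2]], c(6239L, 6279L))
  expect_equal(h$taxid, c(6239L, 6239L, 100L))
  expect_equal(h$file_rank, 0:2)
  expect_equal(h$evalue, c(NA, NA, 1e-30))
  expect_equal(h$bitscore, c(NA, NA, 250.1))

  bad <- tempfile()
  writeLines(c("c1\t6239", "c2\tnot_a_taxid"), bad)
  expect_error(read_hits(bad), "line 2")
})

test_that("read_taxdump parses the dump dialect and prefers scientific names", {
  nodes <- tempfile()
  names_f <- tempfile()
  writeLines(c("1\t|\t1\t|\tno rank\t|",
               "2\t|\t1\t|\torder\t|",
               "3\t|\t2\t|\tspecies\t|"), nodes)
  writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|",
               "2\t|\tBadName\t|\t\t|\tsynonym\t|",
               "2\t|\tGoodOrder\t|\t\t|\tscientific name\t|",
               "3\t|\tOnlySynonym\t|\t\t|\tsynonym\t|"), names_f)
  tree <- read_taxdump(nodes, names_f)
  expect_equal(length(tree$taxid), 3L)
  expect_equal(tree$root_taxid, 1L)
  expect_equal(tree$name[tree$taxid == 2], "GoodOrder")
  # no scientific name: first listed name wins
  expect_equal(tree$name[tree$taxid == 3], "OnlySynonym")

  # orphan parent reference is a structural error
  writeLines(c("1\t|\t1\t|\tno rank\t|",
               "2\t|\t99\t|\torder\t|"), nodes)
  expect_error(read_taxdump(nodes, names_f), "absent from nodes")
})

test_that("TAGC TSV header grammar, precision and round-trip", {
  tab <- toy_tagc_table()
  f <- tempfile(fileext = ".tsv")
  write_tagc_tsv(tab, f)
  header <- readLines(f, n = 1)
  expect_identical(header,
                   "seqid\tlength\tgc\tcov_lib1\tcov_lib2\tcov_total\ttaxlevel_order")
  back <- read_tagc_tsv(f)
  expect_equal(back$seqid, tab$seqid)
  expect_equal(back$gc, round(tab$gc, 4))
  expect_equal(back$cov_lib1, round(tab$cov_lib1, 3))
  expect_equal(back$taxlevel_order, tab$taxlevel_order)

  # two successive write/read cycles are idempotent
  f2 <- tempfile(fileext = ".tsv")
  write_tagc_tsv(back, f2)
  expect_identical(readLines(f), readLines(f2))

  # unknown column on read is a format error naming the column
  lines <- readLines(f)
  lines[1] <- sub("taxlevel_order", "bogus_column", lines[1])
  writeLines(lines, f2)
  expect_error(read_tagc_tsv(f2), "bogus_column")
})

test_that("FASTQ pairing, normalization and error handling", {
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(c("@r1/1", "ACGT", "+", "IIII", "@r2 comment", "GGGG", "+", "IIII"), f1)
  writeLines(c("@r1/2", "TTTT", "+", "IIII", "@r2", "CCCC", "+", "IIII"), f2)
  p <- read_fastq_pairs(f1, f2)
  expect_equal(p$id, c("r1", "r2"))

  # desynchronized ids fail at the first offending record
  writeLines(c("@rX/2", "TTTT", "+", "IIII", "@r2", "CCCC", "+", "IIII"), f2)
  expect_error(read_fastq_pairs(f1, f2), "record 1")

  # truncated file
  writeLines(c("@r1", "ACGT", "+"), f1)
  expect_error(read_fastq(f1), "truncated")

  # write/read round trip
  reads <- data.frame(id = c("a/1", "b/1"), seq = c("AC", "GT"),
                      qual = c("II", "II"), stringsAsFactors = FALSE)
  f3 <- tempfile()
  write_fastq(reads, f3)
  expect_equal(read_fastq(f3), reads)
})

test_that("interval decomposition agrees with the per-base pileup oracle", {
  set.seed(7)
  for (rep in 1:40) {
    rc <- random_cigar()
    pos0 <- sample(0:10, 1)
    iv <- ref_intervals(pos0, rc$cigar)
    from_iv <- if (nrow(iv)) {
      sort(unlist(Map(function(s, e) seq.int(s, e - 1L),
                      iv[, "start"], iv[, "end"])))
    } else integer(0)
    expect_identical(from_iv, sort(oracle_cigar_positions(pos0, rc$cigar)),
                     info = rc$cigar)
  }
})
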