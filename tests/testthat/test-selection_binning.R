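# Ellipse geometry, rule-based selection, conservative discard, read
# binning with mate rescue, FASTQ filtering.

test_that("point_in_ellipse basics", {
  e <- tagc_ellipse(0.5, 1.0, a = 0.1, b = 0.5, rotation = 0.3)
  expect_true(point_in_ellipse(e, 0.5, 1.0))  # center is inside
  # rotation 0, a = b = r reduces to the circle test
  ec <- tagc_ellipse(0.4, 2.0, a = 0.25, b = 0.25)
  set.seed(5)
  gc <- runif(200); y <- runif(200, 1, 3)
  expect_identical(point_in_ellipse(ec, gc, y),
                   sqrt((gc - 0.4)^2 + (y - 2.0)^2) <= 0.25)
  expect_error(tagc_ellipse(0.5, 1, a = 0, b = 1), "a > 0")
})

test_that("ellipse membership equals the rotation-matrix grid oracle", {
  set.seed(9)
  grid <- expand.grid(gc = seq(0, 1, length.out = 60),
                      y = seq(-2, 4, length.out = 60))
  for (rep in 1:10) {
    e <- tagc_ellipse(runif(1), runif(1, -1, 3), a = runif(1, 0.02, 0.4),
                      b = runif(1, 0.05, 1.5), rotation = runif(1, -pi, pi))
    expect_identical(point_in_ellipse(e, grid$gc, grid$y),
                     oracle_in_ellipse(e, grid$gc, grid$y))
  }
})

test_that("select_contigs applies keep/exclude rules in order", {
  tab <- toy_tagc_table()
  # exclude a contaminant order removes exactly its rows
  sel <- select_contigs(tab, selection_rule("exclude",
                                            taxa = "Pseudomonadales"))
  expect_setequal(sel, tab$seqid[tab$taxlevel_order != "Pseudomonadales"])

  # keep by gc range equals an exhaustive row scan
  sel <- select_contigs(tab, selection_rule("keep", gc_range = c(0.35, 0.55)))
  expect_setequal(sel, tab$seqid[tab$gc >= 0.35 & tab$gc <= 0.55])

  # empty rule list selects everything
  expect_identical(select_contigs(tab), tab$seqid)

  # AND within a rule, set algebra between rules
  rules <- list(
    selection_rule("keep", gc_range = c(0.3, 0.7), cov_range = c(50, 400),
                   cov_lib = "total"),
    selection_rule("exclude", taxa = "Actinomycetales"))
  want <- tab$seqid[tab$gc >= 0.3 & tab$gc <= 0.7 &
                      tab$cov_total >= 50 & tab$cov_total <= 400 &
                      tab$taxlevel_order != "Actinomycetales"]
  expect_setequal(select_contigs(tab, rules), want)

  # unknown taxon warns but matches nothing
  expect_warning(sel <- select_contigs(
    tab, selection_rule("exclude", taxa = "NoSuchOrder")), "not present")
  expect_identical(sel, tab$seqid)

  # ellipse criterion over the log coverage axis; zero-coverage contig
  # sits at the floor
  e <- tagc_ellipse(0.4, log10(0.01), a = 0.1, b = 0.2)
  sel <- select_contigs(tab, selection_rule("keep", ellipses = e))
  expect_identical(sel, "t07")

  expect_error(selection_rule("keep"), "at least one criterion")
})

test_that("conservative_discard rescues contigs with permissive target hits", {
  tree <- std_fixture()$tree
  mk <- function(...) {
    rows <- list(...)
    data.frame(query_id = vapply(rows, `[[`, character(1), 1),
               taxid = vapply(rows, function(r) as.integer(r[[2]]), integer(1)),
               evalue = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1)),
               bitscore = NA_real_,
               file_rank = seq_along(rows) - 1L, stringsAsFactors = FALSE)
  }
  pol <- discard_policy(c("Pseudomonadales", "Actinomycetales"),
                        "Rhabditida", permissive_evalue = 1e-2)
  # best hit contaminant but target hit at 1e-3 <= 1e-2: kept
  h <- mk(list("c1", 21L, 1e-30), list("c1", 20L, 1e-3))
  expect_length(conservative_discard(h, tree, pol), 0)
  # best hit contaminant, no target hit: discarded
  h <- mk(list("c2", 21L, 1e-30))
  expect_identical(conservative_discard(h, tree, pol), "c2")
  # best hit target: never discarded
  h <- mk(list("c3", 20L, 1e-30), list("c3", 21L, 1e-10))
  expect_length(conservative_discard(h, tree, pol), 0)
  # target hit above the permissive cutoff does not rescue
  h <- mk(list("c4", 22L, 1e-30), list("c4", 20L, 1e-1))
  expect_identical(conservative_discard(h, tree, pol), "c4")

  # randomized tables vs exhaustive per-contig evaluation
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    h <- data.frame(query_id = sample(sprintf("c%02d", 1:12), n, TRUE),
                    taxid = sample(c(20L, 21L, 22L), n, TRUE),
                    evalue = 10^-sample(0:40, n, TRUE),
                    bitscore = NA_real_,
                    file_rank = seq_len(n) - 1L, stringsAsFactors = FALSE)
    got <- sort(conservative_discard(h, tree, pol))
    want <- character(0)
    for (cg in unique(h$query_id)) {
      sub <- h[h$query_id == cg, ]
      best <- sub[order(sub$evalue, sub$file_rank), ][1, ]
      best_order <- rank_of(tree, best$taxid, "order")
      target_ok <- any(rank_of(tree, sub$taxid, "order") == "Rhabditida" &
                         sub$evalue <= 1e-2)
      if (best_order %in% pol$contaminant_taxa && !target_ok) {
        want <- c(want, cg)
      }
    }
    expect_setequal(got, want)
  }
})

test_that("reads_for_contigs is pair-closed and matches the two-pass oracle", {
  # r1 maps to contaminant with its mate on the target contig; r2 is an
  # unpaired read on the contaminant; r3 has an unmapped mate
  sam <- c("@SQ\tSN:bad\tLN:100", "@SQ\tSN:good\tLN:100",
           "r1\t99\tbad\t1\t60\t10M\t=\t0\t0\tA\tI",
           "r1\t147\tgood\t1\t60\t10M\t=\t0\t0\tA\tI",
           "r2\t0\tbad\t5\t60\t10M\t*\t0\t0\tA\tI",
           "r3/1\t73\tbad\t9\t60\t10M\t*\t0\t0\tA\tI",
           "r3/2\t133\t*\t0\t0\t*\t*\t0\t0\tA\tI",
           "r4\t0\tgood\t1\t60\t10M\t*\t0\t0\tA\tI")
  aln <- read_alignments(write_tmp_sam(sam))
  got <- reads_for_contigs(aln, "bad")
  expect_setequal(got, c("r1", "r2", "r3"))
  expect_identical(sort(got), oracle_reads_for_contigs(aln, "bad"))

  # randomized fixtures vs the oracle; closure is idempotent
  set.seed(55)
  dir <- tempfile(); dir.create(dir)
  for (rep in 1:10) {
    fx <- random_sam_fixture(dir)
    aln <- read_alignments(fx$path)
    subset <- sample(names(fx$contig_lengths),
                     sample(seq_along(fx$contig_lengths), 1))
    got <- sort(reads_for_contigs(aln, subset))
    expect_identical(got, oracle_reads_for_contigs(aln, subset))
    # mate closure applied to its own output adds nothing
    again <- alignments_subset <- aln[tagctools::normalize_read_id(aln$read_id)
                                      %in% got, , drop = FALSE]
    expect_true(all(sort(unique(normalize_read_id(again$read_id))) %in% got))
  }
})

test_that("filter_fastq partitions pairs exactly and supports inversion", {
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(c("@a/1", "AC", "+", "II", "@b/1", "GG", "+", "II",
               "@c/1", "TT", "+", "II"), f1)
  writeLines(c("@a/2", "AC", "+", "II", "@b/2", "GG", "+", "II",
               "@c/2", "TT", "+", "II"), f2)
  k1 <- tempfile(); k2 <- tempfile(); x1 <- tempfile(); x2 <- tempfile()
  n <- filter_fastq(f1, f2, exclusion = "b", k1, k2)
  expect_equal(n$n_out, 2L)
  filter_fastq(f1, f2, exclusion = "b", x1, x2, invert = TRUE)
  kept <- read_fastq_pairs(k1, k2)
  removed <- read_fastq_pairs(x1, x2)
  expect_identical(kept$id, c("a", "c"))
  expect_identical(removed$id, "b")
  # partition: kept + removed = input, disjoint
  expect_setequal(c(kept$id, removed$id), c("a", "b", "c"))
  expect_length(intersect(kept$id, removed$id), 0)
})
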