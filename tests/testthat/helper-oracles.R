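# Independent brute-force oracles.  Each reimplements a computation
# from first principles, by a different route than the package code,
# so agreement is evidence rather than tautology.

# -- per-base pileup oracle -------------------------------------------
# Walks a CIGAR character by character (no regex), marking every
# reference base covered by an M/=/X op, and averages the pile.
oracle_cigar_positions <- function(pos0, cigar) {
  pos <- pos0
  covered <- integer(0)
  num <- ""
  for (ch in strsplit(cigar, "")[[1]]) {
    if (ch >= "0" && ch <= "9") {
      num <- paste0(num, ch)
    } else {
      len <- as.integer(num)
      num <- ""
      if (ch %in% c("M", "=", "X")) {
        covered <- c(covered, seq.int(pos, pos + len - 1L))
        pos <- pos + len
      } else if (ch %in% c("D", "N")) {
        pos <- pos + len
      }
      # I, S, H, P: no reference advance
    }
  }
  covered
}

oracle_pileup_depth <- function(alignments, contig_lengths) {
  depth <- stats::setNames(numeric(length(contig_lengths)),
                           names(contig_lengths))
  prim <- alignments[alignments$is_primary & alignments$is_mapped, ,
                     drop = FALSE]
  piles <- lapply(contig_lengths, function(L) integer(L))
  for (i in seq_len(nrow(prim))) {
    cg <- prim$contig_id[i]
    covered <- oracle_cigar_positions(prim$pos0[i], prim$cigar[i])
    for (p in covered) piles[[cg]][p + 1L] <- piles[[cg]][p + 1L] + 1L
  }
  for (cg in names(piles)) depth[cg] <- mean(piles[[cg]])
  depth
}

# random valid CIGAR over a contig of length L starting at pos0;
# M-type ops at both ends, optional soft clips outside
random_cigar <- function(max_ops = 20L) {
  n_mid <- sample(0:(max_ops - 2L), 1L)
  ops <- c("M", sample(c("M", "=", "X", "I", "D", "N"), n_mid,
                       replace = TRUE), "M")
  lens <- sample(1:5, length(ops), replace = TRUE)
  if (runif(1) < 0.3) {
    ops <- c("S", ops)
    lens <- c(sample(1:5, 1), lens)
  }
  if (runif(1) < 0.3) {
    ops <- c(ops, "S")
    lens <- c(lens, sample(1:5, 1))
  }
  ref_span <- sum(lens[ops %in% c("M", "=", "X", "D", "N")])
  list(cigar = paste0(lens, ops, collapse = ""), ref_span = ref_span)
}

# random toy alignment set written as a SAM file; returns the path and
# the contig lengths
random_sam_fixture <- function(dir) {
  n_contigs <- sample(1:3, 1L)
  lens <- stats::setNames(sample(50:150, n_contigs, replace = TRUE),
                          paste0("c", seq_len(n_contigs)))
  n_rec <- sample(5:30, 1L)
  rows <- character(0)
  for (i in seq_len(n_rec)) {
    cg <- sample(names(lens), 1L)
    repeat {
      rc <- random_cigar()
      if (rc$ref_span < lens[[cg]]) break
    }
    pos0 <- sample.int(lens[[cg]] - rc$ref_span, 1L) - 1L
    flag <- sample(c(0L, 16L, 256L, 4L), 1L,
                   prob = c(0.5, 0.3, 0.1, 0.1))
    if (flag == 4L) {
      rows <- c(rows, sprintf("r%03d\t4\t*\t0\t0\t*\t*\t0\t0\tA\tI", i))
    } else {
      rows <- c(rows, sprintf("r%03d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\tA\tI",
                              i, flag, cg, pos0 + 1L, rc$cigar))
    }
  }
  path <- file.path(dir, paste0("toy", sample.int(1e9, 1), ".sam"))
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens),
               rows), path)
  list(path = path, contig_lengths = lens)
}

# -- taxonomy oracles -------------------------------------------------
# Enumerates the full ancestor-or-self path root-ward (via which(),
# building the whole path before filtering), then picks the first node
# of the requested rank.
oracle_ancestor_path <- function(tree, taxid) {
  path <- integer(0)
  cur <- taxid
  repeat {
    i <- which(tree$taxid == cur)
    if (!length(i)) return(NULL)
    path <- c(path, i)
    if (tree$parent[i] == cur) break
    cur <- tree$parent[i]
    if (length(path) > length(tree$taxid)) stop("cycle")
  }
  path
}

oracle_rank_of <- function(tree, taxid, rank) {
  path <- oracle_ancestor_path(tree, taxid)
  if (is.null(path)) return(tagctools::TAXON_UNRESOLVED)
  hit <- path[tree$rank[path] == rank]
  if (!length(hit)) tagctools::TAXON_UNRESOLVED else tree$name[hit[1]]
}

# random taxonomy tree: node i's parent is a random earlier node
random_tree <- function(n) {
  taxid <- sort(sample.int(10 * n, n))
  parent <- taxid
  for (i in seq_len(n)[-1]) parent[i] <- taxid[sample.int(i - 1L, 1L)]
  structure(list(taxid = taxid, parent = parent,
                 rank = sample(c(tagctools::CANONICAL_RANKS, "no rank",
                                 "clade"), n, replace = TRUE),
                 name = paste0("tax", taxid),
                 root_taxid = taxid[1]),
            class = "taxonomy_tree")
}

# -- geometry oracle --------------------------------------------------
# Explicit rotation-matrix route: x' = R(-theta) (p - c), then the
# axis-aligned quadratic form.
oracle_in_ellipse <- function(e, gc, log10_cov) {
  R <- matrix(c(cos(-e$rotation), sin(-e$rotation),
                -sin(-e$rotation), cos(-e$rotation)), 2, 2)
  p <- R %*% rbind(gc - e$gc, log10_cov - e$log10_cov)
  (p[1, ] / e$a)^2 + (p[2, ] / e$b)^2 <= 1
}

# -- assembly statistics oracle ---------------------------------------
# N50 by the "largest distinct length whose >=L mass reaches half the
# span" characterization, rather than by cumulative scan.
oracle_n50 <- function(lens) {
  if (!length(lens)) return(0L)
  span <- sum(lens)
  for (L in sort(unique(lens), decreasing = TRUE)) {
    if (sum(lens[lens >= L]) >= span / 2) return(as.integer(L))
  }
}

# -- read binning oracle ----------------------------------------------
# Two-pass route: collect raw ids hitting the contig set, then scan the
# whole file again admitting any record whose normalized id is in the
# collected set (mate closure), and normalize at the end.
oracle_reads_for_contigs <- function(alignments, contig_set) {
  hit <- alignments$is_primary & alignments$is_mapped &
    alignments$contig_id %in% contig_set
  raw <- alignments$read_id[hit]
  norm <- unique(tagctools::normalize_read_id(raw))
  mates <- alignments$read_id[
    tagctools::normalize_read_id(alignments$read_id) %in% norm]
  sort(unique(tagctools::normalize_read_id(c(raw, mates))))
}
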