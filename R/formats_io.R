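# Readers and writers for every external format the pipeline touches:
# FASTA assemblies, SAM/BAM alignments, BLAST+ tabular hits, NCBI-style
# taxonomy dumps, paired FASTQ, and the central TAGC TSV table.
# Coordinates are 0-based half-open internally; SAM's 1-based positions
# are converted on read.

# ---------------------------------------------------------------------
# FASTA

#' Read an assembly FASTA file
#'
#' Headers are truncated at the first whitespace and residues are
#' uppercased, so downstream statistics see a uniform alphabet.
#' Gzip-compressed input is handled transparently.
#'
#' @param path path to a FASTA (optionally gzipped) file.
#' @return A [Biostrings::DNAStringSet] named by contig id, in file
#'   order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) format_error("FASTA file not found: %s", path)
  con <- file(path, "r")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) && nzchar(first) && !startsWith(first, ">")) {
    format_error("malformed FASTA %s: line 1 precedes any '>' header", path)
  }
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("[ \t].*$", "", names(x))
  if (anyDuplicated(ids)) {
    format_error("duplicate contig id(s) in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(x) <- ids
  x
}

#' Write contigs to a FASTA file
#'
#' @param contigs a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 60L) {
  Biostrings::writeXStringSet(contigs, path, width = width)
  invisible(path)
}

# ---------------------------------------------------------------------
# SAM / BAM

# CIGAR decomposition.  Only M, = and X consume both reference and read
# and therefore contribute read support; D and N consume reference but
# add no depth; I, S, H, P consume no reference.
cigar_ops <- function(cigar) {
  m <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(m) || paste(m, collapse = "") != cigar) {
    format_error("malformed CIGAR string: %s", cigar)
  }
  list(len = as.integer(sub("[MIDNSHP=X]$", "", m)),
       op  = substring(m, nchar(m), nchar(m)))
}

#' Reference intervals with read support for one alignment
#'
#' Decomposes a CIGAR string into the 0-based half-open reference
#' intervals covered by match/mismatch operations (M, =, X).  Deletions
#' and skips advance the reference cursor but yield no interval.
#'
#' @param pos0 0-based leftmost reference position of the alignment.
#' @param cigar CIGAR string.
#' @return Integer matrix with columns `start`, `end` (possibly 0 rows).
#' @examples
#' ref_intervals(2L, "3M2D4M")   # rbind(c(2,5), c(7,11))
#' @export
ref_intervals <- function(pos0, cigar) {
  ops <- cigar_ops(cigar)
  cur <- as.integer(pos0)
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_along(ops$op)) {
    op <- ops$op[i]
    len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      starts <- c(starts, cur)
      ends <- c(ends, cur + len)
      cur <- cur + len
    } else if (op %in% c("D", "N")) {
      cur <- cur + len
    }
  }
  cbind(start = starts, end = ends)
}

# Total reference-consumed (read-supported) length per CIGAR, vectorized
# through the unique values so that deep libraries with homogeneous
# CIGARs stay cheap.
ref_consumed_len <- function(cigars) {
  u <- unique(cigars)
  per <- vapply(u, function(cg) {
    ops <- cigar_ops(cg)
    sum(ops$len[ops$op %in% c("M", "=", "X")])
  }, integer(1))
  unname(per[match(cigars, u)])
}

sam_mate_role <- function(flag) {
  role <- rep("unpaired", length(flag))
  paired <- bitwAnd(flag, 1L) > 0L
  role[paired & bitwAnd(flag, 64L) > 0L] <- "first"
  role[paired & bitwAnd(flag, 128L) > 0L] <- "second"
  role
}

finish_alignments <- function(df, sq_names, path) {
  bad <- df$is_mapped & !(df$contig_id %in% sq_names)
  if (any(bad)) {
    format_error(
      "alignment file %s: mapped record(s) name reference(s) absent from header: %s",
      path, paste(unique(df$contig_id[bad]), collapse = ", "))
  }
  skip <- df$is_mapped & (is.na(df$cigar) | df$cigar == "*")
  n_skipped <- sum(skip)
  if (n_skipped > 0L) {
    warning(sprintf("%s: skipped %d mapped record(s) without a CIGAR",
                    path, n_skipped), call. = FALSE)
    df <- df[!skip, , drop = FALSE]
  }
  df$contig_id[!df$is_mapped] <- NA_character_
  df$pos0[!df$is_mapped] <- NA_integer_
  df$cigar[!df$is_mapped] <- NA_character_
  rownames(df) <- NULL
  attr(df, "n_skipped_no_cigar") <- n_skipped
  attr(df, "reference_names") <- sq_names
  class(df) <- c("tagc_alignments", "data.frame")
  df
}

#' Read alignments from a SAM or BAM file
#'
#' Returns one record per alignment line with the fields needed to
#' compute read depth and pair membership: canonical-ready read id, flag
#' bits, reference contig, 0-based position and CIGAR.  Secondary
#' (0x100) and supplementary (0x800) alignments are flagged
#' `is_primary = FALSE`; unmapped records keep `NA` coordinates.
#' Mapped records lacking a CIGAR are skipped with a warning (count in
#' attribute `n_skipped_no_cigar`).
#'
#' @param path path to a `.sam` text file or `.bam` binary file.
#' @return A data frame of class `tagc_alignments` with columns
#'   `read_id`, `flag`, `contig_id`, `pos0`, `cigar`, `is_mapped`,
#'   `is_primary`, `mate_role`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) format_error("alignment file not found: %s", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    read_alignments_bam(path)
  } else {
    read_alignments_sam(path)
  }
}

read_alignments_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sq_names <- sub("^SN:", "", unlist(lapply(strsplit(sq, "\t", fixed = TRUE),
                                            function(f) f[startsWith(f, "SN:")])))
  if (!length(rec)) {
    df <- data.frame(read_id = character(0), flag = integer(0),
                     contig_id = character(0), pos0 = integer(0),
                     cigar = character(0), is_mapped = logical(0),
                     is_primary = logical(0), mate_role = character(0),
                     stringsAsFactors = FALSE)
    return(finish_alignments(df, sq_names, path))
  }
  f <- strsplit(rec, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) {
    format_error("%s: SAM record with fewer than 11 fields at data line %d",
                 path, which(nf < 11L)[1])
  }
  field <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(field(2))
  df <- data.frame(
    read_id = field(1),
    flag = flag,
    contig_id = field(3),
    pos0 = as.integer(field(4)) - 1L,
    cigar = field(6),
    is_mapped = bitwAnd(flag, 4L) == 0L,
    is_primary = bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L,
    mate_role = sam_mate_role(flag),
    stringsAsFactors = FALSE)
  finish_alignments(df, sq_names, path)
}

read_alignments_bam <- function(path) {
  bf <- Rsamtools::BamFile(path)
  sq_names <- names(Rsamtools::scanBamHeader(bf)$targets)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"))
  b <- Rsamtools::scanBam(bf, param = p)[[1]]
  flag <- as.integer(b$flag)
  df <- data.frame(
    read_id = b$qname,
    flag = flag,
    contig_id = as.character(b$rname),
    pos0 = as.integer(b$pos) - 1L,
    cigar = b$cigar,
    is_mapped = bitwAnd(flag, 4L) == 0L,
    is_primary = bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L,
    mate_role = sam_mate_role(flag),
    stringsAsFactors = FALSE)
  finish_alignments(df, sq_names, path)
}

# ---------------------------------------------------------------------
# BLAST+ tabular hits

#' Read a BLAST+ tabular best-hit table
#'
#' Expects the minimal two-column layout `qseqid staxids` produced by
#' `-outfmt '6 qseqid staxids'`; a third and fourth column, when
#' present, are interpreted as e-value and bit score.  Multi-taxid
#' fields are split on `";"`.
#'
#' @param path path to a tab-separated hits file.
#' @return Data frame with columns `query_id`, `taxids` (list of
#'   integer vectors), `taxid` (first taxid), `evalue`, `bitscore`,
#'   `file_rank` (0-based input order).
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) format_error("hits file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (length(nf) && any(nf < 2L)) {
    format_error("%s: line %d has fewer than 2 tab-separated columns",
                 path, lineno[which(nf < 2L)[1]])
  }
  taxids <- lapply(seq_along(f), function(i) {
    toks <- strsplit(f[[i]][2], ";", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.integer(toks))
    if (!length(vals) || anyNA(vals)) {
      format_error("%s: line %d: non-integer taxid field '%s'",
                   path, lineno[i], f[[i]][2])
    }
    vals
  })
  opt_num <- function(i) {
    vapply(f, function(x) {
      if (length(x) >= i) suppressWarnings(as.numeric(x[i])) else NA_real_
    }, numeric(1))
  }
  data.frame(
    query_id = vapply(f, `[[`, character(1), 1),
    taxids = I(taxids),
    taxid = vapply(taxids, `[[`, integer(1), 1),
    evalue = opt_num(3),
    bitscore = opt_num(4),
    file_rank = seq_along(f) - 1L,
    stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------
# NCBI-style taxonomy dump

parse_dmp <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t|\t", fixed = TRUE)
}

#' Read an NCBI-style taxonomy dump
#'
#' Parses `nodes.dmp` (taxid, parent, rank) and `names.dmp` (taxid,
#' name, ..., name class) in the `"\t|\t"`-delimited dialect.  A node's
#' name is its scientific name when one exists, otherwise the first
#' listed name, otherwise the taxid itself.
#'
#' @param nodes_path,names_path paths to the two dump files.
#' @return A `taxonomy_tree`: list with parallel vectors `taxid`,
#'   `parent`, `rank`, `name` and scalar `root_taxid`.
#' @export
read_taxdump <- function(nodes_path, names_path) {
  nf <- parse_dmp(nodes_path)
  taxid <- vapply(nf, function(x) as.integer(x[1]), integer(1))
  parent <- vapply(nf, function(x) as.integer(x[2]), integer(1))
  rank <- vapply(nf, `[[`, character(1), 3)
  if (anyNA(taxid) || anyNA(parent)) {
    format_error("%s: non-integer taxid field", nodes_path)
  }
  orphans <- setdiff(parent, taxid)
  if (length(orphans)) {
    format_error("%s: parent taxid(s) absent from nodes: %s", nodes_path,
                 paste(sort(orphans), collapse = ", "))
  }
  roots <- taxid[taxid == parent]
  if (length(roots) != 1L) {
    format_error("%s: expected exactly one self-parent root, found %d",
                 nodes_path, length(roots))
  }

  mf <- parse_dmp(names_path)
  ntax <- vapply(mf, function(x) as.integer(x[1]), integer(1))
  ntxt <- vapply(mf, `[[`, character(1), 2)
  ncls <- vapply(mf, function(x) if (length(x) >= 4) x[4] else "", character(1))
  name <- as.character(taxid)
  # first listed name per taxid, then let scientific names win
  first <- !duplicated(ntax)
  name[match(ntax[first], taxid)] <- ntxt[first]
  sci <- ncls == "scientific name"
  sci_idx <- which(sci)[!duplicated(ntax[sci])]
  name[match(ntax[sci_idx], taxid)] <- ntxt[sci_idx]

  structure(list(taxid = taxid, parent = parent, rank = rank, name = name,
                 root_taxid = roots),
            class = "taxonomy_tree")
}

#' Write a taxonomy tree back out in dump format
#'
#' Inverse of [read_taxdump()]; all names are emitted with class
#' `scientific name`, so a round trip preserves lineage lookups.
#'
#' @param tree a `taxonomy_tree`.
#' @param nodes_path,names_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_taxdump <- function(tree, nodes_path, names_path) {
  nodes <- sprintf("%d\t|\t%d\t|\t%s\t|", tree$taxid, tree$parent, tree$rank)
  nms <- sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", tree$taxid, tree$name)
  writeLines(nodes, nodes_path)
  writeLines(nms, names_path)
  invisible(list(nodes = nodes_path, names = names_path))
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy_tree: %d nodes, root taxid %d\n",
              length(x$taxid), x$root_taxid))
  invisible(x)
}

# ---------------------------------------------------------------------
# TAGC TSV

tagc_cov_labels <- function(table) {
  sub("^cov_", "", grep("^cov_", names(table), value = TRUE))
}

tagc_rank_labels <- function(table) {
  sub("^taxlevel_", "", grep("^taxlevel_", names(table), value = TRUE))
}

validate_tagc_table <- function(df) {
  nm <- names(df)
  if (length(nm) < 3L || !identical(nm[1:3], c("seqid", "length", "gc"))) {
    format_error("TAGC table must start with columns seqid, length, gc")
  }
  rest <- nm[-(1:3)]
  is_cov <- startsWith(rest, "cov_")
  is_tax <- startsWith(rest, "taxlevel_")
  if (any(!is_cov & !is_tax)) {
    format_error("TAGC table: unknown column '%s'",
                 rest[!is_cov & !is_tax][1])
  }
  if (any(is_cov & cumsum(is_tax) > 0)) {
    format_error("TAGC table: cov_ column '%s' appears after a taxlevel_ column",
                 rest[is_cov & cumsum(is_tax) > 0][1])
  }
  if (anyDuplicated(df$seqid)) {
    format_error("TAGC table: duplicate seqid '%s'",
                 df$seqid[duplicated(df$seqid)][1])
  }
  if (nrow(df)) {
    if (any(df$gc < 0 | df$gc > 1)) format_error("TAGC table: gc outside [0,1]")
    covs <- df[, startsWith(nm, "cov_"), drop = FALSE]
    if (length(covs) && any(unlist(covs) < 0)) {
      format_error("TAGC table: negative coverage value")
    }
  }
  class(df) <- c("tagc_table", "data.frame")
  df
}

#' Write a TAGC table as tab-separated text
#'
#' Column order is fixed: `seqid`, `length`, `gc`, then one
#' `cov_<label>` column per library, then one `taxlevel_<rank>` column
#' per rank.  GC is printed with 4 decimals and coverage with 3, so the
#' file is diffable and a write/read cycle is idempotent.
#'
#' @param table a `tagc_table` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tagc_tsv <- function(table, path) {
  table <- validate_tagc_table(as.data.frame(table))
  out <- data.frame(seqid = table$seqid,
                    length = as.integer(table$length),
                    gc = sprintf("%.4f", table$gc),
                    stringsAsFactors = FALSE)
  for (lab in tagc_cov_labels(table)) {
    out[[paste0("cov_", lab)]] <- sprintf("%.3f", table[[paste0("cov_", lab)]])
  }
  for (rk in tagc_rank_labels(table)) {
    out[[paste0("taxlevel_", rk)]] <- table[[paste0("taxlevel_", rk)]]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TAGC table from tab-separated text
#'
#' The header must follow the column grammar of [write_tagc_tsv()];
#' any column outside it is a format error.
#'
#' @param path path to a TAGC TSV file.
#' @return A `tagc_table` data frame.
#' @export
read_tagc_tsv <- function(path) {
  if (!file.exists(path)) format_error("TAGC TSV not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (!ncol(df)) format_error("%s: empty TAGC TSV", path)
  nm <- names(df)
  if (length(nm) < 3L || !identical(nm[1:3], c("seqid", "length", "gc"))) {
    format_error("%s: header must begin 'seqid\tlength\tgc'", path)
  }
  rest <- nm[-(1:3)]
  bad <- rest[!startsWith(rest, "cov_") & !startsWith(rest, "taxlevel_")]
  if (length(bad)) {
    format_error("%s: unknown column '%s' in header", path, bad[1])
  }
  df$length <- as.integer(df$length)
  df$gc <- as.numeric(df$gc)
  for (cc in grep("^cov_", nm, value = TRUE)) df[[cc]] <- as.numeric(df[[cc]])
  validate_tagc_table(df)
}

# ---------------------------------------------------------------------
# FASTQ

#' Read a FASTQ file
#'
#' @param path path to an uncompressed or gzipped 4-line-record FASTQ.
#' @return Data frame with columns `id` (without the leading `@`),
#'   `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) format_error("FASTQ file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    format_error("%s: truncated FASTQ (line count %d not a multiple of 4)",
                 path, length(lines))
  }
  idl <- lines[seq(1L, length(lines), by = 4L)]
  bad <- which(!startsWith(idl, "@"))
  if (length(bad)) {
    format_error("%s: record %d does not start with '@'", path, bad[1])
  }
  plus <- lines[seq(3L, length(lines), by = 4L)]
  if (any(!startsWith(plus, "+"))) {
    format_error("%s: record %d missing '+' separator line", path,
                 which(!startsWith(plus, "+"))[1])
  }
  data.frame(id = sub("^@", "", idl),
             seq = lines[seq(2L, length(lines), by = 4L)],
             qual = lines[seq(4L, length(lines), by = 4L)],
             stringsAsFactors = FALSE)
}

#' Read a pair of synchronized FASTQ files
#'
#' Mate files are processed in lock-step; ids must agree record by
#' record after [normalize_read_id()] suffix stripping.
#'
#' @param path1,path2 paths to the R1 and R2 files.
#' @return list with elements `r1`, `r2` (each as [read_fastq()]) and
#'   `id` (the shared canonical ids).
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- read_fastq(path1)
  r2 <- read_fastq(path2)
  if (nrow(r1) != nrow(r2)) {
    format_error("FASTQ pair files differ in record count (%d vs %d)",
                 nrow(r1), nrow(r2))
  }
  id1 <- normalize_read_id(r1$id)
  id2 <- normalize_read_id(r2$id)
  bad <- which(id1 != id2)
  if (length(bad)) {
    format_error("FASTQ pair files desynchronized at record %d ('%s' vs '%s')",
                 bad[1], r1$id[bad[1]], r2$id[bad[1]])
  }
  list(r1 = r1, r2 = r2, id = id1)
}

#' Write FASTQ records
#'
#' @param reads data frame with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads)) {
    writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq,
                               "+", reads$qual)), path)
  } else {
    writeLines(character(0), path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------
# SAM writing (used by the simulator and available to users)

#' Write alignment records as a SAM file
#'
#' @param records data frame with columns `qname`, `flag`, `rname`,
#'   `pos` (1-based; 0 for unmapped), `mapq`, `cigar`, `rnext`, `pnext`,
#'   `tlen`, `seq`, `qual`.
#' @param contig_lengths named integer vector for the `@SQ` header.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, contig_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  records$qname, records$flag, records$rname,
                  records$pos, records$mapq, records$cigar,
                  records$rnext, records$pnext, records$tlen,
                  records$seq, records$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}
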