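# tagctools

Taxon-annotated GC-coverage (TAGC, or "blob") plots and contig/read
binning for contamination screening of draft genome assemblies.

## The problem

Wild-caught and host-associated organisms rarely yield clean DNA: a
nematode sample carries its bacterial food, symbionts and host tissue,
so a "single-species" sequencing run is really a low-complexity
metagenome. Co-assembling such mixtures hurts the target genome —
assemblers assume one modal coverage, bacteria assemble more easily,
and GC biases pull the assembly toward the mid-GC range. The severity
is set by *molarity*, not read share: if a component contributes a
fraction *f* of the reads and has genome size *g*, its molar abundance
is proportional to *f / g*. A mixture of 45% parasite (100 Mb), 45%
host (3000 Mb) and 10% bacterial (5 Mb) reads contains, in molar
terms, 1 : 0.03 : 4.4 parasite : host : bacterium — the minor
bacterial *read* fraction dominates the mixture molecule-wise.

The remedy implemented here: make a quick preliminary assembly, then
characterize every contig by three nearly orthogonal signals —

* **GC fraction** `(G+C)/(A+C+G+T)` (ambiguous bases excluded),
* **mean read depth per library** (aligned bases / contig length, a
  proxy for the source genome's molarity),
* **taxonomy of the best database hit**, rolled up to a canonical rank
  (e.g. order) through the NCBI taxonomy tree.

Plotted as GC vs log10 coverage with taxon coloring, each genome in
the mixture forms a distinct "blob". Contigs are then binned with
declarative rules (taxon lists, GC/coverage ranges, drawn ellipses),
and the reads mapping to each bin — *plus their mates* — are extracted
so every genome can be reassembled cleanly on its own.

## What is in the package

| area | functions |
|---|---|
| formats | `read_fasta`, `read_alignments` (SAM/BAM), `read_hits`, `read_taxdump`, `read_tagc_tsv`/`write_tagc_tsv`, FASTQ pair IO |
| statistics | `gc_fraction`, `filter_min_length`, `assembly_summary` (N50 = length-weighted median) |
| coverage | `compute_coverage`, `mapped_fraction`, `merge_coverages` |
| taxonomy | `best_hit_per_contig`, `rank_of`, `annotate_contigs` |
| table | `build_table`, `subsample_table`, `legend_taxa`, `relative_molarity` |
| binning | `selection_rule`, `tagc_ellipse`, `select_contigs`, `conservative_discard`, `reads_for_contigs`, `filter_fastq` |
| plotting | `render_tagc` (PNG), `export_svg` (+ JSON legend manifest) |
| simulation | `make_standard_fixture`, `simulate_genome`, `simulate_reads_and_alignments` |
| CLI | `tagc_main()`; launcher in `inst/scripts/tagctools` |

External stages (assembler, read mapper, BLAST search) are *not* run
by the package: it consumes their standard outputs (FASTA, SAM/BAM,
tabular `qseqid staxids` hits, taxdump files).

## Worked example

Relative molarity of the mixture above, normalized to the parasite:

```r
library(tagctools)
mix <- data.frame(label = c("parasite", "host", "bacterium"),
                  read_fraction = c(0.45, 0.45, 0.10),
                  genome_size = c(100, 3000, 5))   # Mb
round(relative_molarity(mix, "parasite"), 3)
#>  parasite      host bacterium
#>     1.000     0.033     4.444
```

A full pipeline run on a simulated contaminated assembly (a
Rhabditida-like target at 100-fold depth plus two bacterial
contaminants at 10- and 200-fold; `--scale 0.25` shrinks genome sizes
for a quick demo):

```r
d <- file.path(tempdir(), "demo")
tagc_main(c("simulate", "--preset", "standard", "--seed", "42",
            "--scale", "0.25", "-o", d))
tagc_main(c("stats", file.path(d, "assembly.fasta")))
#> Assembly summary (min length filter: 200 bp)
#>   contigs:     35
#>   span (bp):   87,500
#>   mean (bp):   2,500
#>   N50 (bp):    2,500
tagc_main(c("tagc", "--assembly", file.path(d, "assembly.fasta"),
            "--bam", file.path(d, "lib1.sam"),
            "--hits", file.path(d, "hits.tsv"),
            "--taxdump", file.path(d, "taxdump"),
            "-o", file.path(d, "table.tsv")))
tab <- read_tagc_tsv(file.path(d, "table.tsv"))
head(tab, 4)
#>        seqid length     gc cov_lib1 cov_total taxlevel_order
#> 1 target_c01   2500 0.4152      100       100     Rhabditida
#> 2 target_c02   2500 0.3844      100       100     Rhabditida
#> 3 target_c03   2500 0.3996      100       100     Rhabditida
#> 4 target_c04   2500 0.4092      100       100     Rhabditida
legend_taxa(tab, "order")
#> [1] "Rhabditida"      "Pseudomonadales" "Actinomycetales"
```

Each row carries the contig's GC, its per-library and combined depth,
and its best-hit order; the legend lists the taxa annotating at least
1% of annotated contigs. Binning then proceeds with

```sh
tagctools plot table.tsv --rank order --format svg -o blobs.svg
tagctools filter-contigs table.tsv --exclude-taxa Pseudomonadales,Actinomycetales -o keep_ids.txt
tagctools extract-reads --ids contam_ids.txt --bam lib1.sam \
    --fastq reads_1.fastq --fastq reads_2.fastq --out-prefix cleaned
```

`extract-reads` removes every pair with a read mapping to the flagged
contigs *and* the mates of those reads (mate rescue), leaving a
pair-complete cleaned read set for reassembly.

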