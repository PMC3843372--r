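---
title: "TAGC plots: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TAGC plots: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A sequencing library prepared from a mixture of organisms is, to first
order, a mixture of genomes at different molar concentrations. For a
component contributing read fraction $f$ from a genome of size $g$,
molarity is proportional to $f/g$ (`relative_molarity()`); read depth
of the contigs deriving from that genome is proportional to the same
quantity. Three per-contig statistics therefore separate the
components of a preliminary co-assembly:

* **GC fraction** — genomes differ in base composition;
  $\mathrm{GC} = (n_G + n_C)/(n_A + n_C + n_G + n_T)$.
* **Mean read depth** — for contig $c$ of length $L_c$,
  $d_c = \frac{1}{L_c}\sum_{r \in \text{primary mapped}(c)} b_r$,
  where $b_r$ is the number of reference bases covered by
  match/mismatch CIGAR operations of record $r$.
* **Best-hit taxonomy** — the taxid of the lowest-e-value database
  match, rolled up to a canonical rank through the taxonomy tree.

In the (GC, $\log_{10}$ depth) plane each genome forms a coherent
cluster ("blob") with a consistent taxonomic color; contigs are binned
by taxon membership, coordinate ranges, or ellipses drawn in that
plane, and the reads aligned to a bin — closed over mate pairs — form
the corresponding read set.

Assumptions worth stating: depth is treated as molarity×length signal
without GC-bias correction; a contig is assigned to a single source
via its best hit (no LCA voting across hits); and binning operates at
contig granularity (chimeric contigs are mitigated only by the
conservative discard rule below).

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `min_len` (stats, `tagc`) | 200 | bp | conventional floor for screening preliminary assemblies; "smaller than" is removed, the boundary length is kept |
| legend `threshold` | 0.01 | fraction of *annotated* contigs | taxa under 1% clutter the key; they still plot (gray). Equality at 1% is shown |
| `y_floor` | 0.01 | depth | zero-depth contigs are undefined on a log axis; a fixed floor keeps them visible well below any real blob |
| `permissive_evalue` | 1e-2 | — | the conservative discard rule keeps a contaminant-best contig if *any* target hit beats this; three orders looser than a typical 1e-5 search cutoff |
| `subsample_table` n | user-set (CLI suggests 20000) | rows | interactive display comfort; explicit seed, sample without replacement, order preserved |
| ranks | `order` | — | the rank at which contaminant groups are typically coherent and nameable |

Coverage semantics (fixed, documented rather than configurable): only
primary alignments count, each read contributes at most once;
duplicates are not removed; deletions/skips consume reference but add
no depth. Whether "coverage" counts reads or bases is ambiguous in
common usage — this package counts aligned bases per reference base.

GC semantics: N and all other IUPAC ambiguity codes are excluded from
numerator *and* denominator, so scaffold gap runs do not depress GC.
A contig with no unambiguous base reports GC 0 and is flagged.

## The synthetic-data generator

`make_standard_fixture()` writes a complete, ground-truthed input
bundle emulating a contaminated nematode assembly:

* target genome, order Rhabditida: 200 kb in 20 contigs, GC 0.40,
  depth 100 — the "major blob";
* contaminant A, Pseudomonadales: 100 kb, GC 0.62, depth 10 — a
  low-molarity contaminant;
* contaminant B, Actinomycetales: 50 kb, GC 0.66, depth 200 — a
  high-molarity contaminant.

Reads are 100 b error-free pairs at insert 300 (mirroring a 101 b
paired-end 300 bp-insert library); 1.31% of pairs are random-sequence
unmapped spike-ins, so the mapped fraction is 98.69%, the figure
reported for the real dataset this scenario abstracts. 10% of target
contigs get no database hit, producing the gray unannotated points a
real blob plot always has. Genomes are i.i.d. base sequences at the
stated GC; fragments are sampled uniformly per contig with a
deterministic fragment count, so realized depth equals the request up
to rounding.

What the generator does **not** model — and hence what a green
recovery test does not establish: sequencing errors and quality decay,
GC-dependent coverage bias (real Illumina data under-represents low-GC
fragments, skewing blobs), repeats and shared sequence between
genomes, chimeric contigs, uneven per-contig molarity (plasmids,
organelles), and taxonomically misleading hits. Recovery of planted
GC/depth/taxa shows the *bookkeeping* is correct, not that real
mixtures always separate.

All randomness flows through explicit integer seeds and an
RNG-state-restoring wrapper; identical seeds give byte-identical
bundles.

## Numerical and procedural choices

* **N50**: length-weighted median — sort contigs by descending length
  (ties broken by id for determinism) and take the length of the first
  contig at which the cumulative sum reaches half the span. Empty
  assemblies report 0.
* **Best-hit tie-breaks**: lowest e-value, then highest bit score,
  then input order; with two-column input (no e-values) input order
  stands in. Of a multi-taxid `staxids` field the first taxid is used.
* **Unknown taxids** resolve to the `unresolved` sentinel with a
  warning rather than an error: public databases contain retired ids,
  and one stale hit should not kill a run. Merged-id remapping
  (`merged.dmp`) is out of scope.
* **Rule algebra**: within a rule, criteria AND; between rules,
  sequential set algebra (keep = intersect, exclude = subtract) in
  user order. Deterministic and compositional; order-dependent by
  design, like any filter chain.
* **Ellipses** are tested boundary-inclusive after translating and
  rotating into axis-aligned form; membership uses the same
  $\log_{10}$ axis (and zero-depth floor) as the plot, so a drawn
  selection means what the eye saw.
* **Pair handling**: read ids are normalized by stripping comments and
  `/1`,`/2` suffixes; exclusion is pair-level (if either mate is
  flagged the pair goes), which makes every output read set
  pair-complete — assemblers want pairs, and half-pairs silently
  degrade scaffolding.
* **TSV precision**: GC printed to 4 decimals, coverage to 3. One
  write/read cycle settles values onto the printed grid; thereafter
  write/read is the identity (asserted in tests).
* **SVG output** is hand-assembled with exactly one element per point
  so rendering is assertable; a JSON legend manifest (taxon, count,
  color) accompanies every image because pixels are not a test
  surface.

## Design decisions that were genuinely open

* *GC denominator*: whether published GC figures include ambiguous
  bases is usually unstated; ACGT-only was chosen and is flagged here
  because the alternative systematically depresses GC for gappy
  scaffolds.
* *Legend boundary*: "less than 1% hidden" implies equality shown;
  implemented that way.
* *Header grammar*: only the `cov_`/`taxlevel_` prefixes are
  conventionally fixed; the exact header strings and column order used
  here are a frozen choice so files round-trip bit-exactly.
* *Permissive cutoff*: no published value exists for the rescue
  threshold; 1e-2 is a documented, configurable default.
* *SAM text parsing in-package*: the BAM route uses Rsamtools, but SAM
  text is parsed directly so text-only fixtures and pipelines need no
  binary intermediates; both routes are tested for agreement.

## Known limitations

* No CRAM; gzip only for FASTA/FASTQ text inputs.
* Whole files are read into memory; fine for preliminary assemblies
  and their alignments at screening scale, not for hundred-gigabase
  BAMs (stream through `samtools view` first, or supply BAM).
* No LCA/voting taxonomy, no k-mer composition features, no automated
  blob discovery: selection is explicit and user-driven.
* Interactive ellipse drawing is out of scope; the geometry is exposed
  programmatically and via the CLI.

No empirical claim in this vignette goes beyond what the package's
tests and `scripts/acceptance.R` themselves compute.
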