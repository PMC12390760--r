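---
title: "Analysing chimeric eCLIP data with chimeRclip"
author: "chimeRclip authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing chimeric eCLIP data with chimeRclip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and the analysis problem

Chimeric eCLIP (miR-eCLIP) crosslinks AGO2 to the RNAs it binds,
immunoprecipitates the complexes, and — before adapter ligation — performs
an on-bead ligation that joins the 3' end of the guiding miRNA to the 5'
end of the bound target fragment. A sequencing library then contains two
informative read populations. *Nonchimeric* reads are ordinary eCLIP reads:
they report where AGO2 sat, but not which miRNA guided it. *Chimeric* reads
carry a full mature miRNA sequence at the 5' end of the insert followed by
the target fragment, so a single read names both partners of a
miRNA:target interaction. A small aliquot (about 2%) of the
pre-immunoprecipitation material is sequenced as the *size-matched input*,
the background against which peak enrichment is measured. When the assay
is applied to subcellular fractions — cytoplasm, nucleus,
chromatin-associated RNA — the comparison across fractions asks where in
the cell miRNA-mediated recognition begins.

`chimeRclip` implements the full computational path for this assay at desk
scale: every stage runs in seconds to minutes on a laptop, on simulated
data with a complete ground-truth table, so every stage can be tested
exactly. The package is organised Bioconductor-style: the central data
object is the S4 `GenomeBundle` (chromosomes as a `DNAStringSet`,
transcript models and repeats as `GRanges`, miRNAs as a `DataFrame`);
aligned fragments and peaks are `GRanges` with metadata columns; standard
formats go through Biostrings and rtracklayer.

## The simulator and what it emulates

`makeGenome()` builds random chromosomes carrying non-overlapping gene
models: coding genes have three exons, a CDS span and non-empty UTRs on
both sides; noncoding genes have two exons; each chromosome ends in a
repeat/rRNA-like interval. Mature miRNAs (20–23 nt) are grouped into seed
families — identical 7-mer at positions 2–8 — and one miRNA per run is
left off the allowlist to exercise the curated-database filter.

`simulateLibraries()` emits, per fraction and replicate, an IP and an
input FASTQ plus one truth row per read. Reads are single-end:
`UMI (10 nt) + insert + 3' adapter`, truncated to the read length (75 nt).
IP inserts are a mixture of four classes: chimeric (miRNA + target
fragment from a planted site), nonchimeric site fragments, transcriptome
background, and repeat-derived reads; input inserts are pure transcriptome
background — the size-matched input models background abundance, not
binding. PCR duplication re-emits an existing molecule's UMI and insert
with independent substitution errors. All randomness flows from one seed,
and outputs are byte-identical across runs.

Deliberate simplifications: substitutions only (no indels), no
crosslink-induced truncations or mutations, no splice-junction reads
(fragments stay within one exon), no paired ends, and a genome orders of
magnitude smaller than a mammalian one. Passing tests on these data
therefore validate the *logic* of each stage — they do not certify
performance on real libraries, where spliced alignment, indels and
crosslink artefacts matter.

Geometry conventions the detector assumes (and the simulator produces):
the miRNA occupies the 5' end of the insert, the target is 3' of it; the
UMI is the first 10 bases of the raw read; read-length bookkeeping
guarantees at least 3 nt of adapter are always visible, so error-free
reads trim exactly to their insert.

## Stage-by-stage model and defaults

**UMI extraction.** The first `umiLength` bases move into the read id
after a `_` delimiter, so deduplication can operate from FASTQ alone.

**Adapter trimming.** Ungapped comparison of the read against the adapter
prefix at every start position; the earliest position with overlap >= 3
and mismatch rate <= 0.1 wins (this removes the longest qualifying
suffix, and a full internal adapter occurrence removes everything from its
first qualifying position). Reads shorter than 18 nt after trimming are
dropped: too short to map or to contain a miRNA. One caveat is documented
rather than hidden: like any greedy 3'-trimmer with a short minimum
overlap, a read whose *insert* happens to end in the first 3–4 adapter
bases can lose those bases; with the guaranteed adapter presence in the
simulated libraries the earliest qualifying window is always the true
adapter start, so trimmed reads equal their truth inserts at error rate 0.

**Repeat filter, then genome mapping.** Reads are first aligned against
the repeat/rRNA sequences and removed on any hit; survivors are mapped to
the genome. The aligner is deliberately simple: exact k-mer seeds
(k = 16) taken at the first and last k bases of the read on both strands,
ungapped extension, mismatch counting, `unique` / `multi` / `unmapped` by
the minimal-mismatch tie count, with multi-mappers discarded (standard
unique-mapping eCLIP practice). Two non-overlapping seeds guarantee that
any alignment with at most one mismatch is found whenever the read is at
least 2k long; at the default `maxMismatches = 2` discovery is heuristic,
which the test suite accounts for by validating against a brute-force
aligner. Coordinates are 0-based half-open internally and converted only
at GTF/report boundaries.

**Chimera detection and resolution.** Only reads that failed genome
mapping (after repeat filtering) are tested — the order of operations is a
tested contract. Every miRNA's 5' end is aligned ungapped to the read's
5' end; the best call is the longest match with >= 18 matched bases and
<= 1 mismatch, ties broken by fewest mismatches then lexicographically
smallest name, with equally scoring miRNAs recorded in `ambiguous_with`.
Same-seed family members are expected to tie on their shared prefix;
family-level summaries are invariant to that tie-break. Reads fully
covered by a miRNA are counted as miRNA-only; residual targets shorter
than 18 nt yield no call. Target fragments then go through the same
genome mapper, and unique hits become fragments tagged with their miRNA.

**Deduplication and clustering.** Fragments collapse on
(UMI, chromosome, start, strand), keeping the first by read id. Clusters
are strand-aware single-linkage merges of fragments overlapping by at
least 1 bp (book-ended fragments stay separate); this documented
simplified caller stands in for heavier CLIP peak callers because the
analysis hinges on the explicit selection criteria, which are implemented
exactly. Chimeric and nonchimeric fragments are clustered separately,
giving two peak universes; chimeric fragments are first restricted to the
allowlisted miRNAs.

**Scoring and selection.** Per cluster, against the replicate's own
input: `input_count` is the same-strand overlap count,
`RPM = ip_count / ip_total * 1e6`, and

```
log2FC = log2( ((ip_count + 1) / ip_total) /
               ((input_count + 1) / input_total) )
```

with a one-read pseudocount on both sides so empty input is defined. The
p-value is the one-sided exact hypergeometric tail (Fisher's exact test in
the enrichment direction; peaks are by construction IP-derived). Final
peaks must have `ip_count >= 3` and `log2FC > 3` (both read strictly as
printed) and a same-strand, >= 1 bp overlapping passing peak in the other
replicate; the final intervals are the per-pair unions with miRNA tallies
summed. The enrichment thresholds are applied to both universes; a
configuration switch exposes this because the convention for chimeric
clusters is genuinely open. No multiple-testing correction is applied —
the analysis reports thresholded peaks, not an FDR set.

**Annotation.** Features are derived per transcript (CDS pieces, UTRs
oriented by strand, introns; noncoding exons/introns) and peaks take the
highest-priority overlapping same-strand category under
`CDS > UTR3 > UTR5 > intron > nc_exon > nc_intron`, falling back to
intergenic. The internal UTR order is a choice the hierarchy's source
leaves open; UTR3 is ranked first among UTRs because it is the canonical
miRNA-target context, and the order is a configuration knob. Annotation
uses the full peak interval (not the midpoint), and gene ties resolve to
the lexicographically smallest gene id, logged as ambiguous.

**Families and prioritization.** Family fractions are computed over
deduplicated chimeric fragments (not raw reads) — the denominator is
logged. Candidate genes require (i) more than five chimeric UTR3 peaks in
one fraction (strict `> 5`, with a `>= 5` switch) *or* at least one in
every fraction ({cytoplasm, nucleus, chromatin} by default, configurable),
and (ii) altered expression, operationalized as `|log2FC| >= 1` together
with a significance flag from the expression table, since the selection
rule's source states no numeric cutoff. Genes missing from the expression
table are flagged and never selected.

**qPCR.** Technical replicates are averaged on the Ct scale before
exponentiation; amplification efficiency is fixed at 2. Relative
expression is `2^-ddCt` against a reference gene (RPL19 in the assays this
mirrors); the splicing readout is `2^-(Ct_inclusion - Ct_skipping)` from
one sample, optionally divided by a user-supplied full-length abundance
factor (the raw ratio is always reported, because the exact normalization
arithmetic is not specified by the assay description). The two-sample
test is the classical pooled-variance Student's t (two-tailed), computed
in closed form and cross-checked against `stats::t.test` in the tests; a
Welch option exists but is off by default to match the test's name.

## Numerical and degenerate-input choices

* Exact test p-values come from `stats::phyper`; the tests compare them to
  direct log-binomial summation to 1e-12 over dense 2x2 sweeps.
* `log2FC` pseudocounts make all fold changes finite; a cluster equal in
  rate to its input gives exactly 0.
* Zero library totals, empty miRNA sets, fragments without UMIs,
  non-positive thresholds, malformed CDS spans and unknown configuration
  keys are hard errors; empty groups (a fraction with no peaks) are empty
  outputs, not errors.
* Degenerate t-test inputs: zero pooled variance with equal means gives
  t = 0, p = 1; with unequal means, a signed infinite statistic and p = 0.
* All list-valued outputs (miRNA tallies) serialize deterministically
  (`name:count;...`), and every table writer is plain `write.table`, so
  fixed-seed runs are byte-identical.

## Study dimensioning

The default `runPipeline()` configuration simulates the full study shape:
3 fractions x 2 replicates, 50,000 IP and 50,000 input reads per library,
2% chimeric reads, 10% PCR duplication, and chimeric plus nonchimeric
sites planted in the 3' UTRs of ten genes. The toy genome behind it (six
chromosomes of 400 kb, 840 genes, ~1.1 Mb exonic) is sized so that the
transcriptome-background read density per nucleotide is low: planted
chimeric clusters (~90 deduplicated reads over ~100 nt) then exceed the
8-fold enrichment implied by `log2FC > 3` with comfortable margin, and
single-linkage clusters do not percolate along exons. Shrinking the
genome while keeping read depth raises the per-nucleotide background rate
and first erodes the chimeric universe — a useful illustration of why
enrichment-based peak calling needs the input's density, not just its
total, under control. Module tests use much smaller configurations
(one to ten genes, 1,500–2,000 reads) chosen to exercise logic rather
than statistics; the vignette-level sizes above are what the acceptance
script runs.

## Known limitations

The aligner is ungapped and unspliced, so real libraries would need a
spliced aligner in its place; the cluster caller has no shape model, so
adjacent sites closer than a fragment length merge; chimera detection
assumes the miRNA-first geometry (a flag exists for the opposite
chemistry but target-first chimeras within the same read are out of
scope); isomiR cataloguing, conservation scoring and differential
expression estimation are outside the package — expression enters as a
table. The simulator's truth table covers read provenance and duplicate
lineage but not crosslink positions, so single-nucleotide binding-site
resolution is not modelled.
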