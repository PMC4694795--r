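---
title: "Deducing tRNA-derived fragments by exact exclusive mapping"
author: "trfspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deducing tRNA-derived fragments by exact exclusive mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfspace)
```

## The problem

Transfer RNAs are repeat elements. Each amino acid is served by several
anticodons (isoacceptors) and each anticodon by several genomic copies
(isodecoders), many of which are sequence-identical or nearly so. A short
RNA-seq read that originates from a tRNA therefore rarely identifies a
single locus, and — worse — segments of genuine tRNAs recur outside tRNA
genes, in partial tRNA copies and in nuclear lookalikes of mitochondrial
tRNAs. Conventional small-RNA mapping (unique mapping, or mapping with a
mismatch allowance, or mapping against a tRNA database alone) misassigns
such reads.

`trfspace` implements a deduction strategy built on three commitments:

1. **Exact matching only.** A single tolerated substitution can merge
   fragments from entirely different locus sets (two 32-mers differing at
   one base can come from five versus two disjoint loci), so no
   mismatches or indels are ever allowed.
2. **Whole-genome occurrence analysis.** A fragment sequence is accepted
   only if *every* exact occurrence in the genome, on either strand,
   falls inside *tRNA space* — the set of annotated nuclear tRNA
   intervals, mitochondrial tRNA intervals, and exact nuclear lookalikes
   of mitochondrial tRNAs, each extended by the three CCA-substituted
   positions downstream of the mature end. A sequence that also occurs
   outside this space (e.g. in a truncated repeat-annotated tRNA relic)
   has ambiguous provenance and is discarded wholesale.
3. **Transcript-aware reference.** Mature tRNAs differ from their genomic
   loci: introns are spliced out and a non-templated `CCA` is appended.
   The package therefore (a) splices annotated introns when assembling
   mature sequences, so fragments straddling an exon–exon junction are
   representable even though they occur nowhere in the genome, and (b)
   mapping-wise replaces the three genomic bases immediately downstream
   of each locus with `CCA` (strand-aware), so CCA-ending fragments have
   an exact genomic image.

Fragments are classified by their endpoints on the mature tRNA of
templated length $L$ (CCA at $L+1..L+3$):

* **3'-tRF** — the 3' end falls within the CCA ($fe \in \{L+1, L+2, L+3\}$),
* **5'-tRF** — otherwise, the 5' end is the first nucleotide ($fs = 1$),
* **i-tRF** — otherwise: wholly internal fragments, $fs \ge 2$ and
  $fe \le L$.

The 3' rule is checked first; in the contrived case of a window that both
starts at +1 and ends in the CCA (only possible when the configured
maximum window length exceeds $L$), the CCA-ending class wins.

## From reference to profile

The pipeline is a pure dictionary construction followed by lookups:

```{r pipeline, eval = FALSE}
space   <- load_annotation("trna.tsv", "lookalikes.tsv")
genome  <- read_genome("genome.fa")
matures <- splice_all(space, genome)
cca     <- build_cca_genome(genome, space)
lookup  <- build_lookup(space, matures, cca, min_len = 16, max_len = 50)
profile <- profile_reads(read_reads("sample.fastq"), lookup)
```

`build_lookup()` enumerates every window of every mature sequence with
length 16–50 nt, merges identical sequences across loci, and decides
exclusivity once by scanning the CCA-substituted genome (per-width
Aho–Corasick dictionaries over both strands). Profiling a read set then
reduces to an exact dictionary lookup: this is equivalent to exact
whole-genome multi-mapping followed by the inside/outside filter, because
that filter was already applied to every possible read sequence when the
table was built. It also enforces single counting: a read found at a
dozen identical loci contributes its count once, to the merged record.

Each record carries an augmented label,

```
trna116_GluCTC_1_-_145399233_145399304@23.45.23__1_0_8
```

encoding the *source-proxy* locus and its genomic interval, the mature
coordinates and length of the fragment (with a `.CCA` infix for
CCA-ending fragments), and three provenance counts: distinct anticodons,
pseudo-tRNA loci, and total tRNA-space loci that can source the
sequence. When several loci can produce a fragment, the proxy is chosen
deterministically: placements are ordered by natural chromosome order
(autosomes numerically, then X, Y, then the mitochondrial chromosome),
locus start, strand, locus id and fragment start, and the first is
taken. This makes lookup tables byte-reproducible.

### Numerical and policy choices

* **Coordinates** are 1-based inclusive throughout (genomic and mature);
  mature position +1 is the first templated nucleotide.
* **Reverse-complement occurrences count against exclusivity.** A
  fragment whose sequence occurs on the opposite strand outside tRNA
  space is discarded; transcription of the other strand cannot be ruled
  out, so this is the conservative choice.
* **Occurrence cap.** Sequences with more than 10,000 genomic
  occurrences are dropped as saturated and logged, mirroring the
  multi-mapping cap a read aligner would impose. We apply the cap both
  at scan time and to the lookup itself.
* **CCA-substituted positions belong to tRNA space.** The three
  downstream positions are included in the space intervals, so a
  CCA-ending read covering them remains attributable to its tRNA.
* **Junction shortcut.** A window spanning an exon–exon junction that
  occurs nowhere in the genome is exclusive by construction; one that
  *does* occur somewhere by chance is subjected to the ordinary test.
* **Overlapping CCA windows** (two loci closer than 3 bp downstream) are
  substituted in locus-sorted order, later writes win, and a warning is
  emitted; this situation does not arise in well-formed annotations.
* **Soft-masking** is ignored: genomes are read uppercase.
* **Region ambiguity.** The region is a property of the merged record
  via its proxy placement. If placements in loci of different lengths
  disagree on the region, the record is flagged `region_ambiguous` and
  the proxy's region is reported.

## Cohort matrices and normalization

`build_expression_matrix()` assembles fragment × dataset raw counts.
Three operations mirror standard practice for heterogeneous small-RNA
cohorts:

* `filter_matrix()` keeps fragments with ≥ `min_reads` raw reads in
  ≥ `min_datasets` datasets. Presets `lcl` (30/30), `brca` (30/20) and
  `clip` (30/3) capture the support thresholds appropriate for large,
  medium and small cohorts. Filtering precedes normalization and acts on
  raw counts.
* `depth_normalize()` converts to reads-per-million using each dataset's
  sequencing depth. Depth is defined as the total collapsed input reads
  of the dataset (including reads later discarded), configurable by
  passing any other depth vector.
* `lab_rescale()` removes laboratory effects when a cohort was sequenced
  by several centers: using the samples sequenced in *every* laboratory,
  it computes per-fragment factors `mean(ref lab) / mean(lab)` on
  depth-normalized values and rescales each laboratory's datasets
  row-wise. The reference defaults to the laboratory with the most
  datasets. Factors are computed on depth-normalized values because raw
  ratios would conflate depth with laboratory effects; undefined factors
  (zero means) fall back to 1 with a warning rather than dropping the
  fragment.
* `rank_normalize()` replaces each column by ascending ranks with
  average ranks for ties (column sums are exactly $n(n+1)/2$). Ranks
  ascend; downstream correlation or ordination is invariant to that
  choice up to sign.

## Summaries

`length_distribution()` sums abundance by fragment length within a
region and converts to fractions, reporting group means ± standard error
($sd/\sqrt{n}$ across datasets). By default the denominator is the
dataset's total over *all* regions, so the per-region panels of a figure
share one scale and their panel sums add to 1; `denominator = "region"`
normalizes within the region instead. For 30-cycle sequencing data,
where every longer molecule is represented by a 30-mer proxy,
`pool_min = 30` reports all lengths ≥ 30 as a single `">=30"` bin; this
is presentation only — storage always keeps true lengths.

`decompose_by_origin()` splits per-length abundance into nuclear and
mitochondrial panels that sum exactly to the combined totals. Fragments
whose proxy is an exact nuclear lookalike of a mitochondrial tRNA are
attributed to the mitochondrial panel: a lookalike is an identical copy
and carries the mitochondrial tRNA's identity, and proxy selection can
land on either copy of an identical pair depending on chromosome order
alone.

`anticodon_correlation()` returns the Pearson matrix of one anticodon's
fragments across datasets (rows ordered by region, start, length;
zero-variance fragments are reported as `NA`). `compare_groups()` is a
two-sided Mann–Whitney U test with tie correction — exact p-values for
small untied samples, normal approximation otherwise — chosen because no
distributional form can be assumed for relative length abundances.
Raw p-values are reported; Benjamini–Hochberg can be applied by the
caller (`p.adjust`) when many per-length comparisons are made.

## The synthetic-data module

Because real cohort-scale data cannot ship with a package, `trfspace`
treats its simulator as first-class, tested code. `simulate_genome()`
plants, in random background sequence, every structural feature the
deduction must handle:

* identical multi-copy isodecoders (default: one anticodon with three
  copies) — windows must stay exclusive with `n_loci` > 1 and be counted
  once;
* minus-strand loci — reverse-complement handling;
* an intron-bearing locus (intron inserted after mature position 37,
  the canonical location of human tRNA introns) — junction-spanning
  windows exist in no genome;
* mitochondrial tRNAs on a separate `MT` record, and an exact nuclear
  lookalike of one of them — the nuclear copy joins tRNA space;
* decoys *outside* tRNA space: a partial 24-nt 5' copy of a tRNA (the
  truncated-relic scenario) and a one-substitution near-copy (the
  non-identical-lookalike scenario). Windows they contain must be
  rejected.

Templated lengths are drawn from 59–95 nt (the biological range of human
tRNA genes; mitochondrial ones from 59–75 nt), background composition is
uniform by default with configurable GC. `simulate_reads()` draws
fragment identities per dataset from a multinomial over the exclusive
fragments matching a region/length law; the default law is
lymphoblastoid-like (internal fragments dominated by 36-mers, 5'-tRFs by
19-mers, CCA-ending fragments at 18/22/33 nt). No sequencing errors are
simulated, so the profiler must reproduce the planted counts *exactly*;
separately requested noise reads (random, decoy-derived, one-substitution
variants) must all be discarded. The ground truth — planted loci, decoys,
per-dataset fragment counts, seed — fully determines the expected output
of every downstream step.

What the simulator does **not** emulate: base-modification-induced
misincorporation (a known cause of apparent mismatches in real tRNA
reads — deliberately out of scope, as mismatch-tolerant rescue is
precisely what the method refuses to do), adapter artifacts, quality
dependent error profiles, and the 5'/3'-phosphate ligation biases that
make real tRF counts an underestimate. Passing tests therefore
demonstrate the correctness of the deduction logic, not the biological
completeness of any real profile.

## Problem sizes and test design

The test suite verifies the exclusivity engine against an independent
brute-force oracle (plain-string scanning of every window on both
strands, arithmetic interval checks) on 20 random genomes of ~5–10 kb
with 6–11 planted loci each, and exact count recovery on 10 simulated
cohorts; these sizes exercise every code path while keeping a full run
in minutes. The statistical layer is calibrated by simulation: under the
null, the Mann–Whitney test at $\alpha = 0.05$ rejects at a rate inside
the binomial 99% interval over 1,000 replicates.

## Known limitations

* Reference quality bounds deduction quality: loci missing from the
  annotation shrink tRNA space and can wrongly disqualify genuine
  fragments that happen to match the missing copy.
* The package deliberately does not quantify fragments of precursor
  origin (5' leaders, 3' trailers) — only sequences within the span of a
  mature tRNA (plus CCA) are enumerated.
* Sequences shared verbatim between a mature tRNA and any non-tRNA locus
  are unquantifiable by design; their counts are reported in the discard
  tallies, not imputed.
* Multivariate analyses (PCA, PLS-DA, SAM) are consumers of the exported
  matrices, not part of the package.
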