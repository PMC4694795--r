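# trfspace

Deduction and profiling of tRNA-derived fragments (tRFs) from short
RNA-seq data by **exact, exclusive, whole-genome mapping**.

## The problem

tRNAs are repeat elements: each anticodon has many genomic copies
(isodecoders), often sequence-identical, and segments of genuine tRNAs
recur outside tRNA genes — in partial tRNA relics and in nuclear
lookalikes of mitochondrial tRNAs. Standard small-RNA pipelines
(mismatch-tolerant mapping, unique mapping, or mapping against a tRNA
database alone) misassign reads from these loci. On top of that, mature
tRNAs differ from their genomic loci: introns are spliced out and a
non-templated `CCA` is appended to the 3' end.

`trfspace` is for transcriptomics researchers who want per-fragment tRF
abundance tables they can defend. It:

* builds a reference **tRNA space** — nuclear tRNAs, mitochondrial
  tRNAs and exact nuclear lookalikes of mitochondrial tRNAs — assembles
  spliced mature sequences with their CCA, and creates a CCA-substituted
  genome so CCA-ending reads have an exact genomic image;
* enumerates every candidate fragment (16–50 nt) of every mature tRNA
  and keeps only sequences **exclusive** to tRNA space: every exact
  genomic occurrence, on either strand, must fall inside it (up to a
  10,000-occurrence multi-mapping cap). Fragments spanning an exon–exon
  junction, which occur in no genome, are handled explicitly;
* classifies fragments into **5'-tRFs** (start at mature +1), **i-tRFs**
  (wholly internal — start ≥ +2, end before the CCA) and **3'-tRFs**
  (end within the CCA), and labels each with its source-proxy locus,
  mature coordinates and provenance counts, e.g.
  `trna116_GluCTC_1_-_145399233_145399304@23.45.23__1_0_8`
  (23-mer at mature positions 23–45; 1 anticodon, 0 pseudo-tRNAs,
  8 source loci);
* profiles read sets by exact dictionary lookup with **single counting**
  of multi-locus sequences, and assembles cohort matrices with support
  filtering (30 reads in ≥ 30/20/3 datasets presets), depth (RPM),
  laboratory and rank normalization;
* summarizes cohorts: per-region length distributions with standard
  errors, nuclear vs. mitochondrial decompositions, per-anticodon
  Pearson correlation matrices, and two-sided Mann–Whitney U group
  comparisons;
* ships a first-class synthetic-data module that plants tRNA loci
  (identical multi-copies, introns, minus-strand, mito + lookalike) and
  decoys with a full ground-truth manifest.

## Worked example

A complete run on a synthetic universe (14 planted loci including one
intron-bearing tRNA, a pseudo-tRNA, 4 mitochondrial tRNAs, one exact
nuclear lookalike, and 3 decoys outside tRNA space):

```r
library(trfspace)

sim <- simulate_genome(sim_config(), seed = 42)
ref <- sim_reference(sim)   # space + matures + CCA genome + lookup
#> tRNA space: 15 loci (10 nuclear [1 pseudo], 4 mitochondrial, 1 lookalike)
nrow(ref$lookup)
#> [1] 17384                 # distinct exclusive fragment sequences

rd <- simulate_reads(sim, n_datasets = 4, total_reads = 20000, seed = 7)
profiles <- lapply(rd$read_sets, profile_reads, ref$lookup)
profiles[[1]]
#> trf_profile 'A_ds01': 1585 fragments, 20000 counted / 20000 reads
#>   (5p 6999, i 8015, 3p 4986)

m    <- depth_normalize(build_expression_matrix(profiles))
info <- fragment_info(ref$lookup, rownames(m))
ld   <- length_distribution(m, info, region = "i", denominator = "region")
head(ld$summary[order(-ld$summary$mean), c("length", "mean", "se")], 3)
#>    length      mean          se
#> 21     36 0.5505454 0.004185849
#> 16     31 0.2469422 0.003404159
#> 5      20 0.2025124 0.002130418
```

The profile line says every one of the 20,000 planted reads was
assigned (nothing discarded: no decoy or mutated reads were requested),
split over the three mature-tRNA regions; the length table shows the
internal-fragment repertoire dominated by 36-mers at 55% of the
region's abundance with a standard error of 0.4 percentage points
across the 4 datasets — exactly the law the simulator planted
(36-mers at weight 0.55). Group comparisons use
`compare_groups(a, b)`, a two-sided Mann–Whitney U test.

A command-line wrapper over the same functions lives at
`inst/cli/trfspace.R`:

```sh
Rscript inst/cli/trfspace.R simulate --seed 1 --out sim/
Rscript inst/cli/trfspace.R build-reference --genome sim/genome.fa \
    --trna sim/trna.tsv --lookalikes sim/lookalikes.tsv --out ref/
Rscript inst/cli/trfspace.R build-lookup --ref ref/ --out lookup.tsv
Rscript inst/cli/trfspace.R profile --lookup lookup.tsv \
    --reads sim/A_ds01.tsv --out prof.tsv
```

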