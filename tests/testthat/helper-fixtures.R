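# Handcrafted deterministic fixtures for the reference and fragment
# modules. All sequences are generated with a local RNG seed and the
# planted truth is returned alongside the genome.

fixture_random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A three-locus fixture:
#   trnaA  chr "1", + strand, intronless, L = 72
#   trnaB  chr "1", - strand, intronless, L = 70
#   trnaC  chr "2", + strand, one 20 nt intron after mature position 37,
#          L = 71 (genomic span 91)
tiny_reference_fixture <- function(seed = 101) {
  withr::local_seed(seed)
  matureA <- fixture_random_seq(72)
  matureB <- fixture_random_seq(70)
  matureC <- fixture_random_seq(71)
  intronC <- fixture_random_seq(20)
  geneC <- paste0(substr(matureC, 1, 37), intronC, substr(matureC, 38, 71))

  chr1 <- fixture_random_seq(400)
  substr(chr1, 101, 172) <- matureA
  substr(chr1, 230, 299) <- oracle_revcomp(matureB)
  chr2 <- fixture_random_seq(300)
  substr(chr2, 51, 141) <- geneC

  annotation <- data.frame(
    id = c("trnaA", "trnaB", "trnaC"),
    anticodon_name = c("GlyGCC", "GluCTC", "TyrGTA"),
    chrom = c("1", "1", "2"),
    strand = c("+", "-", "+"),
    start = c(101L, 230L, 51L),
    end = c(172L, 299L, 141L),
    introns = c("", "", "88-107"),
    origin = "nuclear",
    is_pseudo = FALSE,
    stringsAsFactors = FALSE)

  list(genome = Biostrings::DNAStringSet(c("1" = chr1, "2" = chr2)),
       chroms = c("1" = chr1, "2" = chr2),
       annotation = annotation,
       matures = c(trnaA = matureA, trnaB = matureB, trnaC = matureC),
       intron = intronC, geneC = geneC)
}

# a small simulated universe shared by several tests
small_sim_config <- function(...) {
  sim_config(chrom_lengths = c("1" = 6000, "2" = 4000), mt_length = 1200,
             n_nuclear = 6, isodecoder_copies = 2, n_intron = 1,
             n_minus = 2, n_pseudo = 1, n_mito = 2, n_lookalike = 1,
             ...)
}

expect_same_counts <- function(profile, truth_ds) {
  expect_setequal(profile$counts$label, truth_ds$label)
  m <- match(profile$counts$label, truth_ds$label)
  expect_equal(profile$counts$count, truth_ds$count[m])
}
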