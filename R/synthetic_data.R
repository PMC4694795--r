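# Self-contained synthetic test universes: genomes with planted tRNA loci
# (identical multi-copy isodecoders, introns, minus-strand cases, mito
# tRNAs and their exact nuclear lookalikes), decoy partial / near-identical
# copies outside tRNA space, and read sets drawn from configured
# region/length profiles — all with a ground-truth manifest.

# anticodon names drawn from the real human anticodon alphabet so that
# provenance counts are meaningful
nuclear_anticodons <- c(
  "AlaAGC", "AlaCGC", "AlaTGC", "ArgACG", "ArgCCG", "ArgCCT", "ArgTCG",
  "ArgTCT", "AsnGTT", "AspGTC", "CysGCA", "GlnCTG", "GlnTTG", "GluCTC",
  "GluTTC", "GlyCCC", "GlyGCC", "GlyTCC", "HisGTG", "IleAAT", "IleGAT",
  "IleTAT", "LeuAAG", "LeuCAA", "LeuCAG", "LeuTAA", "LeuTAG", "LysCTT",
  "LysTTT", "MetCAT", "PheGAA", "ProAGG", "ProCGG", "ProTGG", "SerAGA",
  "SerCGA", "SerGCT", "SerTGA", "ThrAGT", "ThrCGT", "ThrTGT", "TrpCCA",
  "TyrGTA", "ValAAC", "ValCAC", "ValTAC")
mito_anticodons <- c(
  "AlaTGC", "ArgTCG", "AsnGTT", "AspGTC", "CysGCA", "GlnTTG", "GluTTC",
  "GlyTCC", "HisGTG", "IleGAT", "LeuTAA", "LeuTAG", "LysTTT", "MetCAT",
  "PheGAA", "ProTGG", "SerGCT", "SerTGA", "ThrTGT", "TrpTCA", "TyrGTA",
  "ValTAC")

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

#' Configuration for the synthetic genome generator
#'
#' Defaults emulate the structural features of human tRNA genomics at
#' desk scale: multiple nuclear chromosomes, a separate mitochondrial
#' record `MT`, identical multi-copy isodecoders, an intron-bearing
#' locus (intron inserted after mature position 37, the canonical
#' position), minus-strand loci, a pseudo-tRNA, exact nuclear lookalikes
#' of mitochondrial tRNAs, and decoys (a partial 5' copy and a
#' one-substitution near-copy of a tRNA placed outside tRNA space).
#' Templated tRNA lengths are drawn from 59-95 nt.
#'
#' @param chrom_lengths named lengths of the nuclear background
#'   chromosomes.
#' @param mt_length length of the mitochondrial record.
#' @param n_nuclear total nuclear tRNA loci.
#' @param isodecoder_copies the first nuclear anticodon is planted as
#'   this many identical copies (counted within `n_nuclear`).
#' @param n_intron number of intron-bearing nuclear loci.
#' @param intron_length intron length (nt).
#' @param n_minus number of nuclear loci planted on the minus strand.
#' @param n_pseudo number of pseudo-tRNA loci.
#' @param n_mito mitochondrial tRNA loci.
#' @param n_lookalike exact nuclear copies of mitochondrial tRNAs.
#' @param trna_length_range,mito_length_range templated length ranges.
#' @param n_decoy_partial partial 5' copies planted outside tRNA space.
#' @param decoy_length length of the partial copies (nt).
#' @param n_decoy_mismatch one-substitution near-copies planted outside
#'   tRNA space.
#' @param gc background GC content.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c("1" = 12000, "2" = 9000),
                       mt_length = 1600,
                       n_nuclear = 10, isodecoder_copies = 3,
                       n_intron = 1, intron_length = 20,
                       n_minus = 3, n_pseudo = 1,
                       n_mito = 4, n_lookalike = 1,
                       trna_length_range = c(59, 95),
                       mito_length_range = c(59, 75),
                       n_decoy_partial = 2, decoy_length = 24,
                       n_decoy_mismatch = 1, gc = 0.5) {
  stopifnot(n_nuclear >= isodecoder_copies,
            trna_length_range[1] >= 16,
            decoy_length >= 16)
  structure(as.list(environment()), class = "sim_config")
}

# place an interval of width `w` on one of `chroms`, avoiding `occupied`
# (list of per-chrom two-column matrices), with a safety pad.
place_interval <- function(w, chrom_lengths, occupied, pad = 6,
                           max_try = 500) {
  chroms <- names(chrom_lengths)
  for (i in seq_len(max_try)) {
    ch <- sample(chroms, 1, prob = chrom_lengths / sum(chrom_lengths))
    maxs <- chrom_lengths[[ch]] - w - pad
    if (maxs < pad + 1) next
    s <- sample(seq(pad + 1, maxs), 1)
    e <- s + w - 1L
    occ <- occupied[[ch]]
    if (!is.null(occ) && nrow(occ) > 0 &&
        any(s <= occ[, 2] + pad & e >= occ[, 1] - pad))
      next
    return(list(chrom = ch, start = as.integer(s), end = as.integer(e)))
  }
  stop("could not place a ", w, " nt element without overlap after ",
       max_try, " retries; enlarge the background")
}

#' Generate a synthetic genome with planted tRNA loci and decoys
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return object of class `trf_simulation`: list with `genome`
#'   ([Biostrings::DNAStringSet] including the `MT` record),
#'   `annotation` (locus table as in [read_trna_annotation()]),
#'   `lookalikes` (table as in [read_lookalikes()]), `decoys`
#'   (data.frame `id`, `type` in `{partial, mismatch}`, `source_id`,
#'   `chrom`, `start`, `end`, `seq`), `config` and `seed`. The planted
#'   loci, decoys and seed constitute the ground-truth manifest.
#' @export
simulate_genome <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  cfg <- config
  chroms <- lapply(cfg$chrom_lengths, random_seq, gc = cfg$gc)
  chroms$MT <- random_seq(cfg$mt_length, gc = cfg$gc)
  chrom_lengths <- vapply(chroms, nchar, 1L)
  occupied <- setNames(vector("list", length(chroms)), names(chroms))

  ann <- list()
  add_locus <- function(id, anticodon, ch, strand, start, glen,
                        introns, origin, pseudo) {
    ann[[length(ann) + 1L]] <<- data.frame(
      id = id, anticodon_name = anticodon, chrom = ch, strand = strand,
      start = start, end = start + glen - 1L,
      introns = introns, origin = origin, is_pseudo = pseudo,
      stringsAsFactors = FALSE)
  }

  # --- nuclear loci ---------------------------------------------------
  n_distinct <- cfg$n_nuclear - cfg$isodecoder_copies + 1L
  antis <- sample(nuclear_anticodons, n_distinct)
  gene_of <- character(0)   # distinct gene sequences (pre-tRNA, sense)
  mature_of <- character(0) # templated mature (no CCA)
  intron_len_of <- integer(0)
  copies <- c(cfg$isodecoder_copies, rep(1L, n_distinct - 1L))
  intron_genes <- if (cfg$n_intron > 0)
    seq(n_distinct, length.out = min(cfg$n_intron, n_distinct - 1),
        by = -1L) else integer(0)
  for (g in seq_len(n_distinct)) {
    L <- sample(seq(cfg$trna_length_range[1], cfg$trna_length_range[2]), 1)
    mat <- random_seq(L, cfg$gc)
    il <- 0L
    gene <- mat
    if (g %in% intron_genes && L > 45) {
      il <- cfg$intron_length
      gene <- paste0(substr(mat, 1, 37), random_seq(il, cfg$gc),
                     substr(mat, 38, L))
    }
    gene_of[g] <- gene
    mature_of[g] <- mat
    intron_len_of[g] <- il
  }
  locus_no <- 0L
  minus_left <- cfg$n_minus
  pseudo_left <- cfg$n_pseudo
  nuc_names <- names(cfg$chrom_lengths)
  for (g in seq_len(n_distinct)) {
    for (k in seq_len(copies[g])) {
      locus_no <- locus_no + 1L
      gene <- gene_of[g]
      strand <- if (minus_left > 0 && g %% 2 == 0) {
        minus_left <- minus_left - 1L; "-"
      } else "+"
      pos <- place_interval(nchar(gene),
                            chrom_lengths[nuc_names], occupied)
      occupied <- within_plant(occupied, pos, nchar(gene))
      planted <- if (strand == "+") gene else revcomp_chr(gene)
      substr(chroms[[pos$chrom]], pos$start,
             pos$start + nchar(gene) - 1L) <- planted
      il <- intron_len_of[g]
      introns <- if (il > 0) {
        off <- if (strand == "+") 37L else
          nchar(mature_of[g]) - 37L  # length of downstream exon
        sprintf("%d-%d", pos$start + off, pos$start + off + il - 1L)
      } else ""
      pseudo <- FALSE
      if (pseudo_left > 0 && copies[g] == 1 && il == 0) {
        pseudo <- TRUE
        pseudo_left <- pseudo_left - 1L
      }
      add_locus(sprintf("trna%d", locus_no), antis[g], pos$chrom,
                strand, pos$start, nchar(gene), introns, "nuclear",
                pseudo)
    }
  }

  # --- mitochondrial loci ---------------------------------------------
  m_antis <- sample(mito_anticodons, cfg$n_mito)
  mito_gene <- character(0)
  mt_cursor <- 30L
  for (g in seq_len(cfg$n_mito)) {
    L <- sample(seq(cfg$mito_length_range[1], cfg$mito_length_range[2]), 1)
    gene <- random_seq(L, cfg$gc)
    mito_gene[g] <- gene
    start <- mt_cursor
    if (start + L + 10 > cfg$mt_length)
      stop("mitochondrial record too short for the requested loci")
    substr(chroms$MT, start, start + L - 1L) <- gene
    occupied$MT <- rbind(occupied$MT, c(start, start + L - 1L))
    add_locus(sprintf("mt-trna%d", g), m_antis[g], "MT", "+", start, L,
              "", "mitochondrial", FALSE)
    mt_cursor <- start + L + sample(20:60, 1)
  }

  # --- exact nuclear lookalikes of mitochondrial tRNAs ----------------
  lookalikes <- NULL
  if (cfg$n_lookalike > 0) {
    la_src <- sample(seq_len(cfg$n_mito), min(cfg$n_lookalike, cfg$n_mito))
    lookalikes <- do.call(rbind, lapply(seq_along(la_src), function(k) {
      g <- la_src[k]
      gene <- mito_gene[g]
      strand <- sample(c("+", "-"), 1)
      pos <- place_interval(nchar(gene), chrom_lengths[nuc_names],
                            occupied)
      occupied <<- within_plant(occupied, pos, nchar(gene))
      planted <- if (strand == "+") gene else revcomp_chr(gene)
      substr(chroms[[pos$chrom]], pos$start,
             pos$start + nchar(gene) - 1L) <<- planted
      data.frame(chrom = pos$chrom, start = pos$start,
                 end = pos$start + nchar(gene) - 1L, strand = strand,
                 id = sprintf("la%d", k), mito_anticodon = m_antis[g],
                 stringsAsFactors = FALSE)
    }))
  }

  # --- decoys outside tRNA space --------------------------------------
  decoys <- list()
  # partial copies of the 5' end of a mature nuclear tRNA
  intronless <- which(intron_len_of == 0)
  if (cfg$n_decoy_partial > 0 && length(intronless) > 0) {
    for (k in seq_len(cfg$n_decoy_partial)) {
      g <- intronless[1 + (k - 1) %% length(intronless)]
      dseq <- substr(mature_of[g], 1, cfg$decoy_length)
      pos <- place_interval(nchar(dseq), chrom_lengths[nuc_names],
                            occupied)
      occupied <- within_plant(occupied, pos, nchar(dseq))
      substr(chroms[[pos$chrom]], pos$start,
             pos$start + nchar(dseq) - 1L) <- dseq
      decoys[[length(decoys) + 1L]] <- data.frame(
        id = sprintf("decoy_partial%d", k), type = "partial",
        source_id = sprintf("gene%d", g), chrom = pos$chrom,
        start = pos$start, end = pos$start + nchar(dseq) - 1L,
        seq = dseq, stringsAsFactors = FALSE)
    }
  }
  # one-substitution near-copies of a whole tRNA
  if (cfg$n_decoy_mismatch > 0 && length(intronless) > 0) {
    for (k in seq_len(cfg$n_decoy_mismatch)) {
      g <- intronless[1 + (k - 1) %% length(intronless)]
      dseq <- mature_of[g]
      p <- sample(seq(2, nchar(dseq) - 1), 1)
      old <- substr(dseq, p, p)
      substr(dseq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      pos <- place_interval(nchar(dseq), chrom_lengths[nuc_names],
                            occupied)
      occupied <- within_plant(occupied, pos, nchar(dseq))
      substr(chroms[[pos$chrom]], pos$start,
             pos$start + nchar(dseq) - 1L) <- dseq
      decoys[[length(decoys) + 1L]] <- data.frame(
        id = sprintf("decoy_mismatch%d", k), type = "mismatch",
        source_id = sprintf("gene%d", g), chrom = pos$chrom,
        start = pos$start, end = pos$start + nchar(dseq) - 1L,
        seq = dseq, stringsAsFactors = FALSE)
    }
  }

  structure(list(
    genome = Biostrings::DNAStringSet(unlist(chroms)),
    annotation = do.call(rbind, ann),
    lookalikes = lookalikes,
    decoys = if (length(decoys) > 0) do.call(rbind, decoys) else NULL,
    config = cfg, seed = seed),
    class = "trf_simulation")
}

# record a placement in the occupied list (helper used inside closures)
within_plant <- function(occupied, pos, w) {
  occupied[[pos$chrom]] <- rbind(occupied[[pos$chrom]],
                                 c(pos$start, pos$start + w - 1L))
  occupied
}

#' @export
print.trf_simulation <- function(x, ...) {
  cat(sprintf(
    "trf_simulation (seed %d): %d chromosomes, %d loci, %d lookalikes, %d decoys\n",
    x$seed, length(x$genome), nrow(x$annotation),
    if (is.null(x$lookalikes)) 0L else nrow(x$lookalikes),
    if (is.null(x$decoys)) 0L else nrow(x$decoys)))
  invisible(x)
}

#' Build the full reference from a simulation
#'
#' Convenience wrapper: tRNA space, mature sequences, CCA-substituted
#' genome and exclusive-fragment lookup for a synthetic genome.
#'
#' @param sim a `trf_simulation` from [simulate_genome()].
#' @param min_len,max_len,cap see [build_lookup()].
#' @return list with `space`, `matures`, `cca_genome`, `lookup`.
#' @export
sim_reference <- function(sim, min_len = 16, max_len = 50, cap = 10000) {
  space <- load_annotation(sim$annotation, sim$lookalikes)
  matures <- splice_all(space, sim$genome)
  cca <- build_cca_genome(sim$genome, space)
  lookup <- build_lookup(space, matures, cca, min_len = min_len,
                         max_len = max_len, cap = cap)
  list(space = space, matures = matures, cca_genome = cca,
       lookup = lookup)
}

#' Default region/length abundance law for simulated reads
#'
#' LCL-like profile: internal fragments dominated by 36-mers, 5'-tRFs by
#' 19-mers (with mass at 22, 26 and 33 nt), CCA-ending fragments at 18,
#' 22 and 33 nt. Region shares and within-region length weights each sum
#' to 1.
#'
#' @return named list of regions, each with `share` and a named
#'   `lengths` weight vector.
#' @export
default_profile_spec <- function() {
  list(
    "5p" = list(share = 0.35,
                lengths = c("19" = 0.45, "22" = 0.15, "26" = 0.10,
                            "33" = 0.30)),
    "i" = list(share = 0.40,
               lengths = c("20" = 0.20, "31" = 0.25, "36" = 0.55)),
    "3p" = list(share = 0.25,
                lengths = c("18" = 0.40, "22" = 0.30, "33" = 0.30)))
}

#' Simulate read sets from a synthetic reference with known truth
#'
#' Fragment identities are drawn per dataset by a multinomial over the
#' exclusive fragments matching the requested region/length law; no
#' sequencing errors are simulated, so the profiler must recover the
#' planted counts exactly. Optional noise reads (random sequences,
#' decoy-derived sequences, one-substitution variants of planted
#' fragments) are recorded separately in the truth manifest and must all
#' be discarded by the profiler.
#'
#' @param sim a `trf_simulation`.
#' @param n_datasets number of datasets to draw.
#' @param total_reads planted (signal) reads per dataset.
#' @param profile_spec region/length law (see [default_profile_spec()]).
#' @param noise list with counts `random`, `decoy`, `mismatch` of noise
#'   sequences per dataset (1 read each).
#' @param group group label stored in each dataset's metadata.
#' @param seed integer seed.
#' @param reference optional precomputed [sim_reference()] result.
#' @return list with `read_sets` (list of `read_set`), `truth`
#'   (data.frame `dataset`, `label`, `seq`, `count` of planted
#'   fragments), `noise` (data.frame `dataset`, `type`, `seq`, `count`),
#'   `reference`, and `seed`.
#' @export
simulate_reads <- function(sim, n_datasets = 4, total_reads = 20000,
                           profile_spec = default_profile_spec(),
                           noise = list(random = 0, decoy = 0,
                                        mismatch = 0),
                           group = "A", seed = 1, reference = NULL) {
  noise <- utils::modifyList(list(random = 0, decoy = 0, mismatch = 0),
                             noise)
  shares <- vapply(profile_spec, function(x) x$share, numeric(1))
  if (abs(sum(shares) - 1) > 1e-8)
    stop("profile_spec region shares must sum to 1")
  if (is.null(reference)) reference <- sim_reference(sim)
  lookup <- reference$lookup
  set.seed(seed + 1L)

  cand_idx <- integer(0)
  cand_w <- numeric(0)
  for (rg in names(profile_spec)) {
    sp <- profile_spec[[rg]]
    if (!rg %in% lookup$region)
      stop("region '", rg, "' absent from the synthetic reference")
    lw <- sp$lengths / sum(sp$lengths)
    for (l in names(lw)) {
      rows <- which(lookup$region == rg & lookup$length == as.integer(l))
      if (length(rows) == 0)
        stop("no exclusive fragment of region '", rg, "' and length ",
             l, " in the synthetic reference")
      cand_idx <- c(cand_idx, rows)
      cand_w <- c(cand_w, rep(sp$share * lw[[l]] / length(rows),
                              length(rows)))
    }
  }

  read_sets <- vector("list", n_datasets)
  truth <- list()
  noise_truth <- list()
  for (j in seq_len(n_datasets)) {
    ds <- sprintf("%s_ds%02d", group, j)
    cnt <- as.numeric(rmultinom(1, total_reads, cand_w))
    used <- cnt > 0
    seqs <- lookup$seq[cand_idx[used]]
    counts <- cnt[used]
    truth[[j]] <- data.frame(dataset = rep(ds, sum(used)),
                             label = lookup$label[cand_idx[used]],
                             seq = seqs, count = counts,
                             stringsAsFactors = FALSE)
    nseq <- character(0)
    ntype <- character(0)
    if (noise$random > 0) {
      for (k in seq_len(noise$random)) {
        repeat {
          s <- random_seq(sample(16:50, 1), sim$config$gc)
          if (!s %in% lookup$seq) break
        }
        nseq <- c(nseq, s)
        ntype <- c(ntype, "random")
      }
    }
    if (noise$decoy > 0 && !is.null(sim$decoys)) {
      for (k in seq_len(noise$decoy)) {
        d <- sim$decoys[1 + (k - 1) %% nrow(sim$decoys), ]
        w <- sample(16:min(50, nchar(d$seq)), 1)
        s0 <- sample(seq_len(nchar(d$seq) - w + 1), 1)
        s <- substr(d$seq, s0, s0 + w - 1)
        if (s %in% lookup$seq) next  # defensively skip (cannot happen)
        nseq <- c(nseq, s)
        ntype <- c(ntype, "decoy")
      }
    }
    if (noise$mismatch > 0 && length(seqs) > 0) {
      for (k in seq_len(noise$mismatch)) {
        repeat {
          s <- sample(seqs, 1)
          p <- sample(nchar(s), 1)
          old <- substr(s, p, p)
          substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
          if (!s %in% lookup$seq) break
        }
        nseq <- c(nseq, s)
        ntype <- c(ntype, "mismatch")
      }
    }
    if (length(nseq) > 0)
      noise_truth[[length(noise_truth) + 1L]] <- data.frame(
        dataset = ds, type = ntype, seq = nseq, count = 1,
        stringsAsFactors = FALSE)
    read_sets[[j]] <- read_set(c(seqs, nseq),
                               c(counts, rep(1, length(nseq))),
                               dataset_id = ds,
                               metadata = list(group = group))
  }
  list(read_sets = read_sets,
       truth = do.call(rbind, truth),
       noise = if (length(noise_truth) > 0) do.call(rbind, noise_truth)
               else NULL,
       reference = reference, seed = seed)
}

#' Synthetic annotation tables with the human tRNA-space composition
#'
#' Builds coordinate-only annotation and lookalike tables whose
#' composition mirrors the reference human tRNA space: 22 mitochondrial
#' tRNAs, 610 nuclear entries (508 true tRNAs and 102 pseudo-tRNAs) and
#' 8 exact nuclear lookalikes of mitochondrial tRNAs — 640 loci in all.
#' Useful for registry-level checks that need the composition but not
#' the sequences.
#'
#' @param n_nuclear nuclear entries (including pseudo-tRNAs).
#' @param n_pseudo pseudo-tRNAs among the nuclear entries.
#' @param n_mito mitochondrial tRNAs.
#' @param n_lookalike exact nuclear lookalikes.
#' @return list with `annotation` and `lookalikes` data.frames suitable
#'   for [load_annotation()].
#' @export
registry_composition <- function(n_nuclear = 610, n_pseudo = 102,
                                 n_mito = 22, n_lookalike = 8) {
  stopifnot(n_pseudo <= n_nuclear)
  gene_len <- 72L
  gap <- 500L
  nuc <- data.frame(
    id = sprintf("trna%d", seq_len(n_nuclear)),
    anticodon_name = rep_len(nuclear_anticodons, n_nuclear),
    chrom = as.character(1 + (seq_len(n_nuclear) - 1) %% 22),
    strand = rep_len(c("+", "-"), n_nuclear),
    start = 10000L + ((seq_len(n_nuclear) - 1) %/% 22) * gap,
    origin = "nuclear",
    is_pseudo = seq_len(n_nuclear) > (n_nuclear - n_pseudo),
    stringsAsFactors = FALSE)
  nuc$end <- nuc$start + gene_len - 1L
  mito <- data.frame(
    id = sprintf("mt-trna%d", seq_len(n_mito)),
    anticodon_name = rep_len(mito_anticodons, n_mito),
    chrom = "MT", strand = "+",
    start = 100L + (seq_len(n_mito) - 1L) * 120L,
    origin = "mitochondrial", is_pseudo = FALSE,
    stringsAsFactors = FALSE)
  mito$end <- mito$start + 68L
  cols <- c("id", "anticodon_name", "chrom", "strand", "start", "end",
            "origin", "is_pseudo")
  annotation <- rbind(nuc[, cols], mito[, cols])
  annotation$introns <- ""
  lookalikes <- if (n_lookalike > 0) data.frame(
    chrom = "1",
    start = 900000L + (seq_len(n_lookalike) - 1L) * 200L,
    end = 900000L + (seq_len(n_lookalike) - 1L) * 200L + 68L,
    strand = rep_len(c("+", "-"), n_lookalike),
    id = sprintf("la%d", seq_len(n_lookalike)),
    mito_anticodon = rep_len(mito_anticodons, n_lookalike),
    stringsAsFactors = FALSE) else NULL
  list(annotation = annotation, lookalikes = lookalikes)
}

#' Write a simulation to disk (FASTA + TSV tables)
#'
#' @param sim a `trf_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  ann <- sim$annotation
  if (is.list(ann$introns)) ann$introns <- format_intron_field(ann$introns)
  write.table(ann, file.path(dir, "trna.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(sim$lookalikes))
    write.table(sim$lookalikes, file.path(dir, "lookalikes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$decoys))
    write.table(sim$decoys, file.path(dir, "decoys.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = sim$seed,
                            config = sim$config[names(sim$config) !=
                                                  "chrom_lengths"],
                            chrom_lengths = as.list(sim$config$chrom_lengths)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
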