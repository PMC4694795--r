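#' @importFrom methods is
#' @importFrom stats cor sd setNames rmultinom runif wilcox.test pnorm
#' @importFrom utils read.delim write.table head modifyList
NULL

# Natural chromosome order used for proxy tie-breaks: autosomes numerically,
# then X, Y, then the mitochondrial chromosome, then anything else.
chrom_order_key <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom))
  n <- suppressWarnings(as.integer(chrom))
  key <- ifelse(!is.na(n), n,
         ifelse(chrom == "X", 100L,
         ifelse(chrom == "Y", 101L,
         ifelse(chrom %in% c("M", "MT"), 200L, 300L))))
  # unknown contigs tie-broken alphabetically via a secondary key
  key + match(chrom, sort(unique(chrom))) / 1e6
}

validate_loci <- function(loci) {
  req <- c("id", "anticodon_name", "chrom", "strand", "start", "end",
           "origin", "is_pseudo")
  missing_cols <- setdiff(req, names(loci))
  if (length(missing_cols) > 0)
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  for (i in seq_len(nrow(loci))) {
    row <- loci[i, ]
    where <- sprintf("annotation row %d (%s)", i, row$id)
    if (is.na(row$start) || is.na(row$end) || row$start < 1 || row$end < 1)
      stop(where, ": coordinates must be positive integers")
    if (row$start > row$end)
      stop(where, ": start > end")
    if (!row$strand %in% c("+", "-"))
      stop(where, ": strand must be '+' or '-'")
    introns <- loci$introns[[i]]
    if (!is.null(introns) && nrow(introns) > 0) {
      if (any(introns[, 1] > introns[, 2]))
        stop(where, ": intron start > end")
      if (any(introns[, 1] <= row$start | introns[, 2] >= row$end))
        stop(where, ": intron not strictly inside the locus interval")
    }
  }
  invisible(loci)
}

parse_intron_field <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || s == "" || s == ".")
      return(matrix(integer(0), ncol = 2,
                    dimnames = list(NULL, c("start", "end"))))
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 2L
    if (any(bad)) stop("malformed intron field: ", s)
    m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("start", "end")))
    m
  })
}

format_intron_field <- function(introns) {
  vapply(introns, function(m) {
    if (is.null(m) || nrow(m) == 0) return("")
    paste(sprintf("%d-%d", m[, 1], m[, 2]), collapse = ",")
  }, character(1))
}

#' Read a gtRNAdb-style tRNA annotation table
#'
#' The table is a TSV with header columns `id`, `anticodon_name`, `chrom`,
#' `strand`, `start`, `end`, `introns`, `origin`, `is_pseudo`. Coordinates
#' are 1-based inclusive; `introns` is a comma-separated list of
#' `start-end` genomic intervals (empty, `"."` or blank for none);
#' `origin` is `nuclear` or `mitochondrial`.
#'
#' @param path path to the TSV file.
#' @return a data.frame of loci with a list-column `introns`.
#' @export
read_trna_annotation <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!"introns" %in% names(tab)) tab$introns <- ""
  tab$introns <- parse_intron_field(tab$introns)
  tab$origin <- normalize_origin(tab$origin)
  tab$is_pseudo <- as.logical(tab$is_pseudo)
  tab
}

normalize_origin <- function(x) {
  x <- tolower(as.character(x))
  out <- ifelse(x %in% c("nuclear", "nuc"), "nuclear",
         ifelse(x %in% c("mitochondrial", "mito", "mt"), "mitochondrial",
         ifelse(x %in% c("lookalike", "la"), "lookalike", NA_character_)))
  if (anyNA(out))
    stop("unknown origin value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Read a table of exact nuclear lookalikes of mitochondrial tRNAs
#'
#' BED-like TSV with header columns `chrom`, `start`, `end`, `strand`,
#' `id`, `mito_anticodon`; coordinates 1-based inclusive. Each row is a
#' nuclear genomic interval that is an exactly identical copy of a
#' mitochondrial tRNA; the lookalike inherits that tRNA's anticodon name.
#'
#' @param path path to the TSV file.
#' @return a data.frame of lookalike intervals.
#' @export
read_lookalikes <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Assemble the reference tRNA space
#'
#' Combines nuclear and mitochondrial tRNA loci with exact nuclear
#' lookalikes of mitochondrial tRNAs into a single registry, and derives
#' the strand-agnostic genomic interval set used for the exclusivity test.
#' Each locus interval is extended by the 3 genomic positions immediately
#' downstream of its mature 3' end (the CCA-substituted positions), so a
#' CCA-ending read covering them remains attributable to the tRNA.
#'
#' @param annotation a data.frame from [read_trna_annotation()] or a file
#'   path.
#' @param lookalikes optional data.frame from [read_lookalikes()] or a
#'   file path; lookalike loci become full members of tRNA space with the
#'   mitochondrial anticodon name they duplicate.
#' @return an object of class `trna_space` with elements `loci` (the
#'   locus table) and `intervals` (a [GenomicRanges::GRanges] of the
#'   tRNA-space intervals).
#' @examples
#' ann <- data.frame(
#'   id = "trna1", anticodon_name = "GlyGCC", chrom = "1", strand = "+",
#'   start = 1001, end = 1071, introns = "", origin = "nuclear",
#'   is_pseudo = FALSE)
#' space <- load_annotation(ann)
#' space
#' @export
load_annotation <- function(annotation, lookalikes = NULL) {
  if (is.character(annotation))
    annotation <- read_trna_annotation(annotation)
  if (is.null(annotation$introns))
    annotation$introns <- rep("", nrow(annotation))
  if (!is.list(annotation$introns))
    annotation$introns <- parse_intron_field(annotation$introns)
  annotation$origin <- normalize_origin(annotation$origin)

  if (is.character(lookalikes))
    lookalikes <- read_lookalikes(lookalikes)
  if (!is.null(lookalikes) && nrow(lookalikes) > 0) {
    la <- data.frame(
      id = lookalikes$id,
      anticodon_name = lookalikes$mito_anticodon,
      chrom = as.character(lookalikes$chrom),
      strand = lookalikes$strand,
      start = as.integer(lookalikes$start),
      end = as.integer(lookalikes$end),
      origin = "lookalike",
      is_pseudo = FALSE,
      stringsAsFactors = FALSE)
    la$introns <- replicate(nrow(la),
      matrix(integer(0), ncol = 2,
             dimnames = list(NULL, c("start", "end"))),
      simplify = FALSE)
    annotation <- rbind(
      annotation[, c("id", "anticodon_name", "chrom", "strand", "start",
                     "end", "origin", "is_pseudo", "introns")],
      la[, c("id", "anticodon_name", "chrom", "strand", "start", "end",
             "origin", "is_pseudo", "introns")])
  }
  annotation$chrom <- as.character(annotation$chrom)
  annotation$start <- as.integer(annotation$start)
  annotation$end <- as.integer(annotation$end)
  if (anyDuplicated(annotation$id))
    stop("duplicate locus id(s): ",
         paste(unique(annotation$id[duplicated(annotation$id)]),
               collapse = ", "))
  validate_loci(annotation)
  rownames(annotation) <- annotation$id
  new_trna_space(annotation)
}

new_trna_space <- function(loci) {
  ext_start <- ifelse(loci$strand == "+", loci$start,
                      pmax(1L, loci$start - 3L))
  ext_end <- ifelse(loci$strand == "+", loci$end + 3L, loci$end)
  intervals <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = ext_start, end = ext_end),
    strand = rep("*", nrow(loci)))
  S4Vectors::mcols(intervals)$locus_id <- loci$id
  structure(list(loci = loci, intervals = intervals),
            class = "trna_space")
}

#' @export
print.trna_space <- function(x, ...) {
  comp <- table(factor(x$loci$origin,
                       levels = c("nuclear", "mitochondrial", "lookalike")))
  cat(sprintf(
    "tRNA space: %d loci (%d nuclear [%d pseudo], %d mitochondrial, %d lookalike)\n",
    nrow(x$loci), comp[["nuclear"]], sum(x$loci$is_pseudo),
    comp[["mitochondrial"]], comp[["lookalike"]]))
  invisible(x)
}

#' Read a genome from FASTA
#'
#' @param path path to a (multi-record) FASTA file.
#' @return a [Biostrings::DNAStringSet]; sequences are uppercased so that
#'   soft-masked lowercase bases are treated as ordinary bases.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  Biostrings::DNAStringSet(toupper(g))
}

as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    return(read_genome(genome))
  if (is.character(genome) && !is.null(names(genome)))
    return(Biostrings::DNAStringSet(toupper(genome)))
  stop("genome must be a DNAStringSet, a named character vector, ",
       "or a FASTA path")
}

#' Splice a mature tRNA sequence from the genome
#'
#' Extracts the locus sequence (reverse-complemented for minus-strand
#' loci), removes annotated introns, and appends the non-templated `CCA`
#' trinucleotide. Exon-exon junction positions are recorded in mature
#' coordinates (1-based; position `j` means the junction falls between
#' mature positions `j` and `j + 1`).
#'
#' @param locus a single row of a `trna_space` locus table (data.frame).
#' @param genome a [Biostrings::DNAStringSet] (or named character vector /
#'   FASTA path) holding the chromosome sequences.
#' @return an object of class `mature_trna`: list with the locus fields,
#'   `seq` (character, ends in `"CCA"`), templated length `L`
#'   (`nchar(seq) == L + 3`), and integer vector `junctions`.
#' @export
splice_mature <- function(locus, genome) {
  genome <- as_genome(locus_genome_check(locus, genome))
  chrom_seq <- genome[[locus$chrom]]
  introns <- locus$introns[[1]]
  if (is.null(introns))
    introns <- matrix(integer(0), ncol = 2)
  # exon intervals in genomic order
  bounds <- c(locus$start - 1L, t(introns), locus$end + 1L)
  exon_start <- bounds[seq(1, length(bounds), by = 2)] + 1L
  exon_end <- bounds[seq(2, length(bounds), by = 2)] - 1L
  exon_seqs <- vapply(seq_along(exon_start), function(k)
    as.character(Biostrings::subseq(chrom_seq, exon_start[k], exon_end[k])),
    character(1))
  spliced <- paste(exon_seqs, collapse = "")
  exon_len <- exon_end - exon_start + 1L
  if (locus$strand == "-") {
    spliced <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(spliced)))
    exon_len <- rev(exon_len)
  }
  L <- nchar(spliced)
  junctions <- if (length(exon_len) > 1) cumsum(exon_len)[-length(exon_len)]
               else integer(0)
  structure(list(
    id = locus$id, anticodon_name = locus$anticodon_name,
    chrom = locus$chrom, strand = locus$strand,
    start = locus$start, end = locus$end,
    origin = locus$origin, is_pseudo = locus$is_pseudo,
    seq = paste0(spliced, "CCA"), L = L,
    junctions = as.integer(junctions)),
    class = "mature_trna")
}

locus_genome_check <- function(locus, genome) {
  genome <- as_genome(genome)
  if (!locus$chrom %in% names(genome))
    stop("locus ", locus$id, ": chromosome '", locus$chrom,
         "' not in genome")
  if (locus$end > length(genome[[locus$chrom]]))
    stop("locus ", locus$id, ": interval exceeds chromosome bounds")
  genome
}

#' @export
print.mature_trna <- function(x, ...) {
  cat(sprintf("mature tRNA %s (%s) %s:%d-%d(%s)  L=%d%s\n",
              x$id, x$anticodon_name, x$chrom, x$start, x$end, x$strand,
              x$L,
              if (length(x$junctions) > 0)
                paste0("  junctions at ", paste(x$junctions, collapse = ","))
              else ""))
  invisible(x)
}

#' Splice all mature tRNAs of a tRNA space
#'
#' @param space a `trna_space`.
#' @param genome genome sequences (see [splice_mature()]).
#' @return a named list of `mature_trna` objects, one per locus.
#' @export
splice_all <- function(space, genome) {
  genome <- as_genome(genome)
  out <- lapply(seq_len(nrow(space$loci)), function(i)
    splice_mature(space$loci[i, ], genome))
  names(out) <- space$loci$id
  out
}

#' Build the CCA-substituted genome
#'
#' Returns a copy of the genome in which, for every locus of the tRNA
#' space, the 3 genomic nucleotides immediately downstream of the mature
#' 3' end are replaced so that the transcribed strand reads `CCA`
#' (`CCA` written at `end+1..end+3` for plus-strand loci, `TGG` at
#' `start-3..start-1` on the forward strand for minus-strand loci). All
#' other positions are unchanged. Substitutions are applied in locus
#' order (chromosome, start); overlapping substitution windows trigger a
#' warning and later writes win.
#'
#' @param genome genome sequences (see [splice_mature()]).
#' @param space a `trna_space`.
#' @return a [Biostrings::DNAStringSet].
#' @export
build_cca_genome <- function(genome, space) {
  genome <- as_genome(genome)
  loci <- space$loci
  if (nrow(loci) == 0) return(genome)
  ord <- order(chrom_order_key(loci$chrom), loci$start)
  loci <- loci[ord, ]
  sub_start <- ifelse(loci$strand == "+", loci$end + 1L, loci$start - 3L)
  sub_end <- sub_start + 2L
  bad <- loci$chrom %in% names(genome) &
    (sub_start < 1L |
       sub_end > vapply(loci$chrom,
                        function(ch) length(genome[[ch]]), 1L))
  if (any(!loci$chrom %in% names(genome)))
    stop("chromosome(s) missing from genome: ",
         paste(unique(loci$chrom[!loci$chrom %in% names(genome)]),
               collapse = ", "))
  if (any(bad))
    stop("locus at contig edge with fewer than 3 downstream bases: ",
         paste(loci$id[bad], collapse = ", "))
  # detect overlapping substitution windows (and windows hitting another
  # locus body) before writing
  sub_gr <- GenomicRanges::GRanges(loci$chrom,
                                   IRanges::IRanges(sub_start, sub_end))
  hits <- GenomicRanges::findOverlaps(sub_gr, sub_gr)
  if (any(S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits))) {
    ov <- unique(loci$id[S4Vectors::queryHits(hits)[
      S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)]])
    warning("overlapping CCA-substitution windows (later writes win): ",
            paste(ov, collapse = ", "))
  }
  for (i in seq_len(nrow(loci))) {
    repl <- if (loci$strand[i] == "+") "CCA" else "TGG"
    Biostrings::subseq(genome[[loci$chrom[i]]],
                       sub_start[i], sub_end[i]) <-
      Biostrings::DNAString(repl)
  }
  genome
}
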