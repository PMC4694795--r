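# Read-set handling and conversion of reads to per-fragment counts.

#' Classify a fragment into the three mature-tRNA regions
#'
#' Regions follow the three-way taxonomy of fragment endpoints on the
#' mature tRNA of templated length `L` (CCA at `L+1..L+3`):
#' * `3p` — the 3' terminus coincides with any base of the CCA
#'   (`frag_end` in `L+1..L+3`); CCA-ending fragments, 3'-tRFs.
#' * `5p` — otherwise, the 5' terminus begins exactly at `+1`
#'   (`frag_start == 1`); 5'-tRFs.
#' * `i` — otherwise: wholly internal fragments (i-tRFs), starting at
#'   `+2` or later and ending before the first `C` of the CCA.
#'
#' The `3p` rule is checked first, so a fragment that both starts at `+1`
#' and ends in the CCA (possible only for atypical length windows) is
#' classified `3p`.
#'
#' @param frag_start,frag_end mature coordinates, 1-based inclusive
#'   (vectors recycle).
#' @param L templated length(s) of the mature tRNA.
#' @return character vector over `{"5p", "i", "3p"}`.
#' @examples
#' classify_region(1, 19, 72)   # "5p"
#' classify_region(13, 43, 65)  # "i"
#' classify_region(57, 76, 73)  # "3p"
#' @export
classify_region <- function(frag_start, frag_end, L) {
  n <- max(length(frag_start), length(frag_end), length(L))
  frag_start <- rep_len(as.integer(frag_start), n)
  frag_end <- rep_len(as.integer(frag_end), n)
  L <- rep_len(as.integer(L), n)
  if (any(frag_start < 1 | frag_start > frag_end | frag_end > L + 3L))
    stop("fragment coordinates out of range: need 1 <= frag_start <= ",
         "frag_end <= L + 3")
  ifelse(frag_end > L, "3p", ifelse(frag_start == 1L, "5p", "i"))
}

#' Construct a collapsed read set
#'
#' Reads are collapsed by exact sequence; sequences with characters
#' outside `A/C/G/T` (after uppercasing) are dropped and tallied.
#'
#' @param seqs character vector of read sequences (may repeat), or a
#'   two-column data.frame `(seq, count)` of already-collapsed reads.
#' @param counts optional counts aligned with `seqs`.
#' @param dataset_id dataset identifier.
#' @param metadata named list of dataset attributes (lab, tissue, group
#'   labels, ...).
#' @return object of class `read_set`: list with `dataset_id`, `reads`
#'   (data.frame `seq`, `count`), `total_reads` (sequencing depth: total
#'   collapsed input reads including later discards), `bad_bases` tally,
#'   and `metadata`.
#' @export
read_set <- function(seqs, counts = NULL, dataset_id = "dataset",
                     metadata = list()) {
  if (is.data.frame(seqs)) {
    counts <- seqs[[2]]
    seqs <- seqs[[1]]
  }
  if (is.null(counts)) counts <- rep(1L, length(seqs))
  stopifnot(length(seqs) == length(counts), all(counts >= 1))
  seqs <- toupper(seqs)
  ok <- !grepl("[^ACGT]", seqs)
  bad_bases <- sum(counts[!ok])
  seqs <- seqs[ok]
  counts <- counts[ok]
  agg <- rowsum(as.numeric(counts), seqs)
  reads <- data.frame(seq = rownames(agg), count = as.numeric(agg[, 1]),
                      stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  structure(list(dataset_id = dataset_id, reads = reads,
                 total_reads = sum(reads$count) + bad_bases,
                 bad_bases = bad_bases, metadata = metadata),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set '%s': %d distinct sequences, %.0f reads\n",
              x$dataset_id, nrow(x$reads), x$total_reads))
  invisible(x)
}

#' Read a short-RNA read set from FASTQ or collapsed TSV
#'
#' FASTQ input (optionally gzipped) is collapsed by exact sequence;
#' TSV input is a two-column `seq<TAB>count` table (header optional).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"fastq"` or `"tsv"`.
#' @param dataset_id dataset identifier (defaults to the file name).
#' @param metadata named list of dataset attributes.
#' @return a `read_set`.
#' @export
read_reads <- function(path, format = c("auto", "fastq", "tsv"),
                       dataset_id = NULL, metadata = list()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "tsv"
  if (is.null(dataset_id))
    dataset_id <- sub("\\.(fastq|fq|tsv|txt)(\\.gz)?$", "", basename(path))
  if (format == "fastq") {
    sq <- Biostrings::readDNAStringSet(path, format = "fastq")
    read_set(as.character(sq), dataset_id = dataset_id,
             metadata = metadata)
  } else {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                      comment.char = "#")
    if (tolower(tab[1, 1]) == "seq") tab <- tab[-1, , drop = FALSE]
    read_set(tab[[1]], as.numeric(tab[[2]]), dataset_id = dataset_id,
             metadata = metadata)
  }
}

#' Profile a read set against the exclusive-fragment lookup table
#'
#' Each read sequence found in the lookup contributes its collapsed count
#' to exactly one fragment record — the merged record whose label is
#' determined by the source-proxy locus — so a read present at many
#' tRNA-space loci is counted once, never per locus. Reads with length
#' outside the lookup's window are tallied `out_of_range`; reads absent
#' from the lookup (non-exclusive, decoy-derived, sequencing-error or
#' non-tRNA reads) are tallied `not_in_lookup`.
#'
#' @param reads a `read_set`.
#' @param lookup a `trf_lookup` from [build_lookup()].
#' @return object of class `trf_profile`: list with `dataset_id`,
#'   `counts` (data.frame `label`, `seq`, `region`, `length`, `origin`,
#'   `count`), `region_totals`, `tallies` (counted, not_in_lookup,
#'   out_of_range, bad_bases), `total_reads` and `metadata`.
#' @export
profile_reads <- function(reads, lookup) {
  stopifnot(inherits(reads, "read_set"))
  p <- attr(lookup, "params")
  min_len <- if (is.null(p)) min(lookup$length) else p$min_len
  max_len <- if (is.null(p)) max(lookup$length) else p$max_len
  r <- reads$reads
  len <- nchar(r$seq)
  in_range <- len >= min_len & len <= max_len
  idx <- match(r$seq, lookup$seq)
  hit <- in_range & !is.na(idx)
  counts <- data.frame(
    label = lookup$label[idx[hit]],
    seq = r$seq[hit],
    region = lookup$region[idx[hit]],
    length = lookup$length[idx[hit]],
    origin = lookup$origin[idx[hit]],
    count = r$count[hit],
    stringsAsFactors = FALSE)
  counts <- counts[order(counts$label), , drop = FALSE]
  rownames(counts) <- NULL
  region_totals <- vapply(c("5p", "i", "3p"), function(rg)
    sum(counts$count[counts$region == rg]), numeric(1))
  tallies <- list(
    counted = sum(counts$count),
    not_in_lookup = sum(r$count[in_range & is.na(idx)]),
    out_of_range = sum(r$count[!in_range]),
    bad_bases = reads$bad_bases)
  structure(list(dataset_id = reads$dataset_id, counts = counts,
                 region_totals = region_totals, tallies = tallies,
                 total_reads = reads$total_reads,
                 metadata = reads$metadata),
            class = "trf_profile")
}

#' @export
print.trf_profile <- function(x, ...) {
  cat(sprintf(
    "trf_profile '%s': %d fragments, %.0f counted / %.0f reads (5p %.0f, i %.0f, 3p %.0f)\n",
    x$dataset_id, nrow(x$counts), x$tallies$counted, x$total_reads,
    x$region_totals[["5p"]], x$region_totals[["i"]],
    x$region_totals[["3p"]]))
  invisible(x)
}

#' Write a profile as TSV (+ JSON sidecar of discard tallies)
#'
#' @param profile a `trf_profile`.
#' @param path output TSV path; tallies go to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  write.table(profile$counts[, c("label", "count")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  side <- c(list(dataset_id = profile$dataset_id,
                 total_reads = profile$total_reads),
            profile$tallies)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
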