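# Independent brute-force oracles built on base string operations only.
# They never touch the Biostrings-based scanning path they are used to
# check.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# all exact occurrences of seq (both strands) in a named character genome
oracle_occurrences <- function(seq, chroms) {
  out <- list()
  for (ch in names(chroms)) {
    for (str in c("+", "-")) {
      pat <- if (str == "+") seq else oracle_revcomp(seq)
      hits <- gregexpr(pat, chroms[[ch]], fixed = TRUE)[[1]]
      if (hits[1] != -1) {
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, strand = str, start = as.integer(hits),
          end = as.integer(hits) + nchar(pat) - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0)))
  do.call(rbind, out)
}

# strand-aware tRNA-space intervals (locus body + 3 downstream positions)
# from annotation + lookalike tables, by plain arithmetic
oracle_intervals <- function(annotation, lookalikes = NULL) {
  iv <- data.frame(chrom = as.character(annotation$chrom),
                   start = ifelse(annotation$strand == "+",
                                  annotation$start, annotation$start - 3L),
                   end = ifelse(annotation$strand == "+",
                                annotation$end + 3L, annotation$end),
                   stringsAsFactors = FALSE)
  if (!is.null(lookalikes) && nrow(lookalikes) > 0) {
    iv2 <- data.frame(chrom = as.character(lookalikes$chrom),
                      start = ifelse(lookalikes$strand == "+",
                                     lookalikes$start,
                                     lookalikes$start - 3L),
                      end = ifelse(lookalikes$strand == "+",
                                   lookalikes$end + 3L, lookalikes$end),
                      stringsAsFactors = FALSE)
    iv <- rbind(iv, iv2)
  }
  iv$start <- pmax(1L, iv$start)
  iv
}

oracle_within_space <- function(occ, iv) {
  if (nrow(occ) == 0) return(logical(0))
  vapply(seq_len(nrow(occ)), function(i) {
    sel <- iv$chrom == occ$chrom[i]
    any(iv$start[sel] <= occ$start[i] & occ$end[i] <= iv$end[sel])
  }, logical(1))
}

# brute-force exclusivity decision for a set of sequences against a CCA
# genome given as a named character vector
oracle_exclusive <- function(seqs, cca_chroms, iv, junction_seqs) {
  vapply(seqs, function(s) {
    occ <- oracle_occurrences(s, cca_chroms)
    if (nrow(occ) == 0) return(s %in% junction_seqs)
    all(oracle_within_space(occ, iv))
  }, logical(1), USE.NAMES = TRUE)
}

# direct Pearson correlation from the definition
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

genome_as_char <- function(genome) {
  setNames(as.character(genome), names(genome))
}
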