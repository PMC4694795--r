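# Candidate fragment enumeration, whole-genome exclusivity analysis,
# provenance resolution and the augmented label grammar.

#' Enumerate candidate fragment windows of a mature tRNA
#'
#' Every substring of the mature sequence (including the CCA tail) with
#' length in `[min_len, max_len]` is a candidate fragment. Coordinates
#' are mature coordinates, 1-based, `+1` = first templated nucleotide;
#' the CCA occupies positions `L+1..L+3`. Windows crossing exon-exon
#' junctions are included (the mature sequence is contiguous).
#'
#' @param mature a `mature_trna` from [splice_mature()].
#' @param min_len,max_len inclusive fragment length bounds (nt).
#' @return data.frame with columns `seq`, `frag_start`, `frag_end`.
#' @examples
#' m <- structure(list(seq = paste0(strrep("A", 16), "CCA"), L = 16,
#'                     junctions = integer(0)), class = "mature_trna")
#' nrow(enumerate_windows(m))  # 4+3+2+1 windows of a 19 nt mature
#' @export
enumerate_windows <- function(mature, min_len = 16, max_len = 50) {
  stopifnot(min_len <= max_len, min_len >= 1)
  n <- nchar(mature$seq)
  if (n == 0) stop("empty mature sequence")
  lens <- seq(min_len, min(max_len, n))
  if (length(lens) == 0 || min_len > n)
    return(data.frame(seq = character(0), frag_start = integer(0),
                      frag_end = integer(0)))
  fs <- unlist(lapply(lens, function(k) seq_len(n - k + 1L)))
  fe <- unlist(lapply(lens, function(k) seq_len(n - k + 1L) + k - 1L))
  data.frame(seq = substring(mature$seq, fs, fe),
             frag_start = as.integer(fs), frag_end = as.integer(fe),
             stringsAsFactors = FALSE)
}

# windows of one mature plus the locus metadata needed downstream
all_windows <- function(mature, min_len = 16, max_len = 50) {
  w <- enumerate_windows(mature, min_len, max_len)
  if (nrow(w) == 0) return(NULL)
  jn <- mature$junctions
  crosses <- if (length(jn) == 0) rep(FALSE, nrow(w)) else
    vapply(seq_len(nrow(w)), function(i)
      any(jn >= w$frag_start[i] & jn < w$frag_end[i]), logical(1))
  data.frame(w,
             region = classify_region(w$frag_start, w$frag_end, mature$L),
             junction = crosses,
             locus_id = mature$id, anticodon = mature$anticodon_name,
             chrom = mature$chrom, strand = mature$strand,
             locus_start = mature$start, locus_end = mature$end,
             origin = mature$origin, is_pseudo = mature$is_pseudo,
             L = mature$L, stringsAsFactors = FALSE)
}

#' Find all exact genomic occurrences of a sequence
#'
#' Scans every chromosome of the (CCA-substituted) genome for exact
#' occurrences of `seq` and of its reverse complement — no mismatches,
#' no indels. Minus-strand occurrences are reported with forward-strand
#' coordinates.
#'
#' @param seq a nucleotide string over `A`, `C`, `G`, `T`.
#' @param genome a [Biostrings::DNAStringSet] (typically from
#'   [build_cca_genome()]).
#' @param cap occurrence cap mirroring the multi-mapping limit; if the
#'   number of occurrences exceeds `cap`, the result carries attribute
#'   `saturated = TRUE` and must be excluded downstream.
#' @return data.frame with columns `chrom`, `strand`, `start`, `end`
#'   (1-based inclusive) and attribute `saturated`.
#' @export
genome_occurrences <- function(seq, genome, cap = 10000) {
  genome <- as_genome(genome)
  if (grepl("[^ACGT]", seq))
    stop("ambiguous base in sequence: only A/C/G/T are allowed")
  pat_fwd <- Biostrings::DNAString(seq)
  pat_rev <- Biostrings::reverseComplement(pat_fwd)
  out <- list()
  total <- 0L
  for (ch in names(genome)) {
    for (str in c("+", "-")) {
      m <- Biostrings::matchPattern(
        if (str == "+") pat_fwd else pat_rev, genome[[ch]])
      if (length(m) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, strand = str,
          start = Biostrings::start(m), end = Biostrings::end(m),
          stringsAsFactors = FALSE)
        total <- total + length(m)
      }
    }
  }
  res <- if (length(out) == 0)
    data.frame(chrom = character(0), strand = character(0),
               start = integer(0), end = integer(0))
  else do.call(rbind, out)
  res <- res[order(chrom_order_key(res$chrom), res$start, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  attr(res, "saturated") <- total > cap
  res
}

#' Decide tRNA-space exclusivity of a fragment sequence
#'
#' A sequence is exclusive to tRNA space when every exact genomic
#' occurrence (either strand) lies fully within a tRNA-space interval. A
#' sequence with zero genomic occurrences is exclusive only when it spans
#' an exon-exon junction of a spliced mature tRNA (`junction_hit`); such
#' sequences exist in the mature transcript but nowhere in the genome.
#'
#' @param placements occurrence table from [genome_occurrences()] run on
#'   the CCA-substituted genome.
#' @param space a `trna_space`.
#' @param junction_hit does the sequence occur across an exon-exon
#'   junction of some mature tRNA?
#' @return logical scalar.
#' @export
assess_exclusivity <- function(placements, space, junction_hit = FALSE) {
  if (isTRUE(attr(placements, "saturated"))) return(FALSE)
  if (nrow(placements) == 0) return(isTRUE(junction_hit))
  gr <- GenomicRanges::GRanges(placements$chrom,
                               IRanges::IRanges(placements$start,
                                                placements$end))
  all(GenomicRanges::countOverlaps(gr, space$intervals,
                                   type = "within",
                                   ignore.strand = TRUE) > 0)
}

#' Resolve the tRNA provenance of an exclusive fragment sequence
#'
#' Locates every occurrence of `seq` in the mature tRNA sequences,
#' counts distinct anticodons, pseudo-tRNA loci and total source loci,
#' and deterministically selects the single source-proxy placement:
#' placements are ordered by natural chromosome order (autosomes, X, Y,
#' then the mitochondrial chromosome), locus start, strand, locus id and
#' fragment start, and the first is the proxy.
#'
#' @param seq fragment sequence.
#' @param matures list of `mature_trna` objects (see [splice_all()]).
#' @return list with `placements` (data.frame `locus_id`, `frag_start`,
#'   `frag_end`, `region`), `n_anticodons`, `n_pseudo`, `n_loci`, and
#'   `proxy` (single-row data.frame).
#' @export
resolve_provenance <- function(seq, matures) {
  pl <- lapply(matures, function(m) {
    hits <- gregexpr(seq, m$seq, fixed = TRUE)[[1]]
    if (hits[1] == -1) return(NULL)
    fs <- as.integer(hits)
    data.frame(locus_id = m$id, frag_start = fs,
               frag_end = fs + nchar(seq) - 1L,
               region = classify_region(fs, fs + nchar(seq) - 1L, m$L),
               anticodon = m$anticodon_name, chrom = m$chrom,
               strand = m$strand, locus_start = m$start,
               locus_end = m$end, origin = m$origin,
               is_pseudo = m$is_pseudo, L = m$L,
               stringsAsFactors = FALSE)
  })
  pl <- do.call(rbind, pl)
  if (is.null(pl) || nrow(pl) == 0)
    stop("sequence not found in any mature tRNA (inconsistent index)")
  ord <- order(chrom_order_key(pl$chrom), pl$locus_start, pl$strand,
               pl$locus_id, pl$frag_start)
  pl <- pl[ord, , drop = FALSE]
  rownames(pl) <- NULL
  list(placements = pl[, c("locus_id", "frag_start", "frag_end", "region")],
       n_anticodons = length(unique(pl$anticodon)),
       n_pseudo = length(unique(pl$locus_id[pl$is_pseudo])),
       n_loci = length(unique(pl$locus_id)),
       proxy = pl[1, , drop = FALSE])
}

#' Format an augmented fragment label
#'
#' The grammar is
#' `{id}_{anticodon}_{chrom}_{strand}_{start}_{end}@{fs}.{fe}.{len}[.CCA]__{nA}_{nP}_{nL}`:
#' the source-proxy locus and its genomic interval, the fragment's mature
#' coordinates and length, a `CCA` infix when the fragment's 3' end falls
#' within the non-templated CCA, and the number of distinct anticodons,
#' pseudo-tRNA loci and total tRNA-space loci that can source the
#' fragment.
#'
#' @param id,anticodon,chrom,strand,start,end source-proxy locus fields.
#' @param frag_start,frag_end fragment mature coordinates (1-based
#'   inclusive).
#' @param cca does the fragment's 3' end fall within the CCA tail?
#' @param n_anticodons,n_pseudo,n_loci provenance counts.
#' @return character label(s); all arguments recycle.
#' @examples
#' make_label("trna116", "GluCTC", "1", "-", 145399233, 145399304,
#'            23, 45, FALSE, 1, 0, 8)
#' @export
make_label <- function(id, anticodon, chrom, strand, start, end,
                       frag_start, frag_end, cca,
                       n_anticodons, n_pseudo, n_loci) {
  sprintf("%s_%s_%s_%s_%d_%d@%d.%d.%d%s__%d_%d_%d",
          id, anticodon, sub("^chr", "", as.character(chrom)), strand,
          as.integer(start), as.integer(end),
          as.integer(frag_start), as.integer(frag_end),
          as.integer(frag_end) - as.integer(frag_start) + 1L,
          ifelse(cca, ".CCA", ""),
          as.integer(n_anticodons), as.integer(n_pseudo),
          as.integer(n_loci))
}

label_regex <- paste0(
  "^([^_]+)_([^_]+)_([^_]+)_([+-])_([0-9]+)_([0-9]+)",
  "@([0-9]+)\\.([0-9]+)\\.([0-9]+)(\\.CCA)?",
  "__([0-9]+)_([0-9]+)_([0-9]+)$")

#' Parse an augmented fragment label
#'
#' Total inverse of [make_label()] on valid labels; validates that the
#' encoded length equals `frag_end - frag_start + 1`.
#'
#' @param s character vector of labels.
#' @return data.frame with columns `id`, `anticodon_name`, `chrom`,
#'   `strand`, `start`, `end`, `frag_start`, `frag_end`, `length`,
#'   `cca`, `n_anticodons`, `n_pseudo`, `n_loci`.
#' @export
parse_label <- function(s) {
  m <- regmatches(s, regexec(label_regex, s))
  bad <- vapply(m, length, 1L) == 0
  if (any(bad)) {
    b <- s[bad][1]
    at <- regexpr("@", b, fixed = TRUE)
    stop(sprintf("malformed fragment label '%s' (near position %d)",
                 b, max(1L, as.integer(at))))
  }
  f <- do.call(rbind, m)
  out <- data.frame(
    id = f[, 2], anticodon_name = f[, 3], chrom = f[, 4], strand = f[, 5],
    start = as.integer(f[, 6]), end = as.integer(f[, 7]),
    frag_start = as.integer(f[, 8]), frag_end = as.integer(f[, 9]),
    length = as.integer(f[, 10]), cca = f[, 11] == ".CCA",
    n_anticodons = as.integer(f[, 12]), n_pseudo = as.integer(f[, 13]),
    n_loci = as.integer(f[, 14]), stringsAsFactors = FALSE)
  incons <- out$length != out$frag_end - out$frag_start + 1L
  if (any(incons))
    stop("label length field inconsistent with fragment coordinates: ",
         s[incons][1])
  out
}

# batch occurrence scan over the CCA genome using Aho-Corasick dictionaries
# (one constant-width PDict per fragment length, both strands).
scan_occurrences <- function(seqs, genome, space, cap = 10000) {
  n_occ <- numeric(length(seqs))
  all_within <- rep(TRUE, length(seqs))
  widths <- nchar(seqs)
  sp_chrom <- as.character(GenomicRanges::seqnames(space$intervals))
  sp_ir <- split(IRanges::ranges(space$intervals), sp_chrom)
  for (w in sort(unique(widths))) {
    idx <- which(widths == w)
    dset <- Biostrings::DNAStringSet(seqs[idx])
    dicts <- list(Biostrings::PDict(dset),
                  Biostrings::PDict(Biostrings::reverseComplement(dset)))
    for (ch in names(genome)) {
      subject <- genome[[ch]]
      if (length(subject) < w) next
      ivs <- if (ch %in% names(sp_ir)) sp_ir[[ch]] else
        IRanges::IRanges()
      for (d in dicts) {
        m <- Biostrings::matchPDict(d, subject)
        cnt <- S4Vectors::elementNROWS(m)
        hit <- which(cnt > 0)
        if (length(hit) == 0) next
        n_occ[idx[hit]] <- n_occ[idx[hit]] + cnt[hit]
        ir <- unlist(m, use.names = FALSE)
        within <- IRanges::countOverlaps(ir, ivs, type = "within") > 0
        grp <- rep.int(seq_along(cnt), cnt)
        ok <- as.logical(tapply(within, factor(grp, levels = hit), all))
        all_within[idx[hit]] <- all_within[idx[hit]] & ok
      }
    }
  }
  data.frame(seq = seqs, n_occ = n_occ,
             all_within = all_within & n_occ > 0,
             stringsAsFactors = FALSE)
}

#' Build the exclusive-fragment lookup table
#'
#' Enumerates all candidate windows over every mature tRNA, merges
#' identical sequences, decides tRNA-space exclusivity by exact
#' whole-genome occurrence analysis on the CCA-substituted genome, and
#' resolves provenance and labels for the exclusive records. Sequences
#' with more genomic occurrences than `cap` are dropped as saturated
#' (reported in attribute `saturated`); windows spanning an exon-exon
#' junction that never occur in the genome are exclusive by construction.
#'
#' @param space a `trna_space`.
#' @param matures list of `mature_trna` objects from [splice_all()].
#' @param cca_genome the CCA-substituted genome from [build_cca_genome()].
#' @param min_len,max_len fragment length window (nt).
#' @param cap multi-mapping occurrence cap.
#' @return data.frame (class `trf_lookup`), one row per distinct
#'   exclusive fragment sequence, sorted by sequence: columns `seq`,
#'   `label`, `region`, `length`, `frag_start`, `n_anticodons`,
#'   `n_pseudo`, `n_loci`, `anticodon`, `origin`, `cca`, `full_span`
#'   (fragment both starts at +1 and ends in the CCA — only possible
#'   when the window length bound exceeds L), `junction_spanning`,
#'   `region_ambiguous`, `placements`
#'   (semicolon-separated `locus:fs-fe` list). Attributes: `saturated`
#'   (dropped sequences), `params`.
#' @export
build_lookup <- function(space, matures, cca_genome,
                         min_len = 16, max_len = 50, cap = 10000) {
  win <- do.call(rbind, lapply(matures, all_windows,
                               min_len = min_len, max_len = max_len))
  if (is.null(win) || nrow(win) == 0)
    stop("no candidate windows: empty reference?")
  rownames(win) <- NULL
  useq <- sort(unique(win$seq))
  occ <- scan_occurrences(useq, cca_genome, space, cap)
  junction_seq <- unique(win$seq[win$junction])
  saturated <- occ$seq[occ$n_occ > cap]
  exclusive <- (occ$all_within |
                  (occ$n_occ == 0 & occ$seq %in% junction_seq)) &
    !(occ$seq %in% saturated)
  keep <- occ$seq[exclusive]

  w <- win[win$seq %in% keep, , drop = FALSE]
  ord <- order(w$seq, chrom_order_key(w$chrom), w$locus_start, w$strand,
               w$locus_id, w$frag_start)
  w <- w[ord, , drop = FALSE]
  first <- !duplicated(w$seq)
  proxy <- w[first, , drop = FALSE]

  # provenance counts over distinct (seq, locus) pairs
  pair_key <- !duplicated(paste(w$seq, w$locus_id, sep = "\r"))
  pairs <- w[pair_key, c("seq", "locus_id", "anticodon", "is_pseudo")]
  n_loci <- table(pairs$seq)
  anti_key <- !duplicated(paste(pairs$seq, pairs$anticodon, sep = "\r"))
  n_anti <- table(pairs$seq[anti_key])
  n_pseudo <- table(factor(pairs$seq[pairs$is_pseudo],
                           levels = names(n_loci)))
  reg_key <- !duplicated(paste(w$seq, w$region, sep = "\r"))
  n_regions <- table(w$seq[reg_key])
  junc_any <- tapply(w$junction, w$seq, any)

  sq <- proxy$seq  # sorted unique, aligned with the tables by name
  stopifnot(identical(sq, names(n_loci)[match(sq, names(n_loci))]))
  placements <- vapply(
    split(sprintf("%s:%d-%d", w$locus_id, w$frag_start, w$frag_end),
          factor(w$seq, levels = sq)),
    paste, character(1), collapse = ";")

  cca <- proxy$frag_end > proxy$L
  out <- data.frame(
    seq = sq,
    label = make_label(proxy$locus_id, proxy$anticodon, proxy$chrom,
                       proxy$strand, proxy$locus_start, proxy$locus_end,
                       proxy$frag_start, proxy$frag_end, cca,
                       as.integer(n_anti[sq]),
                       as.integer(n_pseudo[sq]),
                       as.integer(n_loci[sq])),
    region = proxy$region,
    length = nchar(sq),
    frag_start = proxy$frag_start,
    n_anticodons = as.integer(n_anti[sq]),
    n_pseudo = as.integer(n_pseudo[sq]),
    n_loci = as.integer(n_loci[sq]),
    anticodon = proxy$anticodon,
    origin = proxy$origin,
    cca = cca,
    full_span = proxy$frag_start == 1L & cca,
    junction_spanning = as.logical(junc_any[sq]),
    region_ambiguous = as.integer(n_regions[sq]) > 1,
    placements = unname(placements[sq]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "saturated") <- saturated
  attr(out, "params") <- list(min_len = min_len, max_len = max_len,
                              cap = cap)
  class(out) <- c("trf_lookup", "data.frame")
  if (length(saturated) > 0)
    message(length(saturated),
            " sequence(s) exceeded the occurrence cap and were dropped")
  out
}

#' Write / read a fragment lookup table as TSV
#'
#' @param lookup a `trf_lookup` from [build_lookup()].
#' @param path output file path.
#' @return `write_lookup` returns `path` invisibly; `read_lookup`
#'   returns the `trf_lookup` data.frame.
#' @export
write_lookup <- function(lookup, path) {
  p <- attr(lookup, "params")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(p))
    writeLines(sprintf("# trfspace lookup min_len=%d max_len=%d cap=%d",
                       p$min_len, p$max_len, p$cap), con)
  write.table(lookup, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lookup
#' @export
read_lookup <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  class(out) <- c("trf_lookup", "data.frame")
  out
}
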