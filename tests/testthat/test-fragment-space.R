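# Window enumeration, exact occurrence analysis, exclusivity,
# provenance and the augmented label grammar.

test_that("window counts follow the closed form", {
  withr::local_seed(3)
  mk <- function(L) structure(
    list(seq = paste0(fixture_random_seq(L), "CCA"), L = L,
         junctions = integer(0)), class = "mature_trna")
  # L = 72: total length 75, sum_{k=16..50} (76 - k) = 1505
  expect_equal(nrow(enumerate_windows(mk(72))), 1505)
  # mature of 19 nt total: 4 + 3 + 2 + 1 = 10
  expect_equal(nrow(enumerate_windows(mk(16))), 10)
  m <- mk(40)
  w <- enumerate_windows(m, min_len = 43, max_len = 43)
  expect_equal(nrow(w), 1)
  expect_equal(w$seq, m$seq)
  # coordinates always consistent with the length
  w2 <- enumerate_windows(m)
  expect_true(all(nchar(w2$seq) == w2$frag_end - w2$frag_start + 1))
  expect_true(all(substring(m$seq, w2$frag_start, w2$frag_end) == w2$seq))
})

test_that("genome occurrences find planted copies on both strands", {
  withr::local_seed(5)
  frag <- fixture_random_seq(24)
  chr1 <- fixture_random_seq(500)
  substr(chr1, 101, 124) <- oracle_revcomp(frag)  # one minus-strand copy
  occ <- genome_occurrences(frag, c("1" = chr1))
  expect_equal(nrow(occ), 1)
  expect_equal(occ$strand, "-")
  expect_equal(occ$start, 101)
  expect_equal(occ$end, 124)

  # a 72 nt sequence planted identically at 11 loci across chromosomes
  seq72 <- fixture_random_seq(72)
  chroms <- list("1" = fixture_random_seq(1000),
                 "6" = fixture_random_seq(800),
                 "12" = fixture_random_seq(800),
                 "17" = fixture_random_seq(600))
  plan <- rbind(data.frame(ch = "1", at = c(10, 120, 230, 340, 450)),
                data.frame(ch = "6", at = c(50, 200)),
                data.frame(ch = "12", at = c(80, 190, 300)),
                data.frame(ch = "17", at = 100))
  for (i in seq_len(nrow(plan)))
    substr(chroms[[plan$ch[i]]], plan$at[i], plan$at[i] + 71) <- seq72
  occ11 <- genome_occurrences(seq72, unlist(chroms))
  expect_equal(nrow(occ11), 11)
  expect_equal(as.vector(table(occ11$chrom)[c("1", "6", "12", "17")]),
               c(5, 2, 3, 1))

  # absent sequence and ambiguous bases
  expect_equal(nrow(genome_occurrences(fixture_random_seq(30),
                                       c("1" = chr1))), 0)
  expect_error(genome_occurrences("ACGTN", c("1" = chr1)), "ambiguous")
})

test_that("occurrence cap marks saturated sequences", {
  chr <- paste(rep("ACGTACGTACGTACGTACGT", 60), collapse = "")
  occ <- genome_occurrences(substr(chr, 1, 16), c("1" = chr), cap = 5)
  expect_true(attr(occ, "saturated"))
  space <- load_annotation(data.frame(
    id = "t", anticodon_name = "GlyGCC", chrom = "1", strand = "+",
    start = 1, end = 80, introns = "", origin = "nuclear",
    is_pseudo = FALSE))
  expect_false(assess_exclusivity(occ, space))
})

test_that("exclusivity admits in-space multi-mappers and rejects decoy hits", {
  withr::local_seed(9)
  gene <- fixture_random_seq(72)
  chr <- fixture_random_seq(1200)
  at <- c(101, 301, 501, 701, 901)       # five identical tRNA copies
  for (a in at) substr(chr, a, a + 71) <- gene
  ann <- data.frame(id = sprintf("t%d", 1:5), anticodon_name = "AlaAGC",
                    chrom = "1", strand = "+", start = at,
                    end = at + 71, introns = "", origin = "nuclear",
                    is_pseudo = FALSE)
  space <- load_annotation(ann)
  frag <- substr(gene, 1, 32)
  occ <- genome_occurrences(frag, c("1" = chr))
  expect_equal(nrow(occ), 5)
  expect_true(assess_exclusivity(occ, space))

  # plant a partial-tRNA decoy outside tRNA space: now non-exclusive
  substr(chr, 1150, 1181) <- frag
  occ2 <- genome_occurrences(frag, c("1" = chr))
  expect_equal(nrow(occ2), 6)
  expect_false(assess_exclusivity(occ2, space))

  # junction-spanning sequence with zero genomic occurrences
  none <- genome_occurrences(fixture_random_seq(19), c("1" = chr))
  expect_equal(nrow(none), 0)
  expect_true(assess_exclusivity(none, space, junction_hit = TRUE))
  expect_false(assess_exclusivity(none, space, junction_hit = FALSE))
})

test_that("provenance counts distinct anticodons, pseudo loci and loci", {
  withr::local_seed(13)
  shared <- fixture_random_seq(22)
  mk <- function(id, anti, prefix_len, pseudo = FALSE, chrom = "1",
                 start = 100) {
    L <- prefix_len + 22 + 20
    seqs <- paste0(fixture_random_seq(prefix_len), shared,
                   fixture_random_seq(20), "CCA")
    structure(list(id = id, anticodon_name = anti, chrom = chrom,
                   strand = "+", start = start, end = start + L - 1,
                   origin = "nuclear", is_pseudo = pseudo, seq = seqs,
                   L = L, junctions = integer(0)),
              class = "mature_trna")
  }
  matures <- list(mk("t1", "AlaAGC", 10, start = 100),
                  mk("t2", "AlaCGC", 12, start = 300, chrom = "2"),
                  mk("t3", "AlaAGC", 14, pseudo = TRUE, start = 500),
                  mk("t4", "CysGCA", 16, start = 700))
  pr <- resolve_provenance(shared, matures)
  expect_equal(pr$n_loci, 4)
  expect_equal(pr$n_anticodons, 3)
  expect_equal(pr$n_pseudo, 1)
  # proxy: chromosome 1 before 2, then locus start
  expect_equal(pr$proxy$locus_id, "t1")
  expect_equal(pr$proxy$frag_start, 11)
  expect_error(resolve_provenance("GATTACAGATTACAGG", matures),
               "not found")
})

test_that("labels follow the augmented grammar and round-trip", {
  lab <- make_label("trna116", "GluCTC", "1", "-", 145399233, 145399304,
                    23, 45, FALSE, 1, 0, 8)
  expect_equal(lab, "trna116_GluCTC_1_-_145399233_145399304@23.45.23__1_0_8")
  lab2 <- make_label("trna75", "MetCAT", "6", "+", 28912352, 28912424,
                     57, 76, TRUE, 1, 0, 2)
  expect_equal(lab2, "trna75_MetCAT_6_+_28912352_28912424@57.76.20.CCA__1_0_2")
  p <- parse_label(lab)
  expect_equal(p$frag_start, 23)
  expect_equal(p$frag_end, 45)
  expect_equal(p$length, 23)
  expect_false(p$cca)
  expect_equal(p$n_loci, 8)

  # property: parse . make = identity over random valid records
  withr::local_seed(17)
  for (i in 1:50) {
    fs <- sample(1:60, 1)
    len <- sample(16:50, 1)
    x <- list(id = sprintf("trna%d", sample(1:999, 1)),
              anticodon = sample(c("GluCTC", "LysTTT", "SerGCT"), 1),
              chrom = sample(c("1", "12", "X", "MT"), 1),
              strand = sample(c("+", "-"), 1),
              start = sample(1:2e8, 1), end = sample(1:2e8, 1),
              fs = fs, fe = fs + len - 1,
              cca = sample(c(TRUE, FALSE), 1),
              nA = sample(1:5, 1), nP = sample(0:3, 1),
              nL = sample(1:20, 1))
    lab <- make_label(x$id, x$anticodon, x$chrom, x$strand, x$start,
                      x$end, x$fs, x$fe, x$cca, x$nA, x$nP, x$nL)
    p <- parse_label(lab)
    expect_equal(p$id, x$id)
    expect_equal(p$frag_start, x$fs)
    expect_equal(p$frag_end, x$fe)
    expect_equal(p$length, len)
    expect_equal(p$cca, x$cca)
    expect_equal(c(p$n_anticodons, p$n_pseudo, p$n_loci),
                 c(x$nA, x$nP, x$nL))
    expect_equal(make_label(p$id, p$anticodon_name, p$chrom, p$strand,
                            p$start, p$end, p$frag_start, p$frag_end,
                            p$cca, p$n_anticodons, p$n_pseudo, p$n_loci),
                 lab)
  }
  expect_error(parse_label("not_a_label"), "malformed")
  expect_error(parse_label("t_A_1_+_1_2@5.10.99__1_0_1"), "inconsistent")
})

test_that("a reference alone in its genome yields all windows exclusive", {
  withr::local_seed(21)
  gene <- fixture_random_seq(72)
  chr <- paste0(fixture_random_seq(40), gene, fixture_random_seq(40))
  ann <- data.frame(id = "t1", anticodon_name = "AspGTC", chrom = "1",
                    strand = "+", start = 41, end = 112, introns = "",
                    origin = "nuclear", is_pseudo = FALSE)
  space <- load_annotation(ann)
  matures <- splice_all(space, c("1" = chr))
  cca <- build_cca_genome(c("1" = chr), space)
  lk <- build_lookup(space, matures, cca)
  expect_equal(nrow(lk), 1505)  # every window of the single mature
  expect_true(all(lk$n_loci == 1))

  # an identical second copy inside tRNA space: still exclusive, n_loci=2
  chr2 <- paste0(chr, fixture_random_seq(30), gene, fixture_random_seq(40))
  ann2 <- rbind(ann, data.frame(
    id = "t2", anticodon_name = "AspGTC", chrom = "1", strand = "+",
    start = 183, end = 254, introns = "", origin = "nuclear",
    is_pseudo = FALSE))
  space2 <- load_annotation(ann2)
  matures2 <- splice_all(space2, c("1" = chr2))
  cca2 <- build_cca_genome(c("1" = chr2), space2)
  lk2 <- build_lookup(space2, matures2, cca2)
  expect_equal(nrow(lk2), 1505)
  expect_true(all(lk2$n_loci == 2))
  expect_true(all(lk2$n_anticodons == 1))
})

test_that("lookup matches the brute-force exclusivity oracle", {
  for (seed in c(31, 32)) {
    sim <- simulate_genome(small_sim_config(), seed = seed)
    ref <- sim_reference(sim)
    cca_chr <- genome_as_char(ref$cca_genome)
    iv <- oracle_intervals(sim$annotation, sim$lookalikes)
    win <- do.call(rbind, lapply(ref$matures, function(m) {
      w <- enumerate_windows(m)
      jn <- m$junctions
      j <- if (length(jn) == 0) rep(FALSE, nrow(w)) else
        vapply(seq_len(nrow(w)), function(i)
          any(jn >= w$frag_start[i] & jn < w$frag_end[i]), logical(1))
      data.frame(seq = w$seq, junction = j, stringsAsFactors = FALSE)
    }))
    junction_seqs <- unique(win$seq[win$junction])
    useq <- unique(win$seq)
    oracle <- oracle_exclusive(useq, cca_chr, iv, junction_seqs)
    expect_setequal(ref$lookup$seq, useq[oracle])
  }
})

test_that("adding a decoy only removes records (monotonicity)", {
  sim <- simulate_genome(small_sim_config(n_decoy_partial = 0,
                                          n_decoy_mismatch = 0),
                         seed = 41)
  ref <- sim_reference(sim)
  # copy the 5' 24-mer of one mature into empty background
  m1 <- ref$matures[[which(vapply(ref$matures, function(m)
    length(m$junctions) == 0 && m$origin == "nuclear", logical(1)))[1]]]
  decoy <- substr(m1$seq, 1, 24)
  chroms <- genome_as_char(sim$genome)
  substr(chroms[["2"]], 3900, 3923) <- decoy
  sim2 <- sim
  sim2$genome <- Biostrings::DNAStringSet(chroms)
  ref2 <- sim_reference(sim2)
  expect_true(all(ref2$lookup$seq %in% ref$lookup$seq))
  removed <- setdiff(ref$lookup$seq, ref2$lookup$seq)
  expect_true(length(removed) > 0)
  # exactly the windows contained in the decoy copy disappear
  expect_true(all(vapply(removed, function(s)
    grepl(s, decoy, fixed = TRUE), logical(1))))
  in_decoy <- ref$lookup$seq[vapply(ref$lookup$seq, function(s)
    grepl(s, decoy, fixed = TRUE), logical(1))]
  expect_setequal(removed, in_decoy)
})

test_that("junction-spanning fragments survive in the lookup", {
  sim <- simulate_genome(small_sim_config(), seed = 51)
  ref <- sim_reference(sim)
  jm <- ref$matures[[which(vapply(ref$matures, function(m)
    length(m$junctions) > 0, logical(1)))[1]]]
  jn <- jm$junctions[1]
  span <- substr(jm$seq, jn - 9, jn + 10)  # 20-mer straddling the junction
  expect_equal(nrow(genome_occurrences(span, ref$cca_genome)), 0)
  row <- ref$lookup[ref$lookup$seq == span, ]
  expect_equal(nrow(row), 1)
  expect_true(row$junction_spanning)
})

test_that("lookup tables are deterministic and round-trip through TSV", {
  sim <- simulate_genome(small_sim_config(), seed = 61)
  ref_a <- sim_reference(sim)
  ref_b <- sim_reference(sim)
  expect_identical(ref_a$lookup, ref_b$lookup)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lookup(ref_a$lookup, path)
  back <- read_lookup(path)
  expect_equal(back$seq, ref_a$lookup$seq)
  expect_equal(back$label, ref_a$lookup$label)
  expect_equal(back$n_loci, ref_a$lookup$n_loci)
})
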